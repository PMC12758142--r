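#' @include AllGenerics.R
NULL

#' Model parameters for the T3-feedback (signaling) model
#'
#' Container for all rate constants and condition flags of the signaling
#' model. Rates are per cell per day; T3 and the Hill constants `K_S`, `K_L`
#' are in arbitrary concentration units (only ratios to the T3 scale matter);
#' times are organoid ages in days.
#'
#' Slots (constructor arguments use the same names):
#' \describe{
#'   \item{lambda_S_max}{maximal per-cell S-cone specification rate (1/day).}
#'   \item{K_S}{T3 half-saturation of the S program (concentration units).}
#'   \item{lambda_L_max}{maximal per-cell L/M-cone specification rate (1/day).}
#'   \item{K_L}{T3 half-saturation of the L/M program; `K_L > K_S` orders
#'     S-cone before L/M-cone generation as T3 rises.}
#'   \item{lambda_N}{constant per-cell non-cone differentiation rate (1/day).}
#'   \item{mu_S, mu_L}{constant maturation rates of immature S / L/M cones.}
#'   \item{sigma_basal}{constant basal T3 source (concentration/day).}
#'   \item{sigma_exo}{additional exogenous T3 source switched on at `t_exo`
#'     (concentration/day); 0 in unsupplemented cultures.}
#'   \item{t_exo}{day the exogenous source starts.}
#'   \item{delta}{per-cell first-order T3 degradation constant of a
#'     DIO3-expressing cell (1/(cell day)).}
#'   \item{mutant_degradation_fraction}{scaling of `delta`; 1 for wild type,
#'     0.06 for the DIO3-mutant condition (6\% residual deiodination).}
#'   \item{dio3_in_immature_cones}{if `TRUE`, immature cones also degrade T3
#'     (model variant in which DIO3 expression persists in immature cones).}
#'   \item{t_max}{simulation horizon guard (day).}
#' }
#'
#' The numeric defaults are the package's reference parameter set, calibrated
#' so that the wild-type condition generates S cones before L/M cones with a
#' small coexpressing population, and the mutant/exogenous-T3 presets
#' reproduce the accelerated, L/M-shifted phenotypes (see the package
#' vignette for the calibration rationale).
#'
#' @param ... named slot values overriding the defaults.
#' @return A `ConeModelParams` object.
#' @examples
#' ConeModelParams()
#' ConeModelParams(mutant_degradation_fraction = 0.06)
#' @aliases ConeModelParams-class
#' @export ConeModelParams
#' @exportClass ConeModelParams
ConeModelParams <- setClass(
  "ConeModelParams",
  slots = c(
    lambda_S_max = "numeric", K_S = "numeric",
    lambda_L_max = "numeric", K_L = "numeric",
    lambda_N = "numeric", mu_S = "numeric", mu_L = "numeric",
    sigma_basal = "numeric", sigma_exo = "numeric", t_exo = "numeric",
    delta = "numeric", mutant_degradation_fraction = "numeric",
    dio3_in_immature_cones = "logical", t_max = "numeric"),
  prototype = list(
    lambda_S_max = 0.0105, K_S = 0.6,
    lambda_L_max = 0.0175, K_L = 1.55,
    lambda_N = 0.044, mu_S = 0.16, mu_L = 0.16,
    sigma_basal = 1, sigma_exo = 0, t_exo = 42,
    delta = 1e-3, mutant_degradation_fraction = 1,
    dio3_in_immature_cones = FALSE, t_max = 400))

setValidity("ConeModelParams", function(object) {
  msg <- character()
  num <- setdiff(slotNames(object), "dio3_in_immature_cones")
  for (s in num) {
    v <- slot(object, s)
    if (length(v) != 1L || !is.finite(v))
      msg <- c(msg, sprintf("'%s' must be a single finite number", s))
    else if (v < 0) msg <- c(msg, sprintf("'%s' must be non-negative", s))
  }
  if (length(object@dio3_in_immature_cones) != 1L ||
      is.na(object@dio3_in_immature_cones))
    msg <- c(msg, "'dio3_in_immature_cones' must be TRUE or FALSE")
  if (length(msg)) return(msg)
  if (object@K_S <= 0) msg <- c(msg, "'K_S' must be > 0")
  if (object@K_L <= 0) msg <- c(msg, "'K_L' must be > 0")
  if (object@mutant_degradation_fraction > 1)
    msg <- c(msg, "'mutant_degradation_fraction' must be <= 1")
  if (object@t_max <= 0) msg <- c(msg, "'t_max' must be > 0")
  if (length(msg)) msg else TRUE
})

#' Parameters of the cell-intrinsic comparator model
#'
#' In the cell-intrinsic model RPCs differentiate with constant,
#' T3-independent rates `lambda_S`, `lambda_L`, `lambda_N` (competing
#' exponential risks), and immature cones mature at `mu_S` / `mu_L`.
#' Maturation rates do not affect final counts; they are carried so that
#' outputs share the signaling model's schema.
#'
#' @param ... named slot values.
#' @return An `IntrinsicParams` object.
#' @examples
#' IntrinsicParams(lambda_S = 0.005, lambda_L = 0.005, lambda_N = 0.01)
#' @aliases IntrinsicParams-class
#' @export IntrinsicParams
#' @exportClass IntrinsicParams
IntrinsicParams <- setClass(
  "IntrinsicParams",
  slots = c(lambda_S = "numeric", lambda_L = "numeric", lambda_N = "numeric",
            mu_S = "numeric", mu_L = "numeric"),
  prototype = list(lambda_S = 0.005, lambda_L = 0.005, lambda_N = 0.044,
                   mu_S = 0.16, mu_L = 0.16))

setValidity("IntrinsicParams", function(object) {
  v <- vapply(slotNames(object), function(s) slot(object, s), numeric(1))
  if (any(!is.finite(v)) || any(v < 0))
    return("all rates must be single finite non-negative numbers")
  if (object@lambda_S + object@lambda_L + object@lambda_N <= 0)
    return("lambda_S + lambda_L + lambda_N must be > 0")
  TRUE
})

#' Single-organoid simulation trajectory
#'
#' Time-ordered population snapshots from one hybrid simulation. The
#' `snapshots` slot is a data.frame with a `time` column, one integer count
#' column per cell class (see [cellClasses()]) and a `T3` column. `terminal`
#' is `"complete"` when every cell reached a terminal fate before the horizon
#' and `"horizon"` otherwise.
#'
#' @aliases Trajectory-class
#' @exportClass Trajectory
setClass(
  "Trajectory",
  slots = c(snapshots = "data.frame", terminal = "character",
            seed = "numeric", condition = "character",
            params = "ConeModelParams", step = "numeric",
            initial_rpc = "numeric", t3_initial = "numeric"))

setValidity("Trajectory", function(object) {
  sn <- object@snapshots
  need <- c("time", cellClasses(), "T3")
  if (!all(need %in% names(sn)))
    return(paste("snapshots must have columns:", paste(need, collapse = ", ")))
  if (nrow(sn) < 1L) return("snapshots must have at least one row")
  if (sn$time[1L] != 0) return("first snapshot must be at time 0")
  if (is.unsorted(sn$time, strictly = TRUE))
    return("snapshot times must be strictly increasing")
  cts <- as.matrix(sn[, cellClasses()])
  if (any(cts < 0)) return("counts must be non-negative")
  tot <- rowSums(cts)
  if (any(tot != tot[1L])) return("total cell number must be conserved")
  if (any(sn$T3 < 0)) return("T3 must be non-negative")
  for (cl in .TERMINAL_CLASSES)
    if (is.unsorted(sn[[cl]])) return(sprintf("'%s' must be non-decreasing", cl))
  if (!object@terminal %in% c("complete", "horizon"))
    return("terminal must be 'complete' or 'horizon'")
  TRUE
})

#' Replicate experiment result
#'
#' Final counts from a set of replicate simulations of one model under one
#' condition. Summary statistics (mean, sd, CV of total photoreceptors) are
#' always recomputed from the stored per-replicate counts via
#' [summaryStats()], never stored.
#'
#' @aliases ExperimentResult-class
#' @exportClass ExperimentResult
setClass(
  "ExperimentResult",
  slots = c(counts = "data.frame", model = "character",
            condition = "character", seed = "numeric", params = "ANY"))

setValidity("ExperimentResult", function(object) {
  need <- c("replicate", "initial_rpc", cellClasses())
  if (!all(need %in% names(object@counts)))
    return(paste("counts must have columns:", paste(need, collapse = ", ")))
  if (!object@model %in% c("signaling", "intrinsic"))
    return("model must be 'signaling' or 'intrinsic'")
  TRUE
})

#' Parameter-space sweep result
#'
#' One record per sampled parameter set: the sampled values and the
#' coefficient of variation of final total photoreceptor count for the
#' signaling model and for the per-set recalibrated intrinsic model.
#'
#' @aliases SweepResult-class
#' @exportClass SweepResult
setClass(
  "SweepResult",
  slots = c(records = "data.frame", fold_range = "numeric",
            n_reps_per_set = "numeric", seed = "numeric"))

setValidity("SweepResult", function(object) {
  need <- c("set", "cv_signaling", "cv_intrinsic")
  if (!all(need %in% names(object@records)))
    return(paste("records must have columns:", paste(need, collapse = ", ")))
  TRUE
})

#' Synthetic opsin-density observation table
#'
#' Emulated immunohistochemistry quantification: per (day, organoid, class)
#' cell densities (cells/mm^2) derived from a simulated trajectory with
#' multiplicative organoid-level noise. Classes are `S_opsin`, `LM_opsin`,
#' `S_and_LM` (coexpressing) and `Rho_like` (a configurable fraction of the
#' non-cone pool standing in for rods, which the cone model does not track
#' explicitly).
#'
#' @aliases ObservationTable-class
#' @exportClass ObservationTable
setClass(
  "ObservationTable",
  slots = c(observations = "data.frame", scale = "numeric",
            noise_cv = "numeric", rho_fraction = "numeric", seed = "numeric"))

setValidity("ObservationTable", function(object) {
  obs <- object@observations
  need <- c("day", "organoid_id", "class", "density")
  if (!all(need %in% names(obs)))
    return(paste("observations must have columns:", paste(need, collapse = ", ")))
  if (any(obs$density < 0)) return("densities must be non-negative")
  ok <- c("S_opsin", "LM_opsin", "Rho_like", "S_and_LM")
  if (!all(obs$class %in% ok))
    return(paste("class must be one of:", paste(ok, collapse = ", ")))
  TRUE
})

## ---- show methods ----

setMethod("show", "ConeModelParams", function(object) {
  cat("ConeModelParams (signaling model)\n")
  for (s in slotNames(object))
    cat(sprintf("  %-28s %s\n", s, format(slot(object, s))))
})

setMethod("show", "IntrinsicParams", function(object) {
  cat("IntrinsicParams (cell-intrinsic model)\n")
  for (s in slotNames(object))
    cat(sprintf("  %-10s %s\n", s, format(slot(object, s))))
})

setMethod("show", "Trajectory", function(object) {
  sn <- object@snapshots
  fin <- sn[nrow(sn), ]
  cat(sprintf("Trajectory: %s, %d snapshots, t in [0, %g] d (%s)\n",
              object@condition, nrow(sn), fin$time, object@terminal))
  cat(sprintf("  initial RPC %d, seed %d, step %g d\n",
              as.integer(object@initial_rpc), as.integer(object@seed),
              object@step))
  cat("  final counts:\n")
  print(unlist(fin[cellClasses()]))
  cat(sprintf("  final T3: %.4g\n", fin$T3))
})

setMethod("show", "ExperimentResult", function(object) {
  cat(sprintf("ExperimentResult: %s model, condition '%s', %d replicates\n",
              object@model, object@condition, nrow(object@counts)))
  s <- summaryStats(object)
  cat(sprintf("  total photoreceptors: mean %.1f, sd %.1f, CV %.4f\n",
              s$mean, s$sd, s$cv))
})

setMethod("show", "SweepResult", function(object) {
  r <- object@records
  frac <- mean(r$cv_signaling < r$cv_intrinsic, na.rm = TRUE)
  cat(sprintf("SweepResult: %d parameter sets x %d replicates (fold range %g)\n",
              nrow(r), as.integer(object@n_reps_per_set), object@fold_range))
  cat(sprintf("  CV_signaling < CV_intrinsic in %.1f%% of sets\n", 100 * frac))
})

setMethod("show", "ObservationTable", function(object) {
  obs <- object@observations
  cat(sprintf("ObservationTable: days %s; %d organoids/day; noise CV %g\n",
              paste(sort(unique(obs$day)), collapse = ", "),
              length(unique(obs$organoid_id)), object@noise_cv))
})

## ---- simple accessors ----

#' Snapshot table of a trajectory
#' @param object A [Trajectory-class] object.
#' @return data.frame of time-ordered snapshots.
#' @rdname snapshots
#' @export
setMethod("snapshots", "Trajectory", function(object) object@snapshots)

#' Terminal status of a trajectory
#' @param object A [Trajectory-class] object.
#' @return `"complete"` or `"horizon"`.
#' @rdname terminalStatus
#' @export
setMethod("terminalStatus", "Trajectory", function(object) object@terminal)

#' Condition label
#' @param object A [Trajectory-class] or [ExperimentResult-class] object.
#' @return Character condition label.
#' @rdname conditionLabel
#' @export
setMethod("conditionLabel", "Trajectory", function(object) object@condition)

#' @rdname conditionLabel
#' @export
setMethod("conditionLabel", "ExperimentResult", function(object) object@condition)

#' Final population state of a trajectory
#' @param object A [Trajectory-class] object.
#' @return List with elements `counts` (named integer vector over
#'   [cellClasses()]), `T3` and `time`.
#' @rdname finalState
#' @export
setMethod("finalState", "Trajectory", function(object) {
  fin <- object@snapshots[nrow(object@snapshots), ]
  list(counts = unlist(fin[cellClasses()]), T3 = fin$T3, time = fin$time)
})

#' Model parameters of an object
#' @param object A [Trajectory-class] object.
#' @return The [ConeModelParams-class] used for the simulation.
#' @rdname modelParams
#' @export
setMethod("modelParams", "Trajectory", function(object) object@params)

#' Per-replicate final counts
#' @param object An [ExperimentResult-class] object.
#' @return data.frame with one row per replicate.
#' @rdname replicateCounts
#' @export
setMethod("replicateCounts", "ExperimentResult", function(object) object@counts)

#' Sweep records
#' @param object A [SweepResult-class] object.
#' @return data.frame with one row per sampled parameter set.
#' @rdname sweepRecords
#' @export
setMethod("sweepRecords", "SweepResult", function(object) object@records)

#' Observation rows of a synthetic density table
#' @param object An [ObservationTable-class] object.
#' @return data.frame with columns day, organoid_id, class, density.
#' @rdname observations
#' @export
setMethod("observations", "ObservationTable", function(object)
  object@observations)

#' Summary statistics of an experiment
#'
#' Mean, standard deviation and coefficient of variation of the final total
#' photoreceptor count (mature S + mature L/M + coexpressing), recomputed
#' from the per-replicate table.
#'
#' @param object An [ExperimentResult-class] object.
#' @return List with elements `mean`, `sd`, `cv`, `n`.
#' @rdname summaryStats
#' @export
setMethod("summaryStats", "ExperimentResult", function(object) {
  tot <- object@counts$MATURE_S + object@counts$MATURE_LM +
    object@counts$COEXPRESSING
  list(mean = mean(tot), sd = sd(tot),
       cv = coefficientOfVariation(tot), n = length(tot))
})
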