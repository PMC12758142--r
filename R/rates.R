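#' @include AllClasses.R
NULL

#' First-order activating Hill function
#'
#' Per-cell rate `lambda_max * T3 / (K + T3)` (Hill coefficient n = 1):
#' zero at zero ligand, half-maximal at `T3 = K`, saturating at `lambda_max`.
#' Used for both cone specification programs: the S program with
#' half-saturation `K_S` and the L/M program with `K_L > K_S`, so rising T3
#' opens the S gate before the L/M gate.
#'
#' @param t3 T3 concentration(s), non-negative (vectorised).
#' @param lambda_max Maximal per-cell rate (1/day), non-negative.
#' @param K Half-saturation constant, strictly positive.
#' @return Per-cell rate(s), in `[0, lambda_max]`.
#' @examples
#' hillActivating(5, lambda_max = 1, K = 5)   # 0.5
#' @export
hillActivating <- function(t3, lambda_max, K) {
  .checkHillArgs(t3, lambda_max, K)
  lambda_max * t3 / (K + t3)
}

#' First-order repressing Hill function
#'
#' Per-cell rate `lambda_max * K / (K + T3)`: maximal at zero ligand,
#' half-maximal at `T3 = K`, decreasing to zero at saturating T3. Provided as
#' the complementary rate-law primitive for repressive T3 couplings; the
#' default model wires both specification programs through
#' [hillActivating()].
#'
#' @inheritParams hillActivating
#' @return Per-cell rate(s), in `[0, lambda_max]`.
#' @examples
#' hillRepressing(5, lambda_max = 1, K = 5)   # 0.5
#' @export
hillRepressing <- function(t3, lambda_max, K) {
  .checkHillArgs(t3, lambda_max, K)
  lambda_max * K / (K + t3)
}

.checkHillArgs <- function(t3, lambda_max, K) {
  if (!is.numeric(t3) || any(!is.finite(t3)) || any(t3 < 0))
    stop("'t3' must be finite and non-negative")
  if (!is.numeric(lambda_max) || length(lambda_max) != 1L ||
      !is.finite(lambda_max) || lambda_max < 0)
    stop("'lambda_max' must be a single non-negative number")
  if (!is.numeric(K) || length(K) != 1L || !is.finite(K) || K <= 0)
    stop("'K' must be a single positive number")
  invisible(TRUE)
}

#' Event set of the signaling model
#'
#' The seven stochastic cell-fate events. Specification of immature S and L/M
#' cones from RPCs follows the T3-dependent per-cell rates `f` (S program,
#' half-saturation `K_S`) and `g` (L/M program, `K_L`); non-cone
#' differentiation and maturation are constant-rate. Secondary firing uses the
#' opposite lineage's program: an immature S cone fires the L/M program `g`
#' (and vice versa) to become a coexpressing cone.
#'
#' @return data.frame with columns `source`, `target`, `rate_kind`,
#'   `rate_param` (one row per event, in the order used throughout the
#'   package).
#' @examples
#' eventTable()
#' @export
eventTable <- function() {
  data.frame(
    source = c("RPC", "RPC", "RPC", "IMMATURE_S", "IMMATURE_LM",
               "IMMATURE_S", "IMMATURE_LM"),
    target = c("IMMATURE_S", "IMMATURE_LM", "NONCONE", "MATURE_S",
               "MATURE_LM", "COEXPRESSING", "COEXPRESSING"),
    rate_kind = c("HILL_ACTIVATING", "HILL_ACTIVATING", "CONSTANT",
                  "CONSTANT", "CONSTANT", "HILL_ACTIVATING",
                  "HILL_ACTIVATING"),
    rate_param = c("lambda_S_max/K_S", "lambda_L_max/K_L", "lambda_N",
                   "mu_S", "mu_L", "lambda_L_max/K_L", "lambda_S_max/K_S"),
    stringsAsFactors = FALSE)
}

.checkCounts <- function(counts) {
  if (!is.numeric(counts) || !all(cellClasses() %in% names(counts)))
    stop("'counts' must be a numeric vector named by cellClasses()")
  counts <- counts[cellClasses()]
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(counts != round(counts)))
    stop("counts must be non-negative integers")
  counts
}

#' Event propensities at a population state
#'
#' Propensity of each of the seven events: source-class count times the
#' per-cell rate evaluated at the current T3.
#'
#' @param counts Named numeric vector of class counts (names
#'   [cellClasses()]).
#' @param t3 Current T3 concentration (non-negative scalar).
#' @param params A [ConeModelParams-class] object.
#' @return Named numeric vector of 7 propensities (1/day), named
#'   `"source->target"`.
#' @examples
#' cts <- setNames(c(100, 0, 0, 0, 0, 0, 0), cellClasses())
#' propensities(cts, t3 = 0.5, params = ConeModelParams())
#' @export
propensities <- function(counts, t3, params) {
  counts <- .checkCounts(counts)
  stopifnot(is(params, "ConeModelParams"))
  validObject(params)
  if (!is.numeric(t3) || length(t3) != 1L || !is.finite(t3) || t3 < 0)
    stop("'t3' must be a single non-negative number")
  f <- hillActivating(t3, params@lambda_S_max, params@K_S)
  g <- hillActivating(t3, params@lambda_L_max, params@K_L)
  ev <- eventTable()
  a <- c(counts[["RPC"]] * f,
         counts[["RPC"]] * g,
         counts[["RPC"]] * params@lambda_N,
         counts[["IMMATURE_S"]] * params@mu_S,
         counts[["IMMATURE_LM"]] * params@mu_L,
         counts[["IMMATURE_S"]] * g,
         counts[["IMMATURE_LM"]] * f)
  names(a) <- paste0(ev$source, "->", ev$target)
  a
}

#' Rate of change of the T3 concentration
#'
#' `dT3/dt = sigma_basal + sigma_exo * [time >= t_exo] - delta_eff * D * T3`,
#' where `delta_eff = delta * mutant_degradation_fraction` and the
#' DIO3-expressing (degrading) pool `D` is the RPC count, plus the immature
#' cone counts when `dio3_in_immature_cones` is set.
#'
#' @inheritParams propensities
#' @param time Current simulation time (day).
#' @return dT3/dt (concentration/day).
#' @examples
#' cts <- setNames(c(1000, 0, 0, 0, 0, 0, 0), cellClasses())
#' t3Derivative(cts, t3 = 2, time = 0,
#'   params = ConeModelParams(delta = 1e-3, sigma_basal = 0,
#'                            mutant_degradation_fraction = 0.06))
#' @export
t3Derivative <- function(counts, t3, time, params) {
  counts <- .checkCounts(counts)
  stopifnot(is(params, "ConeModelParams"))
  validObject(params)
  src <- params@sigma_basal + if (time >= params@t_exo) params@sigma_exo else 0
  d <- counts[["RPC"]]
  if (params@dio3_in_immature_cones)
    d <- d + counts[["IMMATURE_S"]] + counts[["IMMATURE_LM"]]
  deff <- params@delta * params@mutant_degradation_fraction
  unname(src - deff * d * t3)
}

#' Apply one cell-fate event to a population state
#'
#' Decrements the source class and increments the target class of event
#' `event_index` (row of [eventTable()]); T3 and time are untouched, total
#' cell number is conserved.
#'
#' @inheritParams propensities
#' @param event_index Integer in 1..7, row of [eventTable()].
#' @return Updated named count vector.
#' @examples
#' cts <- setNames(c(5, 0, 0, 0, 0, 0, 0), cellClasses())
#' applyEvent(cts, 3)   # one RPC -> NONCONE
#' @export
applyEvent <- function(counts, event_index) {
  counts <- .checkCounts(counts)
  ev <- eventTable()
  if (!is.numeric(event_index) || length(event_index) != 1L ||
      !event_index %in% seq_len(nrow(ev)))
    stop("'event_index' must be a single integer in 1..", nrow(ev))
  src <- ev$source[event_index]; tgt <- ev$target[event_index]
  if (counts[[src]] < 1)
    stop(sprintf("cannot fire %s->%s: no '%s' cells left", src, tgt, src))
  counts[[src]] <- counts[[src]] - 1
  counts[[tgt]] <- counts[[tgt]] + 1
  counts
}
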