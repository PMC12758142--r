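#' @include rates.R
NULL

#' Simulate one organoid with the hybrid Gillespie/ODE scheme
#'
#' Runs a single stochastic trajectory of the signaling model. Within each
#' operator-splitting step of length `step`, per-cell rates are frozen at the
#' step-start T3 and cell-fate events are sampled exactly with the Gillespie
#' algorithm (propensities follow the changing class counts); T3 is then
#' advanced over the step by classical 4th-order Runge-Kutta integration
#' (automatically substepped for stiff degradation) using the step-end
#' counts. The simulation stops when no RPC or immature cone remains
#' (`terminal = "complete"`) or at the `t_max` horizon (`"horizon"`).
#' Identical `(params, initial_rpc, t3_initial, seed, step)` give a
#' bit-identical trajectory.
#'
#' @param params A [ConeModelParams-class] object.
#' @param initial_rpc Positive integer, starting RPC count.
#' @param seed Integer seed for this trajectory's random stream.
#' @param t3_initial Initial T3 concentration (default 0).
#' @param step Operator-splitting step in days (default 0.1).
#' @param record_every Record a snapshot every `record_every` step boundaries
#'   (default 10, i.e. once per simulated day at the default step); the
#'   initial and final states are always recorded.
#' @param condition Condition label stored in the trajectory.
#' @return A [Trajectory-class] object.
#' @examples
#' tr <- simulateOrganoid(ConeModelParams(), initial_rpc = 500, seed = 1)
#' tr
#' @export
simulateOrganoid <- function(params, initial_rpc, seed, t3_initial = 0,
                             step = 0.1, record_every = 10L,
                             condition = "custom") {
  stopifnot(is(params, "ConeModelParams"))
  validObject(params)
  if (!is.numeric(initial_rpc) || length(initial_rpc) != 1L ||
      initial_rpc < 1 || initial_rpc != round(initial_rpc))
    stop("'initial_rpc' must be a positive integer")
  if (!is.numeric(step) || length(step) != 1L || step <= 0)
    stop("'step' must be a single positive number")
  if (params@t_max <= 0) stop("'t_max' must be > 0")
  if (!is.numeric(t3_initial) || t3_initial < 0)
    stop("'t3_initial' must be non-negative")
  record_every <- max(1L, as.integer(record_every))

  pv <- c(params@lambda_S_max, params@K_S, params@lambda_L_max, params@K_L,
          params@lambda_N, params@mu_S, params@mu_L, params@sigma_basal,
          params@sigma_exo, params@t_exo, params@delta,
          params@mutant_degradation_fraction, params@t_max)
  set.seed(as.integer(seed %% 2147483647))
  res <- .hybridSimCpp(as.integer(initial_rpc), t3_initial, pv,
                       params@dio3_in_immature_cones, step, record_every)
  sn <- as.data.frame(res$snapshots)
  new("Trajectory", snapshots = sn, terminal = res$terminal,
      seed = as.numeric(seed), condition = condition, params = params,
      step = step, initial_rpc = as.numeric(initial_rpc),
      t3_initial = t3_initial)
}

#' Closed-form T3 solution at constant degrader count
#'
#' Analytic solution of `dT3/dt = sigma - delta_eff * D * T3` with a constant
#' degrading-cell count `D` (no exogenous source): exponential relaxation to
#' the steady state `sigma / (delta_eff * D)`, or linear growth when `D = 0`.
#' Serves as the independent oracle for the numerical integrator.
#'
#' @param t Time(s) in days (vectorised).
#' @param rpc_const Constant degrading-cell count `D` (non-negative).
#' @param params A [ConeModelParams-class] object; uses `sigma_basal`,
#'   `delta` and `mutant_degradation_fraction`.
#' @param t3_initial T3 at time 0.
#' @return T3 concentration(s) at `t`.
#' @examples
#' p <- ConeModelParams(sigma_basal = 1, delta = 5e-4)
#' t3ClosedForm(2, rpc_const = 1000, params = p, t3_initial = 0)
#' @export
t3ClosedForm <- function(t, rpc_const, params, t3_initial = 0) {
  stopifnot(is(params, "ConeModelParams"))
  if (!is.numeric(rpc_const) || length(rpc_const) != 1L || rpc_const < 0)
    stop("'rpc_const' must be a single non-negative number")
  sigma <- params@sigma_basal
  lam <- params@delta * params@mutant_degradation_fraction * rpc_const
  if (lam == 0) return(t3_initial + sigma * t)
  sigma / lam + (t3_initial - sigma / lam) * exp(-lam * t)
}

.CONDITIONS <- c("WT", "MUT", "WT_T3", "MUT_T3")

#' Apply a condition preset to a parameter set
#'
#' `WT` leaves the parameters unchanged (no exogenous T3); `MUT` scales the
#' DIO3-mediated degradation constant to 6\% of its wild-type value (the
#' residual deiodination measured in DIO3-mutant organoids); `WT_T3` and
#' `MUT_T3` additionally switch on the exogenous T3 source `exo_rate` from
#' day `t_exo`.
#'
#' @param condition One of `"WT"`, `"MUT"`, `"WT_T3"`, `"MUT_T3"`.
#' @param base_params A [ConeModelParams-class] object.
#' @param exo_rate Exogenous T3 source used by the `*_T3` presets
#'   (concentration/day). The default 3 gives supplemented wild-type cultures
#'   a four-fold T3 elevation while the mutant, whose endogenous T3 already
#'   saturates both specification programs, is left effectively unchanged.
#' @param mutant_fraction Residual degradation fraction of the mutant preset.
#' @return A [ConeModelParams-class] object with the preset applied.
#' @examples
#' conditionParams("MUT", ConeModelParams())
#' @export
conditionParams <- function(condition, base_params = ConeModelParams(),
                            exo_rate = 3, mutant_fraction = 0.06) {
  stopifnot(is(base_params, "ConeModelParams"))
  if (!is.character(condition) || length(condition) != 1L ||
      !condition %in% .CONDITIONS)
    stop("'condition' must be one of: ", paste(.CONDITIONS, collapse = ", "))
  p <- base_params
  p@sigma_exo <- 0
  if (condition %in% c("MUT", "MUT_T3"))
    p@mutant_degradation_fraction <- mutant_fraction
  if (condition %in% c("WT_T3", "MUT_T3"))
    p@sigma_exo <- exo_rate
  validObject(p)
  p
}

#' Simulate one organoid under a named experimental condition
#'
#' Applies the condition preset (see [conditionParams()]) and simulates a
#' single organoid seeded with `initial_rpc` RPCs (default 10^4, the
#' experimental scale).
#'
#' @inheritParams conditionParams
#' @param seed Integer seed.
#' @param initial_rpc Starting RPC count (default 10000).
#' @param ... Further arguments passed to [simulateOrganoid()].
#' @return A [Trajectory-class] object with the condition label set.
#' @examples
#' tr <- runCondition("MUT", ConeModelParams(), seed = 1, initial_rpc = 500)
#' conditionLabel(tr)
#' @export
runCondition <- function(condition, base_params = ConeModelParams(), seed,
                         initial_rpc = 10000L, exo_rate = 3,
                         mutant_fraction = 0.06, ...) {
  p <- conditionParams(condition, base_params, exo_rate, mutant_fraction)
  simulateOrganoid(p, initial_rpc = initial_rpc, seed = seed,
                   condition = condition, ...)
}

#' Representative trajectories for the four experimental conditions
#'
#' One simulation per condition (WT, MUT, WT_T3, MUT_T3) from a shared base
#' parameter set, each with its own random stream derived from `seed`.
#'
#' @inheritParams runCondition
#' @return Named list of four [Trajectory-class] objects.
#' @examples
#' panel <- conditionPanel(ConeModelParams(), seed = 1, initial_rpc = 300)
#' vapply(panel, conditionLabel, character(1))
#' @export
conditionPanel <- function(base_params = ConeModelParams(), seed,
                           initial_rpc = 10000L, exo_rate = 3,
                           mutant_fraction = 0.06, ...) {
  out <- lapply(seq_along(.CONDITIONS), function(i)
    runCondition(.CONDITIONS[i], base_params,
                 seed = deriveSeed(seed, i - 1L),
                 initial_rpc = initial_rpc, exo_rate = exo_rate,
                 mutant_fraction = mutant_fraction, ...))
  names(out) <- .CONDITIONS
  out
}
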