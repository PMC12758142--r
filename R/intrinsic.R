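#' @include AllClasses.R
NULL

#' Calibrate the cell-intrinsic model to target mean outputs
#'
#' Adjusts the constant specification rates `lambda_S` and `lambda_L` of the
#' cell-intrinsic model so that its mean final S and L/M cone counts match
#' given targets, with `lambda_N` inherited from the signaling parameter set.
#' Closed-form competing-risks solution: with fate probabilities
#' `p_S = target_mean_S / n0_mean`, `p_L = target_mean_LM / n0_mean` and
#' `p_N = 1 - p_S - p_L`, the rates are `lambda_S = lambda_N * p_S / p_N`
#' and `lambda_L = lambda_N * p_L / p_N`, so the implied multinomial mean
#' final counts equal the targets exactly.
#'
#' @param target_mean_S,target_mean_LM Target mean final counts.
#' @param lambda_N Non-cone rate (1/day), must be positive.
#' @param n0_mean Mean initial RPC count.
#' @param mu_S,mu_L Maturation rates carried through to the result (do not
#'   affect final counts).
#' @return An [IntrinsicParams-class] object.
#' @examples
#' calibrateIntrinsic(2500, 2500, lambda_N = 0.01, n0_mean = 1e4)
#' @export
calibrateIntrinsic <- function(target_mean_S, target_mean_LM, lambda_N,
                               n0_mean, mu_S = 0.16, mu_L = 0.16) {
  stopifnot(is.numeric(target_mean_S), is.numeric(target_mean_LM),
            target_mean_S >= 0, target_mean_LM >= 0, n0_mean > 0)
  if (!is.numeric(lambda_N) || lambda_N <= 0)
    stop("'lambda_N' must be positive")
  p_S <- target_mean_S / n0_mean
  p_L <- target_mean_LM / n0_mean
  p_N <- 1 - p_S - p_L
  if (p_N <= 0)
    stop("infeasible calibration: targets must sum to less than 'n0_mean'")
  IntrinsicParams(lambda_S = lambda_N * p_S / p_N,
                  lambda_L = lambda_N * p_L / p_N,
                  lambda_N = lambda_N, mu_S = mu_S, mu_L = mu_L)
}

#' Simulate the cell-intrinsic model
#'
#' Each RPC independently adopts a fate with probabilities proportional to
#' the constant rates — the outcome distribution of a Gillespie race of three
#' exponential clocks, sampled directly as one multinomial draw. Immature
#' cones always mature (maturation does not compete with any other event), so
#' final counts land in the mature classes.
#'
#' @param params An [IntrinsicParams-class] object.
#' @param initial_rpc Positive integer.
#' @param seed Integer seed.
#' @return Final-state list as [finalState()]: `counts`, `T3` (always 0; the
#'   intrinsic model has no T3 coupling), `time` (`NA`).
#' @examples
#' p <- calibrateIntrinsic(2500, 2500, lambda_N = 0.01, n0_mean = 1e4)
#' simulateIntrinsic(p, initial_rpc = 1e4, seed = 1)$counts
#' @export
simulateIntrinsic <- function(params, initial_rpc, seed) {
  stopifnot(is(params, "IntrinsicParams"))
  validObject(params)
  if (!is.numeric(initial_rpc) || length(initial_rpc) != 1L ||
      initial_rpc < 1 || initial_rpc != round(initial_rpc))
    stop("'initial_rpc' must be a positive integer")
  tot <- params@lambda_S + params@lambda_L + params@lambda_N
  pr <- c(params@lambda_S, params@lambda_L, params@lambda_N) / tot
  set.seed(as.integer(seed %% 2147483647))
  draw <- as.vector(rmultinom(1L, size = as.integer(initial_rpc), prob = pr))
  counts <- setNames(numeric(7), cellClasses())
  counts["MATURE_S"] <- draw[1L]
  counts["MATURE_LM"] <- draw[2L]
  counts["NONCONE"] <- draw[3L]
  list(counts = counts, T3 = 0, time = NA_real_)
}

#' Closed-form moments of the intrinsic total photoreceptor count
#'
#' For the cell-intrinsic model with per-RPC photoreceptor probability
#' `p_pr` and a random initial pool `N0 ~ Normal(n0_mean, n0_sd)`, the final
#' photoreceptor count is Binomial(N0, p_pr); by the law of total variance
#' its mean is `p * mu0`, its variance `p(1-p) * mu0 + p^2 * sd0^2`, and its
#' coefficient of variation the square root of the variance over the mean.
#' This is the analytic anchor for the intrinsic arm of the noise-filtering
#' comparison: initial-pool noise propagates to the output in full.
#'
#' @param p_pr Per-RPC probability of any photoreceptor fate, in [0, 1].
#' @param n0_mean,n0_sd Mean and standard deviation of the initial RPC pool.
#' @return List with elements `mean`, `variance`, `cv`.
#' @examples
#' intrinsicMoments(0.5, 1e4, 2000)
#' @export
intrinsicMoments <- function(p_pr, n0_mean, n0_sd) {
  if (!is.numeric(p_pr) || p_pr < 0 || p_pr > 1)
    stop("'p_pr' must be in [0, 1]")
  stopifnot(n0_mean > 0, n0_sd >= 0)
  m <- p_pr * n0_mean
  v <- p_pr * (1 - p_pr) * n0_mean + p_pr^2 * n0_sd^2
  list(mean = m, variance = v, cv = if (m > 0) sqrt(v) / m else NaN)
}
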