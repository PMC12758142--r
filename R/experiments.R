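#' @include simulate.R
NULL

#' @include intrinsic.R
NULL

#' Draw initial RPC counts
#'
#' Initial progenitor pools are normally distributed across organoids
#' (experimental reference: mean 10^4, standard deviation 2000). Draws are
#' rounded to the nearest integer and redrawn until positive. Uses the
#' current RNG state; call `set.seed()` (or rely on the experiment drivers,
#' which derive their own streams) for reproducibility.
#'
#' @param n Number of draws.
#' @param mean,sd Mean (> 0) and standard deviation (>= 0) of the pool size.
#' @return Integer vector of length `n`, all values >= 1.
#' @examples
#' set.seed(1); sampleInitialRPC(3, 1e4, 2000)
#' @export
sampleInitialRPC <- function(n, mean = 10000, sd = 2000) {
  stopifnot(n >= 1, mean > 0, sd >= 0)
  out <- as.integer(round(rnorm(n, mean, sd)))
  bad <- which(out < 1L)
  while (length(bad)) {
    out[bad] <- as.integer(round(rnorm(length(bad), mean, sd)))
    bad <- bad[out[bad] < 1L]
  }
  out
}

.finalCountsRow <- function(counts, replicate, n0, seed, t3 = NA_real_,
                            terminal = NA_character_) {
  cbind(data.frame(replicate = replicate, initial_rpc = n0, seed = seed),
        as.data.frame(as.list(counts)),
        data.frame(T3_final = t3, terminal = terminal))
}

.safeCV <- function(x) {
  m <- mean(x)
  if (m <= 0) return(NaN)
  sd(x) / m
}

#' Noise-filtering experiment: signaling vs cell-intrinsic model
#'
#' Quantifies how initial-pool noise propagates to final photoreceptor
#' counts. Runs `n_reps` signaling simulations, each seeded with a random
#' initial RPC count from Normal(`n0_mean`, `n0_sd`); calibrates the
#' cell-intrinsic model so its mean final S and L/M counts match the
#' signaling means ([calibrateIntrinsic()]); then runs `n_reps` intrinsic
#' simulations with the same initial-pool distribution. The coefficient of
#' variation of the total photoreceptor count in each arm (via
#' [summaryStats()]) measures output noise; T3 feedback filters initial-pool
#' noise, so the signaling CV falls below the intrinsic CV.
#'
#' @param params [ConeModelParams-class] for the signaling arm.
#' @param n_reps Number of replicates per arm (>= 2).
#' @param n0_mean,n0_sd Initial-pool distribution (defaults 10^4 and 2000).
#' @param seed Integer master seed; replicate streams are derived with
#'   [deriveSeed()].
#' @param step,record_every Passed to [simulateOrganoid()].
#' @return List with elements `signaling` and `intrinsic` (both
#'   [ExperimentResult-class]) and `intrinsic_params`.
#' @examples
#' res <- noiseFilterExperiment(ConeModelParams(), n_reps = 5,
#'                              n0_mean = 300, n0_sd = 50, seed = 1)
#' summaryStats(res$signaling)$cv
#' @export
noiseFilterExperiment <- function(params, n_reps, n0_mean = 10000,
                                  n0_sd = 2000, seed,
                                  step = 0.1, record_every = 1000000L) {
  stopifnot(is(params, "ConeModelParams"))
  if (!is.numeric(n_reps) || n_reps < 2)
    stop("'n_reps' must be at least 2 (CV is undefined otherwise)")
  n_reps <- as.integer(n_reps)

  set.seed(deriveSeed(seed, 0L))
  n0_sig <- sampleInitialRPC(n_reps, n0_mean, n0_sd)
  n0_int <- sampleInitialRPC(n_reps, n0_mean, n0_sd)

  sig <- vector("list", n_reps)
  for (i in seq_len(n_reps)) {
    tr <- simulateOrganoid(params, initial_rpc = n0_sig[i],
                           seed = deriveSeed(seed, i), step = step,
                           record_every = record_every,
                           condition = "signaling")
    fs <- finalState(tr)
    sig[[i]] <- .finalCountsRow(fs$counts, i, n0_sig[i],
                                deriveSeed(seed, i), fs$T3, tr@terminal)
  }
  sig <- do.call(rbind, sig)

  ip <- calibrateIntrinsic(mean(sig$MATURE_S), mean(sig$MATURE_LM),
                           lambda_N = params@lambda_N, n0_mean = n0_mean,
                           mu_S = params@mu_S, mu_L = params@mu_L)

  intr <- vector("list", n_reps)
  for (i in seq_len(n_reps)) {
    fs <- simulateIntrinsic(ip, initial_rpc = n0_int[i],
                            seed = deriveSeed(seed, n_reps + i))
    intr[[i]] <- .finalCountsRow(fs$counts, i, n0_int[i],
                                 deriveSeed(seed, n_reps + i), 0, "complete")
  }
  intr <- do.call(rbind, intr)

  list(signaling = new("ExperimentResult", counts = sig, model = "signaling",
                       condition = "signaling", seed = as.numeric(seed),
                       params = params),
       intrinsic = new("ExperimentResult", counts = intr, model = "intrinsic",
                       condition = "intrinsic", seed = as.numeric(seed),
                       params = ip),
       intrinsic_params = ip)
}

.SAMPLED_PARAMS <- c("lambda_S_max", "lambda_L_max", "K_S", "K_L", "lambda_N",
                     "mu_S", "mu_L", "delta", "sigma_basal")

#' Sample a random parameter set around defaults
#'
#' Each of the nine rate/affinity constants (`lambda_S_max`, `lambda_L_max`,
#' `K_S`, `K_L`, `lambda_N`, `mu_S`, `mu_L`, `delta`, `sigma_basal`) is drawn
#' log-uniformly over a `fold_range`-fold interval centred on its default:
#' `[default / sqrt(fold_range), default * sqrt(fold_range)]`, i.e.
#' `[default/10, default*10]` for the reference 100-fold range. Structural
#' fields (condition flags, `sigma_exo`, `t_exo`, `t_max`) are not sampled.
#' Uses the current RNG state.
#'
#' @param defaults [ConeModelParams-class] providing the centres; all sampled
#'   entries must be positive.
#' @param fold_range Total fold range (>= 1); 1 returns the defaults.
#' @return A [ConeModelParams-class] object.
#' @examples
#' set.seed(1); sampleParameters(ConeModelParams(), 100)
#' @export
sampleParameters <- function(defaults = ConeModelParams(), fold_range = 100) {
  stopifnot(is(defaults, "ConeModelParams"))
  if (!is.numeric(fold_range) || length(fold_range) != 1L || fold_range < 1)
    stop("'fold_range' must be a single number >= 1")
  p <- defaults
  if (fold_range == 1) return(p)
  half <- sqrt(fold_range)
  for (s in .SAMPLED_PARAMS) {
    d <- slot(p, s)
    if (d <= 0)
      stop(sprintf("cannot sample '%s': default is zero", s))
    slot(p, s) <- d * half^runif(1L, -1, 1)
  }
  validObject(p)
  p
}

#' Parameter-space robustness sweep
#'
#' Repeats the noise-filtering comparison across `n_sets` randomly sampled
#' parameter sets ([sampleParameters()]), recalibrating the intrinsic model
#' to each set's signaling means, and records the CV pair per set. Sets in
#' which no photoreceptors are produced have undefined CVs recorded as `NaN`.
#'
#' @param n_sets Number of sampled parameter sets (>= 1).
#' @param n_reps_per_set Replicates per set and arm (>= 2; the reference
#'   design uses 50).
#' @param fold_range Sampling range (default 100-fold).
#' @param seed Integer master seed.
#' @param base_params Defaults around which parameters are sampled.
#' @param n0_mean,n0_sd Initial-pool distribution.
#' @param step Operator-splitting step for the signaling simulations.
#' @return A [SweepResult-class] object.
#' @examples
#' sw <- parameterSweep(n_sets = 2, n_reps_per_set = 3, seed = 1,
#'                      n0_mean = 300, n0_sd = 50)
#' sweepRecords(sw)[, c("set", "cv_signaling", "cv_intrinsic")]
#' @export
parameterSweep <- function(n_sets, n_reps_per_set = 50, fold_range = 100,
                           seed, base_params = ConeModelParams(),
                           n0_mean = 10000, n0_sd = 2000, step = 0.1) {
  stopifnot(n_sets >= 1, n_reps_per_set >= 2)
  recs <- vector("list", n_sets)
  for (s in seq_len(n_sets)) {
    set.seed(deriveSeed(seed, 1000000L + s))
    ps <- sampleParameters(base_params, fold_range)
    res <- noiseFilterExperiment(ps, n_reps = n_reps_per_set,
                                 n0_mean = n0_mean, n0_sd = n0_sd,
                                 seed = deriveSeed(seed, s), step = step)
    sigc <- replicateCounts(res$signaling)
    intc <- replicateCounts(res$intrinsic)
    sampled <- setNames(lapply(.SAMPLED_PARAMS, function(nm) slot(ps, nm)),
                        .SAMPLED_PARAMS)
    recs[[s]] <- cbind(
      data.frame(set = s),
      as.data.frame(sampled),
      data.frame(
        cv_signaling = .safeCV(sigc$MATURE_S + sigc$MATURE_LM +
                                 sigc$COEXPRESSING),
        cv_intrinsic = .safeCV(intc$MATURE_S + intc$MATURE_LM +
                                 intc$COEXPRESSING),
        mean_S_signaling = mean(sigc$MATURE_S),
        mean_LM_signaling = mean(sigc$MATURE_LM),
        mean_S_intrinsic = mean(intc$MATURE_S),
        mean_LM_intrinsic = mean(intc$MATURE_LM),
        n_reps = n_reps_per_set))
  }
  new("SweepResult", records = do.call(rbind, recs),
      fold_range = fold_range, n_reps_per_set = n_reps_per_set,
      seed = as.numeric(seed))
}
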