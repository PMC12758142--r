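#' @include simulate.R
NULL

#' Synthesize an opsin-density observation time course
#'
#' Emulates immunohistochemistry quantification of organoid sections:
#' for each requested day and observation class, the cell density is the
#' trajectory count at that day times a `scale` (cells/mm^2 per simulated
#' cell), with independent multiplicative lognormal noise of coefficient of
#' variation `noise_cv` per organoid (densities are positive and
#' right-skewed across organoids). `S_opsin`, `LM_opsin` and `S_and_LM`
#' derive from the mature S, mature L/M and coexpressing counts; `Rho_like`
#' is `rho_fraction` of the non-cone pool, an emulation convenience standing
#' in for rods, which the cone model does not track explicitly.
#'
#' @param trajectory A [Trajectory-class] object.
#' @param days Integer days to sample; must lie within the trajectory span.
#'   Defaults to the study's quantification ages (100 to 200 every 20 days),
#'   truncated to the trajectory span.
#' @param n_organoids_per_day Number of emulated organoids per day.
#' @param scale Density per simulated cell (default 0.25 cells/mm^2, mapping
#'   a 10^4-cell organoid onto the 10^2-10^3 cells/mm^2 scale of measured
#'   opsin densities; arbitrary).
#' @param noise_cv Organoid-level noise CV (default 0.3; 0 disables noise).
#' @param rho_fraction Fraction of non-cone cells counted as Rho-like
#'   (default 0.4).
#' @param seed Integer seed.
#' @return An [ObservationTable-class] object.
#' @examples
#' tr <- simulateOrganoid(ConeModelParams(), initial_rpc = 500, seed = 1)
#' obs <- synthesizeDensityTimecourse(tr, days = c(100, 200),
#'                                    n_organoids_per_day = 3, seed = 1)
#' head(observations(obs))
#' @export
synthesizeDensityTimecourse <- function(trajectory,
                                        days = seq(100, 200, by = 20),
                                        n_organoids_per_day = 5,
                                        scale = 0.25, noise_cv = 0.3,
                                        rho_fraction = 0.4, seed = 1) {
  stopifnot(is(trajectory, "Trajectory"))
  if (!is.numeric(scale) || scale <= 0) stop("'scale' must be positive")
  if (!is.numeric(noise_cv) || noise_cv < 0)
    stop("'noise_cv' must be non-negative")
  stopifnot(rho_fraction >= 0, rho_fraction <= 1, n_organoids_per_day >= 1)
  sn <- trajectory@snapshots
  days <- as.integer(days)
  # after completion every cell is terminal, so counts persist beyond the
  # last snapshot; only a horizon-truncated trajectory cannot be extrapolated
  if (any(days < 0) ||
      (trajectory@terminal == "horizon" && any(days > max(sn$time))))
    stop("requested days outside the trajectory span [0, ",
         max(sn$time), "]")

  # count at the last snapshot at or before each day (terminal states persist)
  atDay <- function(day) sn[max(which(sn$time <= day)), ]
  sdlog <- sqrt(log(1 + noise_cv^2))
  set.seed(as.integer(seed %% 2147483647))
  rows <- vector("list", length(days))
  for (k in seq_along(days)) {
    st <- atDay(days[k])
    base <- c(S_opsin = st$MATURE_S, LM_opsin = st$MATURE_LM,
              Rho_like = rho_fraction * st$NONCONE,
              S_and_LM = st$COEXPRESSING) * scale
    nobs <- n_organoids_per_day * length(base)
    noise <- if (noise_cv > 0)
      rlnorm(nobs, meanlog = -sdlog^2 / 2, sdlog = sdlog) else rep(1, nobs)
    rows[[k]] <- data.frame(
      day = days[k],
      organoid_id = rep(seq_len(n_organoids_per_day), each = length(base)),
      class = rep(names(base), times = n_organoids_per_day),
      density = rep(base, times = n_organoids_per_day) * noise,
      stringsAsFactors = FALSE)
  }
  new("ObservationTable", observations = do.call(rbind, rows),
      scale = scale, noise_cv = noise_cv, rho_fraction = rho_fraction,
      seed = as.numeric(seed))
}

#' Summarize a synthetic observation table
#'
#' Per (day, class): mean density and standard error of the mean (n - 1
#' standard deviation over sqrt(n)); plus, per day, the percentage of
#' S-lineage cells coexpressing L/M opsin,
#' `100 * S_and_LM / (S_opsin + S_and_LM)` on mean densities.
#'
#' @param table An [ObservationTable-class] object with at least 2 organoids
#'   per (day, class).
#' @return List with `densities` (data.frame: day, class, mean, sem, n) and
#'   `coexpression_percent` (data.frame: day, percent).
#' @examples
#' tr <- simulateOrganoid(ConeModelParams(), initial_rpc = 500, seed = 1)
#' obs <- synthesizeDensityTimecourse(tr, days = 200,
#'                                    n_organoids_per_day = 4, seed = 1)
#' summarizeObservations(obs)$densities
#' @export
summarizeObservations <- function(table) {
  stopifnot(is(table, "ObservationTable"))
  obs <- table@observations
  grp <- interaction(obs$day, obs$class, drop = TRUE)
  n <- tapply(obs$density, grp, length)
  if (any(n < 2))
    stop("SEM undefined: need at least 2 organoids per (day, class)")
  agg <- do.call(rbind, lapply(split(obs, grp), function(d)
    data.frame(day = d$day[1L], class = d$class[1L],
               mean = mean(d$density),
               sem = sd(d$density) / sqrt(nrow(d)), n = nrow(d))))
  rownames(agg) <- NULL
  agg <- agg[order(agg$day, agg$class), ]
  co <- do.call(rbind, lapply(split(agg, agg$day), function(d) {
    s <- d$mean[d$class == "S_opsin"]; b <- d$mean[d$class == "S_and_LM"]
    pct <- if (s + b > 0) 100 * b / (s + b) else 0
    data.frame(day = d$day[1L], percent = pct)
  }))
  rownames(co) <- NULL
  list(densities = agg, coexpression_percent = co)
}

#' Deiodination-assay calibration arithmetic
#'
#' Converts measured deiodination activities (pmol T3 converted per hour per
#' mg protein) of wild-type and mutant organoids into the percent reduction
#' of DIO3 activity and the residual mutant fraction. The residual fraction
#' divided by 100 is the value to install as
#' `mutant_degradation_fraction` in [ConeModelParams-class]. With the
#' reference day-74 measurements (wild type 16.8, mutant 1.0) the activity
#' reduction is ~94\% and the residual fraction ~6\%.
#'
#' @param wt_activity Wild-type activity (> 0).
#' @param mut_activity Mutant activity (>= 0).
#' @return List with `percent_reduction`, `mutant_fraction` (both in
#'   percent), their integer-rounded versions, and
#'   `degradation_fraction` (= `mutant_fraction` / 100).
#' @examples
#' deiodinationCalibration(16.8, 1.0)
#' @export
deiodinationCalibration <- function(wt_activity, mut_activity) {
  if (!is.numeric(wt_activity) || wt_activity <= 0)
    stop("'wt_activity' must be positive (ratio undefined at 0)")
  if (!is.numeric(mut_activity) || mut_activity < 0)
    stop("'mut_activity' must be non-negative")
  frac <- 100 * mut_activity / wt_activity
  red <- 100 - frac
  list(percent_reduction = red, mutant_fraction = frac,
       percent_reduction_rounded = round(red),
       mutant_fraction_rounded = round(frac),
       degradation_fraction = frac / 100)
}
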