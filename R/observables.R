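#' @include AllClasses.R
NULL

#' Coefficient of variation
#'
#' Sample standard deviation (n - 1 denominator) divided by the sample mean;
#' the noise metric used for final photoreceptor counts.
#'
#' @param values Numeric vector with at least 2 elements and positive mean.
#' @return Dimensionless CV.
#' @examples
#' coefficientOfVariation(c(1, 2, 3))   # 0.5
#' @export
coefficientOfVariation <- function(values) {
  if (!is.numeric(values) || length(values) < 2L)
    stop("'values' must be a numeric vector of length >= 2")
  m <- mean(values)
  if (m <= 0) stop("CV undefined: mean must be positive")
  sd(values) / m
}

.asCounts <- function(object) {
  if (is(object, "Trajectory")) return(finalState(object)$counts)
  if (is.list(object) && !is.null(object$counts)) return(.checkCounts(object$counts))
  .checkCounts(object)
}

#' Total photoreceptor count
#'
#' Mature S cones + mature L/M cones + coexpressing cones of a final state.
#'
#' @param object A [Trajectory-class], a final-state list, or a named count
#'   vector.
#' @return Integer total.
#' @examples
#' cts <- setNames(c(0, 0, 0, 3, 4, 2, 0), cellClasses())
#' totalPhotoreceptors(cts)   # 9
#' @rdname totalPhotoreceptors
#' @export
setMethod("totalPhotoreceptors", "ANY", function(object) {
  counts <- .asCounts(object)
  unname(counts[["MATURE_S"]] + counts[["MATURE_LM"]] +
           counts[["COEXPRESSING"]])
})

#' First time a class count reaches a threshold
#'
#' First snapshot time at which the count of `cls` is at least `threshold`;
#' `NA` when the threshold is never reached. Used to operationalise the
#' timing of cone-subtype generation (e.g. mutant acceleration).
#'
#' @param object A [Trajectory-class] object.
#' @param cls One of [cellClasses()].
#' @param threshold Count threshold (>= 1).
#' @return Time in days, or `NA_real_`.
#' @examples
#' tr <- simulateOrganoid(ConeModelParams(), initial_rpc = 500, seed = 1)
#' timeToThreshold(tr, "MATURE_S", 10)
#' @rdname timeToThreshold
#' @export
setMethod("timeToThreshold", "Trajectory", function(object, cls, threshold) {
  stopifnot(cls %in% cellClasses())
  if (!is.numeric(threshold) || threshold < 1)
    stop("'threshold' must be >= 1")
  sn <- object@snapshots
  i <- which(sn[[cls]] >= threshold)
  if (!length(i)) NA_real_ else sn$time[i[1L]]
})

#' L/M-cone to S-cone ratio
#'
#' `MATURE_LM / MATURE_S` of a final state. Coexpressing cones are excluded
#' from both numerator and denominator: the ratio concerns single-opsin
#' identities, whereas coexpressing cones carry both. When no mature S cones
#' exist the ratio is `Inf` with a warning (flagged sentinel).
#'
#' @inheritParams totalPhotoreceptors
#' @return Non-negative ratio, possibly `Inf`.
#' @examples
#' cts <- setNames(c(0, 0, 0, 4, 8, 1, 0), cellClasses())
#' lmToSRatio(cts)   # 2
#' @rdname lmToSRatio
#' @export
setMethod("lmToSRatio", "ANY", function(object) {
  counts <- .asCounts(object)
  s <- counts[["MATURE_S"]]; lm <- counts[["MATURE_LM"]]
  if (s == 0) {
    warning("no mature S cones: L/M:S ratio is infinite")
    return(Inf)
  }
  unname(lm / s)
})

#' Fraction of cones coexpressing both opsins
#'
#' `COEXPRESSING / (MATURE_S + MATURE_LM + COEXPRESSING)` of a final state.
#'
#' @inheritParams totalPhotoreceptors
#' @return Fraction in [0, 1].
#' @examples
#' cts <- setNames(c(0, 0, 0, 4, 4, 2, 0), cellClasses())
#' coexpressionFraction(cts)   # 0.2
#' @rdname coexpressionFraction
#' @export
setMethod("coexpressionFraction", "ANY", function(object) {
  counts <- .asCounts(object)
  tot <- counts[["MATURE_S"]] + counts[["MATURE_LM"]] +
    counts[["COEXPRESSING"]]
  if (tot == 0) stop("coexpression fraction undefined: no cone-lineage cells")
  unname(counts[["COEXPRESSING"]] / tot)
})
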