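#' @rdname snapshots
#' @export
setGeneric("snapshots", function(object) standardGeneric("snapshots"))

#' @rdname terminalStatus
#' @export
setGeneric("terminalStatus", function(object) standardGeneric("terminalStatus"))

#' @rdname conditionLabel
#' @export
setGeneric("conditionLabel", function(object) standardGeneric("conditionLabel"))

#' @rdname finalState
#' @export
setGeneric("finalState", function(object) standardGeneric("finalState"))

#' @rdname modelParams
#' @export
setGeneric("modelParams", function(object) standardGeneric("modelParams"))

#' @rdname totalPhotoreceptors
#' @export
setGeneric("totalPhotoreceptors", function(object) standardGeneric("totalPhotoreceptors"))

#' @rdname lmToSRatio
#' @export
setGeneric("lmToSRatio", function(object) standardGeneric("lmToSRatio"))

#' @rdname coexpressionFraction
#' @export
setGeneric("coexpressionFraction", function(object) standardGeneric("coexpressionFraction"))

#' @rdname timeToThreshold
#' @export
setGeneric("timeToThreshold", function(object, cls, threshold)
  standardGeneric("timeToThreshold"))

#' @rdname replicateCounts
#' @export
setGeneric("replicateCounts", function(object) standardGeneric("replicateCounts"))

#' @rdname summaryStats
#' @export
setGeneric("summaryStats", function(object) standardGeneric("summaryStats"))

#' @rdname sweepRecords
#' @export
setGeneric("sweepRecords", function(object) standardGeneric("sweepRecords"))

#' @rdname observations
#' @export
setGeneric("observations", function(object) standardGeneric("observations"))
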