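#' @rdname ExpressionSeries
#' @export
setGeneric("seriesId", function(x) standardGeneric("seriesId"))

#' @rdname ExpressionSeries
#' @export
setGeneric("sampleTimes", function(x) standardGeneric("sampleTimes"))

#' @rdname ExpressionSeries
#' @export
setGeneric("startCT", function(x) standardGeneric("startCT"))

#' @rdname ExpressionSeries
#' @export
setGeneric("timeResolution", function(x) standardGeneric("timeResolution"))

#' @rdname ExpressionSeries
#' @export
setGeneric("exprScale", function(x) standardGeneric("exprScale"))

#' @rdname ScaledComparison-accessors
#' @export
setGeneric("probeIds", function(x) standardGeneric("probeIds"))

#' @rdname ScaledComparison-accessors
#' @export
setGeneric("foldRatios", function(x) standardGeneric("foldRatios"))

#' @rdname ScaledComparison-accessors
#' @export
setGeneric("ratioRanks", function(x) standardGeneric("ratioRanks"))

#' @rdname ScaledComparison-accessors
#' @export
setGeneric("scalingFactors", function(x) standardGeneric("scalingFactors"))

#' @rdname ScaledComparison-accessors
#' @export
setGeneric("scaledAverages", function(x) standardGeneric("scaledAverages"))
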