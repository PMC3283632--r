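#' Construct an ExpressionSeries
#'
#' Bundles a probe x sample expression matrix with the circadian metadata the
#' downstream comparison and rhythm scans need. Sample times are circadian
#' hours and may exceed 24 across multi-day series; the starting circadian
#' time of the series is `times[1] %% 24`. Values are GC-RMA-style normalized
#' log2 intensities by default; this package never normalizes.
#'
#' @param values numeric matrix, probes in rows, samples in columns.
#' @param probeIds character vector of unique probe ids (defaults to
#'   `rownames(values)`).
#' @param times numeric vector of sample times in hours, strictly increasing.
#' @param seriesId single character identifier.
#' @param resolution sampling resolution in hours; defaults to the median
#'   spacing of `times`.
#' @param scale `"log2"` (default) or `"linear"`.
#'
#' @return An [ExpressionSeries-class] object.
#'
#' @examples
#' m <- matrix(rnorm(12, mean = 7), nrow = 3,
#'             dimnames = list(paste0("p", 1:3), NULL))
#' es <- ExpressionSeries(m, times = c(2, 6, 10, 14), seriesId = "demo")
#' startCT(es)
#' @export
ExpressionSeries <- function(values, probeIds = rownames(values), times,
                             seriesId = "series", resolution = NULL,
                             scale = c("log2", "linear")) {
    scale <- match.arg(scale)
    values <- as.matrix(values)
    if (is.null(probeIds))
        stop("probe ids are required (rownames or probeIds=)")
    if (nrow(values) != length(probeIds))
        stop("values must have one row per probe id")
    if (ncol(values) != length(times))
        stop("values must have one column per sample time")
    if (is.null(resolution)) {
        resolution <- if (length(times) > 1L) stats::median(diff(times)) else 1
    }
    rownames(values) <- probeIds
    colnames(values) <- sprintf("t%g", times)
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(exprs = values),
        colData = S4Vectors::DataFrame(time = as.numeric(times)))
    .ExpressionSeries(se, seriesId = as.character(seriesId),
                      resolution = as.numeric(resolution),
                      exprScale = scale)
}

#' Accessors for ExpressionSeries
#'
#' `seriesId()` returns the series identifier, `sampleTimes()` the sample
#' times in hours, `startCT()` the starting circadian time
#' (`times[1] %% 24`), `timeResolution()` the sampling resolution and
#' `exprScale()` whether values are `"log2"` or `"linear"`. Use
#' `SummarizedExperiment::assay()` for the expression matrix.
#'
#' @param x an [ExpressionSeries-class].
#' @name ExpressionSeries-accessors
#' @aliases seriesId sampleTimes startCT timeResolution exprScale
NULL

#' @rdname ExpressionSeries-accessors
#' @export
setMethod("seriesId", "ExpressionSeries", function(x) x@seriesId)

#' @rdname ExpressionSeries-accessors
#' @export
setMethod("sampleTimes", "ExpressionSeries",
          function(x) SummarizedExperiment::colData(x)$time)

#' @rdname ExpressionSeries-accessors
#' @export
setMethod("startCT", "ExpressionSeries",
          function(x) sampleTimes(x)[1] %% 24)

#' @rdname ExpressionSeries-accessors
#' @export
setMethod("timeResolution", "ExpressionSeries", function(x) x@resolution)

#' @rdname ExpressionSeries-accessors
#' @export
setMethod("exprScale", "ExpressionSeries", function(x) x@exprScale)

setMethod("show", "ExpressionSeries", function(object) {
    tm <- sampleTimes(object)
    cat(sprintf("ExpressionSeries '%s': %d probes x %d samples (%s scale)\n",
                seriesId(object), nrow(object), ncol(object),
                exprScale(object)))
    cat(sprintf("  start CT %g, resolution %g h, span %g h\n",
                startCT(object), timeResolution(object),
                if (length(tm)) diff(range(tm)) else 0))
})
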