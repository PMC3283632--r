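#' ExpressionSeries: a probe x timepoint expression matrix with circadian
#' metadata
#'
#' Extends \linkS4class{SummarizedExperiment}. Rows are probe sets, columns
#' are samples ordered by circadian time; sample times (hours, possibly
#' spanning several days) live in `colData()$time`. The series records its
#' identifier, starting circadian time (CT), sampling resolution and whether
#' values are on the log2 or linear scale.
#'
#' @slot seriesId single character identifier.
#' @slot resolution sampling resolution in hours.
#' @slot exprScale `"log2"` or `"linear"`.
#'
#' @aliases ExpressionSeries-class
#' @exportClass ExpressionSeries
.ExpressionSeries <- setClass(
    "ExpressionSeries",
    contains = "SummarizedExperiment",
    slots = c(
        seriesId = "character",
        resolution = "numeric",
        exprScale = "character"
    )
)

setValidity("ExpressionSeries", function(object) {
    msg <- character()
    if (length(object@seriesId) != 1L || is.na(object@seriesId))
        msg <- c(msg, "seriesId must be a single non-NA string")
    if (!"time" %in% colnames(SummarizedExperiment::colData(object)))
        msg <- c(msg, "colData must contain a 'time' column (hours)")
    else {
        tm <- SummarizedExperiment::colData(object)$time
        if (anyNA(tm) || !is.numeric(tm))
            msg <- c(msg, "sample times must be numeric and non-missing")
        else if (length(tm) > 1L && any(diff(tm) <= 0))
            msg <- c(msg, "sample times must be strictly increasing")
    }
    ids <- rownames(object)
    if (is.null(ids) && nrow(object) > 0L)
        msg <- c(msg, "probe ids (rownames) are required")
    if (!is.null(ids) && anyDuplicated(ids))
        msg <- c(msg, sprintf("duplicated probe id(s): %s",
                              paste(unique(ids[duplicated(ids)])[1:min(3, sum(duplicated(ids)))],
                                    collapse = ", ")))
    if (length(object@resolution) != 1L || !is.finite(object@resolution) ||
        object@resolution <= 0)
        msg <- c(msg, "resolution must be a single positive number of hours")
    if (length(object@exprScale) != 1L ||
        !object@exprScale %in% c("log2", "linear"))
        msg <- c(msg, "exprScale must be 'log2' or 'linear'")
    else if (object@exprScale == "linear" && nrow(object) > 0L &&
             any(SummarizedExperiment::assay(object) <= 0))
        msg <- c(msg, "linear-scale values must all be > 0")
    if (length(msg)) msg else TRUE
})

#' ScaledComparison: two series' probe-set averages on a common scale
#'
#' Holds the common probe set of a pairwise cross-series comparison, the
#' per-probe daily averages after overall-average scaling, the scaling
#' factors, the a:b fold ratios (linear scale) and the descending rank of
#' each ratio (ties broken by probe id).
#'
#' @slot probeIds common probe ids (order of the first series).
#' @slot scaledA,scaledB scaled per-probe daily averages (linear).
#' @slot factorA,factorB scaling factors applied to each side.
#' @slot ratios per-probe a:b fold ratios.
#' @slot ranks rank of each ratio when sorted descending.
#' @slot seriesIdA,seriesIdB identifiers of the two series.
#'
#' @aliases ScaledComparison-class
#' @exportClass ScaledComparison
.ScaledComparison <- setClass(
    "ScaledComparison",
    slots = c(
        probeIds = "character",
        scaledA = "numeric",
        scaledB = "numeric",
        factorA = "numeric",
        factorB = "numeric",
        ratios = "numeric",
        ranks = "integer",
        seriesIdA = "character",
        seriesIdB = "character"
    )
)

setValidity("ScaledComparison", function(object) {
    n <- length(object@probeIds)
    msg <- character()
    if (length(object@scaledA) != n || length(object@scaledB) != n ||
        length(object@ratios) != n || length(object@ranks) != n)
        msg <- c(msg, "probeIds, scaledA, scaledB, ratios, ranks must have equal length")
    if (anyDuplicated(object@probeIds))
        msg <- c(msg, "probe ids must be unique")
    if (n > 0L) {
        if (any(object@ratios <= 0))
            msg <- c(msg, "ratios must be positive")
        if (!setequal(object@ranks, seq_len(n)))
            msg <- c(msg, "ranks must be a permutation of 1..n")
        ma <- mean(object@scaledA); mb <- mean(object@scaledB)
        if (abs(ma - mb) > 1e-9 * max(ma, mb))
            msg <- c(msg, "scaled means must agree to 1e-9 relative tolerance")
    }
    if (length(msg)) msg else TRUE
})

#' ReferenceWaveSet: cosine reference waveforms over a lag grid
#'
#' Templates are cosines of a fixed period evaluated at the series' sample
#' times measured from the first sample (lag 0 peaks at the first sample).
#' Lags whose sampled template coincides with an earlier lag's are dropped.
#'
#' @slot period oscillation period in hours (24 by default).
#' @slot lags retained lag grid (hours).
#' @slot templates samples x lags matrix of sampled cosine values.
#' @slot times the relative sample times the templates were evaluated at.
#'
#' @aliases ReferenceWaveSet-class
#' @exportClass ReferenceWaveSet
.ReferenceWaveSet <- setClass(
    "ReferenceWaveSet",
    slots = c(
        period = "numeric",
        lags = "numeric",
        templates = "matrix",
        times = "numeric"
    )
)

setValidity("ReferenceWaveSet", function(object) {
    msg <- character()
    if (length(object@period) != 1L || object@period <= 0)
        msg <- c(msg, "period must be a single positive number")
    if (anyDuplicated(object@lags))
        msg <- c(msg, "lags must be unique")
    if (any(object@lags < 0) || any(object@lags >= object@period))
        msg <- c(msg, "lags must lie in [0, period)")
    if (nrow(object@templates) != length(object@times))
        msg <- c(msg, "templates must have one row per sample")
    if (ncol(object@templates) != length(object@lags))
        msg <- c(msg, "templates must have one column per lag")
    if (length(msg)) msg else TRUE
})

#' SyntheticConfig: parameters of the paired-platform simulator
#'
#' Describes two microarray "platforms" sharing a common probe subset,
#' one or more circadian sampling grids, planted stage-specific enrichment,
#' planted cosine rhythms, and i.i.d. Gaussian noise on the log2 scale.
#'
#' @slot nProbesA,nProbesB probes per platform.
#' @slot nCommon probes shared across platforms.
#' @slot series data.frame with one row per generated series: columns
#'   `series_id`, `start_ct` (hours in \[0,24)), `resolution` (hours),
#'   `n_samples`, `platform` ("a" or "b") and `offset` (a planted global
#'   log2 shift the scaling step must undo).
#' @slot nEnrichedUp,nEnrichedDown planted counts enriched in platform a /
#'   platform b.
#' @slot plantedLog2Fold planted log2 fold difference (log2 units).
#' @slot nRhythmic planted rhythmic probes.
#' @slot amplitude cosine amplitude (log2 units).
#' @slot phaseDistribution `"uniform"` or a numeric vector of allowed peak
#'   phases (hours CT).
#' @slot phaseShiftB phase offset (hours) added to rhythmic probes on
#'   platform-b series.
#' @slot noiseSd,baselineMean,baselineSd Gaussian noise and baseline
#'   parameters (log2 units).
#' @slot seed integer RNG seed.
#'
#' @aliases SyntheticConfig-class
#' @exportClass SyntheticConfig
.SyntheticConfig <- setClass(
    "SyntheticConfig",
    slots = c(
        nProbesA = "integer",
        nProbesB = "integer",
        nCommon = "integer",
        series = "data.frame",
        nEnrichedUp = "integer",
        nEnrichedDown = "integer",
        plantedLog2Fold = "numeric",
        nRhythmic = "integer",
        amplitude = "numeric",
        phaseDistribution = "ANY",
        phaseShiftB = "numeric",
        noiseSd = "numeric",
        baselineMean = "numeric",
        baselineSd = "numeric",
        seed = "integer"
    )
)

setValidity("SyntheticConfig", function(object) {
    msg <- character()
    if (object@nCommon > min(object@nProbesA, object@nProbesB))
        msg <- c(msg, "nCommon must be <= min(nProbesA, nProbesB)")
    if (object@nEnrichedUp + object@nEnrichedDown + object@nRhythmic >
        object@nCommon)
        msg <- c(msg, "nEnrichedUp + nEnrichedDown + nRhythmic must be <= nCommon")
    s <- object@series
    need <- c("series_id", "start_ct", "resolution", "n_samples", "platform",
              "offset")
    if (!all(need %in% names(s)))
        msg <- c(msg, sprintf("series table must have columns %s",
                              paste(need, collapse = ", ")))
    else {
        if (any(s$resolution <= 0))
            msg <- c(msg, "resolution must be > 0")
        if (any(s$n_samples < 4))
            msg <- c(msg, "n_samples must be >= 4")
        if (any(s$start_ct < 0 | s$start_ct >= 24))
            msg <- c(msg, "start_ct must lie in [0,24)")
        if (!all(s$platform %in% c("a", "b")))
            msg <- c(msg, "platform must be 'a' or 'b'")
        if (anyDuplicated(s$series_id))
            msg <- c(msg, "series_id must be unique")
    }
    if (object@noiseSd < 0)
        msg <- c(msg, "noiseSd must be >= 0")
    if (is.character(object@phaseDistribution)) {
        if (!identical(object@phaseDistribution, "uniform"))
            msg <- c(msg, "phaseDistribution must be 'uniform' or a numeric vector")
    } else if (is.numeric(object@phaseDistribution)) {
        if (any(object@phaseDistribution < 0 | object@phaseDistribution >= 24))
            msg <- c(msg, "fixed phases must lie in [0,24)")
    } else msg <- c(msg, "phaseDistribution must be 'uniform' or a numeric vector")
    if (length(msg)) msg else TRUE
})

#' SyntheticTruth: everything the simulator planted
#'
#' @slot enrichedUp,enrichedDown probe ids planted as enriched in platform a
#'   / platform b (disjoint).
#' @slot rhythmic data.frame `probe_id`, `phase` (hours CT in \[0,24)),
#'   `amplitude` (log2 units).
#' @slot seriesOffsets named numeric: the planted global log2 shift of each
#'   series, which overall-average scaling must undo.
#'
#' @aliases SyntheticTruth-class
#' @exportClass SyntheticTruth
.SyntheticTruth <- setClass(
    "SyntheticTruth",
    slots = c(
        enrichedUp = "character",
        enrichedDown = "character",
        rhythmic = "data.frame",
        seriesOffsets = "numeric"
    )
)

setValidity("SyntheticTruth", function(object) {
    msg <- character()
    ids <- list(object@enrichedUp, object@enrichedDown,
                object@rhythmic$probe_id)
    all_ids <- unlist(ids)
    if (anyDuplicated(all_ids))
        msg <- c(msg, "planted id sets must be disjoint")
    if (nrow(object@rhythmic) &&
        any(object@rhythmic$phase < 0 | object@rhythmic$phase >= 24))
        msg <- c(msg, "rhythmic phases must lie in [0,24)")
    if (length(msg)) msg else TRUE
})
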