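#' Intersect probe ids across series
#'
#' Returns the ids present in every series, in the order of the first
#' series. Cross-platform comparisons are restricted to this common set;
#' unmapped or control probes are retained as long as both platforms carry
#' them.
#'
#' @param seriesList list of two or more [ExpressionSeries-class] objects.
#' @return Character vector of common probe ids.
#' @export
intersectProbes <- function(seriesList) {
    stopifnot(is.list(seriesList), length(seriesList) >= 2L)
    common <- rownames(seriesList[[1]])
    for (s in seriesList[-1])
        common <- common[common %in% rownames(s)]
    if (!length(common))
        stop("no probe ids are shared by all series")
    common
}

#' Per-probe daily average expression on the linear scale
#'
#' The arithmetic mean across all time points of each probe, computed on the
#' LINEAR intensity scale: log2 input is exponentiated first, so a probe
#' with log2 values 1 and 3 averages to `(2 + 8)/2 = 5`, not `2^2 = 4`.
#' Fold language ("10-fold enriched") refers to ratios of these linear
#' daily averages.
#'
#' @param series an [ExpressionSeries-class].
#' @return A data.frame with columns `probe_id`, `mean` (linear scale) and
#'   attribute `n_timepoints`; the `series_id` attribute carries the source.
#' @export
dailyAverage <- function(series) {
    stopifnot(is(series, "ExpressionSeries"))
    if (nrow(series) == 0L) stop("series has no probes")
    m <- SummarizedExperiment::assay(series)
    lin <- if (exprScale(series) == "log2") 2^m else m
    out <- data.frame(probe_id = rownames(series),
                      mean = rowMeans(lin), stringsAsFactors = FALSE)
    attr(out, "n_timepoints") <- ncol(series)
    attr(out, "series_id") <- seriesId(series)
    out
}

#' Scale two series' probe-set averages to a common overall level
#'
#' Both platforms interrogate the bulk of the transcriptome, so their
#' overall averages over the common probe set are assumed equal. Each side's
#' probe-set averages are multiplied by `factor = target / overall`, with
#' `target` the geometric mean of the two overall averages (any positive
#' target cancels in the ratios). Fold ratios `scaled_a / scaled_b` and
#' their descending ranks (ties broken by probe id) are attached.
#'
#' @param avgA,avgB data.frames from [dailyAverage()].
#' @param common common probe ids (e.g. from [intersectProbes()]); must be a
#'   subset of both sides' probes.
#' @return A [ScaledComparison-class].
#' @export
scaleToCommonLevel <- function(avgA, avgB, common) {
    ia <- match(common, avgA$probe_id)
    ib <- match(common, avgB$probe_id)
    if (anyNA(ia) || anyNA(ib))
        stop("common probe ids must be present in both averages")
    a <- avgA$mean[ia]
    b <- avgB$mean[ib]
    if (any(a <= 0) || any(b <= 0))
        stop("probe-set averages must be positive (linear scale)")
    overall_a <- mean(a)
    overall_b <- mean(b)
    target <- sqrt(overall_a * overall_b)
    fa <- target / overall_a
    fb <- target / overall_b
    sa <- a * fa
    sb <- b * fb
    ratios <- sa / sb
    rk <- order(-ratios, common)          # descending; ties by probe id
    ranks <- integer(length(common))
    ranks[rk] <- seq_along(common)
    .ScaledComparison(probeIds = common, scaledA = sa, scaledB = sb,
                      factorA = fa, factorB = fb, ratios = ratios,
                      ranks = ranks,
                      seriesIdA = attr(avgA, "series_id") %||% "a",
                      seriesIdB = attr(avgB, "series_id") %||% "b")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @rdname ScaledComparison-accessors
#' @export
setMethod("probeIds", "ScaledComparison", function(x) x@probeIds)

#' Accessors for ScaledComparison
#'
#' `foldRatios()` returns the per-probe a:b fold ratios, `ratioRanks()`
#' their descending ranks, `scalingFactors()` the two factors and
#' `scaledAverages()` a data.frame of the scaled per-probe averages.
#'
#' @param x a [ScaledComparison-class].
#' @name ScaledComparison-accessors
#' @aliases probeIds foldRatios ratioRanks scalingFactors scaledAverages
NULL

#' @rdname ScaledComparison-accessors
#' @export
setMethod("foldRatios", "ScaledComparison",
          function(x) stats::setNames(x@ratios, x@probeIds))

#' @rdname ScaledComparison-accessors
#' @export
setMethod("ratioRanks", "ScaledComparison",
          function(x) stats::setNames(x@ranks, x@probeIds))

#' @rdname ScaledComparison-accessors
#' @export
setMethod("scalingFactors", "ScaledComparison",
          function(x) c(a = x@factorA, b = x@factorB))

#' @rdname ScaledComparison-accessors
#' @export
setMethod("scaledAverages", "ScaledComparison", function(x)
    data.frame(probe_id = x@probeIds, scaled_a = x@scaledA,
               scaled_b = x@scaledB, ratio = x@ratios, rank = x@ranks,
               stringsAsFactors = FALSE))

setMethod("show", "ScaledComparison", function(object) {
    cat(sprintf("ScaledComparison '%s' vs '%s': %d common probes\n",
                object@seriesIdA, object@seriesIdB,
                length(object@probeIds)))
    cat(sprintf("  scaling factors a=%.4g b=%.4g; ratio range [%.3g, %.3g]\n",
                object@factorA, object@factorB, min(object@ratios),
                max(object@ratios)))
})

#' Pearson correlation of log2 scaled averages
#'
#' Correlation between the two platforms' scaled probe-set averages on the
#' log2 scale (the conventional scale for microarray scatterplots).
#'
#' @param scaled a [ScaledComparison-class] with at least 3 probes.
#' @return Pearson r in \[-1, 1\].
#' @export
correlationLog <- function(scaled) {
    stopifnot(is(scaled, "ScaledComparison"))
    x <- log2(scaled@scaledA)
    y <- log2(scaled@scaledB)
    if (length(x) < 3L) stop("need at least 3 probes")
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
        stop("correlation undefined: constant log2 averages")
    stats::cor(x, y)
}

#' Derive an empirical enrichment threshold from a replicate comparison
#'
#' Replicate series of the same tissue should show no true enrichment, so
#' the largest fold difference seen between replicates bounds the technical
#' scatter. Symmetric folds `max(ratio, 1/ratio)` are sorted and the largest
#' `outlierAllowance` values are discarded; the maximum of the rest is the
#' threshold.
#'
#' @param replicateComparison a [ScaledComparison-class] built from two
#'   replicate series.
#' @param outlierAllowance number of extreme probes to ignore (default 0).
#' @return A fold threshold `>= 1`.
#' @export
deriveEmpiricalThreshold <- function(replicateComparison,
                                     outlierAllowance = 0L) {
    stopifnot(is(replicateComparison, "ScaledComparison"),
              outlierAllowance >= 0)
    r <- replicateComparison@ratios
    if (outlierAllowance >= length(r))
        stop("outlierAllowance must be smaller than the number of probes")
    folds <- sort(pmax(r, 1 / r), decreasing = TRUE)
    if (outlierAllowance > 0)
        folds <- folds[-seq_len(outlierAllowance)]
    max(folds)
}

#' Call probes enriched in one tissue across multiple comparisons
#'
#' A probe is `up_in_a` when its fold ratio is `>= threshold` in EVERY
#' comparison (the boundary is inclusive), `up_in_b` when the ratio is
#' `<= 1/threshold` in every comparison, otherwise `none`. With the default
#' replicate design this implements "commonly enriched" calls: the
#' intersection of per-replicate enrichment.
#'
#' @param comparisons list of [ScaledComparison-class] sharing the same
#'   probe universe (and reference side b).
#' @param threshold fold threshold `> 1` (default 10).
#' @return A data.frame `probe_id`, `direction`
#'   (`up_in_a`/`up_in_b`/`none`), plus one `ratio_<i>` column per
#'   comparison.
#' @export
callEnriched <- function(comparisons, threshold = 10) {
    if (is(comparisons, "ScaledComparison"))
        comparisons <- list(comparisons)
    stopifnot(length(comparisons) >= 1L, threshold > 1)
    ids <- comparisons[[1]]@probeIds
    for (cmp in comparisons[-1])
        if (!identical(sort(cmp@probeIds), sort(ids)))
            stop("comparisons do not share the same probe universe")
    ratio_mat <- vapply(comparisons,
                        function(cmp) cmp@ratios[match(ids, cmp@probeIds)],
                        numeric(length(ids)))
    ratio_mat <- matrix(ratio_mat, nrow = length(ids))
    up_a <- rowSums(ratio_mat >= threshold) == ncol(ratio_mat)
    up_b <- rowSums(ratio_mat <= 1 / threshold) == ncol(ratio_mat)
    direction <- ifelse(up_a, "up_in_a", ifelse(up_b, "up_in_b", "none"))
    out <- data.frame(probe_id = ids, direction = direction,
                      stringsAsFactors = FALSE)
    colnames(ratio_mat) <- sprintf("ratio_%d", seq_len(ncol(ratio_mat)))
    cbind(out, as.data.frame(ratio_mat))
}

#' Convert an RT-PCR delta-Ct to a fold difference
#'
#' `fold = (1 + efficiency)^(-deltaCt)` with
#' `deltaCt = Ct_target - Ct_reference`; at the ideal amplification
#' efficiency of 1.0 each cycle is a doubling, so `fold = 2^(-deltaCt)`.
#'
#' @param deltaCt difference in threshold cycles.
#' @param efficiency amplification efficiency in (0, 1\]; default 1.0.
#' @return Fold difference (vectorized over `deltaCt`).
#' @examples
#' deltaCtToFold(-1)        # one cycle earlier: 2-fold
#' deltaCtToFold(1, 0.9)    # 1.9^-1
#' @export
deltaCtToFold <- function(deltaCt, efficiency = 1.0) {
    if (length(efficiency) != 1L || !is.finite(efficiency) ||
        efficiency <= 0 || efficiency > 1)
        stop("efficiency must lie in (0, 1]")
    (1 + efficiency)^(-deltaCt)
}
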