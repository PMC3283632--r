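#' Configure the paired-platform circadian simulator
#'
#' The defaults emulate the study design the package targets: two fetal-style
#' replicate series on platform "a" (12 time points at 4 h resolution,
#' starting at CT2) and one adult-style reference series on platform "b"
#' (48 time points at 1 h resolution, starting at CT18), sharing `nCommon`
#' probe ids across platforms. Planted effects live on common probes:
#' `nEnrichedUp` probes carry `plantedLog2Fold` extra log2 units on platform
#' "a", `nEnrichedDown` on platform "b", and `nRhythmic` probes oscillate as
#' `amplitude * cos(2*pi*(t - phase)/24)` in circadian time. Platform-b
#' series carry a planted global `offset` (+1 log2 by default) so
#' overall-average scaling is exercised non-trivially. Noise is i.i.d.
#' Gaussian on the log2 scale (multiplicative on the linear scale).
#'
#' @param nProbesA,nProbesB probes per platform.
#' @param nCommon shared probes (`<= min(nProbesA, nProbesB)`).
#' @param series data.frame describing the series to generate (see
#'   [SyntheticConfig-class]); the default is the two-fetal-plus-adult
#'   design above.
#' @param nEnrichedUp,nEnrichedDown planted enrichment counts.
#' @param plantedLog2Fold planted log2 fold difference.
#' @param nRhythmic planted rhythmic probes.
#' @param amplitude cosine amplitude, log2 units.
#' @param phaseDistribution `"uniform"` for phases uniform on \[0,24), or a
#'   numeric vector of allowed phases (sampled from, or used directly when
#'   its length equals `nRhythmic`).
#' @param phaseShiftB phase offset (hours) added on platform-b series.
#' @param noiseSd Gaussian noise SD, log2 units.
#' @param baselineMean,baselineSd per-probe baseline distribution, log2.
#' @param seed integer RNG seed.
#' @return A validated [SyntheticConfig-class].
#' @export
syntheticConfig <- function(nProbesA = 2000, nProbesB = 2000, nCommon = 1500,
                            series = NULL,
                            nEnrichedUp = 50, nEnrichedDown = 50,
                            plantedLog2Fold = 4.5,
                            nRhythmic = 100, amplitude = 2,
                            phaseDistribution = "uniform",
                            phaseShiftB = 0,
                            noiseSd = 0.25, baselineMean = 7,
                            baselineSd = 1.5, seed = 1L) {
    if (is.null(series))
        series <- data.frame(
            series_id = c("fetal1", "fetal2", "adult"),
            start_ct = c(2, 2, 18),
            resolution = c(4, 4, 1),
            n_samples = c(12L, 12L, 48L),
            platform = c("a", "a", "b"),
            offset = c(0, 0, 1),
            stringsAsFactors = FALSE)
    cfg <- .SyntheticConfig(
        nProbesA = as.integer(nProbesA), nProbesB = as.integer(nProbesB),
        nCommon = as.integer(nCommon), series = series,
        nEnrichedUp = as.integer(nEnrichedUp),
        nEnrichedDown = as.integer(nEnrichedDown),
        plantedLog2Fold = as.numeric(plantedLog2Fold),
        nRhythmic = as.integer(nRhythmic),
        amplitude = as.numeric(amplitude),
        phaseDistribution = phaseDistribution,
        phaseShiftB = as.numeric(phaseShiftB),
        noiseSd = as.numeric(noiseSd),
        baselineMean = as.numeric(baselineMean),
        baselineSd = as.numeric(baselineSd),
        seed = as.integer(seed))
    msg <- validObject(cfg, test = TRUE)
    if (is.character(msg))
        stop(sprintf("invalid synthetic configuration: %s",
                     paste(msg, collapse = "; ")))
    cfg
}

setMethod("show", "SyntheticConfig", function(object) {
    cat(sprintf(
        "SyntheticConfig: %d/%d probes (platform a/b), %d common\n",
        object@nProbesA, object@nProbesB, object@nCommon))
    cat(sprintf("  planted: %d up + %d down at %.3g log2-fold; %d rhythmic (amp %.3g)\n",
                object@nEnrichedUp, object@nEnrichedDown,
                object@plantedLog2Fold, object@nRhythmic, object@amplitude))
    cat(sprintf("  noise sd %.3g log2; seed %d; %d series\n",
                object@noiseSd, object@seed, nrow(object@series)))
})

setMethod("show", "SyntheticTruth", function(object) {
    cat(sprintf(
        "SyntheticTruth: %d up, %d down, %d rhythmic; offsets: %s\n",
        length(object@enrichedUp), length(object@enrichedDown),
        nrow(object@rhythmic),
        paste(sprintf("%s=%+g", names(object@seriesOffsets),
                      object@seriesOffsets), collapse = ", ")))
})

#' Generate paired-platform circadian expression series with planted truth
#'
#' Each configured series gets a log2 expression matrix
#' `baseline + planted fold (on the designated platform) +
#' amplitude*cos(2*pi*(t - phase)/24) + global offset + N(0, noiseSd)`
#' over its circadian time grid. Common probes share ids (and baselines)
#' across platforms; platform-private probes get independent baselines so
#' the probe-intersection step is exercised. Identical seeds give
#' bit-identical output.
#'
#' @param config a [SyntheticConfig-class] from [syntheticConfig()].
#' @return A list with `series` (list of [ExpressionSeries-class], named by
#'   series id) and `truth` (a [SyntheticTruth-class]).
#' @examples
#' cfg <- syntheticConfig(nProbesA = 60, nProbesB = 60, nCommon = 50,
#'                        nEnrichedUp = 5, nEnrichedDown = 5, nRhythmic = 5,
#'                        noiseSd = 0, seed = 7)
#' sim <- generatePairedSeries(cfg)
#' sim$truth
#' @export
generatePairedSeries <- function(config) {
    stopifnot(is(config, "SyntheticConfig"))
    msg <- validObject(config, test = TRUE)
    if (is.character(msg))
        stop(sprintf("invalid synthetic configuration: %s",
                     paste(msg, collapse = "; ")))
    set.seed(config@seed)

    common_ids <- sprintf("cmn_%05d", seq_len(config@nCommon))
    a_only <- sprintf("pa_%05d", seq_len(config@nProbesA - config@nCommon))
    b_only <- sprintf("pb_%05d", seq_len(config@nProbesB - config@nCommon))
    ids_a <- c(common_ids, a_only)
    ids_b <- c(common_ids, b_only)

    # planted roles drawn from the common set
    n_plant <- config@nEnrichedUp + config@nEnrichedDown + config@nRhythmic
    planted <- if (n_plant) sample(common_ids, n_plant) else character()
    up_ids <- planted[seq_len(config@nEnrichedUp)]
    down_ids <- planted[config@nEnrichedUp + seq_len(config@nEnrichedDown)]
    rhy_ids <- planted[config@nEnrichedUp + config@nEnrichedDown +
                           seq_len(config@nRhythmic)]

    phases <- if (is.numeric(config@phaseDistribution)) {
        grid <- config@phaseDistribution
        if (length(grid) == config@nRhythmic) grid
        else grid[sample.int(length(grid), config@nRhythmic, replace = TRUE)]
    } else {
        stats::runif(config@nRhythmic, 0, 24)
    }

    base_common <- stats::rnorm(config@nCommon, config@baselineMean,
                                config@baselineSd)
    base_a_only <- stats::rnorm(length(a_only), config@baselineMean,
                                config@baselineSd)
    base_b_only <- stats::rnorm(length(b_only), config@baselineMean,
                                config@baselineSd)

    tab <- config@series
    out <- vector("list", nrow(tab))
    names(out) <- tab$series_id
    for (s in seq_len(nrow(tab))) {
        platform <- tab$platform[s]
        ids <- if (platform == "a") ids_a else ids_b
        base <- if (platform == "a") c(base_common, base_a_only)
                else c(base_common, base_b_only)
        times <- tab$start_ct[s] + tab$resolution[s] *
            (seq_len(tab$n_samples[s]) - 1L)
        m <- matrix(base, nrow = length(ids), ncol = length(times))
        fold_ids <- if (platform == "a") up_ids else down_ids
        m[match(fold_ids, ids), ] <- m[match(fold_ids, ids), ] +
            config@plantedLog2Fold
        if (length(rhy_ids)) {
            ph <- phases + if (platform == "b") config@phaseShiftB else 0
            osc <- config@amplitude *
                cos(2 * pi * outer(ph, times, function(p, t) t - p) / 24)
            m[match(rhy_ids, ids), ] <- m[match(rhy_ids, ids), ] + osc
        }
        m <- m + tab$offset[s]
        if (config@noiseSd > 0)
            m <- m + stats::rnorm(length(m), 0, config@noiseSd)
        out[[s]] <- ExpressionSeries(m, probeIds = ids, times = times,
                                     seriesId = tab$series_id[s],
                                     resolution = tab$resolution[s],
                                     scale = "log2")
    }

    truth <- .SyntheticTruth(
        enrichedUp = up_ids, enrichedDown = down_ids,
        rhythmic = data.frame(probe_id = rhy_ids,
                              phase = phases %% 24,
                              amplitude = rep(config@amplitude,
                                              length(rhy_ids)),
                              stringsAsFactors = FALSE),
        seriesOffsets = stats::setNames(tab$offset, tab$series_id))
    validObject(truth)
    list(series = out, truth = truth)
}

#' Confusion counts of calls against planted truth
#'
#' @param called probe ids called positive (enriched or rhythmic).
#' @param truthIds probe ids planted positive.
#' @param universe all evaluated probe ids; `called` and `truthIds` must be
#'   subsets of it.
#' @return Named integer vector `TP`, `FP`, `TN`, `FN`; the four counts sum
#'   to `length(universe)`.
#' @export
truthConfusion <- function(called, truthIds, universe) {
    if (anyDuplicated(universe))
        stop("probe universe contains duplicated ids")
    if (!all(called %in% universe))
        stop("calls refer to probes outside the evaluated universe")
    if (!all(truthIds %in% universe))
        stop("truth refers to probes outside the evaluated universe")
    pos <- universe %in% called
    tru <- universe %in% truthIds
    c(TP = sum(pos & tru), FP = sum(pos & !tru),
      TN = sum(!pos & !tru), FN = sum(!pos & tru))
}

#' Write planted truth as a TSV sidecar
#'
#' One row per planted probe: `probe_id`, `role`
#' (`enriched_up`/`enriched_down`/`rhythmic`), `phase`, `amplitude`,
#' `log2fold` (empty where not applicable).
#'
#' @param truth a [SyntheticTruth-class].
#' @param path output file.
#' @param log2Fold the planted fold to record for enriched probes.
#' @return `path`, invisibly.
#' @export
writeTruthTSV <- function(truth, path, log2Fold = NA_real_) {
    stopifnot(is(truth, "SyntheticTruth"))
    block <- function(ids, role, phase = NA_real_, amplitude = NA_real_,
                      fold = NA_real_) {
        n <- length(ids)
        data.frame(probe_id = ids, role = rep(role, n),
                   phase = rep_len(phase, n),
                   amplitude = rep_len(amplitude, n),
                   log2fold = rep_len(fold, n), stringsAsFactors = FALSE)
    }
    df <- rbind(
        block(truth@enrichedUp, "enriched_up", fold = log2Fold),
        block(truth@enrichedDown, "enriched_down", fold = log2Fold),
        block(truth@rhythmic$probe_id, "rhythmic",
              phase = truth@rhythmic$phase,
              amplitude = truth@rhythmic$amplitude))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "")
    invisible(path)
}
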