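.pipelineDefaults <- function() {
    list(
        synthetic = list(),        # arguments to syntheticConfig()
        series_paths = NULL,       # or a data.frame: path, start_ct,
                                   # resolution, platform
        threshold = 10,            # fold-enrichment cutoff (inclusive)
        outlier_allowance = 0,     # extreme probes ignored when deriving
                                   # the empirical threshold
        p_cut = 0.1,               # rhythmicity rule for short series
        q_cut = 0.1,               # rhythmicity rule for dense series
        period = 24,               # hours
        lag_step = NULL,           # default: each series' resolution
        seed = 1,
        out_dir = "crossclock_out")
}

#' Validate a pipeline configuration
#'
#' Applies defaults, rejects unknown keys (typo safety) and checks the
#' invariants: `threshold > 1`, `period > 0`, `p_cut` and `q_cut` in (0,1).
#'
#' @param raw a named list, or the path of a YAML file holding one. An
#'   empty document yields the all-defaults configuration.
#' @return The validated configuration list.
#' @export
validatePipelineConfig <- function(raw = list()) {
    if (is.character(raw) && length(raw) == 1L)
        raw <- yaml::read_yaml(raw)
    if (is.null(raw)) raw <- list()
    if (!is.list(raw)) stop("configuration must be a named list")
    defaults <- .pipelineDefaults()
    unknown <- setdiff(names(raw), names(defaults))
    if (length(unknown))
        stop(sprintf("unknown configuration key(s): %s",
                     paste(unknown, collapse = ", ")))
    cfg <- utils::modifyList(defaults, raw)
    if (!is.numeric(cfg$threshold) || cfg$threshold <= 1)
        stop("threshold must be > 1")
    if (cfg$period <= 0) stop("period must be > 0")
    for (k in c("p_cut", "q_cut"))
        if (cfg[[k]] <= 0 || cfg[[k]] >= 1)
            stop(sprintf("%s must lie in (0,1)", k))
    if (cfg$outlier_allowance < 0)
        stop("outlier_allowance must be >= 0")
    cfg$seed <- as.integer(cfg$seed)
    cfg
}

# one deterministic RNG substream per stage, all derived from the config
# seed so stages can be rerun independently
.substreamSeed <- function(seed, stage) {
    off <- c(simulate = 101L, rhythm = 211L, phases = 307L)[[stage]]
    as.integer((as.numeric(seed) * 7919 + off) %% .Machine$integer.max)
}

.stage <- function(name, expr) {
    t0 <- Sys.time()
    message(sprintf("[crossclock] stage %s ...", name))
    out <- tryCatch(expr, error = function(e)
        stop(sprintf("stage %s failed: %s", name, conditionMessage(e)),
             call. = FALSE))
    message(sprintf("[crossclock] stage %s done (%.2fs)", name,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    out
}

#' Run the full comparison pipeline
#'
#' simulate (or load) -> cross-platform comparison and enrichment calls ->
#' rhythmicity scans -> phase agreement, writing every result as TSV plus a
#' JSON manifest recording parameters, seed, output paths and summary
#' counts. Identical configuration and seed reproduce every output file
#' byte-identically.
#'
#' @param config a configuration list or YAML path (see
#'   [validatePipelineConfig()]).
#' @return The manifest, invisibly (also written to
#'   `<out_dir>/manifest.json`).
#' @export
runPipeline <- function(config = list()) {
    cfg <- validatePipelineConfig(config)
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    outfile <- function(...) file.path(cfg$out_dir, ...)
    outputs <- list()

    truth <- NULL
    if (is.null(cfg$series_paths)) {
        sim <- .stage("simulate", {
            args <- cfg$synthetic
            args$seed <- .substreamSeed(cfg$seed, "simulate")
            gen <- do.call(syntheticConfig, args)
            c(generatePairedSeries(gen), list(design = gen@series))
        })
        series <- sim$series
        truth <- sim$truth
        for (id in names(series)) {
            f <- outfile(sprintf("series_%s.tsv", id))
            writeMatrixTSV(series[[id]], f)
            outputs[[sprintf("series_%s", id)]] <- f
        }
        writeTruthTSV(truth, outfile("truth.tsv"))
        outputs$truth <- outfile("truth.tsv")
        platforms <- stats::setNames(sim$design$platform, names(series))
        start_cts <- vapply(series, startCT, numeric(1))
    } else {
        sp <- cfg$series_paths
        series <- .stage("load", {
            out <- lapply(seq_len(nrow(sp)), function(i)
                readMatrixTSV(sp$path[i], startCt = sp$start_ct[i],
                              resolution = sp$resolution[i]))
            stats::setNames(out, vapply(out, seriesId, character(1)))
        })
        platforms <- stats::setNames(sp$platform, names(series))
        start_cts <- vapply(series, startCT, numeric(1))
    }
    a_ids <- names(series)[platforms == "a"]
    b_ids <- names(series)[platforms == "b"]
    if (!length(a_ids) || !length(b_ids))
        stop("need at least one platform-a and one platform-b series")
    ref <- b_ids[1]

    cmp <- .stage("compare", {
        common <- intersectProbes(series)
        avgs <- lapply(series, dailyAverage)
        scaled <- lapply(a_ids, function(id)
            scaleToCommonLevel(avgs[[id]], avgs[[ref]], common))
        names(scaled) <- a_ids
        for (id in a_ids) {
            f <- outfile(sprintf("scaled_%s_vs_%s.tsv", id, ref))
            utils::write.table(scaledAverages(scaled[[id]]), f, sep = "\t",
                               quote = FALSE, row.names = FALSE)
            outputs[[sprintf("scaled_%s", id)]] <- f
        }
        empirical <- if (length(a_ids) >= 2L) {
            rep_cmp <- scaleToCommonLevel(avgs[[a_ids[1]]],
                                          avgs[[a_ids[2]]], common)
            deriveEmpiricalThreshold(rep_cmp,
                                     outlierAllowance =
                                         cfg$outlier_allowance)
        } else NA_real_
        calls <- callEnriched(unname(scaled), threshold = cfg$threshold)
        f <- outfile("enrichment_calls.tsv")
        utils::write.table(calls, f, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        outputs$enrichment_calls <- f
        list(calls = calls, empirical_threshold = empirical,
             n_common = length(common))
    })

    scans <- .stage("rhythm", {
        set.seed(.substreamSeed(cfg$seed, "rhythm"))
        out <- lapply(names(series), function(id) {
            s <- series[[id]]
            waves <- buildReferenceWaves(
                sampleTimes(s), period = cfg$period,
                lagStep = cfg$lag_step %||% timeResolution(s))
            res <- jtkScan(s, waves)
            f <- outfile(sprintf("rhythm_%s.tsv", id))
            utils::write.table(res, f, sep = "\t", quote = FALSE,
                               row.names = FALSE)
            outputs[[sprintf("rhythm_%s", id)]] <<- f
            res
        })
        stats::setNames(out, names(series))
    })

    phases <- .stage("phases", {
        pa <- commonRhythmic(scans[[a_ids[1]]], scans[[ref]],
                             start_cts[[a_ids[1]]], start_cts[[ref]],
                             ruleA = list(stat = "p", cutoff = cfg$p_cut),
                             ruleB = list(stat = "q", cutoff = cfg$q_cut))
        f <- outfile("phases.tsv")
        utils::write.table(pa, f, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        outputs$phases <- f
        assoc <- if (nrow(pa) >= 4L &&
                     stats::sd(pa$phase_a) > 0 && stats::sd(pa$phase_b) > 0) {
            cc <- circularCorrelation(pa$phase_a, pa$phase_b,
                                      units = "hours")
            list(linear_r = linearPhaseCorrelation(pa),
                 circular_r = cc$rho, p_circular = cc$p_value)
        } else list(linear_r = NA, circular_r = NA, p_circular = NA)
        c(list(n_common_rhythmic = nrow(pa)), assoc)
    })

    counts <- table(factor(cmp$calls$direction,
                           levels = c("up_in_a", "up_in_b", "none")))
    manifest <- list(
        parameters = cfg[c("threshold", "outlier_allowance", "p_cut",
                           "q_cut", "period")],
        seed = cfg$seed,
        outputs = lapply(outputs, as.character),
        summary = c(list(
            n_common_probes = cmp$n_common,
            empirical_threshold = cmp$empirical_threshold,
            n_up_in_a = as.integer(counts[["up_in_a"]]),
            n_up_in_b = as.integer(counts[["up_in_b"]]),
            n_not_enriched = as.integer(counts[["none"]])), phases))
    jsonlite::write_json(manifest, outfile("manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         na = "null")
    outputs$manifest <- outfile("manifest.json")
    invisible(manifest)
}
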