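#' Read an expression matrix from TSV
#'
#' The dialect is UTF-8, tab-delimited, header `probe_id<TAB>t<h1><TAB>...`
#' where each remaining header field names a sample time in hours (a number,
#' optionally prefixed with `t`). If the header carries labels that are not
#' times, supply `times` (or `startCt` plus `resolution`) explicitly.
#'
#' @param path file to read.
#' @param times optional numeric sample times overriding the header.
#' @param startCt,resolution optional: construct the time grid
#'   `startCt + resolution * (0:(k-1))` when the header has no parseable
#'   times and `times` is not given.
#' @param scale `"log2"` (default) or `"linear"`.
#' @param seriesId identifier for the returned series; defaults to the file
#'   name without extension.
#'
#' @return An [ExpressionSeries-class].
#' @seealso [writeMatrixTSV()], [readGEOSeriesMatrix()]
#' @export
readMatrixTSV <- function(path, times = NULL, startCt = NULL,
                          resolution = NULL, scale = c("log2", "linear"),
                          seriesId = NULL) {
    scale <- match.arg(scale)
    if (!file.exists(path)) stop(sprintf("file not found: %s", path))
    lines <- readLines(path, encoding = "UTF-8")
    if (!length(lines)) stop(sprintf("%s: empty file", path))
    header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
    ncol_expected <- length(header)
    k <- ncol_expected - 1L
    body <- lines[-1]
    body <- body[nzchar(body)]
    n <- length(body)
    ids <- character(n)
    vals <- if (n) matrix(NA_real_, n, k) else matrix(numeric(0), 0, k)
    for (i in seq_len(n)) {
        fields <- strsplit(body[[i]], "\t", fixed = TRUE)[[1]]
        if (length(fields) != ncol_expected)
            stop(sprintf("%s line %d: expected %d fields, found %d",
                         path, i + 1L, ncol_expected, length(fields)))
        ids[i] <- fields[1]
        v <- suppressWarnings(as.numeric(fields[-1]))
        if (anyNA(v))
            stop(sprintf("%s line %d: non-numeric expression value", path,
                         i + 1L))
        vals[i, ] <- v
    }
    if (anyDuplicated(ids))
        stop(sprintf("%s: duplicated probe id '%s'", path,
                     ids[duplicated(ids)][1]))
    if (is.null(times)) {
        parsed <- suppressWarnings(as.numeric(sub("^t", "", header[-1])))
        if (k > 0 && !anyNA(parsed)) {
            times <- parsed
        } else if (!is.null(startCt) && !is.null(resolution)) {
            times <- startCt + resolution * (seq_len(k) - 1L)
        } else {
            stop(sprintf("%s: header does not give sample times; supply times= or startCt=/resolution=",
                         path))
        }
    }
    if (is.null(seriesId))
        seriesId <- sub("\\.[^.]*$", "", basename(path))
    ExpressionSeries(vals, probeIds = ids, times = times,
                     seriesId = seriesId, resolution = resolution,
                     scale = scale)
}

#' Write an expression series as canonical TSV
#'
#' Deterministic output: header `probe_id` then `t<time>` per sample, values
#' printed with 15 significant digits so a write/read round trip is the
#' identity to floating-point text precision.
#'
#' @param series an [ExpressionSeries-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeMatrixTSV <- function(series, path) {
    stopifnot(is(series, "ExpressionSeries"))
    tm <- sampleTimes(series)
    header <- paste(c("probe_id", sprintf("t%.15g", tm)), collapse = "\t")
    m <- SummarizedExperiment::assay(series)
    rows <- if (nrow(m)) {
        txt <- matrix(sprintf("%.15g", m), nrow = nrow(m))
        paste(rownames(m), apply(txt, 1L, paste, collapse = "\t"), sep = "\t")
    } else character()
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines(c(header, rows), con, sep = "\n")
    invisible(path)
}

#' Read a GEO Series Matrix file
#'
#' Parses the NCBI GEO Series Matrix dialect: metadata lines prefixed `!`,
#' with the expression table delimited by `!series_matrix_table_begin` /
#' `!series_matrix_table_end` and probe ids in the `ID_REF` column. Values
#' are taken as provided (assumed already normalized, log2 scale); sample
#' order is preserved. The deposit rarely states circadian times, so the
#' grid is constructed from `startCt` and `resolution`.
#'
#' @param path Series Matrix file.
#' @param startCt circadian time (hours in \[0,24)) of the first sample.
#' @param resolution sampling resolution in hours.
#' @param seriesId identifier; defaults to the file name without extension.
#' @return An [ExpressionSeries-class].
#' @export
readGEOSeriesMatrix <- function(path, startCt, resolution, seriesId = NULL) {
    if (!file.exists(path)) stop(sprintf("file not found: %s", path))
    lines <- readLines(path, encoding = "UTF-8")
    beg <- grep("^!series_matrix_table_begin", lines, ignore.case = TRUE)
    end <- grep("^!series_matrix_table_end", lines, ignore.case = TRUE)
    if (length(beg) != 1L || length(end) != 1L || end <= beg + 1L)
        stop(sprintf("%s: missing !series_matrix_table_begin/_end delimiters",
                     path))
    tbl <- lines[(beg + 1L):(end - 1L)]
    unquote <- function(x) gsub('^"|"$', "", x)
    header <- unquote(strsplit(tbl[[1]], "\t", fixed = TRUE)[[1]])
    if (toupper(header[1]) != "ID_REF")
        stop(sprintf("%s: table header must start with ID_REF", path))
    k <- length(header) - 1L
    body <- tbl[-1]
    n <- length(body)
    ids <- character(n)
    vals <- matrix(NA_real_, n, k)
    for (i in seq_len(n)) {
        fields <- unquote(strsplit(body[[i]], "\t", fixed = TRUE)[[1]])
        if (length(fields) != k + 1L)
            stop(sprintf("%s table row %d: expected %d fields, found %d",
                         path, i, k + 1L, length(fields)))
        ids[i] <- fields[1]
        v <- suppressWarnings(as.numeric(fields[-1]))
        if (anyNA(v))
            stop(sprintf("%s table row %d: non-numeric value", path, i))
        vals[i, ] <- v
    }
    if (anyDuplicated(ids))
        stop(sprintf("%s: duplicated probe id '%s'", path,
                     ids[duplicated(ids)][1]))
    if (is.null(seriesId))
        seriesId <- sub("\\.[^.]*$", "", basename(path))
    times <- startCt + resolution * (seq_len(k) - 1L)
    ExpressionSeries(vals, probeIds = ids, times = times,
                     seriesId = seriesId, resolution = resolution,
                     scale = "log2")
}

#' Split a multi-day series into first and last day
#'
#' Returns the sub-series of samples inside the first `dayLength`-hour
#' window and inside the last `dayLength`-hour window. For a 48-sample
#' hourly series these are the first and last 24 samples; shorter series
#' give overlapping windows, and a series whose total duration does not
#' exceed `dayLength` (both windows identical) is an error.
#'
#' @param series an [ExpressionSeries-class].
#' @param dayLength window length in hours (default 24).
#' @return A list of two [ExpressionSeries-class] objects, `first` and
#'   `last`.
#' @export
splitDays <- function(series, dayLength = 24) {
    stopifnot(is(series, "ExpressionSeries"), dayLength > 0)
    tm <- sampleTimes(series)
    duration <- diff(range(tm)) + timeResolution(series)
    if (duration <= dayLength)
        stop(sprintf("series duration (%g h) does not exceed the %g h window; cannot split",
                     duration, dayLength))
    first_idx <- which(tm < tm[1] + dayLength)
    last_idx <- which(tm > tm[length(tm)] - dayLength)
    sub <- function(idx, tag) {
        ExpressionSeries(SummarizedExperiment::assay(series)[, idx,
                                                             drop = FALSE],
                         probeIds = rownames(series), times = tm[idx],
                         seriesId = paste0(seriesId(series), tag),
                         resolution = timeResolution(series),
                         scale = exprScale(series))
    }
    list(first = sub(first_idx, "_day1"), last = sub(last_idx, "_day2"))
}
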