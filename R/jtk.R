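#' Build cosine reference waveforms over a lag grid
#'
#' One template per lag in `{0, lagStep, ..., period - lagStep}`, each the
#' cosine `cos(2*pi*(t - lag)/period)` evaluated at the series' sample times
#' measured from the first sample (so lag 0 peaks at the first sample, and a
#' best-fitting lag is hours-after-series-start of the expression peak).
#' Sampled values are rounded to 9 decimals so mathematically tied values
#' (the cosine sampled on a coarse grid repeats values exactly) compare
#' equal; lags whose sampled template duplicates an earlier lag's are
#' dropped.
#'
#' @param times sample times in hours (the series' times; only differences
#'   from the first sample matter).
#' @param period oscillation period in hours, fixed at 24 by default.
#' @param lagStep lag grid spacing in hours; must divide `period`. Defaults
#'   to the sampling resolution implied by `times`.
#' @return A [ReferenceWaveSet-class].
#' @examples
#' buildReferenceWaves(seq(0, 44, by = 4))   # 6 distinct templates
#' @export
buildReferenceWaves <- function(times, period = 24, lagStep = NULL) {
    if (length(times) < 4L)
        stop("need at least 4 samples to scan for rhythmicity")
    if (any(diff(times) <= 0))
        stop("times must be strictly increasing")
    if (is.null(lagStep)) lagStep <- stats::median(diff(times))
    ratio <- period / lagStep
    if (abs(ratio - round(ratio)) > 1e-9)
        stop(sprintf("lagStep (%g) must divide the period (%g)", lagStep,
                     period))
    rel <- times - times[1]
    lags <- seq(0, period - lagStep, by = lagStep)
    tpl <- vapply(lags, function(l) round(cos(2 * pi * (rel - l) / period),
                                          9),
                  numeric(length(rel)))
    tpl <- matrix(tpl, nrow = length(rel))
    keep <- !duplicated(lapply(seq_along(lags), function(j) tpl[, j]))
    .ReferenceWaveSet(period = period, lags = lags[keep],
                      templates = tpl[, keep, drop = FALSE], times = rel)
}

setMethod("show", "ReferenceWaveSet", function(object) {
    cat(sprintf(
        "ReferenceWaveSet: period %g h, %d distinct lags (step %g h), %d samples\n",
        object@period, length(object@lags),
        if (length(object@lags) > 1) diff(object@lags[1:2]) else NA,
        length(object@times)))
})

#' Kendall S statistic between data and a reference template
#'
#' `S = sum over pairs i < j of sign(x_j - x_i) * sign(y_j - y_i)`: the
#' number of concordant minus discordant pairs. Pairs tied in either vector
#' contribute zero.
#'
#' @param x,y numeric vectors of equal length (>= 2).
#' @return Integer S.
#' @export
kendallS <- function(x, y) {
    if (length(x) != length(y)) stop("x and y must have equal length")
    if (length(x) < 2L) stop("need at least 2 observations")
    dx <- sign(outer(x, x, "-"))
    dy <- sign(outer(y, y, "-"))
    ut <- upper.tri(dx)
    as.integer(sum(dx[ut] * dy[ut]))
}

# Exact null distribution of S against a fixed (possibly tied) template,
# for untied exchangeable data. Sorting samples by template value gives
# ordered tie groups of sizes m_1..m_g; only cross-group pairs contribute,
# so S = 2U - M with M the number of cross-group pairs and U a
# Jonckheere-Terpstra-type count. Under a uniform random ordering U is the
# independent sum of Mann-Whitney counts of group l against all earlier
# groups, each with the Gaussian-binomial distribution [N_{l-1}+m_l, m_l]_q;
# the full pmf follows by convolution (Harding's algorithm).
.qbinomialCounts <- function(a, b) {
    # coefficient vector of the Gaussian binomial [a+b, b]_q, degrees 0..a*b
    L <- a * b
    co <- numeric(L + 1)
    co[1] <- 1
    if (L == 0L) return(co)
    for (i in seq_len(b)) {
        if (a + i <= L)
            co[(a + i + 1):(L + 1)] <- co[(a + i + 1):(L + 1)] -
                co[1:(L - a - i + 1)]
        if (i <= L)
            for (u in i:L) co[u + 1] <- co[u + 1] + co[u + 1 - i]
    }
    co
}

.jtkNullDist <- function(template) {
    sizes <- as.integer(table(factor(template, levels = sort(unique(template)))))
    n <- sum(sizes)
    M <- (n * (n - 1L) - sum(sizes * (sizes - 1L))) %/% 2L
    counts <- 1
    Nprev <- sizes[1]
    for (l in seq_along(sizes)[-1]) {
        mw <- .qbinomialCounts(Nprev, sizes[l])
        new <- numeric(length(counts) + length(mw) - 1L)
        for (v in seq_along(mw))
            if (mw[v] != 0)
                new[v:(v + length(counts) - 1L)] <-
                    new[v:(v + length(counts) - 1L)] + counts * mw[v]
        counts <- new
        Nprev <- Nprev + sizes[l]
    }
    total <- sum(counts)
    # tail[u + 1] = Pr(U >= u), u in 0..M
    tail <- rev(cumsum(rev(counts))) / total
    list(M = M, tail = tail, total = total, counts = counts)
}

#' Exact one-sided p-value of Kendall S under the conditional null
#'
#' `Pr(S >= sObserved)` when untied exchangeable data are ordered uniformly
#' at random against the fixed template, conditioned on the template's tie
#' pattern. Computed exactly by convolving the Mann-Whitney count
#' distributions of successive template tie groups (no permutation
#' enumeration), so it scales to 48-sample series.
#'
#' @param sObserved observed S statistic.
#' @param template the reference values the data were compared against.
#' @return Exact p in (0, 1\].
#' @export
exactNullPvalue <- function(sObserved, template) {
    if (length(template) < 2L) stop("template must have >= 2 values")
    nd <- .jtkNullDist(template)
    u <- ceiling((sObserved + nd$M) / 2)
    if (u <= 0) return(1)
    if (u > nd$M) stop("sObserved exceeds the maximum attainable S")
    nd$tail[u + 1L]
}

#' Rank-based rhythmicity scan at a fixed period
#'
#' For every probe, the Kendall S statistic against every reference
#' template and its exact conditional null p-value are computed; the best
#' template is the one with the smallest p (ties resolved toward the
#' smaller lag), and the reported p-value is the group Bonferroni
#' `min(1, p_best * number of distinct templates)`. Constant probes get
#' `p = 1` at lag 0. Benjamini-Hochberg q-values are attached across all
#' probes.
#'
#' The exact null assumes untied data values (ties in the data contribute
#' zero to S, which only makes the test conservative); probes with tied
#' values are flagged in `data_ties`, and `tieMethod = "montecarlo"`
#' switches them to a permutation p-value with `mcPermutations` draws
#' (add-one estimator; uses the current RNG stream).
#'
#' @param series an [ExpressionSeries-class].
#' @param waves a [ReferenceWaveSet-class] built on the same sample times;
#'   defaults to 24 h cosines at the series' sampling resolution.
#' @param tieMethod `"exact"` (default) or `"montecarlo"`.
#' @param mcPermutations permutations for the Monte-Carlo fallback.
#' @return data.frame: `probe_id`, `best_lag` (hours after series start),
#'   `s_statistic`, `p_value`, `q_value`, `n_samples`, `data_ties`,
#'   `method`.
#' @export
jtkScan <- function(series, waves = NULL,
                    tieMethod = c("exact", "montecarlo"),
                    mcPermutations = 1e5) {
    tieMethod <- match.arg(tieMethod)
    stopifnot(is(series, "ExpressionSeries"))
    tm <- sampleTimes(series)
    if (is.null(waves))
        waves <- buildReferenceWaves(tm, period = 24,
                                     lagStep = timeResolution(series))
    if (length(waves@times) != length(tm) ||
        max(abs(waves@times - (tm - tm[1]))) > 1e-8)
        stop("series and reference waves do not share sample times")
    X <- SummarizedExperiment::assay(series)
    np <- nrow(X)
    n <- ncol(X)
    nt <- length(waves@lags)
    Tm <- waves@templates

    S <- matrix(0, np, nt)
    for (i in seq_len(n - 1L)) {
        for (j in (i + 1L):n) {
            ts <- sign(Tm[j, ] - Tm[i, ])
            if (all(ts == 0)) next
            sv <- sign(X[, j] - X[, i])
            S <- S + tcrossprod(sv, ts)
        }
    }

    nulls <- lapply(seq_len(nt), function(t) .jtkNullDist(Tm[, t]))
    P <- matrix(1, np, nt)
    for (t in seq_len(nt)) {
        u <- ceiling((S[, t] + nulls[[t]]$M) / 2)
        pos <- u > 0
        P[pos, t] <- nulls[[t]]$tail[pmin(u[pos], nulls[[t]]$M) + 1L]
    }

    ties <- apply(X, 1L, function(x) anyDuplicated(x) > 0L)
    method <- rep("exact", np)
    if (tieMethod == "montecarlo" && any(ties)) {
        ut <- which(upper.tri(diag(n)))
        TSu <- apply(Tm, 2L, function(tt) sign(outer(tt, tt,
                                                     function(a, b) b - a))[ut])
        for (pi in which(ties)) {
            x <- X[pi, ]
            exceed <- numeric(nt)
            for (b in seq_len(mcPermutations)) {
                xp <- x[sample.int(n)]
                dv <- sign(outer(xp, xp, function(a, bb) bb - a))[ut]
                Sb <- as.numeric(crossprod(TSu, dv))
                exceed <- exceed + (Sb >= S[pi, ])
            }
            P[pi, ] <- (1 + exceed) / (mcPermutations + 1)
            method[pi] <- "montecarlo"
        }
    }

    best <- max.col(-P, ties.method = "first")
    idx <- cbind(seq_len(np), best)
    p_best <- P[idx]
    p_rep <- pmin(1, p_best * nt)
    best_lag <- waves@lags[best]
    s_best <- S[idx]

    const <- apply(X, 1L, function(x) all(x == x[1]))
    p_rep[const] <- 1
    best_lag[const] <- 0
    s_best[const] <- 0

    data.frame(probe_id = rownames(X), best_lag = best_lag,
               s_statistic = as.integer(round(s_best)), p_value = p_rep,
               q_value = bhAdjust(p_rep), n_samples = n,
               data_ties = ties, method = method,
               stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Standard step-up adjustment controlling the false discovery rate across
#' probes; order-preserving with `q <= 1`.
#'
#' @param p p-values in (0, 1\].
#' @return q-values in the input order.
#' @export
bhAdjust <- function(p) {
    if (!length(p)) return(numeric(0))
    if (anyNA(p) || any(p <= 0) || any(p > 1))
        stop("p-values must lie in (0, 1]")
    stats::p.adjust(p, method = "BH")
}
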