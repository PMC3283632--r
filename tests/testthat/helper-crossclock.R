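# shared fixtures and independent oracles, built in code

makeSeries <- function(values, times, id = "s", scale = "log2") {
    if (is.null(rownames(values)))
        rownames(values) <- sprintf("p%03d", seq_len(nrow(values)))
    ExpressionSeries(values, times = times, seriesId = id, scale = scale)
}

# all permutations of 1..n as a matrix (n! rows)
allPerms <- function(n) {
    if (n == 1L) return(matrix(1L, 1L, 1L))
    p <- allPerms(n - 1L)
    do.call(rbind, lapply(seq_len(n), function(i)
        cbind(i, p + (p >= i))))
}

# O(n^2) pair-counting oracle for the Kendall S statistic
bruteKendallS <- function(x, y) {
    s <- 0L
    n <- length(x)
    for (i in seq_len(n - 1L))
        for (j in (i + 1L):n)
            s <- s + sign(x[j] - x[i]) * sign(y[j] - y[i])
    as.integer(s)
}

# exact tail probability by full permutation enumeration
enumNullPvalue <- function(s, template) {
    pm <- allPerms(length(template))
    stats <- apply(pm, 1L, function(x) bruteKendallS(x, template))
    sum(stats >= s) / nrow(pm)
}

# O(n^2) double-loop oracle for the circular-circular coefficient (radians)
bruteCircRho <- function(th, ph) {
    num <- d1 <- d2 <- 0
    n <- length(th)
    for (i in seq_len(n - 1L))
        for (j in (i + 1L):n) {
            num <- num + sin(th[i] - th[j]) * sin(ph[i] - ph[j])
            d1 <- d1 + sin(th[i] - th[j])^2
            d2 <- d2 + sin(ph[i] - ph[j])^2
        }
    num / sqrt(d1 * d2)
}

# build a ScaledComparison carrying exactly the requested fold ratios.
# Valid comparisons have equal scaled means, so side weights are solved to
# balance the two sides (requires ratios on both sides of 1, or all 1).
.scaledFromRatios <- function(ids, ratios) {
    w <- ratios - 1
    stopifnot(all(ratios > 0),
              any(w > 0) == any(w < 0) || all(w == 0))
    beta <- rep(1, length(ratios))
    if (any(w > 0))
        beta[w > 0] <- sum(-w[w < 0]) / sum(w[w > 0])
    a <- ratios * beta
    rk <- order(-ratios, ids)
    ranks <- integer(length(ids)); ranks[rk] <- seq_along(ids)
    methods::new("ScaledComparison", probeIds = ids, scaledA = a,
                 scaledB = beta, factorA = 1, factorB = 1,
                 ratios = ratios, ranks = ranks,
                 seriesIdA = "a", seriesIdB = "b")
}

# independent Benjamini-Hochberg step-up oracle
bhOracle <- function(p) {
    m <- length(p)
    o <- order(p)
    q <- rev(cummin(rev(m * p[o] / seq_len(m))))
    pmin(1, q)[order(o)]
}
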