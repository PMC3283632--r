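#' Convert a rhythm-scan lag to a circadian peak phase
#'
#' The scan's lag counts hours after the first sample of its series, so the
#' circadian time of the expression peak is `(start CT + lag) mod 24`. A
#' series starting at CT18 whose probe peaks at lag 8 therefore peaks at
#' CT2.
#'
#' @param lag best-fit lag in hours (vectorized).
#' @param startCt circadian time of the series' first sample, hours in
#'   \[0,24).
#' @return Phase in circadian hours, \[0, 24).
#' @export
lagToPhase <- function(lag, startCt) {
    if (any(lag < 0)) stop("lags must be >= 0")
    if (startCt < 0 || startCt >= 24) stop("startCt must lie in [0,24)")
    (startCt + lag) %% 24
}

#' Per-probe phase records from a rhythm scan
#'
#' @param results data.frame from [jtkScan()].
#' @param startCt circadian time of the series' first sample.
#' @return data.frame `probe_id`, `phase_ct` (hours, \[0,24)), `phase_deg`
#'   (degrees, exactly `phase_ct * 15`).
#' @export
phaseRecords <- function(results, startCt) {
    ph <- lagToPhase(results$best_lag, startCt)
    data.frame(probe_id = results$probe_id, phase_ct = ph,
               phase_deg = ph * 15, stringsAsFactors = FALSE)
}

.passesRule <- function(results, rule) {
    stat <- match.arg(rule$stat, c("p", "q"))
    col <- if (stat == "p") "p_value" else "q_value"
    results[[col]] < rule$cutoff
}

#' Rhythmic probes common to two series, with paired phases
#'
#' Each side's rhythmicity rule is a threshold on the scan's p-value or
#' q-value (strict `<`); the paired set is the probes passing both rules
#' and present in both scans, in the order of side a. Lags are converted to
#' circadian phases with each series' own start CT.
#'
#' @param resultsA,resultsB data.frames from [jtkScan()].
#' @param startCtA,startCtB each series' starting circadian time.
#' @param ruleA,ruleB lists `list(stat = "p"|"q", cutoff = ...)`; the
#'   defaults mirror dense reference series being held to `q < 0.1` and
#'   short series to `p < 0.1`.
#' @return data.frame `probe_id`, `phase_a`, `phase_b` (hours CT),
#'   `phase_deg_a`, `phase_deg_b`.
#' @export
commonRhythmic <- function(resultsA, resultsB, startCtA, startCtB,
                           ruleA = list(stat = "p", cutoff = 0.1),
                           ruleB = list(stat = "q", cutoff = 0.1)) {
    passA <- resultsA$probe_id[.passesRule(resultsA, ruleA)]
    passB <- resultsB$probe_id[.passesRule(resultsB, ruleB)]
    ids <- passA[passA %in% passB]
    pa <- phaseRecords(resultsA, startCtA)
    pb <- phaseRecords(resultsB, startCtB)
    data.frame(probe_id = ids,
               phase_a = pa$phase_ct[match(ids, pa$probe_id)],
               phase_b = pb$phase_ct[match(ids, pb$probe_id)],
               phase_deg_a = pa$phase_deg[match(ids, pa$probe_id)],
               phase_deg_b = pb$phase_deg[match(ids, pb$probe_id)],
               stringsAsFactors = FALSE)
}

#' Pearson correlation of paired phases treated as plain numbers
#'
#' Phases in \[0,24) are correlated as ordinary numbers, ignoring
#' wrap-around; pairs straddling the midnight boundary can make this differ
#' sharply from the circular coefficient, which is why both are reported.
#'
#' @param phaseA,phaseB paired phases in hours (or a data.frame from
#'   [commonRhythmic()] as the first argument).
#' @return Pearson r.
#' @export
linearPhaseCorrelation <- function(phaseA, phaseB = NULL) {
    if (is.data.frame(phaseA)) {
        phaseB <- phaseA$phase_b
        phaseA <- phaseA$phase_a
    }
    if (length(phaseA) != length(phaseB))
        stop("phase vectors must have equal length")
    if (length(phaseA) < 3L) stop("need at least 3 pairs")
    if (stats::sd(phaseA) == 0 || stats::sd(phaseB) == 0)
        stop("correlation undefined: constant phases")
    stats::cor(phaseA, phaseB)
}

#' Circular-circular correlation of paired phases
#'
#' The Fisher-Lee T-linear association coefficient
#' `rho = sum_{i<j} sin(a_i - a_j) sin(b_i - b_j) /
#'  sqrt(sum_{i<j} sin^2(a_i - a_j) * sum_{i<j} sin^2(b_i - b_j))`,
#' evaluated through its O(n) closed form in the component sums
#' (`sum cos a cos b`, `sum sin a sin b`, ... and the second-harmonic
#' resultants of each margin). It is invariant under independent rotations
#' of either margin. Significance comes from the large-sample normal
#' approximation to the jackknifed statistic.
#'
#' @param a,b paired angles; `units` says how they are expressed
#'   (`"hours"` on the 24 h clock, `"degrees"`, or `"radians"`).
#' @param units unit of `a` and `b`; default hours.
#' @return list `rho` (in \[-1,1\]) and `p_value` (two-sided jackknife
#'   normal approximation; `NA` when n < 4).
#' @export
circularCorrelation <- function(a, b,
                                units = c("hours", "degrees", "radians")) {
    units <- match.arg(units)
    if (length(a) != length(b)) stop("angle vectors must have equal length")
    n <- length(a)
    if (n < 4L) stop("need at least 4 pairs")
    f <- switch(units, hours = pi / 12, degrees = pi / 180, radians = 1)
    th <- a * f
    ph <- b * f
    rho_of <- function(th, ph) {
        n <- length(th)
        A <- sum(cos(th) * cos(ph)); B <- sum(sin(th) * sin(ph))
        C <- sum(cos(th) * sin(ph)); D <- sum(sin(th) * cos(ph))
        num <- A * B - C * D
        d1 <- (n^2 - sum(cos(2 * th))^2 - sum(sin(2 * th))^2) / 4
        d2 <- (n^2 - sum(cos(2 * ph))^2 - sum(sin(2 * ph))^2) / 4
        list(num = num, d1 = d1, d2 = d2)
    }
    parts <- rho_of(th, ph)
    if (parts$d1 <= 1e-12 * length(th)^2)
        stop("first margin is angularly degenerate (all angles identical)")
    if (parts$d2 <= 1e-12 * length(th)^2)
        stop("second margin is angularly degenerate (all angles identical)")
    rho <- parts$num / sqrt(parts$d1 * parts$d2)

    # jackknife pseudo-values for a normal-approximation test of rho = 0
    loo <- vapply(seq_len(n), function(i) {
        p <- rho_of(th[-i], ph[-i])
        if (p$d1 <= 0 || p$d2 <= 0) return(NA_real_)
        p$num / sqrt(p$d1 * p$d2)
    }, numeric(1))
    pseudo <- n * rho - (n - 1) * loo
    pseudo <- pseudo[is.finite(pseudo)]
    p_value <- if (length(pseudo) >= 4L && stats::sd(pseudo) > 0) {
        z <- mean(pseudo) / (stats::sd(pseudo) / sqrt(length(pseudo)))
        2 * stats::pnorm(-abs(z))
    } else if (abs(rho) > 0) 0 else 1
    list(rho = rho, p_value = p_value)
}

#' Signed circular difference between two phases
#'
#' `phaseA - phaseB` wrapped to `(-12, 12]` hours; antiphase maps to +12 by
#' convention. A 23 h vs 1 h comparison wraps across midnight to -2 h.
#'
#' @param phaseA,phaseB phases in hours, \[0,24) (vectorized).
#' @return Signed difference in hours.
#' @export
phaseDifference <- function(phaseA, phaseB) {
    if (any(phaseA < 0 | phaseA >= 24) || any(phaseB < 0 | phaseB >= 24))
        stop("phases must lie in [0,24)")
    d <- (phaseA - phaseB) %% 24
    d[d > 12] <- d[d > 12] - 24
    d
}
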