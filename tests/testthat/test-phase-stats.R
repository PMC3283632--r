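fakeScan <- function(ids, lags, p = NULL, q = NULL) {
    n <- length(ids)
    data.frame(probe_id = ids, best_lag = lags,
               s_statistic = rep(0L, n),
               p_value = if (is.null(p)) rep(0.5, n) else p,
               q_value = if (is.null(q)) rep(0.5, n) else q,
               n_samples = 12L, data_ties = FALSE, method = "exact",
               stringsAsFactors = FALSE)
}

test_that("lag plus series start gives the circadian peak phase", {
    expect_equal(lagToPhase(8, 18), 2)     # CT18 start, peak 8 h later
    expect_equal(lagToPhase(0, 2), 2)
    expect_equal(lagToPhase(0, 0), 0)
    expect_equal(lagToPhase(30, 20), 2)    # lags beyond one day wrap
    expect_error(lagToPhase(-1, 0), ">= 0")
    expect_error(lagToPhase(0, 24), "\\[0,24\\)")

    pr <- phaseRecords(fakeScan(c("a", "b"), c(8, 20)), startCt = 18)
    expect_equal(pr$phase_ct, c(2, 14))
    expect_equal(pr$phase_deg, pr$phase_ct * 15)
})

test_that("common rhythmic set applies each side's rule then intersects", {
    a <- fakeScan(c("p1", "p2", "p3", "p4"), c(0, 4, 8, 12),
                  p = c(0.01, 0.05, 0.5, 0.02))
    b <- fakeScan(c("p2", "p3", "p4", "p5"), c(2, 6, 10, 14),
                  q = c(0.01, 0.02, 0.5, 0.01))
    pairs <- commonRhythmic(a, b, startCtA = 2, startCtB = 18,
                            ruleA = list(stat = "p", cutoff = 0.1),
                            ruleB = list(stat = "q", cutoff = 0.1))
    # p4 fails side b's q rule; p1/p5 absent from the other side
    expect_identical(pairs$probe_id, "p2")
    expect_equal(pairs$phase_a, (2 + 4) %% 24)
    expect_equal(pairs$phase_b, (18 + 2) %% 24)
    expect_equal(pairs$phase_deg_a, pairs$phase_a * 15)

    # disjoint rhythmic sets -> empty pairing
    none <- commonRhythmic(fakeScan("x", 0, p = 0.01),
                           fakeScan("y", 0, q = 0.01), 0, 0)
    expect_equal(nrow(none), 0L)

    # identical sets of k probes -> k pairs; matches a brute-force
    # filter-then-intersect oracle on random inputs
    set.seed(51)
    for (i in 1:20) {
        ids_a <- sample(sprintf("g%02d", 1:30), 20)
        ids_b <- sample(sprintf("g%02d", 1:30), 20)
        pa <- runif(20); qb <- runif(20)
        ra <- fakeScan(ids_a, sample(seq(0, 20, 4), 20, TRUE), p = pa)
        rb <- fakeScan(ids_b, sample(seq(0, 20, 4), 20, TRUE), q = qb)
        got <- commonRhythmic(ra, rb, 2, 18)
        want <- intersect(ids_a[pa < 0.1], ids_b[qb < 0.1])
        expect_setequal(got$probe_id, want)
    }
})

test_that("linear phase correlation is plain Pearson on the hour scale", {
    ph <- c(1, 5, 9, 13, 17, 21)
    expect_equal(linearPhaseCorrelation(ph, ph), 1)
    expect_equal(linearPhaseCorrelation(ph, 24 - ph), -1)
    set.seed(52)
    a <- runif(30, 0, 24); b <- runif(30, 0, 24)
    oracle <- sum((a - mean(a)) * (b - mean(b))) /
        sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
    expect_equal(linearPhaseCorrelation(a, b), oracle, tolerance = 1e-12)
    expect_error(linearPhaseCorrelation(rep(3, 5), runif(5)), "constant")
})

test_that("circular correlation matches the O(n^2) defining sum", {
    set.seed(53)
    for (i in 1:30) {
        n <- sample(4:40, 1)
        a <- runif(n, 0, 24); b <- runif(n, 0, 24)
        got <- circularCorrelation(a, b, units = "hours")
        expect_equal(got$rho, bruteCircRho(a * pi / 12, b * pi / 12),
                     tolerance = 1e-12)
        expect_gte(got$rho, -1); expect_lte(got$rho, 1)
    }
    # identity and reflection are exactly +/-1
    a <- c(1, 5, 9, 14, 20, 22)
    expect_equal(circularCorrelation(a, a)$rho, 1, tolerance = 1e-12)
    expect_equal(circularCorrelation(a, (24 - a) %% 24)$rho, -1,
                 tolerance = 1e-12)
    # degenerate margins are refused by side
    expect_error(circularCorrelation(rep(3, 6), a), "first margin")
    expect_error(circularCorrelation(a, rep(3, 6)), "second margin")
    # degrees and hours agree
    expect_equal(circularCorrelation(a * 15, a * 15 + 30,
                                     units = "degrees")$rho,
                 circularCorrelation(a, a + 2, units = "hours")$rho,
                 tolerance = 1e-12)
})

test_that("circular correlation is invariant under independent rotations", {
    set.seed(54)
    a <- runif(20, 0, 24); b <- runif(20, 0, 24)
    base <- circularCorrelation(a, b)$rho
    for (i in 1:10) {
        ra <- (a + runif(1, 0, 24)) %% 24
        rb <- (b + runif(1, 0, 24)) %% 24
        expect_equal(circularCorrelation(ra, rb)$rho, base,
                     tolerance = 1e-9)
    }
})

test_that("linear correlation is not rotation-invariant on wrapped phases", {
    # a perfect 12 h rotation: identical rhythms shifted by half a day.
    # The circular coefficient is exactly 1; wrapping the rotated phases
    # back into [0,24) breaks them into two branches and the linear
    # Pearson drops to -0.5 -- the reason both statistics are reported
    a <- seq(0.25, 23.75, length.out = 48)
    b <- (a + 12) %% 24
    expect_equal(circularCorrelation(a, b)$rho, 1, tolerance = 1e-9)
    lin <- linearPhaseCorrelation(a, b)
    expect_lt(lin, 0)
    expect_equal(lin, -0.5, tolerance = 0.05)
})

test_that("phase recovery: circular r approaches 1 as angular noise vanishes", {
    set.seed(56)
    a <- runif(50, 0, 24)
    offset <- 6
    rhos <- vapply(c(2, 0.5, 0.05), function(noise) {
        b <- (a + offset + rnorm(50, 0, noise)) %% 24
        circularCorrelation(a, b)$rho
    }, numeric(1))
    expect_true(all(diff(rhos) > 0))
    expect_gt(rhos[3], 0.99)
})

test_that("signed phase differences wrap to (-12, 12] with +12 at antiphase", {
    expect_equal(phaseDifference(2, 2), 0)
    expect_equal(phaseDifference(23, 1), -2)
    expect_equal(phaseDifference(1, 23), 2)
    expect_equal(phaseDifference(14, 2), 12)   # antiphase maps to +12
    expect_equal(phaseDifference(2, 14), 12)
    grid <- seq(0, 23.5, by = 0.5)
    for (aa in grid) {
        d <- phaseDifference(aa, grid)
        expect_true(all(d > -12 & d <= 12))
        # brute-force circular distance agreement
        brute <- pmin(abs(aa - grid), 24 - abs(aa - grid))
        expect_equal(abs(d), brute, tolerance = 1e-12)
        # antisymmetry away from antiphase
        swap <- phaseDifference(grid, aa)
        off <- abs(d) < 12 - 1e-9
        expect_equal(swap[off], -d[off], tolerance = 1e-12)
    }
    expect_error(phaseDifference(25, 0), "\\[0,24\\)")
})
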