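test_that("IF preprocessing rounds, jitters, clips and is deterministic", {
    set.seed(1)
    out <- preprocessIF(c(0.50004, 0.49996))
    expect_lt(abs(out[1] - out[2]), 0.001)   # both rounded to 0.500
    expect_true(all(abs(out - 0.5) <= 5e-4))

    expect_identical(preprocessIF(numeric(0)), numeric(0))

    set.seed(42); a <- preprocessIF(runif(50))
    set.seed(42); b <- preprocessIF(runif(50))
    expect_identical(a, b)

    set.seed(2)
    edge <- preprocessIF(c(0, 1, NA))
    expect_true(all(edge >= 0 & edge <= 1, na.rm = TRUE))
    expect_true(is.na(edge[3]))
})

test_that("the KDE matches a closed-form Gaussian mixture and normalizes", {
    h <- 0.05
    vals <- c(rep(0.1, 25), rep(0.9, 25))
    curve <- fitIFDensity(vals, h)
    # oracle: density of equal-weight Gaussians at the data points
    oracle <- 0.5 * dnorm(curve$grid, 0.1, h) +
        0.5 * dnorm(curve$grid, 0.9, h)
    expect_lt(max(abs(curve$density - oracle)), 0.02 * max(oracle))

    set.seed(5)
    for (i in 1:5) {
        v <- runif(40)
        cv <- fitIFDensity(v, 0.08)
        integral <- sum(diff(cv$grid) *
                        (head(cv$density, -1) + tail(cv$density, -1)) / 2)
        expect_equal(integral, 1, tolerance = 1e-3)
    }
    expect_error(fitIFDensity(0.4, 0.1), "at least 2")
    expect_error(fitIFDensity(c(0.2, 0.4), 0), "positive")
})

test_that("split points exist only for genuinely bimodal densities", {
    uni <- fitIFDensity(rnorm(60, 0.9, 0.02), 0.09)
    expect_true(is.na(findSplitPoint(uni)))

    bi <- fitIFDensity(c(rep(0.1, 30), rep(0.9, 30)), 0.05)
    m <- findSplitPoint(bi)
    expect_equal(m, 0.5, tolerance = 0.02)

    # grid-scan oracle on the analytic mixture: lowest interior minimum
    y <- 0.5 * dnorm(bi$grid, 0.1, 0.05) + 0.5 * dnorm(bi$grid, 0.9, 0.05)
    interior <- which(diff(sign(diff(y))) == 2) + 1
    expect_equal(m, bi$grid[interior[which.min(y[interior])]],
                 tolerance = 0.01)

    # oversmoothing suppresses a weak split
    set.seed(8)
    weak <- c(rnorm(40, 0.45, 0.05), rnorm(20, 0.7, 0.05))
    expect_false(is.na(findSplitPoint(fitIFDensity(weak, 0.03))))
    expect_true(is.na(findSplitPoint(fitIFDensity(weak, 0.2))))
})

test_that("split detection is order-invariant and outlier-robust at h >= 0.09", {
    set.seed(9)
    vals <- c(rnorm(25, 0.25, 0.04), rnorm(25, 0.75, 0.04))
    m1 <- findSplitPoint(fitIFDensity(vals, 0.09))
    m2 <- findSplitPoint(fitIFDensity(sample(vals), 0.09))
    expect_identical(m1, m2)
    withOut <- findSplitPoint(fitIFDensity(c(vals, 0.999), 0.09))
    expect_equal(withOut, m1, tolerance = 0.05)
})

test_that("more smoothing never creates additional splits", {
    set.seed(10)
    fixtures <- replicate(8, {
        n1 <- sample(10:40, 1)
        c(rnorm(n1, runif(1, 0.1, 0.4), 0.05),
          rnorm(50 - n1, runif(1, 0.6, 0.9), 0.05))
    }, simplify = FALSE)
    hGrid <- seq(0.02, 0.20, by = 0.01)
    nSplit <- vapply(hGrid, function(h)
        sum(vapply(fixtures, function(v)
            !is.na(findSplitPoint(fitIFDensity(pmin(pmax(v, 0), 1), h))),
            logical(1))), numeric(1))
    expect_true(all(diff(nSplit) <= 0))
})

test_that("tails follow the split-point definition with size guards", {
    ifCase <- setNames(c(rep(0.1, 12), rep(0.9, 12)), paste0("c", 1:24))
    ifCtrl <- setNames(seq(0.3, 0.95, length.out = 20), paste0("k", 1:20))
    tp <- defineTails(ifCase, ifCtrl, m = 0.5, nSmall = 12)
    expect_equal(tp$mode, "split")
    expect_length(tp$lCase, 12)
    expect_length(tp$rCase, 12)
    # control left tail holds 6 samples <= 0.5; expanded to nearest 12
    expect_length(tp$lControl, 12)
    expect_setequal(tp$lControl, paste0("k", 1:12))  # sorted IF grid
    expect_length(tp$rControl, 14)

    # case tail below nSmall: stratification deemed outlier-driven
    ifCase2 <- setNames(c(rep(0.1, 3), rep(0.9, 21)), paste0("c", 1:24))
    tp2 <- defineTails(ifCase2, ifCtrl, m = 0.5, nSmall = 12)
    expect_equal(tp2$mode, "whole-group")
    expect_setequal(tp2$lCase, names(ifCase2))
})

test_that("exact Mann-Whitney p-values match exhaustive enumeration", {
    # full separation 3 vs 3: 2/20 assignments are as extreme
    expect_equal(mannWhitneyP(1:3, 4:6), 0.1)
    set.seed(12)
    for (m in 2:7) for (n in 2:7) {
        x <- runif(m); y <- runif(n)
        expect_equal(mannWhitneyP(x, y), enumMWU(x, y),
                     tolerance = 1e-12,
                     label = sprintf("exact p (%d vs %d)", m, n))
    }
})

test_that("Mann-Whitney agrees with stats::wilcox.test on both branches", {
    set.seed(13)
    x <- runif(5); y <- runif(6)
    expect_equal(mannWhitneyP(x, y),
                 wilcox.test(x, y, exact = TRUE)$p.value)
    x2 <- runif(30); y2 <- runif(25)
    expect_equal(mannWhitneyP(x2, y2),
                 wilcox.test(x2, y2, exact = FALSE,
                             correct = TRUE)$p.value)
    # tie-corrected approximation
    x3 <- round(runif(20), 1); y3 <- round(runif(20), 1)
    expect_equal(mannWhitneyP(x3, y3),
                 suppressWarnings(wilcox.test(x3, y3, exact = FALSE,
                                              correct = TRUE)$p.value))
    # identical groups: no evidence
    z <- runif(10)
    expect_equal(mannWhitneyP(z, z), 1)
    expect_error(mannWhitneyP(numeric(0), 1:3), "non-empty")
})

test_that("normal approximation tracks enumeration on moderate sizes", {
    set.seed(14)
    x <- runif(7); y <- runif(7)
    exact <- enumMWU(x, y)
    approx <- heteroDTU:::.mwuP(x, y, exactMax = 2L)  # force approximation
    expect_lt(abs(exact - approx), 0.01)
})

test_that("per-transcript testing finds planted subgroup shifts", {
    set.seed(15)
    ifCase <- setNames(preprocessIF(c(rnorm(12, 0.1, 0.02),
                                      rnorm(12, 0.9, 0.02))),
                       paste0("c", 1:24))
    ifCtrl <- setNames(preprocessIF(rnorm(24, 0.9, 0.02)),
                       paste0("k", 1:24))
    tr <- testTranscript(ifCase, ifCtrl, h = 0.09, nSmall = 12)
    expect_equal(tr$mode, "split")
    expect_lt(tr$p_left, 1e-4)
    expect_gt(tr$p_right, 0.01)
    expect_equal(tr$p, tr$p_left)
    # the shifted left tail is the marked one; controls stay 0
    expect_setequal(names(tr$v)[tr$v == 1], paste0("c", 1:12))

    # all-case shift with no bimodality: whole-group call, v all-1
    ifCase2 <- setNames(preprocessIF(rnorm(24, 0.1, 0.02)),
                        paste0("c", 1:24))
    tr2 <- testTranscript(ifCase2, ifCtrl, h = 0.09, nSmall = 12)
    expect_equal(tr2$mode, "whole-group")
    expect_lt(tr2$p, 1e-6)
    expect_true(all(tr2$v[paste0("c", 1:24)] == 1))
    expect_true(all(tr2$v[paste0("k", 1:24)] == 0))

    # matched distributions: no signal
    set.seed(16)
    p0 <- replicate(40, {
        a <- setNames(preprocessIF(runif(20, 0.7, 0.9)), paste0("c", 1:20))
        b <- setNames(preprocessIF(runif(20, 0.7, 0.9)), paste0("k", 1:20))
        testTranscript(a, b, h = 0.2, nSmall = 10)$p
    })
    expect_gt(mean(p0), 0.2)
    expect_gt(min(p0), 1e-4)
})
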