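# helper: design with response driven by one binary column
stubDesign <- function(n = 24, driver = c("v", "cov"), flip = 0,
                       noise = 0.03) {
    driver <- match.arg(driver)
    v <- rep(c(1, 0), each = n / 2)
    age <- rnorm(n, 50, 10)
    if (driver == "v") {
        y <- 0.2 + 0.5 * v + rnorm(n, 0, noise)
    } else {
        hi <- as.numeric(age > 50)
        y <- 0.2 + 0.5 * hi + rnorm(n, 0, noise)
        v <- hi
        if (flip > 0) {
            i <- sample(n, flip)
            v[i] <- 1 - v[i]
        }
    }
    list(X = cbind(v = v, age = age), y = y)
}

test_that("stub trees split on the dominant column and score by R2", {
    set.seed(1)
    d <- stubDesign(driver = "v")
    forest <- fitStubForest(d$X, d$y, nTrees = 50, nSmall = 6)
    splitCols <- vapply(forest, function(t) t$col, numeric(1))
    expect_gt(mean(splitCols == 1, na.rm = TRUE), 0.9)
    expect_gt(forestR2(forest, d$X, d$y), 0.8)

    # pure noise: near-zero explained variance
    set.seed(2)
    yN <- rnorm(24)
    fN <- fitStubForest(d$X, yN, nTrees = 50, nSmall = 6)
    expect_lt(abs(forestR2(fN, d$X, yN)), 0.3)

    # constant response: no-split stubs, R2 defined as 0
    fC <- fitStubForest(d$X, rep(0.5, 24), nTrees = 10, nSmall = 6)
    expect_true(all(is.na(vapply(fC, function(t) t$col, numeric(1)))))
    expect_equal(forestR2(fC, d$X, rep(0.5, 24)), 0)

    # below nSmall the root is never split
    fS <- fitStubForest(d$X, d$y, nTrees = 10, nSmall = 100)
    expect_true(all(is.na(vapply(fS, function(t) t$col, numeric(1)))))
})

test_that("tree-level R2 matches hand arithmetic on a 6-sample case", {
    X <- cbind(v = c(0, 0, 0, 1, 1, 1))
    y <- c(1, 2, 3, 7, 8, 9)
    forest <- list(list(col = 1L, thr = 0.5))
    # leaves {1,2,3} and {7,8,9}: u = 2 + 2 = 4; v = sum((y-5)^2) = 58
    expect_equal(forestR2(forest, X, y), 1 - 4 / 58)
    # leaf means equal to y: perfect score
    expect_equal(forestR2(forest, X, c(0, 0, 0, 1, 1, 1)), 1)
    # no-split stub
    expect_equal(forestR2(list(list(col = NA_integer_, thr = NA_real_)),
                          X, y), 0)
})

test_that("permutation importance isolates the informative column", {
    set.seed(3)
    d <- stubDesign(driver = "v")
    forest <- fitStubForest(d$X, d$y, nTrees = 60, nSmall = 6)
    base <- forestR2(forest, d$X, d$y)
    gV <- permutationImportance(forest, d$X, d$y, 1, nPerm = 50)
    gA <- permutationImportance(forest, d$X, d$y, 2, nPerm = 50)
    expect_length(gV, 50)
    expect_gt(median(gV), 0.5 * base)   # shuffling v destroys the fit
    expect_lt(median(abs(gA)), 0.05)    # the ignored column is inert
})

test_that("the quartile rule keeps v-driven and drops covariate-driven calls", {
    fix <- smallInjectedCohort(seed = 4, nGenes = 60, nDTU = 5,
                               genesPer = 4, nSpliceotypes = 1)
    set.seed(40)
    res <- detectDTU(fix$data, nIterations = 20)
    ncand <- sum(transcriptResults(res)$call)
    expect_gt(ncand, 0)

    # no covariates: everything is kept
    cf0 <- confounderFilter(res, fix$data, covariates = character(0))
    expect_true(all(cf0$keep))

    # an age covariate that mirrors the event partition of a transcript
    # steals its importance; an unrelated one does not
    obj <- fix$data
    tx <- transcriptResults(res)$transcript_id[transcriptResults(res)$call][1]
    v <- res@vMatrix[tx, colnames(obj)]
    SummarizedExperiment::colData(obj)$age <-
        50 + 20 * v + rnorm(ncol(obj), 0, 1)
    set.seed(41)
    cfA <- confounderFilter(res, obj, covariates = "age",
                            nTrees = 60, nPerm = 30)
    expect_false(cfA$keep[tx])

    SummarizedExperiment::colData(obj)$age <- rnorm(ncol(obj), 50, 10)
    set.seed(42)
    cfB <- confounderFilter(res, obj, covariates = "age",
                            nTrees = 60, nPerm = 30)
    expect_true(cfB$keep[tx])
    # vetoed transcripts leave the rebuilt result and DTU matrix
    expect_true(setequal(
        rownames(dtuMatrix(cfA$result)),
        unique(transcriptResults(cfA$result)$gene_id[
            transcriptResults(cfA$result)$call])))

    # single-level covariates are dropped with a warning
    SummarizedExperiment::colData(obj)$batch <- "b1"
    set.seed(43)
    expect_warning(confounderFilter(res, obj,
                                    covariates = c("age", "batch"),
                                    nTrees = 20, nPerm = 10),
                   "single level")
})

test_that("the filter decision is invariant to covariate order and recoding", {
    set.seed(5)
    d <- stubDesign(driver = "cov", flip = 2)
    batch <- sample(c("a", "b", "c"), 24, replace = TRUE)
    run <- function(covDf, seed) {
        set.seed(seed)
        enc <- heteroDTU:::.encodeCovariates(covDf)
        X <- cbind(v = d$X[, "v"], enc$X)
        forest <- fitStubForest(X, d$y, nTrees = 40, nSmall = 6)
        gam <- vapply(seq_len(ncol(X)), function(col)
            permutationImportance(forest, X, d$y, col, nPerm = 20),
            numeric(20))
        q1v <- quantile(gam[, 1], 0.25, names = FALSE)
        q3 <- -Inf
        for (cv in unique(enc$groups)) {
            g <- apply(gam[, which(enc$groups == cv) + 1, drop = FALSE],
                       1, max)
            q3 <- max(q3, quantile(g, 0.75, names = FALSE))
        }
        q1v > q3
    }
    d1 <- run(data.frame(age = d$X[, "age"], batch = batch), 10)
    d2 <- run(data.frame(batch = batch, age = d$X[, "age"]), 10)
    expect_identical(d1, d2)
    # monotone recoding of the categorical labels
    recoded <- c(a = "z3", b = "z2", c = "z1")[batch]
    d3 <- run(data.frame(age = d$X[, "age"], batch = recoded), 10)
    expect_identical(d1, d3)
})
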