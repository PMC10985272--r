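# A hand-built cohort where each filter step has known casualties.
prefilterFixture <- function() {
    nS <- 20                            # 10 case + 10 control
    mk <- function(v) matrix(rep(v, nS), ncol = nS)
    rows <- list(
        # gene A: two healthy transcripts, dominant t1 everywhere
        A.t1 = rep(300, nS), A.t2 = rep(100, nS),
        # gene B: t2 positive in 5 case samples but no controls
        # (survives step 1 with nSmall = 5, fails step 2)
        B.t1 = rep(200, nS), B.t2 = c(rep(50, 5), rep(0, nS - 5)),
        B.t3 = rep(150, nS),
        # gene C: gene count below gc = 10 in all samples (fails step 3)
        C.t1 = rep(4, nS), C.t2 = rep(4, nS),
        # gene D: t2 IF never above f = 0.1 (fails step 4), leaving one
        # transcript, so the gene then falls at step 5
        D.t1 = rep(950, nS), D.t2 = rep(50, nS),
        # gene E: dominance alternates sample-to-sample within the
        # controls (50% consistency, fails step 6)
        E.t1 = rep(c(300, 100), nS / 2),
        E.t2 = rep(c(100, 300), nS / 2))
    cts <- do.call(rbind, rows)
    colnames(cts) <- sprintf("s%02d", seq_len(nS))
    map <- data.frame(transcript_id = rownames(cts),
                      gene_id = sub("\\..*", "", rownames(cts)))
    meta <- data.frame(sample_id = colnames(cts),
                       condition = rep(c("case", "control"), each = 10))
    DTUDataSet(cts, map, meta)
}

test_that("each filter step removes exactly the engineered casualties", {
    dds <- prefilterFixture()
    fp <- filterParams(nSmall = 5, pr = 0.2, gc = 10, gn = 1, f = 0.1,
                       pd = 0.75)
    out <- applyPrefilter(dds, fp)
    expect_setequal(rownames(out$data), c("A.t1", "A.t2", "B.t1", "B.t3"))
    st <- out$report$steps
    expect_equal(st$transcripts_removed, c(0, 1, 2, 1, 1, 2))
    expect_equal(st$genes_removed, c(0, 0, 1, 0, 1, 1))  # C, D, E
    expect_setequal(out$report$surviving_genes, c("A", "B"))
})

test_that("dominance step removes genes below the consistency fraction", {
    # top isoform dominant in 70% of controls < pd = 0.75 -> removed
    nC <- 10
    cts <- rbind(t1 = c(rep(60, nC), rep(60, 7), rep(20, 3)),
                 t2 = c(rep(40, nC), rep(40, 7), rep(80, 3)))
    colnames(cts) <- sprintf("s%02d", 1:(2 * nC))
    dds <- DTUDataSet(cts,
        data.frame(transcript_id = c("t1", "t2"), gene_id = "g"),
        data.frame(sample_id = colnames(cts),
                   condition = rep(c("case", "control"), each = nC)))
    expect_warning(out <- applyPrefilter(dds, filterParams(nSmall = 3,
                                                           steps = 6)),
                   "no transcripts")
    expect_equal(nrow(out$data), 0)
    out2 <- applyPrefilter(dds, filterParams(nSmall = 3, pd = 0.7,
                                             steps = 6))
    expect_equal(nrow(out2$data), 2)
})

test_that("prefilter is idempotent and disabling all steps is a no-op", {
    set.seed(7)
    dds <- simulateCohort(cohortParams(nGenes = 80, nCase = 12,
                                       nControl = 12))
    fp <- filterParams(nSmall = 6)
    once <- applyPrefilter(dds, fp)
    twice <- applyPrefilter(once$data, fp)
    expect_identical(rownames(twice$data), rownames(once$data))

    off <- applyPrefilter(dds, filterParams(steps = integer(0)))
    expect_identical(counts(off$data), counts(dds))
})

test_that("prefilter dominance step agrees with the simulator eligibility", {
    set.seed(11)
    dds <- simulateCohort(cohortParams(nGenes = 60, nCase = 10,
                                       nControl = 10))
    dom <- dominantGenes(dds, pd = 0.75)
    out <- applyPrefilter(dds, filterParams(steps = 6, nSmall = 1))
    expect_setequal(out$report$surviving_genes,
                    dom$gene_id[dom$eligible])
})

test_that("filtered-CPM mask gates low-expression samples per gene", {
    # 10 samples with realistic library depth; gene g1 reaches CPM 10
    # (1e-5 of the library) in exactly 3 of them
    g1 <- c(2, 6, 3, 2000, 1500, 2, 4, 5, 3, 1800)
    g2 <- rep(1e6, 10)
    cts <- rbind(g1.t1 = g1 * 0.6, g1.t2 = g1 * 0.4,
                 g2.t1 = g2 * 0.7, g2.t2 = g2 * 0.3)
    colnames(cts) <- sprintf("s%02d", 1:10)
    dds <- DTUDataSet(cts,
        data.frame(transcript_id = rownames(cts),
                   gene_id = rep(c("g1", "g2"), each = 2)),
        data.frame(sample_id = colnames(cts),
                   condition = rep(c("case", "control"), 5)))
    mask <- filteredCpmMask(dds, cpmGate = 10)
    # oracle: recompute CPM over the gene totals by hand
    gt <- rbind(g1, g2)
    cpm <- sweep(gt, 2, colSums(gt), "/") * 1e6
    expect_identical(unname(mask), unname(cpm >= 10))
    expect_equal(sum(mask["g1", ]), 3)
    expect_true(all(mask["g2", ]))
})

test_that("MAD sample QC drops only extreme low-expression samples", {
    nS <- 20
    # per sample, the first L genes are silent (below the CPM gate) and
    # the rest sit far above it; sample 1 has ten times the typical L
    L <- c(40, rep(c(3, 4, 5, 4), 5))[1:nS]
    base <- matrix(1000, 50, nS)
    for (j in seq_len(nS)) base[seq_len(L[j]), j] <- 0
    base <- base[rep(1:50, each = 2), ] / 2      # two transcripts per gene
    rownames(base) <- paste0("g", sprintf("%03d", rep(1:50, each = 2)),
                             ".t", 1:2)
    colnames(base) <- sprintf("s%02d", seq_len(nS))
    dds <- DTUDataSet(base,
        data.frame(transcript_id = rownames(base),
                   gene_id = sub("\\.t.$", "", rownames(base))),
        data.frame(sample_id = colnames(base),
                   condition = rep(c("case", "control"), each = nS / 2)))
    kept <- sampleQC(dds, cpmGate = 10)
    expect_false("s01" %in% kept)
    # oracle: recompute the modified z-scores directly
    low <- colSums(!filteredCpmMask(dds, 10))
    expect_equal(unname(low), L)
    z <- 0.6745 * (low - median(low)) / median(abs(low - median(low)))
    expect_setequal(kept, colnames(dds)[z <= 3.5])

    # identical samples: MAD = 0, warn and keep everything
    same <- matrix(500, 4, 4, dimnames = list(
        paste0("g", 1:2, ".t", rep(1:2, 2))[c(1, 3, 2, 4)],
        paste0("s", 1:4)))
    rownames(same) <- c("g1.t1", "g1.t2", "g2.t1", "g2.t2")
    dds2 <- DTUDataSet(same,
        data.frame(transcript_id = rownames(same),
                   gene_id = rep(c("g1", "g2"), each = 2)),
        data.frame(sample_id = colnames(same),
                   condition = c("case", "case", "control", "control")))
    expect_warning(kept2 <- sampleQC(dds2), "MAD")
    expect_length(kept2, 4)
    expect_error(sampleQC(dds2[, 1:3]), "at least 4")
})
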