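# Shared fixtures, generated in code.

# tiny deterministic count set: 2 genes, 5 transcripts, 4 samples
tinyDataSet <- function() {
    cts <- matrix(c(2, 6, 2, 5, 5,
                    4, 4, 2, 0, 10,
                    1, 8, 1, 3, 3,
                    3, 3, 4, 2, 8),
                  nrow = 5,
                  dimnames = list(c("g1.t1", "g1.t2", "g1.t3",
                                    "g2.t1", "g2.t2"),
                                  c("s1", "s2", "s3", "s4")))
    map <- data.frame(transcript_id = rownames(cts),
                      gene_id = c("g1", "g1", "g1", "g2", "g2"))
    meta <- data.frame(sample_id = colnames(cts),
                       condition = c("case", "case", "control", "control"))
    DTUDataSet(cts, map, meta)
}

# write the three standard TSVs for a DTUDataSet, return paths
writeFixtureFiles <- function(dds, dir = withr::local_tempdir(
                                  .local_envir = parent.frame())) {
    cf <- file.path(dir, "counts.tsv")
    writeMatrixTSV(counts(dds), cf)
    tf <- file.path(dir, "tx2gene.tsv")
    utils::write.table(txGene(dds), tf, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    mf <- file.path(dir, "meta.tsv")
    meta <- data.frame(sample_id = colnames(dds),
                       as.data.frame(SummarizedExperiment::colData(dds)))
    utils::write.table(meta, mf, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    list(counts = cf, tx2gene = tf, meta = mf)
}

# exact two-sided Mann-Whitney p by exhaustive enumeration of all
# C(m+n, m) rank assignments (independent oracle for the exact branch)
enumMWU <- function(x, y) {
    m <- length(x); n <- length(y)
    pooled <- c(x, y)
    r <- rank(pooled)
    U <- sum(r[seq_len(m)]) - m * (m + 1) / 2
    combs <- utils::combn(m + n, m)
    Us <- apply(combs, 2, function(idx) sum(r[idx]) - m * (m + 1) / 2)
    mu <- m * n / 2
    mean(abs(Us - mu) >= abs(U - mu) - 1e-12)
}

# small injected cohort shared by several pipeline tests
smallInjectedCohort <- function(seed = 1, nGenes = 150, nCase = 24,
                                nControl = 24, nDTU = 12,
                                nSpliceotypes = 2, genesPer = 8) {
    set.seed(seed)
    dds <- simulateCohort(cohortParams(nGenes = nGenes, nCase = nCase,
                                       nControl = nControl))
    sim <- injectDTU(dds, nDTU = nDTU, nSpliceotypes = nSpliceotypes,
                     genesPer = genesPer)
    filt <- applyPrefilter(sim$data, filterParams())
    list(data = filt$data, truth = sim$truth,
         universe = unique(geneIds(filt$data)))
}
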