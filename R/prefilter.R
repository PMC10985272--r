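## Stringent six-step transcript/gene pre-filter, the filtered-CPM gating
## mask, and MAD-based sample QC. Steps run in a fixed order on the
## progressively surviving set and each can be switched off individually.

#' Pre-filter parameters
#'
#' @param nSmall smallest presumed subgroup size; also the sample-count
#'   threshold of steps 1 and 4.
#' @param pr fraction of samples (within each of the case and control
#'   groups separately) that must have a positive count, step 2.
#' @param gc,gn step 3: a gene must reach count `gc` in at least `gn`
#'   samples.
#' @param f minimum isoform fraction of step 4.
#' @param pd dominance consistency fraction of step 6: the same isoform
#'   must carry the largest IF in at least this fraction of control
#'   samples.
#' @param cpmGate filtered-CPM gating threshold used by
#'   [filteredCpmMask()] and [sampleQC()].
#' @param steps integer vector selecting which of steps 1..6 to apply.
#' @return a named list of validated parameters.
#' @export
filterParams <- function(nSmall = 12, pr = 0.2, gc = 10, gn = 1, f = 0.1,
                         pd = 0.75, cpmGate = 10, steps = 1:6) {
    stopifnot(pr > 0, pr <= 1, f > 0, f <= 1, pd > 0, pd <= 1,
              nSmall >= 1, gn >= 1, gc >= 0, cpmGate >= 0,
              all(steps %in% 1:6))
    list(nSmall = nSmall, pr = pr, gc = gc, gn = gn, f = f, pd = pd,
         cpmGate = cpmGate, steps = as.integer(steps))
}

## most frequent top-IF isoform per gene across control samples and the
## fraction of control samples in which it is on top; NA IFs ignored
.dominance <- function(ifm, gene) {
    genes <- unique(gene)
    out <- data.frame(gene_id = genes, dominant = NA_character_,
                      frac = 0, stringsAsFactors = FALSE)
    rows <- split(seq_along(gene), gene)
    for (k in seq_along(genes)) {
        idx <- rows[[genes[k]]]
        sub <- ifm[idx, , drop = FALSE]
        ok <- colSums(!is.na(sub)) > 0
        if (!any(ok)) next
        top <- rownames(sub)[apply(sub[, ok, drop = FALSE], 2, which.max)]
        tab <- table(top)
        out$dominant[k] <- names(tab)[which.max(tab)]
        out$frac[k] <- max(tab) / sum(ok)
    }
    out
}

#' Apply the six-step pre-filter
#'
#' Steps, in order, each on the set surviving the previous ones:
#' \enumerate{
#'   \item transcript CPM >= 1 in at least `nSmall` samples;
#'   \item transcript has a positive count in at least fraction `pr` of the
#'     case samples and of the control samples;
#'   \item gene count >= `gc` in at least `gn` samples;
#'   \item transcript IF > `f` in at least `nSmall` samples;
#'   \item at least 2 surviving transcripts per gene;
#'   \item the same isoform carries the largest IF in at least fraction
#'     `pd` of control samples (consistently dominant isoform).
#' }
#'
#' @param object a [DTUDataSet-class].
#' @param params list from [filterParams()].
#' @return list with `data` (the filtered `DTUDataSet`) and `report`, a
#'   data.frame of per-step transcript/gene attrition plus the per-gene
#'   dominant control isoform for surviving genes.
#' @examples
#' set.seed(1)
#' dds <- simulateCohort(cohortParams(nGenes = 50, nCase = 12, nControl = 12))
#' fp <- filterParams()
#' filt <- applyPrefilter(dds, fp)
#' filt$report$steps
#' @export
applyPrefilter <- function(object, params = filterParams()) {
    stopifnot(is(object, "DTUDataSet"))
    cts <- counts(object)
    isCase <- object$condition == "case"
    keepTx <- rownames(cts)
    steps <- data.frame(step = 1:6, applied = 1:6 %in% params$steps,
                        transcripts_removed = 0L, genes_removed = 0L)
    .surv <- function() cts[keepTx, , drop = FALSE]
    .genes <- function(tx) {
        g <- geneIds(object)[match(tx, rownames(object))]
        names(g) <- tx
        g
    }
    .record <- function(i, before) {
        steps$transcripts_removed[i] <<- length(before) - length(keepTx)
        steps$genes_removed[i] <<-
            length(unique(.genes(before))) - length(unique(.genes(keepTx)))
    }

    if (1 %in% params$steps && length(keepTx)) {
        before <- keepTx
        cpm <- computeCPM(.surv(), colSums(cts))
        keepTx <- keepTx[rowSums(cpm >= 1) >= params$nSmall]
        .record(1, before)
    }
    if (2 %in% params$steps && length(keepTx)) {
        before <- keepTx
        s <- .surv()
        okCase <- rowMeans(s[, isCase, drop = FALSE] > 0) >= params$pr
        okCtrl <- rowMeans(s[, !isCase, drop = FALSE] > 0) >= params$pr
        keepTx <- keepTx[okCase & okCtrl]
        .record(2, before)
    }
    if (3 %in% params$steps && length(keepTx)) {
        before <- keepTx
        s <- .surv()
        gene <- .genes(keepTx)
        gt <- rowsum(s, gene, reorder = FALSE)
        okGene <- rownames(gt)[rowSums(gt >= params$gc) >= params$gn]
        keepTx <- keepTx[gene %in% okGene]
        .record(3, before)
    }
    if (4 %in% params$steps && length(keepTx)) {
        before <- keepTx
        s <- .surv()
        ifm <- computeIF(s, txGene(object))
        keepTx <- keepTx[rowSums(ifm > params$f, na.rm = TRUE) >=
                             params$nSmall]
        .record(4, before)
    }
    if (5 %in% params$steps && length(keepTx)) {
        before <- keepTx
        gene <- .genes(keepTx)
        tab <- table(gene)
        keepTx <- keepTx[gene %in% names(tab)[tab >= 2]]
        .record(5, before)
    }
    dominant <- NULL
    if (6 %in% params$steps && length(keepTx)) {
        before <- keepTx
        s <- .surv()
        gene <- .genes(keepTx)
        ifm <- computeIF(s, txGene(object))[, !isCase, drop = FALSE]
        dom <- .dominance(ifm, gene)
        okGene <- dom$gene_id[dom$frac >= params$pd]
        keepTx <- keepTx[gene %in% okGene]
        dominant <- dom[dom$gene_id %in% okGene, ]
        .record(6, before)
    }
    if (!length(keepTx))
        warning("no transcripts survive the pre-filter")
    list(data = object[keepTx, ],
         report = list(steps = steps,
                       surviving_transcripts = keepTx,
                       surviving_genes = unique(.genes(keepTx)),
                       dominant = dominant))
}

#' Consistently dominant genes of the control group
#'
#' Stand-alone application of pre-filter step 6: returns, per gene, the
#' control-group dominant isoform and whether it is dominant in at least
#' fraction `pd` of control samples. Used by the simulator to select genes
#' eligible for a dominance-swap DTU injection.
#'
#' @param object a [DTUDataSet-class].
#' @param pd consistency fraction.
#' @return data.frame with `gene_id`, `dominant`, `frac`, `eligible`.
#' @export
dominantGenes <- function(object, pd = 0.75) {
    isCtrl <- object$condition == "control"
    ifm <- ifValues(object)[, isCtrl, drop = FALSE]
    dom <- .dominance(ifm, geneIds(object))
    dom$eligible <- dom$frac >= pd
    dom
}

#' Filtered-CPM gating mask
#'
#' Gene-level CPM computed on the pre-filter-surviving gene subset only
#' (library size = per-sample total of surviving genes' counts). Samples
#' with a gene CPM below `cpmGate` are masked out of the rank tests of
#' that gene's transcripts: at such depths a handful of reads can swing an
#' isoform fraction wildly without carrying usage information.
#'
#' @param object a prefiltered [DTUDataSet-class].
#' @param cpmGate gating threshold (default 10).
#' @return logical matrix, genes x samples; `TRUE` where the sample is kept.
#' @export
filteredCpmMask <- function(object, cpmGate = 10) {
    gene <- geneIds(object)
    gt <- rowsum(counts(object), gene, reorder = FALSE)
    cpm <- computeCPM(gt, colSums(gt))
    cpm >= cpmGate
}

#' MAD-based sample quality control
#'
#' Counts, per sample, the genes whose filtered CPM falls below `cpmGate`,
#' and drops samples whose modified z-score
#' `0.6745 * (x - median) / MAD` exceeds `madCutoff` on the high side
#' (too many low-expression genes).
#'
#' @param object a prefiltered [DTUDataSet-class] with >= 4 samples.
#' @param cpmGate filtered-CPM threshold.
#' @param madCutoff modified z-score cutoff (conventional 3.5).
#' @return character vector of retained sample ids.
#' @export
sampleQC <- function(object, cpmGate = 10, madCutoff = 3.5) {
    if (ncol(object) < 4)
        stop("sample QC needs at least 4 samples")
    low <- colSums(!filteredCpmMask(object, cpmGate))
    md <- stats::median(low)
    mad0 <- stats::median(abs(low - md))
    if (mad0 == 0) {
        warning("MAD is zero; no sample dropped")
        return(colnames(object))
    }
    z <- 0.6745 * (low - md) / mad0
    colnames(object)[z <= madCutoff]
}
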