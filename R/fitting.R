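## Hyperparameter fitting: simulate DTU into random halves of the user's
## control group, then leave-one-out cross-validate (h, kappa) over a grid,
## scoring gene-level F. The null distribution does not depend on h (its
## iterations use random split points, not the KDE), so each experiment
## needs one null build plus one test pass per bandwidth.

#' F-score
#'
#' Harmonic-mean F of precision and recall in count form,
#' `F = 2tp / (2tp + fp + fn)`.
#'
#' @param tp,fp,fn non-negative counts.
#' @return numeric in `[0, 1]`; defined as 0 (with a warning) when all
#'   three counts are zero.
#' @export
fScore <- function(tp, fp, fn) {
    stopifnot(tp >= 0, fp >= 0, fn >= 0)
    if (tp + fp + fn == 0) {
        warning("F-score undefined with tp = fp = fn = 0; returning 0")
        return(0)
    }
    2 * tp / (2 * tp + fp + fn)
}

#' Fitting configuration
#'
#' @param ne number of simulated experiments.
#' @param ng spliceotypes per experiment (1 for simple genetic
#'   architectures where no case substructure is expected).
#' @param epsilon injection noise half-width.
#' @param nDTU,genesPer injection sizes per experiment.
#' @param hGrid,kappaGrid search grids.
#' @param nSmall,nIterations detection settings used during fitting.
#' @param filter [filterParams()] list; step 6 is always skipped here
#'   (keeping it would bias the pre-filtered gene set toward the genes
#'   about to be injected).
#' @return named list.
#' @export
fitConfig <- function(ne = 10, ng = 5, epsilon = 0.05, nDTU = 100,
                      genesPer = 30, hGrid = seq(0.02, 0.20, by = 0.01),
                      kappaGrid = seq(0.1, 1, by = 0.1), nSmall = 12,
                      nIterations = 100, filter = filterParams()) {
    stopifnot(ne >= 2, length(hGrid) >= 1, length(kappaGrid) >= 1)
    filter$steps <- setdiff(filter$steps, 6L)
    list(ne = ne, ng = ng, epsilon = epsilon, nDTU = nDTU,
         genesPer = genesPer, hGrid = hGrid, kappaGrid = kappaGrid,
         nSmall = nSmall, nIterations = nIterations, filter = filter)
}

#' Build the simulated fitting experiments from a control group
#'
#' Each experiment randomly halves the control samples into simulated
#' case/control groups, pre-filters (without the dominance step), and
#' injects `ng`-spliceotype DTU per the simulator recipe, keeping the
#' truth.
#'
#' @param object a [DTUDataSet-class]; only its control samples are used.
#' @param config list from [fitConfig()].
#' @return list of experiments, each `list(data, truth, universe)`.
#' @export
makeFitExperiments <- function(object, config = fitConfig()) {
    ctrlIds <- colnames(object)[object$condition == "control"]
    n <- length(ctrlIds)
    if (n < 16)
        stop("hyperparameter fitting needs at least 16 control samples; ",
             "fitted thresholds from fewer are unreliable (>= 32 ",
             "recommended)")
    if (n < 32)
        warning("control group below 32 samples; fitted values may be noisy")
    cts <- counts(object)[, ctrlIds, drop = FALSE]
    lapply(seq_len(config$ne), function(e) {
        perm <- sample(ctrlIds)
        simCase <- perm[seq_len(floor(n / 2))]
        meta <- data.frame(
            sample_id = ctrlIds,
            condition = ifelse(ctrlIds %in% simCase, "case", "control"),
            stringsAsFactors = FALSE)
        dds <- DTUDataSet(cts, txGene(object), meta)
        filt <- applyPrefilter(dds, config$filter)
        inj <- injectDTU(filt$data, nDTU = config$nDTU,
                         nSpliceotypes = config$ng,
                         genesPer = config$genesPer,
                         epsilon = config$epsilon)
        list(data = inj$data, truth = inj$truth,
             universe = unique(geneIds(inj$data)))
    })
}

## Cached detection over the grid for one experiment: one jitter + null,
## one test pass per h. Returns p matrix (transcripts x h) and the null
## minima. Seeded so the result is independent of evaluation order.
.gridScan <- function(exp, config, seed) {
    obj <- exp$data
    isCase <- obj$condition == "case"
    gene <- geneIds(obj)
    set.seed(seed)
    ifm <- preprocessIF(ifValues(obj))
    null <- buildNullDistribution(
        ifm[, !isCase, drop = FALSE],
        nullParams(nIterations = config$nIterations),
        caseSize = sum(isCase))
    pMat <- vapply(config$hGrid, function(h)
        .testAll(ifm, gene, isCase, h, config$nSmall)$results$p,
        numeric(nrow(ifm)))
    list(p = pMat, gene = gene, null = null)
}

## F-score of one experiment at one grid point, from its cached scan
.gridF <- function(scan, exp, hIdx, kappa) {
    thr <- nullThreshold(scan$null, kappa)
    p <- scan$p[, hIdx]
    called <- unique(scan$gene[!is.na(p) & p <= thr])
    evaluateCalls(called, exp$truth, exp$universe)$F
}

#' Leave-one-out cross-validated (h, kappa) fit
#'
#' For each held-out experiment the remaining experiments are scored at
#' every grid pair and the pair with the best mean F is selected, then
#' evaluated on the held-out experiment. The final estimate is the most
#' frequent selected pair; ties (in both the per-step argmax and the
#' consensus) break toward the more conservative pair — smaller kappa,
#' then larger h. Experiments are scanned with per-experiment derived
#' seeds, so the result is invariant to evaluation order.
#'
#' @param experiments list from [makeFitExperiments()].
#' @param config list from [fitConfig()].
#' @return list with `hStar`, `kappaStar`, `Fbar`, `perIteration`
#'   (data.frame of per-step selections and held-out F), and `gridF`
#'   (experiments x h x kappa array of F-scores).
#' @export
fitHyperparameters <- function(experiments, config = fitConfig()) {
    ne <- length(experiments)
    stopifnot(ne >= 2)
    seeds <- sample.int(.Machine$integer.max, ne)
    scans <- lapply(seq_len(ne), function(e)
        .gridScan(experiments[[e]], config, seeds[e]))
    nh <- length(config$hGrid); nk <- length(config$kappaGrid)
    gridF <- array(NA_real_, c(ne, nh, nk),
                   dimnames = list(NULL, paste0("h=", config$hGrid),
                                   paste0("kappa=", config$kappaGrid)))
    for (e in seq_len(ne))
        for (i in seq_len(nh))
            for (k in seq_len(nk))
                gridF[e, i, k] <- .gridF(scans[[e]], experiments[[e]],
                                         i, config$kappaGrid[k])
    ## conservative tie-break: smaller kappa first, then larger h
    pickBest <- function(Fmat) {
        best <- -Inf; pick <- c(NA, NA)
        for (k in seq_len(nk))
            for (i in rev(seq_len(nh)))
                if (Fmat[i, k] > best) {
                    best <- Fmat[i, k]; pick <- c(i, k)
                }
        pick
    }
    perIter <- data.frame(step = seq_len(ne), hStar = NA_real_,
                          kappaStar = NA_real_, F = NA_real_)
    for (s in seq_len(ne)) {
        meanF <- apply(gridF[-s, , , drop = FALSE], c(2, 3), mean)
        pick <- pickBest(meanF)
        perIter$hStar[s] <- config$hGrid[pick[1]]
        perIter$kappaStar[s] <- config$kappaGrid[pick[2]]
        perIter$F[s] <- gridF[s, pick[1], pick[2]]
    }
    pairs <- paste(perIter$hStar, perIter$kappaStar)
    tab <- table(pairs)
    modal <- names(tab)[tab == max(tab)]
    cand <- unique(perIter[pairs %in% modal, c("hStar", "kappaStar")])
    cand <- cand[order(cand$kappaStar, -cand$hStar), , drop = FALSE]
    list(hStar = cand$hStar[1], kappaStar = cand$kappaStar[1],
         Fbar = mean(perIter$F), perIteration = perIter, gridF = gridF)
}
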