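## End-to-end detection: per-transcript tests on preprocessed IFs, the
## control-split null threshold, optional inferential-replicate majority
## voting, likelihood-score gene flags, and the binary DTU event matrix.

## Run testTranscript over every row of a preprocessed IF matrix.
## mask: optional logical gene x sample matrix (filtered-CPM gate);
## masked-out samples are removed from that gene's transcripts.
.testAll <- function(ifm, gene, isCase, h, nSmall, mask = NULL) {
    nT <- nrow(ifm)
    caseIds <- colnames(ifm)[isCase]
    ctrlIds <- colnames(ifm)[!isCase]
    res <- data.frame(transcript_id = rownames(ifm), gene_id = gene,
                      p_left = NA_real_, p_right = NA_real_, p = NA_real_,
                      split_point = NA_real_, mode = NA_character_,
                      skipped = NA_character_, stringsAsFactors = FALSE)
    v <- matrix(0L, nT, ncol(ifm),
                dimnames = list(rownames(ifm), colnames(ifm)))
    for (j in seq_len(nT)) {
        keep <- rep(TRUE, ncol(ifm))
        if (!is.null(mask) && gene[j] %in% rownames(mask))
            keep <- mask[gene[j], colnames(ifm)]
        x <- ifm[j, isCase & keep]
        y <- ifm[j, (!isCase) & keep]
        tr <- testTranscript(x, y, h, nSmall)
        res$p_left[j] <- tr$p_left; res$p_right[j] <- tr$p_right
        res$p[j] <- tr$p; res$split_point[j] <- tr$split_point
        res$mode[j] <- tr$mode; res$skipped[j] <- tr$skipped
        v[j, names(tr$v)] <- tr$v
    }
    list(results = res, v = v)
}

#' Majority vote over inferential replicates
#'
#' A call stands only if strictly more than half of the replicate runs
#' made it (a tie is a no-call).
#'
#' @param calls logical vector (or list of logicals) of per-replicate
#'   calls for one transcript.
#' @return logical.
#' @export
majorityVote <- function(calls) {
    calls <- unlist(calls)
    if (!length(calls)) stop("majority vote needs at least one replicate")
    sum(calls) > length(calls) / 2
}

#' Likelihood-score flags for candidate DTU genes
#'
#' For each candidate transcript the control-group KDE is evaluated at the
#' case IFs; the likelihood score L is the mean log density (mean rather
#' than sum, so L does not scale with subgroup size). When the case group
#' is split, each tail gets its own score and the smaller one is assigned.
#' Scores are screened with a modified z-score MAD test (cutoff 3.5, low
#' side only: case IFs sitting where the control density vanishes are the
#' suspicious direction), and a gene is flagged when at least one of its
#' transcripts is an outlier.
#'
#' @param results per-transcript results data.frame (candidates only).
#' @param ifm preprocessed IF matrix over all samples.
#' @param isCase logical vector over columns of `ifm`.
#' @param h KDE bandwidth.
#' @param madCutoff modified z-score threshold.
#' @return data.frame with `gene_id`, `transcript_id`, `L`, `outlier`,
#'   `gene_flag`.
#' @export
likelihoodFlags <- function(results, ifm, isCase, h, madCutoff = 3.5) {
    empty <- data.frame(gene_id = character(), transcript_id = character(),
                        L = numeric(), outlier = logical(),
                        gene_flag = logical(), stringsAsFactors = FALSE)
    if (!nrow(results)) return(empty)
    L <- rep(NA_real_, nrow(results))
    for (k in seq_len(nrow(results))) {
        j <- results$transcript_id[k]
        yC <- ifm[j, !isCase]; yC <- yC[!is.na(yC)]
        x <- ifm[j, isCase]; x <- x[!is.na(x)]
        if (length(yC) < 2 || !length(x)) next
        kde <- fitIFDensity(yC, h)
        dens <- function(v) {
            d <- stats::approx(kde$grid, kde$density, v, rule = 2)$y
            pmax(d, 1e-12)
        }
        if (!is.na(results$split_point[k])) {
            m <- results$split_point[k]
            parts <- list(x[x <= m], x[x > m])
            parts <- parts[lengths(parts) > 0]
            L[k] <- min(vapply(parts, function(p) mean(log(dens(p))),
                               numeric(1)))
        } else {
            L[k] <- mean(log(dens(x)))
        }
    }
    med <- stats::median(L, na.rm = TRUE)
    mad0 <- stats::median(abs(L - med), na.rm = TRUE)
    out <- if (mad0 > 0) {
        z <- 0.6745 * (L - med) / mad0
        !is.na(z) & z < -madCutoff
    } else rep(FALSE, length(L))
    out[!is.na(L) & L == -Inf] <- TRUE
    flagged <- unique(results$gene_id[out])
    data.frame(gene_id = results$gene_id,
               transcript_id = results$transcript_id, L = L,
               outlier = out, gene_flag = results$gene_id %in% flagged,
               stringsAsFactors = FALSE)
}

#' Calibration chart table
#'
#' One row per tested transcript: the median of its null p-values across
#' the control-split iterations against the p-value observed in the actual
#' case/control comparison. Plotted on -log10 axes, transcripts far above
#' the diagonal are the DTU candidates; no transformation is applied here.
#'
#' @param null a [NullDistribution-class] built with per-transcript
#'   p-values retained.
#' @param results per-transcript results data.frame (or a
#'   [DTUResult-class]).
#' @return data.frame with `transcript_id`, `median_null_p`, `observed_p`.
#' @export
calibrationTable <- function(null, results) {
    if (is(results, "DTUResult")) {
        if (missing(null)) null <- results@null
        results <- results@results
    }
    med <- apply(null@perTranscript, 1, stats::median, na.rm = TRUE)
    idx <- match(results$transcript_id, rownames(null@perTranscript))
    keep <- !is.na(idx)
    if (any(!keep))
        message(sum(!keep), " transcript(s) missing from the null; skipped")
    data.frame(transcript_id = results$transcript_id[keep],
               median_null_p = med[idx[keep]],
               observed_p = results$p[keep], stringsAsFactors = FALSE)
}

#' Detect differential transcript usage
#'
#' The main entry point. On a (pre-filtered) [DTUDataSet-class] it
#' computes isoform fractions, rounds and jitters them, tests every
#' transcript for a case-subgroup split against the controls, builds the
#' control-split null, and calls transcripts whose observed p-value falls
#' at or below the `kappa` threshold. With inferential replicate count
#' matrices the per-transcript testing is repeated on every replicate and
#' calls must survive a strict majority vote. Gene-level calls are the
#' union over transcripts; the binary DTU matrix takes each called gene's
#' event vector from its smallest-p transcript.
#'
#' All randomness (jitter, null splits) draws from the R session RNG:
#' fix `set.seed()` for reproducible runs.
#'
#' @param object a [DTUDataSet-class], normally the output of
#'   [applyPrefilter()].
#' @param h KDE bandwidth (default 0.09, the routine fitted value; use
#'   [fitHyperparameters()] to fit per dataset, or `h = 1` to suppress
#'   subgroup search entirely).
#' @param kappa null-quantile parameter (default 0.6; smaller is more
#'   conservative).
#' @param nSmall minimum subgroup size.
#' @param nIterations control-split null iterations.
#' @param replicates optional list of inferential-replicate count matrices
#'   sharing ids with `counts(object)`.
#' @param cpmGate optional filtered-CPM gate; `NULL` (default) disables
#'   masking.
#' @param flagMadCutoff MAD cutoff for the likelihood flags.
#' @return a [DTUResult-class].
#' @examples
#' set.seed(1)
#' dds <- simulateCohort(cohortParams(nGenes = 40))
#' sim <- injectDTU(dds, nDTU = 5, nSpliceotypes = 1, genesPer = 5)
#' filt <- applyPrefilter(sim$data, filterParams(steps = c(1, 5, 6)))
#' res <- detectDTU(filt$data, nIterations = 20)
#' res
#' @export
detectDTU <- function(object, h = 0.09, kappa = 0.6, nSmall = 12,
                      nIterations = 100, replicates = NULL, cpmGate = NULL,
                      flagMadCutoff = 3.5) {
    stopifnot(is(object, "DTUDataSet"))
    isCase <- object$condition == "case"
    if (!any(isCase) || !any(!isCase))
        stop("both case and control groups must be non-empty")
    gene <- geneIds(object)
    mask <- if (!is.null(cpmGate)) filteredCpmMask(object, cpmGate)
    ifm <- preprocessIF(ifValues(object))
    point <- .testAll(ifm, gene, isCase, h, nSmall, mask)
    null <- buildNullDistribution(
        ifm[, !isCase, drop = FALSE],
        nullParams(nIterations = nIterations, kappa = kappa),
        caseSize = sum(isCase))
    thr <- nullThreshold(null, kappa)
    res <- point$results
    res$call <- !is.na(res$p) & res$p <= thr
    if (!is.null(replicates)) {
        votes <- matrix(FALSE, nrow(res), length(replicates) + 1L)
        votes[, 1] <- res$call
        for (r in seq_along(replicates)) {
            rc <- replicates[[r]][rownames(object), colnames(object),
                                  drop = FALSE]
            rif <- preprocessIF(computeIF(rc, txGene(object)))
            rp <- .testAll(rif, gene, isCase, h, nSmall, mask)$results$p
            votes[, r + 1] <- !is.na(rp) & rp <= thr
        }
        res$call <- apply(votes, 1, majorityVote)
    }
    cand <- res[res$call, , drop = FALSE]
    flags <- likelihoodFlags(cand, ifm, isCase, h, flagMadCutoff)
    vMat <- point$v[res$call, , drop = FALSE]
    caseIds <- colnames(object)[isCase]
    genesCalled <- unique(cand$gene_id)
    M <- matrix(0L, length(genesCalled), length(caseIds),
                dimnames = list(genesCalled, caseIds))
    for (g in genesCalled) {
        sub <- cand[cand$gene_id == g, , drop = FALSE]
        win <- sub$transcript_id[which.min(sub$p)]
        M[g, ] <- point$v[win, caseIds]
    }
    new("DTUResult", results = res, dtuMatrix = M, vMatrix = vMat,
        flags = flags, null = null, threshold = thr,
        params = list(h = h, kappa = kappa, nSmall = nSmall,
                      nIterations = nIterations, cpmGate = cpmGate))
}
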