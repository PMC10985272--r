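## The control-split null: an empirical distribution of minimal U-statistic
## p-values estimated by repeatedly halving the control group, comparing
## the halves tail-against-tail per transcript, and keeping the smallest
## p-value over transcripts. Emulates min-P style procedures: a single
## global null absorbs the dataset's dispersion without per-transcript
## dispersion modelling.

#' Null-build parameters
#'
#' @param nIterations number of control-split iterations (100 is the
#'   routine evaluation setting; larger values refine the threshold grid).
#' @param kappa fraction in (0, 1] converting the null into a calling
#'   threshold, see [nullThreshold()].
#' @param smallSample `NA` to trigger automatically when the control group
#'   has fewer than 16 samples (each half then below 8, where the normal
#'   approximation of the U statistic degrades), or an explicit logical.
#' @param leftTailFraction in small-sample mode the per-iteration minimum
#'   is replaced by a uniform draw from this lowest fraction of the
#'   iteration's p-values, restoring p-value variability.
#' @return named list.
#' @export
nullParams <- function(nIterations = 100, kappa = 0.6, smallSample = NA,
                       leftTailFraction = 0.01) {
    stopifnot(nIterations >= 1, kappa > 0, kappa <= 1,
              leftTailFraction > 0, leftTailFraction <= 1)
    list(nIterations = as.integer(nIterations), kappa = kappa,
         smallSample = smallSample, leftTailFraction = leftTailFraction)
}

#' Pad small control halves with imputed isoform fractions
#'
#' With fewer than 16 controls each random half has fewer than 8 samples
#' and the rank-test p-values collapse onto a few discrete values. Both
#' halves are therefore padded up to the sizes of the actual case and
#' control groups with IFs resampled (with replacement) from the
#' transcript's own pooled control IFs, which preserves the transcript's
#' marginal distribution while adding rank noise.
#'
#' @param h1,h2 numeric IF vectors (the two halves) for one transcript.
#' @param targetCase,targetControl sizes to pad `h1`/`h2` to.
#' @param pool pooled control IFs of the transcript to draw imputed values
#'   from.
#' @return list of the two padded vectors.
#' @export
imputeSmallGroups <- function(h1, h2, targetCase, targetControl, pool) {
    pad <- function(v, target) {
        if (length(v) >= target || !length(pool)) return(v)
        c(v, sample(pool, target - length(v), replace = TRUE))
    }
    list(h1 = pad(h1, targetCase), h2 = pad(h2, targetControl))
}

#' Draw a left-tail p-value for one iteration
#'
#' Small-sample replacement for the per-iteration minimum: a uniform draw
#' from the lowest `ceiling(fraction * length(p))` p-values.
#'
#' @param p per-transcript p-values of one iteration (NA allowed).
#' @param fraction left-tail fraction.
#' @return list with `p` (the drawn value) and `transcript` (its index).
#' @export
leftTailDraw <- function(p, fraction = 0.01) {
    ok <- which(!is.na(p))
    if (!length(ok)) return(list(p = NA_real_, transcript = NA_integer_))
    k <- min(length(ok), ceiling(fraction * length(ok)))
    lowest <- ok[order(p[ok])[seq_len(k)]]
    pick <- if (length(lowest) == 1) lowest else sample(lowest, 1)
    list(p = p[pick], transcript = pick)
}

## One control-split iteration. ifControl: transcripts x control samples
## matrix (already preprocessed). Returns per-transcript minimal tail
## p-values. In regular mode a single random split point shared by all
## transcripts defines the tails; in small-sample mode halves are padded
## and compared whole.
.nullIteration <- function(ifControl, caseSize, smallSample) {
    nC <- ncol(ifControl)
    half <- sample(nC)
    n1 <- ceiling(nC / 2)              # odd counts: larger first half
    i1 <- half[seq_len(n1)]
    i2 <- half[-seq_len(n1)]
    os <- if (smallSample) NA_real_ else stats::runif(1)
    nT <- nrow(ifControl)
    p <- rep(NA_real_, nT)
    for (j in seq_len(nT)) {
        x1 <- ifControl[j, i1]; x1 <- x1[!is.na(x1)]
        x2 <- ifControl[j, i2]; x2 <- x2[!is.na(x2)]
        if (length(x1) < .MIN_TEST_N || length(x2) < .MIN_TEST_N) next
        if (smallSample) {
            padded <- imputeSmallGroups(x1, x2, caseSize, nC,
                                        c(x1, x2))
            p[j] <- .mwuP(padded$h1, padded$h2)
        } else {
            l1 <- x1[x1 <= os]; r1 <- x1[x1 > os]
            l2 <- x2[x2 <= os]; r2 <- x2[x2 > os]
            pl <- if (length(l1) >= .MIN_TEST_N &&
                      length(l2) >= .MIN_TEST_N) .mwuP(l1, l2) else NA_real_
            pr <- if (length(r1) >= .MIN_TEST_N &&
                      length(r2) >= .MIN_TEST_N) .mwuP(r1, r2) else NA_real_
            if (!is.na(pl) || !is.na(pr))
                p[j] <- min(pl, pr, na.rm = TRUE)
        }
    }
    p
}

#' Build the empirical null distribution from the control group
#'
#' Runs `nIterations` control-split iterations and accumulates one minimal
#' p-value per iteration. To keep a single overdispersed transcript from
#' dominating the null, a transcript contributes the minimum at most once
#' across all iterations. Per-transcript p-values of every iteration are
#' retained for the calibration chart ([calibrationTable()]).
#'
#' @param ifControl matrix of preprocessed IFs, transcripts x control
#'   samples (at least 2 controls), or a [DTUDataSet-class] from which the
#'   control IFs are taken (with rounding/jitter applied).
#' @param params list from [nullParams()].
#' @param caseSize size of the case group, used for small-sample padding.
#' @return a [NullDistribution-class].
#' @export
buildNullDistribution <- function(ifControl, params = nullParams(),
                                  caseSize = NULL) {
    if (is(ifControl, "DTUDataSet")) {
        obj <- ifControl
        if (is.null(caseSize)) caseSize <- sum(obj$condition == "case")
        ifControl <- preprocessIF(
            ifValues(obj)[, obj$condition == "control", drop = FALSE])
    }
    if (ncol(ifControl) < 2)
        stop("need at least 2 control samples")
    if (is.null(caseSize)) caseSize <- ncol(ifControl)
    smallSample <- params$smallSample
    if (is.na(smallSample)) smallSample <- ncol(ifControl) < 16
    nT <- nrow(ifControl)
    perT <- matrix(NA_real_, nT, params$nIterations,
                   dimnames = list(rownames(ifControl), NULL))
    pPrime <- rep(NA_real_, params$nIterations)
    used <- logical(nT)
    for (s in seq_len(params$nIterations)) {
        p <- .nullIteration(ifControl, caseSize, smallSample)
        perT[, s] <- p
        avail <- p
        avail[used] <- NA_real_
        if (all(is.na(avail))) next
        if (smallSample) {
            draw <- leftTailDraw(avail, params$leftTailFraction)
            pPrime[s] <- draw$p
            used[draw$transcript] <- TRUE
        } else {
            j <- which.min(avail)
            pPrime[s] <- avail[j]
            used[j] <- TRUE
        }
    }
    new("NullDistribution", pPrime = pPrime, perTranscript = perT,
        nIterations = params$nIterations,
        sampledTranscripts = rownames(ifControl)[used],
        smallSample = smallSample)
}

#' Convert the null into a p-value calling threshold
#'
#' The threshold is the k-th smallest element of the null's minimal
#' p-values with `k = max(1, floor(kappa * n))`; e.g. `kappa = 0.1` over
#' 1000 iterations selects the 100th smallest. Transcripts with observed
#' p-value at or below the threshold become DTU candidates.
#'
#' @param null a [NullDistribution-class] (or numeric vector of minimal
#'   p-values).
#' @param kappa fraction in (0, 1].
#' @return numeric threshold.
#' @export
nullThreshold <- function(null, kappa) {
    if (is(null, "NullDistribution")) null <- null@pPrime
    null <- null[!is.na(null)]
    if (!length(null)) stop("empty null distribution")
    if (!is.numeric(kappa) || kappa <= 0 || kappa > 1)
        stop("kappa must lie in (0, 1]")
    k <- max(1, floor(kappa * length(null)))
    sort(null, partial = k)[k]
}
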