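## Confounder control: a candidate DTU transcript is kept only if its
## event indicator v explains the IF partition better than every provided
## covariate does. Importance is measured by permutation on an ensemble of
## depth-one regression trees ("stubs") so the question is purely "which
## single column partitions high vs low IF best", not prediction accuracy.

## One depth-1 tree on a bootstrap sample. Split (column, threshold)
## minimizes the L1 loss against the leaf means; leaf prediction is the
## leaf mean. No split if the bootstrap node holds fewer than nSmall
## samples or no candidate threshold improves on the root.
.fitStub <- function(X, y, idx, nSmall) {
    xb <- X[idx, , drop = FALSE]
    yb <- y[idx]
    best <- list(col = NA_integer_, thr = NA_real_,
                 loss = sum(abs(yb - mean(yb))))
    if (length(idx) >= nSmall) {
        ## columns are scanned in random order per tree, so two columns
        ## that induce the same partition (tied loss) share the splits
        ## across the ensemble instead of the first one absorbing all of
        ## them -- a covariate that separates exactly as well as the
        ## event vector must show comparable importance
        for (col in sample(ncol(X))) {
            vals <- sort(unique(xb[, col]))
            if (length(vals) < 2) next
            thrs <- (vals[-1] + vals[-length(vals)]) / 2
            for (thr in thrs) {
                left <- xb[, col] <= thr
                loss <- sum(abs(yb[left] - mean(yb[left]))) +
                    sum(abs(yb[!left] - mean(yb[!left])))
                if (loss < best$loss)
                    best <- list(col = col, thr = thr, loss = loss)
            }
        }
    }
    best[c("col", "thr")]
}

#' Fit an ensemble of depth-one regression stubs
#'
#' Each of `nTrees` trees is trained on a bootstrap of the full sample
#' size; the root is split only when it holds at least `nSmall` samples,
#' and the split minimizes the L1 loss around the leaf means of the
#' response.
#'
#' @param X numeric design matrix (rows = samples; columns = the binary
#'   event vector plus encoded covariates).
#' @param y numeric response (the transcript's IFs).
#' @param nTrees ensemble size.
#' @param nSmall minimum samples to split the root.
#' @return list of trees, each `list(col, thr)` with `col = NA` for a
#'   no-split stub.
#' @export
fitStubForest <- function(X, y, nTrees = 100, nSmall = 12) {
    X <- as.matrix(X)
    stopifnot(nrow(X) == length(y))
    lapply(seq_len(nTrees), function(t)
        .fitStub(X, y, sample(nrow(X), replace = TRUE), nSmall))
}

#' Coefficient of determination of a stub forest
#'
#' Per tree, samples are assigned to the two leaves by the stored split
#' and `R^2 = 1 - u/v` with `u` the within-leaf sum of squares around the
#' leaf means and `v` the total sum of squares; a no-split stub scores 0,
#' as does a zero-variance response. The ensemble score is the mean of
#' tree-level scores.
#'
#' @param forest list from [fitStubForest()].
#' @param X,y evaluation data.
#' @return numeric R-squared.
#' @export
forestR2 <- function(forest, X, y) {
    X <- as.matrix(X)
    v <- sum((y - mean(y))^2)
    if (v == 0) return(0)
    r2 <- vapply(forest, function(tr) {
        if (is.na(tr$col)) return(0)
        left <- X[, tr$col] <= tr$thr
        if (all(left) || !any(left)) return(0)
        u <- sum((y[left] - mean(y[left]))^2) +
            sum((y[!left] - mean(y[!left]))^2)
        1 - u / v
    }, numeric(1))
    mean(r2)
}

#' Permutation importance of one design column
#'
#' For each of `nPerm` permutations the column is shuffled, the ensemble
#' R-squared recomputed, and the importance recorded as the decrease
#' `gamma = R2(original) - R2(shuffled)`.
#'
#' @param forest list from [fitStubForest()].
#' @param X,y evaluation data.
#' @param column column index to permute.
#' @param nPerm number of permutations (default 50).
#' @return numeric vector of `nPerm` gamma values.
#' @export
permutationImportance <- function(forest, X, y, column, nPerm = 50) {
    X <- as.matrix(X)
    base <- forestR2(forest, X, y)
    vapply(seq_len(nPerm), function(p) {
        Xp <- X
        Xp[, column] <- sample(Xp[, column])
        base - forestR2(forest, Xp, y)
    }, numeric(1))
}

## one-hot encode a covariate data.frame; numeric columns pass through.
## Returns the matrix plus a grouping vector mapping columns back to the
## original covariate names.
.encodeCovariates <- function(cov) {
    cols <- list(); groups <- character()
    for (nm in colnames(cov)) {
        x <- cov[[nm]]
        if (is.numeric(x)) {
            cols[[length(cols) + 1L]] <- x
            groups <- c(groups, nm)
        } else {
            lev <- unique(as.character(x))
            if (length(lev) < 2) {
                warning("covariate '", nm, "' has a single level; dropped")
                next
            }
            for (l in lev) {
                cols[[length(cols) + 1L]] <- as.numeric(x == l)
                groups <- c(groups, nm)
            }
        }
    }
    if (!length(cols))
        return(list(X = matrix(numeric(0), nrow(cov), 0),
                    groups = character()))
    list(X = do.call(cbind, cols), groups = groups)
}

#' Veto confounded DTU candidates
#'
#' For every candidate transcript a design matrix `[v, x1..xk]` over all
#' samples is regressed on the transcript's IFs with a depth-one stub
#' forest, and permutation importances are collected for the event vector
#' `v` and each covariate. The candidate is kept only when the first
#' quartile of the `v` importances exceeds the largest third quartile
#' among the covariates; i.e. `v` must dominate every covariate even
#' under permutation noise. Categorical covariates are one-hot encoded and
#' score per original covariate as the per-permutation maximum over their
#' dummies (conservative toward dropping). With no covariates every
#' candidate is kept.
#'
#' @param result a [DTUResult-class] from [detectDTU()].
#' @param object the [DTUDataSet-class] the result came from; covariate
#'   columns are taken from its `colData`.
#' @param covariates character vector of covariate column names (default:
#'   every `colData` column except `condition`).
#' @param nTrees,nPerm,nSmall forest and permutation settings.
#' @return list with `keep` (named logical over candidate transcripts),
#'   `importance` (data.frame of Q1/Q3 summaries), and `result`, a copy of
#'   `result` with vetoed calls removed and the DTU matrix rebuilt.
#' @export
confounderFilter <- function(result, object, covariates = NULL,
                             nTrees = 100, nPerm = 50, nSmall = 12) {
    stopifnot(is(result, "DTUResult"), is(object, "DTUDataSet"))
    if (is.null(covariates))
        covariates <- setdiff(colnames(colData(object)), "condition")
    cand <- result@results[result@results$call, , drop = FALSE]
    keep <- stats::setNames(rep(TRUE, nrow(cand)), cand$transcript_id)
    imp <- NULL
    if (length(covariates) && nrow(cand)) {
        covDf <- as.data.frame(colData(object))[, covariates, drop = FALSE]
        enc <- .encodeCovariates(covDf)
        ifm <- ifValues(object)
        for (tx in cand$transcript_id) {
            y <- ifm[tx, ]
            v <- result@vMatrix[tx, colnames(object)]
            ok <- !is.na(y)
            X <- cbind(v = v[ok], enc$X[ok, , drop = FALSE])
            groups <- c("v", enc$groups)
            forest <- fitStubForest(X, y[ok], nTrees, nSmall)
            gam <- vapply(seq_len(ncol(X)), function(col)
                permutationImportance(forest, X, y[ok], col, nPerm),
                numeric(nPerm))
            q1v <- stats::quantile(gam[, 1], 0.25, names = FALSE)
            q3cov <- -Inf
            for (cv in unique(groups[-1])) {
                gcv <- gam[, groups == cv, drop = FALSE]
                gcv <- apply(gcv, 1, max)     # max over dummies, per perm
                q3cov <- max(q3cov, stats::quantile(gcv, 0.75,
                                                    names = FALSE))
            }
            keep[tx] <- q1v > q3cov
            imp <- rbind(imp, data.frame(
                transcript_id = tx, q1_v = q1v, max_q3_cov = q3cov,
                keep = keep[tx], stringsAsFactors = FALSE))
        }
    }
    out <- result
    drop <- names(keep)[!keep]
    out@results$call[out@results$transcript_id %in% drop] <- FALSE
    kept <- out@results[out@results$call, , drop = FALSE]
    caseIds <- colnames(result@dtuMatrix)
    genes <- unique(kept$gene_id)
    M <- matrix(0L, length(genes), length(caseIds),
                dimnames = list(genes, caseIds))
    for (g in genes) {
        sub <- kept[kept$gene_id == g, , drop = FALSE]
        win <- sub$transcript_id[which.min(sub$p)]
        M[g, ] <- result@vMatrix[win, caseIds]
    }
    out@dtuMatrix <- M
    out@vMatrix <- result@vMatrix[kept$transcript_id, , drop = FALSE]
    list(keep = keep, importance = imp, result = out)
}
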