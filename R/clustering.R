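## Spliceotype clustering: case samples are compared by the proportion of
## DTU events unique to either sample relative to their pairwise union of
## events (Jaccard distance on the binary gene x sample event matrix), and
## grouped by agglomerative hierarchical clustering.

#' Distance between two binary DTU event vectors
#'
#' `d = |symmetric difference| / |union|` of the event sets; two samples
#' with no events at all are at distance 0.
#'
#' @param a,b equal-length binary (0/1) vectors.
#' @return numeric distance in `[0, 1]`.
#' @examples
#' eventDistance(c(1, 1, 0), c(0, 1, 1))  # 2/3
#' @export
eventDistance <- function(a, b) {
    if (length(a) != length(b))
        stop("event vectors must have equal length")
    uni <- sum(a | b)
    if (uni == 0) return(0)
    sum(xor(a, b)) / uni
}

## full pairwise distance matrix over the columns (samples) of M
.eventDist <- function(M) {
    S <- t(M > 0)
    inter <- tcrossprod(S * 1)
    rs <- rowSums(S)
    uni <- outer(rs, rs, "+") - inter
    d <- 1 - inter / uni
    d[uni == 0] <- 0
    diag(d) <- 0
    stats::as.dist(d)
}

#' Cluster case samples into spliceotype groups
#'
#' Agglomerative hierarchical clustering of the case samples under the
#' binary event distance. Flat labels come from a user-supplied `k` or,
#' by default, from cutting at the largest gap in merge heights.
#'
#' @param M binary gene x case-sample matrix (e.g. [dtuMatrix()] of a
#'   [DTUResult-class]), or a `DTUResult`.
#' @param k number of flat clusters; `NULL` for the height-gap heuristic.
#' @param linkage linkage method passed to [stats::hclust()] (default
#'   `"average"`).
#' @return list with `hclust`, `labels` (named integer vector) and `k`.
#' @export
clusterCases <- function(M, k = NULL, linkage = "average") {
    if (is(M, "DTUResult")) M <- dtuMatrix(M)
    if (ncol(M) < 2)
        stop("clustering needs at least 2 case samples")
    if (!nrow(M) || all(M == 0)) {
        warning("no DTU events: all samples fall in one cluster")
        hc <- stats::hclust(stats::dist(rep(0, ncol(M))), method = linkage)
        hc$labels <- colnames(M)
        return(list(hclust = hc,
                    labels = stats::setNames(rep(1L, ncol(M)),
                                             colnames(M)),
                    k = 1L))
    }
    hc <- stats::hclust(.eventDist(M), method = linkage)
    if (is.null(k)) {
        ## cut just below the merge with the largest height rise: if that
        ## rise arrives at merge i, the i-1 earlier merges leave n-(i-1)
        ## flat clusters
        hgt <- hc$height
        k <- if (max(hgt) < 1e-12) 1L     # all samples share their events
             else if (length(hgt) < 2) 2L
             else length(hgt) + 2L - which.max(diff(c(0, hgt)))
    }
    labels <- stats::cutree(hc, k = k)
    list(hclust = hc, labels = labels, k = as.integer(k))
}

#' Write a dendrogram as Newick
#'
#' Branch lengths are the merge-height differences of the tree.
#'
#' @param clustering list from [clusterCases()] (or an `hclust`).
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeNewick <- function(clustering, path) {
    hc <- if (inherits(clustering, "hclust")) clustering
          else clustering$hclust
    ape::write.tree(ape::as.phylo(hc), file = path)
    invisible(path)
}

#' Adjusted Rand index between two labelings
#'
#' @param a,b equal-length cluster label vectors.
#' @return numeric ARI (1 = identical partitions up to renaming).
#' @export
adjustedRandIndex <- function(a, b) {
    stopifnot(length(a) == length(b))
    tab <- table(a, b)
    comb2 <- function(x) x * (x - 1) / 2
    sumij <- sum(comb2(tab))
    sumi <- sum(comb2(rowSums(tab)))
    sumj <- sum(comb2(colSums(tab)))
    n <- comb2(length(a))
    expected <- sumi * sumj / n
    maxidx <- (sumi + sumj) / 2
    if (maxidx == expected) return(1)
    (sumij - expected) / (maxidx - expected)
}
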