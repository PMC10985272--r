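## Per-transcript machinery: IF rounding/jitter, Gaussian KDE on a fixed
## grid, split-point detection, Eq.-style tail construction with subgroup
## size guards, and the Mann-Whitney U test (exact for small tie-free
## groups, tie- and continuity-corrected normal approximation otherwise).

#' Round and jitter isoform fractions
#'
#' Rounds IF values to three decimals (differences below that resolution
#' are quantification noise, not usage signal) and then adds a uniform
#' jitter on (-0.0005, 0.0005) to break the ties the rounding creates.
#' Deterministic under a fixed RNG seed. `NA` values pass through.
#'
#' @param values numeric vector or matrix of IFs in `[0, 1]`.
#' @return object of the same shape, clipped to `[0, 1]`.
#' @export
preprocessIF <- function(values) {
    if (!length(values)) return(values)
    v <- round(values, 3)
    jit <- stats::runif(length(v), -5e-4, 5e-4)
    jit[is.na(v)] <- 0
    pmin(pmax(v + jit, 0), 1)
}

#' Gaussian kernel density on a fixed grid
#'
#' Evaluates a Gaussian KDE with bandwidth `h` on a 512-point grid
#' covering `[0, 1]` extended by `3h` on each side, so boundary modes are
#' represented without truncation. The discrete grid makes extremum
#' detection reproducible and resolution-independent at the 3-decimal IF
#' precision.
#'
#' @param values numeric vector (NA dropped); at least 2 values required.
#' @param h bandwidth (standard deviation of the Gaussian kernel), > 0.
#' @return list with `grid`, `density`, `h`.
#' @export
fitIFDensity <- function(values, h) {
    values <- values[!is.na(values)]
    if (length(values) < 2)
        stop("need at least 2 non-missing values for a density fit")
    if (!is.numeric(h) || h <= 0)
        stop("bandwidth h must be positive")
    if (length(unique(values)) == 1 && h < 1e-8)
        stop("degenerate density: identical values with vanishing bandwidth")
    d <- stats::density(values, bw = h, kernel = "gaussian", n = 512,
                        from = -3 * h, to = 1 + 3 * h)
    list(grid = d$x, density = d$y, h = h)
}

#' Locate the split point of a bimodal IF density
#'
#' Returns the grid point of lowest density among interior local minima
#' that lie strictly between two local maxima, or `NA` when the curve has
#' fewer than two local maxima (unimodal: no subgroup structure).
#' Boundary minima are never split points.
#'
#' @param curve list from [fitIFDensity()].
#' @return numeric split point, or `NA_real_`.
#' @export
findSplitPoint <- function(curve) {
    y <- curve$density
    s <- sign(diff(y))
    ## compress zero slopes so plateaus do not hide extrema
    idx <- which(s != 0)
    if (length(idx) < 2) return(NA_real_)
    chg <- which(s[idx][-1] != s[idx][-length(idx)])
    if (!length(chg)) return(NA_real_)
    extPos <- idx[chg] + 1L          # grid index of each interior extremum
    extType <- s[idx][chg]           # +1 -> maximum, -1 -> minimum
    ## sub-epsilon wiggles of the FFT density in numerically-zero tails
    ## are not modes: a maximum must carry non-negligible density
    maxPos <- extPos[extType > 0 & y[extPos] >= 1e-6 * max(y)]
    minPos <- extPos[extType < 0]
    if (length(maxPos) < 2 || !length(minPos)) return(NA_real_)
    bracketed <- minPos[minPos > min(maxPos) & minPos < max(maxPos)]
    if (!length(bracketed)) return(NA_real_)
    curve$grid[bracketed[which.min(y[bracketed])]]
}

#' Tail partition of case and control IFs at a split point
#'
#' Left tails are samples with IF <= `m`, right tails IF > `m`, in both
#' groups. A control tail smaller than `nSmall` is expanded across the
#' split with the nearest-IF control samples (stable order, ties broken by
#' input position) until it holds `nSmall` members (or all controls). If
#' either case tail is smaller than `nSmall` the stratification is deemed
#' outlier-driven and the whole groups are compared instead
#' (`mode = "whole-group"`).
#'
#' @param ifCase,ifControl named numeric vectors of IFs (NA dropped).
#' @param m split point from [findSplitPoint()]; `NA` forces whole-group
#'   mode.
#' @param nSmall minimum reliable subgroup size.
#' @return list with `mode` (`"split"` or `"whole-group"`), `m`, and the
#'   four name vectors `lCase`, `rCase`, `lControl`, `rControl`.
#' @export
defineTails <- function(ifCase, ifControl, m, nSmall) {
    ifCase <- ifCase[!is.na(ifCase)]
    ifControl <- ifControl[!is.na(ifControl)]
    whole <- list(mode = "whole-group", m = NA_real_,
                  lCase = names(ifCase), rCase = names(ifCase),
                  lControl = names(ifControl), rControl = names(ifControl))
    if (is.na(m)) return(whole)
    lCase <- names(ifCase)[ifCase <= m]
    rCase <- names(ifCase)[ifCase > m]
    if (length(lCase) < nSmall || length(rCase) < nSmall) return(whole)
    expand <- function(side) {
        inTail <- if (side == "l") ifControl <= m else ifControl > m
        tail <- names(ifControl)[inTail]
        if (length(tail) >= nSmall) return(tail)
        other <- ifControl[!inTail]
        need <- min(nSmall - length(tail), length(other))
        if (need > 0) {
            ord <- order(abs(other - m))  # stable: ties keep input order
            tail <- c(tail, names(other)[ord[seq_len(need)]])
        }
        tail
    }
    list(mode = "split", m = m, lCase = lCase, rCase = rCase,
         lControl = expand("l"), rControl = expand("r"))
}

## Fast two-sided Mann-Whitney U p-value. Exact null distribution when both
## groups are smaller than `exactMax` and the pooled values are tie-free;
## otherwise normal approximation with tie correction and continuity
## correction. No input validation: hot path.
.mwuP <- function(x, y, exactMax = 8L) {
    m <- length(x); n <- length(y)
    r <- rank(c(x, y))
    U <- sum(r[seq_len(m)]) - m * (m + 1) / 2
    N <- m + n
    tieTab <- tabulate(match(r, unique(r)))
    ties <- any(tieTab > 1L)
    if (m < exactMax && n < exactMax && !ties) {
        p <- if (U > m * n / 2)
            2 * (1 - stats::pwilcox(U - 1, m, n))
        else
            2 * stats::pwilcox(U, m, n)
        return(min(1, p))
    }
    tieTerm <- sum(tieTab^3 - tieTab)
    sigma2 <- m * n / 12 * ((N + 1) - tieTerm / (N * (N - 1)))
    if (sigma2 <= 0) return(1)
    z <- (abs(U - m * n / 2) - 0.5) / sqrt(sigma2)
    min(1, 2 * stats::pnorm(-max(z, 0)))
}

#' Two-sided Mann-Whitney U test p-value
#'
#' Exact p-values are computed when both group sizes are below 8 and the
#' pooled data are tie-free; otherwise a normal approximation with tie
#' correction and continuity correction is used.
#'
#' @param x,y non-empty numeric vectors.
#' @return two-sided p-value in `[0, 1]`.
#' @examples
#' mannWhitneyP(1:3, 4:6)   # full rank separation, exact p = 0.1
#' @export
mannWhitneyP <- function(x, y) {
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (!length(x) || !length(y))
        stop("both groups must be non-empty")
    .mwuP(x, y)
}

## minimal usable group size for a tail comparison
.MIN_TEST_N <- 2L

#' Test one transcript for DTU
#'
#' Fits the case-group KDE, looks for a split point, builds tails, and
#' compares case against control tails (or whole groups) with Mann-Whitney
#' U tests. The transcript p-value is the minimum of the available tail
#' p-values. The event indicator `v` is 1 for the case samples on the side
#' whose tail test drove the call (both tails in whole-group mode) and 0
#' for every control sample.
#'
#' @param ifCase,ifControl named numeric IF vectors, already rounded and
#'   jittered via [preprocessIF()]; masked-out samples removed.
#' @param h KDE bandwidth.
#' @param nSmall minimum subgroup size.
#' @return list with `p_left`, `p_right`, `p`, `split_point`, `mode`,
#'   `v` (named 0/1 vector over case then control samples), and `skipped`
#'   (reason string or NA).
#' @export
testTranscript <- function(ifCase, ifControl, h, nSmall) {
    ifCase <- ifCase[!is.na(ifCase)]
    ifControl <- ifControl[!is.na(ifControl)]
    v <- stats::setNames(rep(0L, length(ifCase) + length(ifControl)),
                         c(names(ifCase), names(ifControl)))
    out <- list(p_left = NA_real_, p_right = NA_real_, p = NA_real_,
                split_point = NA_real_, mode = NA_character_, v = v,
                skipped = NA_character_)
    if (length(ifCase) < .MIN_TEST_N || length(ifControl) < .MIN_TEST_N) {
        out$skipped <- "fewer than 2 usable samples in a group"
        return(out)
    }
    m <- findSplitPoint(fitIFDensity(ifCase, h))
    tails <- defineTails(ifCase, ifControl, m, nSmall)
    out$mode <- tails$mode
    if (tails$mode == "split") {
        out$split_point <- tails$m
        if (length(tails$lCase) >= .MIN_TEST_N &&
            length(tails$lControl) >= .MIN_TEST_N)
            out$p_left <- .mwuP(ifCase[tails$lCase], ifControl[tails$lControl])
        if (length(tails$rCase) >= .MIN_TEST_N &&
            length(tails$rControl) >= .MIN_TEST_N)
            out$p_right <- .mwuP(ifCase[tails$rCase], ifControl[tails$rControl])
        ps <- c(out$p_left, out$p_right)
        if (all(is.na(ps))) {
            out$skipped <- "fewer than 2 usable samples in every tail"
            return(out)
        }
        out$p <- min(ps, na.rm = TRUE)
        marked <- if (!is.na(out$p_left) &&
                      (is.na(out$p_right) || out$p_left <= out$p_right))
            tails$lCase else tails$rCase
        out$v[marked] <- 1L
    } else {
        out$p <- .mwuP(ifCase, ifControl)
        out$v[names(ifCase)] <- 1L
    }
    out
}
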