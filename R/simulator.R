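## Synthetic cohort generator and dominance-swap DTU injector. The
## generator emulates a bulk RNA-seq control population: log-normal gene
## means, negative-binomial (super-Poisson) per-sample gene totals, and
## per-gene isoform fractions with a consistently dominant isoform plus
## per-sample Dirichlet jitter. The injector reproduces the evaluation
## recipe: swap the dominance status of the most and least dominant
## isoforms for overlapping case subgroups ("spliceotypes").

#' Cohort simulation parameters
#'
#' @param nGenes number of genes.
#' @param nCase,nControl group sizes (testing needs >= 8 per group).
#' @param txPerGeneProbs probabilities of 1..k transcripts per gene.
#' @param muLog,sdLog log-normal parameters of the gene mean counts.
#' @param nbSize negative-binomial size (1/dispersion) of per-sample gene
#'   totals; the default gives clearly super-Poisson counts.
#' @param domRange range the dominant isoform's base fraction is drawn
#'   from.
#' @param concentration Dirichlet concentration of the per-sample isoform
#'   fraction jitter (larger = more consistent dominance).
#' @return named list.
#' @export
cohortParams <- function(nGenes = 1000, nCase = 12, nControl = 12,
                         txPerGeneProbs = c(0.15, 0.45, 0.25, 0.15),
                         muLog = log(200), sdLog = 1, nbSize = 5,
                         domRange = c(0.55, 0.9), concentration = 100) {
    stopifnot(nGenes >= 1, nCase >= 1, nControl >= 1, nbSize > 0,
              all(txPerGeneProbs >= 0), sum(txPerGeneProbs) > 0,
              concentration > 0, length(domRange) == 2)
    list(nGenes = nGenes, nCase = nCase, nControl = nControl,
         txPerGeneProbs = txPerGeneProbs / sum(txPerGeneProbs),
         muLog = muLog, sdLog = sdLog, nbSize = nbSize,
         domRange = domRange, concentration = concentration)
}

## stochastic rounding: preserves the expectation of fractional counts
.stochRound <- function(x) {
    f <- floor(x)
    f + (stats::runif(length(x)) < (x - f))
}

#' Simulate a control-like case/control cohort
#'
#' No DTU signal is injected: case and control samples are exchangeable
#' draws from the same generative model, so the output doubles as a null
#' cohort. Gene totals are negative binomial around log-normal means;
#' isoform fractions follow a per-gene base profile with one dominant
#' isoform, jittered per sample by a Dirichlet draw; transcript counts are
#' the stochastically rounded product of the two. Reproducible under
#' `set.seed()`.
#'
#' @param params list from [cohortParams()].
#' @return a [DTUDataSet-class].
#' @examples
#' set.seed(1)
#' dds <- simulateCohort(cohortParams(nGenes = 20))
#' dds
#' @export
simulateCohort <- function(params = cohortParams()) {
    nS <- params$nCase + params$nControl
    kMax <- length(params$txPerGeneProbs)
    tpg <- sample(seq_len(kMax), params$nGenes, replace = TRUE,
                  prob = params$txPerGeneProbs)
    geneId <- sprintf("g%05d", seq_len(params$nGenes))
    gene <- rep(geneId, tpg)
    tx <- paste0(gene, ".t", unlist(lapply(tpg, seq_len)))
    ## per-gene base fractions with a dominant isoform at a random slot
    base <- numeric(length(tx))
    off <- c(0L, cumsum(tpg))
    for (g in seq_len(params$nGenes)) {
        k <- tpg[g]
        rows <- off[g] + seq_len(k)
        if (k == 1) { base[rows] <- 1; next }
        d <- stats::runif(1, params$domRange[1], params$domRange[2])
        rest <- stats::rgamma(k - 1, 1)
        b <- c(d, (1 - d) * rest / sum(rest))
        base[rows] <- b[sample.int(k)][seq_len(k)]
    }
    ## per-sample Dirichlet jitter around the base profile
    shape <- matrix(rep(params$concentration * base, nS),
                    ncol = nS)
    gm <- matrix(stats::rgamma(length(shape), shape = shape),
                 ncol = nS)
    gm[base == 0, ] <- 0
    tot <- rowsum(gm, gene, reorder = FALSE)
    frac <- gm / tot[match(gene, rownames(tot)), , drop = FALSE]
    frac[is.na(frac)] <- 0
    ## gene totals
    mu <- stats::rlnorm(params$nGenes, params$muLog, params$sdLog)
    gt <- matrix(stats::rnbinom(params$nGenes * nS,
                                mu = rep(mu, nS), size = params$nbSize),
                 ncol = nS)
    cts <- .stochRound(frac * gt[match(gene, geneId), , drop = FALSE])
    sampleIds <- c(sprintf("case_%03d", seq_len(params$nCase)),
                   sprintf("ctrl_%03d", seq_len(params$nControl)))
    dimnames(cts) <- list(tx, sampleIds)
    DTUDataSet(cts,
               data.frame(transcript_id = tx, gene_id = gene,
                          stringsAsFactors = FALSE),
               data.frame(sample_id = sampleIds,
                          condition = rep(c("case", "control"),
                                          c(params$nCase, params$nControl)),
                          stringsAsFactors = FALSE))
}

#' Inject heterogeneous dominance-swap DTU events
#'
#' Selects `nDTU` genes with a consistently dominant isoform in the
#' control group (and at least two transcripts), partitions the case
#' samples into `nSpliceotypes` disjoint equal-size subgroups, draws
#' `genesPer` genes per subgroup from the superset with replacement (so
#' events are shared between some subgroups and exclusive to others), and
#' for every affected (gene, case sample) swaps the dominance of the most
#' dominant isoform `alpha` (control mean IF `u`) and the least dominant
#' isoform `beta` (control mean IF `v`): the new fractions are `v` and `u`
#' respectively, each perturbed by a uniform noise on `[-epsilon,
#' +epsilon]` and truncated into (0, 1). The two transcripts' counts are
#' rebuilt as the sample's gene total times the new fraction; gene totals
#' are re-summed and fractions renormalize on recomputation.
#'
#' @param object a [DTUDataSet-class] (typically from [simulateCohort()]).
#' @param nDTU size of the DTU gene superset.
#' @param nSpliceotypes number of case subgroups.
#' @param genesPer genes drawn (with replacement) per subgroup.
#' @param epsilon fraction noise half-width.
#' @param pd dominance consistency required for eligibility.
#' @return list with `data` (new `DTUDataSet`) and `truth`: `D` (the
#'   superset), `spliceotypes` (sample id list), `genesPerSpliceotype`,
#'   `injected` (genes actually perturbed: the union over subgroups),
#'   `swaps` (per-gene alpha/beta/u/v table).
#' @export
injectDTU <- function(object, nDTU = 100, nSpliceotypes = 5, genesPer = 30,
                      epsilon = 0.05, pd = 0.75) {
    stopifnot(is(object, "DTUDataSet"))
    dom <- dominantGenes(object, pd)
    gene <- geneIds(object)
    multi <- names(table(gene))[table(gene) >= 2]
    eligible <- dom$gene_id[dom$eligible & dom$gene_id %in% multi]
    if (length(eligible) < nDTU)
        stop("only ", length(eligible), " genes eligible for injection; ",
             "asked for ", nDTU)
    D <- sample(eligible, nDTU)
    caseIds <- colnames(object)[object$condition == "case"]
    grp <- split(sample(caseIds),
                 rep_len(seq_len(nSpliceotypes), length(caseIds)))
    Dper <- lapply(seq_len(nSpliceotypes),
                   function(s) sample(D, genesPer, replace = TRUE))
    cts <- counts(object)
    ifm <- ifValues(object)
    isCtrl <- object$condition == "control"
    injected <- sort(unique(unlist(Dper)))
    swaps <- data.frame(gene_id = injected, alpha = NA_character_,
                        beta = NA_character_, u = NA_real_, v = NA_real_,
                        stringsAsFactors = FALSE)
    for (k in seq_along(injected)) {
        g <- injected[k]
        rows <- which(gene == g)
        ctrlMean <- rowMeans(ifm[rows, isCtrl, drop = FALSE], na.rm = TRUE)
        alpha <- rows[which.max(ctrlMean)]
        beta <- rows[which.min(ctrlMean)]
        u <- ctrlMean[which.max(ctrlMean)]
        v <- ctrlMean[which.min(ctrlMean)]
        affected <- unique(unlist(
            grp[vapply(Dper, function(d) g %in% d, logical(1))]))
        gTot <- colSums(cts[rows, affected, drop = FALSE])
        nA <- length(affected)
        newA <- pmin(pmax(v + stats::runif(nA, -epsilon, epsilon),
                          1e-6), 1 - 1e-6)
        newB <- pmin(pmax(u + stats::runif(nA, -epsilon, epsilon),
                          1e-6), 1 - 1e-6)
        cts[alpha, affected] <- gTot * newA
        cts[beta, affected] <- gTot * newB
        swaps$alpha[k] <- rownames(cts)[alpha]
        swaps$beta[k] <- rownames(cts)[beta]
        swaps$u[k] <- u; swaps$v[k] <- v
    }
    out <- DTUDataSet(cts, txGene(object),
                      as.data.frame(colData(object)))
    list(data = out,
         truth = list(D = D, spliceotypes = grp,
                      genesPerSpliceotype = lapply(Dper, unique),
                      injected = injected, swaps = swaps,
                      epsilon = epsilon))
}

#' Generate pseudo inferential replicates
#'
#' Each replicate resamples every count from a Poisson centred on the
#' point estimate, a simple stand-in for quantification (read assignment)
#' uncertainty; real bootstrap/Gibbs replicate matrices can be supplied to
#' [detectDTU()] instead.
#'
#' @param object a [DTUDataSet-class] or count matrix.
#' @param nRep number of replicates (default 30).
#' @return list of count matrices with ids preserved.
#' @export
generateReplicates <- function(object, nRep = 30) {
    cts <- if (is(object, "DTUDataSet")) counts(object) else object
    lapply(seq_len(nRep), function(r) {
        m <- matrix(stats::rpois(length(cts), lambda = cts),
                    nrow = nrow(cts), dimnames = dimnames(cts))
        m
    })
}

#' Score gene-level calls against an injection truth
#'
#' The truth is restricted to genes surviving the pre-filter (`universe`):
#' events filtered away upstream are not scored as misses, mirroring how
#' filter-aware DTU benchmarks define their positives.
#'
#' @param called character vector of called gene ids.
#' @param truth truth list from [injectDTU()] (or a character vector of
#'   true genes).
#' @param universe gene ids surviving the pre-filter.
#' @return list with `tp`, `fp`, `fn`, `TPR`, `FDR`, `F`.
#' @export
evaluateCalls <- function(called, truth, universe) {
    trueGenes <- if (is.list(truth)) truth$injected else truth
    trueGenes <- intersect(trueGenes, universe)
    called <- intersect(called, universe)
    tp <- length(intersect(called, trueGenes))
    fp <- length(setdiff(called, trueGenes))
    fn <- length(setdiff(trueGenes, called))
    list(tp = tp, fp = fp, fn = fn,
         TPR = if (tp + fn > 0) tp / (tp + fn) else 0,
         FDR = if (tp + fp > 0) fp / (tp + fp) else 0,
         F = fScore(tp, fp, fn))
}
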