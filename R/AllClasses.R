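#' @import methods
#' @import SummarizedExperiment
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

#' DTUDataSet: transcript-level counts with gene mapping and sample groups
#'
#' `DTUDataSet` extends [SummarizedExperiment::SummarizedExperiment] and is
#' the container every stage of the pipeline consumes. The `"counts"` assay
#' holds non-negative (possibly fractional, e.g. scaledTPM-style) transcript
#' by sample estimated read counts; `rowData` carries the `gene_id` of each
#' transcript; `colData` carries the `condition` factor (levels `case` and
#' `control`) plus any covariate columns.
#'
#' @slot .. inherited from `SummarizedExperiment`.
#'
#' @seealso [DTUDataSet()] the constructor, [computeIF()], [applyPrefilter()]
#' @export
setClass("DTUDataSet", contains = "SummarizedExperiment")

setValidity("DTUDataSet", function(object) {
    msg <- NULL
    if (!"counts" %in% assayNames(object))
        msg <- c(msg, "assay 'counts' is required")
    else {
        cts <- assay(object, "counts")
        if (any(is.na(cts)) || any(cts < 0))
            msg <- c(msg, "counts must be non-negative and non-missing")
    }
    if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
        msg <- c(msg, "transcript ids (rownames) must be present and unique")
    if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
        msg <- c(msg, "sample ids (colnames) must be present and unique")
    if (!"gene_id" %in% colnames(rowData(object)))
        msg <- c(msg, "rowData must contain a 'gene_id' column")
    if (!"condition" %in% colnames(colData(object)))
        msg <- c(msg, "colData must contain a 'condition' column")
    else {
        cond <- object$condition
        if (!all(cond %in% c("case", "control")))
            msg <- c(msg, "condition must only contain 'case' and 'control'")
        else if (!all(c("case", "control") %in% cond))
            msg <- c(msg, "both 'case' and 'control' conditions must be non-empty")
    }
    if (is.null(msg)) TRUE else msg
})

#' Construct a DTUDataSet
#'
#' @param counts numeric matrix (transcripts x samples) of non-negative
#'   estimated counts, with transcript ids as rownames and sample ids as
#'   colnames. Fractional counts are kept as-is.
#' @param tx2gene `data.frame` with columns `transcript_id` and `gene_id`
#'   covering every transcript in `counts`; each transcript must map to
#'   exactly one gene.
#' @param samples `data.frame` with one row per sample: a `sample_id` column
#'   (or rownames) matching the columns of `counts`, a `condition` column
#'   with values in `case`/`control`, and optional covariate columns.
#'
#' @return A [DTUDataSet-class] object.
#' @examples
#' cts <- matrix(c(2, 6, 8, 4), 2, 2,
#'               dimnames = list(c("tx1", "tx2"), c("s1", "s2")))
#' map <- data.frame(transcript_id = c("tx1", "tx2"), gene_id = "g1")
#' meta <- data.frame(sample_id = c("s1", "s2"),
#'                    condition = c("case", "control"))
#' dds <- DTUDataSet(cts, map, meta)
#' @export
DTUDataSet <- function(counts, tx2gene, samples) {
    counts <- as.matrix(counts)
    if (!is.numeric(counts))
        stop("counts must be numeric")
    tx2gene <- as.data.frame(tx2gene)
    if (!all(c("transcript_id", "gene_id") %in% colnames(tx2gene)))
        stop("tx2gene needs columns 'transcript_id' and 'gene_id'")
    if (anyDuplicated(tx2gene$transcript_id))
        stop("tx2gene maps a transcript to more than one gene: ",
             paste(unique(tx2gene$transcript_id[
                 duplicated(tx2gene$transcript_id)]), collapse = ", "))
    missing_tx <- setdiff(rownames(counts), tx2gene$transcript_id)
    if (length(missing_tx))
        stop("transcripts absent from tx2gene: ",
             paste(utils::head(missing_tx, 5), collapse = ", "))
    samples <- as.data.frame(samples)
    if ("sample_id" %in% colnames(samples)) {
        rownames(samples) <- samples$sample_id
        samples$sample_id <- NULL
    }
    if (!setequal(rownames(samples), colnames(counts)) ||
        nrow(samples) != ncol(counts))
        stop("sample table must contain every count column exactly once")
    samples <- samples[colnames(counts), , drop = FALSE]
    gene <- tx2gene$gene_id[match(rownames(counts), tx2gene$transcript_id)]
    se <- SummarizedExperiment(
        assays = list(counts = counts),
        rowData = DataFrame(gene_id = gene, row.names = rownames(counts)),
        colData = DataFrame(samples))
    new("DTUDataSet", se)
}

#' Empirical null distribution of minimal U-statistic p-values
#'
#' Built by [buildNullDistribution()] from the control group: each iteration
#' randomly halves the controls, compares the two halves tail-against-tail
#' per transcript, and keeps the minimal p-value across transcripts. The set
#' of per-iteration minima is the empirical null against which observed
#' p-values are thresholded (see [nullThreshold()]).
#'
#' @slot pPrime numeric, one minimal p-value per iteration.
#' @slot perTranscript numeric matrix (transcripts x iterations) of the
#'   per-transcript minimal tail p-values, for calibration diagnostics.
#' @slot nIterations integer number of iterations run.
#' @slot sampledTranscripts character, transcripts that have contributed a
#'   minimum (each transcript contributes at most once).
#' @slot smallSample logical, whether the small-control-group mode was used.
#' @export
setClass("NullDistribution",
    representation(pPrime = "numeric", perTranscript = "matrix",
                   nIterations = "integer", sampledTranscripts = "character",
                   smallSample = "logical"))

setValidity("NullDistribution", function(object) {
    msg <- NULL
    if (length(object@pPrime) != object@nIterations)
        msg <- c(msg, "length(pPrime) must equal nIterations")
    pp <- object@pPrime[!is.na(object@pPrime)]
    if (any(pp < 0 | pp > 1))
        msg <- c(msg, "pPrime values must lie in [0, 1]")
    if (anyDuplicated(object@sampledTranscripts))
        msg <- c(msg, "a transcript may contribute a minimum at most once")
    if (is.null(msg)) TRUE else msg
})

#' Result container for a DTU detection run
#'
#' Returned by [detectDTU()]. Holds the per-transcript test table, the
#' empirical null and derived threshold, the binary gene x case-sample DTU
#' event matrix, and the likelihood-score gene flags.
#'
#' @slot results `data.frame` with one row per tested transcript:
#'   `transcript_id`, `gene_id`, `p_left`, `p_right`, `p`, `split_point`,
#'   `mode` (`split`/`whole-group`), `call`.
#' @slot dtuMatrix binary matrix, called genes x case samples; entry 1 marks
#'   a DTU event for that sample, taken from the winning (smallest-p)
#'   transcript of the gene.
#' @slot vMatrix binary matrix, called transcripts x all samples (controls
#'   all zero); the per-transcript event indicator vectors.
#' @slot flags `data.frame` of gene-level likelihood-score outlier flags.
#' @slot null the [NullDistribution-class] used for thresholding.
#' @slot threshold numeric p-value calling threshold.
#' @slot params list of run parameters (h, kappa, nSmall, ...).
#' @export
setClass("DTUResult",
    representation(results = "data.frame", dtuMatrix = "matrix",
                   vMatrix = "matrix", flags = "data.frame",
                   null = "NullDistribution", threshold = "numeric",
                   params = "list"))
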