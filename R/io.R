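## Readers and the two transformations (isoform fractions, CPM) everything
## downstream consumes. Files are UTF-8 tab-separated with a header; gzip is
## accepted transparently through the connection layer.

#' Read a transcript-level count matrix
#'
#' Expects a tab-separated file whose first column holds transcript ids and
#' whose header row holds sample ids. Counts may be fractional (scaledTPM
#' style estimates) and are not rounded.
#'
#' @param path path to a TSV (optionally gzip-compressed).
#' @return numeric matrix, transcripts x samples.
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines(c("transcript_id\ts1\ts2", "tx1\t3\t7", "tx2\t0\t2"), f)
#' readCounts(f)
#' @export
readCounts <- function(path) {
    df <- utils::read.delim(path, check.names = FALSE,
                            stringsAsFactors = FALSE)
    if (ncol(df) < 2)
        stop("count file needs a transcript id column plus sample columns")
    ids <- as.character(df[[1]])
    if (anyDuplicated(ids))
        stop("duplicated transcript id: ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
    m <- as.matrix(df[, -1, drop = FALSE])
    if (!is.numeric(m) || any(is.na(m)))
        stop("non-numeric count value encountered")
    if (any(m < 0))
        stop("negative count value encountered")
    if (anyDuplicated(colnames(m)))
        stop("duplicated sample id in header")
    rownames(m) <- ids
    m
}

#' Read a transcript-to-gene map
#'
#' @param path two-column TSV (`transcript_id`, `gene_id`), header required.
#' @return data.frame with columns `transcript_id` and `gene_id`.
#' @export
readTx2Gene <- function(path) {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    if (ncol(df) < 2)
        stop("tx2gene file needs two columns")
    df <- df[, 1:2]
    colnames(df) <- c("transcript_id", "gene_id")
    if (anyDuplicated(df$transcript_id))
        stop("transcript mapped to more than one gene: ",
             paste(unique(df$transcript_id[duplicated(df$transcript_id)]),
                   collapse = ", "))
    df
}

#' Read a sample metadata table
#'
#' @param path TSV with a `sample_id` column (or first column), a
#'   `condition` column restricted to `case`/`control`, and any number of
#'   covariate columns.
#' @return data.frame with rownames set to sample ids.
#' @export
readSampleTable <- function(path) {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    if (!"sample_id" %in% colnames(df))
        colnames(df)[1] <- "sample_id"
    if (!"condition" %in% colnames(df))
        stop("metadata needs a 'condition' column")
    bad <- setdiff(unique(df$condition), c("case", "control"))
    if (length(bad))
        stop("unknown condition label(s): ", paste(bad, collapse = ", "))
    if (anyDuplicated(df$sample_id))
        stop("duplicated sample id in metadata")
    rownames(df) <- df$sample_id
    df$sample_id <- NULL
    df
}

#' Assemble a DTUDataSet from the three standard input files
#'
#' @param countsFile,tx2geneFile,samplesFile paths passed to [readCounts()],
#'   [readTx2Gene()] and [readSampleTable()].
#' @return a [DTUDataSet-class].
#' @export
readDTUDataSet <- function(countsFile, tx2geneFile, samplesFile) {
    DTUDataSet(readCounts(countsFile), readTx2Gene(tx2geneFile),
               readSampleTable(samplesFile))
}

## gene id per row of a count matrix, from a tx2gene data.frame
.geneOf <- function(counts, tx2gene) {
    g <- tx2gene$gene_id[match(rownames(counts), tx2gene$transcript_id)]
    if (anyNA(g))
        stop("transcript missing from tx2gene map: ",
             paste(utils::head(rownames(counts)[is.na(g)], 5),
                   collapse = ", "))
    g
}

## per-(gene, sample) totals expanded back to transcript rows
.geneTotals <- function(counts, gene) {
    gt <- rowsum(counts, gene, reorder = FALSE)
    gt[match(gene, rownames(gt)), , drop = FALSE]
}

#' Isoform fractions
#'
#' Transforms transcript counts into isoform fractions: each count divided
#' by the total count of its gene in the same sample. Where a gene has zero
#' total count in a sample the fraction is undefined and stored as `NA` (a
#' 0/0 ratio carries no usage information), and such entries are excluded
#' from all downstream density fits and rank tests.
#'
#' @param counts numeric matrix (transcripts x samples) or a
#'   [DTUDataSet-class].
#' @param tx2gene transcript-to-gene data.frame; ignored when `counts` is a
#'   `DTUDataSet`.
#' @return matrix of fractions in `[0, 1]` with `NA` where undefined;
#'   within each (gene, sample) with positive gene count the fractions sum
#'   to 1.
#' @examples
#' cts <- matrix(c(2, 6, 2), 3, 1,
#'               dimnames = list(c("a", "b", "c"), "s1"))
#' map <- data.frame(transcript_id = c("a", "b", "c"), gene_id = "g1")
#' computeIF(cts, map)   # 0.2, 0.6, 0.2
#' @export
computeIF <- function(counts, tx2gene = NULL) {
    if (is(counts, "DTUDataSet")) {
        tx2gene <- txGene(counts)
        counts <- assay(counts, "counts")
    }
    gene <- .geneOf(counts, tx2gene)
    tot <- .geneTotals(counts, gene)
    ifm <- counts / tot
    ifm[tot == 0] <- NA_real_
    ifm
}

#' Counts per million
#'
#' @param counts numeric matrix, transcripts (or genes) x samples.
#' @param librarySizes per-sample totals; defaults to the column sums of
#'   `counts`. Must be positive.
#' @return matrix of CPM values.
#' @export
computeCPM <- function(counts, librarySizes = colSums(counts)) {
    if (any(librarySizes <= 0))
        stop("library sizes must be positive")
    sweep(counts, 2, librarySizes, "/") * 1e6
}

#' Write a matrix as TSV (id column first, NA for missing)
#'
#' @param x matrix with row and column names.
#' @param path output path.
#' @param idName header of the id column.
#' @export
writeMatrixTSV <- function(x, path, idName = "transcript_id") {
    df <- data.frame(rownames(x), x, check.names = FALSE,
                     stringsAsFactors = FALSE)
    colnames(df)[1] <- idName
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
    invisible(path)
}
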