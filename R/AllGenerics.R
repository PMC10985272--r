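#' @importFrom BiocGenerics counts
NULL

#' Accessors for DTUDataSet and DTUResult
#'
#' `counts()` returns the count assay; `txGene()` the transcript-to-gene
#' map as a data.frame; `condition()` the case/control factor;
#' `ifValues()` the isoform-fraction assay (computing and caching it on
#' first use); `geneIds()` the per-transcript gene ids.
#'
#' @param object a [DTUDataSet-class] or [DTUResult-class]
#' @param ... unused
#' @name accessors
#' @return matrix, data.frame or character vector as described.
#' @examples
#' dds <- simulateCohort(cohortParams(nGenes = 10, nCase = 4, nControl = 4))
#' dim(counts(dds))
#' head(txGene(dds))
NULL

#' @rdname accessors
#' @export
setGeneric("txGene", function(object) standardGeneric("txGene"))

#' @rdname accessors
#' @export
setGeneric("condition", function(object) standardGeneric("condition"))

#' @rdname accessors
#' @export
setGeneric("ifValues", function(object, ...) standardGeneric("ifValues"))

#' @rdname accessors
#' @export
setGeneric("geneIds", function(object) standardGeneric("geneIds"))

#' @rdname accessors
#' @export
setGeneric("dtuMatrix", function(object) standardGeneric("dtuMatrix"))

#' @rdname accessors
#' @export
setGeneric("transcriptResults", function(object) standardGeneric("transcriptResults"))

#' @rdname accessors
#' @export
setGeneric("geneFlags", function(object) standardGeneric("geneFlags"))

#' @rdname accessors
#' @export
setGeneric("calledGenes", function(object) standardGeneric("calledGenes"))
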