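#' @rdname accessors
#' @export
setMethod("counts", "DTUDataSet", function(object, ...) {
    assay(object, "counts")
})

#' @rdname accessors
#' @export
setMethod("txGene", "DTUDataSet", function(object) {
    data.frame(transcript_id = rownames(object),
               gene_id = rowData(object)$gene_id,
               stringsAsFactors = FALSE)
})

#' @rdname accessors
#' @export
setMethod("condition", "DTUDataSet", function(object) {
    factor(object$condition, levels = c("case", "control"))
})

#' @rdname accessors
#' @export
setMethod("geneIds", "DTUDataSet", function(object) {
    as.character(rowData(object)$gene_id)
})

#' @rdname accessors
#' @export
setMethod("ifValues", "DTUDataSet", function(object, ...) {
    if ("ifrac" %in% assayNames(object))
        return(assay(object, "ifrac"))
    computeIF(assay(object, "counts"), txGene(object))
})

setMethod("show", "DTUDataSet", function(object) {
    cond <- table(object$condition)
    cat("DTUDataSet:", nrow(object), "transcripts,",
        length(unique(rowData(object)$gene_id)), "genes\n")
    cat("  samples:", ncol(object),
        sprintf("(%d case / %d control)\n",
                cond[["case"]], cond[["control"]]))
    covs <- setdiff(colnames(colData(object)), "condition")
    if (length(covs))
        cat("  covariates:", paste(covs, collapse = ", "), "\n")
})

setMethod("show", "NullDistribution", function(object) {
    cat("NullDistribution:", object@nIterations, "iterations",
        if (object@smallSample) "(small-sample mode)", "\n")
    cat("  minimal p-values: median",
        format(stats::median(object@pPrime), digits = 3),
        " range [", format(min(object@pPrime), digits = 3), ",",
        format(max(object@pPrime), digits = 3), "]\n")
})

#' @rdname accessors
#' @export
setMethod("dtuMatrix", "DTUResult", function(object) object@dtuMatrix)

#' @rdname accessors
#' @export
setMethod("transcriptResults", "DTUResult", function(object) object@results)

#' @rdname accessors
#' @export
setMethod("geneFlags", "DTUResult", function(object) object@flags)

#' @rdname accessors
#' @export
setMethod("calledGenes", "DTUResult", function(object) {
    unique(object@results$gene_id[object@results$call])
})

setMethod("show", "DTUResult", function(object) {
    cat("DTUResult:", nrow(object@results), "transcripts tested\n")
    cat("  threshold:", format(object@threshold, digits = 4),
        sprintf("(kappa = %s, %d null iterations)\n",
                object@params$kappa, object@null@nIterations))
    cat("  calls:", sum(object@results$call), "transcripts in",
        length(calledGenes(object)), "genes\n")
})
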