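#' @rdname GeneMatrix
#' @param object,x a GeneMatrix.
#' @export
setGeneric("sampleIDs", function(object) standardGeneric("sampleIDs"))

#' @rdname GeneMatrix
#' @export
setGeneric("geneIDs", function(object) standardGeneric("geneIDs"))

#' @rdname GeneMatrix
#' @export
setGeneric("exprValues", function(object) standardGeneric("exprValues"))

#' @rdname GeneMatrix
#' @export
setGeneric("metaInfo", function(object) standardGeneric("metaInfo"))

#' @rdname GeneMatrix
#' @export
setGeneric("nSamples", function(object) standardGeneric("nSamples"))

#' @rdname GeneMatrix
#' @export
setGeneric("nGenes", function(object) standardGeneric("nGenes"))

#' @rdname hierarchy-accessors
#' @export
setGeneric("nodeCodes", function(object) standardGeneric("nodeCodes"))

#' @rdname hierarchy-accessors
#' @export
setGeneric("rootCode", function(object) standardGeneric("rootCode"))

#' @rdname hierarchy-accessors
#' @export
setGeneric("leafCodes", function(object) standardGeneric("leafCodes"))

#' @rdname FilterReport-accessors
#' @param object a FilterReport.
#' @export
setGeneric("keptIDs", function(object) standardGeneric("keptIDs"))

#' @rdname FilterReport-accessors
#' @export
setGeneric("droppedIDs", function(object) standardGeneric("droppedIDs"))

setMethod("sampleIDs", "GeneMatrix", function(object) rownames(object@values))
setMethod("geneIDs", "GeneMatrix", function(object) colnames(object@values))
setMethod("exprValues", "GeneMatrix", function(object) object@values)
setMethod("metaInfo", "GeneMatrix", function(object) object@metadata)
setMethod("nSamples", "GeneMatrix", function(object) nrow(object@values))
setMethod("nGenes", "GeneMatrix", function(object) ncol(object@values))

#' Subset a GeneMatrix by samples (i) and genes (j)
#'
#' @param i,j sample / gene indices or identifiers.
#' @param drop ignored; subsetting always returns a GeneMatrix.
#' @param ... ignored.
#' @rdname GeneMatrix
#' @export
setMethod("[", "GeneMatrix", function(x, i, j, ..., drop = FALSE) {
  v <- x@values
  if (!missing(i)) v <- v[i, , drop = FALSE]
  if (!missing(j)) v <- v[, j, drop = FALSE]
  new("GeneMatrix", values = v, metadata = x@metadata)
})

setMethod("nodeCodes", "ClassHierarchy", function(object) names(object@nodes))
setMethod("rootCode", "ClassHierarchy", function(object) object@rootCode)
setMethod("leafCodes", "ClassHierarchy", function(object)
  names(object@nodes)[vapply(object@nodes, function(n) length(n$children) == 0L, logical(1))])

setMethod("keptIDs", "FilterReport", function(object) object@keptIDs)
setMethod("droppedIDs", "FilterReport", function(object) object@droppedIDs)
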