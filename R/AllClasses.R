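#' @import methods
NULL

#' GeneMatrix: a samples-by-genes expression table
#'
#' Thin S4 container for an expression matrix with unique sample and gene
#' identifiers. Samples are rows in memory; readers accept the common
#' genes-per-line on-disk layout as well (see [readGeneMatrix()]). Values are
#' expected on the log2(TPM + 1) scale unless the \code{metadata} list says
#' otherwise (e.g. \code{metadata$scale = "counts"}).
#'
#' @slot values numeric matrix, samples x genes, with dimnames.
#' @slot metadata free-form list (normalisation tag, generator seed, ...).
#' @exportClass GeneMatrix
setClass("GeneMatrix",
  representation(values = "matrix", metadata = "list"),
  prototype(values = matrix(numeric(0), 0, 0), metadata = list()))

setValidity("GeneMatrix", function(object) {
  v <- object@values
  msgs <- character(0)
  if ((nrow(v) > 0 && is.null(rownames(v))) ||
      (ncol(v) > 0 && is.null(colnames(v))))
    msgs <- c(msgs, "values must carry sample (row) and gene (column) names")
  else {
    if (anyDuplicated(rownames(v))) msgs <- c(msgs, "duplicate sample identifiers")
    if (anyDuplicated(colnames(v))) msgs <- c(msgs, "duplicate gene identifiers")
  }
  if (!is.numeric(v)) msgs <- c(msgs, "values must be numeric")
  else if (length(v) && !all(is.finite(v))) msgs <- c(msgs, "values must be finite")
  if (length(msgs)) msgs else TRUE
})

#' Construct a GeneMatrix
#'
#' @param values numeric matrix, samples x genes.
#' @param sampleIDs,geneIDs optional identifier vectors; taken from dimnames
#'   when missing.
#' @param metadata optional list of free-form metadata.
#' @return a [GeneMatrix-class] object.
#' @examples
#' gm <- GeneMatrix(matrix(1:6, 2, 3), c("s1", "s2"), c("g1", "g2", "g3"))
#' nSamples(gm)
#' @export
GeneMatrix <- function(values, sampleIDs = rownames(values),
                       geneIDs = colnames(values), metadata = list()) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  dimnames(values) <- list(as.character(sampleIDs %||% character(0)),
                           as.character(geneIDs %||% character(0)))
  new("GeneMatrix", values = values, metadata = metadata)
}

#' ClassHierarchy: a tree of expression classes
#'
#' Each node carries a code, a label, a parent code (NA for the root), child
#' codes, the identifiers of its member samples and its depth (root = 0).
#' Children of one parent are pairwise disjoint and every child's members are
#' a subset of its parent's.
#'
#' @slot nodes named list of node records
#'   (\code{list(code, label, parent, children, members, level)}).
#' @slot rootCode code of the unique root node.
#' @exportClass ClassHierarchy
setClass("ClassHierarchy",
  representation(nodes = "list", rootCode = "character"))

setValidity("ClassHierarchy", function(object) {
  nodes <- object@nodes
  if (!length(nodes)) return("empty hierarchy")
  codes <- names(nodes)
  if (anyDuplicated(codes)) return("duplicate node codes")
  if (!object@rootCode %in% codes) return("root code not among nodes")
  roots <- codes[vapply(nodes, function(n) is.na(n$parent), logical(1))]
  if (length(roots) != 1L || roots != object@rootCode)
    return("hierarchy must have exactly one root")
  for (code in codes) {
    n <- nodes[[code]]
    if (!is.na(n$parent)) {
      if (!n$parent %in% codes)
        return(sprintf("parent of '%s' not in tree", code))
      p <- nodes[[n$parent]]
      if (!code %in% p$children)
        return(sprintf("'%s' missing from its parent's children", code))
      if (!all(n$members %in% p$members))
        return(sprintf("members of '%s' not a subset of its parent's", code))
      if (n$level != p$level + 1L)
        return(sprintf("level of '%s' inconsistent with its parent", code))
    } else if (n$level != 0L) return("root level must be 0")
    kids <- n$children
    if (length(kids)) {
      if (!all(kids %in% codes)) return(sprintf("unknown child of '%s'", code))
      mem <- unlist(lapply(kids, function(k) nodes[[k]]$members))
      if (anyDuplicated(mem))
        return(sprintf("children of '%s' are not pairwise disjoint", code))
    }
  }
  # acyclicity: every node must reach the root in < |nodes| steps
  for (code in codes) {
    cur <- code; steps <- 0L
    while (!is.na(nodes[[cur]]$parent)) {
      cur <- nodes[[cur]]$parent; steps <- steps + 1L
      if (steps > length(nodes)) return("cycle detected")
    }
  }
  TRUE
})

#' FilterReport: outcome of a sample or gene filter
#'
#' @slot keptIDs,droppedIDs identifier vectors partitioning the input.
#' @slot criterion short description of the rule applied.
#' @slot threshold numeric threshold used.
#' @exportClass FilterReport
setClass("FilterReport",
  representation(keptIDs = "character", droppedIDs = "character",
                 criterion = "character", threshold = "numeric"))

setValidity("FilterReport", function(object) {
  if (length(intersect(object@keptIDs, object@droppedIDs)))
    "kept and dropped identifiers overlap" else TRUE
})

#' SearchGrid: per-level clustering parameter grid
#'
#' @slot filterCutoffs fractions of lowest-variance features removed.
#' @slot neighborCounts neighbourhood sizes for the nonlinear embedding.
#' @slot densityParams maximum clustering distances (DBSCAN eps) tried.
#' @slot targetDims embedding dimensionality (default 12).
#' @slot minPts DBSCAN core-point threshold.
#' @exportClass SearchGrid
setClass("SearchGrid",
  representation(filterCutoffs = "numeric", neighborCounts = "integer",
                 densityParams = "numeric", targetDims = "integer",
                 minPts = "integer"))

setValidity("SearchGrid", function(object) {
  msgs <- character(0)
  if (!length(object@filterCutoffs) || any(object@filterCutoffs < 0 | object@filterCutoffs >= 1))
    msgs <- c(msgs, "filterCutoffs must be non-empty fractions in [0, 1)")
  if (!length(object@neighborCounts) || any(object@neighborCounts < 2))
    msgs <- c(msgs, "neighborCounts must be non-empty positive integers")
  if (!length(object@densityParams) || any(object@densityParams <= 0))
    msgs <- c(msgs, "densityParams must be non-empty positive reals")
  if (object@targetDims < 2L) msgs <- c(msgs, "targetDims must be >= 2")
  if (length(msgs)) msgs else TRUE
})

#' Construct a SearchGrid
#'
#' @param filterCutoffs,neighborCounts,densityParams grid axes; see
#'   [SearchGrid-class].
#' @param targetDims embedding dimensionality, default 12.
#' @param minPts DBSCAN core-point threshold, default 5.
#' @return a [SearchGrid-class] object.
#' @export
SearchGrid <- function(filterCutoffs = c(0, 0.3, 0.6, 0.9),
                       neighborCounts = c(10L, 15L, 30L),
                       densityParams = c(0.3, 0.5, 0.8), targetDims = 12L,
                       minPts = 5L) {
  new("SearchGrid", filterCutoffs = as.numeric(filterCutoffs),
      neighborCounts = as.integer(neighborCounts),
      densityParams = as.numeric(densityParams),
      targetDims = as.integer(targetDims), minPts = as.integer(minPts))
}

#' ArchitectureSpec: a member of the classifier architecture family
#'
#' One-dimensional convolutional layers (shared filter count and kernel size,
#' each followed by batch normalisation and max pooling of size 4, stride 2)
#' feeding fully connected layers whose width halves at every step, with
#' dropout, sigmoid outputs and binary cross-entropy loss.
#'
#' @slot convLayers number of convolutional layers (>= 1).
#' @slot filters filters per convolutional layer (shared).
#' @slot kernelSize convolution kernel width.
#' @slot denseLayers number of hidden dense layers (>= 1).
#' @slot firstDenseSize width of the first dense layer; halved afterwards.
#' @slot dropout dropout fraction in [0, 1).
#' @slot poolSize,poolStride max-pooling geometry, fixed at 4 / 2.
#' @exportClass ArchitectureSpec
setClass("ArchitectureSpec",
  representation(convLayers = "integer", filters = "integer",
                 kernelSize = "integer", denseLayers = "integer",
                 firstDenseSize = "integer", dropout = "numeric",
                 poolSize = "integer", poolStride = "integer"))

setValidity("ArchitectureSpec", function(object) {
  msgs <- character(0)
  if (object@convLayers < 1L) msgs <- c(msgs, "convLayers must be >= 1")
  if (object@filters < 1L) msgs <- c(msgs, "filters must be >= 1")
  if (object@kernelSize < 1L) msgs <- c(msgs, "kernelSize must be >= 1")
  if (object@denseLayers < 1L) msgs <- c(msgs, "denseLayers must be >= 1")
  if (object@firstDenseSize < 1L) msgs <- c(msgs, "firstDenseSize must be >= 1")
  if (object@dropout < 0 || object@dropout >= 1) msgs <- c(msgs, "dropout must be in [0, 1)")
  if (object@poolSize != 4L || object@poolStride != 2L)
    msgs <- c(msgs, "pool size/stride are fixed at 4/2")
  if (length(msgs)) msgs else TRUE
})

#' Construct an ArchitectureSpec
#'
#' @param convLayers,filters,kernelSize,denseLayers,firstDenseSize,dropout see
#'   [ArchitectureSpec-class].
#' @return an [ArchitectureSpec-class] object.
#' @export
ArchitectureSpec <- function(convLayers = 1L, filters = 4L, kernelSize = 5L,
                             denseLayers = 1L, firstDenseSize = 32L,
                             dropout = 0.2) {
  new("ArchitectureSpec", convLayers = as.integer(convLayers),
      filters = as.integer(filters), kernelSize = as.integer(kernelSize),
      denseLayers = as.integer(denseLayers),
      firstDenseSize = as.integer(firstDenseSize), dropout = as.numeric(dropout),
      poolSize = 4L, poolStride = 2L)
}

#' TrainedEnsemble: classifier members plus their shared input conditioning
#'
#' @slot members list of trained model handles (shared gene order and labels).
#' @slot geneOrder correlation-derived gene permutation applied to inputs.
#' @slot scalingBounds per-gene (min, max) used by the 0-1 input scaling.
#' @slot nodeCodes label space (all non-root hierarchy codes).
#' @slot treeRef checksum of the hierarchy the ensemble was trained against.
#' @slot trainingLog free-form list (seeds, backbone, early stopping, ...).
#' @exportClass TrainedEnsemble
setClass("TrainedEnsemble",
  representation(members = "list", geneOrder = "character",
                 scalingBounds = "matrix", nodeCodes = "character",
                 treeRef = "character", trainingLog = "list"))

setValidity("TrainedEnsemble", function(object) {
  if (!length(object@members)) return("ensemble needs at least one member")
  TRUE
})

#' PredictionReport: calibrated hierarchy-consistent sample predictions
#'
#' @slot calibrated samples x nodes matrix of calibrated probabilities.
#' @slot consistent samples x nodes matrix after consistency enforcement,
#'   before calibration (satisfies child <= parent on every edge).
#' @slot raw samples x nodes matrix of raw ensemble means.
#' @slot majorityPath per-sample root-to-deepest chain of argmax children.
#' @slot flags data.frame with per-sample logical flags
#'   (\code{normalDominant}, \code{multiClass}, \code{lowConfidence}).
#' @exportClass PredictionReport
setClass("PredictionReport",
  representation(calibrated = "matrix", consistent = "matrix", raw = "matrix",
                 majorityPath = "character", flags = "data.frame"))

setMethod("show", "GeneMatrix", function(object) {
  cat(sprintf("GeneMatrix: %d samples x %d genes\n",
              nrow(object@values), ncol(object@values)))
  if (length(object@metadata))
    cat("  metadata:", paste(names(object@metadata), collapse = ", "), "\n")
})

setMethod("show", "ClassHierarchy", function(object) {
  lv <- vapply(object@nodes, `[[`, integer(1), "level")
  cat(sprintf("ClassHierarchy: %d nodes (%d leaves), depth %d, root '%s' (%d samples)\n",
              length(object@nodes), sum(lengths(lapply(object@nodes, `[[`, "children")) == 0),
              max(lv), object@rootCode,
              length(object@nodes[[object@rootCode]]$members)))
})

setMethod("show", "FilterReport", function(object) {
  cat(sprintf("FilterReport [%s, threshold %g]: kept %d, dropped %d\n",
              object@criterion, object@threshold,
              length(object@keptIDs), length(object@droppedIDs)))
})

setMethod("show", "ArchitectureSpec", function(object) {
  cat(sprintf("ArchitectureSpec: %d conv (%d filters, kernel %d) + %d dense (first %d), dropout %.2f\n",
              object@convLayers, object@filters, object@kernelSize,
              object@denseLayers, object@firstDenseSize, object@dropout))
})

setMethod("show", "TrainedEnsemble", function(object) {
  cat(sprintf("TrainedEnsemble: %d member(s), %d genes, %d label nodes (backbone: %s)\n",
              length(object@members), length(object@geneOrder),
              length(object@nodeCodes),
              object@trainingLog$backbone %||% "unknown"))
})

setMethod("show", "PredictionReport", function(object) {
  cat(sprintf("PredictionReport: %d samples x %d nodes; flags: %s\n",
              nrow(object@calibrated), ncol(object@calibrated),
              paste(names(object@flags), collapse = ", ")))
})
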