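# Cohort quality filters, gene filtering and classifier input conditioning.

#' Drop samples with too many unexpressed coding genes
#'
#' A sample is excluded when the fraction of protein-coding genes with
#' expression exactly zero (TPM = 0, i.e. log2(TPM + 1) = 0) strictly exceeds
#' `maxZeroFrac`. The default 0.25 reproduces the standard more-than-25%
#' zero-coding-genes quality rule.
#'
#' @param gm a [GeneMatrix-class].
#' @param codingGenes character vector of protein-coding gene ids; only their
#'   intersection with the matrix is considered.
#' @param maxZeroFrac maximum tolerated zero fraction (strict inequality).
#' @return a [FilterReport-class] over sample ids.
#' @export
filterZeroFraction <- function(gm, codingGenes, maxZeroFrac = 0.25) {
  coding <- intersect(codingGenes, geneIDs(gm))
  if (!length(coding)) stop("empty coding-gene set after intersection")
  v <- exprValues(gm)[, coding, drop = FALSE]
  zf <- rowMeans(v == 0)
  dropped <- sampleIDs(gm)[zf > maxZeroFrac]
  new("FilterReport", keptIDs = setdiff(sampleIDs(gm), dropped),
      droppedIDs = dropped, criterion = "zero_fraction",
      threshold = maxZeroFrac)
}

#' Keep the high-variance genes covering a cumulative-variance fraction
#'
#' Genes are ranked by variance (descending, ties broken by gene-id order)
#' and the smallest prefix whose summed variance reaches `frac` of the total
#' is kept. With the default `frac = 0.99` this is the usual
#' 99%-cumulative-variance feature reduction.
#'
#' @param gm a [GeneMatrix-class].
#' @param frac fraction of total variance to retain, in (0, 1].
#' @return a [FilterReport-class] over gene ids.
#' @export
filterCumulativeVariance <- function(gm, frac = 0.99) {
  assertScalarNumber(frac, "frac", lower = 1e-12, upper = 1)
  v <- exprValues(gm)
  vars <- apply(v, 2L, stats::var)
  if (all(vars == 0)) stop("all genes have zero variance")
  ord <- order(-vars, geneIDs(gm))
  cum <- cumsum(vars[ord])
  nKeep <- which(cum >= frac * sum(vars) - 1e-12)[1L]
  kept <- geneIDs(gm)[ord][seq_len(nKeep)]
  new("FilterReport", keptIDs = kept,
      droppedIDs = setdiff(geneIDs(gm), kept),
      criterion = "cumulative_variance", threshold = frac)
}

#' Apply a FilterReport to a GeneMatrix
#'
#' @param gm a [GeneMatrix-class].
#' @param report a [FilterReport-class]; sample filters subset rows, gene
#'   filters subset columns (decided by which axis the kept ids match).
#' @return the filtered [GeneMatrix-class].
#' @export
applyFilter <- function(gm, report) {
  ids <- keptIDs(report)
  if (all(ids %in% sampleIDs(gm)) && !all(ids %in% geneIDs(gm))) {
    gm[intersect(sampleIDs(gm), ids), ]
  } else {
    gm[, intersect(geneIDs(gm), ids)]
  }
}

#' Serialise a FilterReport as TSV
#'
#' @param report a [FilterReport-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeFilterReport <- function(report, path) {
  df <- data.frame(
    id = c(keptIDs(report), droppedIDs(report)),
    status = rep(c("kept", "dropped"),
                 c(length(keptIDs(report)), length(droppedIDs(report)))),
    criterion = report@criterion, threshold = report@threshold)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Order genes by expression correlation
#'
#' Deterministic leaf order of an average-linkage agglomerative dendrogram on
#' 1 - Pearson correlation distances between genes, so that co-expressed
#' genes sit next to each other in the classifier's input array. Constant
#' genes (undefined correlation) are assigned distance 1 to every other gene,
#' with a warning.
#'
#' @param gm a [GeneMatrix-class] on the log2 scale.
#' @return character permutation of the gene ids.
#' @export
orderGenesByCorrelation <- function(gm) {
  v <- exprValues(gm)
  if (ncol(v) < 2L) stop("need at least 2 genes")
  if (nrow(v) < 3L) stop("need at least 3 samples")
  sds <- apply(v, 2L, stats::sd)
  if (any(sds == 0))
    warning(sum(sds == 0), " constant gene(s): correlation undefined, distance set to 1")
  cc <- suppressWarnings(stats::cor(v))
  cc[!is.finite(cc)] <- 0
  d <- 1 - cc
  diag(d) <- 0
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  geneIDs(gm)[hc$order]
}

#' Scale gene values to the unit interval
#'
#' Train mode (no `bounds`): per-gene min-max scaling; the bounds are stored
#' for reuse at prediction time. Apply mode: uses the provided bounds and
#' clips the output to [0, 1]. Constant genes scale to 0 with a warning.
#'
#' @param gm a [GeneMatrix-class].
#' @param bounds optional 2-row matrix (`min`, `max`) with one column per
#'   gene, as returned in the `bounds` attribute of a train-mode call.
#' @return a [GeneMatrix-class] with values in [0, 1]; train mode attaches
#'   the bounds as `attr(result, "bounds")` and in `metaInfo(result)$bounds`.
#' @export
scaleUnitInterval <- function(gm, bounds = NULL) {
  v <- exprValues(gm)
  if (is.null(bounds)) {
    lo <- apply(v, 2L, min)
    hi <- apply(v, 2L, max)
    if (any(hi == lo)) warning(sum(hi == lo), " constant gene(s) scaled to 0")
    bounds <- rbind(min = lo, max = hi)
    colnames(bounds) <- geneIDs(gm)
    applyMode <- FALSE
  } else {
    if (!setequal(colnames(bounds), geneIDs(gm)))
      stop("bounds gene set does not match the matrix")
    bounds <- bounds[, geneIDs(gm), drop = FALSE]
    applyMode <- TRUE
  }
  span <- bounds["max", ] - bounds["min", ]
  span[span == 0] <- 1
  out <- sweep(sweep(v, 2L, bounds["min", ], "-"), 2L, span, "/")
  out[, bounds["max", ] == bounds["min", ]] <- 0
  if (applyMode) out <- pmin(pmax(out, 0), 1)
  res <- GeneMatrix(out, metadata = c(metaInfo(gm), list(bounds = bounds)))
  attr(res, "bounds") <- bounds
  res
}

#' Invert a unit-interval scaling
#'
#' @param gm a scaled [GeneMatrix-class].
#' @param bounds the bounds used to scale it.
#' @return a [GeneMatrix-class] on the original scale (constant genes return
#'   at their stored minimum).
#' @export
unscaleUnitInterval <- function(gm, bounds) {
  bounds <- bounds[, geneIDs(gm), drop = FALSE]
  span <- bounds["max", ] - bounds["min", ]
  v <- sweep(sweep(exprValues(gm), 2L, span, "*"), 2L, bounds["min", ], "+")
  GeneMatrix(v, metadata = metaInfo(gm))
}
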