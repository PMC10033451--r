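# Readers and writers: matrices (TSV, gzip-transparent), hierarchies (JSON),
# labels and prediction tables (TSV). Missing values are never imputed;
# readers fail loudly.

.openText <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
}

#' Read an expression matrix from delimited text
#'
#' Tab-separated with a header row; the first column holds gene or sample
#' identifiers. Orientation is auto-detected from the first header field:
#' `gene`/`gene_id` means one gene per line (genes x samples on disk),
#' `sample`/`sample_id` means one sample per line. Unrecognised headers fall
#' back to the common genes-per-line dialect with a message. Gzip-compressed
#' files are read transparently. The in-memory contract is always samples x
#' genes.
#'
#' @param path file path (optionally .gz).
#' @param metadata optional metadata list attached to the result.
#' @return a [GeneMatrix-class].
#' @export
readGeneMatrix <- function(path, metadata = list()) {
  con <- .openText(path)
  on.exit(close(con))
  df <- utils::read.delim(con, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("matrix file needs an id column plus data columns")
  idName <- tolower(names(df)[1L])
  ids <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric values in matrix file")
  if (anyNA(m)) stop("missing values in matrix file; imputation is not supported")
  rownames(m) <- ids
  rowsAreGenes <- if (idName %in% c("gene", "gene_id", "genes")) TRUE
    else if (idName %in% c("sample", "sample_id", "samples")) FALSE
    else {
      message("unrecognised id header '", names(df)[1L],
              "'; assuming one gene per line")
      TRUE
    }
  if (rowsAreGenes) m <- t(m)
  GeneMatrix(m, metadata = metadata)
}

#' Write an expression matrix as tab-separated text
#'
#' @param gm a [GeneMatrix-class].
#' @param path output path; `.gz` suffix triggers compression.
#' @param orientation `"genes"` writes one gene per line (default, the common
#'   expression-table dialect); `"samples"` writes one sample per line.
#' @return `path`, invisibly.
#' @export
writeGeneMatrix <- function(gm, path, orientation = c("genes", "samples")) {
  orientation <- match.arg(orientation)
  v <- exprValues(gm)
  if (orientation == "genes") {
    df <- data.frame(gene_id = geneIDs(gm), t(v), check.names = FALSE)
  } else {
    df <- data.frame(sample_id = sampleIDs(gm), v, check.names = FALSE)
  }
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a class hierarchy as JSON
#'
#' One record per node with fields `code`, `label`, `parent` (null for the
#' root) and `members`; children and levels are derived on load.
#'
#' @param tree a [ClassHierarchy-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeHierarchy <- function(tree, path) {
  recs <- lapply(tree@nodes, function(n)
    list(code = n$code, label = n$label,
         parent = if (is.na(n$parent)) NULL else n$parent,
         members = I(n$members)))
  jsonlite::write_json(unname(recs), path, auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' Read a class hierarchy from JSON
#'
#' @param path path written by [writeHierarchy()] (or hand-authored with the
#'   same fields).
#' @return a [ClassHierarchy-class].
#' @export
readHierarchy <- function(path) {
  recs <- jsonlite::read_json(path, simplifyVector = FALSE)
  codes <- vapply(recs, function(r) as.character(r$code), character(1))
  parents <- vapply(recs, function(r)
    if (is.null(r$parent)) NA_character_ else as.character(r$parent), character(1))
  labels <- vapply(recs, function(r)
    as.character(r$label %||% r$code), character(1))
  members <- lapply(recs, function(r) as.character(unlist(r$members)))
  makeHierarchy(codes, parents, members, labels)
}

#' Read / write sample-to-class label tables
#'
#' Two-column TSV: `sample_id`, `node_code`.
#'
#' @param path file path.
#' @param tree optional [ClassHierarchy-class]; when given, unknown codes
#'   raise an error listing the offenders.
#' @return named character vector sample id -> node code.
#' @export
readLabels <- function(path, tree = NULL) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("label file needs columns sample_id, node_code")
  out <- setNames(as.character(df[[2L]]), as.character(df[[1L]]))
  if (!is.null(tree)) {
    bad <- setdiff(unique(out), nodeCodes(tree))
    if (length(bad))
      stop("unknown node code(s) in labels: ", paste(bad, collapse = ", "))
  }
  out
}

#' @rdname readLabels
#' @param labels named character vector sample id -> node code.
#' @export
writeLabels <- function(labels, path) {
  utils::write.table(
    data.frame(sample_id = names(labels), node_code = unname(labels)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a prediction report as TSV
#'
#' One column per node code (calibrated probabilities) plus `majority_path`
#' and the per-sample flags.
#'
#' @param report a [PredictionReport-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writePredictions <- function(report, path) {
  df <- data.frame(sample_id = rownames(report@calibrated),
                   report@calibrated, check.names = FALSE)
  df$majority_path <- report@majorityPath
  df <- cbind(df, report@flags)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
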