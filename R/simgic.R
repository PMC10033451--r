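# SimGIC-weighted hierarchical similarity (H and its one-sided variant eta)
# and multilabel evaluation scores.

#' Information-content node weights
#'
#' w(n) = -ln p(n), with p(n) the class frequency of node n in the training
#' hierarchy. The root has weight 0; weights are non-decreasing with depth
#' along every root-to-leaf path because frequencies are non-increasing.
#'
#' @param tree a [ClassHierarchy-class].
#' @return named numeric vector of weights (nats).
#' @export
simgicWeights <- function(tree) {
  p <- classFrequencies(tree)
  if (any(p == 0))
    stop("node(s) with zero members: ",
         paste(names(p)[p == 0], collapse = ", "))
  -log(p)
}

.alignVectors <- function(v1, v2, w) {
  nodes <- names(w)
  a <- setNames(numeric(length(nodes)), nodes)
  b <- a
  a[intersect(names(v1), nodes)] <- v1[intersect(names(v1), nodes)]
  b[intersect(names(v2), nodes)] <- v2[intersect(names(v2), nodes)]
  if (any(a < -1e-9 | a > 1 + 1e-9 | b < -1e-9 | b > 1 + 1e-9))
    stop("membership probabilities must lie in [0, 1]")
  list(a = pmin(pmax(a, 0), 1), b = pmin(pmax(b, 0), 1))
}

#' Hierarchical similarity between two membership vectors
#'
#' The SimGIC-style weighted fuzzy Jaccard over tree nodes:
#' H = sum(w * min(v1, v2)) / sum(w * max(v1, v2)). Symmetric, in [0, 1],
#' and invariant to probability mass on zero-weight nodes (the root) and to
#' the logarithm base used for the weights.
#'
#' @param v1,v2 named numeric membership vectors over the same tree
#'   (missing entries read as 0).
#' @param w weights from [simgicWeights()].
#' @return similarity in [0, 1].
#' @export
hierarchicalSimilarity <- function(v1, v2, w) {
  al <- .alignVectors(v1, v2, w)
  den <- sum(w * pmax(al$a, al$b))
  if (den <= 0) stop("undefined similarity: no weighted support")
  sum(w * pmin(al$a, al$b)) / den
}

#' One-sided (false-positive-blind) hierarchical similarity
#'
#' eta = sum(w * min(truth, pred)) / sum(w * truth): only the branches
#' active in the ground truth contribute to the denominator, so extra
#' predicted branches are not penalised. Always >= the symmetric H.
#'
#' @param truth,pred named numeric membership vectors (truth first).
#' @param w weights from [simgicWeights()].
#' @return similarity in [0, 1].
#' @export
partialHierarchicalSimilarity <- function(truth, pred, w) {
  al <- .alignVectors(truth, pred, w)
  den <- sum(w * al$a)
  if (den <= 0) stop("truth has no weighted support")
  sum(w * pmin(al$a, al$b)) / den
}

#' Crisp membership vector for a deepest-class assignment
#'
#' Activates the assigned node and all its ancestors (probability 1),
#' including the root (harmless: its weight is 0).
#'
#' @param tree a [ClassHierarchy-class].
#' @param code the assigned node.
#' @return named 0/1 vector over all tree nodes.
#' @export
crispMembership <- function(tree, code) {
  v <- setNames(numeric(length(nodeCodes(tree))), nodeCodes(tree))
  v[c(code, ancestors(tree, code))] <- 1
  v
}

#' Multilabel classification scores
#'
#' Per-node precision, recall, F1 and accuracy plus micro and macro
#' aggregates; average-precision AUCPR per node (and macro) when
#' pre-binarisation scores are supplied. Nodes with no positive example are
#' excluded from the macro averages (with a message).
#'
#' @param targets binary matrix, samples x nodes.
#' @param preds binary matrix of the same shape.
#' @param scores optional numeric matrix of raw scores for AUCPR.
#' @return list with `per_node` (data.frame) and `aggregate` (named vector:
#'   micro_precision, micro_recall, micro_F1, accuracy, macro_precision,
#'   macro_recall, macro_F1, macro_AUCPR).
#' @export
multilabelScores <- function(targets, preds, scores = NULL) {
  stopifnot(all(dim(targets) == dim(preds)))
  targets <- targets > 0; preds <- preds > 0
  tp <- colSums(targets & preds)
  fp <- colSums(!targets & preds)
  fn <- colSums(targets & !preds)
  tn <- colSums(!targets & !preds)
  prec <- ifelse(tp + fp > 0, tp / (tp + fp), NA_real_)
  rec <- ifelse(tp + fn > 0, tp / (tp + fn), NA_real_)
  f1 <- ifelse(is.na(prec) | is.na(rec) | (prec + rec) == 0, 0,
               2 * prec * rec / (prec + rec))
  acc <- (tp + tn) / nrow(targets)
  aucpr <- rep(NA_real_, ncol(targets))
  if (!is.null(scores)) {
    for (j in seq_len(ncol(targets)))
      if (any(targets[, j])) aucpr[j] <- .averagePrecision(scores[, j], targets[, j])
  }
  hasPos <- colSums(targets) > 0
  if (any(!hasPos))
    message(sum(!hasPos), " node(s) without positives excluded from macro averages")
  per <- data.frame(node = colnames(targets) %||% seq_len(ncol(targets)),
                    tp = tp, fp = fp, fn = fn,
                    precision = prec, recall = rec, F1 = f1,
                    accuracy = acc, AUCPR = aucpr,
                    row.names = NULL, stringsAsFactors = FALSE)
  TP <- sum(tp); FP <- sum(fp); FN <- sum(fn)
  microP <- if (TP + FP > 0) TP / (TP + FP) else 0
  microR <- if (TP + FN > 0) TP / (TP + FN) else 0
  agg <- c(
    micro_precision = microP, micro_recall = microR,
    micro_F1 = if (microP + microR > 0) 2 * microP * microR / (microP + microR) else 0,
    accuracy = mean(targets == preds),
    macro_precision = mean(prec[hasPos], na.rm = TRUE),
    macro_recall = mean(rec[hasPos], na.rm = TRUE),
    macro_F1 = mean(f1[hasPos]),
    macro_AUCPR = if (all(is.na(aucpr))) NA_real_ else mean(aucpr[hasPos], na.rm = TRUE))
  list(per_node = per, aggregate = agg)
}

# Average precision: sum over positives of precision at each recall step,
# scores sorted descending (ties grouped by midrank-free convention: stable
# descending order, equivalent to step integration of the PR curve).
.averagePrecision <- function(scores, labels) {
  ord <- order(-scores)
  lab <- labels[ord]
  tp <- cumsum(lab)
  prec <- tp / seq_along(lab)
  sum(prec[lab]) / sum(lab)
}

#' Micro-F1 restricted to the nodes at one hierarchy level
#'
#' @param tree a [ClassHierarchy-class].
#' @param targets,preds binary matrices with node-code columns.
#' @param level hierarchy depth (default 1).
#' @return the micro-F1 over the level's columns.
#' @export
levelMicroF1 <- function(tree, targets, preds, level = 1L) {
  codes <- intersect(colnames(targets),
                     nodeCodes(tree)[vapply(nodeCodes(tree), function(k)
                       nodeLevel(tree, k) == level, logical(1))])
  if (!length(codes)) stop("no label columns at the requested level")
  res <- multilabelScores(targets[, codes, drop = FALSE],
                          preds[, codes, drop = FALSE])
  unname(res$aggregate["micro_F1"])
}
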