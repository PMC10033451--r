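# Class-hierarchy construction and arithmetic.

#' Build a ClassHierarchy from flat node records
#'
#' Children and levels are reconstructed from the parent links; the root is
#' the unique node whose parent is missing.
#'
#' @param codes character vector of node codes.
#' @param parents parent code per node (NA for the root).
#' @param members list of member sample-id vectors, one per node.
#' @param labels optional human-readable labels (default = codes).
#' @return a [ClassHierarchy-class] object.
#' @examples
#' tr <- makeHierarchy(c("R", "A", "B"), c(NA, "R", "R"),
#'                     list(c("s1", "s2"), "s1", "s2"))
#' leafCodes(tr)
#' @export
makeHierarchy <- function(codes, parents, members, labels = codes) {
  codes <- as.character(codes)
  parents <- as.character(parents)
  stopifnot(length(codes) == length(parents), length(codes) == length(members))
  if (anyDuplicated(codes)) stop("duplicate node codes")
  rootIdx <- which(is.na(parents))
  if (length(rootIdx) != 1L) stop("hierarchy must have exactly one root")
  nodes <- vector("list", length(codes))
  names(nodes) <- codes
  for (i in seq_along(codes)) {
    nodes[[i]] <- list(code = codes[i], label = as.character(labels[i]),
                       parent = parents[i], children = character(0),
                       members = as.character(members[[i]]), level = NA_integer_)
  }
  for (i in seq_along(codes)) {
    p <- parents[i]
    if (!is.na(p)) {
      if (!p %in% codes) stop(sprintf("parent '%s' of '%s' not in tree", p, codes[i]))
      nodes[[p]]$children <- c(nodes[[p]]$children, codes[i])
    }
  }
  # levels by breadth-first walk from the root
  nodes[[rootIdx]]$level <- 0L
  queue <- codes[rootIdx]
  while (length(queue)) {
    cur <- queue[1L]; queue <- queue[-1L]
    for (k in nodes[[cur]]$children) {
      nodes[[k]]$level <- nodes[[cur]]$level + 1L
      queue <- c(queue, k)
    }
  }
  if (anyNA(vapply(nodes, `[[`, integer(1), "level")))
    stop("disconnected nodes in hierarchy")
  new("ClassHierarchy", nodes = nodes, rootCode = codes[rootIdx])
}

#' @rdname hierarchy-accessors
#' @name hierarchy-accessors
#' @title Accessors for ClassHierarchy nodes
#' @param object,tree a [ClassHierarchy-class].
#' @param code a node code.
#' @return `nodeMembers`, `nodeChildren`: character vectors; `nodeParent`:
#'   a code or NA; `nodeLevel`: integer depth; `nodeLabel`: the label.
NULL

#' @rdname hierarchy-accessors
#' @export
nodeMembers <- function(tree, code) .node(tree, code)$members

#' @rdname hierarchy-accessors
#' @export
nodeChildren <- function(tree, code) .node(tree, code)$children

#' @rdname hierarchy-accessors
#' @export
nodeParent <- function(tree, code) .node(tree, code)$parent

#' @rdname hierarchy-accessors
#' @export
nodeLevel <- function(tree, code) .node(tree, code)$level

#' @rdname hierarchy-accessors
#' @export
nodeLabel <- function(tree, code) .node(tree, code)$label

.node <- function(tree, code) {
  n <- tree@nodes[[code]]
  if (is.null(n)) stop(sprintf("unknown node code '%s'", code))
  n
}

#' Ancestor chain of a node
#'
#' @param tree a [ClassHierarchy-class].
#' @param code a node code.
#' @return codes from the node's parent up to the root, nearest first; empty
#'   for the root.
#' @export
ancestors <- function(tree, code) {
  cur <- .node(tree, code)
  out <- character(0)
  while (!is.na(cur$parent)) {
    out <- c(out, cur$parent)
    cur <- tree@nodes[[cur$parent]]
  }
  out
}

#' Class frequencies over a hierarchy
#'
#' The empirical probability that a sample of the root cohort falls into each
#' node: p(n) = |members(n)| / |members(root)|. These frequencies are the
#' information-content weights' input for the SimGIC similarity.
#'
#' @param tree a [ClassHierarchy-class].
#' @return named numeric vector of frequencies, p(root) = 1.
#' @export
classFrequencies <- function(tree) {
  rootN <- length(nodeMembers(tree, rootCode(tree)))
  if (rootN == 0L) stop("empty hierarchy")
  vapply(tree@nodes, function(n) length(n$members) / rootN, numeric(1))
}

#' Multilabel one-hot encoding of deepest-class assignments
#'
#' Each sample's row activates its assigned node and every ancestor except
#' the root (the root is always true and carries zero information weight, so
#' it is excluded from the label space).
#'
#' @param tree a [ClassHierarchy-class].
#' @param labels named character vector, sample id -> deepest known node code.
#' @return binary matrix, samples x non-root nodes (column order: by level,
#'   then code).
#' @export
multiHotLabels <- function(tree, labels) {
  codes <- labelSpace(tree)
  bad <- setdiff(unique(labels), nodeCodes(tree))
  if (length(bad))
    stop("unknown node code(s) in labels: ", paste(bad, collapse = ", "))
  out <- matrix(0L, nrow = length(labels), ncol = length(codes),
                dimnames = list(names(labels), codes))
  for (i in seq_along(labels)) {
    on <- setdiff(c(labels[[i]], ancestors(tree, labels[[i]])), rootCode(tree))
    out[i, on] <- 1L
  }
  out
}

#' Label space of a hierarchy
#'
#' All non-root node codes, ordered by level then code — the column order used
#' by [multiHotLabels()], trained ensembles and prediction reports.
#'
#' @param tree a [ClassHierarchy-class].
#' @return character vector of codes.
#' @export
labelSpace <- function(tree) {
  codes <- setdiff(nodeCodes(tree), rootCode(tree))
  lv <- vapply(codes, function(k) nodeLevel(tree, k), integer(1))
  codes[order(lv, codes)]
}

#' Deepest assigned class per sample from a hierarchy's membership sets
#'
#' Utility inverse of the truth tree: each root member is mapped to the code
#' of the deepest node containing it.
#'
#' @param tree a [ClassHierarchy-class].
#' @return named character vector sample id -> code.
#' @export
deepestAssignment <- function(tree) {
  root <- rootCode(tree)
  out <- setNames(rep(root, length(nodeMembers(tree, root))),
                  nodeMembers(tree, root))
  lv <- vapply(tree@nodes, `[[`, integer(1), "level")
  for (code in names(sort(lv))) {  # shallow to deep: deeper nodes overwrite
    out[nodeMembers(tree, code)] <- code
  }
  out
}

#' Level-wise partition induced by a hierarchy
#'
#' Assigns every root member to its ancestor at the requested level (samples
#' not covered by any node at that level keep their deepest shallower
#' assignment, i.e. stay with the parent they were never split from).
#'
#' @param tree a [ClassHierarchy-class].
#' @param level positive integer depth.
#' @return named character vector sample id -> code at (or above) `level`.
#' @export
levelAssignment <- function(tree, level = 1L) {
  root <- rootCode(tree)
  out <- setNames(rep(root, length(nodeMembers(tree, root))),
                  nodeMembers(tree, root))
  lv <- vapply(tree@nodes, `[[`, integer(1), "level")
  for (code in names(sort(lv[lv <= level & lv > 0L]))) {
    out[nodeMembers(tree, code)] <- code
  }
  out
}

.treeChecksum <- function(tree) {
  sig <- paste(vapply(tree@nodes[order(names(tree@nodes))], function(n)
    paste(n$code, n$parent, length(n$members), sep = ":"), character(1)),
    collapse = "|")
  # small rolling hash; stable across sessions
  h <- 0
  for (ch in utf8ToInt(sig)) h <- (h * 31 + ch) %% 2147483647
  sprintf("%s-%d-%d", rootCode(tree), length(tree@nodes), as.integer(h))
}
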