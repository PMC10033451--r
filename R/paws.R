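# PaWS: population-weighted split score over the class hierarchy, and the
# entropy-vs-PaWS correlation report.

#' Population-weighted split score of a node
#'
#' PaWS(n) = (|L_n| / |L|) * (log|root| / log|n|), where L is the set of all
#' leaves of the hierarchy, L_n the leaves descending from n (a leaf counts
#' itself, |L_n| = 1), |n| the node population and |root| the cohort size.
#' The log-ratio weight compensates smaller clusters' lower chance of being
#' split further. The log base cancels in the ratio. PaWS(root) = 1.
#'
#' @param tree a [ClassHierarchy-class].
#' @param code a node code with population >= 2.
#' @return the PaWS value (>= 0).
#' @export
paws <- function(tree, code) {
  n <- .node(tree, code)
  pop <- length(n$members)
  if (pop < 2L) stop("population too small for PaWS")
  allLeaves <- leafCodes(tree)
  own <- .descendantLeaves(tree, code)
  rootPop <- length(nodeMembers(tree, rootCode(tree)))
  (length(own) / length(allLeaves)) * (log(rootPop) / log(pop))
}

.descendantLeaves <- function(tree, code) {
  kids <- nodeChildren(tree, code)
  if (!length(kids)) return(code)
  unlist(lapply(kids, .descendantLeaves, tree = tree))
}

#' PaWS table for a whole hierarchy
#'
#' @param tree a [ClassHierarchy-class].
#' @return data.frame with columns `node`, `paws`, `leaf_count`,
#'   `population`, `is_leaf`; nodes with fewer than 2 members get NA.
#' @export
pawsTable <- function(tree) {
  codes <- nodeCodes(tree)
  data.frame(
    node = codes,
    paws = vapply(codes, function(k) {
      if (length(nodeMembers(tree, k)) < 2L) NA_real_ else paws(tree, k)
    }, numeric(1)),
    leaf_count = vapply(codes, function(k) length(.descendantLeaves(tree, k)),
                        integer(1)),
    population = vapply(codes, function(k) length(nodeMembers(tree, k)),
                        integer(1)),
    is_leaf = vapply(codes, function(k) length(nodeChildren(tree, k)) == 0L,
                     logical(1)),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Correlation report between median entropy and PaWS
#'
#' Spearman rank correlation between per-class median adjusted entropy and
#' PaWS over the internal (non-leaf) nodes of the hierarchy. Leaves are
#' excluded: they may hide subtypes the clustering lacked the population to
#' resolve, so their PaWS is uninformative.
#'
#' @param summary output of [entropySummary()] (its `class` column must use
#'   hierarchy node codes).
#' @param pawsTab output of [pawsTable()].
#' @return a list with `rho`, `p_value`, `n_nodes` and the merged data.
#' @export
heterogeneityReport <- function(summary, pawsTab) {
  tab <- merge(summary, pawsTab[!pawsTab$is_leaf, ],
               by.x = "class", by.y = "node")
  tab <- tab[is.finite(tab$paws), , drop = FALSE]
  if (nrow(tab) < 3L) stop("need at least 3 usable non-leaf nodes")
  ct <- suppressWarnings(
    stats::cor.test(tab$median_S, tab$paws, method = "spearman"))
  list(rho = unname(ct$estimate), p_value = ct$p.value,
       n_nodes = nrow(tab), data = tab)
}
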