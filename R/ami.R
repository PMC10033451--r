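# Adjusted mutual information between two partitions, with the exact
# expected mutual information under the permutation (hypergeometric) model
# and arithmetic-mean normalisation.

#' Adjusted mutual information between two labelings
#'
#' Chance-corrected agreement between two partitions of the same items:
#' AMI = (MI - E[MI]) / (mean(H(U), H(V)) - E[MI]), where the expectation is
#' taken over random contingency tables with fixed margins and entropies are
#' in nats. Used to compare recovered hierarchy partitions against planted
#' truth. Identical partitions give 1; independent ones give approximately 0
#' (can be slightly negative).
#'
#' @param a,b label vectors of equal length (any atomic type).
#' @return the AMI value.
#' @export
adjustedMutualInformation <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors must have equal length")
  n <- length(a)
  if (n == 0L) stop("empty labelings")
  a <- as.integer(factor(a)); b <- as.integer(factor(b))
  tab <- table(a, b)
  ai <- rowSums(tab); bj <- colSums(tab)
  if (length(ai) == 1L && length(bj) == 1L) return(1)

  Hu <- .partitionEntropy(ai, n)
  Hv <- .partitionEntropy(bj, n)
  mi <- 0
  for (i in seq_along(ai)) for (j in seq_along(bj)) {
    nij <- tab[i, j]
    if (nij > 0) mi <- mi + nij / n * log(nij * n / (ai[i] * bj[j]))
  }
  emi <- .expectedMI(ai, bj, n)
  denom <- (Hu + Hv) / 2 - emi
  if (abs(denom) < .Machine$double.eps) return(0)
  unname((mi - emi) / denom)
}

.partitionEntropy <- function(counts, n) {
  p <- counts[counts > 0] / n
  -sum(p * log(p))
}

# E[MI] under fixed margins: sum over cells and admissible nij of
# nij/n * log(n*nij/(ai*bj)) * P_hypergeom(nij; ai, bj, n).
.expectedMI <- function(ai, bj, n) {
  emi <- 0
  lgN <- lgamma(n + 1)
  for (i in seq_along(ai)) {
    for (j in seq_along(bj)) {
      lo <- max(1, ai[i] + bj[j] - n)
      hi <- min(ai[i], bj[j])
      if (hi < lo) next
      nij <- lo:hi
      logp <- lgamma(ai[i] + 1) + lgamma(bj[j] + 1) +
        lgamma(n - ai[i] + 1) + lgamma(n - bj[j] + 1) - lgN -
        lgamma(nij + 1) - lgamma(ai[i] - nij + 1) - lgamma(bj[j] - nij + 1) -
        lgamma(n - ai[i] - bj[j] + nij + 1)
      term <- nij / n * log(nij * n / (ai[i] * bj[j]))
      emi <- emi + sum(exp(logp) * term)
    }
  }
  emi
}

#' Recovery of planted classes by a computed hierarchy
#'
#' For every planted class, the best Jaccard index between its member set
#' and any node of the computed hierarchy. A class counts as recovered when
#' that best Jaccard reaches `threshold`.
#'
#' @param tree a computed [ClassHierarchy-class].
#' @param truthLabels named vector sample id -> planted class.
#' @param threshold Jaccard needed to call a class recovered (default 0.5).
#' @return data.frame with columns `class`, `best_jaccard`, `best_node`,
#'   `recovered`.
#' @export
classRecovery <- function(tree, truthLabels, threshold = 0.5) {
  planted <- split(names(truthLabels), truthLabels)
  codes <- nodeCodes(tree)
  res <- lapply(names(planted), function(cl) {
    tgt <- planted[[cl]]
    jac <- vapply(codes, function(k) {
      m <- nodeMembers(tree, k)
      length(intersect(m, tgt)) / length(union(m, tgt))
    }, numeric(1))
    best <- which.max(jac)
    data.frame(class = cl, best_jaccard = jac[best], best_node = codes[best],
               recovered = jac[best] >= threshold,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(res, list(make.row.names = FALSE)))
}
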