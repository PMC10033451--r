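# Seeded generator of hierarchical expression cohorts: negative-binomial
# counts with nested marker-gene blocks, class-controlled dispersion,
# log-normal library sizes, sample mixing and binomial count thinning.

#' Specification of a synthetic hierarchical cohort
#'
#' Defines a balanced class tree (one branching factor per level) and the
#' count model: every non-root node owns a disjoint block of marker genes,
#' up-shifted by `markerLog2FC` in its members, so effects nest down the
#' tree; counts are negative binomial with per-node dispersion (which drives
#' within-class entropy) and log-normal library sizes.
#'
#' Defaults model a desk-scale bulk RNA-seq cohort: 500-gene panel, two-level
#' 4 x 3 hierarchy, 40 samples per leaf, 25 markers per node, strong lineage
#' and moderate subtype marker shifts (log2 fold-changes 3 and 0.8), NB
#' dispersion 0.15 (typical bulk overdispersion) and 1e6 mean library size
#' over the panel.
#'
#' @param depth tree depth (levels below the root).
#' @param branching integer vector of length `depth`: children per node at
#'   each level.
#' @param samplesPerLeaf samples drawn for every leaf class.
#' @param nGenes total gene panel size.
#' @param markersPerNode marker genes owned by each non-root node.
#' @param markerLog2FC log2 fold-change applied to a node's markers in its
#'   members; a single value, or one value per level (recycled), so that
#'   lineage-level contrasts can dominate subtype-level ones as they do in
#'   real cohorts (default c(3, 0.8): ~8-fold lineage markers, ~1.7-fold
#'   subtype markers).
#' @param dispersion negative-binomial dispersion (1/size): a single value,
#'   or a named vector keyed by node code for class-specific dispersion
#'   (unnamed entries fall back to `dispersion[["default"]]` or the first
#'   value).
#' @param librarySizeMean mean total counts per sample.
#' @param librarySizeSdLog log-scale sd of library sizes (default 0.3).
#' @param seed integer seed; the output is fully determined by it.
#' @return a `TreeSpec` list (class `"TreeSpec"`).
#' @export
TreeSpec <- function(depth = 2L, branching = c(4L, 3L), samplesPerLeaf = 40L,
                     nGenes = 500L, markersPerNode = 25L,
                     markerLog2FC = c(3, 0.8),
                     dispersion = 0.15, librarySizeMean = 1e6,
                     librarySizeSdLog = 0.3, seed = 1L) {
  depth <- as.integer(depth)
  branching <- as.integer(branching)
  if (length(branching) != depth) stop("branching length must equal depth")
  if (any(branching < 1L) || samplesPerLeaf < 1L || nGenes < 1L ||
      markersPerNode < 0L)
    stop("all counts must be positive")
  if (any(dispersion <= 0)) stop("dispersion must be > 0")
  structure(list(depth = depth, branching = branching,
                 samplesPerLeaf = as.integer(samplesPerLeaf),
                 nGenes = as.integer(nGenes),
                 markersPerNode = as.integer(markersPerNode),
                 markerLog2FC = rep_len(as.numeric(markerLog2FC), depth),
                 dispersion = dispersion,
                 librarySizeMean = as.numeric(librarySizeMean),
                 librarySizeSdLog = as.numeric(librarySizeSdLog),
                 seed = as.integer(seed)),
            class = "TreeSpec")
}

.specDispersion <- function(spec, code) {
  d <- spec$dispersion
  if (is.null(names(d))) return(d[[1L]])
  if (code %in% names(d)) return(d[[code]])
  if ("default" %in% names(d)) return(d[["default"]])
  d[[1L]]
}

#' Generate a synthetic hierarchical expression cohort
#'
#' @param spec a [TreeSpec()].
#' @return a list with elements `counts` (a [GeneMatrix-class] of integer
#'   counts, samples x genes), `tree` (the truth [ClassHierarchy-class]) and
#'   `labels` (named vector sample id -> leaf code).
#' @examples
#' cohort <- generateCohort(TreeSpec(depth = 1, branching = 3,
#'                                   samplesPerLeaf = 5, nGenes = 60,
#'                                   markersPerNode = 5, seed = 7))
#' cohort$tree
#' @export
generateCohort <- function(spec) {
  stopifnot(inherits(spec, "TreeSpec"))
  set.seed(spec$seed)

  # enumerate nodes breadth-first with deterministic codes T000 (root), T001...
  codes <- "T000"; parents <- NA_character_; levels <- 0L
  frontier <- "T000"; counter <- 1L
  for (lev in seq_len(spec$depth)) {
    newFrontier <- character(0)
    for (p in frontier) {
      for (b in seq_len(spec$branching[lev])) {
        code <- sprintf("T%03d", counter); counter <- counter + 1L
        codes <- c(codes, code); parents <- c(parents, p)
        levels <- c(levels, lev); newFrontier <- c(newFrontier, code)
      }
    }
    frontier <- newFrontier
  }
  leaves <- frontier
  nonRoot <- codes[-1L]
  needed <- length(nonRoot) * spec$markersPerNode
  if (needed > spec$nGenes)
    stop(sprintf("marker blocks need %d genes but the panel has %d",
                 needed, spec$nGenes))

  genes <- sprintf("g%04d", seq_len(spec$nGenes))
  markers <- list()
  if (spec$markersPerNode > 0L) {
    for (i in seq_along(nonRoot))
      markers[[nonRoot[i]]] <-
        genes[seq.int((i - 1L) * spec$markersPerNode + 1L,
                      i * spec$markersPerNode)]
  }

  # baseline expression propensities: log-normal, heavy-ish tail
  baseline <- stats::rlnorm(spec$nGenes, meanlog = 0, sdlog = 1)

  sampleIdsByLeaf <- list(); idx <- 0L
  for (lf in leaves) {
    sampleIdsByLeaf[[lf]] <- sprintf("s%04d", idx + seq_len(spec$samplesPerLeaf))
    idx <- idx + spec$samplesPerLeaf
  }
  allSamples <- unlist(sampleIdsByLeaf, use.names = FALSE)

  ancOf <- function(code) {
    out <- character(0)
    while (!is.na(parents[match(code, codes)])) {
      code <- parents[match(code, codes)]
      out <- c(out, code)
    }
    out
  }

  counts <- matrix(0L, nrow = length(allSamples), ncol = spec$nGenes,
                   dimnames = list(allSamples, genes))
  for (lf in leaves) {
    active <- setdiff(c(lf, ancOf(lf)), "T000")
    prop <- baseline
    for (nd in active) {
      gi <- match(markers[[nd]], genes)
      lfc <- spec$markerLog2FC[levels[match(nd, codes)]]
      prop[gi] <- prop[gi] * 2^lfc
    }
    prop <- prop / sum(prop)
    disp <- .specDispersion(spec, lf)
    for (sid in sampleIdsByLeaf[[lf]]) {
      lib <- stats::rlnorm(1, meanlog = log(spec$librarySizeMean) -
                              spec$librarySizeSdLog^2 / 2,
                           sdlog = spec$librarySizeSdLog)
      mu <- prop * lib
      counts[sid, ] <- stats::rnbinom(spec$nGenes, mu = mu, size = 1 / disp)
    }
  }

  members <- lapply(codes, function(cd) {
    below <- codes[vapply(codes, function(k) cd %in% c(k, ancOf(k)), logical(1))]
    unlist(sampleIdsByLeaf[intersect(leaves, below)], use.names = FALSE) %||% character(0)
  })
  tree <- makeHierarchy(codes, parents, members)
  labels <- setNames(rep(leaves, vapply(sampleIdsByLeaf[leaves], length, integer(1))),
                     unlist(sampleIdsByLeaf[leaves], use.names = FALSE))
  list(counts = GeneMatrix(counts,
                           metadata = list(scale = "counts", seed = spec$seed,
                                           markers = markers)),
       tree = tree, labels = labels)
}

#' Convert a count matrix to the log2 TPM-like analysis scale
#'
#' Counts are scaled within each sample to a fixed total (gene lengths taken
#' as 1, so this is a TPM-style within-sample normalisation) and
#' log2(x + 1)-transformed.
#'
#' @param gm a [GeneMatrix-class] of counts.
#' @param total target per-sample total (default 1e6).
#' @return a [GeneMatrix-class] on the log2 scale
#'   (`metaInfo(.)$scale == "log2tpm"`).
#' @export
normalizeCounts <- function(gm, total = 1e6) {
  v <- exprValues(gm)
  libs <- rowSums(v)
  if (any(libs == 0)) stop("sample(s) with zero total counts")
  out <- log2(v / libs * total + 1)
  GeneMatrix(out, metadata = c(metaInfo(gm)[setdiff(names(metaInfo(gm)), "scale")],
                               list(scale = "log2tpm")))
}

#' Mix two expression vectors on the linear scale
#'
#' Convex combination `alpha * a + (1 - alpha) * b`, emulating the admixture
#' of distinct cell populations within one sample (tumor mixtures, normal
#' contamination).
#'
#' @param a,b named numeric vectors over the same gene panel.
#' @param alpha mixing weight of `a`, in [0, 1].
#' @return the mixed vector, on `a`'s gene order.
#' @export
mixSamples <- function(a, b, alpha) {
  assertScalarNumber(alpha, "alpha", 0, 1)
  if (is.null(names(a)) || !setequal(names(a), names(b)))
    stop("mismatched gene panels")
  alpha * a + (1 - alpha) * b[names(a)]
}

#' Binomially thin a count matrix
#'
#' Every count is replaced by a Binomial(count, keepFraction) draw — the
#' count-level surrogate for shallower sequencing.
#'
#' @param gm a [GeneMatrix-class] of non-negative integer counts.
#' @param keepFraction keep probability in (0, 1].
#' @param seed integer seed.
#' @return the thinned [GeneMatrix-class].
#' @export
thinCounts <- function(gm, keepFraction, seed = 1L) {
  assertScalarNumber(keepFraction, "keepFraction", 1e-12, 1)
  v <- exprValues(gm)
  if (any(v < 0)) stop("negative counts")
  if (any(v != round(v))) stop("counts required")
  if (keepFraction == 1) return(gm)
  set.seed(seed)
  out <- matrix(stats::rbinom(length(v), size = as.integer(v), prob = keepFraction),
                nrow = nrow(v), dimnames = dimnames(v))
  GeneMatrix(out, metadata = c(metaInfo(gm),
                               list(thinned = keepFraction, thinSeed = seed)))
}
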