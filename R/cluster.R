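# Scale-adaptive recursive clustering: per-level grid search over
# low-variance feature removal, nonlinear embedding neighbourhood size and
# density-clustering distance, scored by the mean silhouette in embedded
# space; depth-first hierarchy construction with stop and prune rules.

#' Embed samples into a low-dimensional space
#'
#' Default is a seeded UMAP (single-threaded for reproducibility); `"pca"`
#' gives a deterministic linear fallback used by fast tests and degenerate
#' inputs. Coordinates are rescaled to unit root-mean-square so one density
#' (eps) grid is meaningful at every recursion level; the silhouette
#' objective is invariant to this uniform rescaling.
#'
#' @param x numeric matrix, samples x features.
#' @param dims target dimensionality.
#' @param neighbors neighbourhood size (UMAP only).
#' @param method `"umap"` or `"pca"`.
#' @param seed integer seed.
#' @return samples x dims coordinate matrix (unit RMS).
#' @export
embedSamples <- function(x, dims = 12L, neighbors = 15L,
                         method = c("umap", "pca"), seed = 1L) {
  method <- match.arg(method)
  n <- nrow(x)
  dims <- min(as.integer(dims), n - 2L, ncol(x))
  if (dims < 2L) stop("too few samples/features to embed")
  emb <- if (method == "umap") {
    nb <- max(2L, min(as.integer(neighbors), n - 1L))
    set.seed(seed)
    tryCatch(
      suppressWarnings(uwot::umap(x, n_neighbors = nb, n_components = dims,
                                  n_threads = 1, n_sgd_threads = 1,
                                  verbose = FALSE)),
      error = function(e) .pcaEmbed(x, dims))
  } else .pcaEmbed(x, dims)
  rms <- sqrt(mean(emb^2))
  if (rms > 0) emb <- emb / rms
  rownames(emb) <- rownames(x)
  emb
}

.pcaEmbed <- function(x, dims) {
  keep <- apply(x, 2L, stats::sd) > 0
  p <- stats::prcomp(x[, keep, drop = FALSE], center = TRUE, scale. = FALSE)
  p$x[, seq_len(min(dims, ncol(p$x))), drop = FALSE]
}

# Classic DBSCAN on a coordinate matrix; labels 1..k, -1 = noise.
# O(n^2) with an explicit distance matrix; deterministic over row order.
.dbscan <- function(x, eps, minPts = 5L) {
  n <- nrow(x)
  D <- as.matrix(stats::dist(x))
  neigh <- lapply(seq_len(n), function(i) which(D[i, ] <= eps))
  core <- lengths(neigh) >= minPts
  labels <- integer(n)  # 0 = unassigned
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !core[i]) next
    cl <- cl + 1L
    labels[i] <- cl
    queue <- neigh[[i]]
    while (length(queue)) {
      j <- queue[1L]; queue <- queue[-1L]
      if (labels[j] != 0L) next
      labels[j] <- cl
      if (core[j]) queue <- c(queue, neigh[[j]])
    }
  }
  labels[labels == 0L] <- -1L
  labels
}

# Mean silhouette width over non-noise points; NA when undefined.
.silhouetteScore <- function(emb, labels) {
  mask <- labels > 0
  k <- length(unique(labels[mask]))
  if (k < 2L || sum(mask) <= k) return(NA_real_)
  sil <- cluster::silhouette(labels[mask], stats::dist(emb[mask, , drop = FALSE]))
  mean(sil[, "sil_width"])
}

#' Optimise one clustering level over a parameter grid
#'
#' For every combination of feature-removal cutoff, embedding neighbourhood
#' and density parameter: the stated fraction of lowest-variance features is
#' removed, the samples are embedded ([embedSamples()]), density clustering
#' is run at the given eps, and the partition is scored by the mean
#' silhouette of the non-noise points in embedded space. The best-scoring
#' combination is returned; the level is accepted only when that best
#' silhouette is >= `minSilhouette` (default 0) with at least two clusters —
#' otherwise the node under scrutiny is not split.
#'
#' @param gm a [GeneMatrix-class] (the node's samples).
#' @param grid a [SearchGrid()].
#' @param seed integer seed (controls the embedding).
#' @param embedMethod `"umap"` (default) or `"pca"`.
#' @param minSilhouette acceptance threshold on the best silhouette.
#' @return a list (`ClusterOutcome`): `labels` (named integer vector, -1 =
#'   noise), `silhouette`, `chosenParams`, `accepted`, `reason`, `searchLog`
#'   (one row per grid combination).
#' @export
optimizeLevel <- function(gm, grid, seed = 1L, embedMethod = c("umap", "pca"),
                          minSilhouette = 0) {
  embedMethod <- match.arg(embedMethod)
  stopifnot(is(grid, "SearchGrid"))
  n <- nSamples(gm)
  noLabels <- setNames(rep(-1L, n), sampleIDs(gm))
  if (n <= grid@targetDims)
    return(list(labels = noLabels, silhouette = NA_real_,
                chosenParams = NULL, accepted = FALSE,
                reason = "degenerate: no more samples than target dimensions",
                searchLog = NULL))
  v <- exprValues(gm)
  vars <- apply(v, 2L, stats::var)
  runs <- list(); best <- NULL; combo <- 0L
  for (fc in grid@filterCutoffs) {
    nKeep <- max(2L, ceiling((1 - fc) * ncol(v)))
    keep <- order(-vars, colnames(v))[seq_len(nKeep)]
    xf <- v[, keep, drop = FALSE]
    for (nb in grid@neighborCounts) {
      combo <- combo + 1L
      emb <- embedSamples(xf, dims = grid@targetDims, neighbors = nb,
                          method = embedMethod, seed = deriveSeed(seed, combo))
      for (eps in grid@densityParams) {
        labels <- .dbscan(emb, eps, grid@minPts)
        k <- length(unique(labels[labels > 0]))
        sil <- .silhouetteScore(emb, labels)
        runs[[length(runs) + 1L]] <- data.frame(
          filter_cutoff = fc, neighbors = nb, density_param = eps,
          n_clusters = k, silhouette = sil)
        if (!is.na(sil) && k >= 2L && (is.null(best) || sil > best$silhouette)) {
          best <- list(labels = setNames(labels, sampleIDs(gm)),
                       silhouette = sil,
                       chosenParams = list(filterCutoff = fc, neighbors = nb,
                                           densityParam = eps))
        }
      }
    }
  }
  searchLog <- do.call(rbind, runs)
  if (is.null(best))
    return(list(labels = noLabels, silhouette = NA_real_, chosenParams = NULL,
                accepted = FALSE, reason = "no multi-cluster partition found",
                searchLog = searchLog))
  accepted <- best$silhouette >= minSilhouette
  c(best, list(accepted = accepted,
               reason = if (accepted) "accepted"
                        else "best silhouette below threshold",
               searchLog = searchLog))
}

#' Recursive top-down clustering into a class hierarchy
#'
#' Depth-first: a node with fewer than `minSplit` members is a leaf;
#' otherwise [optimizeLevel()] runs on its members and, when the level is
#' accepted, one child is created per cluster. Children with fewer than
#' `minKeep` members are pruned (their samples stay with the parent, as do
#' density-noise samples). Node codes are the branch prefix plus a
#' zero-padded creation index, assigned deterministically.
#'
#' @param gm a [GeneMatrix-class] (preprocessed cohort).
#' @param grid a [SearchGrid()].
#' @param minSplit population cutoff that stops the search (default 25).
#' @param minKeep smallest admissible child (default 10).
#' @param seed integer seed.
#' @param prefix node-code prefix (default "T").
#' @param embedMethod,minSilhouette passed to [optimizeLevel()].
#' @return a [ClassHierarchy-class].
#' @export
recursiveCluster <- function(gm, grid, minSplit = 25L, minKeep = 10L,
                             seed = 1L, prefix = "T",
                             embedMethod = c("umap", "pca"),
                             minSilhouette = 0) {
  embedMethod <- match.arg(embedMethod)
  if (minSplit < 2L) stop("minSplit must be >= 2")
  env <- new.env(parent = emptyenv())
  env$codes <- character(0); env$parents <- character(0)
  env$members <- list(); env$counter <- 0L
  newNode <- function(parent, ids) {
    code <- sprintf("%s%03d", prefix, env$counter)
    env$counter <- env$counter + 1L
    env$codes <- c(env$codes, code)
    env$parents <- c(env$parents, parent)
    env$members[[code]] <- ids
    code
  }
  recurse <- function(code) {
    force(code)  # code may be a just-created node; force before touching env
    ids <- env$members[[code]]
    if (length(ids) < minSplit) return(invisible(NULL))
    out <- optimizeLevel(gm[ids, ], grid, seed = deriveSeed(seed, env$counter),
                         embedMethod = embedMethod,
                         minSilhouette = minSilhouette)
    txMessage(sprintf("node %s (n=%d): %s (silhouette %.3f)", code,
                      length(ids), out$reason, out$silhouette %||% NA))
    if (!isTRUE(out$accepted)) return(invisible(NULL))
    labs <- out$labels
    for (cl in sort(unique(labs[labs > 0]))) {
      ids_k <- names(labs)[labs == cl]
      if (length(ids_k) < minKeep) next  # pruned; samples stay with parent
      recurse(newNode(code, ids_k))
    }
    invisible(NULL)
  }
  recurse(newNode(NA_character_, sampleIDs(gm)))
  makeHierarchy(env$codes, env$parents, env$members[env$codes])
}

#' Build a multi-cohort atlas with separate first-stage branches
#'
#' Each cohort (e.g. tumor and normal) is clustered independently with
#' [recursiveCluster()]; the resulting trees are attached as branches under
#' a synthetic global root, so cohorts are never mixed at the first stage.
#'
#' @param cohorts named list of [GeneMatrix-class] objects with disjoint
#'   sample ids; names become the branch code prefixes.
#' @param grid a [SearchGrid()].
#' @param seed integer seed.
#' @param rootCode code of the synthetic global root (default "ROOT").
#' @param ... passed to [recursiveCluster()].
#' @return a [ClassHierarchy-class].
#' @export
buildAtlas <- function(cohorts, grid, seed = 1L, rootCode = "ROOT", ...) {
  if (is.null(names(cohorts)) || anyDuplicated(names(cohorts)))
    stop("cohorts must be uniquely named")
  if (any(vapply(cohorts, nSamples, integer(1)) == 0L))
    stop("empty cohort")
  ids <- unlist(lapply(cohorts, sampleIDs), use.names = FALSE)
  if (anyDuplicated(ids)) stop("overlapping sample ids across cohorts")
  codes <- rootCode; parents <- NA_character_
  members <- list(ids); names(members) <- rootCode
  for (i in seq_along(cohorts)) {
    sub <- recursiveCluster(cohorts[[i]], grid,
                            seed = deriveSeed(seed, i), prefix = names(cohorts)[i],
                            ...)
    codes <- c(codes, nodeCodes(sub))
    parents <- c(parents, ifelse(is.na(vapply(sub@nodes, `[[`, character(1), "parent")),
                                 rootCode,
                                 vapply(sub@nodes, `[[`, character(1), "parent")))
    members <- c(members, lapply(sub@nodes, `[[`, "members"))
  }
  makeHierarchy(codes, parents, members[codes])
}
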