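# Hierarchical multiclass-multilabel classifier: architecture search by
# cross-validated micro-F1, ensemble training (unweighted mean of three),
# parent-child probability consistency enforcement, adapted-Youden
# piecewise-linear recalibration, prediction reports and the count-thinning
# depth-robustness benchmark.

.descendants <- function(tree, code) {
  kids <- nodeChildren(tree, code)
  if (!length(kids)) return(character(0))
  c(kids, unlist(lapply(kids, .descendants, tree = tree)))
}

# Stratified fold assignment by deepest class; classes too small to cover
# every fold are merged into their parent stratum (logged via message).
.foldAssignment <- function(strata, folds, seed, tree = NULL) {
  set.seed(seed)
  strata <- as.character(strata)
  if (!is.null(tree)) {
    tab <- table(strata)
    small <- names(tab)[tab < folds]
    merged <- character(0)
    while (length(small)) {
      for (cl in small) {
        up <- if (cl %in% nodeCodes(tree)) nodeParent(tree, cl) else NA
        strata[strata == cl] <- if (is.na(up)) cl else up
        merged <- c(merged, cl)
        if (is.na(up)) break
      }
      tab <- table(strata)
      small <- setdiff(names(tab)[tab < folds], rootCode(tree))
      if (!length(small) || all(strata %in% rootCode(tree))) break
    }
    if (length(merged))
      message(length(unique(merged)),
              " class(es) too small to stratify; merged into parent for CV")
  }
  fold <- integer(length(strata))
  for (cl in unique(strata)) {
    idx <- sample(which(strata == cl))
    fold[idx] <- rep_len(seq_len(folds), length(idx))
  }
  fold
}

.fitLogisticMember <- function(X, Y, seed, bagFraction = 0.8, lambda = 0.01) {
  set.seed(seed)
  idx <- sort(sample.int(nrow(X), max(2L, round(bagFraction * nrow(X)))))
  Xb <- X[idx, , drop = FALSE]; Yb <- Y[idx, , drop = FALSE]
  fits <- vector("list", ncol(Y)); names(fits) <- colnames(Y)
  const <- setNames(rep(NA_real_, ncol(Y)), colnames(Y))
  for (j in seq_len(ncol(Y))) {
    y <- Yb[, j]
    if (length(unique(y)) < 2L) {
      const[j] <- min(max(mean(y), 1e-6), 1 - 1e-6)
    } else {
      fits[[j]] <- glmnet::glmnet(Xb, y, family = "binomial", alpha = 0,
                                  lambda = lambda, standardize = FALSE)
    }
  }
  structure(list(fits = fits, const = const, backbone = "logistic"),
            class = "txatlasMember")
}

.memberPredict <- function(member, X) {
  if (member$backbone == "cnn") return(.nnPredict(member, X))
  out <- matrix(NA_real_, nrow(X), length(member$const),
                dimnames = list(rownames(X), names(member$const)))
  for (j in seq_along(member$const)) {
    out[, j] <- if (is.na(member$const[j]))
      as.vector(stats::predict(member$fits[[j]], newx = X, type = "response"))
    else member$const[j]
  }
  out
}

.trainMember <- function(X, Y, backbone, spec, epochs, seed, ...) {
  if (backbone == "logistic") .fitLogisticMember(X, Y, seed = seed, ...)
  else .nnTrain(X, Y, spec, epochs = epochs, seed = seed, ...)
}

#' Search the classifier architecture space
#'
#' Candidate architectures are sampled from the supplied value ranges
#' (seeded) and each is evaluated by stratified k-fold cross-validation
#' repeated over randomised rounds (default 5 x 5-fold), training with early
#' stopping (patience 3) and scoring the held-out folds. Candidates are
#' ranked by mean micro-F1; mean macro-F1 and macro-AUCPR are retained as
#' secondary rankings.
#'
#' @param gm training [GeneMatrix-class] (already conditioned: ordered,
#'   0-1 scaled).
#' @param labels binary label matrix from [multiHotLabels()].
#' @param space named list of candidate values for `convLayers`, `filters`,
#'   `kernelSize`, `denseLayers`, `firstDenseSize`, `dropout`.
#' @param budget number of candidate architectures (>= 1).
#' @param seed integer seed (sampling and fold assignment).
#' @param rounds randomised CV rounds (default 5).
#' @param folds folds per round (default 5).
#' @param strata optional named vector sample id -> deepest class for
#'   stratification.
#' @param tree optional [ClassHierarchy-class] used to merge unstratifiable
#'   classes into their parents.
#' @param backbone `"cnn"` (default) or `"logistic"` (fast, ignores the
#'   architecture fields).
#' @param epochs training epochs per fold (cnn backbone).
#' @return list with `ranking` (data.frame, best first) and `specs` (the
#'   sampled [ArchitectureSpec-class] objects, ranking order).
#' @export
searchArchitectures <- function(gm, labels, space = list(), budget = 5L,
                                seed = 1L, rounds = 5L, folds = 5L,
                                strata = NULL, tree = NULL,
                                backbone = c("cnn", "logistic"),
                                epochs = 20L) {
  backbone <- match.arg(backbone)
  if (budget < 1L) stop("budget must be >= 1")
  defaults <- list(convLayers = 1:2, filters = c(2L, 4L, 8L),
                   kernelSize = c(3L, 5L, 9L), denseLayers = 1:2,
                   firstDenseSize = c(16L, 32L, 64L), dropout = c(0, 0.2, 0.4))
  space <- utils::modifyList(defaults, space)
  set.seed(deriveSeed(seed, 3L))
  specs <- lapply(seq_len(budget), function(i)
    ArchitectureSpec(
      convLayers = sample(space$convLayers, 1L),
      filters = sample(space$filters, 1L),
      kernelSize = sample(space$kernelSize, 1L),
      denseLayers = sample(space$denseLayers, 1L),
      firstDenseSize = sample(space$firstDenseSize, 1L),
      dropout = sample(space$dropout, 1L)))
  X <- exprValues(gm)
  strat <- if (is.null(strata)) rep("all", nrow(X)) else strata[rownames(X)]
  res <- lapply(seq_along(specs), function(si) {
    mf1 <- c(); Mf1 <- c(); Mauc <- c()
    for (r in seq_len(rounds)) {
      fold <- .foldAssignment(strat, folds, deriveSeed(seed, 31L * r), tree)
      for (f in seq_len(folds)) {
        tr <- fold != f; te <- !tr
        member <- .trainMember(X[tr, , drop = FALSE], labels[tr, , drop = FALSE],
                               backbone, specs[[si]], epochs,
                               seed = deriveSeed(seed, 1000L * si + 10L * r + f))
        p <- .memberPredict(member, X[te, , drop = FALSE])
        sc <- multilabelScores(labels[te, , drop = FALSE], p >= 0.5, scores = p)
        mf1 <- c(mf1, sc$aggregate["micro_F1"])
        Mf1 <- c(Mf1, sc$aggregate["macro_F1"])
        Mauc <- c(Mauc, sc$aggregate["macro_AUCPR"])
      }
    }
    c(micro_F1 = mean(mf1), macro_F1 = mean(Mf1), macro_AUCPR = mean(Mauc))
  })
  tab <- do.call(rbind, res)
  ord <- order(-tab[, "micro_F1"])
  ranking <- data.frame(candidate = ord, tab[ord, , drop = FALSE],
                        row.names = NULL)
  list(ranking = ranking, specs = specs[ord])
}

#' Train the classifier ensemble
#'
#' Inputs are conditioned once for all members (genes ordered by
#' correlation, values scaled to 0-1; both stored for prediction), labels
#' are the multilabel one-hot encoding, and each member is trained with
#' sigmoid outputs and binary cross-entropy (Adadelta, initial rate 0.001,
#' early stopping for the cnn backbone; seeded 80% bagging differentiates
#' logistic members). The ensemble output is the unweighted arithmetic mean
#' of the members.
#'
#' @param gm training [GeneMatrix-class] (log2 scale, unconditioned).
#' @param labels named vector sample id -> deepest class code.
#' @param tree the [ClassHierarchy-class] defining the label space.
#' @param specs list of [ArchitectureSpec-class] (top-k from the search);
#'   recycled over members.
#' @param nMembers ensemble size (default 3).
#' @param backbone `"cnn"` or `"logistic"`.
#' @param epochs cnn training epochs.
#' @param lr initial Adadelta learning rate (default 0.001).
#' @param seed integer seed.
#' @return a [TrainedEnsemble-class].
#' @export
trainEnsemble <- function(gm, labels, tree, specs = list(ArchitectureSpec()),
                          nMembers = 3L, backbone = c("cnn", "logistic"),
                          epochs = 50L, lr = 0.001, seed = 1L) {
  backbone <- match.arg(backbone)
  if (!length(specs)) stop("specs must be non-empty")
  geneOrder <- orderGenesByCorrelation(gm)
  scaled <- scaleUnitInterval(gm[, geneOrder])
  bounds <- attr(scaled, "bounds")
  X <- exprValues(scaled)
  Y <- multiHotLabels(tree, labels)[rownames(X), , drop = FALSE]
  members <- lapply(seq_len(nMembers), function(m) {
    spec <- specs[[((m - 1L) %% length(specs)) + 1L]]
    if (backbone == "cnn")
      .nnTrain(X, Y, spec, epochs = epochs, lr = lr,
               seed = deriveSeed(seed, 100L + m))
    else .fitLogisticMember(X, Y, seed = deriveSeed(seed, 100L + m))
  })
  new("TrainedEnsemble", members = members, geneOrder = geneOrder,
      scalingBounds = bounds, nodeCodes = colnames(Y),
      treeRef = .treeChecksum(tree),
      trainingLog = list(backbone = backbone, seed = seed, epochs = epochs,
                         lr = lr, nMembers = nMembers, specs = specs))
}

# Align a new matrix to the ensemble's gene space (missing genes imputed as
# zero, with a message), apply the stored order and scaling bounds.
.conditionInput <- function(ensemble, gm) {
  if (nSamples(gm) == 0L) stop("empty matrix")
  v <- exprValues(gm)
  missing <- setdiff(ensemble@geneOrder, colnames(v))
  if (length(missing)) {
    message(length(missing), " gene(s) missing from input; imputed as 0")
    v <- cbind(v, matrix(0, nrow(v), length(missing),
                         dimnames = list(rownames(v), missing)))
  }
  v <- v[, ensemble@geneOrder, drop = FALSE]
  scaled <- scaleUnitInterval(GeneMatrix(v), bounds = ensemble@scalingBounds)
  exprValues(scaled)
}

#' Raw ensemble scores for new samples
#'
#' @param ensemble a [TrainedEnsemble-class].
#' @param gm a [GeneMatrix-class] on the training scale.
#' @param member optional single member index (for member-level evaluation).
#' @return samples x nodes matrix of raw scores (unweighted member mean).
#' @export
ensembleScores <- function(ensemble, gm, member = NULL) {
  X <- .conditionInput(ensemble, gm)
  .ensembleRaw(ensemble, X, member)
}

.ensembleRaw <- function(ensemble, X, member = NULL) {
  out <- if (!is.null(member)) .memberPredict(ensemble@members[[member]], X)
  else {
    preds <- lapply(ensemble@members, function(m) .memberPredict(m, X))
    Reduce(`+`, preds) / length(preds)
  }
  dimnames(out) <- list(rownames(X), ensemble@nodeCodes)
  out
}

#' Enforce parent-child probability consistency
#'
#' Processing the deepest level first: whenever an offspring node carries a
#' higher probability than its parent, both are set to their mean, and
#' descendants of the parent exceeding the new value (the offspring's
#' siblings and their subtrees) are clipped to it. The correction is
#' propagated upward until no violation remains; the result satisfies
#' child <= parent on every edge and is a fixed point of the procedure.
#'
#' @param v named membership vector over the tree's non-root nodes (missing
#'   entries read as 0).
#' @param tree a [ClassHierarchy-class].
#' @return the corrected vector over the full label space.
#' @export
enforceHierarchy <- function(v, tree) {
  codes <- labelSpace(tree)
  out <- setNames(numeric(length(codes)), codes)
  out[intersect(names(v), codes)] <- v[intersect(names(v), codes)]
  lv <- vapply(codes, function(k) nodeLevel(tree, k), integer(1))
  root <- rootCode(tree)
  ordered <- codes[order(-lv, codes)]
  repeat {
    changed <- FALSE
    for (code in ordered) {
      p <- nodeParent(tree, code)
      pv <- if (p == root) 1 else out[p]
      if (out[code] > pv + 1e-12) {
        m <- (out[code] + pv) / 2
        out[code] <- m
        if (p != root) out[p] <- m
        for (d in .descendants(tree, p)) if (out[d] > m) out[d] <- m
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  out
}

#' Fit per-node calibration cutoffs (adapted Youden J)
#'
#' For every node the candidate cutoffs are the midpoints between
#' consecutive unique sorted scores; the cutoff maximising precision +
#' recall (positives = scores strictly above the cutoff) is chosen, ties
#' resolved toward the smallest qualifying cutoff. Nodes without both a
#' positive and a negative example, or with constant scores, fall back to
#' 0.5 with a warning.
#'
#' @param rawScores samples x nodes score matrix (post-enforcement).
#' @param targets binary matrix of the same shape.
#' @return named numeric vector of cutoffs in (0, 1) (a `CalibrationMap`).
#' @export
fitCalibration <- function(rawScores, targets) {
  stopifnot(all(dim(rawScores) == dim(targets)))
  nodes <- colnames(rawScores)
  map <- setNames(rep(0.5, length(nodes)), nodes)
  fallback <- character(0)
  for (j in seq_along(nodes)) {
    s <- rawScores[, j]; y <- targets[, j] > 0
    u <- sort(unique(s))
    if (!any(y) || all(y) || length(u) < 2L) {
      fallback <- c(fallback, nodes[j]); next
    }
    cand <- (u[-1] + u[-length(u)]) / 2
    J <- vapply(cand, function(cc) {
      pred <- s > cc
      tp <- sum(pred & y)
      prec <- if (any(pred)) tp / sum(pred) else 0
      rec <- tp / sum(y)
      prec + rec
    }, numeric(1))
    best <- cand[which(J >= max(J) - 1e-12)]
    map[j] <- min(best)
  }
  if (length(fallback))
    warning("fallback cutoff 0.5 for node(s): ",
            paste(fallback, collapse = ", "))
  pmin(pmax(map, 1e-6), 1 - 1e-6)
}

#' Piecewise-linear probability recalibration
#'
#' Maps each node's score so that its binary cutoff c lands exactly at 0.5:
#' s <= c -> s * 0.5 / c; s > c -> 0.5 + (s - c) * 0.5 / (1 - c). Monotone
#' and continuous per node, preserving 0 and 1; c = 0.5 is the identity.
#' Thresholding the calibrated score at 0.5 is exactly equivalent to
#' thresholding the raw score at c.
#'
#' @param v named membership vector, or a samples x nodes matrix.
#' @param map named cutoff vector from [fitCalibration()]; must cover the
#'   nodes of `v`, with every cutoff strictly inside (0, 1).
#' @return the recalibrated vector or matrix.
#' @export
applyCalibration <- function(v, map) {
  if (any(map <= 0 | map >= 1)) stop("cutoffs must lie strictly inside (0, 1)")
  calib1 <- function(s, cc) ifelse(s <= cc, s * 0.5 / cc,
                                   0.5 + (s - cc) * 0.5 / (1 - cc))
  if (is.matrix(v)) {
    if (!all(colnames(v) %in% names(map))) stop("map does not cover all nodes")
    out <- v
    for (j in colnames(v)) out[, j] <- calib1(v[, j], map[[j]])
    return(out)
  }
  if (!all(names(v) %in% names(map))) stop("map does not cover all nodes")
  setNames(calib1(v, map[names(v)]), names(v))
}

#' Fit calibration cutoffs for an ensemble
#'
#' Out-of-fold by default: members are refit on each training split with the
#' ensemble's own settings, held-out samples are scored and
#' consistency-enforced, and [fitCalibration()] runs on the pooled
#' out-of-fold scores — avoiding the optimistic cutoffs of training-set
#' scores. `"resubstitution"` scores the given ensemble on its own training
#' data instead (cheaper for expensive backbones).
#'
#' @param ensemble a [TrainedEnsemble-class].
#' @param gm,labels,tree the training cohort as given to [trainEnsemble()].
#' @param folds CV folds (default 5).
#' @param seed integer seed.
#' @param method `"oof"` or `"resubstitution"`.
#' @return a named cutoff vector (`CalibrationMap`).
#' @export
calibrateEnsemble <- function(ensemble, gm, labels, tree, folds = 5L,
                              seed = 1L, method = c("oof", "resubstitution")) {
  method <- match.arg(method)
  Y <- multiHotLabels(tree, labels)[sampleIDs(gm), , drop = FALSE]
  if (method == "resubstitution") {
    raw <- ensembleScores(ensemble, gm)
  } else {
    lg <- ensemble@trainingLog
    fold <- .foldAssignment(labels[sampleIDs(gm)], folds,
                            deriveSeed(seed, 7L), tree)
    raw <- matrix(NA_real_, nSamples(gm), ncol(Y),
                  dimnames = list(sampleIDs(gm), colnames(Y)))
    for (f in seq_len(folds)) {
      tr <- sampleIDs(gm)[fold != f]; te <- sampleIDs(gm)[fold == f]
      if (!length(te)) next
      ens_f <- trainEnsemble(gm[tr, ], labels[tr], tree,
                             specs = lg$specs, nMembers = lg$nMembers,
                             backbone = lg$backbone, epochs = lg$epochs,
                             lr = lg$lr, seed = deriveSeed(seed, 50L + f))
      raw[te, ] <- ensembleScores(ens_f, gm[te, ])
    }
  }
  enforced <- t(apply(raw, 1L, enforceHierarchy, tree = tree))
  colnames(enforced) <- colnames(raw)
  suppressWarnings(fitCalibration(enforced, Y))
}

#' Predict new samples and build the report
#'
#' Pipeline: raw ensemble mean -> [enforceHierarchy()] ->
#' [applyCalibration()] -> report. The majority path follows the
#' highest-probability child at each level while its calibrated probability
#' stays >= 0.5. Flags: `lowConfidence` (no first-level class reaches 0.5),
#' `multiClass` (a second first-level class exceeds `secondaryThreshold`),
#' `normalDominant` (the designated normal branch outweighs every tumor
#' branch at the first level; NA when `normalCode` is not given).
#' Samples whose conditioned input is identically zero carry no membership
#' evidence: their scores are reported as 0, which flags them low-confidence
#' with a path that stops at the root.
#'
#' @param ensemble a [TrainedEnsemble-class].
#' @param gm a [GeneMatrix-class] on the training scale.
#' @param tree the [ClassHierarchy-class] of the label space.
#' @param map optional calibration cutoffs (skipped when NULL).
#' @param secondaryThreshold secondary-class flag threshold (default 0.02).
#' @param normalCode optional first-level code of the normal branch.
#' @return a [PredictionReport-class].
#' @export
predictSamples <- function(ensemble, gm, tree, map = NULL,
                           secondaryThreshold = 0.02, normalCode = NULL) {
  X <- .conditionInput(ensemble, gm)
  raw <- .ensembleRaw(ensemble, X)
  # an all-zero conditioned profile carries no membership evidence: report
  # zero scores rather than intercept-driven artifacts
  degenerate <- rowSums(X != 0) == 0L
  raw[degenerate, ] <- 0
  codes <- colnames(raw)
  consistent <- t(apply(raw, 1L, enforceHierarchy, tree = tree))
  colnames(consistent) <- codes
  calibrated <- if (is.null(map)) consistent
                else applyCalibration(consistent, map)
  root <- rootCode(tree)
  level1 <- intersect(codes, nodeChildren(tree, root))
  paths <- character(nrow(raw))
  for (i in seq_len(nrow(raw))) {
    cur <- root; path <- root
    repeat {
      kids <- intersect(nodeChildren(tree, cur), codes)
      if (!length(kids)) break
      best <- kids[which.max(calibrated[i, kids])]
      if (calibrated[i, best] < 0.5) break
      path <- c(path, best); cur <- best
    }
    paths[i] <- paste(path, collapse = ">")
  }
  l1 <- calibrated[, level1, drop = FALSE]
  top2 <- apply(l1, 1L, function(x) sort(x, decreasing = TRUE)[min(2L, length(x))])
  flags <- data.frame(
    lowConfidence = apply(l1, 1L, max) < 0.5,
    multiClass = length(level1) > 1L & top2 > secondaryThreshold,
    normalDominant = if (is.null(normalCode)) NA else
      l1[, normalCode] > apply(l1[, setdiff(level1, normalCode), drop = FALSE],
                               1L, max),
    row.names = rownames(raw))
  new("PredictionReport", calibrated = calibrated, consistent = consistent,
      raw = raw, majorityPath = paths, flags = flags)
}

#' Prediction robustness to sequencing depth (count thinning)
#'
#' Counts are binomially thinned at each fraction (several replicate
#' seeds), renormalised to the log2 analysis scale, predicted, and compared
#' to the full-depth prediction by the hierarchical similarity H of the
#' output membership vectors.
#'
#' @param ensemble a [TrainedEnsemble-class] trained on the normalised
#'   scale.
#' @param countsGm a [GeneMatrix-class] of raw integer counts.
#' @param tree the [ClassHierarchy-class].
#' @param map optional calibration cutoffs.
#' @param fractions keep fractions in (0, 1].
#' @param seed integer seed.
#' @param replicates thinning replicates per fraction (default 5).
#' @return data.frame with columns `fraction`, `mean_H`, `sd_H`.
#' @export
depthRobustness <- function(ensemble, countsGm, tree, map = NULL,
                            fractions = c(1, 0.5, 0.1, 0.01), seed = 1L,
                            replicates = 5L) {
  if (any(fractions <= 0 | fractions > 1)) stop("fractions must lie in (0, 1]")
  w <- simgicWeights(tree)
  baseline <- predictSamples(ensemble, normalizeCounts(countsGm), tree, map)
  base <- baseline@calibrated
  res <- lapply(fractions, function(f) {
    hs <- vapply(seq_len(replicates), function(r) {
      thinned <- thinCounts(countsGm, f, seed = deriveSeed(seed, 997L * r + round(1e4 * f)))
      pred <- predictSamples(ensemble, normalizeCounts(thinned), tree, map)
      mean(vapply(seq_len(nrow(base)), function(i)
        hierarchicalSimilarity(base[i, ], pred@calibrated[i, ], w), numeric(1)))
    }, numeric(1))
    data.frame(fraction = f, mean_H = mean(hs), sd_H = stats::sd(hs))
  })
  do.call(rbind, res)
}
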