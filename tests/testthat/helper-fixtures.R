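# Shared fixtures, built in code and cached for the session.

.fix <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fix[[name]])) .fix[[name]] <- builder()
  .fix[[name]]
}

# Small two-level hand tree: R -> (A -> A1, A2; B), 8 samples.
toyTree <- function() {
  makeHierarchy(
    codes = c("R", "A", "B", "A1", "A2"),
    parents = c(NA, "R", "R", "A", "A"),
    members = list(paste0("s", 1:8), paste0("s", 1:4), paste0("s", 5:8),
                   paste0("s", 1:2), paste0("s", 3:4)))
}

# Tree realising the PaWS worked examples: root of 256 with 4 children of
# 64; three split 32/32 and one 48/16; 8 leaves in total.
pawsTree <- function() {
  ids <- sprintf("p%03d", 1:256)
  blocks <- split(ids, rep(1:8, each = 32))
  d1 <- c(blocks[[7]], blocks[[8]][1:16])
  d2 <- blocks[[8]][17:32]
  makeHierarchy(
    codes = c("R", "A", "B", "C", "D", "A1", "A2", "B1", "B2",
              "C1", "C2", "D1", "D2"),
    parents = c(NA, "R", "R", "R", "R", "A", "A", "B", "B", "C", "C", "D", "D"),
    members = list(ids,
                   c(blocks[[1]], blocks[[2]]), c(blocks[[3]], blocks[[4]]),
                   c(blocks[[5]], blocks[[6]]), c(blocks[[7]], blocks[[8]]),
                   blocks[[1]], blocks[[2]], blocks[[3]], blocks[[4]],
                   blocks[[5]], blocks[[6]], d1, d2))
}

# Random hierarchy with nested random membership, for property tests.
randomTree <- function(seed, nNodes = 10L, nSamples = 40L) {
  set.seed(seed)
  ids <- sprintf("r%03d", seq_len(nSamples))
  codes <- "N1"; parents <- NA_character_; members <- list(N1 = ids)
  for (k in 2:nNodes) {
    # pick a parent with enough members to carve a disjoint child from
    free <- vapply(codes, function(cd) {
      used <- unlist(members[codes[!is.na(parents) & parents == cd]])
      length(setdiff(members[[cd]], used))
    }, integer(1))
    cand <- codes[free >= 2L]
    if (!length(cand)) break
    p <- sample(cand, 1L)
    used <- unlist(members[codes[!is.na(parents) & parents == p]])
    pool <- setdiff(members[[p]], used)
    take <- sample(pool, sample(seq_len(max(1L, length(pool) - 1L)), 1L))
    code <- paste0("N", k)
    codes <- c(codes, code); parents <- c(parents, p)
    members[[code]] <- take
  }
  makeHierarchy(codes, parents, members[codes])
}

# Brute-force hierarchical similarity oracle: explicit loop over nodes.
bruteH <- function(v1, v2, w) {
  num <- 0; den <- 0
  for (n in names(w)) {
    a <- if (n %in% names(v1)) v1[[n]] else 0
    b <- if (n %in% names(v2)) v2[[n]] else 0
    num <- num + w[[n]] * min(a, b)
    den <- den + w[[n]] * max(a, b)
  }
  num / den
}

bruteEta <- function(truth, pred, w) {
  num <- 0; den <- 0
  for (n in names(w)) {
    a <- if (n %in% names(truth)) truth[[n]] else 0
    b <- if (n %in% names(pred)) pred[[n]] else 0
    num <- num + w[[n]] * min(a, b)
    den <- den + w[[n]] * a
  }
  num / den
}

# Direct-formula mean silhouette (independent of cluster::silhouette).
silhouetteOracle <- function(x, labels) {
  D <- as.matrix(dist(x))
  n <- nrow(x)
  mean(vapply(seq_len(n), function(i) {
    own <- labels == labels[i]
    a <- mean(D[i, own & seq_len(n) != i])
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(l)
      mean(D[i, labels == l]), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1)))
}

# Shared trained classifier cohort (8 leaves, 2 levels, 40 per leaf).
classifierFixture <- function() {
  fixture("clf", function() {
    co <- generateCohort(TreeSpec(depth = 2, branching = c(4L, 2L),
                                  samplesPerLeaf = 40, seed = 21))
    norm <- normalizeCounts(co$counts)
    ens <- trainEnsemble(norm, co$labels, co$tree, backbone = "logistic",
                         seed = 33)
    map <- suppressMessages(
      calibrateEnsemble(ens, norm, co$labels, co$tree, seed = 33))
    list(cohort = co, norm = norm, ensemble = ens, map = map)
  })
}
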