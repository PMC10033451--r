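# Deterministic PCA embedding is used for most unit tests; the UMAP default
# is exercised once for seeding behaviour. The planted-recovery benchmark on
# the full synthetic cohort lives in the acceptance suite.

blobCohort <- function(n1 = 100, n2 = 100, genes = 50, shift = 2, seed = 17) {
  set.seed(seed)
  v <- rbind(matrix(rnorm(n1 * genes), n1),
             matrix(rnorm(n2 * genes, mean = shift), n2))
  dimnames(v) <- list(sprintf("b%03d", seq_len(n1 + n2)),
                      sprintf("g%03d", seq_len(genes)))
  list(gm = GeneMatrix(v), labels = rep(1:2, c(n1, n2)))
}

test_that("two separated blobs are found with a high silhouette", {
  bc <- blobCohort()
  grid <- SearchGrid(filterCutoffs = 0, neighborCounts = 10L,
                     densityParams = c(2, 2.5))
  out <- optimizeLevel(bc$gm, grid, seed = 5, embedMethod = "pca")
  expect_true(out$accepted)
  expect_equal(length(unique(out$labels[out$labels > 0])), 2L)
  expect_gt(out$silhouette, 0.5)
  # the planted partition is recovered on the assigned points, with at
  # most a small density-noise fringe
  assigned <- out$labels > 0
  expect_lt(mean(!assigned), 0.1)
  expect_equal(adjustedMutualInformation(out$labels[assigned],
                                         bc$labels[assigned]), 1)
  # silhouette agrees with a direct-formula oracle on the same embedding
  emb <- embedSamples(exprValues(bc$gm), dims = grid@targetDims,
                      method = "pca")
  mask <- out$labels > 0
  expect_equal(out$silhouette,
               silhouetteOracle(emb[mask, , drop = FALSE], out$labels[mask]),
               tolerance = 1e-9)
  # chosen parameters attain the maximum recorded silhouette
  expect_equal(out$silhouette, max(out$searchLog$silhouette, na.rm = TRUE))
})

test_that("a single isotropic blob is not split", {
  set.seed(23)
  v <- matrix(rnorm(120 * 30), 120,
              dimnames = list(sprintf("x%03d", 1:120), sprintf("g%02d", 1:30)))
  out <- optimizeLevel(GeneMatrix(v), SearchGrid(filterCutoffs = 0,
                                                 neighborCounts = 10L),
                       seed = 3, embedMethod = "pca")
  expect_false(out$accepted)
})

test_that("degenerate inputs are rejected with a reason", {
  set.seed(1)
  v <- matrix(rnorm(10 * 20), 10,
              dimnames = list(paste0("s", 1:10), paste0("g", 1:20)))
  out <- optimizeLevel(GeneMatrix(v), SearchGrid(), seed = 1)
  expect_false(out$accepted)
  expect_match(out$reason, "degenerate")
})

test_that("population cutoff stops the search and small children are pruned", {
  # 24 separable samples: below the population cutoff of 25, never split
  bc <- blobCohort(n1 = 12, n2 = 12, seed = 29)
  tr <- recursiveCluster(bc$gm, SearchGrid(filterCutoffs = 0,
                                           neighborCounts = 5L,
                                           densityParams = c(2.5, 3)),
                         minSplit = 25, minKeep = 10, seed = 2,
                         embedMethod = "pca")
  expect_length(nodeCodes(tr), 1L)
  # 21 + 9 blobs: the 9-sample candidate child is pruned, its samples
  # remain members of the parent only
  bc2 <- blobCohort(n1 = 21, n2 = 9, seed = 31)
  tr2 <- recursiveCluster(bc2$gm, SearchGrid(filterCutoffs = 0,
                                             neighborCounts = 5L,
                                             densityParams = c(2.5, 3)),
                          minSplit = 25, minKeep = 10, seed = 2,
                          embedMethod = "pca")
  kids <- nodeChildren(tr2, rootCode(tr2))
  for (k in kids) expect_gte(length(nodeMembers(tr2, k)), 10L)
  covered <- unlist(lapply(kids, nodeMembers, tree = tr2))
  expect_lte(length(covered), 21L)
  expect_setequal(nodeMembers(tr2, rootCode(tr2)), sampleIDs(bc2$gm))
})

test_that("recursive clustering returns a valid, deterministic hierarchy", {
  co <- generateCohort(TreeSpec(depth = 1, branching = 3L,
                                samplesPerLeaf = 25, nGenes = 120,
                                markersPerNode = 12, markerLog2FC = 3,
                                seed = 37))
  norm <- normalizeCounts(co$counts)
  grid <- SearchGrid(filterCutoffs = c(0, 0.5), neighborCounts = 10L,
                     densityParams = c(2, 2.5))
  tr1 <- recursiveCluster(norm, grid, seed = 4, embedMethod = "pca")
  tr2 <- recursiveCluster(norm, grid, seed = 4, embedMethod = "pca")
  expect_identical(lapply(tr1@nodes, `[[`, "members"),
                   lapply(tr2@nodes, `[[`, "members"))
  expect_true(validObject(tr1))
  # sibling disjointness and child-subset are enforced by the class; check
  # the level-1 recovery of the planted classes
  found <- levelAssignment(tr1, 1L)
  expect_gte(adjustedMutualInformation(found, co$labels[names(found)]), 0.9)
})

test_that("UMAP embedding is reproducible under a fixed seed", {
  set.seed(41)
  v <- matrix(rnorm(60 * 30), 60,
              dimnames = list(paste0("u", 1:60), paste0("g", 1:30)))
  e1 <- embedSamples(v, dims = 5, neighbors = 10, method = "umap", seed = 11)
  e2 <- embedSamples(v, dims = 5, neighbors = 10, method = "umap", seed = 11)
  expect_equal(e1, e2, tolerance = 1e-12)
  expect_equal(sqrt(mean(e1^2)), 1, tolerance = 1e-9)  # unit-RMS rescaling
})

test_that("multi-cohort atlases keep cohorts as separate branches", {
  coA <- generateCohort(TreeSpec(depth = 1, branching = 2L,
                                 samplesPerLeaf = 30, nGenes = 150,
                                 markersPerNode = 15, markerLog2FC = 3,
                                 seed = 61))
  coB <- generateCohort(TreeSpec(depth = 1, branching = 2L,
                                 samplesPerLeaf = 30, nGenes = 150,
                                 markersPerNode = 15, markerLog2FC = 3,
                                 seed = 62))
  vB <- exprValues(coB$counts)
  rownames(vB) <- sub("^s", "n", rownames(vB))
  cohorts <- list(T = normalizeCounts(coA$counts),
                  N = normalizeCounts(GeneMatrix(vB)))
  atlas <- buildAtlas(cohorts, SearchGrid(filterCutoffs = 0,
                                          neighborCounts = 10L,
                                          densityParams = c(2, 2.5)),
                      seed = 4, embedMethod = "pca")
  kids <- nodeChildren(atlas, rootCode(atlas))
  expect_setequal(kids, c("T000", "N000"))
  # branch members partition the root
  expect_setequal(unlist(lapply(kids, nodeMembers, tree = atlas)),
                  nodeMembers(atlas, rootCode(atlas)))
  expect_error(buildAtlas(list(T = cohorts$T, N = cohorts$T),
                          SearchGrid(), seed = 1), "overlapping")
  empty <- GeneMatrix(matrix(numeric(0), 0, 3,
                             dimnames = list(NULL, c("g1", "g2", "g3"))))
  expect_error(buildAtlas(list(T = cohorts$T, E = empty), SearchGrid(),
                          seed = 1), "empty cohort")
  names(cohorts) <- NULL
  expect_error(buildAtlas(cohorts, SearchGrid(), seed = 1), "named")
})
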