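test_that("GeneMatrix enforces unique identifiers and finite values", {
  m <- matrix(1:6, 2, 3)
  gm <- GeneMatrix(m, c("s1", "s2"), c("g1", "g2", "g3"))
  expect_equal(nSamples(gm), 2L)
  expect_equal(geneIDs(gm), c("g1", "g2", "g3"))
  expect_error(GeneMatrix(m, c("s1", "s1"), c("g1", "g2", "g3")), "duplicate")
  bad <- m; bad[1] <- NA
  expect_error(GeneMatrix(bad, c("s1", "s2"), c("g1", "g2", "g3")), "finite")
  sub <- gm["s2", c("g1", "g3")]
  expect_s4_class(sub, "GeneMatrix")
  expect_equal(dim(exprValues(sub)), c(1L, 2L))
})

test_that("hierarchy construction validates tree invariants", {
  tr <- toyTree()
  expect_equal(rootCode(tr), "R")
  expect_setequal(leafCodes(tr), c("A1", "A2", "B"))
  expect_equal(nodeLevel(tr, "A1"), 2L)
  # two roots
  expect_error(makeHierarchy(c("a", "b"), c(NA, NA), list("x", "y")),
               "exactly one root")
  # child members not a subset of parent
  expect_error(makeHierarchy(c("a", "b"), c(NA, "a"),
                             list(c("x"), c("x", "z"))), "subset")
  # overlapping siblings
  expect_error(makeHierarchy(c("a", "b", "c"), c(NA, "a", "a"),
                             list(c("x", "y"), "x", c("x", "y"))),
               "disjoint")
  expect_error(makeHierarchy(c("a", "b"), c(NA, "zz"), list("x", "x")),
               "not in tree")
})

test_that("ancestors walks to the root, nearest first", {
  tr <- toyTree()
  expect_equal(ancestors(tr, "R"), character(0))
  expect_equal(ancestors(tr, "A1"), c("A", "R"))
  expect_equal(ancestors(tr, "B"), "R")
  expect_error(ancestors(tr, "nope"), "unknown node")
  # chain of length k yields k ancestors
  chain <- makeHierarchy(paste0("c", 1:5), c(NA, paste0("c", 1:4)),
                         rep(list("x"), 5))
  expect_length(ancestors(chain, "c5"), 4L)
})

test_that("class frequencies follow membership counts", {
  tr <- toyTree()
  p <- classFrequencies(tr)
  expect_identical(unname(p["R"]), 1)
  expect_identical(unname(p["A1"]), 0.25)
  # frequencies non-increasing from parent to child
  for (code in setdiff(nodeCodes(tr), "R"))
    expect_lte(p[code], p[nodeParent(tr, code)])
  # leaves partition the root: frequencies sum to 1
  expect_equal(sum(p[leafCodes(tr)]), 1)
  empty <- makeHierarchy("r", NA, list(character(0)))
  expect_error(classFrequencies(empty), "empty hierarchy")
})

test_that("multi-hot labels activate the node and its non-root ancestors", {
  tr <- toyTree()
  labs <- c(s1 = "A1", s5 = "B", s3 = "A")
  Y <- multiHotLabels(tr, labs)
  expect_equal(sum(Y["s1", ]), 2)                  # A1 + A, root excluded
  expect_equal(Y["s1", c("A", "A1")], c(A = 1L, A1 = 1L))
  expect_equal(sum(Y["s5", ]), 1)                  # depth-1 assignment
  expect_equal(sum(Y["s3", ]), 1)
  # sibling leaves share exactly their common non-root ancestors
  Y2 <- multiHotLabels(tr, c(x = "A1", y = "A2"))
  shared <- colnames(Y2)[Y2[1, ] == 1 & Y2[2, ] == 1]
  expect_equal(shared, "A")
  expect_error(multiHotLabels(tr, c(s1 = "Z9")), "Z9")
  # downward-closed rows: every active node's non-root ancestors are active
  for (i in seq_len(nrow(Y))) {
    on <- colnames(Y)[Y[i, ] == 1]
    for (k in on)
      expect_true(all(setdiff(ancestors(tr, k), "R") %in% on))
  }
})

test_that("matrix TSV round trip is exact in both orientations", {
  set.seed(8)
  gm <- GeneMatrix(matrix(rnorm(12) * 1e3, 3, 4,
                          dimnames = list(paste0("s", 1:3), paste0("g", 1:4))))
  for (orient in c("genes", "samples")) {
    path <- tempfile(fileext = ".tsv")
    writeGeneMatrix(gm, path, orientation = orient)
    back <- readGeneMatrix(path)
    expect_identical(sampleIDs(back), sampleIDs(gm))
    expect_identical(geneIDs(back), geneIDs(gm))
    expect_equal(exprValues(back), exprValues(gm), tolerance = 1e-12)
  }
  # gzip transparency
  gz <- tempfile(fileext = ".tsv.gz")
  writeGeneMatrix(gm, gz)
  expect_equal(exprValues(readGeneMatrix(gz)), exprValues(gm),
               tolerance = 1e-12)
})

test_that("hierarchy JSON round trip reproduces the tree", {
  tr <- toyTree()
  path <- tempfile(fileext = ".json")
  writeHierarchy(tr, path)
  back <- readHierarchy(path)
  expect_identical(nodeCodes(back), nodeCodes(tr))
  for (code in nodeCodes(tr)) {
    expect_identical(nodeMembers(back, code), nodeMembers(tr, code))
    expect_identical(nodeParent(back, code), nodeParent(tr, code))
    expect_identical(nodeLevel(back, code), nodeLevel(tr, code))
  }
})

test_that("label tables round trip and validate codes", {
  tr <- toyTree()
  labs <- c(s1 = "A1", s5 = "B")
  path <- tempfile(fileext = ".tsv")
  writeLabels(labs, path)
  expect_identical(readLabels(path, tr), labs)
  bad <- c(s1 = "XX")
  badPath <- tempfile(fileext = ".tsv")
  writeLabels(bad, badPath)
  expect_error(readLabels(badPath, tr), "XX")
})
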