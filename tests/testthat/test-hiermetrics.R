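test_that("information-content weights follow class frequencies", {
  tr <- toyTree()
  w <- simgicWeights(tr)
  expect_identical(unname(w["R"]), 0)
  expect_equal(unname(w["A"]), log(2), tolerance = 1e-12)   # p = 0.5
  expect_equal(unname(w["A"]), 0.6931, tolerance = 1e-4)
  for (code in setdiff(nodeCodes(tr), "R"))
    expect_gte(w[code], w[nodeParent(tr, code)])
  withEmpty <- makeHierarchy(c("r", "a", "b"), c(NA, "r", "r"),
                             list(c("x", "y"), c("x", "y"), character(0)))
  expect_error(simgicWeights(withEmpty), "zero members")
})

test_that("hierarchical similarity reproduces hand-computed cases", {
  tr <- toyTree()
  w <- simgicWeights(tr)
  v1 <- crispMembership(tr, "A1")
  v2 <- crispMembership(tr, "A2")
  expect_equal(hierarchicalSimilarity(v1, v1, w), 1)
  # shared branch A only: w(A) / (w(A) + w(A1) + w(A2)) = ln2 / (ln2 + 2 ln4)
  expect_equal(hierarchicalSimilarity(v1, v2, w),
               log(2) / (log(2) + 2 * log(4)), tolerance = 1e-12)
  expect_equal(hierarchicalSimilarity(v1, v2, w), 0.2, tolerance = 1e-12)
  # disjoint crisp branches share only the zero-weight root
  vB <- crispMembership(tr, "B")
  expect_equal(hierarchicalSimilarity(v1, vB, w), 0)
  expect_error(hierarchicalSimilarity(setNames(1, "R"), setNames(1, "R"), w),
               "undefined")
})

test_that("partial similarity ignores false-positive branches", {
  tr <- toyTree()
  w <- simgicWeights(tr)
  v1 <- crispMembership(tr, "A1")
  v2 <- crispMembership(tr, "A2")
  expect_equal(partialHierarchicalSimilarity(v1, v1, w), 1)
  # truth = {A, A1}: eta = w(A) / (w(A) + w(A1)) = 1/3
  expect_equal(partialHierarchicalSimilarity(v1, v2, w), 1 / 3,
               tolerance = 1e-12)
  # prediction strictly wider than the truth: eta = 1 while H < 1
  truth <- crispMembership(tr, "A")
  wide <- crispMembership(tr, "A1")
  expect_equal(partialHierarchicalSimilarity(truth, wide, w), 1)
  expect_lt(hierarchicalSimilarity(truth, wide, w), 1)
  expect_error(partialHierarchicalSimilarity(setNames(1, "R"), v1, w),
               "no weighted support")
})

test_that("H and eta match brute-force summation on random trees and vectors", {
  for (seed in 1:6) {
    tr <- randomTree(seed)
    w <- simgicWeights(tr)
    set.seed(seed + 100)
    v1 <- setNames(runif(length(w)), names(w))
    v2 <- setNames(runif(length(w)), names(w))
    H <- hierarchicalSimilarity(v1, v2, w)
    eta <- partialHierarchicalSimilarity(v1, v2, w)
    expect_equal(H, bruteH(v1, v2, w), tolerance = 1e-12)
    expect_equal(eta, bruteEta(v1, v2, w), tolerance = 1e-12)
    # 0 <= H <= eta <= 1; H symmetric, eta generally not
    expect_gte(H, 0); expect_lte(H, eta + 1e-12); expect_lte(eta, 1)
    expect_equal(H, hierarchicalSimilarity(v2, v1, w), tolerance = 1e-12)
    # base change rescales numerator and denominator identically
    expect_equal(hierarchicalSimilarity(v1, v2, w / log(10)), H,
                 tolerance = 1e-12)
    # probability mass on the zero-weight root never matters
    v1r <- c(v1, setNames(0.77, rootCode(tr)))
    expect_equal(hierarchicalSimilarity(v1r, v2, w), H, tolerance = 1e-12)
  }
})

test_that("multilabel scores recover textbook confusion values", {
  t1 <- cbind(a = c(1, 1, 1, 1, 0), b = c(0, 1, 0, 1, 1))
  perfect <- multilabelScores(t1, t1)
  expect_true(all(perfect$aggregate[c("micro_F1", "macro_F1", "accuracy")] == 1))
  none <- multilabelScores(t1, t1 * 0)
  expect_equal(unname(none$aggregate["micro_recall"]), 0)
  # TP = 3, FP = 1, FN = 1 -> F1 = 0.75
  targets <- cbind(x = c(1, 1, 1, 1, 0, 0))
  preds <- cbind(x = c(1, 1, 1, 0, 1, 0))
  sc <- multilabelScores(targets, preds)
  expect_equal(sc$per_node$F1, 0.75)
  # node without positives excluded from macro averages, with a message
  t2 <- cbind(a = c(1, 0), b = c(0, 0))
  expect_message(res <- multilabelScores(t2, t2), "without positives")
  expect_equal(unname(res$aggregate["macro_F1"]), 1)
  # average precision on a separable score column is 1
  sc2 <- multilabelScores(targets, preds, scores = cbind(x = c(.9, .8, .7, .6, .2, .1)))
  expect_equal(sc2$per_node$AUCPR, 1)
})

test_that("adjusted mutual information matches the reference implementation", {
  # expected values computed once with scikit-learn's
  # adjusted_mutual_info_score (arithmetic normalisation) and frozen
  expect_equal(adjustedMutualInformation(c(0, 0, 0, 1, 1, 1),
                                         c(0, 0, 1, 1, 2, 2)),
               0.2987924581708901, tolerance = 1e-10)
  a2 <- c(3, 0, 1, 2, 3, 3, 3, 3, 0, 1, 2, 3, 0, 1, 2, 2, 2, 0, 3, 2, 0, 0,
          3, 3, 0, 0, 3, 3, 2, 2)
  b2 <- c(0, 0, 1, 0, 0, 1, 0, 1, 0, 2, 0, 1, 2, 2, 0, 2, 1, 0, 0, 1, 0, 0,
          2, 1, 0, 0, 0, 2, 1, 0)
  expect_equal(adjustedMutualInformation(a2, b2), 0.08119852797131753,
               tolerance = 1e-10)
  a3 <- rep(0:2, each = 10)
  b3 <- c(1, 0, 0, 0, 0, 0, 0, 0, 0, 0, 1, 1, 1, 1, 1, 2, 1, 1, 1, 1, 2, 2,
          2, 2, 2, 2, 2, 2, 2, 0)
  expect_equal(adjustedMutualInformation(a3, b3), 0.6825640811878988,
               tolerance = 1e-10)
  # identical partitions (up to relabeling) give exactly 1
  expect_equal(adjustedMutualInformation(letters[c(1, 1, 2, 2, 3)],
                                         c(9, 9, 4, 4, 7)), 1)
})
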