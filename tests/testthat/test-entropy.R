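test_that("gene entropy matches a brute-force KDE oracle", {
  bruteKDE <- function(x, bw, G) {
    g <- seq(min(x) - 4 * bw, max(x) + 4 * bw, length.out = G)
    d <- rowSums(sapply(x, function(xi) dnorm(g, xi, bw)))
    p <- d / sum(d); p <- p[p > 0]
    -sum(p * log(p))
  }
  set.seed(3)
  for (x in list(rnorm(40), rexp(60), sample(0:3, 50, replace = TRUE) + 0)) {
    expect_equal(geneEntropy(x, 0.2, 2000), bruteKDE(x, 0.2, 2000),
                 tolerance = 1e-4)
  }
})

test_that("gene entropy is permutation- and shift-invariant and scale-monotone", {
  set.seed(11)
  x <- rnorm(200)
  # accumulation order differs, so agreement is up to float round-off
  expect_equal(geneEntropy(x, 0.2, 5000), geneEntropy(sample(x), 0.2, 5000),
               tolerance = 1e-12)
  expect_equal(geneEntropy(x, 0.2, 5000), geneEntropy(x + 12.3, 0.2, 5000),
               tolerance = 1e-12)
  # wider distributions carry more entropy (Gaussian differential entropy
  # grows with sigma); same draws scaled keeps the comparison paired
  set.seed(12)
  z <- rnorm(500)
  expect_gt(geneEntropy(2 * z, 0.2, 1e4), geneEntropy(z, 0.2, 1e4))
  # negative-binomial analogue on the log scale
  set.seed(13)
  n1 <- log2(rnbinom(500, mu = 500, size = 1 / 0.1) + 1)
  n2 <- log2(rnbinom(500, mu = 500, size = 1 / 0.4) + 1)
  sharedRange <- range(c(n1, n2))
  expect_gt(geneEntropy(n2, 0.2, 1e4, range = sharedRange),
            geneEntropy(n1, 0.2, 1e4, range = sharedRange))
})

test_that("grid refinement changes raw entropy by less than log 2 on doubling", {
  set.seed(21)
  x <- rnorm(150)
  s1 <- geneEntropy(x, 0.2, 5e4)
  s2 <- geneEntropy(x, 0.2, 1e5)
  # the grid-spacing term contributes log((1e5-1)/(5e4-1)), marginally above
  # log 2 itself; allow that exact discrete correction
  expect_lt(abs(s2 - s1), log(2) * (1 + 1e-3))
})

test_that("gene entropy rejects degenerate input", {
  expect_error(geneEntropy(1), "at least 2")
  expect_error(geneEntropy(c(1, NA)), "non-finite")
  expect_error(geneEntropy(c(1, 2), bandwidth = 0), "bandwidth")
  expect_error(geneEntropy(c(1, 2), gridPoints = 10), "gridPoints")
})

test_that("class entropy table self-normalises the reference class", {
  co <- generateCohort(TreeSpec(depth = 1, branching = 3L,
                                samplesPerLeaf = 30, nGenes = 80,
                                markersPerNode = 5, seed = 31))
  norm <- normalizeCounts(co$counts)
  classes <- setNames(lapply(paste0("T00", 1:3), nodeMembers, tree = co$tree),
                      paste0("T00", 1:3))
  tab <- classEntropyTable(norm, classes, "T002", gridPoints = 5000)
  expect_identical(median(tab$norm_S[tab$class == "T002"]), 1)
  # classes drawn from one distribution agree within Monte-Carlo tolerance
  meds <- tapply(tab$norm_S, tab$class, median)
  expect_lt(max(abs(meds - 1)), 0.05)
  expect_error(classEntropyTable(norm, classes, "T009"), "reference class")
  small <- classes; small$T001 <- small$T001[1:3]
  expect_error(classEntropyTable(norm, small, "T002"), "below minimum")
})

test_that("entropy adjustment residualises the expression dependence", {
  set.seed(41)
  n <- 400
  medExpr <- runif(n, 0, 10)
  tab <- data.frame(gene = paste0("g", seq_len(n)), class = "C",
                    raw_S = 1, norm_S = 0.5 * medExpr + rnorm(n, sd = 0.3),
                    adj_S = NA_real_, median_expr = medExpr)
  adj <- adjustEntropy(tab)
  fit <- attr(adj, "fit")
  expect_equal(fit$slope, 0.5, tolerance = 0.05)          # planted slope
  expect_lt(abs(cor(adj$adj_S, adj$median_expr)), 1e-10)  # orthogonality
  expect_equal(mean(adj$adj_S), mean(adj$norm_S), tolerance = 1e-10)
  expect_error(adjustEntropy(tab[1:2, ]), "at least 3")
})

test_that("entropy summary computes median and MAD per class", {
  tab <- data.frame(gene = c("a", "b", "c", "a", "b", "c"),
                    class = rep(c("X", "Y"), each = 3),
                    raw_S = 1, norm_S = 1,
                    adj_S = c(1, 2, 3, 5, 5, 5), median_expr = 0)
  s <- entropySummary(tab)
  expect_equal(s$median_S[s$class == "X"], 2)
  expect_equal(s$MAD[s$class == "X"], 1)
  expect_equal(s$MAD[s$class == "Y"], 0)
  # invariant to row order
  s2 <- entropySummary(tab[sample(6), ])
  expect_equal(s[order(s$class), ], s2[order(s2$class), ])
})
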