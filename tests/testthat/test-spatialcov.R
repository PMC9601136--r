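# Spatial covariation: weight construction, Lee's L against oracles, ROC /
# AUC / threshold selection, label transfer and enrichment.

test_that("weights are block-diagonal, row-standardised chain adjacency", {
  W <- gutWeights()
  V <- weightsMatrix(W)
  expect_equal(dim(V), c(6L, 6L))
  expect_equal(unname(rowSums(V)), rep(1, 6))
  expect_true(all(V[1:3, 4:6] == 0) && all(V[4:6, 1:3] == 0))
  expect_true(validObject(W))

  # include_self = FALSE on a 3-site chain: end rows load only the middle
  W2 <- buildWeights("i1", c("a", "b", "c"), includeSelf = FALSE)
  V2 <- weightsMatrix(W2)
  expect_equal(unname(V2[1, ]), c(0, 1, 0))
  expect_equal(unname(V2[3, ]), c(0, 1, 0))
  expect_equal(unname(V2[2, ]), c(0.5, 0, 0.5))

  expect_error(buildWeights("i1", "onlysite", includeSelf = FALSE),
               "all-zero|single site")
})

test_that("lee's L reduces to Pearson at V = I and matches the oracle", {
  expect_equal(leeL(c(1, 2, 3), c(3, 2, 1), diag(3)), -1)
  set.seed(501)
  for (i in 1:50) {
    x <- rnorm(6); y <- rnorm(6)
    expect_equal(leeL(x, y, diag(6)), cor(x, y), tolerance = 1e-12)
    expect_equal(leeL(x, x, diag(6)), 1, tolerance = 1e-12)
  }
  W <- gutWeights()
  V <- weightsMatrix(W)
  for (i in 1:50) {
    x <- rnorm(6); y <- rnorm(6)
    expect_equal(leeL(x, y, W), oracleLeeL(x, y, V), tolerance = 1e-12)
  }
  expect_error(leeL(rep(1, 6), rnorm(6), W), "constant")
})

test_that("lee's L is symmetric and invariant to positive affine maps", {
  W <- gutWeights()
  set.seed(502)
  for (i in 1:30) {
    x <- rnorm(6); y <- rnorm(6)
    a <- runif(1, 0.1, 5); b <- rnorm(1)
    expect_equal(leeL(x, y, W), leeL(y, x, W), tolerance = 1e-12)
    expect_equal(leeL(a * x + b, y, W), leeL(x, y, W), tolerance = 1e-12)
    expect_equal(leeL(x, a * y + b, W), leeL(x, y, W), tolerance = 1e-12)
  }
})

test_that("leeLMatrix agrees with elementwise leeL", {
  W <- gutWeights()
  set.seed(503)
  X <- matrix(rnorm(30), 5, 6)
  rownames(X) <- paste0("c", 1:5)
  Lm <- leeLMatrix(X, W)
  for (i in 1:5) for (j in 1:5)
    expect_equal(Lm[i, j], leeL(X[i, ], X[j, ], W), tolerance = 1e-12)
})

test_that("ROC, AUC and theta selection behave on constructed score sets", {
  b1 <- scoreBenchmark(c(0.9, 0.8, 0.7, 0.1), c(TRUE, TRUE, FALSE, FALSE),
                       targetFpr = 0.05)
  expect_equal(rocAuc(b1), 1.0)
  expect_lte(lThreshold(b1), 0.8)
  expect_equal(b1@fpr, 0)
  expect_equal(b1@sensitivity, 1)

  b2 <- scoreBenchmark(c(0.9, 0.4, 0.8, 0.1), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(rocAuc(b2), 0.75)

  # permuted labels give a null AUC near 0.5
  set.seed(504)
  scores <- rnorm(400)
  labels <- sample(rep(c(TRUE, FALSE), each = 200))
  b3 <- scoreBenchmark(scores, labels)
  expect_gt(rocAuc(b3), 0.45)
  expect_lt(rocAuc(b3), 0.55)
})

test_that("trapezoid AUC equals the pair-counting estimator with ties", {
  set.seed(505)
  for (i in 1:50) {
    n <- sample(20:80, 1)
    scores <- sample(seq(0, 1, by = 0.05), n, replace = TRUE)  # many ties
    labels <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(labels) || all(labels)) next
    b <- scoreBenchmark(scores, labels)
    expect_equal(rocAuc(b), oracleAuc(scores, labels), tolerance = 1e-12)
  }
})

test_that("selected threshold always achieves the target FPR bound", {
  set.seed(506)
  for (i in 1:50) {
    n <- sample(30:100, 1)
    scores <- rnorm(n)
    labels <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(labels) || all(labels)) next
    b <- scoreBenchmark(scores, labels, targetFpr = 0.1)
    emp <- mean(scores[!labels] >= lThreshold(b))
    expect_lte(emp, 0.1)
    expect_equal(emp, b@fpr)
  }
})

test_that("benchmarkKnown wires profiles, reactions and the ROC together", {
  W <- gutWeights()
  sim <- simulateClusterProfiles(40L, 0L, effectSize = 2, noiseSd = 0.02,
                                 seed = 507L)
  rx <- as.list(setNames(sprintf("R%03d", rep(seq_len(40L), 2)),
                         c(sim$pairs$id1, sim$pairs$id2)))
  b <- benchmarkKnown(sim$profiles, rx, W)
  expect_s4_class(b, "BenchmarkResult")
  expect_gt(rocAuc(b), 0.8)
  expect_lte(b@fpr, 0.05)
  roc <- rocTable(b)
  expect_true(all(diff(roc$fpr) >= 0))
  expect_true(all(diff(roc$sensitivity) >= 0))
  # degenerate truth sets error out
  expect_error(benchmarkKnown(sim$profiles, rx[1], W), "undefined")
  oneClass <- as.list(setNames(rep("R1", nrow(sim$profiles)),
                               rownames(sim$profiles)))
  expect_error(benchmarkKnown(sim$profiles, oneClass, W), "undefined")
})

test_that("function transfer links by threshold and inherits labels", {
  n <- 6
  V <- diag(n)
  x <- c(1, 5, 2, 8, 3, 9)
  unk <- rbind(u1 = x, u2 = -x + 20)
  kn <- rbind(k1 = 2 * x + 1, k2 = rev(x))
  labels <- list(k1 = c("transport"), k2 = c("metabolism"))
  tr <- transferFunctions(unk, kn, labels, V, theta = 0.9,
                          membership = data.frame(cluster_id = "u1",
                                                  gene_id = "geneA"))
  expect_true(nrow(tr$links[tr$links$unknown == "u1" &
                              tr$links$known == "k1"]) == 1L)
  expect_false(any(tr$links$unknown == "u2" & tr$links$known == "k1"))
  expect_equal(tr$predictions$u1, "transport")
  expect_equal(tr$genePredictions$labels, "transport")
  expect_equal(tr$nAnnotatedGenes, 1L)
  expect_true(all(tr$links$L >= 0.9))
})

test_that("enrichment reproduces the hypergeometric example and BH flag", {
  # 2x2 table [[3,1],[1,3]]: category in 3/4 unknown vs 1/4 known clusters
  transfer <- list(predictions = list(u1 = "A", u2 = "A", u3 = "A",
                                      u4 = "B"))
  known <- list(k1 = "A", k2 = "B", k3 = "B", k4 = "B")
  er <- enrichFunctions(transfer, known, alpha = 0.01)
  pA <- er$p[er$category == "A"]
  expect_equal(pA, 34 / 70, tolerance = 1e-12)
  expect_true(all(er$p_adj >= er$p))
  expect_false(any(er$enriched))
  # identical composition in both groups: nothing enriched
  er2 <- enrichFunctions(list(predictions = known), known)
  expect_false(any(er2$enriched))
  expect_true(all(er2$p == 1))
})

test_that("cluster profiles aggregate, transform and exclude masked rows", {
  mat <- rbind(g1 = c(1, 2, 3, 4, 5, 6),
               g2 = c(2, 4, 6, 8, 10, 12),
               g3 = c(NA, 1, 1, 1, 1, 1),
               g4 = c(7, 7, 7, 7, 7, 7))
  cl <- data.frame(cluster_id = c("c1", "c1", "c2", "c3"),
                   gene_id = c("g1", "g2", "g3", "g4"))
  expect_message(p <- clusterProfiles(mat, cl), "excluded")
  expect_equal(rownames(p), "c1")
  expect_equal(unname(p[1, ]), log2(1 + c(3, 6, 9, 12, 15, 18)))
  pm <- suppressMessages(clusterProfiles(mat, cl, aggregate = "mean",
                                         log2p1 = FALSE))
  expect_equal(unname(pm["c1", ]), c(1.5, 3, 4.5, 6, 7.5, 9))
})

test_that("community layer beats per-cell when abundance carries the signal", {
  # confounded fixture: each designed pair sits on one species whose
  # abundance follows a strong smooth gradient; per-gene expression is
  # nearly flat noise.  The whole-community layer (abundance x expression)
  # then carries the pairing signal; the per-cell layer (expression only)
  # does not.
  W <- gutWeights()
  set.seed(509)
  nPairs <- 40L
  z <- c(-1, 0, 1)
  siteIdx <- rep(1:3, 2)
  indIdx <- rep(1:2, each = 3)
  commP <- matrix(0, 2 * nPairs, 6)
  cellP <- matrix(0, 2 * nPairs, 6)
  rn <- sprintf("cl%03d", seq_len(2 * nPairs))
  rownames(commP) <- rownames(cellP) <- rn
  rx <- list()
  for (p in seq_len(nPairs)) {
    slope <- runif(2, -2, 2)              # per-individual species gradient
    offs <- rnorm(2, 0, 0.8)
    abProf <- exp(slope[indIdx] * z[siteIdx] + offs[indIdx])
    for (m in 1:2) {
      i <- (p - 1L) * 2L + m
      expr <- exp(rnorm(6, 2, 0.05))      # flat per-cell expression
      commP[i, ] <- log2(1 + abProf * expr)
      cellP[i, ] <- log2(1 + expr)
      rx[[rn[i]]] <- sprintf("R%03d", p)
    }
  }
  bComm <- benchmarkKnown(commP, rx, W)
  bCell <- benchmarkKnown(cellP, rx, W)
  expect_gt(rocAuc(bComm), rocAuc(bCell))
  expect_gt(rocAuc(bComm), 0.8)
  expect_lt(rocAuc(bCell), 0.65)
})
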