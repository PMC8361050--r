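test_that("generated precision matrices are symmetric positive definite", {
  for (spec in list(list(n = 5, d = 0.5, s = 7), list(n = 30, d = 0.1, s = 1),
                    list(n = 12, d = 0.9, s = 42))) {
    P <- generateSparsePrecision(spec$n, spec$d, seed = spec$s)
    expect_identical(P, t(P))
    ev <- eigen(P, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), 0)
  }
})

test_that("vanishing edge density gives a diagonal SPD matrix", {
  P <- generateSparsePrecision(2, 1e-12, diagonalBoost = 1, seed = 1)
  expect_true(all(P[upper.tri(P)] == 0))
  expect_true(all(diag(P) > 0))
})

test_that("precision generation is seed-deterministic and validates inputs", {
  a <- generateSparsePrecision(5, 0.5, seed = 7)
  b <- generateSparsePrecision(5, 0.5, seed = 7)
  expect_identical(a, b)
  expect_false(identical(a, generateSparsePrecision(5, 0.5, seed = 8)))
  expect_error(generateSparsePrecision(1, 0.5), "nGenes")
  expect_error(generateSparsePrecision(5, 0.5, diagonalBoost = 0), "diagonalBoost")
  expect_error(generateSparsePrecision(5, 0), "edgeDensity")
})

test_that("identity-precision samples have near-unit per-gene variance", {
  se <- sampleExpression(diag(20), 1e5, seed = 11)
  v <- apply(SummarizedExperiment::assay(se), 1L, var)
  expect_true(all(abs(v - 1) < 0.05))
})

test_that("single-sample draws are valid but unusable for covariance", {
  se <- sampleExpression(diag(4), 1, seed = 3)
  expect_equal(dim(se), c(4L, 1L))
  expect_error(estimateCovariance(se), "2 samples")
})

test_that("non-SPD precision is rejected by the sampler", {
  bad <- matrix(c(1, 2, 2, 1), 2)    # indefinite
  expect_error(sampleExpression(bad, 10), "positive definite")
})

test_that("sample covariance converges to the true inverse precision", {
  P <- generateSparsePrecision(5, 0.4, seed = 2)
  Sigma <- chol2inv(chol(P))
  se <- sampleExpression(P, 5e4, seed = 21)
  C <- estimateCovariance(se)@covariance
  expect_lt(norm(C - Sigma, "F"), 0.05)
})

test_that("covariance estimation error shrinks as sample size grows", {
  # averaged over seeds, Frobenius error decreases over n = 100, 1000, 10000
  P <- generateSparsePrecision(5, 0.4, seed = 5)
  Sigma <- chol2inv(chol(P))
  err <- sapply(c(100, 1000, 10000), function(n)
    mean(sapply(1:20, function(s) {
      C <- estimateCovariance(sampleExpression(P, n, seed = s))@covariance
      norm(C - Sigma, "F")
    })))
  expect_true(all(diff(err) < 0))
})

test_that("toy fixtures match their definitions", {
  c4 <- generateToyNetwork("cycle_4")
  expect_equal(nNodes(c4), 4L)
  expect_equal(nEdges(c4), 4L)
  expect_true(all(couplings(c4) %in% c(0, 1)))
  oct <- generateToyNetwork("octahedron")
  expect_equal(nNodes(oct), 6L)
  expect_equal(nEdges(oct), 12L)
  expect_true(all(rowSums(couplings(oct) != 0) == 4))
  k5 <- generateToyNetwork("complete_5")
  expect_equal(nEdges(k5), 10L)
  f2 <- generateToyNetwork("fig2_analog")
  w <- couplings(f2)[upper.tri(couplings(f2))]
  expect_false(anyDuplicated(w[w != 0]) > 0)   # distinct weights
  expect_error(generateToyNetwork("no_such_fixture"), "unknown")
})

test_that("cohort pairs share support and differ only in weight width", {
  pair <- generateCohortPair(nGenes = 20, nSamplesA = 10, nSamplesB = 10,
                             widthA = c(0.1, 0.2), widthB = c(0.1, 0.8),
                             seed = 4)
  pa <- pair[[1]]@truePrecision
  pb <- pair[[2]]@truePrecision
  expect_identical(pa != 0, pb != 0)
  offA <- precisionWeights(pa); offB <- precisionWeights(pb)
  expect_identical(sign(offA), sign(offB))
  expect_lt(sd(abs(offA)), sd(abs(offB)))
  expect_identical(pair[[1]]@label, "cancer-like")
})

test_that("equal widths give statistically indistinguishable weight sets", {
  pair <- generateCohortPair(nGenes = 25, nSamplesA = 5, nSamplesB = 5,
                             widthA = c(0.2, 0.5), widthB = c(0.2, 0.5),
                             seed = 9)
  a <- abs(precisionWeights(pair[[1]]@truePrecision))
  b <- abs(precisionWeights(pair[[2]]@truePrecision))
  expect_gt(suppressWarnings(ks.test(a, b)$p.value), 0.01)
})

test_that("cohort pair generation is seed-deterministic", {
  p1 <- generateCohortPair(nGenes = 10, nSamplesA = 20, nSamplesB = 20, seed = 5)
  p2 <- generateCohortPair(nGenes = 10, nSamplesA = 20, nSamplesB = 20, seed = 5)
  expect_identical(p1[[1]]@truePrecision, p2[[1]]@truePrecision)
  expect_identical(SummarizedExperiment::assay(p1[[2]]@expression),
                   SummarizedExperiment::assay(p2[[2]]@expression))
})

test_that("toy fixture homology agrees with the rank oracle", {
  for (nm in c("cycle_4", "cycle_6", "complete_4", "octahedron",
               "fig1c_analog")) {
    net <- generateToyNetwork(nm)
    pd <- computePersistence(buildCliqueFiltration(net))
    expect_identical(unname(essentialFeatures(pd)$counts),
                     unname(as.integer(bettiNumbersStatic(net, 1))),
                     label = nm)
  }
})
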