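test_that("RPKM formula matches direct evaluation", {
  # single count: 10 reads, 1 kb gene, library of 10 -> 1e6
  m <- matrix(10, 1, 1)
  expect_equal(unname(SummarizedExperiment::assay(
    rpkmNormalize(m, 1000))[1, 1]), 1e6)
  # zero counts stay zero whatever the length / library
  m2 <- rbind(c(0, 3), c(5, 7))
  r2 <- SummarizedExperiment::assay(rpkmNormalize(m2, c(500, 2000)))
  expect_equal(r2[1, 1], 0)
  # brute-force elementwise recomputation on a random count matrix
  set.seed(1)
  counts <- matrix(rpois(12, 50), 4, 3)
  lens <- c(300, 1500, 800, 2200)
  got <- SummarizedExperiment::assay(rpkmNormalize(counts, lens))
  for (g in 1:4) for (s in 1:3)
    expect_equal(got[g, s],
                 1e9 * counts[g, s] / (lens[g] * sum(counts[, s])))
})

test_that("RPKM rejects degenerate inputs", {
  expect_error(rpkmNormalize(matrix(0, 2, 2), c(100, 100)), "library")
  expect_error(rpkmNormalize(matrix(1, 2, 2), c(0, 100)), "positive")
  expect_error(rpkmNormalize(matrix(1, 2, 2), 100), "align")
})

test_that("variance filter keeps the k most variable genes in order", {
  m <- rbind(a = rep(1, 4), b = c(0, 1, 0, 1), c = c(0, 2, 0, 2),
             d = c(0, 3, 0, 3), e = c(0, 4, 0, 4))
  top2 <- selectTopVarianceGenes(m, 2)
  expect_identical(rownames(top2), c("e", "d"))
  # identity case: k = all positive-variance genes keeps that set
  all4 <- selectTopVarianceGenes(m, 4)
  expect_setequal(rownames(all4), c("b", "c", "d", "e"))
  v <- apply(SummarizedExperiment::assay(all4), 1L, var)
  expect_false(is.unsorted(rev(v)))    # descending variance
  # k beyond the positive-variance genes is an error (gene "a" is constant)
  expect_error(selectTopVarianceGenes(m, 5), "positive variance")
})

test_that("variance ties are broken by input order", {
  m <- rbind(x = c(0, 1), y = c(0, 1), z = c(0, 2))
  expect_identical(rownames(selectTopVarianceGenes(m, 3)), c("z", "x", "y"))
})

test_that("covariance model matches hand and brute-force computation", {
  m <- rbind(g1 = c(0, 2), g2 = c(0, 2))
  mod <- estimateCovariance(m)
  expect_equal(unname(mod@mean), c(1, 1))
  expect_true(all(mod@covariance == 1))   # ML divisor n = 2
  # brute-force two-pass loop on a random matrix
  set.seed(2)
  x <- matrix(rnorm(200), 4, 50)
  C <- estimateCovariance(x)@covariance
  for (i in 1:4) for (j in 1:4) {
    mi <- mean(x[i, ]); mj <- mean(x[j, ])
    expect_equal(unname(C[i, j]), sum((x[i, ] - mi) * (x[j, ] - mj)) / 50)
  }
})

test_that("constant genes are removed with a warning", {
  m <- rbind(g1 = c(1, 1, 1), g2 = c(0, 1, 2))
  expect_warning(mod <- estimateCovariance(m), "zero-variance")
  expect_identical(geneIds(mod), "g2")
})

test_that("couplings negate the precision off-diagonal with zero diagonal", {
  th <- diag(3)
  net <- interactionsFromPrecision(th)
  expect_true(all(couplings(net) == 0))
  expect_equal(sparsity(net), 1)
  th2 <- rbind(c(1, -0.5, 0), c(-0.5, 1, 0.2), c(0, 0.2, 1))
  net2 <- interactionsFromPrecision(th2, geneIds = c("a", "b", "c"))
  expect_equal(couplings(net2)["a", "b"], 0.5)
  expect_equal(couplings(net2)["b", "c"], -0.2)
  expect_true(all(diag(couplings(net2)) == 0))
  expect_error(interactionsFromPrecision(th2, geneIds = c("a", "b")), "length")
})

test_that("model log-density matches the closed Gaussian form", {
  mod1 <- new("CovarianceModel", geneIds = "g1", mean = c(g1 = 0),
              covariance = matrix(1, dimnames = list("g1", "g1")),
              nSamplesUsed = 10L)
  expect_equal(modelLogDensity(mod1, 0), log(1 / sqrt(2 * pi)))
  # translation invariance: shifting s and the mean together changes nothing
  C <- rbind(c(2, 0.3), c(0.3, 1))
  mod2 <- new("CovarianceModel", geneIds = c("a", "b"), mean = c(1, -2),
              covariance = C, nSamplesUsed = 5L)
  s <- c(0.4, 0.9); shift <- c(3, -1)
  mod2s <- mod2; mod2s@mean <- mod2@mean + shift
  expect_equal(modelLogDensity(mod2, s), modelLogDensity(mod2s, s + shift))
})

test_that("the bivariate model density integrates to one", {
  C <- rbind(c(1.5, -0.4), c(-0.4, 0.8))
  mod <- new("CovarianceModel", geneIds = c("a", "b"), mean = c(0.5, -0.5),
             covariance = C, nSamplesUsed = 5L)
  g <- seq(-8, 8, length.out = 321)
  h <- g[2] - g[1]
  dens <- outer(g, g, Vectorize(function(x, y)
    exp(modelLogDensity(mod, c(x + 0.5, y - 0.5)))))
  expect_lt(abs(sum(dens) * h^2 - 1), 1e-3)
})

test_that("singular covariance is rejected by the density", {
  C <- matrix(1, 2, 2)
  mod <- new("CovarianceModel", geneIds = c("a", "b"), mean = c(0, 0),
             covariance = C, nSamplesUsed = 5L)
  expect_error(modelLogDensity(mod, c(0, 0)), "singular")
})
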