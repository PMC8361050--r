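test_that("filtration applies the max-edge rule and enters vertices at 0", {
  W <- matrix(0, 3, 3)
  W[1, 2] <- W[2, 1] <- 0.1
  W[2, 3] <- W[3, 2] <- -0.2     # absolute transform
  W[1, 3] <- W[3, 1] <- 0.3
  filt <- buildCliqueFiltration(InteractionNetwork(W))
  tri <- which(filt@dims == 2L)
  expect_length(tri, 1L)
  expect_equal(filt@values[tri], 0.3)
  expect_true(all(filt@values[filt@dims == 0L] == 0))
  edgeVals <- sort(filt@values[filt@dims == 1L])
  expect_equal(edgeVals, c(0.1, 0.2, 0.3))
})

test_that("an edgeless network yields a vertex-only filtration", {
  filt <- buildCliqueFiltration(InteractionNetwork(matrix(0, 5, 5)))
  expect_length(filt@simplices, 5L)
  expect_true(all(filt@dims == 0L))
})

test_that("filtration simplices equal exhaustive clique enumeration", {
  set.seed(5)
  for (rep in 1:5) {
    net <- randomNetwork(10, 0.5)
    filt <- buildCliqueFiltration(net, maxDim = 3)
    W <- abs(couplings(net))
    # brute force: test every vertex subset of size <= 4 for clique-ness
    expected <- list()
    for (k in 1:4) {
      subs <- utils::combn(10, k)
      for (c0 in seq_len(ncol(subs))) {
        v <- subs[, c0]
        pairs <- if (k > 1) utils::combn(v, 2) else NULL
        isClique <- k == 1 || all(W[t(pairs)] > 0)
        if (isClique) {
          val <- if (k == 1) 0 else max(W[t(pairs)])
          expected[[paste(v, collapse = ".")]] <- val
        }
      }
    }
    keys <- vapply(filt@simplices, paste, character(1), collapse = ".")
    expect_setequal(keys, names(expected))
    expect_equal(filt@values, unname(unlist(expected[keys])))
  }
})

test_that("filtration order is value, then dimension, then lexicographic", {
  net <- generateToyNetwork("fig1c_analog")
  filt <- buildCliqueFiltration(net)
  expect_false(is.unsorted(filt@values))
  same <- which(diff(filt@values) == 0)
  expect_true(all(filt@dims[same + 1L] >= filt@dims[same] |
                  filt@values[same + 1L] > filt@values[same]))
  # face-closure: every facet precedes its coface
  keys <- vapply(filt@simplices, paste, character(1), collapse = ".")
  pos <- setNames(seq_along(keys), keys)
  for (i in seq_along(filt@simplices)) {
    v <- filt@simplices[[i]]
    if (length(v) > 1L)
      for (f in boundaryOf(v)$facets)
        expect_lt(pos[[paste(f, collapse = ".")]], i)
  }
})

test_that("raw transform rejects negative weights", {
  W <- matrix(0, 2, 2); W[1, 2] <- W[2, 1] <- -0.5
  expect_error(buildCliqueFiltration(InteractionNetwork(W),
                                     weightTransform = "raw"), "non-negative")
  expect_silent(buildCliqueFiltration(InteractionNetwork(abs(W)),
                                      weightTransform = "raw"))
})

test_that("boundaries follow the facet-deletion rule and compose to zero", {
  expect_equal(boundaryOf(c(0L, 1L))$facets, list(1L, 0L))
  expect_setequal(boundaryOf(c(0L, 1L))$facets, list(0L, 1L))
  expect_equal(boundaryOf(c(0L, 1L, 2L))$facets,
               list(c(1L, 2L), c(0L, 2L), c(0L, 1L)))
  expect_length(boundaryOf(5L)$facets, 0L)
  # del del = 0 over Z2: every (k-2)-face appears an even number of times
  for (v in list(c(1L, 2L, 3L), c(1L, 2L, 3L, 4L), c(2L, 4L, 6L, 8L))) {
    faces <- boundaryOf(v)$facets
    grand <- unlist(lapply(faces, function(f)
      vapply(boundaryOf(f)$facets, paste, character(1), collapse = ".")))
    expect_true(all(table(grand) %% 2 == 0))
  }
  expect_error(boundaryOf(c(3L, 1L)), "increasing")
})

test_that("persistence on canonical fixtures matches known homology", {
  # 4-cycle: 4 components born at 0, three die at 1, one survives;
  # a single essential loop born at 1
  pd <- computePersistence(buildCliqueFiltration(generateToyNetwork("cycle_4")))
  p0 <- persistencePairs(pd)[persistencePairs(pd)$dimension == 0, ]
  expect_equal(nrow(p0), 4L)
  expect_true(all(p0$birth == 0))
  expect_equal(sum(is.finite(p0$death)), 3L)
  expect_true(all(p0$death[is.finite(p0$death)] == 1))
  p1 <- persistencePairs(pd)[persistencePairs(pd)$dimension == 1, ]
  expect_equal(nrow(p1), 1L)
  expect_true(is.infinite(p1$death) && p1$birth == 1)
  # octahedron: one essential void, no essential loop
  pdo <- computePersistence(buildCliqueFiltration(generateToyNetwork("octahedron")))
  expect_equal(unname(essentialFeatures(pdo)$counts), c(1L, 0L, 1L))
  # complete graphs are contractible
  pdk <- computePersistence(buildCliqueFiltration(generateToyNetwork("complete_6")))
  expect_equal(unname(essentialFeatures(pdk)$counts), c(1L, 0L, 0L))
  # octahedron with two pendant cycles: Betti vector (1, 2, 1)
  pdf1 <- computePersistence(buildCliqueFiltration(generateToyNetwork("fig1c_analog")))
  expect_equal(unname(essentialFeatures(pdf1)$counts), c(1L, 2L, 1L))
})

test_that("static Betti oracle handles canonical complexes", {
  expect_equal(unname(bettiNumbersStatic(generateToyNetwork("complete_5"), 1)),
               c(1L, 0L, 0L))
  expect_equal(unname(bettiNumbersStatic(generateToyNetwork("cycle_4"), 1)),
               c(1L, 1L, 0L))
  expect_equal(unname(bettiNumbersStatic(generateToyNetwork("octahedron"), 1)),
               c(1L, 0L, 1L))
  # below the edge weight the complex is the vertex set
  expect_equal(unname(bettiNumbersStatic(generateToyNetwork("cycle_4"), 0.5)),
               c(4L, 0L, 0L))
  expect_error(bettiNumbersStatic(generateToyNetwork("complete_5"), 1,
                                  sizeGuard = 3), "size guard")
})

test_that("persistence-derived Betti numbers equal the rank oracle", {
  set.seed(99)
  for (rep in 1:30) {
    net <- randomNetwork(sample(4:12, 1), runif(1, 0.3, 0.8))
    filt <- buildCliqueFiltration(net)
    pd <- computePersistence(filt)
    curve <- bettiCurve(pd, thresholds = sort(unique(filt@values)))
    for (i in seq_along(curve@thresholds)) {
      w <- curve@thresholds[i]
      expect_equal(unname(curve@beta[i, ]),
                   unname(as.integer(bettiNumbersStatic(net, w))),
                   label = sprintf("rep %d threshold %g", rep, w))
    }
  }
})

test_that("Euler characteristic identity holds for small-clique complexes", {
  set.seed(123)
  for (rep in 1:10) {
    net <- randomNetwork(sample(5:10, 1), 0.45)
    g <- igraph::graph_from_adjacency_matrix(couplings(net) != 0,
                                             mode = "undirected")
    if (igraph::clique_num(g) > 4L) next   # identity needs the full complex
    filt <- buildCliqueFiltration(net, maxDim = 3)
    pd <- computePersistence(filt)
    curve <- bettiCurve(pd, thresholds = sort(unique(filt@values)))
    for (i in seq_along(curve@thresholds)) {
      w <- curve@thresholds[i]
      counts <- simplexCountsAt(filt, w, 3L)
      chi <- counts[1] - counts[2] + counts[3] - counts[4]
      expect_equal(chi,
                   curve@beta[i, "b0"] - curve@beta[i, "b1"] + curve@beta[i, "b2"],
                   ignore_attr = TRUE)
    }
  }
})

test_that("dimension-0 accounting: births, deaths, monotone b0", {
  set.seed(17)
  for (rep in 1:10) {
    n <- sample(4:12, 1)
    net <- randomNetwork(n, runif(1, 0.2, 0.7))
    pd <- computePersistence(buildCliqueFiltration(net))
    p <- persistencePairs(pd)
    p0 <- p[p$dimension == 0, ]
    # every vertex is born at 0 and edges carry positive value, so no dim-0
    # pair can have zero lifetime: dim-0 births = node count exactly
    expect_equal(nrow(p0), n)
    expect_true(all(p0$birth == 0))
    # essential components = graph components
    g <- igraph::graph_from_adjacency_matrix(couplings(net) != 0,
                                             mode = "undirected")
    expect_equal(sum(p0$birth == 0 & is.infinite(p0$death)),
                 igraph::count_components(g))
    curve <- bettiCurve(pd)
    expect_true(all(diff(curve@beta[, "b0"]) <= 0))
  }
})

test_that("betti curves count alive pairs on the half-open convention", {
  pairs <- data.frame(dimension = c(0L, 0L, 1L), birth = c(0, 0, 0.5),
                      death = c(1, Inf, 2), lifetime = c(1, Inf, 1.5))
  pd <- new("PersistenceDiagram", pairs = pairs, maxDim = 3L,
            nodeCount = 2L, zeroLifetimeDropped = 0L)
  bc <- bettiCurve(pd, thresholds = c(0, 0.5, 0.99, 1, 2, 10))
  expect_equal(unname(bc@beta[, "b0"]), c(2L, 2L, 2L, 1L, 1L, 1L))
  expect_equal(unname(bc@beta[, "b1"]), c(0L, 1L, 1L, 1L, 0L, 0L))
  # beyond all finite deaths the curve equals the essential counts
  expect_equal(unname(bc@beta[6, ]),
               unname(essentialFeatures(pd)$counts))
  expect_error(bettiCurve(pd, thresholds = numeric()), "nonempty")
  expect_error(bettiCurve(pd, thresholds = c(1, 1)), "increasing")
})

test_that("empty diagrams give zero curves", {
  pd <- new("PersistenceDiagram",
            pairs = data.frame(dimension = integer(), birth = numeric(),
                               death = numeric(), lifetime = numeric()),
            maxDim = 3L, nodeCount = 0L, zeroLifetimeDropped = 0L)
  bc <- bettiCurve(pd)
  expect_true(all(bc@beta == 0L))
})

test_that("disjoint components each survive as essential classes", {
  W <- matrix(0, 6, 6)
  for (tri in list(1:3, 4:6))
    for (pr in utils::combn(tri, 2, simplify = FALSE))
      W[pr[1], pr[2]] <- W[pr[2], pr[1]] <- 1
  pd <- computePersistence(buildCliqueFiltration(InteractionNetwork(W)))
  expect_equal(unname(essentialFeatures(pd)$counts)[1], 2L)
})

test_that("face-closure violations are rejected", {
  bad <- new("Filtration",
             simplices = list(c(1L, 2L), 1L, 2L),
             values = c(0, 0, 0), dims = c(1L, 0L, 0L),
             nodeCount = 2L, maxDim = 3L)
  expect_error(computePersistence(bad), "face-closed")
})

test_that("persistence is deterministic and stable under tiny perturbation", {
  set.seed(31)
  net <- randomNetwork(10, 0.5)
  pd1 <- computePersistence(buildCliqueFiltration(net))
  pd2 <- computePersistence(buildCliqueFiltration(net))
  expect_identical(persistencePairs(pd1), persistencePairs(pd2))
  # perturb weights by < half the minimum gap between distinct values
  W <- couplings(net)
  vals <- sort(unique(abs(W[upper.tri(W)])))
  gap <- min(diff(vals))
  eps <- gap / 4
  set.seed(32)
  noise <- matrix(runif(100, -eps, eps), 10, 10)
  noise <- (noise + t(noise)) / 2; diag(noise) <- 0
  Wp <- W + sign(W) * abs(noise)     # keep support identical
  pdp <- computePersistence(buildCliqueFiltration(InteractionNetwork(Wp)))
  a <- persistencePairs(pd1); b <- persistencePairs(pdp)
  expect_equal(nrow(a), nrow(b))
  expect_identical(a$dimension, b$dimension)
  expect_true(all(abs(a$birth - b$birth) <= eps + 1e-12))
  finite <- is.finite(a$death)
  expect_identical(finite, is.finite(b$death))
  expect_true(all(abs(a$death[finite] - b$death[finite]) <= eps + 1e-12))
})
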