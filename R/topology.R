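#' @useDynLib grntda, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# value matrix for the filtration: |J| (default) or raw J (must be >= 0)
.filtrationValues <- function(net, weightTransform) {
  weightTransform <- match.arg(weightTransform, c("absolute", "raw"))
  W <- couplings(net)
  if (weightTransform == "absolute") return(abs(W))
  if (any(W < 0))
    stop("raw weight transform requires non-negative weights for a sublevel filtration")
  W
}

# enumerate cliques of the support graph up to size maxDim+1; returns a list
# of sorted integer vertex vectors plus the max-edge filtration value of each
.cliqueComplex <- function(valueMat, maxDim, threshold = Inf) {
  p <- nrow(valueMat)
  adj <- valueMat != 0 & valueMat <= threshold
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  cl <- igraph::cliques(g, min = 1L, max = maxDim + 1L)
  simplices <- lapply(cl, function(v) sort(as.integer(v)))
  values <- vapply(simplices, function(v) {
    if (length(v) == 1L) return(0)
    pairs <- utils::combn(v, 2L)
    max(valueMat[cbind(pairs[1L, ], pairs[2L, ])])
  }, numeric(1))
  list(simplices = simplices, values = values,
       dims = vapply(simplices, length, integer(1)) - 1L)
}

# deterministic filtration order: value, then dimension, then lexicographic
.filtrationOrder <- function(simplices, values, dims, maxDim) {
  pad <- t(vapply(simplices, function(v) c(v, rep(0L, maxDim + 1L - length(v))),
                  integer(maxDim + 1L)))
  do.call(order, c(list(values, dims), asplit(pad, 2L)))
}

#' Build the weighted clique-complex filtration of a network
#'
#' Maps the network to its clique (flag) simplicial complex: every
#' (k+1)-clique of the support graph is a k-simplex. Vertices enter the
#' filtration at value 0, an edge at its weight (by default the absolute
#' coupling |J|), and every higher simplex at the maximum of its edges'
#' values, so the complex at threshold w is exactly the clique complex of
#' the subgraph of edges with value at most w (sublevel filtration: weak
#' couplings enter first, and raising the threshold from 0 adds ever
#' stronger links). Simplices are ordered by (value, dimension,
#' lexicographic vertices), which is face-consistent and deterministic.
#'
#' @param net an [InteractionNetwork-class].
#' @param maxDim dimension cap (default 3, so that void counts are exact).
#' @param weightTransform `"absolute"` (filter on |J|, the default) or
#'   `"raw"` (filter on J itself; negative weights are rejected).
#' @return a [Filtration-class].
#' @examples
#' filt <- buildCliqueFiltration(generateToyNetwork("cycle_4"))
#' filt
#' @export
buildCliqueFiltration <- function(net, maxDim = 3L,
                                  weightTransform = c("absolute", "raw")) {
  stopifnot(methods::is(net, "InteractionNetwork"))
  if (maxDim < 0L) stop("maxDim must be >= 0")
  maxDim <- as.integer(maxDim)
  vm <- .filtrationValues(net, match.arg(weightTransform))
  cc <- .cliqueComplex(vm, maxDim)
  ord <- .filtrationOrder(cc$simplices, cc$values, cc$dims, maxDim)
  new("Filtration",
      simplices = cc$simplices[ord],
      values = cc$values[ord],
      dims = cc$dims[ord],
      nodeCount = nrow(vm),
      maxDim = maxDim)
}

#' Boundary of a simplex
#'
#' The boundary operator maps a k-simplex \eqn{[v_0, \ldots, v_k]} to the
#' alternating sum of the k+1 facets obtained by deleting one vertex each.
#' Over Z2 every coefficient reduces to 1; the alternating labels are still
#' reported for reference.
#'
#' @param vertices strictly increasing integer vector (the simplex).
#' @return data-frame-free list: `facets` (list of integer vectors) and
#'   `signs` (the alternating \eqn{(-1)^i} labels); both empty for a vertex.
#' @examples
#' boundaryOf(c(0L, 1L, 2L))$facets   # the three edges of a triangle
#' @export
boundaryOf <- function(vertices) {
  vertices <- as.integer(vertices)
  if (is.unsorted(vertices, strictly = TRUE))
    stop("simplex vertices must be strictly increasing")
  k <- length(vertices) - 1L
  if (k < 1L) return(list(facets = list(), signs = integer()))
  facets <- lapply(seq_along(vertices), function(i) vertices[-i])
  list(facets = facets, signs = (-1L)^(seq_along(vertices) - 1L))
}

.simplexKeys <- function(simplices) {
  vapply(simplices, paste, character(1), collapse = ".")
}

# boundary columns (facet filtration indices) for every simplex; errors if
# the filtration is not face-closed
.boundaryColumns <- function(filt) {
  keys <- .simplexKeys(filt@simplices)
  idx <- stats::setNames(seq_along(keys), keys)
  lapply(seq_along(filt@simplices), function(j) {
    v <- filt@simplices[[j]]
    if (length(v) == 1L) return(integer())
    fk <- .simplexKeys(boundaryOf(v)$facets)
    fi <- idx[fk]
    if (any(is.na(fi)) || any(fi >= j))
      stop("filtration is not face-closed: simplex ", keys[j],
           " precedes one of its facets")
    sort(unname(fi))
  })
}

#' Persistent homology of a filtration over Z2
#'
#' Standard boundary-matrix column reduction in filtration order with Z2
#' coefficients. Each simplex either creates a homology class (positive) or
#' kills the youngest class among its facets' (negative); a pair (i, j)
#' yields one topological hole of dimension dim(i), born at the filtration
#' value of i and dying at that of j. Classes never killed are essential
#' (death = Inf). Zero-lifetime pairs — artifacts of simultaneous
#' insertions — are dropped and counted. Dimensions 0 .. maxDim-1 are
#' reported; classes of the cap dimension are suppressed since the truncated
#' complex cannot resolve them.
#'
#' @param filt a [Filtration-class]; face-closure is verified and violations
#'   rejected.
#' @return a [PersistenceDiagram-class]. Deterministic given the filtration.
#' @examples
#' pd <- computePersistence(buildCliqueFiltration(generateToyNetwork("octahedron")))
#' pd
#' @export
computePersistence <- function(filt) {
  stopifnot(methods::is(filt, "Filtration"))
  methods::validObject(filt)
  cols <- .boundaryColumns(filt)
  lows <- reduce_boundary(cols)
  n <- length(cols)
  dims <- filt@dims
  vals <- filt@values
  killer <- integer(n)                   # killer[i] = j if low(j) = i
  killed <- lows != 0L
  killer[lows[killed]] <- which(killed)
  positive <- which(!killed)
  birthIdx <- positive
  deathIdx <- killer[positive]           # 0 = essential
  birth <- vals[birthIdx]
  death <- ifelse(deathIdx == 0L, Inf, vals[ifelse(deathIdx == 0L, 1L, deathIdx)])
  dimk <- dims[birthIdx]
  keep <- dimk <= filt@maxDim - 1L
  pairs <- data.frame(dimension = dimk[keep], birth = birth[keep],
                      death = death[keep])
  pairs$lifetime <- pairs$death - pairs$birth
  dropped <- sum(pairs$lifetime == 0)
  pairs <- pairs[pairs$lifetime > 0, , drop = FALSE]
  ord <- order(pairs$dimension, pairs$birth, pairs$death)
  pairs <- pairs[ord, , drop = FALSE]
  rownames(pairs) <- NULL
  new("PersistenceDiagram", pairs = pairs, maxDim = filt@maxDim,
      nodeCount = filt@nodeCount, zeroLifetimeDropped = as.integer(dropped))
}

#' Z2 rank of a binary matrix by Gaussian elimination
#'
#' Independent small-scale linear algebra used by the static Betti oracle.
#'
#' @param m logical or 0/1 matrix.
#' @return integer rank over the field with two elements.
#' @export
z2Rank <- function(m) {
  if (length(m) == 0L) return(0L)
  m <- matrix(as.logical(m), nrow(m), ncol(m))
  rank <- 0L
  row <- 1L
  for (col in seq_len(ncol(m))) {
    piv <- which(m[row:nrow(m), col])[1]
    if (is.na(piv)) next
    piv <- piv + row - 1L
    if (piv != row) m[c(row, piv), ] <- m[c(piv, row), ]
    hit <- which(m[, col]); hit <- hit[hit != row]
    if (length(hit))
      m[hit, ] <- xor(m[hit, , drop = FALSE],
                      matrix(m[row, ], length(hit), ncol(m), byrow = TRUE))
    rank <- rank + 1L
    row <- row + 1L
    if (row > nrow(m)) break
  }
  rank
}

#' Static Betti numbers by dense Z2 rank computation (oracle)
#'
#' Brute-force reference independent of the reduction algorithm: builds the
#' clique complex of the thresholded graph, assembles dense Z2 boundary
#' matrices and returns \eqn{\beta_k = \dim C_k - \mathrm{rank}\,\partial_k
#' - \mathrm{rank}\,\partial_{k+1}} by Gaussian elimination. Intended for
#' small instances; a size guard rejects complexes that are too large.
#'
#' @param net an [InteractionNetwork-class].
#' @param threshold filtration weight; the complex contains all edges with
#'   value <= threshold.
#' @param maxDim dimension cap (default 3; Betti numbers 0 .. maxDim-1 are
#'   exact).
#' @param weightTransform as in [buildCliqueFiltration()].
#' @param sizeGuard maximum number of simplices the oracle accepts.
#' @return integer vector `c(b0, b1, ..., b_{maxDim-1})`.
#' @examples
#' bettiNumbersStatic(generateToyNetwork("cycle_4"), threshold = 1)  # 1, 1, 0
#' @export
bettiNumbersStatic <- function(net, threshold, maxDim = 3L,
                               weightTransform = c("absolute", "raw"),
                               sizeGuard = 20000L) {
  stopifnot(methods::is(net, "InteractionNetwork"))
  if (threshold < 0) stop("threshold must be >= 0")
  maxDim <- as.integer(maxDim)
  vm <- .filtrationValues(net, match.arg(weightTransform))
  cc <- .cliqueComplex(vm, maxDim, threshold = threshold)
  if (length(cc$simplices) > sizeGuard)
    stop("complex has ", length(cc$simplices),
         " simplices, exceeding the oracle size guard (", sizeGuard, ")")
  keys <- .simplexKeys(cc$simplices)
  counts <- integer(maxDim + 1L)
  for (k in 0:maxDim) counts[k + 1L] <- sum(cc$dims == k)
  ranks <- numeric(maxDim + 1L)        # ranks[k+1] = rank of boundary_k
  for (k in seq_len(maxDim)) {
    rows <- which(cc$dims == k - 1L)
    colsIdx <- which(cc$dims == k)
    if (length(rows) == 0L || length(colsIdx) == 0L) { ranks[k + 1L] <- 0; next }
    rowPos <- stats::setNames(seq_along(rows), keys[rows])
    Bm <- matrix(FALSE, length(rows), length(colsIdx))
    for (cj in seq_along(colsIdx)) {
      fk <- .simplexKeys(boundaryOf(cc$simplices[[colsIdx[cj]]])$facets)
      Bm[rowPos[fk], cj] <- TRUE
    }
    ranks[k + 1L] <- z2Rank(Bm)
  }
  beta <- integer(maxDim)
  for (k in 0:(maxDim - 1L)) {
    rkNext <- if (k + 1L <= maxDim) ranks[k + 2L] else 0
    beta[k + 1L] <- counts[k + 1L] - ranks[k + 1L] - rkNext
  }
  stats::setNames(beta, paste0("b", 0:(maxDim - 1L)))
}

#' Betti curves from persistence pairs
#'
#' Counts, at every grid threshold w, the pairs of each dimension alive at
#' w under the half-open convention birth <= w < death, so that beyond the
#' last finite death each curve equals the number of essential classes of
#' its dimension.
#'
#' @param pd a [PersistenceDiagram-class].
#' @param thresholds increasing grid; default the sorted distinct finite
#'   birth/death values of the diagram.
#' @return a [BettiCurve-class].
#' @examples
#' pd <- computePersistence(buildCliqueFiltration(generateToyNetwork("fig2_analog")))
#' bettiCurve(pd)
#' @export
bettiCurve <- function(pd, thresholds = NULL) {
  stopifnot(methods::is(pd, "PersistenceDiagram"))
  p <- pd@pairs
  if (is.null(thresholds)) {
    thresholds <- sort(unique(c(p$birth, p$death[is.finite(p$death)])))
    if (length(thresholds) == 0L) thresholds <- 0
  }
  if (length(thresholds) == 0L) stop("threshold grid must be nonempty")
  if (is.unsorted(thresholds, strictly = TRUE))
    stop("threshold grid must be strictly increasing")
  nd <- pd@maxDim
  beta <- matrix(0L, length(thresholds), nd,
                 dimnames = list(NULL, paste0("b", 0:(nd - 1L))))
  for (k in 0:(nd - 1L)) {
    pk <- p[p$dimension == k, , drop = FALSE]
    if (nrow(pk) == 0L) next
    beta[, k + 1L] <- vapply(thresholds, function(w)
      sum(pk$birth <= w & w < pk$death), integer(1))
  }
  new("BettiCurve", thresholds = as.numeric(thresholds), beta = beta)
}

#' Essential (survived) classes of a diagram
#'
#' Classes with death = Inf persist through the whole filtration: essential
#' components, loops, voids. The dimension-0 count equals the number of
#' connected components of the full network (1 iff it is path-connected).
#'
#' @param pd a [PersistenceDiagram-class].
#' @return list with `counts` (integer per dimension 0..maxDim-1) and
#'   `births` (list of birth values per dimension).
#' @examples
#' pd <- computePersistence(buildCliqueFiltration(generateToyNetwork("octahedron")))
#' essentialFeatures(pd)$counts   # 1 component, 0 loops, 1 void
#' @export
essentialFeatures <- function(pd) {
  stopifnot(methods::is(pd, "PersistenceDiagram"))
  p <- pd@pairs
  dimsOut <- 0:(pd@maxDim - 1L)
  counts <- integer(length(dimsOut))
  births <- vector("list", length(dimsOut))
  for (k in dimsOut) {
    ek <- p[p$dimension == k & is.infinite(p$death), , drop = FALSE]
    counts[k + 1L] <- nrow(ek)
    births[[k + 1L]] <- ek$birth
  }
  names(counts) <- names(births) <- paste0("dim", dimsOut)
  list(counts = counts, births = births)
}
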