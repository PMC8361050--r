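# Independent oracles used across the suite. These deliberately use naive
# algorithms (triple loops, exhaustive pair enumeration, proximal-gradient
# optimization) so they share no code path with the package implementations
# they check.

# exhaustive triple-loop triad census on a weight matrix
bruteTriadCensus <- function(W) {
  n <- nrow(W)
  rows <- list()
  for (i in seq_len(n)) for (j in seq_len(n)) for (k in seq_len(n)) {
    if (i < j && j < k &&
        W[i, j] != 0 && W[j, k] != 0 && W[k, i] != 0) {
      e <- W[i, j] * W[j, k] * W[k, i]
      rows[[length(rows) + 1L]] <- data.frame(
        i = i, j = j, k = k, energy = e,
        state = if (e > 0) "balanced" else "imbalanced")
    }
  }
  if (!length(rows))
    return(data.frame(i = integer(), j = integer(), k = integer(),
                      energy = numeric(), state = character()))
  do.call(rbind, rows)
}

# exhaustive quartic energy: all unordered pairs of distinct triangles,
# kept iff they share exactly one edge (on a simple graph two distinct
# triangles can share at most one)
bruteQuartic <- function(W, weighted = FALSE) {
  tc <- bruteTriadCensus(W)
  if (nrow(tc) < 2L) return(list(H = 0, s = 0))
  val <- if (weighted) tc$energy else sign(tc$energy)
  triEdges <- lapply(seq_len(nrow(tc)), function(r) {
    v <- c(tc$i[r], tc$j[r], tc$k[r])
    apply(utils::combn(v, 2L), 2L, function(e) paste(sort(e), collapse = "-"))
  })
  s <- 0
  for (a in seq_len(nrow(tc) - 1L)) for (b in (a + 1L):nrow(tc)) {
    shared <- length(intersect(triEdges[[a]], triEdges[[b]]))
    if (shared == 1L) s <- s + val[a] * val[b]
  }
  list(H = -s, s = s)
}

# random signed network weight matrix (distinct magnitudes wp 1)
randSignedWeights <- function(n, edgeProb = 0.5, negProb = 0.5) {
  W <- matrix(0, n, n)
  ut <- which(upper.tri(W))
  on <- runif(length(ut)) < edgeProb
  w <- runif(sum(on), 0.1, 1) * ifelse(runif(sum(on)) < negProb, -1, 1)
  W[ut[on]] <- w
  W + t(W)
}

randomNetwork <- function(n, edgeProb = 0.5, negProb = 0.5) {
  InteractionNetwork(randSignedWeights(n, edgeProb, negProb))
}

# FISTA proximal-gradient solver for the graphical lasso objective
#   -logdet(Theta) + tr(S Theta) + lambda * sum_offdiag |Theta_ij|
# (diagonal unpenalized). Independent of the block-coordinate-descent
# implementation; intended for small p only.
fistaGlasso <- function(S, lambda, maxIter = 50000L, objTol = 1e-13) {
  p <- nrow(S)
  smooth <- function(Th) {
    R <- tryCatch(chol(Th), error = function(e) NULL)
    if (is.null(R)) return(Inf)
    -2 * sum(log(diag(R))) + sum(S * Th)
  }
  penalty <- function(Th) lambda * 2 * sum(abs(Th[upper.tri(Th)]))
  prox <- function(Th, t) {
    off <- !diag(TRUE, p)
    Th[off] <- sign(Th[off]) * pmax(abs(Th[off]) - t * lambda, 0)
    Th
  }
  Th <- diag(1 / diag(S))
  Y <- Th
  tk <- 1
  step <- 1
  objOld <- smooth(Th) + penalty(Th)
  for (it in seq_len(maxIter)) {
    gY <- smooth(Y)
    if (!is.finite(gY)) { Y <- Th; tk <- 1; gY <- smooth(Y) }
    G <- S - chol2inv(chol(Y))
    repeat {
      Thn <- prox(Y - step * G, step)
      Thn <- (Thn + t(Thn)) / 2
      gN <- smooth(Thn)
      if (is.finite(gN) &&
          gN <= gY + sum(G * (Thn - Y)) + sum((Thn - Y)^2) / (2 * step) + 1e-15)
        break
      step <- step / 2
      if (step < 1e-14) break
    }
    tk1 <- (1 + sqrt(1 + 4 * tk^2)) / 2
    Y <- Thn + ((tk - 1) / tk1) * (Thn - Th)
    obj <- gN + penalty(Thn)
    if (obj > objOld) { Y <- Thn; tk1 <- 1 }   # restart on non-descent
    done <- abs(objOld - obj) < objTol && it > 10L
    Th <- Thn; tk <- tk1; objOld <- min(objOld, obj)
    if (done) break
    step <- min(step * 2, 1)
  }
  list(theta = Th, objective = objOld, iterations = it)
}

# random SPD covariance via a generated sparse precision
randSPDCovariance <- function(p, seed = NULL) {
  P <- generateSparsePrecision(p, 0.3, seed = seed)
  chol2inv(chol(P))
}

# support F1 between an estimated and a true precision matrix
supportF1 <- function(thetaHat, thetaTrue, eps = 1e-8) {
  est <- abs(thetaHat[upper.tri(thetaHat)]) > eps
  tru <- abs(thetaTrue[upper.tri(thetaTrue)]) > eps
  tp <- sum(est & tru)
  if (tp == 0L) return(0)
  2 * tp / (2 * tp + sum(est & !tru) + sum(!est & tru))
}

# number of k-simplices of a filtration present at threshold w
simplexCountsAt <- function(filt, w, maxDim) {
  vapply(0:maxDim, function(k)
    sum(filt@dims == k & filt@values <= w), integer(1))
}
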