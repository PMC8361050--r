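#' Sparse precision estimation by the graphical lasso
#'
#' Solves the l1-penalized Gaussian maximum-likelihood problem
#' \deqn{\min_{\Theta \succ 0} \; -\log\det\Theta + \mathrm{tr}(S\Theta)
#'       + \lambda \sum_{i \ne j} |\Theta_{ij}|}
#' by block coordinate descent over columns of the working covariance, each
#' column update an l1-regularized quadratic program solved by coordinate
#' descent. The diagonal is not penalized, so at the optimum
#' \eqn{\mathrm{diag}(\Theta^{-1}) = \mathrm{diag}(S)} and every off-diagonal
#' satisfies \eqn{|(\Theta^{-1} - S)_{ij}| \le \lambda}, with equality where
#' \eqn{\Theta_{ij} \ne 0}.
#'
#' @param S symmetric covariance (or correlation) matrix with positive
#'   diagonal.
#' @param lambda penalty, >= 0. At `lambda >=` max off-diagonal `|S|` the
#'   estimate is diagonal with \eqn{\Theta_{ii} = 1/S_{ii}}; at `lambda = 0`
#'   (S invertible) it is \eqn{S^{-1}}.
#' @param tol convergence tolerance: relative change of \eqn{\Theta} between
#'   sweeps.
#' @param maxIter maximum number of block sweeps.
#' @return list with elements `theta` (sparse SPD precision estimate),
#'   `lambda`, `iterations`, `converged`, `delta` (final relative change),
#'   `kkt` (the [kktOptimality()] summary of the returned estimate).
#'   Non-convergence is reported as a warning carrying the final gap.
#' @examples
#' S <- rbind(c(2, 0.4), c(0.4, 1))
#' fit <- graphicalLasso(S, lambda = 0.1)
#' fit$theta
#' @export
graphicalLasso <- function(S, lambda, tol = 1e-6, maxIter = 500L) {
  checkSymmetric(S, "S")
  if (any(diag(S) <= 0)) stop("S must have a strictly positive diagonal")
  if (lambda < 0) stop("lambda must be >= 0")
  if (tol <= 0) stop("tol must be positive")
  if (maxIter < 1L) stop("maxIter must be >= 1")
  p <- nrow(S)
  if (p == 1L) {
    theta <- matrix(1 / S[1, 1], dimnames = dimnames(S))
    return(list(theta = theta, lambda = lambda, iterations = 0L,
                converged = TRUE, delta = 0,
                kkt = kktOptimality(theta, S, lambda)))
  }
  S <- (S + t(S)) / 2
  res <- glasso_bcd(S, lambda, tol, as.integer(maxIter))
  theta <- (res$theta + t(res$theta)) / 2
  # preserve exact zeros lost by the symmetrization average
  theta[res$theta == 0 & t(res$theta) == 0] <- 0
  dimnames(theta) <- dimnames(S)
  if (!res$converged)
    warning(sprintf(
      "graphical lasso did not converge in %d sweeps (relative change %.3g)",
      maxIter, res$delta))
  list(theta = theta, lambda = lambda, iterations = res$iterations,
       converged = res$converged, delta = res$delta,
       kkt = kktOptimality(theta, S, lambda))
}

#' KKT optimality summary of a graphical-lasso estimate
#'
#' For the unpenalized-diagonal convention the stationarity conditions are
#' \eqn{(\Theta^{-1} - S)_{ii} = 0}, \eqn{|(\Theta^{-1} - S)_{ij}| \le
#' \lambda} off-diagonally, with \eqn{(\Theta^{-1} - S)_{ij} =
#' \lambda\,\mathrm{sign}(\Theta_{ij})} wherever \eqn{\Theta_{ij} \ne 0}.
#'
#' @param theta candidate precision matrix (SPD).
#' @param S the covariance matrix the fit used.
#' @param lambda the penalty used.
#' @return list: `maxViolation` (largest violation over all three condition
#'   groups), `offDiagonalBound`, `activeGap`, `diagonalGap`.
#' @export
kktOptimality <- function(theta, S, lambda) {
  checkSymmetric(theta, "theta")
  W <- chol2inv(chol(theta))
  G <- W - S
  p <- nrow(S)
  off <- upper.tri(S)
  diagGap <- if (p > 0) max(abs(diag(G))) else 0
  bound <- if (any(off)) max(0, max(abs(G[off])) - lambda) else 0
  act <- off & theta != 0
  activeGap <- if (any(act)) max(abs(G[act] - lambda * sign(theta[act]))) else 0
  list(maxViolation = max(diagGap, bound, activeGap),
       offDiagonalBound = bound, activeGap = activeGap, diagonalGap = diagGap)
}

#' Penalized negative log-likelihood objective of the graphical lasso
#'
#' \eqn{-\log\det\Theta + \mathrm{tr}(S\Theta) + \lambda\sum_{i\ne j}|\Theta_{ij}|}.
#'
#' @param theta SPD precision matrix.
#' @param S covariance matrix.
#' @param lambda penalty.
#' @return numeric objective value.
#' @export
glassoObjective <- function(theta, S, lambda) {
  R <- chol(theta)
  -2 * sum(log(diag(R))) + sum(S * theta) +
    lambda * sum(abs(theta[upper.tri(theta)])) * 2
}

#' Choose the graphical-lasso penalty by held-out likelihood
#'
#' The penalty is a free parameter of the method; this heuristic picks the
#' value maximizing the average held-out Gaussian log-likelihood
#' \eqn{\log\det\Theta - \mathrm{tr}(S_{test}\Theta)} over a log-spaced grid,
#' with deterministic interleaved sample folds.
#'
#' @param expr SummarizedExperiment or matrix, genes x samples.
#' @param grid candidate penalties; default 8 log-spaced values from
#'   `0.01 * lambdaMax` to `lambdaMax`, where `lambdaMax` is the largest
#'   off-diagonal `|S|` (full shrinkage point).
#' @param nFolds number of cross-validation folds (default 5).
#' @param tol,maxIter passed to [graphicalLasso()].
#' @return list: `lambda` (the selected value), `grid`, `heldOutLogLik`.
#' @export
selectLambda <- function(expr, grid = NULL, nFolds = 5L,
                         tol = 1e-4, maxIter = 200L) {
  m <- exprMatrix(expr)
  n <- ncol(m)
  if (n < 2L * nFolds) nFolds <- max(2L, n %/% 2L)
  Sfull <- estimateCovariance(m)@covariance
  if (is.null(grid)) {
    lmax <- max(abs(Sfull[upper.tri(Sfull)]))
    grid <- exp(seq(log(0.01 * lmax), log(lmax), length.out = 8L))
  }
  fold <- (seq_len(n) - 1L) %% nFolds + 1L
  mlCov <- function(x) {
    cc <- x - rowMeans(x)
    tcrossprod(cc) / ncol(x)
  }
  ll <- matrix(NA_real_, length(grid), nFolds)
  for (f in seq_len(nFolds)) {
    Ctr <- mlCov(m[, fold != f, drop = FALSE])
    Cte <- mlCov(m[, fold == f, drop = FALSE])
    for (g in seq_along(grid)) {
      fit <- suppressWarnings(graphicalLasso(Ctr, grid[g], tol = tol,
                                             maxIter = maxIter))
      R <- chol(fit$theta)
      ll[g, f] <- 2 * sum(log(diag(R))) - sum(Cte * fit$theta)
    }
  }
  avg <- rowMeans(ll)
  list(lambda = grid[which.max(avg)], grid = grid, heldOutLogLik = avg)
}
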