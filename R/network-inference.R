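#' RPKM-normalize a read-count matrix
#'
#' Reads Per Kilobase of transcript per Million mapped reads: normalizes each
#' count for the library size (its column sum) and the gene length,
#' \eqn{10^9 \cdot c_{gs} / (L_g \cdot N_s)} with \eqn{L_g} the gene length
#' in bp and \eqn{N_s} the column sum.
#'
#' @param counts non-negative count matrix, genes x samples.
#' @param geneLengths positive integer gene lengths in bp, aligned to rows.
#' @return a [SummarizedExperiment][SummarizedExperiment::SummarizedExperiment-class]
#'   of RPKM values.
#' @examples
#' counts <- matrix(c(10, 0, 5, 5), 2, 2)
#' rpkmNormalize(counts, geneLengths = c(1000, 2000))
#' @export
rpkmNormalize <- function(counts, geneLengths) {
  counts <- exprMatrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (length(geneLengths) != nrow(counts))
    stop("geneLengths must align with count rows")
  if (any(geneLengths <= 0)) stop("gene lengths must be positive")
  libSize <- colSums(counts)
  if (any(libSize == 0)) stop("every column (library) sum must be positive")
  vals <- 1e9 * sweep(counts / geneLengths, 2L, libSize, "/")
  ExpressionSE(vals, geneIds = rownames(counts), sampleIds = colnames(counts))
}

#' Per-gene expression variance
#'
#' Sample variance of each gene's expression across samples (ranking
#' statistic for [selectTopVarianceGenes()]).
#'
#' @param expr SummarizedExperiment or matrix, genes x samples.
#' @return named numeric vector of variances.
#' @export
geneVariances <- function(expr) {
  m <- exprMatrix(expr)
  apply(m, 1L, stats::var)
}

#' Keep the k most variable genes
#'
#' Computes each gene's expression variance over its samples and retains the
#' `k` genes of largest variance, rows ordered by descending variance (ties
#' broken by input order).
#'
#' @param expr SummarizedExperiment or matrix, genes x samples.
#' @param k number of genes to keep; must not exceed the number of genes
#'   with strictly positive variance.
#' @return a SummarizedExperiment with `k` rows.
#' @examples
#' m <- matrix(rnorm(50), 10, 5, dimnames = list(paste0("g", 1:10), NULL))
#' dim(selectTopVarianceGenes(m, 3))
#' @export
selectTopVarianceGenes <- function(expr, k) {
  m <- exprMatrix(expr)
  v <- apply(m, 1L, stats::var)
  nPos <- sum(v > 0)
  if (k < 1L || k > nPos)
    stop("k must be between 1 and the number of genes with positive variance (",
         nPos, ")")
  ord <- order(-v)           # stable: ties keep input order
  keep <- ord[seq_len(k)]
  gid <- rownames(m); if (is.null(gid)) gid <- paste0("g", seq_len(nrow(m)))
  sid <- colnames(m); if (is.null(sid)) sid <- paste0("s", seq_len(ncol(m)))
  ExpressionSE(m[keep, , drop = FALSE], geneIds = gid[keep], sampleIds = sid)
}

#' Maximum-likelihood covariance model of an expression matrix
#'
#' Per-gene means and the maximum-likelihood gene-gene covariance (divisor
#' n, not n-1), the moments the maximum-entropy Gaussian model matches to
#' the data. Genes with zero variance are removed with a warning, since they
#' make the covariance singular.
#'
#' @param expr SummarizedExperiment or matrix, genes x samples, >= 2 samples.
#' @return a [CovarianceModel-class].
#' @examples
#' m <- rbind(g1 = c(0, 2), g2 = c(0, 2))
#' estimateCovariance(m)
#' @export
estimateCovariance <- function(expr) {
  m <- exprMatrix(expr)
  if (ncol(m) < 2L)
    stop("covariance estimation needs at least 2 samples")
  gid <- rownames(m); if (is.null(gid)) gid <- paste0("g", seq_len(nrow(m)))
  v <- apply(m, 1L, stats::var)
  if (any(v == 0)) {
    warning("removing ", sum(v == 0), " zero-variance gene(s): ",
            paste(utils::head(gid[v == 0], 10L), collapse = ", "))
    m <- m[v > 0, , drop = FALSE]
    gid <- gid[v > 0]
  }
  if (nrow(m) == 0L) stop("no genes with positive variance")
  n <- ncol(m)
  mu <- rowMeans(m)
  centered <- m - mu
  C <- tcrossprod(centered) / n
  C <- (C + t(C)) / 2
  dimnames(C) <- list(gid, gid)
  new("CovarianceModel", geneIds = gid, mean = stats::setNames(mu, gid),
      covariance = C, nSamplesUsed = as.integer(n))
}

#' Couplings from a precision matrix
#'
#' The maximum-entropy pairwise model identifies the coupling between genes
#' i and j as minus the (i, j) entry of the inverse covariance (precision)
#' matrix: \eqn{J_{ij} = -\Theta_{ij}} for \eqn{i \ne j}, \eqn{J_{ii} = 0}.
#'
#' @param theta symmetric precision matrix (e.g. a [graphicalLasso()] fit).
#' @param geneIds identifiers, length matching `theta`; defaults to
#'   rownames or `g1..`.
#' @return an [InteractionNetwork-class].
#' @examples
#' th <- rbind(c(1, -0.5), c(-0.5, 1))
#' couplings(interactionsFromPrecision(th))[1, 2]   # +0.5
#' @export
interactionsFromPrecision <- function(theta, geneIds = NULL) {
  checkSymmetric(theta, "theta")
  if (!is.null(geneIds) && length(geneIds) != nrow(theta))
    stop("geneIds length must match precision dimension")
  J <- -theta
  diag(J) <- 0
  if (is.null(geneIds)) geneIds <- rownames(theta)
  InteractionNetwork(J, geneIds = geneIds)
}

#' Log-density of the fitted Gaussian model
#'
#' Evaluates the log of the multivariate Gaussian density
#' \deqn{P(s) = \frac{\exp[-\tfrac12 (s-\mu)^T C^{-1} (s-\mu)]}
#'                   {(2\pi)^{L/2} \det(C)^{1/2}}}
#' at a point `s`, with `L` the number of genes.
#'
#' @param model a [CovarianceModel-class] with invertible covariance.
#' @param s numeric vector of length L.
#' @return the log-density (numeric scalar).
#' @examples
#' mod <- new("CovarianceModel", geneIds = "g1", mean = c(g1 = 0),
#'            covariance = matrix(1, dimnames = list("g1", "g1")),
#'            nSamplesUsed = 10L)
#' modelLogDensity(mod, 0)   # log(1/sqrt(2*pi))
#' @export
modelLogDensity <- function(model, s) {
  stopifnot(methods::is(model, "CovarianceModel"))
  C <- model@covariance
  L <- nrow(C)
  if (length(s) != L) stop("s must have one entry per gene")
  R <- tryCatch(chol(C), error = function(e)
    stop("covariance is singular (not positive definite)"))
  d <- s - model@mean
  z <- backsolve(R, d, transpose = TRUE)
  -0.5 * sum(z^2) - (L / 2) * log(2 * pi) - sum(log(diag(R)))
}
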