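#' Wrap an expression matrix in a SummarizedExperiment
#'
#' Genes in rows, samples in columns, assay name `"expression"`. This is the
#' container every inference function in the package accepts.
#'
#' @param values numeric matrix, genes x samples, no missing values.
#' @param geneIds,sampleIds identifiers; defaults taken from dimnames or
#'   generated as `g1..` / `s1..`.
#' @return a [SummarizedExperiment][SummarizedExperiment::SummarizedExperiment-class].
#' @examples
#' se <- ExpressionSE(matrix(rnorm(20), 4, 5))
#' dim(se)
#' @export
ExpressionSE <- function(values, geneIds = NULL, sampleIds = NULL) {
  values <- as.matrix(values)
  if (any(is.na(values))) stop("expression values must not contain NA")
  if (is.null(geneIds))
    geneIds <- if (!is.null(rownames(values))) rownames(values)
               else paste0("g", seq_len(nrow(values)))
  if (is.null(sampleIds))
    sampleIds <- if (!is.null(colnames(values))) colnames(values)
                 else paste0("s", seq_len(ncol(values)))
  if (anyDuplicated(geneIds)) stop("gene identifiers must be unique")
  if (anyDuplicated(sampleIds)) stop("sample identifiers must be unique")
  dimnames(values) <- list(geneIds, sampleIds)
  SummarizedExperiment::SummarizedExperiment(assays = list(expression = values))
}

#' Generate a sparse signed symmetric positive-definite precision matrix
#'
#' Ground truth for the Gaussian model: off-diagonal support is drawn
#' Bernoulli(`edgeDensity`) per unordered pair, magnitudes uniform in
#' `[weightLow, weightHigh]`, signs negative with probability
#' `negativeFraction`. Each diagonal entry is set to the absolute sum of its
#' row's off-diagonals plus `diagonalBoost`, making the matrix strictly
#' diagonally dominant and hence symmetric positive definite for any support
#' and sign pattern.
#'
#' @param nGenes number of genes (>= 2).
#' @param edgeDensity edge probability, in (0, 1).
#' @param weightLow,weightHigh positive bounds on off-diagonal magnitudes.
#' @param negativeFraction probability a coupling is negative, in \[0, 1\].
#' @param diagonalBoost positive value added to each diagonal beyond the
#'   row absolute sum.
#' @param seed integer seed; identical seeds give identical matrices.
#' @return a symmetric positive-definite numeric matrix.
#' @examples
#' P <- generateSparsePrecision(10, 0.2, seed = 1)
#' min(eigen(P, symmetric = TRUE, only.values = TRUE)$values) > 0
#' @export
generateSparsePrecision <- function(nGenes, edgeDensity,
                                    weightLow = 0.2, weightHigh = 0.8,
                                    negativeFraction = 0.5,
                                    diagonalBoost = 1, seed = NULL) {
  if (nGenes < 2L) stop("nGenes must be at least 2")
  if (edgeDensity <= 0 || edgeDensity >= 1)
    stop("edgeDensity must lie strictly between 0 and 1")
  if (weightLow <= 0 || weightHigh < weightLow)
    stop("need 0 < weightLow <= weightHigh")
  if (negativeFraction < 0 || negativeFraction > 1)
    stop("negativeFraction must lie in [0, 1]")
  if (diagonalBoost <= 0) stop("diagonalBoost must be positive")
  withSeed(seed, {
    p <- as.integer(nGenes)
    P <- matrix(0, p, p)
    ut <- which(upper.tri(P))
    on <- runif(length(ut)) < edgeDensity
    mag <- runif(sum(on), weightLow, weightHigh)
    sgn <- ifelse(runif(sum(on)) < negativeFraction, -1, 1)
    P[ut[on]] <- mag * sgn
    P <- P + t(P)
    diag(P) <- rowSums(abs(P)) + diagonalBoost
    P
  })
}

#' Sample Gaussian expression with a known precision matrix
#'
#' Draws `nSamples` i.i.d. vectors from the multivariate Gaussian whose
#' covariance is the inverse of `precision` and whose mean is `mean`,
#' emulating expression levels under the pairwise maximum-entropy model.
#'
#' @param precision symmetric positive-definite matrix (genes x genes).
#' @param nSamples number of samples (columns) to draw, >= 1. A single
#'   sample is valid for sampling but unusable for covariance estimation.
#' @param mean per-gene mean vector, recycled scalar allowed (default 0).
#' @param seed integer seed for reproducibility.
#' @return a [SummarizedExperiment][SummarizedExperiment::SummarizedExperiment-class],
#'   genes x samples.
#' @examples
#' se <- sampleExpression(diag(3), 100, seed = 1)
#' dim(se)
#' @export
sampleExpression <- function(precision, nSamples, mean = 0, seed = NULL) {
  checkSymmetric(precision, "precision")
  if (!isSPD(precision)) stop("precision must be symmetric positive definite")
  if (nSamples < 1L) stop("nSamples must be >= 1")
  p <- nrow(precision)
  mu <- rep_len(mean, p)
  Sigma <- chol2inv(chol(precision))
  Sigma <- (Sigma + t(Sigma)) / 2
  vals <- withSeed(seed, t(MASS::mvrnorm(n = nSamples, mu = mu, Sigma = Sigma)))
  if (nSamples == 1L) vals <- matrix(vals, nrow = p)
  gid <- rownames(precision)
  if (is.null(gid)) gid <- paste0("g", seq_len(p))
  ExpressionSE(vals, geneIds = gid, sampleIds = paste0("s", seq_len(nSamples)))
}

# registry of deterministic toy networks with known homology
.toyRegistry <- local({
  cycleNet <- function(n) {
    w <- matrix(0, n, n)
    for (i in seq_len(n)) {
      j <- if (i == n) 1L else i + 1L
      w[i, j] <- w[j, i] <- 1
    }
    w
  }
  completeNet <- function(n) {
    w <- matrix(1, n, n); diag(w) <- 0; w
  }
  # octahedron = K_{2,2,2}: node i misses only its antipode i+3
  octaNet <- function() {
    w <- matrix(1, 6, 6); diag(w) <- 0
    for (i in 1:3) { w[i, i + 3] <- 0; w[i + 3, i] <- 0 }
    w
  }
  # octahedron plus two pendant 4-cycles hanging off vertex 1, all weights 1:
  # one component, two independent loops (the pendant cycles), one void
  fig1cNet <- function() {
    w <- matrix(0, 12, 12)
    w[1:6, 1:6] <- octaNet()
    link <- function(i, j) w[i, j] <<- w[j, i] <<- 1
    link(1, 7); link(7, 8); link(8, 9); link(9, 1)
    link(1, 10); link(10, 11); link(11, 12); link(12, 1)
    w
  }
  # 8 nodes, distinct weights; a 4-cycle filled by a chord (finite loop bar)
  # plus a chordless 4-cycle through the hub (essential loop)
  fig2Net <- function() {
    w <- matrix(0, 8, 8)
    link <- function(i, j, v) w[i, j] <<- w[j, i] <<- v
    link(1, 2, 0.10); link(2, 3, 0.20); link(3, 4, 0.30); link(4, 1, 0.40)
    link(1, 3, 0.50)                    # chord: fills the first loop
    link(1, 5, 0.60); link(5, 6, 0.70); link(6, 2, 0.80)
    link(7, 8, 0.90)                    # separate component for a while
    link(4, 7, 0.95)
    w
  }
  list(
    octahedron   = octaNet,
    fig1c_analog = fig1cNet,
    fig2_analog  = fig2Net
  )
})

#' Toy weighted networks with known homology
#'
#' Deterministic small fixtures: `"cycle_<n>"` (an n-cycle, unit weights),
#' `"complete_<n>"` (K_n, unit weights), `"octahedron"` (6 nodes, 12 unit
#' edges, clique complex a 2-sphere), `"fig1c_analog"` (the octahedron with
#' two edge-disjoint pendant 4-cycles attached at one vertex, all weights 1;
#' Betti vector (1, 2, 1)), and `"fig2_analog"` (an 8-node network with
#' distinct edge weights whose barcodes are nonempty in dimensions 0 and 1).
#'
#' @param name fixture identifier (see Details above).
#' @return an [InteractionNetwork-class].
#' @examples
#' generateToyNetwork("cycle_4")
#' generateToyNetwork("octahedron")
#' @export
generateToyNetwork <- function(name) {
  stopifnot(is.character(name), length(name) == 1L)
  if (grepl("^cycle_[0-9]+$", name)) {
    n <- as.integer(sub("^cycle_", "", name))
    if (n < 3L) stop("cycle fixtures need at least 3 nodes")
    w <- matrix(0, n, n)
    idx <- cbind(seq_len(n), c(seq_len(n)[-1], 1L))
    w[idx] <- 1; w[idx[, 2:1]] <- 1
    return(InteractionNetwork(w))
  }
  if (grepl("^complete_[0-9]+$", name)) {
    n <- as.integer(sub("^complete_", "", name))
    if (n < 1L) stop("complete fixtures need at least 1 node")
    w <- matrix(1, n, n); diag(w) <- 0
    return(InteractionNetwork(w))
  }
  maker <- .toyRegistry[[name]]
  if (is.null(maker))
    stop("unknown toy network '", name, "'; known: cycle_<n>, complete_<n>, ",
         paste(names(.toyRegistry), collapse = ", "))
  InteractionNetwork(maker())
}

#' Generate a matched cohort pair differing only in coupling-weight width
#'
#' Emulates the cancer-like vs normal-like contrast: two Gaussian cohorts
#' whose true precision matrices share the same off-diagonal support and sign
#' pattern, but whose coupling magnitudes are drawn from intervals of
#' different widths — a narrow interval for the "cancer-like" member and a
#' broad one for the "normal-like" member. With the weight width as the only
#' contrast, downstream topological differences are attributable to it.
#'
#' The defaults are the package's reference study conditions: 50 genes,
#' 2000 samples per cohort, support density 0.3, narrow magnitudes in
#' (0.1, 0.2), broad magnitudes in (0.1, 0.8). The support density is set
#' high enough that the inferred clique complexes carry two-dimensional
#' holes, the feature the cohort contrast is read off from; sparse random
#' supports yield flag complexes with no voids at all.
#'
#' @param nGenes genes per cohort.
#' @param nSamplesA,nSamplesB samples per cohort.
#' @param widthA,widthB numeric length-2 magnitude intervals for the two
#'   cohorts' off-diagonal couplings.
#' @param edgeDensity shared support density, in (0, 1).
#' @param negativeFraction shared probability of a negative coupling.
#' @param diagonalBoost diagonal dominance margin (see
#'   [generateSparsePrecision()]).
#' @param labels labels for the two cohorts.
#' @param seed integer seed; the pair is a deterministic function of it.
#' @return list of two [SyntheticCohort-class] objects, named by label.
#' @examples
#' pair <- generateCohortPair(nGenes = 10, nSamplesA = 50, nSamplesB = 50, seed = 1)
#' vapply(pair, function(ch) ch@label, character(1))
#' @export
generateCohortPair <- function(nGenes = 50, nSamplesA = 2000, nSamplesB = 2000,
                               widthA = c(0.1, 0.2), widthB = c(0.1, 0.8),
                               edgeDensity = 0.3, negativeFraction = 0.5,
                               diagonalBoost = 1,
                               labels = c("cancer-like", "normal-like"),
                               seed = NULL) {
  stopifnot(length(widthA) == 2L, length(widthB) == 2L,
            all(widthA > 0), all(widthB > 0),
            widthA[1] <= widthA[2], widthB[1] <= widthB[2],
            nGenes >= 2, nSamplesA >= 1, nSamplesB >= 1,
            length(labels) == 2L)
  withSeed(seed, {
    p <- as.integer(nGenes)
    support <- matrix(FALSE, p, p)
    ut <- which(upper.tri(support))
    support[ut] <- runif(length(ut)) < edgeDensity
    sgn <- matrix(1, p, p)
    sgn[ut] <- ifelse(runif(length(ut)) < negativeFraction, -1, 1)
    makePrec <- function(width) {
      P <- matrix(0, p, p)
      k <- sum(support[ut])
      P[ut[support[ut]]] <- runif(k, width[1], width[2]) * sgn[ut[support[ut]]]
      P <- P + t(P)
      diag(P) <- rowSums(abs(P)) + diagonalBoost
      P
    }
    precA <- makePrec(widthA)
    precB <- makePrec(widthB)
    exprA <- sampleExpression(precA, nSamplesA)
    exprB <- sampleExpression(precB, nSamplesB)
    out <- list(
      new("SyntheticCohort", expression = exprA, truePrecision = precA,
          label = labels[1]),
      new("SyntheticCohort", expression = exprB, truePrecision = precB,
          label = labels[2]))
    names(out) <- labels
    out
  })
}

#' Off-diagonal coupling weights of a precision matrix
#'
#' Convenience summary used when contrasting cohort weight distributions:
#' returns the nonzero off-diagonal entries, either signed (as couplings
#' J = -P would negate them, the width is identical) or in absolute value.
#'
#' @param precision symmetric matrix.
#' @param absolute return |weights| instead of signed values.
#' @return numeric vector, one entry per unordered pair with nonzero weight.
#' @export
precisionWeights <- function(precision, absolute = FALSE) {
  checkSymmetric(precision, "precision")
  w <- precision[upper.tri(precision)]
  w <- w[w != 0]
  if (absolute) abs(w) else w
}
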