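#' @import methods
#' @importFrom stats var sd quantile rnorm runif setNames
NULL

#' InteractionNetwork: a signed weighted gene interaction network
#'
#' Symmetric signed weighted coupling matrix \eqn{J} over a set of genes with
#' zero diagonal. The off-diagonal entries are the net pairwise couplings of
#' the maximum-entropy Gaussian model, \eqn{J_{ij} = -\Theta_{ij}} for a
#' precision matrix \eqn{\Theta}; a zero entry means "no interaction".
#'
#' @slot geneIds character vector of unique gene identifiers, one per node.
#' @slot weights numeric symmetric matrix with zero diagonal (couplings).
#'
#' @seealso [interactionsFromPrecision()], [generateToyNetwork()]
#' @exportClass InteractionNetwork
setClass("InteractionNetwork",
  representation(geneIds = "character", weights = "matrix"))

setValidity("InteractionNetwork", function(object) {
  w <- object@weights
  msgs <- character()
  if (nrow(w) != ncol(w)) msgs <- c(msgs, "weight matrix must be square")
  if (length(object@geneIds) != nrow(w))
    msgs <- c(msgs, "geneIds length must match weight matrix dimension")
  if (anyDuplicated(object@geneIds))
    msgs <- c(msgs, "geneIds must be unique")
  if (nrow(w) > 0L) {
    if (any(is.na(w))) msgs <- c(msgs, "weights must not contain NA")
    else {
      if (max(abs(w - t(w))) > 1e-10)
        msgs <- c(msgs, "weight matrix must be symmetric")
      if (any(diag(w) != 0))
        msgs <- c(msgs, "diagonal must be zero (no self-coupling)")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct an InteractionNetwork
#'
#' @param weights symmetric numeric matrix with zero diagonal. Small
#'   asymmetries (below `1e-10`) are symmetrized away.
#' @param geneIds character identifiers; defaults to rownames or `g1, g2, ...`.
#' @return An [InteractionNetwork-class] object.
#' @examples
#' net <- InteractionNetwork(rbind(c(0, 1), c(1, 0)))
#' sparsity(net)
#' @export
InteractionNetwork <- function(weights, geneIds = NULL) {
  weights <- as.matrix(weights)
  if (is.null(geneIds)) {
    geneIds <- rownames(weights)
    if (is.null(geneIds)) geneIds <- paste0("g", seq_len(nrow(weights)))
  }
  weights <- (weights + t(weights)) / 2
  diag(weights) <- 0
  dimnames(weights) <- list(geneIds, geneIds)
  new("InteractionNetwork", geneIds = as.character(geneIds), weights = weights)
}

#' CovarianceModel: fitted moments of the maximum-entropy Gaussian model
#'
#' Stores the per-gene means and the maximum-likelihood gene-gene covariance
#' estimated from an expression matrix. The model density is the multivariate
#' Gaussian with these moments; its normalizer is the closed-form
#' \eqn{(2\pi)^{L/2}\det(C)^{1/2}} and is not stored.
#'
#' @slot geneIds character gene identifiers.
#' @slot mean numeric per-gene sample mean.
#' @slot covariance numeric symmetric ML covariance matrix (divisor n).
#' @slot nSamplesUsed integer number of samples the fit used.
#' @exportClass CovarianceModel
setClass("CovarianceModel",
  representation(geneIds = "character", mean = "numeric",
                 covariance = "matrix", nSamplesUsed = "integer"))

setValidity("CovarianceModel", function(object) {
  C <- object@covariance
  msgs <- character()
  if (length(object@mean) != nrow(C) || nrow(C) != ncol(C))
    msgs <- c(msgs, "mean length and covariance dimensions must agree")
  if (length(object@geneIds) != nrow(C))
    msgs <- c(msgs, "geneIds length must match covariance dimension")
  if (nrow(C) > 0L) {
    if (max(abs(C - t(C))) > 1e-8) msgs <- c(msgs, "covariance must be symmetric")
    if (any(diag(C) <= 0))
      msgs <- c(msgs, "covariance diagonal must be strictly positive (zero-variance genes must be removed)")
  }
  if (length(msgs)) msgs else TRUE
})

#' SyntheticCohort: generated expression with known ground truth
#'
#' Couples a generated expression matrix (a
#' [SummarizedExperiment][SummarizedExperiment::SummarizedExperiment-class])
#' with the true sparse signed precision matrix it was sampled from, so that
#' inference can be scored against ground truth.
#'
#' @slot expression SummarizedExperiment, assay `"expression"`, genes in rows.
#' @slot truePrecision numeric symmetric positive-definite matrix.
#' @slot label free-text cohort label (e.g. `"cancer-like"`, `"normal-like"`).
#' @exportClass SyntheticCohort
setClass("SyntheticCohort",
  representation(expression = "ANY", truePrecision = "matrix", label = "character"))

setValidity("SyntheticCohort", function(object) {
  msgs <- character()
  if (!methods::is(object@expression, "SummarizedExperiment"))
    msgs <- c(msgs, "expression must be a SummarizedExperiment")
  else if (nrow(object@expression) != nrow(object@truePrecision))
    msgs <- c(msgs, "expression gene count must match precision dimension")
  if (nrow(object@truePrecision) != ncol(object@truePrecision))
    msgs <- c(msgs, "truePrecision must be square")
  if (length(msgs)) msgs else TRUE
})

#' Filtration: an ordered weighted clique complex
#'
#' A face-closed sequence of simplices of the weighted clique (flag) complex
#' of an interaction network, each with a filtration value. The order is
#' non-decreasing in value, then dimension, then lexicographic in vertices,
#' so the prefix at any threshold w is the clique complex of the subgraph of
#' edges with value at most w (sublevel filtration).
#'
#' @slot simplices list of strictly increasing integer vertex vectors.
#' @slot values numeric filtration value per simplex (vertices enter at 0).
#' @slot dims integer dimension per simplex (|vertices| - 1).
#' @slot nodeCount integer number of vertices of the underlying network.
#' @slot maxDim integer dimension cap used when the complex was built.
#' @seealso [buildCliqueFiltration()], [computePersistence()]
#' @exportClass Filtration
setClass("Filtration",
  representation(simplices = "list", values = "numeric", dims = "integer",
                 nodeCount = "integer", maxDim = "integer"))

setValidity("Filtration", function(object) {
  n <- length(object@simplices)
  msgs <- character()
  if (length(object@values) != n || length(object@dims) != n)
    msgs <- c(msgs, "simplices, values and dims must have equal length")
  if (n > 0L) {
    if (any(object@values < 0)) msgs <- c(msgs, "filtration values must be >= 0")
    if (is.unsorted(object@values))
      msgs <- c(msgs, "filtration values must be non-decreasing")
  }
  if (length(msgs)) msgs else TRUE
})

#' PersistenceDiagram: the persistence pairs of a filtration
#'
#' Each row of `pairs` is one topological hole: its dimension k (0 =
#' connected component, 1 = loop, 2 = void), the filtration weight at which
#' it appears (birth), the weight at which it is filled in (death, `Inf` for
#' essential classes that survive the whole filtration) and the lifetime
#' death - birth. Zero-lifetime pairs are dropped at construction and counted.
#'
#' @slot pairs data.frame with columns `dimension`, `birth`, `death`,
#'   `lifetime`.
#' @slot maxDim integer: dimensions 0 .. maxDim-1 are reported.
#' @slot nodeCount integer node count of the filtered network.
#' @slot zeroLifetimeDropped integer count of suppressed zero-lifetime pairs.
#' @seealso [computePersistence()], [bettiCurve()], [essentialFeatures()]
#' @exportClass PersistenceDiagram
setClass("PersistenceDiagram",
  representation(pairs = "data.frame", maxDim = "integer",
                 nodeCount = "integer", zeroLifetimeDropped = "integer"))

setValidity("PersistenceDiagram", function(object) {
  p <- object@pairs
  msgs <- character()
  need <- c("dimension", "birth", "death", "lifetime")
  if (!all(need %in% names(p)))
    msgs <- c(msgs, "pairs must have columns dimension, birth, death, lifetime")
  else if (nrow(p) > 0L) {
    if (any(p$death <= p$birth))
      msgs <- c(msgs, "stored pairs must have death > birth (zero-lifetime pairs are filtered)")
    if (any(p$dimension < 0 | p$dimension >= object@maxDim))
      msgs <- c(msgs, "pair dimensions must lie in 0 .. maxDim-1")
  }
  if (length(msgs)) msgs else TRUE
})

#' BettiCurve: Betti numbers along a threshold grid
#'
#' @slot thresholds increasing numeric grid of filtration weights.
#' @slot beta integer matrix, one row per threshold, columns `b0, b1, ...`;
#'   `beta[i, k+1]` is the number of k-dimensional holes alive at
#'   `thresholds[i]` (birth <= w < death convention).
#' @seealso [bettiCurve()]
#' @exportClass BettiCurve
setClass("BettiCurve",
  representation(thresholds = "numeric", beta = "matrix"))

setValidity("BettiCurve", function(object) {
  msgs <- character()
  if (length(object@thresholds) != nrow(object@beta))
    msgs <- c(msgs, "one beta row per threshold required")
  if (length(object@thresholds) > 1L && is.unsorted(object@thresholds, strictly = TRUE))
    msgs <- c(msgs, "thresholds must be strictly increasing")
  if (length(msgs)) msgs else TRUE
})

#' TriadCensus: closed signed triangles and their balance energies
#'
#' Enumerates every closed triangle (all three pairwise couplings nonzero)
#' of a signed network with its energy \eqn{E_{ijk} = J_{ij} J_{jk} J_{ki}}
#' and balance state (balanced iff the energy is positive). The total
#' balance energy is the triadic Hamiltonian \eqn{H = -\sum E_{ijk}}.
#'
#' @slot triads data.frame with columns `i`, `j`, `k` (node indices, i<j<k),
#'   `Jij`, `Jjk`, `Jki`, `energy`, `state` ("balanced"/"imbalanced"),
#'   `pattern` (sign pattern, one of `"+++"`, `"++-"`, `"+--"`, `"---"`).
#' @slot counts named integer vector of triangle counts by sign pattern.
#' @slot totalBalanceEnergy numeric, \eqn{-\sum E_{ijk}}.
#' @slot geneIds character node identifiers of the source network.
#' @seealso [enumerateTriads()], [quarticEnergy()]
#' @exportClass TriadCensus
setClass("TriadCensus",
  representation(triads = "data.frame", counts = "integer",
                 totalBalanceEnergy = "numeric", geneIds = "character"))

setValidity("TriadCensus", function(object) {
  msgs <- character()
  cn <- object@counts
  if (!identical(sort(names(cn)), sort(c("+++", "++-", "+--", "---"))))
    msgs <- c(msgs, "counts must be named with the four sign patterns")
  else if (sum(cn) != nrow(object@triads))
    msgs <- c(msgs, "pattern counts must sum to the number of triads")
  if (nrow(object@triads) > 0L) {
    bal <- object@triads$state == "balanced"
    if (!all(bal == (object@triads$energy > 0)))
      msgs <- c(msgs, "state must be balanced iff energy > 0")
  }
  if (length(msgs)) msgs else TRUE
})

#' CohortTopologyReport: full per-cohort analysis summary
#'
#' The result of [runCohort()]: the inferred network, balance census counts,
#' persistence diagram, Betti curves, weight-distribution summary, and the
#' scalar topological signatures used for cohort comparison.
#'
#' @slot label cohort label.
#' @slot network the inferred (or injected) [InteractionNetwork-class].
#' @slot census [TriadCensus-class] of the network.
#' @slot diagram [PersistenceDiagram-class].
#' @slot curve [BettiCurve-class] on the critical-value grid.
#' @slot weightSummary list: `breaks`, `counts`, `sd` (signed weights),
#'   `absQuantiles` (quantiles of |J|), `nEdges`.
#' @slot essentialCounts integer vector of essential class counts by
#'   dimension (components, loops, voids).
#' @slot beta0ConnectThreshold smallest w with a single component
#'   (`NA` when the full network is disconnected; see `connected`).
#' @slot beta1Onset smallest w with at least one loop (`NA` if none).
#' @slot beta2PlateauThreshold smallest w at which b2 attains its maximum.
#' @slot beta2Max maximum b2 over the grid.
#' @slot connected logical, whether the full network is path-connected.
#' @slot lambda numeric penalty actually used (NA for injected networks).
#' @slot config resolved configuration list (see [cohortConfig()]).
#' @exportClass CohortTopologyReport
setClass("CohortTopologyReport",
  representation(label = "character", network = "InteractionNetwork",
                 census = "TriadCensus", diagram = "PersistenceDiagram",
                 curve = "BettiCurve", weightSummary = "list",
                 essentialCounts = "integer",
                 beta0ConnectThreshold = "numeric", beta1Onset = "numeric",
                 beta2PlateauThreshold = "numeric", beta2Max = "numeric",
                 connected = "logical", lambda = "numeric", config = "list"))

#' ComparisonReport: two-cohort topological contrast
#'
#' Deltas (A minus B) of each scalar summary of two
#' [CohortTopologyReport-class]s built under identical configuration, plus
#' directional flags naming which cohort connects earlier, which carries more
#' essential loops/voids, and which saturates its void count earlier/lower.
#' Every flag is recomputable from the two reports.
#'
#' @slot reportA,reportB the two compared reports.
#' @slot deltas named numeric vector of summary differences (A - B).
#' @slot flags named character vector of directional flags (label or "tie").
#' @exportClass ComparisonReport
setClass("ComparisonReport",
  representation(reportA = "CohortTopologyReport",
                 reportB = "CohortTopologyReport",
                 deltas = "numeric", flags = "character"))
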