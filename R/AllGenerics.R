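#' Gene identifiers of an object
#' @param x an object carrying gene identifiers.
#' @return character vector.
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' Coupling matrix of a network
#' @param x an [InteractionNetwork-class].
#' @return the symmetric signed weight matrix J (zero diagonal).
#' @export
setGeneric("couplings", function(x) standardGeneric("couplings"))

#' Fraction of zero off-diagonal couplings
#' @param x an [InteractionNetwork-class].
#' @return numeric in \[0, 1\]; 1 for an empty network.
#' @export
setGeneric("sparsity", function(x) standardGeneric("sparsity"))

#' Number of nodes
#' @param x a network-like object.
#' @return integer node count.
#' @export
setGeneric("nNodes", function(x) standardGeneric("nNodes"))

#' Persistence pairs as a data frame
#' @param x a [PersistenceDiagram-class].
#' @return data.frame with columns dimension, birth, death, lifetime.
#' @export
setGeneric("persistencePairs", function(x) standardGeneric("persistencePairs"))

#' Triad table of a census
#' @param x a [TriadCensus-class].
#' @return data.frame, one row per closed triangle.
#' @export
setGeneric("triads", function(x) standardGeneric("triads"))

setMethod("geneIds", "InteractionNetwork", function(x) x@geneIds)
setMethod("geneIds", "CovarianceModel", function(x) x@geneIds)
setMethod("geneIds", "TriadCensus", function(x) x@geneIds)

setMethod("couplings", "InteractionNetwork", function(x) x@weights)

setMethod("sparsity", "InteractionNetwork", function(x) {
  p <- nrow(x@weights)
  if (p < 2L) return(1)
  nZeroOff <- sum(x@weights == 0) - p   # diagonal is always zero
  nZeroOff / (p * (p - 1L))
})

setMethod("nNodes", "InteractionNetwork", function(x) length(x@geneIds))
setMethod("nNodes", "Filtration", function(x) x@nodeCount)

setMethod("persistencePairs", "PersistenceDiagram", function(x) x@pairs)
setMethod("triads", "TriadCensus", function(x) x@triads)

#' Number of edges (nonzero couplings) of a network
#' @param x an [InteractionNetwork-class].
#' @return integer edge count.
#' @export
nEdges <- function(x) {
  stopifnot(methods::is(x, "InteractionNetwork"))
  sum(x@weights[upper.tri(x@weights)] != 0)
}

setMethod("show", "InteractionNetwork", function(object) {
  cat(sprintf("InteractionNetwork: %d genes, %d edges, sparsity %.3f\n",
              nNodes(object), nEdges(object), sparsity(object)))
  w <- object@weights[upper.tri(object@weights)]
  w <- w[w != 0]
  if (length(w))
    cat(sprintf("  weights: %d positive, %d negative, |J| in [%.4g, %.4g]\n",
                sum(w > 0), sum(w < 0), min(abs(w)), max(abs(w))))
})

setMethod("show", "CovarianceModel", function(object) {
  cat(sprintf("CovarianceModel: %d genes, fitted on %d samples\n",
              length(object@geneIds), object@nSamplesUsed))
})

setMethod("show", "SyntheticCohort", function(object) {
  cat(sprintf("SyntheticCohort '%s': %d genes x %d samples, true precision %dx%d\n",
              object@label, nrow(object@expression), ncol(object@expression),
              nrow(object@truePrecision), ncol(object@truePrecision)))
})

setMethod("show", "Filtration", function(object) {
  tab <- table(factor(object@dims, levels = 0:max(c(object@dims, 0L))))
  cat(sprintf("Filtration: %d simplices on %d nodes (maxDim %d)\n",
              length(object@simplices), object@nodeCount, object@maxDim))
  cat("  by dimension:", paste(sprintf("%s-simplices: %d", names(tab), tab),
                               collapse = ", "), "\n")
})

setMethod("show", "PersistenceDiagram", function(object) {
  p <- object@pairs
  cat(sprintf("PersistenceDiagram: %d pairs (%d zero-lifetime dropped)\n",
              nrow(p), object@zeroLifetimeDropped))
  for (k in 0:(object@maxDim - 1L)) {
    pk <- p[p$dimension == k, , drop = FALSE]
    cat(sprintf("  dim %d: %d pairs, %d essential\n",
                k, nrow(pk), sum(is.infinite(pk$death))))
  }
})

setMethod("show", "BettiCurve", function(object) {
  cat(sprintf("BettiCurve: %d thresholds in [%.4g, %.4g]\n",
              length(object@thresholds),
              min(object@thresholds), max(object@thresholds)))
  last <- object@beta[nrow(object@beta), ]
  cat("  final Betti numbers:", paste(colnames(object@beta), last,
                                      sep = " = ", collapse = ", "), "\n")
})

setMethod("show", "TriadCensus", function(object) {
  cat(sprintf("TriadCensus: %d closed triangles (%d balanced, %d imbalanced)\n",
              nrow(object@triads),
              sum(object@triads$state == "balanced"),
              sum(object@triads$state == "imbalanced")))
  cat("  by sign pattern:",
      paste(names(object@counts), object@counts, sep = ": ", collapse = ", "), "\n")
  cat(sprintf("  triadic Hamiltonian H = %.6g\n", object@totalBalanceEnergy))
})

setMethod("show", "CohortTopologyReport", function(object) {
  cat(sprintf("CohortTopologyReport '%s'\n", object@label))
  cat(sprintf("  network: %d genes, %d edges; lambda = %s\n",
              nNodes(object@network), nEdges(object@network),
              format(object@lambda)))
  cat(sprintf("  essential classes (components, loops, voids): %s\n",
              paste(object@essentialCounts, collapse = ", ")))
  cat(sprintf("  beta0 connect at %s | beta1 onset at %s | beta2 plateau %s (max %d)\n",
              format(object@beta0ConnectThreshold),
              format(object@beta1Onset),
              format(object@beta2PlateauThreshold),
              as.integer(object@beta2Max)))
})

setMethod("show", "ComparisonReport", function(object) {
  cat(sprintf("ComparisonReport: '%s' vs '%s'\n",
              object@reportA@label, object@reportB@label))
  for (nm in names(object@flags))
    cat(sprintf("  %s: %s\n", nm, object@flags[[nm]]))
})
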