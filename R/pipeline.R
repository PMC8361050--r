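#' Analysis configuration for the cohort pipeline
#'
#' Collects the tunable parameters of the end-to-end analysis. `topK` is the
#' variance filter size (483 by default, capped at the number of available
#' positive-variance genes); `lambda = NULL` requests the held-out
#' likelihood heuristic of [selectLambda()].
#'
#' @param topK number of most-variable genes to keep.
#' @param lambda graphical-lasso penalty, or `NULL` to select it by
#'   held-out likelihood.
#' @param tol,maxIter graphical-lasso convergence controls.
#' @param maxDim filtration dimension cap (3 keeps void counts exact).
#' @param weightTransform `"absolute"` or `"raw"` filtration values.
#' @param bins histogram bin count for weight and energy summaries.
#' @param seed integer seed recorded with the run (the pipeline itself is
#'   deterministic; the seed matters when the input is generated).
#' @return a named configuration list.
#' @export
cohortConfig <- function(topK = 483L, lambda = NULL, tol = 1e-6,
                         maxIter = 500L, maxDim = 3L,
                         weightTransform = "absolute", bins = 30L,
                         seed = NULL) {
  list(topK = as.integer(topK), lambda = lambda, tol = tol,
       maxIter = as.integer(maxIter), maxDim = as.integer(maxDim),
       weightTransform = match.arg(weightTransform, c("absolute", "raw")),
       bins = as.integer(bins), seed = seed)
}

#' Histogram and spread of network coupling weights
#'
#' Summarizes the signed weights of the present (nonzero) edges: binned
#' counts, the population standard deviation, and quantiles of the absolute
#' weights. The width of this distribution is the contrast the synthetic
#' cohort pairs are built around (narrow = cancer-like, broad =
#' normal-like).
#'
#' @param net an [InteractionNetwork-class].
#' @param bins bin count (breaks span the weight range).
#' @return list: `breaks`, `mids`, `counts`, `sd` (population sd of the
#'   signed weights, 0 for a single edge), `absQuantiles`, `nEdges`.
#' @export
weightHistogram <- function(net, bins = 30L) {
  stopifnot(methods::is(net, "InteractionNetwork"))
  if (length(bins) != 1L || !is.finite(bins) || bins < 1) stop("invalid bins")
  W <- couplings(net)
  w <- W[upper.tri(W)]
  w <- w[w != 0]
  if (length(w) == 0L)
    return(list(breaks = numeric(), mids = numeric(), counts = integer(),
                sd = NA_real_, absQuantiles = NULL, nEdges = 0L))
  rng <- range(w)
  if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
  breaks <- seq(rng[1], rng[2], length.out = as.integer(bins) + 1L)
  counts <- tabulate(findInterval(w, breaks, rightmost.closed = TRUE,
                                  all.inside = TRUE),
                     nbins = length(breaks) - 1L)
  list(breaks = breaks, mids = (breaks[-1] + breaks[-length(breaks)]) / 2,
       counts = counts,
       sd = sqrt(mean((w - mean(w))^2)),
       absQuantiles = stats::quantile(abs(w), c(0.25, 0.5, 0.75, 0.9, 1)),
       nEdges = length(w))
}

# scalar signatures extracted from a Betti curve on its critical grid
.curveSignatures <- function(curve, essentialCounts) {
  th <- curve@thresholds
  b <- curve@beta
  connected <- essentialCounts[1L] == 1L
  beta0Connect <- if (connected && any(b[, "b0"] == 1L))
    th[which(b[, "b0"] == 1L)[1L]] else NA_real_
  beta1Onset <- if (ncol(b) >= 2L && any(b[, "b1"] > 0L))
    th[which(b[, "b1"] > 0L)[1L]] else NA_real_
  if (ncol(b) >= 3L) {
    b2max <- max(b[, "b2"])
    beta2Plateau <- th[which(b[, "b2"] == b2max)[1L]]
  } else {
    b2max <- 0; beta2Plateau <- NA_real_
  }
  list(connected = connected, beta0Connect = beta0Connect,
       beta1Onset = beta1Onset, beta2Plateau = beta2Plateau,
       beta2Max = as.numeric(b2max))
}

#' Run the full single-cohort analysis
#'
#' Executes the pipeline on one cohort: variance filter, maximum-likelihood
#' covariance, graphical lasso, couplings J, balance census, weighted clique
#' filtration, Z2 persistence, Betti curves and scalar summaries. Accepts a
#' [SyntheticCohort-class], a SummarizedExperiment or matrix of expression,
#' a path to an expression TSV, or — for toy analyses — an
#' [InteractionNetwork-class] directly (the inference stages are then
#' skipped). With `outDir` set, all intermediates (edge list, census,
#' persistence pairs, Betti curve, summary JSON, resolved configuration)
#' are written there.
#'
#' @param x the cohort input (see Description).
#' @param config a [cohortConfig()] list.
#' @param label cohort label (defaults to the SyntheticCohort label or
#'   `"cohort"`).
#' @param outDir optional output directory for intermediates.
#' @param verbose emit per-stage progress messages.
#' @return a [CohortTopologyReport-class].
#' @examples
#' rep <- runCohort(generateToyNetwork("octahedron"), verbose = FALSE)
#' rep@essentialCounts
#' @export
runCohort <- function(x, config = cohortConfig(), label = NULL,
                      outDir = NULL, verbose = TRUE) {
  t0 <- Sys.time()
  lambdaUsed <- NA_real_
  if (methods::is(x, "SyntheticCohort")) {
    if (is.null(label)) label <- x@label
    x <- x@expression
  }
  if (is.null(label)) label <- "cohort"
  if (is.character(x) && length(x) == 1L) {
    infoLog(verbose, "[%s] reading expression from %s", label, x)
    x <- readExpressionTSV(x)
  }
  if (methods::is(x, "InteractionNetwork")) {
    net <- x
    infoLog(verbose, "[%s] injected network: %d genes, %d edges",
            label, nNodes(net), nEdges(net))
  } else {
    m <- exprMatrix(x)
    infoLog(verbose, "[%s] expression: %d genes x %d samples",
            label, nrow(m), ncol(m))
    nPos <- sum(apply(m, 1L, stats::var) > 0)
    k <- min(config$topK, nPos)
    if (k < config$topK)
      infoLog(verbose,
              "[%s] variance filter capped at %d available genes", label, k)
    expr <- selectTopVarianceGenes(m, k)
    model <- estimateCovariance(expr)
    lambdaUsed <- if (is.null(config$lambda)) {
      sel <- selectLambda(expr)
      infoLog(verbose, "[%s] lambda selected by held-out likelihood: %.5g",
              label, sel$lambda)
      sel$lambda
    } else config$lambda
    fit <- graphicalLasso(model@covariance, lambdaUsed,
                          tol = config$tol, maxIter = config$maxIter)
    infoLog(verbose,
            "[%s] graphical lasso: %d sweeps, KKT violation %.3g",
            label, fit$iterations, fit$kkt$maxViolation)
    net <- interactionsFromPrecision(fit$theta, geneIds = geneIds(model))
    infoLog(verbose, "[%s] network: %d edges, sparsity %.3f",
            label, nEdges(net), sparsity(net))
  }
  census <- enumerateTriads(net)
  infoLog(verbose, "[%s] balance: %d closed triangles (%d imbalanced)",
          label, nrow(census@triads),
          sum(census@triads$state == "imbalanced"))
  filt <- buildCliqueFiltration(net, maxDim = config$maxDim,
                                weightTransform = config$weightTransform)
  infoLog(verbose, "[%s] filtration: %d simplices", label,
          length(filt@simplices))
  pd <- computePersistence(filt)
  if (pd@zeroLifetimeDropped > 0L)
    infoLog(verbose, "[%s] dropped %d zero-lifetime pairs", label,
            pd@zeroLifetimeDropped)
  curve <- bettiCurve(pd)
  ess <- essentialFeatures(pd)$counts
  sig <- .curveSignatures(curve, ess)
  wh <- weightHistogram(net, bins = config$bins)
  report <- new("CohortTopologyReport",
                label = label, network = net, census = census, diagram = pd,
                curve = curve, weightSummary = wh,
                essentialCounts = as.integer(ess),
                beta0ConnectThreshold = sig$beta0Connect,
                beta1Onset = sig$beta1Onset,
                beta2PlateauThreshold = sig$beta2Plateau,
                beta2Max = sig$beta2Max,
                connected = sig$connected,
                lambda = lambdaUsed, config = config)
  if (!is.null(outDir)) writeCohortReport(report, outDir)
  infoLog(verbose, "[%s] done in %.2f s", label,
          as.numeric(difftime(Sys.time(), t0, units = "secs")))
  report
}

#' Persist all intermediates of a cohort report
#'
#' Writes the edge list (+ metadata sidecar), triad census, persistence
#' pairs, Betti curve, a JSON summary of the scalar signatures, and the
#' resolved configuration into `outDir` with deterministic names prefixed
#' by the cohort label.
#'
#' @param report a [CohortTopologyReport-class].
#' @param outDir output directory (created if missing).
#' @return named character vector of written paths, invisibly.
#' @export
writeCohortReport <- function(report, outDir) {
  stopifnot(methods::is(report, "CohortTopologyReport"))
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  pre <- file.path(outDir, gsub("[^A-Za-z0-9_.-]", "_", report@label))
  paths <- c(network = paste0(pre, "_network.tsv"),
             census = paste0(pre, "_census.csv"),
             pairs = paste0(pre, "_pairs.csv"),
             betti = paste0(pre, "_betti.csv"),
             summary = paste0(pre, "_summary.json"),
             config = paste0(pre, "_config.txt"))
  writeEdgeList(report@network, paths["network"],
                meta = list(lambda = report@lambda,
                            tol = report@config$tol,
                            n_genes = nNodes(report@network)))
  writeCensus(report@census, paths["census"],
              quartic = quarticEnergy(report@network))
  writePersistencePairs(report@diagram, paths["pairs"])
  writeBettiCurve(report@curve, paths["betti"])
  jsonlite::write_json(cohortSummaryList(report), paths["summary"],
                       auto_unbox = TRUE, digits = NA)
  cfg <- report@config
  cfgLines <- vapply(names(cfg), function(k)
    paste0(k, "\t", if (is.null(cfg[[k]])) "NULL" else format(cfg[[k]])),
    character(1))
  writeLines(c(paste0("label\t", report@label),
               paste0("lambda_used\t", format(report@lambda, digits = 17L)),
               cfgLines), paths["config"])
  invisible(paths)
}

#' Scalar summary of a cohort report as a plain list
#'
#' @param report a [CohortTopologyReport-class].
#' @return named list of the comparison statistics.
#' @export
cohortSummaryList <- function(report) {
  list(label = report@label,
       nGenes = nNodes(report@network),
       nEdges = nEdges(report@network),
       weightSd = report@weightSummary$sd,
       connected = report@connected,
       essentialComponents = report@essentialCounts[1L],
       essentialLoops = report@essentialCounts[2L],
       essentialVoids = report@essentialCounts[3L],
       beta0ConnectThreshold = report@beta0ConnectThreshold,
       beta1Onset = report@beta1Onset,
       beta2PlateauThreshold = report@beta2PlateauThreshold,
       beta2Max = report@beta2Max,
       lambda = report@lambda)
}

#' Compare two cohort reports
#'
#' Computes per-statistic deltas (A minus B) and the directional flags of
#' the cohort contrast: which cohort becomes path-connected at a smaller
#' threshold, which carries more essential loops / voids, and which
#' saturates its void curve earlier and lower. Both reports must have been
#' built with identical configuration.
#'
#' @param reportA,reportB two [CohortTopologyReport-class] objects.
#' @return a [ComparisonReport-class].
#' @export
compareCohorts <- function(reportA, reportB) {
  stopifnot(methods::is(reportA, "CohortTopologyReport"),
            methods::is(reportB, "CohortTopologyReport"))
  ca <- reportA@config; cb <- reportB@config
  ca$seed <- cb$seed <- NULL
  if (!identical(ca, cb))
    stop("reports were built with different configurations")
  sa <- cohortSummaryList(reportA); sb <- cohortSummaryList(reportB)
  nums <- c("nEdges", "weightSd", "essentialComponents", "essentialLoops",
            "essentialVoids", "beta0ConnectThreshold", "beta1Onset",
            "beta2PlateauThreshold", "beta2Max")
  deltas <- vapply(nums, function(k) {
    a <- sa[[k]]; b <- sb[[k]]
    if (is.null(a) || is.null(b)) NA_real_ else as.numeric(a) - as.numeric(b)
  }, numeric(1))
  dirFlag <- function(a, b, smallerWins = TRUE) {
    if (is.na(a) || is.na(b)) return("undefined")
    if (a == b) return("tie")
    winner <- if ((a < b) == smallerWins) reportA@label else reportB@label
    winner
  }
  flags <- c(
    connectsEarlier = dirFlag(sa$beta0ConnectThreshold, sb$beta0ConnectThreshold),
    loopOnsetEarlier = dirFlag(sa$beta1Onset, sb$beta1Onset),
    moreEssentialLoops = dirFlag(sa$essentialLoops, sb$essentialLoops,
                                 smallerWins = FALSE),
    moreEssentialVoids = dirFlag(sa$essentialVoids, sb$essentialVoids,
                                 smallerWins = FALSE),
    beta2SaturatesEarlier = dirFlag(sa$beta2PlateauThreshold,
                                    sb$beta2PlateauThreshold),
    beta2SaturatesLower = dirFlag(sa$beta2Max, sb$beta2Max))
  new("ComparisonReport", reportA = reportA, reportB = reportB,
      deltas = deltas, flags = flags)
}
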