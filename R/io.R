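#' Read / write expression matrices as tab-separated text
#'
#' The on-disk format is a TSV whose first column holds gene identifiers and
#' whose header row holds sample identifiers.
#'
#' @param expr SummarizedExperiment or matrix, genes x samples.
#' @param path file path.
#' @return `writeExpressionTSV` returns the path invisibly;
#'   `readExpressionTSV` returns a
#'   [SummarizedExperiment][SummarizedExperiment::SummarizedExperiment-class].
#' @export
writeExpressionTSV <- function(expr, path) {
  m <- exprMatrix(expr)
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeExpressionTSV
#' @export
readExpressionTSV <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  ExpressionSE(m, geneIds = df[[1L]], sampleIds = colnames(df)[-1L])
}

#' Read / write networks as signed edge lists
#'
#' TSV with columns `gene_i`, `gene_j`, `weight` (signed, full precision),
#' one row per unordered pair with nonzero coupling, i before j in gene-ID
#' order. A sidecar `<path>.meta` records the full gene set (so isolated
#' genes survive the round trip) and any provenance values supplied in
#' `meta` (e.g. lambda, tol, n_samples).
#'
#' @param net an [InteractionNetwork-class].
#' @param path file path for the edge list.
#' @param meta named list of scalar provenance values for the sidecar.
#' @return `writeEdgeList` returns the path invisibly; `readEdgeList`
#'   returns an [InteractionNetwork-class].
#' @export
writeEdgeList <- function(net, path, meta = list()) {
  stopifnot(methods::is(net, "InteractionNetwork"))
  W <- couplings(net)
  idx <- which(upper.tri(W) & W != 0, arr.ind = TRUE)
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  df <- data.frame(gene_i = geneIds(net)[idx[, 1L]],
                   gene_j = geneIds(net)[idx[, 2L]],
                   weight = format(W[idx], digits = 17L, trim = TRUE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  lines <- c(paste0("genes\t", paste(geneIds(net), collapse = ",")),
             paste0("n_genes\t", length(geneIds(net))),
             vapply(names(meta), function(k)
               paste0(k, "\t", format(meta[[k]], digits = 17L)),
               character(1)))
  writeLines(lines, paste0(path, ".meta"))
  invisible(path)
}

#' @param geneIds optional explicit gene set for `readEdgeList`; by default
#'   taken from the sidecar, falling back to the genes present in the edges.
#' @rdname writeEdgeList
#' @export
readEdgeList <- function(path, geneIds = NULL) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c("character", "character", "numeric"),
                          stringsAsFactors = FALSE)
  metaPath <- paste0(path, ".meta")
  if (is.null(geneIds) && file.exists(metaPath)) {
    lines <- readLines(metaPath)
    g <- grep("^genes\t", lines, value = TRUE)
    if (length(g)) geneIds <- strsplit(sub("^genes\t", "", g[1]), ",")[[1]]
  }
  if (is.null(geneIds))
    geneIds <- sort(unique(c(df$gene_i, df$gene_j)))
  p <- length(geneIds)
  W <- matrix(0, p, p, dimnames = list(geneIds, geneIds))
  if (nrow(df)) {
    ii <- match(df$gene_i, geneIds)
    jj <- match(df$gene_j, geneIds)
    if (any(is.na(ii)) || any(is.na(jj)))
      stop("edge list references genes absent from the gene set")
    W[cbind(ii, jj)] <- df$weight
    W[cbind(jj, ii)] <- df$weight
  }
  InteractionNetwork(W, geneIds = geneIds)
}

#' Read / write persistence pairs as CSV
#'
#' Columns `dimension`, `birth`, `death`, `lifetime`, full precision, with
#' the literal `inf` marking essential classes.
#'
#' @param pd a [PersistenceDiagram-class].
#' @param path file path.
#' @return `writePersistencePairs` returns the path invisibly;
#'   `readPersistencePairs` returns the pairs data.frame (with an attribute
#'   `meta` carrying maxDim, nodeCount, zeroLifetimeDropped).
#' @export
writePersistencePairs <- function(pd, path) {
  stopifnot(methods::is(pd, "PersistenceDiagram"))
  p <- pd@pairs
  fmt <- function(x) ifelse(is.infinite(x), "inf", format(x, digits = 17L,
                                                          trim = TRUE))
  df <- data.frame(dimension = p$dimension, birth = fmt(p$birth),
                   death = fmt(p$death), lifetime = fmt(p$lifetime))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# maxDim=%d nodeCount=%d zeroLifetimeDropped=%d",
                     pd@maxDim, pd@nodeCount, pd@zeroLifetimeDropped), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writePersistencePairs
#' @export
readPersistencePairs <- function(path) {
  header <- readLines(path, n = 1L)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  for (col in c("birth", "death", "lifetime"))
    df[[col]] <- ifelse(df[[col]] == "inf", Inf, suppressWarnings(as.numeric(df[[col]])))
  meta <- list()
  if (startsWith(header, "#")) {
    kv <- regmatches(header, gregexpr("[a-zA-Z]+=[0-9]+", header))[[1]]
    for (pair in kv) {
      parts <- strsplit(pair, "=")[[1]]
      meta[[parts[1]]] <- as.integer(parts[2])
    }
  }
  attr(df, "meta") <- meta
  df
}

#' Rebuild a PersistenceDiagram from a pairs CSV
#'
#' @param path a file written by [writePersistencePairs()].
#' @return a [PersistenceDiagram-class].
#' @export
loadPersistenceDiagram <- function(path) {
  df <- readPersistencePairs(path)
  meta <- attr(df, "meta")
  attr(df, "meta") <- NULL
  new("PersistenceDiagram", pairs = df,
      maxDim = as.integer(meta$maxDim %||% (max(df$dimension, 0L) + 1L)),
      nodeCount = as.integer(meta$nodeCount %||% NA_integer_),
      zeroLifetimeDropped = as.integer(meta$zeroLifetimeDropped %||% 0L))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a Betti curve as CSV
#'
#' Columns `threshold`, `b0`, `b1`, ... at full precision.
#'
#' @param curve a [BettiCurve-class].
#' @param path file path.
#' @return the path, invisibly (`readBettiCurve` returns a [BettiCurve-class]).
#' @export
writeBettiCurve <- function(curve, path) {
  stopifnot(methods::is(curve, "BettiCurve"))
  df <- data.frame(threshold = format(curve@thresholds, digits = 17L,
                                      trim = TRUE), curve@beta,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeBettiCurve
#' @export
readBettiCurve <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  beta <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(beta) <- "integer"
  new("BettiCurve", thresholds = as.numeric(df$threshold), beta = beta)
}

#' Write a triad census as CSV plus a JSON summary
#'
#' The CSV holds one row per closed triangle (i, j, k, weights, energy,
#' state, pattern); the JSON summary holds the pattern counts, the triadic
#' Hamiltonian and the quartic energy.
#'
#' @param census a [TriadCensus-class].
#' @param path CSV path; the summary goes to `<path>.summary.json`.
#' @param quartic optional result of [quarticEnergy()] to include.
#' @return the path, invisibly.
#' @export
writeCensus <- function(census, path, quartic = NULL) {
  stopifnot(methods::is(census, "TriadCensus"))
  utils::write.csv(census@triads, path, row.names = FALSE, quote = FALSE)
  summary <- list(nTriads = nrow(census@triads),
                  counts = as.list(census@counts),
                  totalBalanceEnergy = census@totalBalanceEnergy)
  if (!is.null(quartic)) summary <- c(summary, quartic[c("H", "s")])
  jsonlite::write_json(summary, paste0(path, ".summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
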