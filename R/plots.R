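#' @importFrom grDevices pdf dev.off
#' @importFrom graphics abline arrows axis hist legend lines plot points
#'   segments barplot par
NULL

.dimCols <- c("black", "darkorange2", "steelblue3")

#' Persistence diagram plot
#'
#' Birth-death scatter, one symbol per dimension (components, loops,
#' voids); essential classes are drawn on a dashed horizontal marker line
#' above the largest finite death.
#'
#' @param pd a [PersistenceDiagram-class].
#' @param main plot title.
#' @return invisibly, the number of points drawn.
#' @export
plotPersistenceDiagram <- function(pd, main = "Persistence diagram") {
  p <- pd@pairs
  finiteMax <- if (any(is.finite(p$death))) max(p$death[is.finite(p$death)])
               else max(p$birth, 1)
  essY <- finiteMax * 1.1 + 1e-9
  lim <- c(0, essY * 1.05)
  plot(NA, xlim = lim, ylim = lim, xlab = "birth weight",
       ylab = "death weight", main = main, asp = 1)
  abline(0, 1, col = "grey60")
  abline(h = essY, col = "red", lty = 2)
  for (k in 0:(pd@maxDim - 1L)) {
    pk <- p[p$dimension == k, , drop = FALSE]
    if (!nrow(pk)) next
    y <- ifelse(is.finite(pk$death), pk$death, essY)
    points(pk$birth, y, col = .dimCols[k + 1L], pch = c(1, 2, 0)[k + 1L])
  }
  legend("bottomright", legend = paste0("dim ", 0:(pd@maxDim - 1L)),
         col = .dimCols[seq_len(pd@maxDim)], pch = c(1, 2, 0), bty = "n")
  invisible(nrow(p))
}

#' Persistence barcode plot
#'
#' One horizontal bar per pair, grouped by dimension; essential classes
#' extend to the right margin and end in an arrow.
#'
#' @param pd a [PersistenceDiagram-class].
#' @param main plot title.
#' @return invisibly, the number of bars drawn.
#' @export
plotBarcode <- function(pd, main = "Persistence barcode") {
  p <- pd@pairs
  p <- p[order(p$dimension, p$birth), , drop = FALSE]
  finiteMax <- if (any(is.finite(p$death))) max(p$death[is.finite(p$death)])
               else max(p$birth, 1)
  xmax <- finiteMax * 1.15 + 1e-9
  n <- nrow(p)
  plot(NA, xlim = c(0, xmax), ylim = c(0, n + 1), xlab = "weight",
       ylab = "", yaxt = "n", main = main)
  if (n) for (r in seq_len(n)) {
    col <- .dimCols[p$dimension[r] + 1L]
    if (is.finite(p$death[r])) {
      segments(p$birth[r], r, p$death[r], r, col = col, lwd = 2)
    } else {
      arrows(p$birth[r], r, xmax, r, col = col, lwd = 2, length = 0.08)
    }
  }
  legend("bottomright", legend = paste0("dim ", 0:(pd@maxDim - 1L)),
         col = .dimCols[seq_len(pd@maxDim)], lwd = 2, bty = "n")
  invisible(n)
}

#' Betti curves plot
#'
#' Step curves of the Betti numbers along the threshold grid.
#'
#' @param curve a [BettiCurve-class].
#' @param main plot title.
#' @return invisibly, the threshold grid length.
#' @export
plotBettiCurves <- function(curve, main = "Betti curves") {
  th <- curve@thresholds
  b <- curve@beta
  ylim <- c(0, max(b, 1))
  plot(NA, xlim = range(th), ylim = ylim, xlab = "threshold",
       ylab = "Betti number", main = main)
  for (k in seq_len(ncol(b)))
    lines(th, b[, k], type = "s", col = .dimCols[k], lwd = 2)
  legend("topright", legend = colnames(b), col = .dimCols[seq_len(ncol(b))],
         lwd = 2, bty = "n")
  invisible(length(th))
}

#' Network weight histogram plot
#'
#' @param wh a [weightHistogram()] summary (or an
#'   [InteractionNetwork-class], which is summarized first).
#' @param main plot title.
#' @return invisibly, the edge count.
#' @export
plotWeightHistogram <- function(wh, main = "Coupling weight distribution") {
  if (methods::is(wh, "InteractionNetwork")) wh <- weightHistogram(wh)
  if (wh$nEdges == 0L) {
    plot(NA, xlim = 0:1, ylim = 0:1, xlab = "weight", ylab = "count",
         main = main)
    return(invisible(0L))
  }
  barplot(wh$counts, names.arg = signif(wh$mids, 3), las = 2,
          col = "steelblue3", border = NA, main = main,
          xlab = "coupling weight", ylab = "count")
  invisible(wh$nEdges)
}

#' Render the standard figure set for one or two cohort reports
#'
#' Writes, per report, the persistence diagram, barcode, Betti curves and
#' weight histogram as PDFs with deterministic names
#' `<label>_{diagram,barcode,betti,weights}.pdf` in `outDir`.
#'
#' @param reports a [CohortTopologyReport-class] or list of them (a
#'   [ComparisonReport-class] renders both members).
#' @param outDir output directory (created if missing).
#' @return named character vector of the files written, invisibly.
#' @export
renderOutputs <- function(reports, outDir) {
  if (methods::is(reports, "CohortTopologyReport")) reports <- list(reports)
  if (methods::is(reports, "ComparisonReport"))
    reports <- list(reports@reportA, reports@reportB)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  out <- character()
  for (rep in reports) {
    stopifnot(methods::is(rep, "CohortTopologyReport"))
    safe <- gsub("[^A-Za-z0-9_.-]", "_", rep@label)
    files <- file.path(outDir, paste0(safe, "_", c("diagram", "barcode",
                                                   "betti", "weights"),
                                      ".pdf"))
    names(files) <- paste0(safe, c("_diagram", "_barcode", "_betti",
                                   "_weights"))
    pdf(files[1]); plotPersistenceDiagram(rep@diagram,
      main = paste(rep@label, "persistence diagram")); dev.off()
    pdf(files[2]); plotBarcode(rep@diagram,
      main = paste(rep@label, "barcode")); dev.off()
    pdf(files[3]); plotBettiCurves(rep@curve,
      main = paste(rep@label, "Betti curves")); dev.off()
    pdf(files[4]); plotWeightHistogram(rep@weightSummary,
      main = paste(rep@label, "weights")); dev.off()
    out <- c(out, files)
  }
  invisible(out)
}
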