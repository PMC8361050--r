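#' Census of closed signed triangles
#'
#' Enumerates every unordered node triple whose three pairwise couplings are
#' all nonzero (closed triangles), with the triangle energy
#' \eqn{E_{ijk} = J_{ij} J_{jk} J_{ki}} and its balance state: balanced when
#' the sign product is positive, imbalanced (frustrated) when negative.
#' Absent (zero-weight) edges never form triads, so the dichotomy is total.
#' The census also records counts by sign pattern and the triadic
#' Hamiltonian \eqn{H = -\sum_{ijk} E_{ijk}}, the network's balance energy.
#'
#' @param net an [InteractionNetwork-class].
#' @return a [TriadCensus-class]; an empty census is valid.
#' @examples
#' w <- matrix(1, 3, 3); diag(w) <- 0; w[1, 2] <- w[2, 1] <- -1
#' enumerateTriads(InteractionNetwork(w))
#' @export
enumerateTriads <- function(net) {
  stopifnot(methods::is(net, "InteractionNetwork"))
  W <- couplings(net)
  adj <- W != 0
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  tri <- igraph::triangles(g)
  emptyCounts <- stats::setNames(integer(4), c("+++", "++-", "+--", "---"))
  if (length(tri) == 0L) {
    df <- data.frame(i = integer(), j = integer(), k = integer(),
                     Jij = numeric(), Jjk = numeric(), Jki = numeric(),
                     energy = numeric(), state = character(),
                     pattern = character())
    return(new("TriadCensus", triads = df, counts = emptyCounts,
               totalBalanceEnergy = 0, geneIds = geneIds(net)))
  }
  m <- matrix(as.integer(tri), ncol = 3L, byrow = TRUE)
  m <- t(apply(m, 1L, sort))
  ord <- order(m[, 1L], m[, 2L], m[, 3L])
  m <- m[ord, , drop = FALSE]
  Jij <- W[m[, 1:2, drop = FALSE]]
  Jjk <- W[m[, 2:3, drop = FALSE]]
  Jki <- W[m[, c(3L, 1L), drop = FALSE]]
  energy <- Jij * Jjk * Jki
  nNeg <- (Jij < 0) + (Jjk < 0) + (Jki < 0)
  pattern <- c("+++", "++-", "+--", "---")[nNeg + 1L]
  df <- data.frame(i = m[, 1L], j = m[, 2L], k = m[, 3L],
                   Jij = Jij, Jjk = Jjk, Jki = Jki, energy = energy,
                   state = ifelse(energy > 0, "balanced", "imbalanced"),
                   pattern = pattern)
  counts <- emptyCounts
  tab <- table(pattern)
  counts[names(tab)] <- as.integer(tab)
  new("TriadCensus", triads = df, counts = counts,
      totalBalanceEnergy = -sum(energy), geneIds = geneIds(net))
}

#' Quartic balance energy: sign agreement of edge-sharing triangles
#'
#' For every unordered pair of distinct closed triangles sharing exactly one
#' common edge, multiply the two triangle signs \eqn{\Delta = \pm 1} (the
#' sign of each triangle's weight product) and sum:
#' \eqn{s(G) = \sum \Delta_a \Delta_b}, with quartic Hamiltonian
#' \eqn{H = -s(G)}. For an all-positive network s equals the number of such
#' pairs ("squares"). Two distinct triangles on a simple graph can share at
#' most one edge, so "sharing an edge" is unambiguous. A weighted variant
#' replaces each sign by the full triangle energy.
#'
#' @param net an [InteractionNetwork-class].
#' @param weighted if `TRUE`, use triangle energies instead of their signs.
#' @return list with elements `H` and `s` (`s` integer-valued in the sign
#'   convention); a triangle-free network gives `H = 0, s = 0`.
#' @examples
#' quarticEnergy(generateToyNetwork("complete_4"))  # s = 6, H = -6
#' @export
quarticEnergy <- function(net, weighted = FALSE) {
  census <- enumerateTriads(net)
  tr <- census@triads
  if (nrow(tr) < 2L) return(list(H = 0, s = 0))
  val <- if (weighted) tr$energy else sign(tr$energy)
  edgeKey <- function(a, b) paste(pmin(a, b), pmax(a, b))
  keys <- c(edgeKey(tr$i, tr$j), edgeKey(tr$j, tr$k), edgeKey(tr$k, tr$i))
  triId <- rep(seq_len(nrow(tr)), 3L)
  s <- 0
  for (grp in split(triId, keys)) {
    if (length(grp) < 2L) next
    tot <- sum(val[grp])
    s <- s + (tot^2 - sum(val[grp]^2)) / 2   # sum over unordered pairs
  }
  list(H = -s, s = s)
}

#' Histogram of triangle energies
#'
#' Binned counts of the census energies \eqn{E_{ijk}}, the network's energy
#' landscape; optionally split by sign pattern.
#'
#' @param census a [TriadCensus-class].
#' @param bins a bin count or an explicit vector of break points covering
#'   the energy range.
#' @param byPattern also return per-sign-pattern counts on the same breaks.
#' @return list: `breaks`, `mids`, `counts`, and if requested `byPattern`
#'   (a named list of count vectors). An empty census yields zero counts.
#' @export
energyDistribution <- function(census, bins = 20L, byPattern = FALSE) {
  stopifnot(methods::is(census, "TriadCensus"))
  e <- census@triads$energy
  if (length(bins) == 1L) {
    if (!is.finite(bins) || bins < 1) stop("invalid bin count")
    rng <- if (length(e)) range(e) else c(-1, 1)
    if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
    breaks <- seq(rng[1], rng[2], length.out = as.integer(bins) + 1L)
  } else {
    breaks <- sort(as.numeric(bins))
    if (length(breaks) < 2L || anyDuplicated(breaks)) stop("invalid breaks")
    if (length(e) && (min(e) < breaks[1] || max(e) > breaks[length(breaks)]))
      stop("breaks must cover the energy range")
  }
  countIn <- function(x) {
    if (!length(x)) return(integer(length(breaks) - 1L))
    tabulate(findInterval(x, breaks, rightmost.closed = TRUE,
                          all.inside = TRUE),
             nbins = length(breaks) - 1L)
  }
  out <- list(breaks = breaks,
              mids = (breaks[-1] + breaks[-length(breaks)]) / 2,
              counts = countIn(e))
  if (byPattern) {
    pats <- c("+++", "++-", "+--", "---")
    out$byPattern <- lapply(stats::setNames(pats, pats), function(p)
      countIn(e[census@triads$pattern == p]))
  }
  out
}
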