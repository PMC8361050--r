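# internal helpers

# Run expr under a local RNG state seeded with `seed`; restores the caller's
# RNG afterwards. seed = NULL leaves the RNG alone.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("seed must be a single integer")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

checkSymmetric <- function(m, what = "matrix", tol = 1e-8) {
  if (!is.matrix(m) || nrow(m) != ncol(m))
    stop(what, " must be a square matrix")
  if (nrow(m) > 0L && max(abs(m - t(m))) > tol)
    stop(what, " must be symmetric")
  invisible(m)
}

# TRUE iff m is symmetric positive definite (Cholesky succeeds)
isSPD <- function(m) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) return(FALSE)
  if (max(abs(m - t(m))) > 1e-8) return(FALSE)
  ok <- tryCatch({ chol(m); TRUE }, error = function(e) FALSE)
  ok
}

# extract the assay matrix from a SummarizedExperiment or pass a matrix through
exprMatrix <- function(x) {
  if (methods::is(x, "SummarizedExperiment"))
    return(SummarizedExperiment::assay(x, 1L))
  if (is.matrix(x)) return(x)
  stop("expected a SummarizedExperiment or a matrix")
}

infoLog <- function(verbose, fmt, ...) {
  if (isTRUE(verbose)) message(sprintf(fmt, ...))
}
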