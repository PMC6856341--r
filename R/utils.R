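## internal numerical helpers

#' Moore-Penrose pseudo-inverse (real or complex)
#'
#' SVD-based pseudo-inverse with the package-wide relative singular-value
#' cutoff. Handles complex matrices, which \code{MASS::ginv} does not.
#'
#' @param A numeric or complex matrix.
#' @param tol relative cutoff on singular values (fraction of the largest).
#' @return matrix of dimension \code{ncol(A) x nrow(A)}.
#' @keywords internal
#' @noRd
pinv <- function(A, tol = .kg_pinv_tol) {
  s <- svd(A)
  keep <- s$d > tol * max(s$d, .Machine$double.xmin)
  if (!any(keep)) return(matrix(0 + 0i, ncol(A), nrow(A)))
  s$v[, keep, drop = FALSE] %*%
    (Conj(t(s$u[, keep, drop = FALSE])) / s$d[keep])
}

## wrap angles to (-pi, pi]
wrap_phase <- function(x) {
  w <- (x + pi) %% (2 * pi) - pi
  w[!is.na(w) & w == -pi] <- pi
  w
}

## phase unwrapping: remove +-2pi jumps between consecutive samples
unwrap_phase <- function(x) {
  if (length(x) < 2L) return(x)
  d <- diff(x)
  corr <- cumsum(round(-d / (2 * pi))) * 2 * pi
  c(x[1L], x[-1L] + corr)
}

## run expr with a temporary RNG seed, restoring global state afterwards
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

## numerical rank with the shared relative cutoff
num_rank <- function(A, tol = .kg_pinv_tol) {
  d <- svd(A, nu = 0, nv = 0)$d
  sum(d > tol * max(d, .Machine$double.xmin))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
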