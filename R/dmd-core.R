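#' Build a snapshot pair from an angle series
#'
#' Arranges the observation sequence \eqn{y_0, \dots, y_\tau} into the paired
#' data matrices \eqn{X = [y_0, \dots, y_{\tau-1}]} and
#' \eqn{Y = [y_1, \dots, y_\tau]} consumed by every DMD variant.
#'
#' @param series an `angle_series` or a data frame with a `time` column.
#' @return A `snapshot_pair`: list with matrices `X`, `Y`, the sampling
#'   interval `dt` and a `meta` list (assembly tag `"plain"`).
#' @examples
#' s <- angle_series(matrix(0:3, nrow = 1), dt = 0.1)
#' build_snapshot_pair(s)$X
#' @export
build_snapshot_pair <- function(series) {
  series <- as_series(series)
  nf <- ncol(series$values)
  if (nf < 2L) stop("build_snapshot_pair: need at least 2 frames", call. = FALSE)
  new_snapshot_pair(series$values[, -nf, drop = FALSE],
                    series$values[, -1L, drop = FALSE],
                    dt = series$dt,
                    meta = list(assembly = "plain", labels = series$labels))
}

new_snapshot_pair <- function(X, Y, dt, meta = list()) {
  stopifnot(all(dim(X) == dim(Y)), ncol(X) >= 1L)
  structure(list(X = X, Y = Y, dt = dt, meta = meta), class = "snapshot_pair")
}

#' @export
print.snapshot_pair <- function(x, ...) {
  cat(sprintf("<snapshot_pair> %s assembly, state dim %d, %d snapshots, dt = %g s\n",
              x$meta$assembly %||% "plain", nrow(x$X), ncol(x$X), x$dt))
  invisible(x)
}

## internal constructor for fitted DMD objects
new_dmd <- function(eigenvalues, modes, amplitudes, dt, method,
                    p = length(eigenvalues), n_snapshots = NA_integer_,
                    rank_clamped = FALSE,
                    zero_mode_fallback = rep(FALSE, length(eigenvalues)),
                    obs_modes = NULL, obs_amplitudes = NULL,
                    labels = NULL, extra = list()) {
  structure(c(list(
    eigenvalues = eigenvalues,
    modes = modes,
    amplitudes = amplitudes,
    frequencies = eigen_to_frequency(eigenvalues, dt),
    p = p, dt = dt, method = method, n_snapshots = n_snapshots,
    rank_clamped = rank_clamped, zero_mode_fallback = zero_mode_fallback,
    obs_modes = obs_modes, obs_amplitudes = obs_amplitudes,
    labels = labels), extra),
    class = "dmd")
}

#' @export
print.dmd <- function(x, ...) {
  cat(sprintf("<dmd> method = %s, p = %d mode(s), dt = %g s\n",
              x$method, x$p, x$dt))
  fr <- sort(unique(round(abs(Im(x$frequencies)), 4)))
  cat("  |frequencies| [Hz]:", paste(head(fr, 8), collapse = ", "),
      if (length(fr) > 8) "...", "\n")
  invisible(x)
}

#' Exact dynamic mode decomposition
#'
#' SVD-based DMD of a snapshot pair: the propagator \eqn{F = Y X^\dagger} is
#' represented on the leading `p` singular directions of `X`
#' (\eqn{\hat F = U^* Y V \Sigma^{-1}}), and its eigenpairs are projected back
#' to modes \eqn{\psi_j = \lambda_j^{-1} Y V \Sigma^{-1} w_j}. Amplitudes are
#' fitted against the first snapshot, \eqn{b_0 = \Psi^\dagger y_0}.
#'
#' @param pair a `snapshot_pair` (see [build_snapshot_pair()]).
#' @param p truncation dimension (number of modes). Clamped, with a warning,
#'   to the numerical rank of `X`.
#' @return A `dmd` object with fields `eigenvalues`, `modes`, `amplitudes`,
#'   `frequencies` (principal-branch \eqn{\ln\lambda/(2\pi\Delta t)}), `p`,
#'   `method`.
#' @examples
#' s <- simulate_linear_system(matrix(c(0, -1, 1, 0), 2), c(1, 0), 8, dt = 0.25)
#' fit <- exact_dmd(build_snapshot_pair(s), p = 2)
#' fit$eigenvalues   # +-i: a quarter-turn rotation per step
#' @export
exact_dmd <- function(pair, p) {
  stopifnot(inherits(pair, "snapshot_pair"))
  X <- pair$X; Y <- pair$Y
  N <- ncol(X); D <- nrow(X)
  if (p < 1L) stop("exact_dmd: p must be >= 1", call. = FALSE)
  p <- min(p, D, N)
  s <- svd(X)
  rk <- sum(s$d > .kg_pinv_tol * max(s$d, .Machine$double.xmin))
  clamped <- FALSE
  if (p > rk) {
    warning(sprintf("exact_dmd: p = %d exceeds numerical rank %d of X; clamped",
                    p, rk), call. = FALSE)
    p <- rk; clamped <- TRUE
  }
  U <- s$u[, seq_len(p), drop = FALSE]
  V <- s$v[, seq_len(p), drop = FALSE]
  sig <- s$d[seq_len(p)]
  B <- Y %*% V %*% diag(1 / sig, p, p)          # = Y V Sigma^{-1}, D x p
  Fhat <- Conj(t(U)) %*% B                      # p x p
  eg <- eigen(Fhat)
  lambda <- eg$values
  W <- eg$vectors
  modes <- matrix(0 + 0i, D, p)
  fallback <- abs(lambda) < .kg_pinv_tol
  for (j in seq_len(p)) {
    modes[, j] <- if (fallback[j]) U %*% W[, j] else (B %*% W[, j]) / lambda[j]
  }
  if (any(fallback))
    warning("exact_dmd: zero eigenvalue; projected-mode fallback used",
            call. = FALSE)
  amps <- mode_amplitudes(modes, X[, 1L])
  new_dmd(lambda, modes, amps, dt = pair$dt, method = "exact",
          p = p, n_snapshots = N, rank_clamped = clamped,
          zero_mode_fallback = fallback,
          labels = pair$meta$labels, extra = list(meta = pair$meta))
}

#' Companion-matrix dynamic mode decomposition
#'
#' The classical DMD formulation: the final snapshot is regressed on all
#' previous ones, \eqn{c = X^\dagger y_N} (minimum-norm least squares), and
#' the eigenvalues of the \eqn{N \times N} companion matrix with `c` in its
#' last column are taken as the spectrum. Modes are recovered through the
#' (pseudo-inverted) Vandermonde matrix of the eigenvalues,
#' \eqn{\Psi = X T^\dagger}. Returns all `N` eigenvalues; no truncation.
#'
#' @param pair a `snapshot_pair` with at least 2 snapshots.
#' @return A `dmd` object (`method = "companion"`).
#' @examples
#' s <- angle_series(matrix(2^(0:3), nrow = 1), dt = 1)
#' companion_dmd(build_snapshot_pair(s))$eigenvalues
#' @export
companion_dmd <- function(pair) {
  stopifnot(inherits(pair, "snapshot_pair"))
  X <- pair$X; Y <- pair$Y
  N <- ncol(X)
  if (N < 2L) stop("companion_dmd: need at least 2 snapshots", call. = FALSE)
  if (num_rank(X) < min(dim(X)))
    warning("companion_dmd: rank-deficient X; minimum-norm coefficients used",
            call. = FALSE)
  cvec <- as.vector(pinv(X) %*% Y[, N])
  C <- matrix(0, N, N)
  C[cbind(seq_len(N - 1L) + 1L, seq_len(N - 1L))] <- 1
  C[, N] <- Re(cvec)      # real data => real coefficients
  lambda <- eigen(C, only.values = TRUE)$values
  ## Vandermonde: T[j, t] = lambda_j^(t-1); X ~ Psi T
  Tv <- t(outer(0:(N - 1L), lambda, function(tt, l) l^tt))
  if (anyDuplicated(round(lambda, 10)))
    warning("companion_dmd: repeated eigenvalues; Vandermonde pseudo-inverted",
            call. = FALSE)
  modes <- X %*% pinv(Tv)
  amps <- mode_amplitudes(modes, X[, 1L])
  new_dmd(lambda, modes, amps, dt = pair$dt, method = "companion",
          p = N, n_snapshots = N,
          labels = pair$meta$labels, extra = list(meta = pair$meta))
}

#' Map a DMD eigenvalue to a complex temporal frequency
#'
#' \eqn{\omega = \ln(\lambda) / (2\pi\,\Delta t)} (principal branch): the
#' imaginary part is the oscillation frequency in Hz, the real part the
#' growth/decay rate.
#'
#' @param lambda complex eigenvalue(s); must be nonzero.
#' @param dt sampling interval in seconds.
#' @return Complex vector of frequencies (1/s).
#' @examples
#' eigen_to_frequency(exp(1i * pi / 2), dt = 0.01)  # 25i: 25 Hz
#' @export
eigen_to_frequency <- function(lambda, dt) {
  if (any(lambda == 0))
    stop("eigen_to_frequency: undefined for lambda = 0", call. = FALSE)
  log(as.complex(lambda)) / (2 * pi * dt)
}

#' Mode amplitudes against an initial snapshot
#'
#' \eqn{b_0 = \Psi^\dagger y_0}: row \eqn{j} of the pseudo-inverse of the mode
#' matrix applied to the first snapshot.
#'
#' @param modes complex matrix (state dim x p) of DMD modes.
#' @param y0 initial snapshot (length = state dim).
#' @return Complex vector of length p.
#' @export
mode_amplitudes <- function(modes, y0) {
  if (length(y0) != nrow(modes))
    stop("mode_amplitudes: y0 length must match mode rows", call. = FALSE)
  as.vector(pinv(modes) %*% y0)
}

#' Reconstruct a signal from a subset of DMD modes
#'
#' \eqn{\hat y_t = \sum_{j \in S} \psi_j \lambda_j^t b_{j,0}}; the imaginary
#' residue is discarded after summation (exactly zero for conjugate-closed
#' subsets of a real-data fit). For Hankel fits the reconstruction is at the
#' observable level (the original d channels) via the de-duplicated
#' observable modes.
#'
#' @param result a `dmd` object.
#' @param mode_subset integer indices of modes to use (default: all). An
#'   empty subset gives zeros.
#' @param t integer vector of time steps (frames, 0-based powers of
#'   \eqn{\lambda}); default `0:(n_snapshots - 1)`.
#' @param level `"auto"` (observable level when available), `"observable"`,
#'   or `"full"` (the fitted state space, e.g. delay windows).
#' @return Real matrix, state-dim x `length(t)`.
#' @export
reconstruct <- function(result, mode_subset = NULL, t = NULL,
                        level = c("auto", "observable", "full")) {
  stopifnot(inherits(result, "dmd"))
  level <- match.arg(level)
  use_obs <- switch(level,
                    auto = !is.null(result$obs_modes),
                    observable = TRUE, full = FALSE)
  M <- if (use_obs) result$obs_modes else result$modes
  b <- if (use_obs) result$obs_amplitudes else result$amplitudes
  if (use_obs && is.null(M))
    stop("reconstruct: no observable-level modes in this fit", call. = FALSE)
  t <- t %||% (0:(max(result$n_snapshots, 2L) - 1L))
  if (is.null(mode_subset)) mode_subset <- seq_len(ncol(M))
  if (length(mode_subset) == 0L)
    return(matrix(0, nrow(M), length(t)))
  if (any(mode_subset < 1L) || any(mode_subset > ncol(M)))
    stop("reconstruct: mode_subset out of range", call. = FALSE)
  lam <- result$eigenvalues[mode_subset]
  gmax <- max(abs(lam))^max(t)
  if (!is.finite(gmax) || gmax > 1e100)
    stop(sprintf(paste0("reconstruct: |lambda| = %.4g grows beyond overflow ",
                        "guard over %d steps"), max(abs(lam)), max(t)),
         call. = FALSE)
  dyn <- outer(lam, t, `^`) * b[mode_subset]   # |S| x T
  Re(M[, mode_subset, drop = FALSE] %*% dyn)
}

## group eigenvalue indices into conjugate pairs (real eigenvalues singletons)
conjugate_groups <- function(lambda, tol = .kg_conj_tol) {
  n <- length(lambda)
  used <- rep(FALSE, n)
  groups <- list()
  for (j in seq_len(n)) {
    if (used[j]) next
    used[j] <- TRUE
    if (abs(Im(lambda[j])) <= tol * (1 + abs(lambda[j]))) {
      groups[[length(groups) + 1L]] <- j
      next
    }
    cand <- which(!used & abs(lambda - Conj(lambda[j])) <=
                    tol * (1 + abs(lambda[j])))
    if (length(cand) == 0L) {
      warning("conjugate_groups: unpaired complex eigenvalue; kept as singleton",
              call. = FALSE)
      groups[[length(groups) + 1L]] <- j
    } else {
      k <- cand[which.min(abs(lambda[cand] - Conj(lambda[j])))]
      used[k] <- TRUE
      groups[[length(groups) + 1L]] <- c(j, k)
    }
  }
  groups
}

#' Rank conjugate mode pairs by single-pair VAF
#'
#' Groups the spectrum into conjugate pairs (real eigenvalues remain
#' singletons) and sorts the groups by the variance accounted for when each
#' group alone reconstructs the original data; this is the ranking used to
#' pick the dominant pairs of a decomposition.
#'
#' @param result a `dmd` object fitted to real data.
#' @param original real matrix (state-dim x frames at the reconstruction
#'   level) or an `angle_series`.
#' @return A tibble with list-column `modes` (eigenvalue indices of each
#'   group), `frequency_hz` (|Im omega| of the group) and `vaf`, sorted by
#'   descending `vaf` (ties broken by ascending frequency, stably).
#' @export
rank_conjugate_pairs_by_vaf <- function(result, original) {
  stopifnot(inherits(result, "dmd"))
  if (inherits(original, "angle_series") || is.data.frame(original))
    original <- as_series(original)$values
  groups <- conjugate_groups(result$eigenvalues)
  tt <- 0:(ncol(original) - 1L)
  v <- vapply(groups, function(g)
    vaf(original, reconstruct(result, g, t = tt)), numeric(1))
  fr <- vapply(groups, function(g)
    abs(Im(result$frequencies[g[1L]])), numeric(1))
  ord <- order(-v, fr)   # stable in R
  tibble::tibble(modes = groups[ord],
                 frequency_hz = fr[ord],
                 vaf = v[ord])
}
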