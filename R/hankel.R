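#' Hankel (delay-embedding) block of one channel
#'
#' Builds the pair of shifted Hankel matrices of a scalar signal:
#' \eqn{H_1[r, c] = y_{r+c}} (0-based), `m` rows by `n + 1` columns, and
#' \eqn{H_2} the same advanced one frame.
#'
#' @param channel numeric vector, at least `m + n + 1` samples.
#' @param m number of embedding rows (delays).
#' @param n number of window shifts (columns minus one).
#' @return List with matrices `H1` and `H2`.
#' @examples
#' hankel_block(0:4, m = 2, n = 2)
#' @export
hankel_block <- function(channel, m, n) {
  need <- m + n + 1L
  if (length(channel) < need)
    stop(sprintf("hankel_block: channel has %d samples but m + n + 1 = %d are required",
                 length(channel), need), call. = FALSE)
  idx <- outer(seq_len(m), 0:n, `+`)   # 1-based: H1[r, c+1] = channel[r + c]
  list(H1 = matrix(channel[idx], m, n + 1L),
       H2 = matrix(channel[idx + 1L], m, n + 1L))
}

#' Delay-embed every channel of an angle series
#'
#' @param series an `angle_series` or coercible data frame.
#' @inheritParams hankel_block
#' @return A `hankel_embedding`: per-channel block pairs plus `(d, m, n, dt)`.
#' @export
hankel_embedding <- function(series, m, n) {
  series <- as_series(series)
  blocks <- lapply(seq_len(nrow(series$values)), function(i)
    hankel_block(series$values[i, ], m, n))
  structure(list(blocks = blocks, d = nrow(series$values), m = m, n = n,
                 dt = series$dt, labels = series$labels),
            class = "hankel_embedding")
}

#' Assemble Hankel blocks into a snapshot pair
#'
#' Row type concatenates the per-channel blocks horizontally
#' (\eqn{X_{H1} = [H_{1,1}, \dots, H_{d,1}]}, shape `m` x `d(n+1)`): each
#' snapshot is an m-long delay window and the propagator advances windows in
#' time. Column type is its transpose (shape `d(n+1)` x `m`): each snapshot
#' stacks all channels at all delays, giving delay-augmented modes.
#'
#' @param embedding a [hankel_embedding()].
#' @return A `snapshot_pair` with meta tag `"hankel-row"` / `"hankel-col"`.
#' @export
assemble_row_type <- function(embedding) {
  stopifnot(inherits(embedding, "hankel_embedding"))
  X <- do.call(cbind, lapply(embedding$blocks, `[[`, "H1"))
  Y <- do.call(cbind, lapply(embedding$blocks, `[[`, "H2"))
  new_snapshot_pair(X, Y, dt = embedding$dt,
                    meta = list(assembly = "hankel-row", d = embedding$d,
                                m = embedding$m, n = embedding$n,
                                labels = embedding$labels))
}

#' @rdname assemble_row_type
#' @export
assemble_column_type <- function(embedding) {
  pr <- assemble_row_type(embedding)
  new_snapshot_pair(t(pr$X), t(pr$Y), dt = embedding$dt,
                    meta = list(assembly = "hankel-col", d = embedding$d,
                                m = embedding$m, n = embedding$n,
                                labels = embedding$labels))
}

## delay-0 row/column indices (1-based) for channel i = 1..d
delay0_indices <- function(d, n) (seq_len(d) - 1L) * (n + 1L) + 1L

## resolve (m, n) from the first cycle when requested as "auto"
resolve_hankel_params <- function(series, m, n, type) {
  auto <- function(x) is.null(x) || identical(x, "auto")
  if (auto(m) || auto(n)) {
    if (is.null(series$events) || length(series$events) < 2L)
      stop("Hankel DMD: m/n = \"auto\" needs at least 2 cycle events; ",
           "pass m and n explicitly", call. = FALSE)
    Tcyc <- diff(series$events[1:2])
    if (auto(n)) n <- Tcyc
    if (auto(m)) m <- if (type == "row") 2L * Tcyc else Tcyc
  }
  list(m = as.integer(m), n = as.integer(n))
}

#' Row-type Hankel DMD
#'
#' Exact DMD on the row-type Hankel assembly. The conventional Hankel DMD
#' modes \eqn{\chi_j} (columns of the mode matrix, length `m`) are sample
#' paths of the Koopman eigenfunctions along the trajectory: for large enough
#' `m`, \eqn{\chi_j(t+1) \approx \lambda_j \chi_j(t)}, and the argument of
#' \eqn{\chi_j} is the phase of the oscillation at frequency
#' \eqn{\mathrm{Im}\,\omega_j}. Channel-level (observable) modes are obtained
#' from the biorthogonal dual vectors; see [row_type_observable_modes()].
#' No per-channel scaling factors are applied to the assembly (angle channels
#' share units); set `scale_channels = TRUE` to z-scale heterogeneous data.
#'
#' @param series an `angle_series` (only the first `m + n + 1` frames are
#'   used) or coercible data frame.
#' @param m embedding rows; `"auto"` = twice the first cycle length.
#' @param n window shifts; `"auto"` = the first cycle length.
#' @param p SVD truncation dimension (default 50).
#' @param scale_channels divide each channel by its standard deviation before
#'   embedding (off by default).
#' @return A `hankel_dmd` object (inherits `dmd`) with the usual spectral
#'   fields plus `chi` (m x p eigenfunction sample paths), `eigenfunctions`
#'   (an `eigenfunction_set`), observable-level modes `obs_modes` (d x p) and
#'   the assembled `pair`.
#' @examples
#' s <- generate_harmonic_gait(gait_config(duration = 5))
#' fit <- row_type_hankel_dmd(s, m = 250, n = 125, p = 10)
#' tidy(fit)
#' @export
row_type_hankel_dmd <- function(series, m = "auto", n = "auto", p = 50,
                                scale_channels = FALSE) {
  series <- as_series(series)
  mn <- resolve_hankel_params(series, m, n, "row")
  m <- mn$m; n <- mn$n
  if (scale_channels)
    series$values <- series$values / apply(series$values, 1, sd)
  nf <- min(ncol(series$values), m + n + 1L)
  win <- angle_series(series$values[, seq_len(nf), drop = FALSE],
                      dt = series$dt, labels = series$labels)
  pair <- assemble_row_type(hankel_embedding(win, m, n))
  p <- min(p, m, ncol(pair$X))
  fit <- exact_dmd(pair, p)
  chi <- fit$modes                       # m x p eigenfunction sample paths
  obs <- row_type_observable_modes(fit, pair)
  fit$obs_modes <- obs
  fit$obs_amplitudes <- chi[1L, ]        # frame-0 eigenfunction values
  fit$method <- "hankel-row"
  fit$labels <- series$labels
  fit$chi <- chi
  fit$eigenfunctions <- new_eigenfunction_set(chi, fit$frequencies,
                                              dt = series$dt)
  fit$pair <- pair
  class(fit) <- c("hankel_dmd", "dmd")
  fit
}

#' Observable-level modes of a row-type Hankel decomposition
#'
#' The dual vectors \eqn{\psi_j^\dagger} are the rows of the pseudo-inverse
#' of the eigenfunction matrix \eqn{[\chi_1 \dots \chi_p]}, so that
#' \eqn{\psi_i^* \chi_j = \delta_{ij}}. Projecting the data,
#' \eqn{\psi_j^* X_{H1} \in \mathbb{C}^{d(n+1)}}, and picking the entry at
#' each channel's first column (the delay window starting at frame 0) gives
#' one weight per original channel: the coordinative structure of mode `j`
#' without delay duplication.
#'
#' @param result a `dmd` fit of a row-type pair.
#' @param pair the `snapshot_pair` with meta tag `"hankel-row"`.
#' @return Complex d x p matrix.
#' @export
row_type_observable_modes <- function(result, pair) {
  stopifnot(inherits(result, "dmd"), inherits(pair, "snapshot_pair"))
  if (!identical(pair$meta$assembly, "hankel-row"))
    stop("row_type_observable_modes: pair must have assembly \"hankel-row\"",
         call. = FALSE)
  chi <- result$modes
  duals <- pinv(chi)                     # p x m; rows psi_j^dagger
  proj <- duals %*% pair$X               # p x d(n+1)
  sel <- delay0_indices(pair$meta$d, pair$meta$n)
  out <- t(proj[, sel, drop = FALSE])    # d x p
  rownames(out) <- pair$meta$labels
  out
}

#' Column-type Hankel DMD
#'
#' Exact DMD on the column-type (transposed) Hankel assembly: snapshots stack
#' all channels at all delays, so the full modes have length `d(n+1)` and the
#' delay-0 entries of each channel give the de-duplicated observable modes
#' used for reconstruction and spectra.
#'
#' @inheritParams row_type_hankel_dmd
#' @param m embedding rows (number of snapshots here); `"auto"` = first
#'   cycle length.
#' @return A `hankel_dmd` object with `obs_modes` (d x p, delay-0 rows of the
#'   full modes) and the assembled `pair`.
#' @examples
#' s <- generate_harmonic_gait(gait_config(duration = 5))
#' fit <- column_type_hankel_dmd(s, m = 125, n = 125, p = 10)
#' @export
column_type_hankel_dmd <- function(series, m = "auto", n = "auto", p = 50,
                                   scale_channels = FALSE) {
  series <- as_series(series)
  mn <- resolve_hankel_params(series, m, n, "col")
  m <- mn$m; n <- mn$n
  if (scale_channels)
    series$values <- series$values / apply(series$values, 1, sd)
  nf <- min(ncol(series$values), m + n + 1L)
  win <- angle_series(series$values[, seq_len(nf), drop = FALSE],
                      dt = series$dt, labels = series$labels)
  pair <- assemble_column_type(hankel_embedding(win, m, n))
  p <- min(p, m, nrow(pair$X))
  fit <- exact_dmd(pair, p)
  sel <- delay0_indices(pair$meta$d, pair$meta$n)
  obs <- fit$modes[sel, , drop = FALSE]
  rownames(obs) <- series$labels
  fit$obs_modes <- obs
  fit$obs_amplitudes <- fit$amplitudes
  fit$method <- "hankel-col"
  fit$labels <- series$labels
  fit$pair <- pair
  class(fit) <- c("hankel_dmd", "dmd")
  fit
}

## eigenfunction sample-path container
new_eigenfunction_set <- function(chi, frequencies, dt, oracle = NULL) {
  phases <- Arg(chi)
  phases[abs(chi) < .kg_zero_mag] <- NA_real_
  structure(list(chi = chi, frequencies = frequencies, phases = phases,
                 dt = dt, oracle = oracle),
            class = "eigenfunction_set")
}

#' @export
print.eigenfunction_set <- function(x, ...) {
  cat(sprintf("<eigenfunction_set> %d sample frame(s) x %d mode(s), dt = %g s\n",
              nrow(x$chi), ncol(x$chi), x$dt))
  invisible(x)
}

#' Phase series of Koopman eigenfunctions
#'
#' The wrapped argument of each eigenfunction sample path
#' \eqn{\theta'_j(t) = \angle\chi_j(t)}. With `align = TRUE` each series is
#' circularly time-shifted by the integer shift (searched over one period of
#' that mode) that brings the frame-0 phase closest to zero, which makes
#' phase portraits at different speeds comparable.
#'
#' @param eset an `eigenfunction_set` (from [row_type_hankel_dmd()]).
#' @param align align initial phases to near zero by circular time shift.
#' @return Real matrix (frames x modes) of phases in \eqn{(-\pi, \pi]};
#'   `NA` where the eigenfunction magnitude is numerically zero.
#' @export
eigenfunction_phase <- function(eset, align = FALSE) {
  stopifnot(inherits(eset, "eigenfunction_set"))
  ph <- eset$phases
  if (!align) return(ph)
  m <- nrow(ph)
  for (j in seq_len(ncol(ph))) {
    fj <- abs(Im(eset$frequencies[j]))
    period <- if (fj * eset$dt > 1e-12)
      min(m, max(1L, round(1 / (fj * eset$dt)))) else 1L
    shifts <- 0:(period - 1L)
    vals <- abs(ph[1L + shifts, j])
    vals[is.na(vals)] <- Inf
    s <- shifts[which.min(vals)]
    if (s > 0L) ph[, j] <- ph[c((s + 1L):m, 1:s), j]
  }
  ph
}
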