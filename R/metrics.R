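## coerce metric inputs to plain matrices
as_value_matrix <- function(x) {
  if (inherits(x, "angle_series")) return(x$values)
  if (is.data.frame(x)) return(as_series(x)$values)
  as.matrix(x)
}

#' Variance accounted for (VAF)
#'
#' \eqn{\mathrm{VAF} = 1 - \|\Theta - \hat\Theta\|_F^2 / \|\Theta\|_F^2}.
#' Can be negative when a reconstruction is worse than predicting zero.
#'
#' @param original,reconstructed real matrices of identical shape (or
#'   `angle_series`).
#' @return Numeric scalar, at most 1.
#' @export
vaf <- function(original, reconstructed) {
  o <- as_value_matrix(original); r <- as_value_matrix(reconstructed)
  if (!all(dim(o) == dim(r)))
    stop("vaf: shapes differ", call. = FALSE)
  denom <- sum(o^2)
  if (denom == 0) stop("vaf: original is all zero", call. = FALSE)
  1 - sum((o - r)^2) / denom
}

#' Mean absolute reconstruction error
#'
#' \eqn{(1/d\tau)\sum_{t}\sum_{i} |\theta_{i,t} - \hat\theta_{i,t}|}, in the
#' units of the data (radians for angle series).
#'
#' @inheritParams vaf
#' @return Nonnegative scalar.
#' @export
reconstruction_error <- function(original, reconstructed) {
  o <- as_value_matrix(original); r <- as_value_matrix(reconstructed)
  if (!all(dim(o) == dim(r)))
    stop("reconstruction_error: shapes differ", call. = FALSE)
  mean(abs(o - r))
}

new_spectrum_table <- function(frequency, magnitude, normalized = FALSE,
                               relative = FALSE, source = "dmd") {
  ord <- order(frequency)
  tibble::new_tibble(
    list(frequency = frequency[ord], magnitude = magnitude[ord]),
    normalized = normalized, relative = relative, source = source,
    class = "spectrum_table")
}

#' DMD spectrum of a decomposition
#'
#' One spectral point per conjugate-collapsed mode at \eqn{|\mathrm{Im}\,
#' \omega_j|}; the magnitude is the channel average
#' \eqn{\mathrm{mean}_i |\psi_{i,j} b_{j,0}|}, summed over the members of a
#' conjugate pair so that a real oscillation of amplitude A contributes A
#' (comparable with the Fourier amplitude convention of
#' [fourier_spectrum()]).
#'
#' @param result a `dmd` object.
#' @param observable_modes optional d x p complex matrix overriding the
#'   modes used for magnitudes (defaults to the fit's observable-level modes
#'   when present, else its full modes).
#' @return A `spectrum_table` tibble with columns `frequency` (Hz) and
#'   `magnitude`.
#' @export
dmd_spectrum <- function(result, observable_modes = NULL) {
  stopifnot(inherits(result, "dmd"))
  M <- observable_modes %||% result$obs_modes %||% result$modes
  b <- if (is.null(observable_modes) && !is.null(result$obs_modes))
    result$obs_amplitudes else result$amplitudes
  permode <- colMeans(abs(M * rep(b, each = nrow(M))))
  groups <- conjugate_groups(result$eigenvalues)
  freq <- vapply(groups, function(g)
    abs(Im(result$frequencies[g[1L]])), numeric(1))
  mag <- vapply(groups, function(g) sum(permode[g]), numeric(1))
  ## merge numerically identical frequencies
  key <- round(freq, 10)
  agg <- rowsum(mag, key)
  new_spectrum_table(as.numeric(rownames(agg)), as.numeric(agg),
                     source = "dmd")
}

#' Channel-averaged Fourier amplitude spectrum
#'
#' Per-channel discrete Fourier amplitudes (rectangular window, no padding;
#' \eqn{2|X_k|/N} for k > 0, \eqn{|X_0|/N} at DC) averaged over channels.
#'
#' @param series an `angle_series` or coercible data frame.
#' @return A `spectrum_table` on the FFT frequency grid up to Nyquist.
#' @export
fourier_spectrum <- function(series) {
  series <- as_series(series)
  N <- ncol(series$values)
  co <- stats::mvfft(t(series$values))          # N x d
  kmax <- floor(N / 2)
  amp <- Mod(co[seq_len(kmax + 1L), , drop = FALSE]) / N
  amp[-1L, ] <- 2 * amp[-1L, , drop = FALSE]
  new_spectrum_table((0:kmax) / (N * series$dt), rowMeans(amp),
                     source = "fourier")
}

#' Normalize a spectrum and rescale its axis to gait-relative frequency
#'
#' Magnitudes are divided by their maximum (peak = 1) and frequencies by the
#' gait frequency, so harmonics sit at integer abscissae.
#'
#' @param spec a `spectrum_table`.
#' @param gait_freq gait (fundamental) frequency in Hz.
#' @return A `spectrum_table` with `normalized` and `relative` flags set.
#' @export
normalize_and_rescale_spectrum <- function(spec, gait_freq) {
  stopifnot(inherits(spec, "spectrum_table"), gait_freq > 0,
            nrow(spec) > 0)
  mx <- max(spec$magnitude)
  if (mx == 0)
    stop("normalize_and_rescale_spectrum: all magnitudes are zero",
         call. = FALSE)
  rel <- isTRUE(attr(spec, "relative"))
  new_spectrum_table(if (rel) spec$frequency else spec$frequency / gait_freq,
                     spec$magnitude / mx,
                     normalized = TRUE, relative = TRUE,
                     source = attr(spec, "source") %||% "dmd")
}

#' Deviation of estimated frequencies from gait harmonics
#'
#' For each harmonic \eqn{k f_0}, k = 1..K, the retained eigenvalue with
#' \eqn{|\mathrm{Im}\,\omega|} nearest \eqn{k f_0} within a half-harmonic
#' window (\eqn{\pm f_0/2}) is matched greedily (ascending k, each
#' eigenvalue used once) and the normalized deviation
#' \eqn{||\mathrm{Im}\,\omega| - k f_0| / (k f_0)} recorded. An empty window
#' yields `NA` (a missing harmonic), not an error.
#'
#' With `retain = "all"` every eigenvalue of the fit is a candidate. With
#' `retain = "top-vaf"` only the frequencies of the `top_pairs` VAF-ranked
#' conjugate pairs are candidates — the computational analogue of reading
#' harmonic frequencies off the dominant modes of a decomposition, under
#' which a method whose dominant modes sit between the harmonics (as
#' companion-matrix DMD's tend to) genuinely misses harmonics.
#'
#' @param result a `dmd` object.
#' @param gait_freq fundamental frequency \eqn{f_0} in Hz.
#' @param K number of harmonics to check.
#' @param retain candidate rule, `"all"` or `"top-vaf"` (see above).
#' @param original real data matrix (state-dim x frames) for the VAF
#'   ranking; required when `retain = "top-vaf"`.
#' @param top_pairs number of VAF-ranked pairs retained (default `K`).
#' @return Tibble with columns `harmonic`, `target_hz`, `matched_hz`,
#'   `deviation`.
#' @export
harmonic_deviation <- function(result, gait_freq, K,
                               retain = c("all", "top-vaf"),
                               original = NULL, top_pairs = K) {
  stopifnot(inherits(result, "dmd"), gait_freq > 0, K >= 1)
  retain <- match.arg(retain)
  if (retain == "top-vaf") {
    if (is.null(original))
      stop("harmonic_deviation: retain = \"top-vaf\" needs the original data",
           call. = FALSE)
    rk <- rank_conjugate_pairs_by_vaf(result, original)
    freqs <- rk$frequency_hz[seq_len(min(top_pairs, nrow(rk)))]
  } else {
    freqs <- abs(Im(result$frequencies))
  }
  used <- rep(FALSE, length(freqs))
  matched <- dev <- rep(NA_real_, K)
  for (k in seq_len(K)) {
    target <- k * gait_freq
    cand <- which(!used & abs(freqs - target) <= gait_freq / 2)
    if (length(cand) == 0L) next
    j <- cand[which.min(abs(freqs[cand] - target))]
    used[j] <- TRUE
    matched[k] <- freqs[j]
    dev[k] <- abs(freqs[j] - target) / target
  }
  tibble::tibble(harmonic = seq_len(K), target_hz = gait_freq * seq_len(K),
                 matched_hz = matched, deviation = dev)
}

#' Fourier-average Koopman eigenfunction oracle
#'
#' Given prior knowledge of a frequency, the harmonic (Fourier) average
#' \eqn{a = N^{-1}\sum_t e^{-i 2\pi f t \Delta t} s(t)} of a scalar
#' observable yields the Koopman eigenfunction value at that frequency; the
#' oracle path \eqn{\phi(t) = e^{i 2\pi f t \Delta t} a} is the ideal
#' oscillator without growth/decay dynamics.
#'
#' @param series an `angle_series`, data frame, or a (possibly complex)
#'   numeric vector used directly as the observable.
#' @param freq frequency in Hz (>= 0); the series must span at least one
#'   period when `freq > 0`.
#' @param observable channel index (or name) of the designated scalar
#'   observable when `series` is multi-channel; default the first channel.
#' @return Complex vector \eqn{\phi(t)} over the frames, with the average
#'   \eqn{a} attached as attribute `"average"`.
#' @export
fourier_average_eigenfunction <- function(series, freq, observable = 1L) {
  if (is.atomic(series) && is.null(dim(series)) && !is.data.frame(series)) {
    s <- series
    dt <- attr(series, "dt") %||% 1
  } else {
    ser <- as_series(series)
    s <- ser$values[observable, ]
    dt <- ser$dt
  }
  stopifnot(freq >= 0)
  N <- length(s)
  if (freq > 0 && (N - 1) * dt < 1 / freq)
    stop("fourier_average_eigenfunction: series spans less than one period",
         call. = FALSE)
  tt <- (seq_len(N) - 1) * dt
  a <- mean(exp(-1i * 2 * pi * freq * tt) * s)
  if (Mod(a) < 1e-10)
    stop(sprintf("fourier_average_eigenfunction: frequency %.4g Hz not present (|a| = %.2e)",
                 freq, Mod(a)), call. = FALSE)
  structure(exp(1i * 2 * pi * freq * tt) * a, average = a)
}

#' Mean absolute phase difference between two phase series
#'
#' The frame-0 phase offset is removed circularly (mimicking initial-phase
#' adjustment), then the mean wrapped absolute difference over frames is
#' reported both in radians and divided by the spanned duration (rad/s).
#'
#' @param theta_a,theta_b phase series in radians, equal length; `NA` frames
#'   (undefined phases) are excluded.
#' @param dt sampling interval in seconds.
#' @return List with `mean_abs` (rad) and `per_second` (rad/s).
#' @export
phase_difference <- function(theta_a, theta_b, dt) {
  if (length(theta_a) != length(theta_b))
    stop("phase_difference: lengths differ", call. = FALSE)
  ok <- !is.na(theta_a) & !is.na(theta_b)
  if (!any(ok)) stop("phase_difference: no defined phases", call. = FALSE)
  d <- wrap_phase(theta_a[ok] - theta_b[ok])
  d <- wrap_phase(d - d[1L])
  mean_abs <- mean(abs(d))
  list(mean_abs = mean_abs,
       per_second = mean_abs / ((length(theta_a) - 1) * dt))
}

#' SVD baseline decomposition
#'
#' The conventional static decomposition: SVD/PCA of the row-centered
#' channel-by-time matrix. The deterministic sign convention makes the
#' largest-magnitude entry of each basis vector positive.
#'
#' @param series an `angle_series` or coercible data frame.
#' @param k number of components, at most `min(d, frames)`.
#' @return List with `basis` (d x k left singular vectors), `temporal`
#'   (k x frames scaled temporal coordinates \eqn{\Sigma V^*}), `explained`
#'   (variance fractions) and `center` (per-channel means).
#' @export
svd_baseline <- function(series, k) {
  series <- as_series(series)
  V <- series$values
  if (k > min(dim(V)))
    stop("svd_baseline: k exceeds min(channels, frames)", call. = FALSE)
  ctr <- rowMeans(V)
  Vc <- V - ctr
  s <- svd(Vc)
  sgn <- vapply(seq_len(k), function(j) {
    e <- s$u[which.max(abs(s$u[, j])), j]
    if (e < 0) -1 else 1
  }, numeric(1))
  basis <- s$u[, seq_len(k), drop = FALSE] * rep(sgn, each = nrow(s$u))
  temporal <- (s$d[seq_len(k)] * sgn) * t(s$v[, seq_len(k), drop = FALSE])
  list(basis = basis, temporal = temporal,
       explained = s$d[seq_len(k)]^2 / sum(s$d^2), center = ctr)
}

#' Maximal deviation of a trajectory from the PC1-PC2 plane
#'
#' Projects a d-channel trajectory onto the third column of an orthonormal
#' basis and returns the maximal absolute coordinate: how far the motion
#' leaves the plane of the planar law of intersegmental coordination.
#'
#' @param trajectory an `angle_series` or d x frames matrix.
#' @param basis d x 3 matrix with orthonormal columns (Gram deviation from
#'   identity at most 1e-8).
#' @return Nonnegative scalar.
#' @export
planar_deviation <- function(trajectory, basis) {
  V <- as_value_matrix(trajectory)
  if (nrow(V) < 3L || !all(dim(basis) == c(nrow(V), 3L)))
    stop("planar_deviation: need d >= 3 channels and a d x 3 basis",
         call. = FALSE)
  if (max(abs(crossprod(basis) - diag(3))) > 1e-8)
    stop("planar_deviation: basis columns are not orthonormal", call. = FALSE)
  max(abs(as.vector(basis[, 3L] %*% V)))
}
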