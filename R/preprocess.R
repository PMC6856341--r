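#' Zero-phase low-pass filter
#'
#' 4th-order Butterworth, applied forward and backward
#' (\code{signal::filtfilt}) so the output is phase-neutral; length is
#' preserved. The biomechanics default for angle recordings is 8 Hz.
#'
#' @param series an `angle_series` or coercible data frame.
#' @param cutoff cutoff frequency in Hz, strictly below Nyquist.
#' @param order filter order.
#' @return A filtered `angle_series`.
#' @export
lowpass_filter <- function(series, cutoff, order = 4) {
  series <- as_series(series)
  nyq <- 1 / (2 * series$dt)
  if (cutoff <= 0 || cutoff >= nyq)
    stop(sprintf("lowpass_filter: cutoff must lie in (0, %g) Hz", nyq),
         call. = FALSE)
  bf <- signal::butter(order, cutoff / nyq)
  out <- series
  len <- ncol(series$values)
  ## odd-reflection padding suppresses the edge transients of plain filtfilt
  npad <- min(len - 1L, max(3L * (order + 1L),
                            ceiling(16 / (cutoff * series$dt))))
  for (i in seq_len(nrow(out$values))) {
    x <- series$values[i, ]
    pre <- 2 * x[1L] - x[(npad + 1L):2L]
    post <- 2 * x[len] - x[(len - 1L):(len - npad)]
    y <- signal::filtfilt(bf, c(pre, x, post))
    out$values[i, ] <- y[npad + seq_len(len)]
  }
  out
}

#' Subtract the mean posture over a window
#'
#' Removes each channel's mean computed over the given frame window
#' (typically one gait cycle) from the whole channel, centering the angles
#' on the mean posture. Idempotent when the window covers the data used to
#' compute the mean.
#'
#' @param series an `angle_series` or coercible data frame.
#' @param window integer vector of 0-based frame indices over which the mean
#'   is taken; default all frames.
#' @return A centered `angle_series`.
#' @export
subtract_mean_posture <- function(series, window = NULL) {
  series <- as_series(series)
  nf <- ncol(series$values)
  window <- window %||% (0:(nf - 1L))
  if (length(window) == 0L)
    stop("subtract_mean_posture: empty window", call. = FALSE)
  if (any(window < 0L) || any(window > nf - 1L))
    stop("subtract_mean_posture: window outside series", call. = FALSE)
  mu <- rowMeans(series$values[, window + 1L, drop = FALSE])
  series$values <- series$values - mu
  series
}

#' Gait frequency from a cycle length
#'
#' The reciprocal of the cycle duration: \eqn{1 / (T \Delta t)}.
#'
#' @param T cycle length in frames.
#' @param dt sampling interval in seconds.
#' @return Frequency in Hz.
#' @examples
#' gait_frequency(126, 0.01)  # 0.79365 Hz
#' @export
gait_frequency <- function(T, dt) {
  stopifnot(T >= 1, dt > 0)
  1 / (T * dt)
}

#' Segment a recording into per-cycle analysis windows
#'
#' Each consecutive pair of cycle events defines a cycle of `T` frames; the
#' analysis window starts at the event and spans `m + n + 1` frames (the
#' cycle plus the additional delay embedding). With `"auto"`, `n = T` and
#' `m = T` (column type) or `2T` (row type). Cycles whose window would run
#' past the end of the recording are skipped with a message.
#'
#' @param series an `angle_series` with at least 2 events.
#' @param m,n embedding parameters or `"auto"`.
#' @param type `"col"` or `"row"` (sets the `"auto"` rule for `m`).
#' @return List of `angle_series` windows; each carries attributes
#'   `cycle_frames` (T), `gait_freq` (Hz), `m`, `n`.
#' @export
segment_cycles <- function(series, m = "auto", n = "auto",
                           type = c("col", "row")) {
  series <- as_series(series)
  type <- match.arg(type)
  ev <- series$events
  if (is.null(ev) || length(ev) < 2L)
    stop("segment_cycles: needs >= 2 cycle events; pass m and n with a ",
         "manual window instead", call. = FALSE)
  nf <- ncol(series$values)
  out <- list()
  for (k in seq_len(length(ev) - 1L)) {
    Tcyc <- ev[k + 1L] - ev[k]
    nn <- if (identical(n, "auto")) Tcyc else as.integer(n)
    mm <- if (identical(m, "auto")) {
      if (type == "row") 2L * Tcyc else Tcyc
    } else as.integer(m)
    len <- mm + nn + 1L
    if (ev[k] + len > nf) {
      message(sprintf("segment_cycles: cycle at frame %d skipped (needs %d frames, %d available)",
                      ev[k], len, nf - ev[k]))
      next
    }
    win <- angle_series(series$values[, ev[k] + seq_len(len), drop = FALSE],
                        dt = series$dt, labels = series$labels)
    attr(win, "cycle_frames") <- Tcyc
    attr(win, "gait_freq") <- gait_frequency(Tcyc, series$dt)
    attr(win, "m") <- mm
    attr(win, "n") <- nn
    out[[length(out) + 1L]] <- win
  }
  out
}
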