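#' Tidy a DMD fit into one row per mode
#'
#' @param x a `dmd` object.
#' @param ... unused.
#' @return Tibble with columns `mode`, `eigenvalue_re/im`, `modulus`,
#'   `frequency_hz` (Im omega), `growth_rate` (Re omega, 1/s) and
#'   `amplitude_mod`.
#' @method tidy dmd
#' @export
tidy.dmd <- function(x, ...) {
  tibble::tibble(
    mode = seq_along(x$eigenvalues),
    eigenvalue_re = Re(x$eigenvalues),
    eigenvalue_im = Im(x$eigenvalues),
    modulus = Mod(x$eigenvalues),
    frequency_hz = Im(x$frequencies),
    growth_rate = Re(x$frequencies),
    amplitude_mod = Mod(x$amplitudes))
}

#' One-row summary of a DMD fit
#'
#' @param x a `dmd` object.
#' @param ... unused.
#' @return Tibble with `method`, `p`, `n_snapshots`, `dt`, `rank_clamped`.
#' @method glance dmd
#' @export
glance.dmd <- function(x, ...) {
  tibble::tibble(method = x$method, p = x$p,
                 n_snapshots = x$n_snapshots, dt = x$dt,
                 rank_clamped = isTRUE(x$rank_clamped))
}

#' Tidy the channel-level modes of a fit
#'
#' One row per (channel, mode) with the magnitude and argument of the
#' observable-level mode entry — the spatial weights of the coordinative
#' structure.
#'
#' @param x a `dmd` object with observable-level (or plain) modes.
#' @return Tibble with `channel`, `mode`, `magnitude`, `argument`.
#' @export
tidy_modes <- function(x) {
  stopifnot(inherits(x, "dmd"))
  M <- x$obs_modes %||% x$modes
  labels <- x$labels %||% paste0("ch", seq_len(nrow(M)))
  tibble::tibble(
    channel = rep(labels, times = ncol(M)),
    mode = rep(seq_len(ncol(M)), each = nrow(M)),
    magnitude = as.vector(Mod(M)),
    argument = as.vector(Arg(M)))
}

#' Tidy eigenfunction sample paths
#'
#' @param x an `eigenfunction_set`.
#' @param align align initial phases to near zero (see
#'   [eigenfunction_phase()]).
#' @param ... unused.
#' @return Tibble with `frame`, `mode`, `frequency_hz`, `re`, `im`, `phase`.
#' @method tidy eigenfunction_set
#' @export
tidy.eigenfunction_set <- function(x, align = FALSE, ...) {
  ph <- eigenfunction_phase(x, align = align)
  m <- nrow(x$chi); p <- ncol(x$chi)
  tibble::tibble(
    frame = rep(0:(m - 1L), times = p),
    mode = rep(seq_len(p), each = m),
    frequency_hz = rep(Im(x$frequencies), each = m),
    re = as.vector(Re(x$chi)),
    im = as.vector(Im(x$chi)),
    phase = as.vector(ph))
}
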