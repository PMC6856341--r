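#' Multi-channel angle time series
#'
#' The basic data container: `d` angle channels sampled at a fixed interval
#' `dt`, with optional cycle-start events (0-based frame indices, e.g. heel
#' contacts). Most users build one from a data frame with [as_angle_series()]
#' or from a CSV file with [read_angle_csv()]; the synthetic generators return
#' one directly.
#'
#' @param values numeric matrix, `d` channels (rows) by frames (columns),
#'   radians.
#' @param dt sampling interval in seconds.
#' @param labels optional character vector of channel names.
#' @param events optional integer vector of cycle-start frame indices,
#'   0-based, strictly increasing, within the recording.
#' @return An object of class `angle_series`.
#' @examples
#' th <- seq(0, 2 * pi, length.out = 101)
#' s <- angle_series(rbind(sin(th), cos(th)), dt = 0.01,
#'                   labels = c("thigh", "shank"))
#' s
#' @export
angle_series <- function(values, dt, labels = NULL, events = NULL) {
  if (!is.matrix(values)) values <- matrix(values, nrow = 1L)
  storage.mode(values) <- "double"
  if (!all(is.finite(values)))
    stop("angle_series: all values must be finite", call. = FALSE)
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0)
    stop("angle_series: dt must be a single positive number", call. = FALSE)
  if (ncol(values) < 2L)
    stop("angle_series: need at least 2 frames", call. = FALSE)
  d <- nrow(values)
  labels <- labels %||% rownames(values) %||% paste0("ch", seq_len(d))
  if (length(labels) != d)
    stop("angle_series: labels length must equal channel count", call. = FALSE)
  rownames(values) <- labels
  if (!is.null(events)) {
    events <- as.integer(events)
    tau <- ncol(values) - 1L
    if (any(diff(events) <= 0L) || any(events < 0L) || any(events > tau))
      stop("angle_series: events must be strictly increasing frame indices in [0, ",
           tau, "]", call. = FALSE)
  }
  structure(list(values = values, dt = dt, labels = labels, events = events),
            class = "angle_series")
}

#' Coerce a data frame to an angle series
#'
#' Expects one time column (seconds, uniformly sampled) and one numeric column
#' per angle channel. The sampling interval is inferred from the time column.
#'
#' @param x a data frame, or an `angle_series` (returned unchanged).
#' @param time_col name of the time column.
#' @param events optional 0-based cycle-start frame indices.
#' @param ... unused.
#' @return An `angle_series`.
#' @examples
#' df <- data.frame(time = seq(0, 1, by = 0.01), a = sin(seq(0, 1, by = 0.01)))
#' as_angle_series(df)
#' @export
as_angle_series <- function(x, time_col = "time", events = NULL, ...) {
  if (inherits(x, "angle_series")) return(x)
  x <- as.data.frame(x)
  if (!time_col %in% names(x))
    stop("as_angle_series: no '", time_col, "' column", call. = FALSE)
  tt <- x[[time_col]]
  if (anyNA(x)) stop("as_angle_series: missing values present", call. = FALSE)
  dts <- diff(tt)
  if (length(dts) < 1L) stop("as_angle_series: need at least 2 rows", call. = FALSE)
  if (max(dts) - min(dts) > 1e-6)
    stop("as_angle_series: non-uniform sampling (time steps differ by more than 1e-6 s)",
         call. = FALSE)
  dt <- stats::median(dts)
  chans <- setdiff(names(x), time_col)
  vals <- t(as.matrix(x[chans]))
  angle_series(vals, dt = dt, labels = chans, events = events)
}

## internal: accept angle_series or data frame everywhere
as_series <- function(x, ...) as_angle_series(x, ...)

#' @export
print.angle_series <- function(x, ...) {
  cat(sprintf("<angle_series> %d channel(s) x %d frames, dt = %g s (%.4g s total)\n",
              nrow(x$values), ncol(x$values), x$dt,
              (ncol(x$values) - 1) * x$dt))
  cat("  channels:", paste(x$labels, collapse = ", "), "\n")
  if (!is.null(x$events))
    cat("  events:", paste(x$events, collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.angle_series <- function(x, ...) {
  nf <- ncol(x$values)
  out <- data.frame(time = (seq_len(nf) - 1) * x$dt)
  for (i in seq_len(nrow(x$values))) out[[x$labels[i]]] <- x$values[i, ]
  out
}

#' @importFrom tibble as_tibble
#' @method as_tibble angle_series
#' @export
as_tibble.angle_series <- function(x, ...) {
  tibble::as_tibble(as.data.frame(x))
}

#' Number of frames / channels of an angle series
#' @param series an `angle_series` or coercible data frame.
#' @return integer scalar.
#' @export
n_frames <- function(series) ncol(as_series(series)$values)

#' @rdname n_frames
#' @export
n_channels <- function(series) nrow(as_series(series)$values)

#' Plot an angle series
#'
#' @param object an `angle_series`.
#' @param ... unused.
#' @return A ggplot object, one line per channel.
#' @method autoplot angle_series
#' @export
autoplot.angle_series <- function(object, ...) {
  df <- tidyr::pivot_longer(as.data.frame(object), -"time",
                            names_to = "channel", values_to = "angle")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$angle,
                                   colour = .data$channel)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time [s]", y = "angle [rad]")
}
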