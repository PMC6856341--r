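#' Read an angle-series CSV
#'
#' Expects a header row, a `time` column in seconds (uniform within 1e-6 s)
#' and one numeric column per angle channel in radians. Cycle events may be
#' supplied as a sidecar CSV with a single `frame` column of 0-based indices,
#' or directly as an integer vector.
#'
#' @param path CSV file path.
#' @param events optional path to an events CSV, or an integer vector.
#' @param time_col name of the time column.
#' @return An `angle_series`.
#' @export
read_angle_csv <- function(path, events = NULL, time_col = "time") {
  if (!file.exists(path))
    stop("read_angle_csv: no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE)
  if (anyNA(df)) {
    bad <- which(rowSums(is.na(df)) > 0)[1L]
    stop(sprintf("read_angle_csv: missing value in row %d of %s", bad, path),
         call. = FALSE)
  }
  ev <- events
  if (is.character(events)) {
    edf <- utils::read.csv(events)
    ev <- as.integer(edf[[1L]])
  }
  as_angle_series(df, time_col = time_col, events = ev)
}

#' Write an angle series to CSV
#'
#' Full double precision, so a write-then-read round trip is lossless to
#' 1e-12. If the series has events, a `<path>_events.csv` sidecar is written.
#'
#' @param series an `angle_series` or coercible data frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_angle_csv <- function(series, path) {
  series <- as_series(series)
  df <- as.data.frame(series)
  df[] <- lapply(df, function(x) sprintf("%.17g", x))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  if (!is.null(series$events)) {
    epath <- sub("\\.csv$", "_events.csv", path)
    utils::write.csv(data.frame(frame = series$events), epath,
                     row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
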