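#' Analysis run configuration
#'
#' Bundles the choices of the end-to-end decomposition pipeline:
#' preprocessing (low-pass cutoff), cycle handling, method and its
#' parameters. `m` / `n` may be `"auto"`, in which case they are derived per
#' cycle from the event spacing (`n = T`; `m = T` for column type, `2T` for
#' row type; companion and exact use one cycle).
#'
#' @param method one of `"exact"`, `"companion"`, `"hankel-row"`,
#'   `"hankel-col"`, `"svd"`.
#' @param p SVD truncation dimension for the Hankel methods.
#' @param m,n embedding parameters or `"auto"`.
#' @param cutoff_hz low-pass cutoff in Hz (NULL = no filtering).
#' @param harmonics number of gait harmonics evaluated, K.
#' @param top_pairs number of VAF-ranked conjugate pairs reported for the
#'   dominant-mode reconstruction (the exact method always uses one pair).
#' @param svd_components components for `method = "svd"`.
#' @param seed optional RNG seed recorded in the report (the pipeline itself
#'   is deterministic).
#' @return A `run_config` list.
#' @export
run_config <- function(method = c("hankel-row", "hankel-col", "exact",
                                  "companion", "svd"),
                       p = 50, m = "auto", n = "auto", cutoff_hz = 8,
                       harmonics = 5, top_pairs = 3, svd_components = 3,
                       seed = NULL) {
  method <- match.arg(method)
  for (x in list(p, harmonics, top_pairs, svd_components))
    stopifnot(is.numeric(x), x >= 1)
  structure(list(method = method, p = p, m = m, n = n,
                 cutoff_hz = cutoff_hz, harmonics = harmonics,
                 top_pairs = top_pairs, svd_components = svd_components,
                 seed = seed),
            class = "run_config")
}

## decompose one analysis window with the configured method
decompose_window <- function(win, config, Tcyc, gait_freq) {
  d <- nrow(win$values)
  cyc <- angle_series(win$values[, seq_len(min(Tcyc, ncol(win$values))),
                                 drop = FALSE],
                      dt = win$dt, labels = win$labels)
  fit <- switch(config$method,
    "exact" = exact_dmd(build_snapshot_pair(cyc), p = min(config$p, d)),
    "companion" = companion_dmd(build_snapshot_pair(cyc)),
    "hankel-row" = row_type_hankel_dmd(win, m = attr(win, "m") %||% config$m,
                                       n = attr(win, "n") %||% config$n,
                                       p = config$p),
    "hankel-col" = column_type_hankel_dmd(win, m = attr(win, "m") %||% config$m,
                                          n = attr(win, "n") %||% config$n,
                                          p = config$p),
    stop("decompose_window: unknown method ", config$method, call. = FALSE))
  npairs <- if (config$method == "exact") 1L else config$top_pairs
  ranking <- rank_conjugate_pairs_by_vaf(fit, cyc$values)
  top <- unlist(head(ranking$modes, npairs))
  recon <- reconstruct(fit, top, t = 0:(ncol(cyc$values) - 1L))
  hd <- harmonic_deviation(fit, gait_freq, config$harmonics,
                           retain = "top-vaf", original = cyc$values)
  list(fit = fit,
       ranking = ranking,
       metrics = list(
         vaf_top = vaf(cyc$values, recon),
         recon_error_top = reconstruction_error(cyc$values, recon),
         n_modes = fit$p,
         harmonic_deviation_mean = mean(hd$deviation, na.rm = TRUE),
         harmonic_missing = sum(is.na(hd$deviation))),
       harmonic = hd,
       spectrum = dmd_spectrum(fit))
}

#' Run the end-to-end decomposition pipeline
#'
#' Preprocesses a recording (zero-phase low-pass, cycle segmentation,
#' mean-posture subtraction over each cycle, in that order), decomposes each
#' cycle with the configured method, evaluates it (VAF and reconstruction
#' error of the dominant conjugate pairs, harmonic deviations, spectrum) and
#' optionally writes the artifacts to an output directory:
#' `eigenvalues.csv`, `modes.csv`, `spectrum.csv`, `eigenfunctions.csv` (row
#' type only), `report.json` — or `basis.csv` / `temporal.csv` /
#' `explained.csv` for the SVD baseline. Deterministic given the input.
#'
#' @param series an `angle_series`, data frame, or CSV path.
#' @param config a [run_config()].
#' @param output_dir directory for artifacts (created if missing); NULL =
#'   nothing written.
#' @param events optional events vector/path forwarded to [read_angle_csv()].
#' @return Invisibly, a list with per-cycle `fits` and a `report` list (also
#'   serialized as JSON when `output_dir` is set).
#' @export
run_decompose <- function(series, config = run_config(), output_dir = NULL,
                          events = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.character(series)) series <- read_angle_csv(series, events = events)
  series <- as_series(series)
  if (!is.null(config$cutoff_hz))
    series <- lowpass_filter(series, config$cutoff_hz)

  if (config$method == "svd") {
    centered <- subtract_mean_posture(series)
    sb <- svd_baseline(centered, config$svd_components)
    report <- list(method = "svd", components = config$svd_components,
                   explained = sb$explained, seed = config$seed)
    if (!is.null(output_dir)) {
      dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
      utils::write.csv(as.data.frame(sb$basis),
                       file.path(output_dir, "basis.csv"), row.names = FALSE)
      utils::write.csv(as.data.frame(t(sb$temporal)),
                       file.path(output_dir, "temporal.csv"), row.names = FALSE)
      utils::write.csv(data.frame(component = seq_along(sb$explained),
                                  explained = sb$explained),
                       file.path(output_dir, "explained.csv"), row.names = FALSE)
      jsonlite::write_json(report, file.path(output_dir, "report.json"),
                           auto_unbox = TRUE, digits = NA)
    }
    return(invisible(list(baseline = sb, report = report)))
  }

  hank_type <- if (config$method == "hankel-row") "row" else "col"
  if (!is.null(series$events) && length(series$events) >= 2L) {
    wins <- segment_cycles(series, m = config$m, n = config$n,
                           type = hank_type)
  } else {
    if (identical(config$m, "auto") || identical(config$n, "auto"))
      stop("run_decompose: no cycle events; set numeric m and n in the config",
           call. = FALSE)
    wins <- list(series)
    attr(wins[[1L]], "cycle_frames") <- as.integer(config$n)
    attr(wins[[1L]], "gait_freq") <- gait_frequency(config$n, series$dt)
    attr(wins[[1L]], "m") <- as.integer(config$m)
    attr(wins[[1L]], "n") <- as.integer(config$n)
  }
  if (length(wins) == 0L)
    stop("run_decompose: no usable cycles", call. = FALSE)

  results <- vector("list", length(wins))
  for (k in seq_along(wins)) {
    Tcyc <- attr(wins[[k]], "cycle_frames")
    win <- subtract_mean_posture(wins[[k]], window = 0:(Tcyc - 1L))
    results[[k]] <- decompose_window(win, config, Tcyc,
                                     attr(wins[[k]], "gait_freq"))
    results[[k]]$cycle_frames <- Tcyc
    results[[k]]$gait_freq <- attr(wins[[k]], "gait_freq")
  }

  report <- list(
    method = config$method,
    p = config$p, m = config$m, n = config$n,
    cutoff_hz = config$cutoff_hz, harmonics = config$harmonics,
    seed = config$seed %||% NA,
    cycles = lapply(results, function(r)
      c(list(cycle_frames = r$cycle_frames, gait_freq = r$gait_freq),
        r$metrics)))

  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    eig <- dplyr::bind_rows(lapply(seq_along(results), function(k)
      dplyr::mutate(tidy(results[[k]]$fit), cycle = k)))
    utils::write.csv(eig, file.path(output_dir, "eigenvalues.csv"),
                     row.names = FALSE)
    modes <- dplyr::bind_rows(lapply(seq_along(results), function(k)
      dplyr::mutate(tidy_modes(results[[k]]$fit), cycle = k)))
    utils::write.csv(modes, file.path(output_dir, "modes.csv"),
                     row.names = FALSE)
    spec <- dplyr::bind_rows(lapply(seq_along(results), function(k)
      dplyr::mutate(as.data.frame(results[[k]]$spectrum), cycle = k)))
    utils::write.csv(spec, file.path(output_dir, "spectrum.csv"),
                     row.names = FALSE)
    if (config$method == "hankel-row") {
      ef <- dplyr::bind_rows(lapply(seq_along(results), function(k)
        dplyr::mutate(tidy(results[[k]]$fit$eigenfunctions), cycle = k)))
      utils::write.csv(ef, file.path(output_dir, "eigenfunctions.csv"),
                       row.names = FALSE)
    }
    jsonlite::write_json(report, file.path(output_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(list(fits = results, report = report))
}
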