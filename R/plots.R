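#' Plot the eigenvalue spectrum of a DMD fit on the complex plane
#'
#' @param object a `dmd` object.
#' @param ... unused.
#' @return A ggplot: eigenvalues as points with the unit circle for
#'   reference (|lambda| = 1 means neither growth nor decay).
#' @method autoplot dmd
#' @export
autoplot.dmd <- function(object, ...) {
  df <- tidy(object)
  th <- seq(0, 2 * pi, length.out = 200)
  circ <- data.frame(x = cos(th), y = sin(th))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$eigenvalue_re,
                                   y = .data$eigenvalue_im)) +
    ggplot2::geom_path(data = circ, ggplot2::aes(x = .data$x, y = .data$y),
                       linetype = 2, colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(size = .data$amplitude_mod),
                        alpha = 0.7) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "Re lambda", y = "Im lambda",
                  size = "|b0|",
                  title = paste0("DMD eigenvalues (", object$method, ")"))
}

#' Plot a spectrum table
#'
#' @param object a `spectrum_table`.
#' @param ... unused.
#' @return A ggplot of magnitude against frequency; the axis label reflects
#'   whether the spectrum is on a gait-relative axis.
#' @method autoplot spectrum_table
#' @export
autoplot.spectrum_table <- function(object, ...) {
  xlab <- if (isTRUE(attr(object, "relative")))
    "frequency / gait frequency" else "frequency [Hz]"
  ylab <- if (isTRUE(attr(object, "normalized")))
    "normalized magnitude" else "magnitude [rad]"
  ggplot2::ggplot(as.data.frame(object),
                  ggplot2::aes(x = .data$frequency, y = .data$magnitude)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$frequency, yend = 0)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = xlab, y = ylab)
}

#' Plot eigenfunction phase portraits on a planar basis
#'
#' Draws the trajectory in the first two temporal coordinates of the SVD
#' baseline, coloured by the phase of a chosen Koopman eigenfunction — the
#' package's version of phase-on-plane portraits.
#'
#' @param fit a row-type `hankel_dmd` fit.
#' @param baseline output of [svd_baseline()] on the same window.
#' @param mode eigenfunction (mode index) to colour by.
#' @param align align the initial phase to near zero.
#' @return A ggplot object.
#' @export
plot_phase_portrait <- function(fit, baseline, mode = 1L, align = TRUE) {
  stopifnot(inherits(fit, "hankel_dmd"), !is.null(fit$eigenfunctions))
  ph <- eigenfunction_phase(fit$eigenfunctions, align = align)[, mode]
  nfr <- min(length(ph), ncol(baseline$temporal))
  df <- data.frame(pc1 = baseline$temporal[1L, seq_len(nfr)],
                   pc2 = baseline$temporal[2L, seq_len(nfr)],
                   phase = ph[seq_len(nfr)])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pc1, y = .data$pc2,
                                   colour = .data$phase)) +
    ggplot2::geom_path() +
    ggplot2::geom_point() +
    ggplot2::scale_colour_gradientn(colours = c("#2166ac", "#f7f7f7",
                                                "#b2182b", "#2166ac"),
                                    limits = c(-pi, pi)) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "PC1", y = "PC2", colour = "phase [rad]")
}
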