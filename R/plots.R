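#' Plot a reflection spectrum
#'
#' @param object An `fp_spectrum`.
#' @param peaks Optional `fp_peaks` tibble to overlay as points.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot fp_spectrum
#' @export
autoplot.fp_spectrum <- function(object, peaks = NULL, ...) {
  p <- ggplot2::ggplot(tibble::as_tibble(object),
                       ggplot2::aes(x = .data$wavelength_nm,
                                    y = .data$intensity)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "Wavelength (nm)",
                  y = expression(I[r] / I[i]),
                  title = "Reflected interference spectrum")
  if (!is.null(peaks)) {
    p <- p + ggplot2::geom_point(
      data = tibble::as_tibble(peaks),
      ggplot2::aes(x = .data$wavelength_nm, y = .data$intensity),
      colour = "red", size = 1)
  }
  p
}

#' Plot a demodulated cavity-length time series
#'
#' Flagged frames (failed demodulation, suspect jumps) are drawn as rug
#' marks along the time axis.
#'
#' @param object An `fp_series`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot fp_series
#' @export
autoplot.fp_series <- function(object, ...) {
  df <- tibble::as_tibble(object)
  p <- ggplot2::ggplot(df[df$flag == "ok" | is.na(df$flag), ],
                       ggplot2::aes(x = .data$timestamp_s,
                                    y = .data$d_um,
                                    colour = .data$channel)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::labs(x = "Time (s)", y = "Cavity length (µm)",
                  colour = "Channel",
                  title = "Demodulated cavity length")
  bad <- df[!(df$flag == "ok" | is.na(df$flag)), ]
  if (nrow(bad) > 0) {
    p <- p + ggplot2::geom_rug(data = bad, sides = "b",
                               ggplot2::aes(x = .data$timestamp_s),
                               inherit.aes = FALSE)
  }
  p
}

#' Plot per-activation displacements of an expansion summary
#'
#' Bar chart of the anterior and posterior displacements, their average
#' and the expected screw-driven value for each activation.
#'
#' @param object An `expansion_summary`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot expansion_summary
#' @export
autoplot.expansion_summary <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object$activations,
    cols = c("anterior_um", "posterior_um", "average_um", "expected_um"),
    names_to = "quantity", values_to = "displacement_um")
  long$quantity <- sub("_um$", "", long$quantity)
  ggplot2::ggplot(long,
                  ggplot2::aes(x = factor(.data$activation),
                               y = .data$displacement_um,
                               fill = .data$quantity)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "Activation", y = "Displacement (µm)",
                  fill = NULL,
                  title = "Per-activation suture opening")
}

#' Plot a displacement calibration fit
#'
#' Measured vs configured displacement with the fitted line and the
#' identity for reference.
#'
#' @param object An `fp_calibration`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot fp_calibration
#' @export
autoplot.fp_calibration <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$configured_um,
                               y = .data$measured_um)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "red", linewidth = 0.5) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Configured displacement (µm)",
                  y = "Measured displacement (µm)",
                  title = "Translation-stage calibration")
}
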