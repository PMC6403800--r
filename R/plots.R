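#' Plot a current trace
#'
#' Line plot of current versus time, downsampled for display when the trace
#' is long (plotting every k-th sample changes nothing visible at screen
#' resolution).
#'
#' @param object An `np_trace` tibble.
#' @param max_points Cap on plotted samples.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.np_trace <- function(object, max_points = 2e5, ...) {
  n <- nrow(object)
  if (n > max_points) {
    object <- object[seq(1, n, by = ceiling(n / max_points)), ]
  }
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time_s, y = .data$current_pA)) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::labs(x = "time (s)", y = "current (pA)") +
    ggplot2::theme_minimal()
}

#' Scatter plot of event duration versus blockade amplitude
#'
#' The standard event-level diagnostic for resistive-pulse data: residence
#' time (log scale) against mean in-event current.
#'
#' @param object An `np_events` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.np_events <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$mean_amplitude_pA,
                               y = .data$duration_s,
                               shape = .data$censored)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "mean event amplitude (pA)", y = "dwell time (s)") +
    ggplot2::theme_minimal()
}

#' Plot a pooled blockade amplitude histogram with its detected peaks
#'
#' @param object A `blockade_stats` from [amplitude_histogram()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.blockade_stats <- function(object, ...) {
  h <- object$histogram
  p <- ggplot2::ggplot(h, ggplot2::aes(x = .data$bin_mid, y = .data$count)) +
    ggplot2::geom_col(width = object$bin_width, fill = "grey70") +
    ggplot2::geom_line(ggplot2::aes(y = .data$smoothed), colour = "black") +
    ggplot2::geom_vline(xintercept = object$i1_level, linetype = 2) +
    ggplot2::labs(x = "in-event current (pA)", y = "samples") +
    ggplot2::theme_minimal()
  if (!is.na(object$i2_level)) {
    p <- p + ggplot2::geom_vline(xintercept = object$i2_level, linetype = 3)
  }
  p
}

#' Plot a rate-versus-voltage fit on a log rate scale
#'
#' Points are the per-voltage rate estimates; the line is the fitted
#' `k0 * exp(a * dV)`.
#'
#' @param object A `rate_fit` from [fit_voltage_dependence()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rate_fit <- function(object, ...) {
  pts <- object$per_voltage
  grid <- tibble(voltage_mV = seq(min(pts$voltage_mV), max(pts$voltage_mV),
                                  length.out = 100))
  grid$k <- predict_rate(object, grid$voltage_mV)
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$voltage_mV, y = .data$k)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, colour = "red", linetype = 2) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "voltage (mV)", y = "rate") +
    ggplot2::theme_minimal()
}

#' Plot a pore area profile as local resistivity 1/A(z)
#'
#' Shows `1/A(z)`, the quasi-1D indicator of the local resistance ions
#' encounter along the pore axis, with the named regions shaded.
#'
#' @param object A `pore_geometry`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pore_geometry <- function(object, ...) {
  regions <- attr(object, "regions", exact = TRUE)
  dat <- tibble(z_A = object$z_A, inv_area = 1 / object$area_A2)
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$z_A, y = .data$inv_area)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "z (Angstrom)", y = expression(1 / A(z) ~ (ring(A)^-2))) +
    ggplot2::theme_minimal()
  if (!is.null(regions)) {
    shade <- purrr::imap_dfr(regions, ~ tibble(region = .y,
                                               xmin = .x[1], xmax = .x[2]))
    p <- p + ggplot2::geom_rect(
      data = shade,
      ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                   ymin = -Inf, ymax = Inf, fill = .data$region),
      alpha = 0.1, inherit.aes = FALSE
    )
  }
  p
}
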