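# ggplot2 diagnostics for the main result types.

#' @export
autoplot.measurement_record <- function(object, ...) {
  chans <- setdiff(names(object), c("t", "saturated"))
  long <- tidyr::pivot_longer(tibble::as_tibble(object)[, c("t", chans)],
                              -"t", names_to = "channel",
                              values_to = "value")
  long$channel <- factor(long$channel, levels = chans)
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$t, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~channel, ncol = 1, scales = "free_y",
                        strip.position = "left") +
    ggplot2::labs(x = "time (s)", y = NULL) +
    ggplot2::theme_minimal()
  ph <- record_phases(object)
  if (!is.null(ph)) {
    p <- p + ggplot2::geom_vline(xintercept = unique(c(ph$start, ph$end)),
                                 linetype = "dotted", colour = "grey50")
  }
  p
}

#' @export
autoplot.flux_fit <- function(object, ...) {
  cv <- object$curves
  long <- dplyr::bind_rows(
    tibble::tibble(t = cv$t, value = cv$y1_mV, panel = "calorimetric signal (mV)",
                   what = "measured"),
    tibble::tibble(t = cv$t, value = cv$y1_fit_mV, panel = "calorimetric signal (mV)",
                   what = "reconstructed"),
    tibble::tibble(t = cv$t, value = cv$W1_fit_mW, panel = "body flux W1 (mW)",
                   what = "fitted model"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t, y = .data$value,
                                     colour = .data$what)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::facet_wrap(~panel, ncol = 1, scales = "free_y") +
    ggplot2::geom_vline(xintercept = object$window, linetype = "dotted") +
    ggplot2::labs(x = "time (s)", y = NULL, colour = NULL,
                  subtitle = sprintf("sigma_y1 = %.2f %%", object$sigma_y1_pct)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.calibration_fit <- function(object, ...) {
  rs <- object$residuals
  long <- tidyr::pivot_longer(rs, -"t", names_to = "channel",
                              values_to = "residual")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t, y = .data$residual)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~channel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = "fit residual") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.thermal_line <- function(object, ...) {
  ggplot2::ggplot(object$points,
                  ggplot2::aes(x = .data$Tcal_C, y = .data$value_mW)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(intercept = object$alpha_mW,
                         slope = object$beta_mW_per_C, colour = "steelblue") +
    ggplot2::labs(x = "thermostat temperature (degC)", y = "amplitude (mW)",
                  subtitle = sprintf("beta = %.2f mW/K, r = %.3f",
                                     object$beta_mW_per_C, object$r)) +
    ggplot2::theme_minimal()
}
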