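# Thermal aggregation: the steady-state flux A0 falls linearly with the
# thermostat temperature; the inverse of that slope is the total thermal
# resistance between thermostat and body core, the sensor's own resistance is
# subtracted, and a flat-wall assumption turns the body's share into an
# order-of-magnitude tissue conductivity.

#' Fit a coefficient-versus-temperature line
#'
#' Ordinary least squares `value = alpha + beta * Tcal` with the RMS residual
#' (`sigma`, computed as sqrt(mean(residual^2))), the maximum absolute
#' deviation and Pearson's correlation coefficient.
#'
#' @param points Data frame with columns `Tcal_C` and `value_mW` (or pass a
#'   coefficient table plus `coefficient` to pick a column, see
#'   [coefficient_lines()]).
#' @param coefficient Optional label stored with the fit (e.g. `"A0"`).
#' @return A `thermal_line` object.
#' @export
fit_line <- function(points, coefficient = NA_character_) {
  if (!all(c("Tcal_C", "value_mW") %in% names(points))) {
    abort("`points` needs columns Tcal_C and value_mW")
  }
  x <- points$Tcal_C; y <- points$value_mW
  if (length(x) < 2) abort("need at least 2 points")
  if (length(unique(x)) < 2) abort("all Tcal values identical: slope undefined")
  fit <- stats::lm(y ~ x)
  resid <- stats::residuals(fit)
  out <- list(
    coefficient = coefficient,
    alpha_mW = unname(stats::coef(fit)[1]),
    beta_mW_per_C = unname(stats::coef(fit)[2]),
    sigma_mW = sqrt(mean(resid^2)),
    max_dev_mW = max(abs(resid)),
    r = stats::cor(x, y),
    n = length(x),
    points = tibble::tibble(Tcal_C = x, value_mW = y,
                            residual_mW = as.numeric(resid)))
  class(out) <- "thermal_line"
  out
}

#' @export
print.thermal_line <- function(x, ...) {
  cat(sprintf("<thermal_line>%s value = %.2f %+.2f * Tcal mW (r = %.3f, sigma = %.2f mW, max dev = %.2f mW, n = %d)\n",
              if (is.na(x$coefficient)) "" else paste0(" ", x$coefficient, ":"),
              x$alpha_mW, x$beta_mW_per_C, x$r, x$sigma_mW, x$max_dev_mW, x$n))
  invisible(x)
}

#' @export
tidy.thermal_line <- function(x, ...) {
  tibble::tibble(term = c("alpha", "beta"),
                 estimate = c(x$alpha_mW, x$beta_mW_per_C),
                 units = c("mW", "mW/degC"))
}

#' @export
glance.thermal_line <- function(x, ...) {
  tibble::tibble(coefficient = x$coefficient, alpha_mW = x$alpha_mW,
                 beta_mW_per_C = x$beta_mW_per_C, sigma_mW = x$sigma_mW,
                 max_dev_mW = x$max_dev_mW, r = x$r, n = x$n)
}

#' Fit the A0/A1/A2 lines of a coefficient table
#'
#' Applies [fit_line()] to each amplitude column of a per-temperature
#' coefficient table (columns `Tcal_C`, `A0_mW`, `A1_mW`, `A2_mW`, any subset)
#' and returns one row per coefficient, mirroring the fitting-line summary
#' tables of these devices.
#'
#' @param coefs Coefficient table.
#' @return A tibble with columns `coefficient`, `alpha_mW`, `beta_mW_per_C`,
#'   `sigma_mW`, `max_dev_mW`, `r`, `n`.
#' @export
coefficient_lines <- function(coefs) {
  cols <- intersect(c("A0_mW", "A1_mW", "A2_mW"), names(coefs))
  if (!length(cols)) abort("no amplitude columns (A0_mW/A1_mW/A2_mW) found")
  purrr::map_dfr(cols, function(cn) {
    pts <- tibble::tibble(Tcal_C = coefs$Tcal_C, value_mW = coefs[[cn]])
    glance(fit_line(pts, coefficient = sub("_mW$", "", cn)))
  })
}

#' Thermal resistances and flat-wall conductivity
#'
#' `total_resistance()` converts the slope of the steady flux versus
#' thermostat temperature (mW/K, negative: the flux falls as the thermostat
#' warms) into the total thermal resistance `R_T = 1/|slope|` (K/W) between
#' thermostat and body core. `body_resistance()` subtracts the sensor's own
#' resistance, `R_body = R_T - R_sensor`. `conductivity()` applies the
#' flat-wall model `lambda = L / (S R_body)` -- an order-of-magnitude device,
#' not a tissue measurement. `sensor_resistance_from_contact()` computes the
#' per-sensor share of a face-to-face contact experiment in which `n` equal
#' sensors in series carry `flux_W` across a total drop of `dT_K`.
#'
#' @param beta_mW_per_K Slope of the A0 line in mW/K (must be < 0).
#' @return `total_resistance()`: `R_T` in K/W.
#' @export
total_resistance <- function(beta_mW_per_K) {
  if (any(!is.finite(beta_mW_per_K)) || any(beta_mW_per_K >= 0)) {
    abort("slope must be finite and < 0 (flux decreases as the thermostat warms)")
  }
  1000 / abs(beta_mW_per_K)
}

#' @rdname total_resistance
#' @param R_T Total thermal resistance (K/W).
#' @param R_sensor Sensor thermal resistance (K/W); 12 K/W for these devices
#'   (11.905 unrounded, see `sensor_resistance_from_contact(10, 2, 0.420)`).
#' @export
body_resistance <- function(R_T, R_sensor = 12) {
  if (any(R_sensor >= R_T)) {
    abort("R_sensor >= R_T: the sensor dominates the path; no body resistance (or conductivity) can be derived")
  }
  R_T - R_sensor
}

#' @rdname total_resistance
#' @param R_body Body thermal resistance (K/W).
#' @param L Wall depth in m (default 0.01: ~half a hand's width).
#' @param S Contact area in m^2 (default 4e-4: the 2 x 2 cm face).
#' @export
conductivity <- function(R_body, L = 0.01, S = 4e-4) {
  if (any(c(L, S) <= 0)) abort("L and S must be > 0")
  if (any(R_body <= 0)) abort("R_body must be > 0")
  L / (S * R_body)
}

#' @rdname total_resistance
#' @param dT_K Total temperature drop across the series stack (K).
#' @param n_sensors_in_series Number of identical sensors in series.
#' @param flux_W Steady heat flow through the stack (W).
#' @export
sensor_resistance_from_contact <- function(dT_K, n_sensors_in_series, flux_W) {
  if (flux_W <= 0) abort("flux must be > 0")
  if (dT_K <= 0) abort("temperature drop must be > 0")
  (dT_K / n_sensors_in_series) / flux_W
}

#' Run the slope-to-conductivity chain
#'
#' Aggregates a per-temperature A0 series (or a precomputed slope) into the
#' full chain: fitted slope, `R_T`, `R_body` and the flat-wall conductivity.
#' `slope_digits` optionally rounds the fitted slope to the precision at
#' which such slopes are conventionally reported (1 decimal in mW/K) before
#' inverting, so the chain reproduces published summary arithmetic exactly;
#' `NULL` (default) keeps full precision.
#'
#' @param points Data frame with columns `Tcal_C` and `value_mW` (the A0
#'   series), or `NULL` when `slope_mW_per_K` is given directly.
#' @param slope_mW_per_K Slope in mW/K, used directly if `points` is `NULL`.
#' @param R_sensor,L,S See [body_resistance()] and [conductivity()].
#' @param slope_digits Optional rounding of the slope before inversion.
#' @return A one-row tibble: `slope_mW_per_K`, `R_T_K_per_W`, `R_body_K_per_W`,
#'   `lambda_W_per_mK`.
#' @export
thermal_chain <- function(points = NULL, slope_mW_per_K = NULL, R_sensor = 12,
                          L = 0.01, S = 4e-4, slope_digits = NULL) {
  if (is.null(slope_mW_per_K)) {
    if (is.null(points)) abort("supply either `points` or `slope_mW_per_K`")
    slope_mW_per_K <- fit_line(points)$beta_mW_per_C
  }
  if (!is.null(slope_digits)) {
    slope_mW_per_K <- round(slope_mW_per_K, slope_digits)
  }
  R_T <- total_resistance(slope_mW_per_K)
  R_body <- body_resistance(R_T, R_sensor)
  tibble::tibble(
    slope_mW_per_K = slope_mW_per_K,
    R_T_K_per_W = R_T,
    R_body_K_per_W = R_body,
    lambda_W_per_mK = conductivity(R_body, L, S))
}
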