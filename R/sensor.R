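# The minisensor as a 2-input/2-output LTI system. Inputs: W1, the power
# crossing the measurement face (calibration resistor or human body), and W2,
# the Joule power holding the thermostat at its setpoint. Outputs: y1, the
# thermopile voltage, and y2, the thermostat temperature. All four transfer
# functions share the same two poles and each carries one zero:
#   TFi(s) = Ki (1 + s taui*) / ((1 + s tau1)(1 + s tau2))

#' Sensor calibration parameters
#'
#' Bundles the ten parameters of the two-pole/one-zero MIMO model: steady-state
#' sensitivities `K1`, `K2` (mV/W, calorimetric signal per watt of face and
#' thermostat power) and `K3`, `K4` (K/W, thermostat temperature per watt),
#' shared pole time constants `tau1 >= tau2` (s) and per-channel zero time
#' constants `tau1_star`..`tau4_star` (s, >= 0; 0 means no zero).
#'
#' Sign conventions for these devices: heat into the measurement face raises
#' the signal (`K1 > 0`), thermostat power raises the thermostat temperature
#' (`K3 > 0`, `K4 > 0`) and lowers the calorimetric signal (`K2 < 0`).
#' Violations are reported as warnings, not errors, so that exploratory fits
#' are not blocked.
#'
#' @param K1,K2 Sensitivities in mV/W.
#' @param K3,K4 Sensitivities in K/W.
#' @param tau1,tau2 Pole time constants in s (must be > 0).
#' @param tau1_star,tau2_star,tau3_star,tau4_star Zero time constants in s
#'   (must be >= 0).
#' @param label Sensor identifier (e.g. "S1").
#' @param K_se Optional named numeric of least-squares standard errors on the
#'   gains.
#' @return An object of class `sensor_calibration`.
#' @seealso [sensor_s1()], [sensor_s2()] for the two characterized devices.
#' @export
sensor_calibration <- function(K1, K2, K3, K4, tau1, tau2,
                               tau1_star = 0, tau2_star = 0,
                               tau3_star = 0, tau4_star = 0,
                               label = "sensor", K_se = NULL) {
  num <- c(K1 = K1, K2 = K2, K3 = K3, K4 = K4, tau1 = tau1, tau2 = tau2,
           tau1_star = tau1_star, tau2_star = tau2_star,
           tau3_star = tau3_star, tau4_star = tau4_star)
  if (any(!is.finite(num))) abort("all sensor parameters must be finite")
  if (tau1 <= 0 || tau2 <= 0) abort("invalid model: pole time constants must be > 0")
  stars <- num[grep("_star$", names(num))]
  if (any(stars < 0)) abort("zero time constants must be >= 0")
  if (K1 <= 0 || K3 <= 0 || K4 <= 0) {
    warn("unexpected sign: K1, K3 and K4 are positive for these devices")
  }
  if (K2 >= 0) warn("unexpected sign: K2 is negative for these devices")
  structure(
    list(K1 = K1, K2 = K2, K3 = K3, K4 = K4,
         tau1 = tau1, tau2 = tau2,
         tau1_star = tau1_star, tau2_star = tau2_star,
         tau3_star = tau3_star, tau4_star = tau4_star,
         label = label, K_se = K_se),
    class = "sensor_calibration")
}

#' @export
print.sensor_calibration <- function(x, ...) {
  cat(sprintf("<sensor_calibration> %s\n", x$label))
  cat(sprintf("  K1 = %8.2f mV/W   K2 = %8.2f mV/W\n", x$K1, x$K2))
  cat(sprintf("  K3 = %8.2f  K/W   K4 = %8.2f  K/W\n", x$K3, x$K4))
  cat(sprintf("  poles: tau1 = %.1f s, tau2 = %.1f s\n", x$tau1, x$tau2))
  cat(sprintf("  zeros: %.1f, %.1f, %.1f, %.1f s\n",
              x$tau1_star, x$tau2_star, x$tau3_star, x$tau4_star))
  invisible(x)
}

#' Characterized minisensors
#'
#' Calibration parameters of the two physical devices, S1 and S2, as
#' determined from their thermostat-programmed calibration runs. These serve
#' as ground truth for the synthetic generator and as worked examples.
#'
#' @return A [sensor_calibration()] object.
#' @export
sensor_s1 <- function() {
  sensor_calibration(
    K1 = 117.98, K2 = -51.33, K3 = 8.98, K4 = 11.92,
    tau1 = 80.8, tau2 = 9.5,
    tau1_star = 64.4, tau2_star = 108.2, tau3_star = 0.0, tau4_star = 22.2,
    label = "S1",
    K_se = c(K1 = 0.33, K2 = 0.50, K3 = 0.21, K4 = 0.18))
}

#' @rdname sensor_s1
#' @export
sensor_s2 <- function() {
  sensor_calibration(
    K1 = 132.40, K2 = -42.22, K3 = 8.67, K4 = 9.82,
    tau1 = 84.0, tau2 = 8.2,
    tau1_star = 73.5, tau2_star = 96.1, tau3_star = 0.0, tau4_star = 18.4,
    label = "S2",
    K_se = c(K1 = 0.48, K2 = 0.75, K3 = 0.20, K4 = 0.15))
}

# (K, tau*) and output units of one of the four SISO channels.
channel_params <- function(cal, channel = c("TF1", "TF2", "TF3", "TF4")) {
  channel <- match.arg(channel)
  switch(channel,
    TF1 = list(K = cal$K1, tau_star = cal$tau1_star, units = "mV"),
    TF2 = list(K = cal$K2, tau_star = cal$tau2_star, units = "mV"),
    TF3 = list(K = cal$K3, tau_star = cal$tau3_star, units = "K"),
    TF4 = list(K = cal$K4, tau_star = cal$tau4_star, units = "K"))
}

#' Closed-form step response of one sensor channel
#'
#' Analytic response of the two-pole/one-zero channel to an input power step
#' of `amplitude` watts applied at `t = 0`:
#' `y(t) = K A (1 - c1 exp(-t/tau1) - c2 exp(-t/tau2))` with
#' `c1 = (tau1 - tau*)/(tau1 - tau2)` and `c2 = (tau* - tau2)/(tau1 - tau2)`,
#' falling back to the confluent form when the poles coincide. Used as the
#' independent oracle against the zero-order-hold state-space integrator.
#'
#' @param cal A [sensor_calibration()].
#' @param channel One of `"TF1"`..`"TF4"`.
#' @param amplitude Step size in W.
#' @param t Numeric vector of times in s (>= 0).
#' @return A tibble with columns `t` and `response` (mV for TF1/TF2, K for
#'   TF3/TF4).
#' @export
tf_step_response <- function(cal, channel = "TF1", amplitude = 1, t) {
  if (!is.finite(amplitude)) abort("amplitude must be finite")
  ch <- channel_params(cal, channel)
  tau1 <- cal$tau1; tau2 <- cal$tau2; ts <- ch$tau_star
  if (tau1 <= 0 || tau2 <= 0) abort("invalid model: non-positive poles")
  if (abs(tau1 - tau2) <= 1e-9 * max(tau1, tau2)) {
    tau <- tau1
    y <- ch$K * amplitude * (1 - exp(-t / tau) * (1 + (t / tau) * (1 - ts / tau)))
  } else {
    c1 <- (tau1 - ts) / (tau1 - tau2)
    c2 <- (ts - tau2) / (tau1 - tau2)
    y <- ch$K * amplitude * (1 - c1 * exp(-t / tau1) - c2 * exp(-t / tau2))
  }
  tibble::tibble(t = t, response = y)
}

#' Steady-state outputs for sustained input changes
#'
#' The steady-state sensitivity relation: a sustained change `(dW1, dW2)` in
#' the two input powers shifts the outputs by `dy1 = K1 dW1 + K2 dW2` (mV) and
#' `dy2 = K3 dW1 + K4 dW2` (K). Vectorized over inputs.
#'
#' @param cal A [sensor_calibration()].
#' @param dW1,dW2 Input power changes in W.
#' @return A tibble with columns `dW1_W`, `dW2_W`, `dy1_mV`, `dy2_K`.
#' @export
steady_state_outputs <- function(cal, dW1 = 0, dW2 = 0) {
  n <- max(length(dW1), length(dW2))
  dW1 <- rep_len(dW1, n); dW2 <- rep_len(dW2, n)
  tibble::tibble(
    dW1_W = dW1, dW2_W = dW2,
    dy1_mV = cal$K1 * dW1 + cal$K2 * dW2,
    dy2_K = cal$K3 * dW1 + cal$K4 * dW2)
}

#' Read or write a sensor parameter file
#'
#' Flat key/value text files (one `key = value` pair per line) holding the
#' [sensor_calibration()] fields in their native units. Files for the two
#' characterized devices ship with the package:
#' `system.file("extdata", "S1.txt", package = "fluxcal")`.
#'
#' @param path File path.
#' @return `read_sensor()` returns a [sensor_calibration()];
#'   `write_sensor()` returns `path` invisibly.
#' @export
read_sensor <- function(path) {
  if (!file.exists(path)) abort(paste0("sensor file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  if (any(lengths(kv) != 2)) abort("sensor file lines must be 'key = value'")
  keys <- trimws(vapply(kv, `[`, "", 1))
  vals <- trimws(vapply(kv, `[`, "", 2))
  get_num <- function(key) {
    i <- match(key, keys)
    if (is.na(i)) abort(paste0("sensor file misses key: ", key))
    as.numeric(vals[i])
  }
  sensor_calibration(
    K1 = get_num("K1_mV_per_W"), K2 = get_num("K2_mV_per_W"),
    K3 = get_num("K3_K_per_W"), K4 = get_num("K4_K_per_W"),
    tau1 = get_num("tau1_s"), tau2 = get_num("tau2_s"),
    tau1_star = get_num("tau1_star_s"), tau2_star = get_num("tau2_star_s"),
    tau3_star = get_num("tau3_star_s"), tau4_star = get_num("tau4_star_s"),
    label = if ("label" %in% keys) vals[match("label", keys)] else "sensor")
}

#' @rdname read_sensor
#' @param cal A [sensor_calibration()] to serialize.
#' @export
write_sensor <- function(cal, path) {
  stopifnot(inherits(cal, "sensor_calibration"))
  fmt <- function(x) format(x, digits = 15, scientific = FALSE, trim = TRUE)
  lines <- c(
    paste0("label = ", cal$label),
    paste0("K1_mV_per_W = ", fmt(cal$K1)),
    paste0("K2_mV_per_W = ", fmt(cal$K2)),
    paste0("K3_K_per_W = ", fmt(cal$K3)),
    paste0("K4_K_per_W = ", fmt(cal$K4)),
    paste0("tau1_s = ", fmt(cal$tau1)),
    paste0("tau2_s = ", fmt(cal$tau2)),
    paste0("tau1_star_s = ", fmt(cal$tau1_star)),
    paste0("tau2_star_s = ", fmt(cal$tau2_star)),
    paste0("tau3_star_s = ", fmt(cal$tau3_star)),
    paste0("tau4_star_s = ", fmt(cal$tau4_star)))
  writeLines(lines, path)
  invisible(path)
}

#' @export
tidy.sensor_calibration <- function(x, ...) {
  se <- x$K_se %||% c(K1 = NA_real_, K2 = NA_real_, K3 = NA_real_, K4 = NA_real_)
  tibble::tibble(
    term = c("K1", "K2", "K3", "K4", "tau1", "tau2",
             "tau1_star", "tau2_star", "tau3_star", "tau4_star"),
    estimate = c(x$K1, x$K2, x$K3, x$K4, x$tau1, x$tau2,
                 x$tau1_star, x$tau2_star, x$tau3_star, x$tau4_star),
    std.error = c(unname(se[c("K1", "K2", "K3", "K4")]), rep(NA_real_, 6)),
    units = c("mV/W", "mV/W", "K/W", "K/W", rep("s", 6)))
}
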