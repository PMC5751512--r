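# Synthetic-data generator: emulates the instrument so every analysis stage is
# testable without hardware. A PID(-in-practice-PI) loop plays the thermostat
# controller; the plant is the sensor's own zero-order-hold state space, both
# stepped jointly sample by sample.

#' Protocol schedules
#'
#' A protocol schedule describes a run: the programmed thermostat setpoint
#' segments, the Joule calibration pulses dissipated on the calibration base,
#' and (for body runs) the skin-contact window.
#'
#' `calibration_protocol()` is the standard calibration program: 24 deg C for
#' 150 s, 28 deg C for 900 s with a 300 mW Joule pulse from t = 450 s to
#' t = 750 s, then back to 24 deg C for 450 s (total 1500 s), yielding five
#' steady-state zones a-e. `body_protocol()` is the three-phase body
#' measurement: baseline on the calibration base, skin contact, return to
#' base.
#'
#' @param segments Tibble with columns `Tcal_C`, `duration_s`.
#' @param W1_events Tibble with columns `start_s`, `duration_s`, `power_mW`
#'   (Joule pulses), or `NULL`.
#' @param contact `c(start_s, duration_s)` of the skin-contact window, or
#'   `NULL`.
#' @return A `protocol_schedule` object.
#' @export
protocol_schedule <- function(segments, W1_events = NULL, contact = NULL) {
  stopifnot(is.data.frame(segments),
            all(c("Tcal_C", "duration_s") %in% names(segments)))
  if (any(segments$duration_s <= 0)) abort("segment durations must be > 0")
  total <- sum(segments$duration_s)
  if (!is.null(W1_events)) {
    stopifnot(all(c("start_s", "duration_s", "power_mW") %in% names(W1_events)))
    if (any(W1_events$duration_s <= 0)) abort("event durations must be > 0")
    if (any(W1_events$start_s < 0 |
            W1_events$start_s + W1_events$duration_s > total)) {
      abort("Joule events must lie within the protocol span")
    }
  }
  if (!is.null(contact)) {
    if (length(contact) != 2 || contact[1] < 0 || contact[2] <= 0 ||
        sum(contact) > total) {
      abort("contact window must be c(start, duration) within the protocol span")
    }
  }
  structure(list(segments = tibble::as_tibble(segments),
                 W1_events = W1_events, contact = contact, total_s = total),
            class = "protocol_schedule")
}

#' @rdname protocol_schedule
#' @export
calibration_protocol <- function() {
  protocol_schedule(
    segments = tibble::tibble(Tcal_C = c(24, 28, 24),
                              duration_s = c(150, 900, 450)),
    W1_events = tibble::tibble(start_s = 450, duration_s = 300, power_mW = 300))
}

#' @rdname protocol_schedule
#' @param Tcal_C Thermostat setpoint of the body run (deg C).
#' @param baseline_s,contact_s,return_s Phase durations in seconds.
#' @export
body_protocol <- function(Tcal_C = 28, baseline_s = 300, contact_s = 300,
                          return_s = 300) {
  protocol_schedule(
    segments = tibble::tibble(Tcal_C = Tcal_C,
                              duration_s = baseline_s + contact_s + return_s),
    contact = c(baseline_s, contact_s))
}

# Per-sample setpoint and W1 series implied by a schedule (t = 0..total-1).
schedule_series <- function(protocol, dt = 1) {
  t <- seq(0, protocol$total_s - dt, by = dt)
  bounds <- cumsum(protocol$segments$duration_s)
  seg <- findInterval(t, c(0, bounds), rightmost.closed = FALSE,
                      left.open = FALSE)
  seg[seg > nrow(protocol$segments)] <- nrow(protocol$segments)
  setpoint <- protocol$segments$Tcal_C[seg]
  W1 <- rep(0, length(t))
  ev <- protocol$W1_events
  if (!is.null(ev)) {
    for (i in seq_len(nrow(ev))) {
      sel <- t >= ev$start_s[i] & t < ev$start_s[i] + ev$duration_s[i]
      W1[sel] <- W1[sel] + ev$power_mW[i]
    }
  }
  tibble::tibble(t = t, setpoint_C = setpoint, W1_mW = W1)
}

# Quiescent zones between protocol change points, with the W1 level in each.
protocol_zones <- function(protocol) {
  stopifnot(inherits(protocol, "protocol_schedule"))
  bounds <- cumsum(protocol$segments$duration_s)
  pts <- c(0, utils::head(bounds, -1), protocol$total_s)
  ev <- protocol$W1_events
  if (!is.null(ev)) pts <- c(pts, ev$start_s, ev$start_s + ev$duration_s)
  pts <- sort(unique(pts))
  starts <- utils::head(pts, -1); ends <- pts[-1]
  W1 <- vapply(starts, function(s) {
    lvl <- 0
    if (!is.null(ev)) {
      inside <- s >= ev$start_s & s < ev$start_s + ev$duration_s
      lvl <- sum(ev$power_mW[inside])
    }
    lvl
  }, numeric(1))
  tibble::tibble(zone = letters[seq_along(starts)],
                 start = starts, end = ends, W1_mW = W1)
}

#' Signal-noise specification
#'
#' Peak oscillation half-amplitudes of the four recorded channels, matching
#' the quiescent oscillations observed on the real instrument
#' (+-0.2 mV on y1, +-5 mK on y2, +-0.1 mW on W1, +-10 mW on W2). The default
#' noise model is band-limited: white Gaussian with sd = half-amplitude / 2
#' smoothed by a 5-sample moving average, which keeps ~95 % of excursions
#' inside the stated band while looking like the smooth quiescent wander of
#' the real traces; `kind = "uniform"` draws strictly bounded white noise
#' instead.
#'
#' The generators add the `y1` and `W1` amplitudes to the recorded channels,
#' while the `y2` amplitude is the Pt-100 measurement noise injected into the
#' control loop (and recorded, since the instrument logs that same
#' measurement). The thermostat-power oscillation is not added: it emerges
#' from the controller reacting to the temperature noise, at the stated
#' +-10 mW with the default gains (Kp x 5 mK = 10 mW); the `W2_mW` field
#' states that expected amplitude and is applied additively only where a
#' record is synthesized without the loop.
#'
#' @param y1_mV,W1_mW,W2_mW Half-amplitudes in the channel's units.
#' @param y2_mK Half-amplitude of the thermostat temperature noise in mK.
#' @param kind `"smoothed"` (band-limited Gaussian) or `"uniform"` (bounded).
#' @param drift Optional slow sinusoidal drift added to the body flux:
#'   `c(amplitude_mW, period_s)`. Reproduces the low-frequency oscillations
#'   that disperse free time-constant fits.
#' @export
noise_spec <- function(y1_mV = 0.2, y2_mK = 5, W1_mW = 0.1, W2_mW = 10,
                       kind = c("smoothed", "uniform"), drift = NULL) {
  kind <- match.arg(kind)
  amps <- c(y1_mV, y2_mK, W1_mW, W2_mW)
  if (any(amps < 0) || any(!is.finite(amps))) {
    abort("noise half-amplitudes must be finite and >= 0")
  }
  structure(list(y1_mV = y1_mV, y2_mK = y2_mK, W1_mW = W1_mW, W2_mW = W2_mW,
                 kind = kind, drift = drift), class = "noise_spec")
}

# One noise channel of length n with the given half-amplitude.
band_noise <- function(n, half_amp, kind = "smoothed") {
  if (half_amp == 0) return(rep(0, n))
  if (kind == "uniform") return(runif(n, -half_amp, half_amp))
  x <- rnorm(n + 4, 0, half_amp / 2)
  as.numeric(stats::filter(x, rep(1 / 5, 5), sides = 2))[3:(n + 2)]
}

#' Body heat-flux ground truth for the generator
#'
#' Defines the flux a synthetic subject dissipates through the 4 cm^2 contact
#' area as a function of the thermostat setpoint. By default the three
#' amplitudes follow the linear-in-temperature coefficient lines of the
#' reference hand series ([reference_coefficient_lines()]) with time constants
#' 3 s and 70 s -- the canonical transient structure: a fast contact
#' discontinuity and a slow adaptation of the body. Alternatives: a fixed
#' [flux_model()] (`flux =`), or the steady-flux coupling rule
#' `A0 = (Tcore - Tcal)/R_T` (set `Tcore_C` and `R_T_K_per_W`), which makes
#' the generated series exactly consistent with a known total thermal
#' resistance.
#'
#' @param Tbody_C Initial body surface temperature (deg C).
#' @param lines Coefficient lines tibble (columns `coefficient`, `alpha_mW`,
#'   `beta_mW_per_C`) used for amplitudes.
#' @param tau_s Time constants of the two transient terms.
#' @param Tcore_C,R_T_K_per_W Optional coupling rule for `A0` (overrides the
#'   `A0` line).
#' @param flux Optional fixed [flux_model()] used verbatim at any `Tcal`.
#' @export
body_model <- function(Tbody_C = 32, lines = reference_coefficient_lines(),
                       tau_s = c(3, 70), Tcore_C = NULL, R_T_K_per_W = NULL,
                       flux = NULL) {
  if (!is.null(flux)) stopifnot(inherits(flux, "flux_model"))
  structure(list(Tbody_C = Tbody_C, lines = lines, tau_s = tau_s,
                 Tcore_C = Tcore_C, R_T_K_per_W = R_T_K_per_W, flux = flux),
            class = "body_model")
}

# Flux model this body dissipates at a given setpoint, anchored at t_origin.
body_flux_at <- function(body, Tcal_C, t_origin = 0) {
  if (!is.null(body$flux)) {
    m <- body$flux
    return(flux_model(m$A0_mW, m$A_mW, m$tau_s, t_origin = t_origin))
  }
  line_val <- function(coefn) {
    row <- body$lines[body$lines$coefficient == coefn, ]
    row$alpha_mW + row$beta_mW_per_C * Tcal_C
  }
  A0 <- if (!is.null(body$Tcore_C) && !is.null(body$R_T_K_per_W)) {
    1000 * (body$Tcore_C - Tcal_C) / body$R_T_K_per_W
  } else {
    line_val("A0")
  }
  flux_model(A0, c(line_val("A1"), line_val("A2")), body$tau_s,
             t_origin = t_origin)
}

#' Simulate the thermostat's PID control loop
#'
#' Steps the closed loop sample by sample: the controller acts on the
#' thermostat temperature error (setpoint minus simulated y2) and outputs the
#' heating power W2, clamped to `bounds_mW` with anti-windup (the integrator
#' is frozen while the actuator saturates); the plant is the sensor's
#' zero-order-hold state space, advanced jointly. The characteristic W2 and
#' y1 oscillations at setpoint changes and at skin contact emerge from the
#' loop, growing with the thermostat-body temperature difference. Default
#' gains (Kp = 2 W/K, Ki = 0.05 W/(K s), Kd = 0 -- PI in practice) settle a
#' +4 K setpoint step to within +-5 mK in under 300 s.
#'
#' The thermostat temperature the controller acts on can carry measurement
#' noise (`y2_noise_K`): the commanded power then fluctuates for real --
#' with the default gains, +-5 mK of sensor noise produces the characteristic
#' +-10 mW quiescent oscillation of the thermostat power -- and the recorded
#' temperature is that same noisy measurement, exactly as on the instrument.
#'
#' @param cal A [sensor_calibration()].
#' @param setpoints_C Per-sample setpoint series (deg C).
#' @param W1_mW Per-sample disturbance power crossing the measurement face
#'   (mW); default zero.
#' @param gains Named vector `c(Kp =, Ki =, Kd =)` in W/K, W/(K s), W s/K.
#' @param bounds_mW Actuator bounds `c(min, max)` on W2 in mW.
#' @param base_power_mW Feedforward (operating-point) thermostat power.
#' @param y2_noise_K Optional per-sample measurement noise (K) on the
#'   thermostat temperature seen by the controller.
#' @param dt Sampling step (s).
#' @return Tibble with per-sample `t`, `W2_mW` (absolute commanded power),
#'   `y1_mV` (delta form), `y2_C` (true temperature) and `y2_meas_C` (the
#'   measurement the controller saw) of the closed loop.
#' @export
pid_thermostat <- function(cal, setpoints_C, W1_mW = NULL,
                           gains = c(Kp = 2, Ki = 0.05, Kd = 0),
                           bounds_mW = c(0, 1000), base_power_mW = 500,
                           y2_noise_K = NULL, dt = 1) {
  stopifnot(inherits(cal, "sensor_calibration"))
  n <- length(setpoints_C)
  if (n < 2) abort("need at least 2 samples")
  if (any(gains < 0)) abort("PID gains must be >= 0")
  W1_W <- if (is.null(W1_mW)) rep(0, n) else W1_mW / 1000
  if (length(W1_W) != n) abort("W1 and setpoints must share the grid")
  nz <- if (is.null(y2_noise_K)) rep(0, n) else y2_noise_K
  if (length(nz) != n) abort("y2_noise_K and setpoints must share the grid")
  d1 <- discretize_channel(cal$K1, cal$tau1_star, cal$tau1, cal$tau2, dt)
  d2 <- discretize_channel(cal$K2, cal$tau2_star, cal$tau1, cal$tau2, dt)
  d3 <- discretize_channel(cal$K3, cal$tau3_star, cal$tau1, cal$tau2, dt)
  d4 <- discretize_channel(cal$K4, cal$tau4_star, cal$tau1, cal$tau2, dt)
  x1 <- x2 <- x3 <- x4 <- c(0, 0)
  T0 <- setpoints_C[1]
  base_W <- base_power_mW / 1000
  lo <- bounds_mW[1] / 1000; hi <- bounds_mW[2] / 1000
  Kp <- gains[["Kp"]]; Ki <- gains[["Ki"]]
  Kd <- if ("Kd" %in% names(gains)) gains[["Kd"]] else 0
  I <- 0; e_prev <- 0
  y1 <- y2 <- y2m <- W2 <- numeric(n)
  for (k in seq_len(n)) {
    y1[k] <- x1[1] + x2[1]
    y2[k] <- T0 + x3[1] + x4[1]
    y2m[k] <- y2[k] + nz[k]
    e <- setpoints_C[k] - y2m[k]
    if (!is.finite(e) || abs(e) > 100) {
      abort(sprintf(
        "unstable thermostat loop (|error| = %.3g K at t = %g s) with gains Kp = %g, Ki = %g, Kd = %g",
        abs(e), (k - 1) * dt, Kp, Ki, Kd))
    }
    de <- if (k == 1) 0 else (e - e_prev) / dt
    u_raw <- base_W + Kp * e + Ki * (I + e * dt) + Kd * de
    if (u_raw >= lo && u_raw <= hi) {
      I <- I + e * dt          # conditional integration: freeze when clamped
      u <- u_raw
    } else {
      u <- min(max(u_raw, lo), hi)
    }
    W2[k] <- u
    e_prev <- e
    du <- u - base_W
    x1 <- d1$Ad %*% x1 + d1$Bd * W1_W[k]
    x2 <- d2$Ad %*% x2 + d2$Bd * du
    x3 <- d3$Ad %*% x3 + d3$Bd * W1_W[k]
    x4 <- d4$Ad %*% x4 + d4$Bd * du
  }
  tibble::tibble(t = seq(0, by = dt, length.out = n),
                 W2_mW = W2 * 1000, y1_mV = y1, y2_C = y2, y2_meas_C = y2m)
}

#' Generate a synthetic calibration run
#'
#' Produces a complete calibration record -- calorimetric signal, thermostat
#' temperature, known Joule power and PID-controlled thermostat power --
#' under a given protocol and noise specification. Deterministic under a
#' fixed seed. The five steady-state zones are attached as phases, and the
#' generating parameters as the record's truth.
#'
#' @param cal Ground-truth [sensor_calibration()].
#' @param protocol A [protocol_schedule()]; default [calibration_protocol()].
#' @param noise A [noise_spec()]; use `noise_spec(0, 0, 0, 0)` for noiseless.
#' @param seed Integer seed (`NULL` leaves the RNG state alone).
#' @param y1_drift_mV_per_s Optional linear drift injected into the recorded
#'   calorimetric signal, for exercising the baseline correction.
#' @param baseline_y1_mV Constant instrumental offset on the recorded y1.
#' @param ... Passed to [pid_thermostat()] (gains, bounds, base power).
#' @return A [new_measurement_record()] with channels `y1_mV`, `y2_C`,
#'   `W1_mW`, `W2_mW`, `Troom_C` and zone phases.
#' @export
generate_calibration_run <- function(cal, protocol = calibration_protocol(),
                                     noise = noise_spec(), seed = NULL,
                                     y1_drift_mV_per_s = 0,
                                     baseline_y1_mV = 0.8, ...) {
  stopifnot(inherits(protocol, "protocol_schedule"),
            inherits(noise, "noise_spec"))
  if (!is.null(seed)) set.seed(seed)
  ser <- schedule_series(protocol)
  n <- nrow(ser)
  loop <- pid_thermostat(cal, ser$setpoint_C, ser$W1_mW,
                         y2_noise_K = band_noise(n, noise$y2_mK, noise$kind) / 1000,
                         ...)
  rec <- tibble::tibble(
    t = ser$t,
    y1_mV = loop$y1_mV + baseline_y1_mV + y1_drift_mV_per_s * ser$t +
      band_noise(n, noise$y1_mV, noise$kind),
    y2_C = loop$y2_meas_C,
    W1_mW = ser$W1_mW + band_noise(n, noise$W1_mW, noise$kind),
    W2_mW = loop$W2_mW,
    Troom_C = rep(24.7, n))
  zones <- protocol_zones(protocol)
  phases <- tibble::tibble(label = zones$zone, start = zones$start,
                           end = zones$end)
  new_measurement_record(
    rec, phases = phases, tcal = unique(ser$setpoint_C), delta = FALSE,
    truth = list(sensor = cal, protocol = protocol, noise = noise),
    sensor = cal$label, seed = seed)
}

#' Generate a synthetic body measurement run
#'
#' Emulates the three-phase body measurement: baseline on the calibration
#' base, skin contact (the body flux of the [body_model()] enters the
#' measurement face and disturbs the PID loop), and return to base. The body
#' run records `y1_mV`, `y2_C`, `W2_mW` and `Troom_C` -- the true flux is not
#' observable on the instrument and is carried only in the record's truth
#' attribute for recovery tests.
#'
#' @param cal Ground-truth [sensor_calibration()].
#' @param Tcal_C Programmed thermostat setpoint (deg C).
#' @param body A [body_model()].
#' @param protocol A [protocol_schedule()] with a contact window; default
#'   [body_protocol()] at `Tcal_C`.
#' @inheritParams generate_calibration_run
#' @return A [new_measurement_record()] with phases `baseline`, `contact`,
#'   `return`.
#' @export
generate_body_run <- function(cal, Tcal_C, body = body_model(),
                              protocol = body_protocol(Tcal_C),
                              noise = noise_spec(), seed = NULL,
                              baseline_y1_mV = 0.8, ...) {
  stopifnot(inherits(protocol, "protocol_schedule"),
            inherits(noise, "noise_spec"))
  if (is.null(protocol$contact)) abort("body protocol needs a contact window")
  if (!is.null(seed)) set.seed(seed)
  ser <- schedule_series(protocol)
  c_start <- protocol$contact[1]
  c_end <- protocol$contact[1] + protocol$contact[2]
  flux <- body_flux_at(body, Tcal_C, t_origin = c_start)
  W1_true <- flux_values(flux, ser$t, t_end = c_end)
  if (!is.null(noise$drift)) {
    inwin <- ser$t >= c_start & ser$t < c_end
    W1_true[inwin] <- W1_true[inwin] +
      noise$drift[1] * sin(2 * pi * (ser$t[inwin] - c_start) / noise$drift[2])
  }
  n <- nrow(ser)
  loop <- pid_thermostat(cal, ser$setpoint_C, W1_true,
                         y2_noise_K = band_noise(n, noise$y2_mK, noise$kind) / 1000,
                         ...)
  rec <- tibble::tibble(
    t = ser$t,
    y1_mV = loop$y1_mV + baseline_y1_mV + band_noise(n, noise$y1_mV, noise$kind),
    y2_C = loop$y2_meas_C,
    W2_mW = loop$W2_mW,
    Troom_C = rep(24.7, n))
  phases <- tibble::tibble(
    label = c("baseline", "contact", "return"),
    start = c(0, c_start, c_end),
    end = c(c_start, c_end, protocol$total_s))
  new_measurement_record(
    rec, phases = phases, tcal = Tcal_C, delta = FALSE,
    truth = list(sensor = cal, flux = flux, body = body, noise = noise,
                 W1_true_mW = W1_true),
    sensor = cal$label, seed = seed)
}
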