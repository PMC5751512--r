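# The body heat-flux model: W1(t) = A0 + sum_i Ai exp(-(t - t0)/taui) during
# the sensor-application window, 0 outside it. A0 is the steady-state flux
# through the 4 cm^2 contact area; the fast term (~3 s) captures the contact
# discontinuity ("Dirac pulse" type), the slow term (~70 s) the body's
# adaptation to the sensor.

#' Exponential-sum body heat-flux model
#'
#' @param A0_mW Steady-state flux in mW.
#' @param A_mW Amplitudes of the transient terms in mW (any sign; may be
#'   empty for a Heaviside-type flux).
#' @param tau_s Time constants in s (> 0); stored sorted increasing with the
#'   amplitudes reordered to match (canonical order).
#' @param t_origin Time of sensor application in s.
#' @return A `flux_model` object.
#' @export
flux_model <- function(A0_mW, A_mW = numeric(), tau_s = numeric(),
                       t_origin = 0) {
  if (length(A_mW) != length(tau_s)) {
    abort("A_mW and tau_s must have the same length")
  }
  if (length(tau_s) && any(tau_s <= 0)) abort("non-positive time constant")
  if (!all(is.finite(c(A0_mW, A_mW, tau_s, t_origin)))) {
    abort("flux model parameters must be finite")
  }
  o <- order(tau_s)
  structure(list(A0_mW = A0_mW, A_mW = A_mW[o], tau_s = tau_s[o],
                 t_origin = t_origin),
            class = "flux_model")
}

#' @export
print.flux_model <- function(x, ...) {
  cat(sprintf("<flux_model> A0 = %.1f mW", x$A0_mW))
  if (length(x$A_mW)) {
    cat(" + ", paste(sprintf("%.1f mW (tau %.1f s)", x$A_mW, x$tau_s),
                     collapse = " + "))
  }
  cat(sprintf("  [t0 = %g s]\n", x$t_origin))
  invisible(x)
}

# Plain numeric evaluation (mW); 0 outside [t_origin, t_end).
flux_values <- function(m, t, t_end = Inf) {
  w <- rep(0, length(t))
  inwin <- t >= m$t_origin & t < t_end
  if (any(inwin)) {
    td <- t[inwin] - m$t_origin
    v <- rep(m$A0_mW, length(td))
    for (i in seq_along(m$A_mW)) {
      v <- v + m$A_mW[i] * exp(-td / m$tau_s[i])
    }
    w[inwin] <- v
  }
  w
}

#' Evaluate a flux model on a time grid
#'
#' `W1(t) = A0 + sum Ai exp(-(t - t_origin)/taui)` inside the application
#' window and 0 outside it (delta form: the sensor sees no body flux before
#' application or after removal).
#'
#' @param m A [flux_model()].
#' @param t Numeric time grid (s).
#' @param t_end End of the application window (s); default unbounded.
#' @return A tibble with columns `t` and `W1_mW`.
#' @export
evaluate_flux <- function(m, t, t_end = Inf) {
  stopifnot(inherits(m, "flux_model"))
  tibble::tibble(t = t, W1_mW = flux_values(m, t, t_end))
}

#' Window mean of a flux model
#'
#' Closed-form mean of the flux over `[t_a, t_b)`:
#' `A0 + sum Ai taui (exp(-(t_a - t0)/taui) - exp(-(t_b - t0)/taui))/(t_b - t_a)`.
#' This is the earlier mean-power estimator that the exponential model
#' supersedes, reproduced for comparison with the steady-state term `A0`.
#'
#' @param m A [flux_model()].
#' @param window `c(t_a, t_b)` in s with `t_b > t_a >= t_origin`.
#' @return Mean power in mW.
#' @export
mean_power <- function(m, window) {
  stopifnot(inherits(m, "flux_model"))
  if (length(window) != 2 || window[2] <= window[1]) {
    abort("window must be c(t_a, t_b) with t_b > t_a")
  }
  if (window[1] < m$t_origin) abort("window must start at or after t_origin")
  ta <- window[1] - m$t_origin
  tb <- window[2] - m$t_origin
  val <- m$A0_mW
  for (i in seq_along(m$A_mW)) {
    val <- val + m$A_mW[i] * m$tau_s[i] *
      (exp(-ta / m$tau_s[i]) - exp(-tb / m$tau_s[i])) / (tb - ta)
  }
  val
}

#' Optimizer settings for the flux fit
#'
#' @inheritParams dynamics_opts
#' @export
flux_opts <- function(reltol = 1e-10, maxit = 2000, restarts = 2,
                      jitter_sd = 0.1, seed = 20171128) {
  list(reltol = reltol, maxit = maxit, restarts = restarts,
       jitter_sd = jitter_sd, seed = seed)
}

#' Recover the body heat flux from a measurement record
#'
#' Inverse-fits the exponential-sum flux model to the calorimetric signal:
#' the candidate flux `W1(t)` and the measured thermostat power `W2(t)` are
#' pushed through the calibrated sensor model, and the normalized error
#' `sigma_y1 = 100 sqrt(sum (y1_exp - y1_cal)^2 / sum y1_exp^2)` (in %) is
#' minimized. Given the time constants, the amplitudes enter linearly and are
#' solved by least squares; the free-time-constant fit wraps this in a
#' Nelder-Mead search over the log time constants (variable projection), so
#' `fixed_taus` reduces to a single linear solve. The report includes `Wmean`,
#' the window-mean estimator, for comparison with `A0`.
#'
#' @param rec A body-run [new_measurement_record()]; if not yet in delta form
#'   it is baseline-corrected automatically (pre-window at the end of the
#'   baseline phase, post-window at the end of the record).
#' @param cal The [sensor_calibration()] of the device that recorded `rec`.
#' @param n_terms Number of exponential terms (0-4; two suffice in practice).
#' @param fixed_taus Optional fixed time constants (s), e.g. `c(3, 70)`; the
#'   fit then recovers amplitudes only.
#' @param window Application window `c(start, end)` in s; defaults to the
#'   record's contact phase. Must span at least 60 s.
#' @param init_taus Starting time constants for the free fit.
#' @param opts See [flux_opts()].
#' @return A `flux_fit`: list with the fitted [flux_model()] (`$model`),
#'   `sigma_y1_pct`, `Wmean_mW`, `n_eval`, `fixed_taus`, and a `curves`
#'   tibble (`t`, `y1_mV`, `y1_fit_mV`, `W1_fit_mW`).
#' @export
fit_flux <- function(rec, cal, n_terms = 2, fixed_taus = NULL, window = NULL,
                     init_taus = c(3, 70), opts = flux_opts()) {
  stopifnot(inherits(rec, "measurement_record"),
            inherits(cal, "sensor_calibration"))
  if (n_terms > 4) {
    abort("n_terms > 4 rejected: unidentifiable at this noise level")
  }
  if (!is_delta(rec)) {
    # Constant-offset correction from the pre-contact baseline only: the end
    # of the return phase still carries the slow-pole decay, so anchoring a
    # drift line there would tilt the whole record. Pass an explicitly
    # corrected record (correct_baseline with both windows) to remove drift.
    bw <- phase_window(rec, "baseline")
    pre <- c(max(bw[1], bw[2] - 100), bw[2])
    inform("baseline-correcting the record (pre-contact window mean)")
    rec <- correct_baseline(rec, pre)
  }
  if (is.null(window)) window <- phase_window(rec, "contact")
  if (diff(window) < 60) abort("application window shorter than 60 s")
  if (!all(c("y1_mV", "W2_mW") %in% names(rec))) {
    abort("record needs channels y1_mV and W2_mW")
  }
  t <- rec$t
  dt <- check_uniform_time(t)
  y1 <- rec$y1_mV
  cache <- pole_cache(cal$tau1, cal$tau2, dt)
  # fixed thermostat-power contribution through TF2
  h <- sim_channel(cal$K2, cal$tau2_star, cal$tau1, cal$tau2,
                   rec$W2_mW / 1000, dt, cache = cache)
  r <- y1 - h
  inwin <- t >= window[1] & t < window[2]
  denom <- sum(y1^2)
  if (denom == 0) abort("calorimetric signal is identically zero")

  basis <- function(taus) {
    cols <- matrix(0, length(t), 1 + length(taus))
    step <- as.numeric(inwin)
    cols[, 1] <- sim_channel(cal$K1, cal$tau1_star, cal$tau1, cal$tau2,
                             step, dt, u0 = 0, cache = cache)
    for (i in seq_along(taus)) {
      shape <- step * exp(-(t - window[1]) / taus[i])
      cols[, 1 + i] <- sim_channel(cal$K1, cal$tau1_star, cal$tau1, cal$tau2,
                                   shape, dt, u0 = 0, cache = cache)
    }
    cols
  }
  solve_amp <- function(taus) {
    B <- basis(taus)
    a <- qr.coef(qr(B), r)
    a[!is.finite(a)] <- 0
    rss <- sum((r - B %*% a)^2)
    list(a = a, rss = rss)
  }

  n_eval <- 0L
  if (!is.null(fixed_taus) || n_terms == 0) {
    taus <- if (n_terms == 0) numeric() else fixed_taus
    if (length(taus) != n_terms) {
      abort("fixed_taus must supply one time constant per term")
    }
    sol <- solve_amp(taus)
    n_eval <- 1L
  } else {
    objective <- function(theta) {
      n_eval <<- n_eval + 1L
      solve_amp(exp(theta))$rss
    }
    theta0 <- log(rep_len(init_taus, n_terms))
    best <- optim(theta0, objective, method = "Nelder-Mead",
                  control = list(reltol = opts$reltol, maxit = opts$maxit))
    for (rs in seq_len(opts$restarts)) {
      start <- jitter_par(best$par, opts$jitter_sd, opts$seed + rs)
      cand <- optim(start, objective, method = "Nelder-Mead",
                    control = list(reltol = opts$reltol, maxit = opts$maxit))
      improved <- cand$value < best$value * (1 - 1e-8)
      if (cand$value < best$value) best <- cand
      if (!improved) break
    }
    if (!is.finite(best$value)) abort("flux fit failed to converge")
    taus <- exp(best$par)
    sol <- solve_amp(taus)
  }

  # amplitudes were solved in W (unit-power basis shapes); report mW
  amps_mW <- sol$a * 1000
  model <- flux_model(amps_mW[1],
                      if (length(taus)) amps_mW[-1] else numeric(),
                      taus, t_origin = window[1])
  sigma_pct <- 100 * sqrt(sol$rss / denom)
  B <- basis(model$tau_s)
  # reorder solved amplitudes to the model's canonical tau order
  a_ord <- c(model$A0_mW, model$A_mW) / 1000
  y1_fit <- as.numeric(B %*% a_ord) + h
  out <- list(
    model = model,
    sigma_y1_pct = sigma_pct,
    Wmean_mW = mean_power(model, window),
    n_eval = n_eval,
    fixed_taus = !is.null(fixed_taus) && n_terms > 0,
    window = window,
    n = length(t),
    curves = tibble::tibble(
      t = t, y1_mV = y1, y1_fit_mV = y1_fit,
      W1_fit_mW = flux_values(model, t, t_end = window[2])))
  class(out) <- "flux_fit"
  out
}

#' @export
print.flux_fit <- function(x, ...) {
  cat("<flux_fit>\n  ")
  print(x$model)
  cat(sprintf("  sigma_y1 = %.3f %%, Wmean = %.1f mW (%s taus, %d evals)\n",
              x$sigma_y1_pct, x$Wmean_mW,
              if (x$fixed_taus) "fixed" else "free", x$n_eval))
  invisible(x)
}

#' @export
tidy.flux_fit <- function(x, ...) {
  m <- x$model
  tibble::tibble(
    term = c("A0", if (length(m$A_mW)) paste0("A", seq_along(m$A_mW)),
             if (length(m$tau_s)) paste0("tau", seq_along(m$tau_s))),
    estimate = c(m$A0_mW, m$A_mW, m$tau_s),
    units = c("mW", rep("mW", length(m$A_mW)), rep("s", length(m$tau_s))))
}

#' @export
glance.flux_fit <- function(x, ...) {
  tibble::tibble(sigma_y1_pct = x$sigma_y1_pct, Wmean_mW = x$Wmean_mW,
                 A0_mW = x$model$A0_mW, n_terms = length(x$model$A_mW),
                 fixed_taus = x$fixed_taus, n_eval = x$n_eval, n = x$n)
}
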