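# Calibration stage: baseline correction, steady-state zone extraction,
# steady-state sensitivity solving, and pole/zero fitting by Nelder-Mead.

#' Remove the baseline from a measurement record
#'
#' Subtracts, per corrected channel, the straight line joining the channel
#' mean over `pre_window` to its mean over `post_window` (linear drift
#' removal, anchored at the window midpoints). With `post_window = NULL` only
#' the pre-window mean is subtracted. The thermostat temperature correction
#' turns `y2_C` into a temperature offset in K; units of the other channels
#' are unchanged. The result is the delta-form record on which the
#' steady-state equations and the dynamic fits operate.
#'
#' @param rec A [new_measurement_record()].
#' @param pre_window,post_window Time intervals `c(start, end)` in seconds
#'   lying in quiescent parts of the record (each must span at least 10
#'   samples and must not overlap a contact phase).
#' @param channels Channels to correct; defaults to all of `y1_mV`, `y2_C`,
#'   `W1_mW`, `W2_mW` that are present.
#' @return The record in delta form (`is_delta()` is `TRUE`).
#' @export
correct_baseline <- function(rec, pre_window, post_window = NULL,
                             channels = c("y1_mV", "y2_C", "W1_mW", "W2_mW")) {
  stopifnot(inherits(rec, "measurement_record"))
  if (is_delta(rec)) abort("record is already in delta form")
  channels <- intersect(channels, names(rec))
  check_window <- function(w, nm) {
    idx <- window_idx(rec$t, w)
    if (length(idx) < 10) abort(paste0(nm, " window spans fewer than 10 samples"))
    ph <- record_phases(rec)
    if (!is.null(ph)) {
      active <- ph[ph$label %in% "contact", , drop = FALSE]
      if (nrow(active) && any(w[1] < active$end & w[2] > active$start)) {
        abort(paste0(nm, " window overlaps the contact phase"))
      }
    }
    idx
  }
  i_pre <- check_window(pre_window, "pre")
  i_post <- if (!is.null(post_window)) check_window(post_window, "post")
  out <- rec
  for (ch in channels) {
    m_pre <- mean(rec[[ch]][i_pre])
    if (is.null(i_post)) {
      base <- rep(m_pre, nrow(rec))
    } else {
      m_post <- mean(rec[[ch]][i_post])
      t_pre <- mean(rec$t[i_pre]); t_post <- mean(rec$t[i_post])
      base <- m_pre + (m_post - m_pre) * (rec$t - t_pre) / (t_post - t_pre)
    }
    out[[ch]] <- rec[[ch]] - base
  }
  attr(out, "delta") <- TRUE
  attr(out, "baseline_windows") <- list(pre = pre_window, post = post_window)
  out
}

#' Extract steady-state zones from a calibration record
#'
#' Splits the (delta-form) record at every protocol change point -- setpoint
#' changes and Joule-pulse edges -- into quiescent zones labelled `a`, `b`,
#' ..., discards the first `settle_multiplier * tau_rough` seconds of each
#' zone to let the slow pole decay (the first zone keeps all samples: the
#' record starts at the steady state), and averages the remainder. Zones whose
#' within-zone standard deviation exceeds the stationarity thresholds are
#' flagged. The known step in `W1` comes from the protocol; the thermostat
#' power change is measured from the `W2_mW` channel.
#'
#' @param rec Delta-form record (see [correct_baseline()]).
#' @param protocol A [protocol_schedule()] giving the setpoint segments and
#'   Joule events.
#' @param settle_multiplier,tau_rough Settle rule: discard
#'   `settle_multiplier * tau_rough` seconds after each change point
#'   (defaults 3 x 50 s = 150 s, retaining half of a 300 s zone).
#' @param thresholds Named stationarity thresholds, `c(y1_mV = 0.2, y2_mK = 5)`.
#' @return A `steady_state_set` tibble with one row per zone: `zone`,
#'   `t_start`, `t_end`, `n`, `dy1_mV`, `dy2_K`, `dW1_W`, `dW2_W`, `sd_y1_mV`,
#'   `sd_y2_mK`, `flagged`.
#' @export
extract_steady_states <- function(rec, protocol,
                                  settle_multiplier = 3, tau_rough = 50,
                                  thresholds = c(y1_mV = 0.2, y2_mK = 5)) {
  stopifnot(inherits(rec, "measurement_record"))
  if (!is_delta(rec)) abort("record must be baseline-corrected first (delta form)")
  zones <- protocol_zones(protocol)
  settle <- settle_multiplier * tau_rough
  dt <- check_uniform_time(rec$t)
  rows <- purrr::pmap_dfr(zones, function(zone, start, end, W1_mW) {
    cut <- if (zone == zones$zone[1]) 0 else settle
    if (start + cut >= end - 10 * dt) {
      abort(sprintf("zone '%s' is shorter than the settle cut (%g s)", zone, cut))
    }
    sel <- window_idx(rec$t, c(start + cut, end))
    tibble::tibble(
      zone = zone, t_start = start, t_end = end, n = length(sel),
      dy1_mV = mean(rec$y1_mV[sel]),
      dy2_K = mean(rec$y2_C[sel]),
      dW1_W = (W1_mW - zones$W1_mW[1]) / 1000,
      dW2_W = mean(rec$W2_mW[sel]) / 1000,
      sd_y1_mV = sd(rec$y1_mV[sel]),
      sd_y2_mK = sd(rec$y2_C[sel]) * 1000)
  })
  rows$flagged <- rows$sd_y1_mV > thresholds[["y1_mV"]] |
    rows$sd_y2_mK > thresholds[["y2_mK"]]
  if (all(rows$flagged)) {
    abort("every steady-state zone violates the stationarity thresholds")
  }
  class(rows) <- c("steady_state_set", class(rows))
  attr(rows, "dt") <- dt
  rows
}

#' Solve the steady-state sensitivities
#'
#' Ordinary least squares on the steady-state system
#' `K1 dW1 + K2 dW2 = dy1`, `K3 dW1 + K4 dW2 = dy2` across all zones, solved
#' independently for the (K1, K2) and (K3, K4) rows. At least two zones with
#' linearly independent `(dW1, dW2)` are required.
#'
#' @param ss A `steady_state_set` from [extract_steady_states()], or any data
#'   frame with columns `dW1_W`, `dW2_W`, `dy1_mV`, `dy2_K`.
#' @return A `sensitivity_fit`: list with `gains` (tibble of term, estimate,
#'   std.error, units) and `residuals` (per-zone, per-channel).
#' @export
solve_sensitivities <- function(ss) {
  need <- c("dW1_W", "dW2_W", "dy1_mV", "dy2_K")
  if (!all(need %in% names(ss))) {
    abort(paste0("need columns ", paste(need, collapse = ", ")))
  }
  X <- cbind(dW1 = ss$dW1_W, dW2 = ss$dW2_W)
  qrX <- qr(X)
  if (qrX$rank < 2) {
    abort(paste0(
      "rank-deficient steady-state design: the zones' (dW1, dW2) pairs are ",
      "proportional, so the two sensitivities of each output cannot be separated"))
  }
  fit_row <- function(y) {
    b <- qr.coef(qrX, y)
    r <- y - X %*% b
    dof <- max(nrow(X) - 2L, 1L)
    s2 <- sum(r^2) / dof
    XtXinv <- chol2inv(qr.R(qrX))
    list(b = b, se = sqrt(diag(XtXinv) * s2), resid = as.numeric(r))
  }
  f1 <- fit_row(ss$dy1_mV)
  f2 <- fit_row(ss$dy2_K)
  out <- list(
    gains = tibble::tibble(
      term = c("K1", "K2", "K3", "K4"),
      estimate = unname(c(f1$b, f2$b)),
      std.error = c(f1$se, f2$se),
      units = c("mV/W", "mV/W", "K/W", "K/W")),
    residuals = tibble::tibble(
      zone = if ("zone" %in% names(ss)) ss$zone else seq_len(nrow(ss)),
      resid_y1_mV = f1$resid,
      resid_y2_K = f2$resid))
  class(out) <- "sensitivity_fit"
  out
}

#' @export
print.sensitivity_fit <- function(x, ...) {
  cat("<sensitivity_fit>\n")
  print(x$gains)
  invisible(x)
}

#' @export
tidy.sensitivity_fit <- function(x, ...) x$gains

gains_vector <- function(gains) {
  if (inherits(gains, "sensitivity_fit")) {
    setNames(gains$gains$estimate, gains$gains$term)
  } else if (inherits(gains, "sensor_calibration")) {
    c(K1 = gains$K1, K2 = gains$K2, K3 = gains$K3, K4 = gains$K4)
  } else {
    if (!all(c("K1", "K2", "K3", "K4") %in% names(gains))) {
      abort("gains must be named K1..K4 (or a sensitivity_fit / sensor_calibration)")
    }
    gains[c("K1", "K2", "K3", "K4")]
  }
}

#' Optimizer settings for the dynamic calibration fit
#'
#' @param reltol Relative convergence tolerance on the objective.
#' @param maxit Maximum objective evaluations per Nelder-Mead run.
#' @param restarts Maximum restarts from a perturbed optimum.
#' @param jitter_sd Standard deviation of the (log-scale) restart jitter.
#' @param seed Seed for the restart jitter.
#' @param weights Noise-normalization of the joint objective:
#'   `sigma_y1 / weights["y1_mV"] + sigma_y2 / weights["y2_mK"]`.
#' @export
dynamics_opts <- function(reltol = 1e-10, maxit = 5000, restarts = 3,
                          jitter_sd = 0.05, seed = 20171128,
                          weights = c(y1_mV = 0.2, y2_mK = 5)) {
  list(reltol = reltol, maxit = maxit, restarts = restarts,
       jitter_sd = jitter_sd, seed = seed, weights = weights)
}

softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))
inv_softplus <- function(y) ifelse(y > 30, y, log(expm1(pmax(y, 1e-8))))
SNAP_ZERO_S <- 1e-3

# Draw restart jitter deterministically without disturbing the caller's RNG.
jitter_par <- function(par, sd, seed) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  par + rnorm(length(par), 0, sd)
}

#' Fit the sensor's poles and zeros to a calibration transient
#'
#' Minimizes the RMS misfit between the recorded and simulated outputs over
#' the shared pole time constants and the four zero time constants, by
#' Nelder-Mead over log-parameterized poles (softplus-parameterized zeros with
#' an exact-zero snap below 1 ms). The two channels are fitted jointly with
#' the noise-normalized objective `sigma_y1/0.2 mV + sigma_y2/5 mK` (the
#' per-channel option restricts to one output). With `refine_gains = TRUE`
#' (default) the four sensitivities are re-estimated by linear least squares
#' at every objective evaluation (variable projection), using `gains` as the
#' starting and reported steady-state values; with `FALSE` the supplied gains
#' are held fixed.
#'
#' @param rec Delta-form calibration record containing both transients.
#' @param gains Steady-state gains: a `sensitivity_fit`, a
#'   [sensor_calibration()], or a named vector `c(K1=, K2=, K3=, K4=)`.
#' @param init Named list with `tau = c(tau1, tau2)` and
#'   `tau_star = c(t1s, t2s, t3s, t4s)` initial values in seconds; the default
#'   reflects the typical magnitudes of these devices.
#' @param refine_gains Re-estimate gains inside the fit (see Details).
#' @param channels `"both"` (joint objective), `"y1"` or `"y2"`.
#' @param label Label for the fitted calibration.
#' @param opts See [dynamics_opts()].
#' @return A `calibration_fit`: list with the fitted [sensor_calibration()]
#'   (`$calibration`), `sigma_y1_mV`, `sigma_y2_mK`, the objective `trace`
#'   (best value at each accepted improvement), evaluation counts and the
#'   steady-state `gains` input.
#' @export
fit_dynamics <- function(rec, gains,
                         init = list(tau = c(80, 10),
                                     tau_star = c(60, 100, 0, 20)),
                         refine_gains = TRUE,
                         channels = c("both", "y1", "y2"),
                         label = "fit", opts = dynamics_opts()) {
  channels <- match.arg(channels)
  stopifnot(inherits(rec, "measurement_record"))
  if (!is_delta(rec)) abort("record must be baseline-corrected first (delta form)")
  if (!all(c("W1_mW", "W2_mW", "y1_mV", "y2_C") %in% names(rec))) {
    abort("calibration record needs channels y1_mV, y2_C, W1_mW, W2_mW")
  }
  K0 <- gains_vector(gains)
  dt <- check_uniform_time(rec$t)
  u1 <- rec$W1_mW / 1000
  u2 <- rec$W2_mW / 1000
  y1 <- rec$y1_mV
  y2 <- rec$y2_C
  n <- length(y1)
  w <- opts$weights

  trace_env <- new.env(parent = emptyenv())
  trace_env$trace <- numeric(0)
  trace_env$neval <- 0L

  decode <- function(theta) {
    tau <- sort(exp(theta[1:2]), decreasing = TRUE)
    stars <- softplus(theta[3:6])
    stars[stars < SNAP_ZERO_S] <- 0
    list(tau = tau, stars = stars)
  }

  eval_fit <- function(theta) {
    p <- decode(theta)
    cache <- pole_cache(p$tau[1], p$tau[2], dt)
    b1 <- sim_channel(1, p$stars[1], p$tau[1], p$tau[2], u1, dt, cache = cache)
    b2 <- sim_channel(1, p$stars[2], p$tau[1], p$tau[2], u2, dt, cache = cache)
    b3 <- sim_channel(1, p$stars[3], p$tau[1], p$tau[2], u1, dt, cache = cache)
    b4 <- sim_channel(1, p$stars[4], p$tau[1], p$tau[2], u2, dt, cache = cache)
    if (refine_gains) {
      K <- c(ls2(b1, b2, y1), ls2(b3, b4, y2))
    } else {
      K <- unname(K0)
    }
    r1 <- y1 - (K[1] * b1 + K[2] * b2)
    r2 <- y2 - (K[3] * b3 + K[4] * b4)
    s1 <- sqrt(mean(r1^2))            # mV
    s2 <- sqrt(mean(r2^2)) * 1000     # mK
    obj <- switch(channels,
      both = s1 / w[["y1_mV"]] + s2 / w[["y2_mK"]],
      y1 = s1 / w[["y1_mV"]],
      y2 = s2 / w[["y2_mK"]])
    list(obj = obj, K = K, s1 = s1, s2 = s2)
  }

  objective <- function(theta) {
    v <- eval_fit(theta)$obj
    if (!is.finite(v) || v < 0) abort("invalid (negative/NaN) objective value")
    trace_env$neval <- trace_env$neval + 1L
    if (!length(trace_env$trace) || v < min(trace_env$trace)) {
      trace_env$trace <- c(trace_env$trace, v)
    }
    v
  }

  theta0 <- c(log(init$tau), inv_softplus(pmax(init$tau_star, SNAP_ZERO_S)))
  best <- optim(theta0, objective, method = "Nelder-Mead",
                control = list(reltol = opts$reltol, maxit = opts$maxit))
  for (r in seq_len(opts$restarts)) {
    start <- jitter_par(best$par, opts$jitter_sd, opts$seed + r)
    cand <- optim(start, objective, method = "Nelder-Mead",
                  control = list(reltol = opts$reltol, maxit = opts$maxit))
    improved <- cand$value < best$value * (1 - 1e-8)
    if (cand$value < best$value) best <- cand
    if (!improved) break
  }
  if (best$convergence != 0 && best$convergence != 1) {
    abort(sprintf("Nelder-Mead failed to converge (code %d)", best$convergence))
  }

  p <- decode(best$par)
  final <- eval_fit(best$par)
  cal <- sensor_calibration(
    K1 = final$K[1], K2 = final$K[2], K3 = final$K[3], K4 = final$K[4],
    tau1 = p$tau[1], tau2 = p$tau[2],
    tau1_star = p$stars[1], tau2_star = p$stars[2],
    tau3_star = p$stars[3], tau4_star = p$stars[4],
    label = label,
    K_se = if (inherits(gains, "sensitivity_fit")) {
      setNames(gains$gains$std.error, gains$gains$term)
    })
  resid <- tibble::tibble(
    t = rec$t,
    resid_y1_mV = y1 - (final$K[1] * sim_channel(1, p$stars[1], p$tau[1], p$tau[2], u1, dt) +
                        final$K[2] * sim_channel(1, p$stars[2], p$tau[1], p$tau[2], u2, dt)),
    resid_y2_K = y2 - (final$K[3] * sim_channel(1, p$stars[3], p$tau[1], p$tau[2], u1, dt) +
                       final$K[4] * sim_channel(1, p$stars[4], p$tau[1], p$tau[2], u2, dt)))
  out <- list(
    calibration = cal,
    sigma_y1_mV = final$s1,
    sigma_y2_mK = final$s2,
    n = n,
    trace = trace_env$trace,
    n_eval = trace_env$neval,
    refine_gains = refine_gains,
    gains = K0,
    residuals = resid,
    convergence = best$convergence)
  class(out) <- "calibration_fit"
  out
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat("<calibration_fit>\n")
  print(x$calibration)
  cat(sprintf("  sigma_y1 = %.4f mV, sigma_y2 = %.3f mK (N = %d, %d evals)\n",
              x$sigma_y1_mV, x$sigma_y2_mK, x$n, x$n_eval))
  invisible(x)
}

#' @export
tidy.calibration_fit <- function(x, ...) tidy(x$calibration)

#' @export
glance.calibration_fit <- function(x, ...) {
  tibble::tibble(sigma_y1_mV = x$sigma_y1_mV, sigma_y2_mK = x$sigma_y2_mK,
                 n = x$n, n_eval = x$n_eval, convergence = x$convergence,
                 refined_gains = x$refine_gains)
}

#' Calibrate a sensor from a full calibration record
#'
#' Convenience pipeline mirroring the calibration protocol: baseline
#' correction (pre-window in the first quiescent zone, post-window at the end
#' of the record), steady-state zone extraction, sensitivity solving and the
#' dynamic pole/zero fit.
#'
#' @param rec Raw (non-delta) calibration record.
#' @param protocol The [protocol_schedule()] that produced the record.
#' @param ... Passed on to [fit_dynamics()].
#' @inheritParams extract_steady_states
#' @return A `calibration_fit` with the `steady_states` tibble and the
#'   `sensitivities` stage attached.
#' @export
calibrate_record <- function(rec, protocol = calibration_protocol(),
                             settle_multiplier = 3, tau_rough = 50, ...) {
  zones <- protocol_zones(protocol)
  z1 <- zones[1, ]
  total <- max(zones$end)
  pre <- c(max(z1$start, z1$end - 100), z1$end)
  post <- c(total - 100, total)
  drec <- correct_baseline(rec, pre, post)
  ss <- extract_steady_states(drec, protocol,
                              settle_multiplier = settle_multiplier,
                              tau_rough = tau_rough)
  sens <- solve_sensitivities(ss)
  fit <- fit_dynamics(drec, sens, ...)
  fit$steady_states <- ss
  fit$sensitivities <- sens
  fit
}
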