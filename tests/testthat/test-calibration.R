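test_that("baseline correction removes constants and linear drift", {
  t <- 0:499
  rec <- new_measurement_record(tibble::tibble(
    t = t, y1_mV = 3.2, y2_C = 24, W1_mW = 0, W2_mW = 500))
  d <- correct_baseline(rec, c(0, 50), c(450, 500))
  expect_equal(d$y1_mV, rep(0, 500))
  expect_true(is_delta(d))

  drifty <- new_measurement_record(tibble::tibble(
    t = t, y1_mV = 1 + 0.01 * t, y2_C = 24 + 0.001 * t,
    W1_mW = 0, W2_mW = 500 - 0.05 * t))
  dd <- correct_baseline(drifty, c(0, 50), c(450, 500))
  expect_equal(max(abs(dd$y1_mV)), 0, tolerance = 1e-10)
  expect_equal(max(abs(dd$W2_mW)), 0, tolerance = 1e-10)
})

test_that("baseline windows are validated", {
  rec <- new_measurement_record(
    tibble::tibble(t = 0:499, y1_mV = 0, y2_C = 24, W2_mW = 500),
    phases = tibble::tibble(label = c("baseline", "contact", "return"),
                            start = c(0, 200, 300), end = c(200, 300, 500)))
  expect_error(correct_baseline(rec, c(0, 5)), "fewer than 10")
  expect_error(correct_baseline(rec, c(0, 100), c(250, 320)), "contact")
  d <- correct_baseline(rec, c(0, 100))
  expect_error(correct_baseline(d, c(0, 100)), "already")
})

test_that("steady-state zones of a settled noiseless run match the sensitivity matrix", {
  # fast-settling sensor and programmed W2 steps aligned to the zone grid,
  # so every zone is at its exact steady state after the settle cut
  cal <- fast_sensor()
  t <- 0:1499
  W2 <- c(rep(500, 150), rep(840, 300), rep(610, 300), rep(840, 300),
          rep(500, 450))
  W1 <- c(rep(0, 450), rep(300, 300), rep(0, 750))
  sim <- simulate_outputs(tibble::tibble(t = t, W1_mW = W1, W2_mW = W2), cal)
  rec <- new_measurement_record(tibble::tibble(
    t = t, y1_mV = sim$y1_mV + 0.7, y2_C = 24 + sim$y2_K,
    W1_mW = W1, W2_mW = W2))
  d <- correct_baseline(rec, c(50, 150), c(1400, 1500))
  ss <- extract_steady_states(d, calibration_protocol())
  expect_equal(ss$zone, letters[1:5])
  pred <- steady_state_outputs(cal, ss$dW1_W, ss$dW2_W)
  expect_equal(ss$dy1_mV, pred$dy1_mV, tolerance = 1e-9)
  expect_equal(ss$dy2_K, pred$dy2_K, tolerance = 1e-9)
  expect_false(any(ss$flagged))
})

test_that("zones shorter than the settle cut raise an error", {
  cal <- fast_sensor()
  proto <- protocol_schedule(
    segments = tibble::tibble(Tcal_C = c(24, 28, 24),
                              duration_s = c(150, 200, 100)),
    W1_events = tibble::tibble(start_s = 200, duration_s = 100, power_mW = 300))
  rec <- generate_calibration_run(cal, proto, noise = noiseless())
  d <- correct_baseline(rec, c(50, 150))
  expect_error(extract_steady_states(d, proto), "settle cut")
})

test_that("sensitivities are recovered exactly from noiseless zones", {
  s1 <- sensor_s1()
  zones <- tibble::tibble(dW1_W = c(0, 0, 0.3, 0, 0),
                          dW2_W = c(0, 0.34, 0.11, 0.34, 0))
  out <- steady_state_outputs(s1, zones$dW1_W, zones$dW2_W)
  fit <- solve_sensitivities(dplyr::bind_cols(zones, out[, c("dy1_mV", "dy2_K")]))
  expect_equal(tidy(fit)$estimate, c(s1$K1, s1$K2, s1$K3, s1$K4),
               tolerance = 1e-9)
})

test_that("noisy zone means recover K1 within the stated uncertainty", {
  s1 <- sensor_s1()
  zones <- tibble::tibble(dW1_W = c(0, 0, 0.3, 0, 0),
                          dW2_W = c(0, 0.34, 0.11, 0.34, 0))
  truth <- steady_state_outputs(s1, zones$dW1_W, zones$dW2_W)
  set.seed(1)
  k1 <- replicate(100, {
    # zone means over 150 samples of the stated band-limited noise
    noisy <- dplyr::bind_cols(zones, truth[, c("dy1_mV", "dy2_K")])
    noisy$dy1_mV <- noisy$dy1_mV +
      vapply(seq_len(5), function(i) mean(fluxcal:::band_noise(150, 0.2)), 0)
    noisy$dy2_K <- noisy$dy2_K +
      vapply(seq_len(5), function(i) mean(fluxcal:::band_noise(150, 5)) / 1000, 0)
    tidy(solve_sensitivities(noisy))$estimate[1]
  })
  expect_lt(abs(mean(k1) - 117.98), 0.33)
})

test_that("proportional zones trigger a singularity error", {
  zones <- tibble::tibble(dW1_W = c(0.1, 0.2), dW2_W = c(0.05, 0.1),
                          dy1_mV = c(1, 2), dy2_K = c(0.5, 1))
  expect_error(solve_sensitivities(zones), "proportional")
})

test_that("the dynamic fit is scale-equivariant and its trace decreases", {
  cal <- sensor_s1()
  rec <- generate_calibration_run(cal, noise = noiseless())
  d <- correct_baseline(rec, c(50, 150), c(1400, 1500))
  opts <- dynamics_opts(maxit = 2000, restarts = 0)
  init <- list(tau = c(100, 12), tau_star = c(70, 90, 0, 25))
  f1 <- fit_dynamics(d, c(K1 = 118, K2 = -51, K3 = 9, K4 = 12),
                     init = init, channels = "y1", opts = opts)
  # objective trace records accepted improvements only: strictly decreasing
  expect_true(all(diff(f1$trace) < 0))
  expect_lt(f1$trace[length(f1$trace)], f1$trace[1])

  # scaling y1 and (K1, K2) together must not move the time constants:
  # the objective landscape only scales, so the search path is unchanged
  d2 <- d
  d2$y1_mV <- d$y1_mV * 7
  f2 <- fit_dynamics(d2, c(K1 = 118 * 7, K2 = -51 * 7, K3 = 9, K4 = 12),
                     init = init, channels = "y1", opts = opts)
  expect_equal(f2$calibration$tau1, f1$calibration$tau1, tolerance = 1e-6)
  expect_equal(f2$calibration$tau2, f1$calibration$tau2, tolerance = 1e-6)
  expect_equal(f2$calibration$K1, 7 * f1$calibration$K1, tolerance = 1e-6)
})

test_that("a zero-valued zero time constant stays snapped at the boundary", {
  cal <- sensor_s1()
  rec <- generate_calibration_run(cal, noise = noiseless())
  fit <- calibrate_record(rec, opts = dynamics_opts(restarts = 1))
  expect_identical(fit$calibration$tau3_star, 0)
})

test_that("injected linear drift leaves the recovered sensitivities unchanged", {
  cal <- sensor_s1()
  clean <- calibrate_record(
    generate_calibration_run(cal, noise = noiseless()),
    opts = dynamics_opts(restarts = 0))
  drifted <- calibrate_record(
    generate_calibration_run(cal, noise = noiseless(),
                             y1_drift_mV_per_s = 0.01),
    opts = dynamics_opts(restarts = 0))
  expect_equal(drifted$calibration$K1, clean$calibration$K1, tolerance = 5e-3)
  expect_equal(drifted$calibration$K2, clean$calibration$K2, tolerance = 5e-3)
})

test_that("randomized ground-truth sensors are identified from noiseless runs", {
  set.seed(20171128)
  for (draw in seq_len(20)) {
    truth <- suppressWarnings(sensor_calibration(
      K1 = runif(1, 100, 140), K2 = runif(1, -60, -35),
      K3 = runif(1, 7, 10), K4 = runif(1, 9, 13),
      tau1 = runif(1, 40, 120), tau2 = runif(1, 4, 15),
      tau1_star = runif(1, 40, 110), tau2_star = runif(1, 60, 120),
      tau3_star = 0, tau4_star = runif(1, 10, 30),
      label = paste0("draw", draw)))
    rec <- generate_calibration_run(truth, noise = noiseless())
    fit <- calibrate_record(rec, opts = dynamics_opts(restarts = 1))
    expect_lt(max(rel_err(sensor_params(fit$calibration),
                          sensor_params(truth))), 0.01)
  }
})
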