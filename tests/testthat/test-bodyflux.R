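test_that("flux models evaluate to the expected values", {
  m <- flux_model(193.7, c(1156.4, 101.0), c(2.0, 21.2))
  # at the application instant all terms contribute fully
  expect_equal(evaluate_flux(m, 0)$W1_mW, 193.7 + 1156.4 + 101.0)
  # exponentials vanish
  expect_equal(evaluate_flux(m, 1e6)$W1_mW, 193.7)
  # Heaviside-type flux: constant A0
  expect_equal(evaluate_flux(flux_model(50), c(0, 10, 100))$W1_mW, rep(50, 3))
  # zero before application and after removal
  m2 <- flux_model(100, 20, 5, t_origin = 10)
  expect_equal(evaluate_flux(m2, c(0, 9.5), t_end = 60)$W1_mW, c(0, 0))
  expect_equal(evaluate_flux(m2, 60, t_end = 60)$W1_mW, 0)
  expect_error(flux_model(1, 1, -3), "time constant")
  expect_error(flux_model(1, c(1, 2), 3), "same length")
})

test_that("flux models are stored in canonical (increasing tau) order", {
  m <- flux_model(10, c(5, 7), c(70, 3))
  expect_equal(m$tau_s, c(3, 70))
  expect_equal(m$A_mW, c(7, 5))
})

test_that("window means follow the closed form", {
  expect_equal(mean_power(flux_model(42), c(0, 123)), 42)
  # single decaying term averaged over a long window tends to A0
  expect_equal(mean_power(flux_model(10, 100, 5), c(0, 1e8)), 10,
               tolerance = 1e-6)
  m <- flux_model(0, 100, 10)
  closed <- mean_power(m, c(0, 100))
  expect_equal(closed, 100 * 10 * (1 - exp(-10)) / 100, tolerance = 1e-12)
  # independent oracle: numerical quadrature of the evaluated flux
  quad <- stats::integrate(function(x) fluxcal:::flux_values(m, x),
                           0, 100, rel.tol = 1e-10)$value / 100
  expect_equal(closed, quad, tolerance = 1e-8)
  expect_error(mean_power(m, c(50, 50)), "window")
})

test_that("a noiseless body run is inverted exactly (free time constants)", {
  cal <- sensor_s1()
  truth <- flux_model(156.6, c(779.3, 25.4), c(3.1, 20.0))
  rec <- generate_body_run(cal, 28, body = body_model(flux = truth),
                           noise = noiseless())
  fit <- quiet_fit_flux(rec, cal)
  est <- c(fit$model$A0_mW, fit$model$A_mW, fit$model$tau_s)
  tru <- c(156.6, 779.3, 25.4, 3.1, 20.0)
  expect_lt(max(rel_err(est, tru)), 0.01)
  expect_lt(fit$sigma_y1_pct, 1e-3)
})

test_that("a signal produced by the candidate model itself has zero error", {
  cal <- sensor_s1()
  rec <- generate_body_run(cal, 32, noise = noiseless())
  fit <- quiet_fit_flux(rec, cal, fixed_taus = c(3, 70))
  # the generator's truth uses exactly these time constants: residual ~ 0
  expect_lt(fit$sigma_y1_pct, 1e-6)
})

test_that("fit_flux rejects bad windows and over-parameterized models", {
  cal <- sensor_s1()
  rec <- generate_body_run(cal, 28, noise = noiseless())
  expect_error(quiet_fit_flux(rec, cal, window = c(300, 350)), "60 s")
  expect_error(quiet_fit_flux(rec, cal, n_terms = 5), "unidentifiable")
  expect_error(quiet_fit_flux(rec, cal, n_terms = 2, fixed_taus = 3),
               "per term")
})

test_that("A0 is insensitive to the slow time-constant choice when taus are fixed", {
  cal <- sensor_s1()
  truth <- flux_model(156.6, c(779.3, 25.4), c(3.1, 20.0))
  rec <- generate_body_run(cal, 28, body = body_model(flux = truth),
                           noise = noiseless())
  a0 <- vapply(c(50, 70, 90), function(t2) {
    quiet_fit_flux(rec, cal, fixed_taus = c(3, t2))$model$A0_mW
  }, numeric(1))
  expect_lt(diff(range(a0)) / mean(a0), 0.005)
})

test_that("tidy and glance expose the fitted flux coefficients", {
  cal <- sensor_s1()
  rec <- generate_body_run(cal, 28, seed = 11)
  fit <- quiet_fit_flux(rec, cal, fixed_taus = c(3, 70))
  td <- tidy(fit)
  expect_equal(td$term, c("A0", "A1", "A2", "tau1", "tau2"))
  expect_equal(td$estimate[4:5], c(3, 70))
  gl <- glance(fit)
  expect_true(gl$fixed_taus)
  expect_gte(gl$sigma_y1_pct, 0)
  expect_equal(gl$A0_mW, fit$model$A0_mW)
})
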