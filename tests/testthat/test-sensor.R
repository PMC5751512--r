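test_that("step responses have the correct steady gain and shape", {
  t <- 0:2000
  # unit gain, no zero: final value is K * A
  unit <- suppressWarnings(sensor_calibration(1, -1, 1, 1, tau1 = 50, tau2 = 5,
                                              label = "unit"))
  st <- tf_step_response(unit, "TF1", amplitude = 1, t = t)
  expect_equal(st$response[length(t)], 1, tolerance = 1e-12)
  expect_equal(st$response[1], 0)

  # S1 with a 0.3 W step reaches K1 * 0.3 = 35.394 mV
  s1 <- sensor_s1()
  st1 <- tf_step_response(s1, "TF1", amplitude = 0.3, t = t)
  expect_equal(st1$response[length(t)], 35.394, tolerance = 1e-6)

  # zero cancelling the slow pole leaves a single exponential in tau2
  pz <- suppressWarnings(sensor_calibration(2, -1, 1, 1, tau1 = 50, tau2 = 5,
                                            tau1_star = 50, label = "pz"))
  st2 <- tf_step_response(pz, "TF1", amplitude = 1, t = t)
  expect_equal(st2$response, 2 * (1 - exp(-t / 5)), tolerance = 1e-12)
})

test_that("invalid models are rejected and sign conventions warned about", {
  expect_error(sensor_calibration(1, -1, 1, 1, tau1 = -2, tau2 = 5),
               "pole")
  expect_error(sensor_calibration(1, -1, 1, 1, tau1 = 10, tau2 = 5,
                                  tau1_star = -1), ">= 0")
  expect_warning(sensor_calibration(-1, -1, 1, 1, tau1 = 10, tau2 = 5),
                 "sign")
  expect_warning(sensor_calibration(1, 2, 1, 1, tau1 = 10, tau2 = 5), "K2")
})

test_that("steady-state outputs follow the sensitivity matrix", {
  s1 <- sensor_s1()
  z <- steady_state_outputs(s1, 0, 0)
  expect_equal(c(z$dy1_mV, z$dy2_K), c(0, 0))
  a <- steady_state_outputs(s1, 0.3, 0)
  expect_equal(a$dy1_mV, 35.394, tolerance = 1e-12)
  expect_equal(a$dy2_K, 2.694, tolerance = 1e-12)
  b <- steady_state_outputs(sensor_s2(), 0, 1)
  expect_equal(b$dy1_mV, -42.22, tolerance = 1e-12)
  expect_equal(b$dy2_K, 9.82, tolerance = 1e-12)
})

test_that("numerical integration matches the closed-form step response", {
  s1 <- sensor_s1()
  t <- 0:1200
  for (ch in c("TF1", "TF2", "TF3", "TF4")) {
    cf <- tf_step_response(s1, ch, amplitude = 0.3, t = t)$response
    inputs <- if (ch %in% c("TF2", "TF4")) {
      tibble::tibble(t = t, W2_mW = rep(300, length(t)))
    } else {
      tibble::tibble(t = t, W1_mW = rep(300, length(t)))
    }
    sim <- suppressWarnings(simulate_outputs(inputs, s1, init = "zero"))
    y <- if (ch %in% c("TF1", "TF2")) sim$y1_mV else sim$y2_K
    expect_lt(max(abs(y - cf)) / max(abs(cf)), 1e-6)
  }
})

test_that("zero inputs with steady init give identically zero outputs", {
  inputs <- tibble::tibble(t = 0:100, W1_mW = 0, W2_mW = 0)
  sim <- simulate_outputs(inputs, sensor_s1())
  expect_equal(sim$y1_mV, rep(0, 101))
  expect_equal(sim$y2_K, rep(0, 101))
})

test_that("constant inputs held to steady state reach the sensitivity values", {
  s1 <- sensor_s1()
  n <- ceiling(10 * s1$tau1) + 200
  inputs <- tibble::tibble(t = seq_len(n) - 1,
                           W1_mW = c(0, rep(250, n - 1)),
                           W2_mW = c(0, rep(400, n - 1)))
  sim <- simulate_outputs(inputs, s1, init = "steady")
  ss <- steady_state_outputs(s1, 0.25, 0.4)
  expect_equal(sim$y1_mV[n], ss$dy1_mV, tolerance = 1e-3)
  expect_equal(sim$y2_K[n], ss$dy2_K, tolerance = 1e-3)
})

test_that("the simulator is linear and time-invariant", {
  s1 <- sensor_s1()
  t <- 0:400
  set.seed(42)
  w_a <- cumsum(rnorm(length(t), 0, 5))
  w_b <- 100 * sin(t / 40)
  simf <- function(w) {
    simulate_outputs(tibble::tibble(t = t, W1_mW = w), s1, init = "zero")$y1_mV
  }
  # superposition
  lhs <- simf(2 * w_a + 3 * w_b)
  rhs <- 2 * simf(w_a) + 3 * simf(w_b)
  expect_equal(lhs, rhs, tolerance = 1e-10)
  # time invariance: shifting a constant-padded input shifts the output
  k <- 25
  w_shift <- c(rep(w_a[1], k), w_a[seq_len(length(t) - k)])
  y <- simulate_outputs(tibble::tibble(t = t, W1_mW = w_a), s1)$y1_mV
  y_shift <- simulate_outputs(tibble::tibble(t = t, W1_mW = w_shift), s1)$y1_mV
  expect_equal(y_shift[(k + 1):length(t)], y[seq_len(length(t) - k)],
               tolerance = 1e-10)
})

test_that("repeated poles fall back to the confluent closed form", {
  rep_cal <- suppressWarnings(sensor_calibration(
    100, -50, 9, 12, tau1 = 20, tau2 = 20, tau2_star = 10, label = "rep"))
  t <- 0:600
  cf <- tf_step_response(rep_cal, "TF1", amplitude = 1, t = t)$response
  # confluent form with tau* = 0: K (1 - (1 + t/tau) exp(-t/tau))
  expect_equal(cf, 100 * (1 - (1 + t / 20) * exp(-t / 20)), tolerance = 1e-12)
  sim <- simulate_outputs(tibble::tibble(t = t, W1_mW = rep(1000, length(t))),
                          rep_cal, init = "zero")
  expect_lt(max(abs(sim$y1_mV - cf)) / 100, 1e-6)
})

test_that("thermostat power outside its actuator range is flagged, not clipped", {
  inputs <- tibble::tibble(t = 0:99, W2_mW = c(rep(500, 90), rep(1500, 10)))
  expect_warning(sim <- simulate_outputs(inputs, sensor_s1()), "flagged")
  expect_equal(sum(sim$saturated), 10)
})

test_that("sensor parameter files round-trip and ship Table-consistent fixtures", {
  p <- withr::local_tempfile(fileext = ".txt")
  write_sensor(sensor_s2(), p)
  back <- read_sensor(p)
  expect_equal(back[1:10], sensor_s2()[1:10])
  s1_file <- read_sensor(system.file("extdata", "S1.txt", package = "fluxcal"))
  expect_equal(s1_file[1:10], sensor_s1()[1:10])
  expect_error(read_sensor(withr::local_tempfile()), "not found")
})

test_that("simulate_outputs validates its inputs", {
  expect_error(simulate_outputs(tibble::tibble(t = c(0, 1, 3), W1_mW = 0),
                                sensor_s1()), "non-uniform")
  expect_error(simulate_outputs(tibble::tibble(t = 0:2, W1_mW = c(0, NA, 0)),
                                sensor_s1()), "NaN")
})
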