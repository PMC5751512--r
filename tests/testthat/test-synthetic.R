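test_that("records are deterministic under a fixed seed", {
  cal <- sensor_s1()
  r1 <- generate_calibration_run(cal, seed = 1)
  r2 <- generate_calibration_run(cal, seed = 1)
  expect_identical(as.data.frame(r1), as.data.frame(r2))
  r3 <- generate_calibration_run(cal, seed = 2)
  expect_false(identical(r1$y1_mV, r3$y1_mV))
  # different seeds differ only within the noise scale
  expect_lt(max(abs(r1$y1_mV - r3$y1_mV)), 5 * 0.2)
})

test_that("noise realizations respect the stated half-amplitudes", {
  set.seed(99)
  u <- fluxcal:::band_noise(20000, 0.2, kind = "uniform")
  expect_lte(max(abs(u)), 0.2)
  g <- fluxcal:::band_noise(20000, 0.2, kind = "smoothed")
  # white sd = half/2, 5-sample moving average -> sd = half/2/sqrt(5)
  expect_equal(sd(g), 0.2 / 2 / sqrt(5), tolerance = 0.1)
  expect_gte(mean(abs(g) <= 0.2), 0.95)
  expect_identical(fluxcal:::band_noise(100, 0), rep(0, 100))
})

test_that("the thermostat loop idles at the feedforward power and tracks steps", {
  cal <- sensor_s1()
  # constant setpoint, no disturbance: zero error, constant W2
  idle <- pid_thermostat(cal, rep(24, 200))
  expect_equal(idle$W2_mW, rep(500, 200))
  expect_equal(idle$y2_C, rep(24, 200))

  # +4 K setpoint step settles to within +-5 mK in at most 300 s
  sp <- c(rep(24, 50), rep(28, 600))
  loop <- pid_thermostat(cal, sp)
  err <- 28 - loop$y2_C[(50 + 300):650]
  expect_lt(max(abs(err)), 0.005)
})

test_that("contact excursions flip sign with the thermostat-body temperature difference", {
  cal <- sensor_s1()
  mk <- function(tcal) {
    body <- body_model(flux = flux_model(100, 800 * (32 - tcal) / 8, 3))
    rec <- generate_body_run(cal, tcal, body = body, noise = noiseless())
    w2 <- rec$W2_mW - mean(rec$W2_mW[250:299])
    w2[301:320]  # just after contact
  }
  cold <- mk(24)   # thermostat below the skin: flux rushes in
  warm <- mk(36)
  expect_gt(max(abs(cold)), 1)
  expect_lt(sum(sign(cold) == sign(warm[which.max(abs(warm))])), 5)
  # the initial excursions point in opposite directions
  expect_true(sign(cold[which.max(abs(cold))]) !=
              sign(warm[which.max(abs(warm))]))
})

test_that("an unstable loop is detected and reported with its gains", {
  cal <- sensor_s1()
  sp <- c(rep(24, 10), rep(28, 400))
  expect_error(
    pid_thermostat(cal, sp, gains = c(Kp = 80, Ki = 20, Kd = 0),
                   bounds_mW = c(-1e6, 1e6)),
    "Kp = 80")
})

test_that("steady contact segments conserve the sensitivity balance", {
  cal <- sensor_s1()
  # long contact with fast flux decay: truly steady by the end
  proto <- protocol_schedule(
    segments = tibble::tibble(Tcal_C = 28, duration_s = 1800),
    contact = c(300, 1200))
  body <- body_model(flux = flux_model(150, 500, 20))
  rec <- generate_body_run(cal, 28, body = body, protocol = proto,
                           noise = noiseless())
  d <- correct_baseline(rec, c(200, 300))
  i <- window_end <- max(which(rec$t < 1500))
  w1 <- attr(rec, "truth")$W1_true_mW[i] / 1000
  w2 <- d$W2_mW[i] / 1000
  expect_equal(d$y1_mV[i], cal$K1 * w1 + cal$K2 * w2, tolerance = 1e-4)
})

test_that("protocol schedules validate their events and windows", {
  expect_error(protocol_schedule(
    tibble::tibble(Tcal_C = 24, duration_s = 100),
    W1_events = tibble::tibble(start_s = 90, duration_s = 20, power_mW = 300)),
    "within the protocol span")
  expect_error(protocol_schedule(
    tibble::tibble(Tcal_C = 24, duration_s = 100), contact = c(50, 60)),
    "contact window")
  expect_error(protocol_schedule(
    tibble::tibble(Tcal_C = 24, duration_s = -5)), "> 0")
})

test_that("body records carry phases, truth and no W1 channel", {
  cal <- sensor_s1()
  rec <- generate_body_run(cal, 28, seed = 5)
  expect_false("W1_mW" %in% names(rec))
  expect_equal(record_phases(rec)$label, c("baseline", "contact", "return"))
  expect_s3_class(attr(rec, "truth")$flux, "flux_model")
  expect_equal(phase_window(rec, "contact"), c(300, 600))
  expect_equal(unique(rec$Troom_C), 24.7)
})
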