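# Shared fixtures: everything is generated in code at test time.

noiseless <- function() noise_spec(0, 0, 0, 0)

# fit_flux announces its automatic baseline correction; keep test output clean
quiet_fit_flux <- function(...) suppressMessages(fit_flux(...))

# A fast-settling sensor: same structure as the real devices but with short
# time constants, so steady state is reached exactly within the zones.
fast_sensor <- function() {
  suppressWarnings(sensor_calibration(
    K1 = 120, K2 = -50, K3 = 9, K4 = 12,
    tau1 = 5, tau2 = 1, tau1_star = 4, tau2_star = 6,
    tau3_star = 0, tau4_star = 2, label = "fast"))
}

# Ground-truth parameter vector of a sensor, in tidy() order.
sensor_params <- function(cal) {
  c(cal$K1, cal$K2, cal$K3, cal$K4, cal$tau1, cal$tau2,
    cal$tau1_star, cal$tau2_star, cal$tau3_star, cal$tau4_star)
}

# Relative error that tolerates exact zeros in the truth (absolute there).
rel_err <- function(est, truth) {
  abs(est - truth) / ifelse(abs(truth) > 0, abs(truth), 1)
}
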