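# Exact zero-order-hold simulation of the sensor channels. Each SISO channel
#   Y(s)/U(s) = K (1 + s tau*) / ((1 + s tau1)(1 + s tau2))
# is realized in observable canonical state space (the numerator derivative is
# absorbed by the B matrix, so no input differentiation is ever performed) and
# advanced one sample at a time under the assumption that the input is held
# constant over each sampling interval. The discrete transition pair (Ad, Bd)
# comes from the eigendecomposition of the 2x2 companion matrix -- the poles
# -1/tau1, -1/tau2 are known analytically -- with a Jordan-form fallback for
# (near-)repeated poles, where the eigenbasis degenerates. The discretized
# system collapses to a second-order linear recurrence evaluated by
# stats::filter, so a full record simulates in microseconds.

# Pole-dependent part of the ZOH discretization, shared by all four channels
# (they have identical denominators). M maps a continuous input matrix B to
# its discrete counterpart Bd = M B.
pole_cache <- function(tau1, tau2, dt) {
  p <- tau1 * tau2
  a1 <- (tau1 + tau2) / p
  a0 <- 1 / p
  A <- matrix(c(-a1, -a0, 1, 0), 2, 2)
  if (abs(tau1 - tau2) <= 1e-6 * max(tau1, tau2)) {
    # (near-)repeated pole: Jordan form exp(A dt) = e^(lambda dt) (I + N dt),
    # with N = A - lambda I nilpotent up to O((tau1 - tau2)^2)
    lam <- -(1 / tau1 + 1 / tau2) / 2
    N <- A - lam * diag(2)
    Ad <- exp(lam * dt) * (diag(2) + N * dt)
  } else {
    V <- matrix(c(1, 1 / tau2, 1, 1 / tau1), 2, 2)
    Ad <- V %*% diag(exp(-dt / c(tau1, tau2))) %*% solve(V)
  }
  list(p = p, Ad = Ad, M = solve(A, Ad - diag(2)),
       tr = Ad[1, 1] + Ad[2, 2],
       det = Ad[1, 1] * Ad[2, 2] - Ad[1, 2] * Ad[2, 1])
}

discretize_channel <- function(K, tau_star, tau1, tau2, dt,
                               cache = pole_cache(tau1, tau2, dt)) {
  B <- c(K * tau_star / cache$p, K / cache$p)
  Bd <- as.numeric(cache$M %*% B)
  # second-order recurrence y[k] = tr y[k-1] - det y[k-2] + n1 u[k-1] + n2 u[k-2]
  list(Ad = cache$Ad, Bd = Bd, tr = cache$tr, det = cache$det,
       n1 = Bd[1],
       n2 = cache$Ad[1, 2] * Bd[2] - cache$Ad[2, 2] * Bd[1])
}

# u in W, returns output in the channel's units (mV or K). With u0 = u[1] the
# system starts at the steady state implied by the first sample (steady init);
# u0 = 0 gives a zero initial state.
sim_channel <- function(K, tau_star, tau1, tau2, u, dt = 1, u0 = u[[1]],
                        cache = NULL) {
  n <- length(u)
  if (n < 2) abort("channel simulation needs at least 2 samples")
  if (is.null(cache)) cache <- pole_cache(tau1, tau2, dt)
  d <- discretize_channel(K, tau_star, tau1, tau2, dt, cache)
  ub <- u - u0
  v <- d$n1 * c(0, ub[-n]) + d$n2 * c(0, 0, ub[seq_len(n - 2)])
  y <- stats::filter(v, c(d$tr, -d$det), method = "recursive")
  as.numeric(y) + K * u0
}

# 2-column least squares via the normal equations (well-conditioned here).
ls2 <- function(b1, b2, y) {
  X <- cbind(b1, b2)
  as.numeric(solve(crossprod(X), crossprod(X, y)))
}

#' Simulate the sensor outputs for arbitrary input powers
#'
#' Integrates the two coupled second-order channel equations
#' `tau1 tau2 y'' + (tau1 + tau2) y' + y = K (tau* W' + W)` (one pair of terms
#' per input, shared poles) with an exact zero-order-hold discretization at the
#' record's sampling step, treating the inputs as piecewise constant over each
#' interval. The zero terms `tau* W'` are absorbed into the state-space input
#' matrix, so no numerical differentiation of the inputs takes place.
#'
#' @param inputs Data frame with a `t` column (s) and input channels `W1_mW`
#'   and/or `W2_mW` (mW); a missing channel is taken as identically zero.
#' @param cal A [sensor_calibration()].
#' @param init `"steady"` (default) starts each channel at the steady state
#'   implied by the first input sample; `"zero"` starts from rest.
#' @param W2max_mW Saturation bound for the thermostat power: samples where
#'   `W2_mW` leaves `[0, W2max_mW]` are flagged in the `saturated` column (and
#'   a warning is raised); the dynamics are not clipped.
#' @return A tibble with columns `t`, `y1_mV`, `y2_K` (both in delta form
#'   relative to the steady baseline) and `saturated`.
#' @export
simulate_outputs <- function(inputs, cal, init = c("steady", "zero"),
                             W2max_mW = 1000) {
  init <- match.arg(init)
  stopifnot(inherits(cal, "sensor_calibration"))
  if (!is.data.frame(inputs) || !"t" %in% names(inputs)) {
    abort("`inputs` must be a data frame with a `t` column")
  }
  dt <- check_uniform_time(inputs$t)
  n <- nrow(inputs)
  u1 <- if ("W1_mW" %in% names(inputs)) inputs$W1_mW / 1000 else rep(0, n)
  u2 <- if ("W2_mW" %in% names(inputs)) inputs$W2_mW / 1000 else rep(0, n)
  if (any(!is.finite(u1)) || any(!is.finite(u2))) abort("NaN/Inf in input powers")
  u10 <- if (init == "steady") u1[1] else 0
  u20 <- if (init == "steady") u2[1] else 0
  y1 <- sim_channel(cal$K1, cal$tau1_star, cal$tau1, cal$tau2, u1, dt, u10) +
        sim_channel(cal$K2, cal$tau2_star, cal$tau1, cal$tau2, u2, dt, u20)
  y2 <- sim_channel(cal$K3, cal$tau3_star, cal$tau1, cal$tau2, u1, dt, u10) +
        sim_channel(cal$K4, cal$tau4_star, cal$tau1, cal$tau2, u2, dt, u20)
  sat <- u2 * 1000 < 0 | u2 * 1000 > W2max_mW
  if (any(sat)) {
    warn(sprintf("thermostat power outside [0, %g] mW at %d sample(s); flagged, not clipped",
                 W2max_mW, sum(sat)))
  }
  tibble::tibble(t = inputs$t, y1_mV = y1, y2_K = y2, saturated = sat)
}
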