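# Shared fixtures for the test suite. Everything here is deterministic or
# seeded; nothing is written outside tempdir().

# Cyclic boxcar activation profile (20 % duty): the round-trip fixture for
# the envelope chain. The trailing-window rank filter preserves plateau
# amplitude only when the window's amplitude mixture is stationary, which a
# cyclic profile with period much shorter than the window guarantees.
boxcar_profile <- function(n_cycles = 10, cycle_s = 2, duty = 0.2,
                           sample_rate = 2000) {
  t <- seq(0, n_cycles * cycle_s - 1 / sample_rate, by = 1 / sample_rate)
  ph <- t %% cycle_s
  tibble::tibble(time_s = t, ch1 = as.numeric(ph < duty * cycle_s))
}

# Analytic decoder calibration with exact weights: maximal DF is pure TA at
# activation 1, maximal PF is pure GAS at activation 0.5, so
# w_ta = 10, w_gas = 40, mu_norm_df = 10, mu_norm_pf = 20.
unit_calibration <- function() {
  t <- seq(0, 2, by = 1e-3)
  df <- tibble::tibble(time_s = t, ta = 1, gas = 0)
  pf <- tibble::tibble(time_s = t, ta = 0, gas = 0.5)
  calibrate_decoder(df, pf)
}

# Smooth activation trial (ramped boxcar) for end-to-end calibration from
# raw EMG.
smooth_plateau_activation <- function(muscle, dur = 8, sample_rate = 2000) {
  t <- seq(0, dur - 1 / sample_rate, by = 1 / sample_rate)
  s <- as.numeric(t > 1 & t < dur - 1)
  s <- stats::filter(s, rep(1 / 400, 400), sides = 2)
  s[is.na(s)] <- 0
  out <- tibble::tibble(time_s = t, ta = 0, gas = 0)
  out[[muscle]] <- as.numeric(s)
  out
}

# Angle trace through planted landmarks via monotone segments on the fixed
# 1001-point grid: initial contact 0 deg, PF minimum -5 deg at 8 %, DF
# maximum +12 deg at 45 %, PF minimum -18 deg at 62 % (stance end), return
# to 0 deg at 100 %.
planted_angle_trace <- function() {
  pct <- seq(0, 100, length.out = 1001)
  knots_x <- c(0, 8, 45, 62, 100)
  knots_y <- c(0, -5, 12, -18, 0)
  seg <- findInterval(pct, knots_x, rightmost.closed = TRUE)
  u <- (pct - knots_x[seg]) / (knots_x[seg + 1] - knots_x[seg])
  smooth <- u * u * (3 - 2 * u)  # monotone within each segment
  knots_y[seg] + smooth * (knots_y[seg + 1] - knots_y[seg])
}

# Smooth random closed (angle, torque) cycle from low-order Fourier series:
# periodic by construction, so the torque-angle loop closes exactly.
fourier_cycle <- function(seed, n_harm = 3) {
  set.seed(seed)
  pct <- seq(0, 100, length.out = 1001)
  th <- 2 * pi * pct / 100
  mk <- function(scale) {
    a <- rnorm(n_harm, 0, scale / seq_len(n_harm))
    b <- rnorm(n_harm, 0, scale / seq_len(n_harm))
    Reduce(`+`, lapply(seq_len(n_harm), function(k) {
      a[k] * cos(k * th) + b[k] * sin(k * th)
    }))
  }
  gait_cycle(angle = 10 * mk(1), torque = 0.8 * mk(1), duration_s = 1)
}
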