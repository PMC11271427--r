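# EMG envelope chain: filter design, zero-phase application, rank filter,
# RMS smoothing, normalization, activation dynamics, and the round trip.

test_that("band-pass design meets the verified stop-band and pass-band levels", {
  filt <- design_bandpass(2000)
  expect_s3_class(filt, "bg_fir")
  expect_length(filt$coef, 199)
  expect_lte(filt$db_45, -60)
  expect_lte(filt$db_400, -60)
  expect_gte(filt$min_passband_db, -3)
  # linear phase: taps symmetric about the center
  expect_equal(filt$coef, rev(filt$coef), tolerance = 1e-12)
})

test_that("band-pass design rejects unusable sampling rates and warns off-nominal", {
  expect_error(design_bandpass(700), "720")
  expect_warning(design_bandpass(2500), "2000")
})

test_that("filter application is zero phase: pass-band tone preserved, drift rejected", {
  sr <- 2000
  t <- seq(0, 2 - 1 / sr, by = 1 / sr)
  tone <- sin(2 * pi * 200 * t)          # mid pass-band
  drift <- 0.5 * sin(2 * pi * 5 * t)     # deep stop-band
  filt <- design_bandpass(sr)
  y <- apply_fir(tone + drift, filt)
  expect_length(y, length(t))
  core <- 500:3500  # away from edge transients
  # zero phase and unit gain: output matches the tone sample-for-sample
  expect_lt(max(abs(y[core] - tone[core])), 0.01)
})

test_that("cumulative histogram filter maps a constant signal to zero rank", {
  x <- rep(0.7, 2000)
  y <- cumulative_histogram_filter(x, sample_rate = 100, window_s = 5)
  # strict rank: no sample in the window is strictly below the current bin
  expect_true(all(y == 0))
})

test_that("cumulative histogram filter ranks a two-level signal correctly", {
  # half the window at a low level, half at a high level: the high samples
  # sit strictly above ~50 % of the window, the low samples above none
  x <- rep(c(rep(0.1, 50), rep(1, 50)), 40)
  y <- cumulative_histogram_filter(x, sample_rate = 100, window_s = 4)
  n <- length(x)
  tail_idx <- (n - 399):n
  hi <- tail_idx[x[tail_idx] == 1]
  lo <- tail_idx[x[tail_idx] < 1]
  expect_true(all(abs(y[hi] - 0.5) < 0.05))
  expect_true(all(y[lo] < 0.05))
})

test_that("RMS envelope of a sine approaches amplitude over sqrt(2)", {
  sr <- 1000
  t <- seq(0, 4, by = 1 / sr)
  x <- 2 * sin(2 * pi * 50 * t)
  y <- rms_envelope(x, sample_rate = sr, window_s = 0.2)
  expect_length(y, length(x))
  core <- 500:3500
  expect_lt(max(abs(y[core] - 2 / sqrt(2))), 0.05)
})

test_that("envelope normalization maps the calibration range onto [0, 1]", {
  y <- normalize_envelope(c(2, 4, 6), cal_min = 2, cal_max = 6)
  expect_equal(y, c(0, 0.5, 1))
  expect_equal(normalize_envelope(c(0, 8), cal_min = 2, cal_max = 6), c(0, 1))
})

test_that("activation dynamics rise fast and decay slow, staying in [0, 1]", {
  sr <- 1000
  u <- c(rep(1, 200), rep(0, 400))
  a <- activation_dynamics(u, sr)
  expect_true(all(a >= 0 & a <= 1))
  # 10 ms activation: close to 1 well before the step ends
  expect_gt(a[100], 0.99)
  # 40 ms deactivation: still high shortly after release, near zero later
  expect_gt(a[220], 0.5)
  expect_lt(a[600], 0.01)
  # time to fall to 1/e is ~4x the time to rise to 1 - 1/e
  rise <- which(a > 1 - exp(-1))[1]
  fall <- which(a[201:600] < exp(-1))[1]
  expect_gt(fall / rise, 2.5)
})

test_that("envelope chain round-trips a cyclic boxcar activation profile", {
  prof <- boxcar_profile()
  emg <- generate_emg(prof, 2000, noise_sd = 0, seed = 7)
  env <- emg_envelope(emg)
  ph <- prof$time_s %% 2
  settled <- prof$time_s > 6  # past rank-filter warm-up
  # interior of the 0.4 s burst: at least one RMS half-window (0.1 s) away
  # from both amplitude edges
  on <- settled & ph > 0.12 & ph < 0.28
  off <- settled & ph > 0.7 & ph < 1.8
  expect_lt(max(abs(env$ch1[on] - 1)), 0.05)
  expect_lt(max(abs(env$ch1[off])), 0.05)
})

test_that("envelope chain refuses non-finite raw input with the channel named", {
  prof <- boxcar_profile(n_cycles = 2)
  emg <- generate_emg(prof, 2000, seed = 1)
  emg$ch1[10] <- NA
  expect_error(emg_envelope(emg), "ch1")
})

test_that("muscle activation wrapper applies the dynamics per channel", {
  t <- seq(0, 1 - 1e-3, by = 1e-3)
  env <- tibble::tibble(time_s = t,
                        ta = as.numeric(t < 0.5), gas = rep(0, length(t)))
  act <- muscle_activation(env)
  expect_named(act, c("time_s", "ta", "gas"))
  expect_true(all(act$gas == 0))
  expect_gt(act$ta[400], 0.99)
})
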