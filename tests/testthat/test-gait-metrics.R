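# Gait metrics: cycle normalization, events, power, work, loops, symmetry,
# and perturbation responses.

test_that("cycle normalization resamples onto the fixed grid and splits cycles", {
  sp <- archetype_spec("AMI", 10, noise_sd = 0, seed = 1)
  tr <- generate_gait_trial(sp, n_cycles = 3)
  cycles <- normalize_cycle(tr)
  expect_length(cycles, 3)
  for (cy in cycles) {
    expect_s3_class(cy, "bg_gait_cycle")
    expect_equal(nrow(cy), 1001)
    expect_equal(range(cy$pct), c(0, 100))
  }
})

test_that("cycle normalization divides by mass when torque is in Nm", {
  t <- seq(0, 0.999, by = 1e-3)
  tr_nm <- tibble::tibble(time_s = t, cycle = 1L,
                          angle = sin(2 * pi * t), torque = 70 * cos(2 * pi * t))
  cy <- normalize_cycle(tr_nm, mass = 70, mass_normalized = FALSE)[[1]]
  expect_equal(max(abs(cy$torque)), 1, tolerance = 1e-6)
})

test_that("implausibly short cycles are rejected, not silently normalized", {
  t <- seq(0, 0.099, by = 1e-3)
  tr <- tibble::tibble(time_s = t, cycle = 1L, angle = t, torque = t)
  expect_error(normalize_cycle(tr), "0.2 s")
})

test_that("level events match a brute-force landmark search on a planted trace", {
  x <- planted_angle_trace()
  ev <- segment_level_events(x, stance_end_pct = 62)
  # brute force: first strict local minimum in stance, stance max, bounds
  pct <- seq(0, 100, length.out = 1001)
  st <- which(pct <= 62)
  i_min <- which(diff(sign(diff(x[st]))) > 0)[1] + 1L
  i_max <- st[which.max(x[st])]
  i_se <- max(st)
  expected <- c(HS = abs(x[i_min] - x[1]),
                LR = abs(x[i_max] - x[i_min]),
                PO = abs(x[i_se] - x[i_max]),
                FC = abs(x[1001] - x[i_se]))
  got <- setNames(ev$excursion_deg, ev$event)
  expect_equal(got[names(expected)], expected, tolerance = 1e-8)
  expect_equal(ev$direction, c("pf", "df", "pf", "df"))
  expect_false(any(ev$absent))
})

test_that("stair events on the planted trace equal the landmark differences", {
  x <- planted_angle_trace()
  ev <- segment_stair_events(x, stance_end_pct = 62, direction = "descent")
  pct <- seq(0, 100, length.out = 1001)
  st <- which(pct <= 62)
  i_max <- st[which.max(x[st])]
  expect_equal(ev$excursion_deg[ev$event == "WA"], abs(x[i_max] - x[1]),
               tolerance = 1e-8)
  expect_equal(ev$excursion_deg[ev$event == "FCo"], abs(x[1001] - x[i_max]),
               tolerance = 1e-8)
})

test_that("a stance with no dorsiflexion rise flags weight acceptance absent", {
  pct <- seq(0, 100, length.out = 1001)
  x <- -10 * sin(pi * pct / 100)  # strictly below initial contact in stance
  ev <- segment_stair_events(x, stance_end_pct = 60, direction = "ascent")
  expect_true(ev$absent[ev$event == "WA"])
  expect_true(ev$absent[ev$event == "PU"])
})

test_that("a flat trace yields degenerate (absent) level events, not errors", {
  ev <- segment_level_events(rep(3, 1001), stance_end_pct = 62)
  expect_true(all(ev$absent))
})

test_that("peak power respects the sign mode and returns 0 when absent", {
  p <- c(rep(-2, 500), rep(0.5, 501))
  expect_equal(peak_power(p, "positive"), 0.5)
  expect_equal(peak_power(p, "negative"), -2)
  expect_equal(peak_power(rep(-1, 1001), "positive"), 0)
  expect_equal(peak_power(rep(1, 1001), "negative"), 0)
})

test_that("net work integrates power over the requested window only", {
  cy <- gait_cycle(angle = rep(0, 1001), torque = rep(0, 1001),
                   power = rep(2, 1001), duration_s = 1)
  expect_equal(net_work(cy), 2, tolerance = 1e-9)
  expect_equal(net_work(cy, c(0, 35)), 0.7, tolerance = 1e-9)
  expect_error(net_work(cy, c(50, 40)), "window")
  expect_error(net_work(cy, c(-5, 50)), "window")
})

test_that("torque-angle loop area matches the analytic ellipse, sign by direction", {
  pct <- seq(0, 100, length.out = 1001)
  th <- 2 * pi * pct / 100
  a_deg <- 5; b_tq <- 1.2
  # elliptic loop with |area| = pi * a * b (angle in rad); the energy-
  # generating traversal (net work = integral of torque d(angle) > 0) is
  # the one labelled ccw
  ccw <- gait_cycle(angle = a_deg * cos(th), torque = -b_tq * sin(th))
  cw <- gait_cycle(angle = a_deg * cos(th), torque = b_tq * sin(th))
  area_true <- pi * (a_deg * pi / 180) * b_tq
  out_ccw <- torque_angle_loop(ccw)
  out_cw <- torque_angle_loop(cw)
  expect_equal(out_ccw$area, area_true, tolerance = 1e-4)
  expect_equal(out_ccw$direction, "ccw")
  expect_equal(out_cw$area, -area_true, tolerance = 1e-4)
  expect_equal(out_cw$direction, "cw")
  expect_true(out_ccw$closed)
})

test_that("an unclosed loop is flagged rather than silently closed", {
  pct <- seq(0, 100, length.out = 1001)
  cy <- gait_cycle(angle = pct / 10, torque = pct / 100)
  expect_false(torque_angle_loop(cy)$closed)
})

test_that("symmetry is 100 iff limbs match, symmetric, and falls with offset", {
  p <- seq(0, 100, length.out = 101)
  a <- tibble::tibble(pct = p, ankle = sin(p / 10), knee = 20 + p / 10,
                      hip = cos(p / 15))
  expect_equal(lek_symmetry(a, a)$lek_symmetry[1], 100)
  b <- a; b$ankle <- b$ankle + 2
  s_ab <- lek_symmetry(a, b)$lek_symmetry[1]
  s_ba <- lek_symmetry(b, a)$lek_symmetry[1]
  expect_lt(s_ab, 100)
  expect_equal(s_ab, s_ba)
  c_ <- a; c_$ankle <- c_$ankle + 4
  expect_lt(lek_symmetry(a, c_)$lek_symmetry[1], s_ab)
})

test_that("symmetry refuses missing joints with a named error", {
  p <- seq(0, 100, length.out = 11)
  a <- tibble::tibble(pct = p, ankle = p)
  expect_error(lek_symmetry(a, a), "knee")
})

test_that("range of motion is the max-min excursion and refuses NA traces", {
  expect_equal(rom(c(-18, 0, 12)), 30)
  expect_error(rom(c(1, NA)), "non-finite")
})

test_that("obstacle cycles raise the swing dorsiflexion peak over baseline", {
  sp <- archetype_spec("AMI", 10.5, noise_sd = 0, seed = 7)
  pert <- normalize_cycle(generate_gait_trial(sp, "obstacle", n_cycles = 2))
  base <- normalize_cycle(
    generate_gait_trial(sp, "unperturbed_baseline", n_cycles = 2))
  expect_gt(obstacle_swing_delta(pert, base), 1)
})

test_that("recovery-step metrics report positive propulsion for biomimetic gait", {
  sp <- archetype_spec("AMI", 11, noise_sd = 0, seed = 7)
  cy <- normalize_cycle(generate_gait_trial(sp, "level_moderate"))[[1]]
  out <- recovery_step_metrics(cy)
  expect_gt(out$peak_power, 0)
  expect_gt(out$net_work, 0)
})
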