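# Impedance controller: force-length/velocity curves, passive structures,
# torque composition, saturation and hard faults.

test_that("maximal torque peaks at the optimal angle and respects isometric bounds", {
  m <- bio_torque_model()
  angles <- seq(-20, 10, by = 0.5)
  tq <- max_bio_torque(angles, 0, "pf", m)
  expect_equal(angles[which.max(tq)], m$fl_opt_pf, tolerance = 0.5)
  expect_equal(max(tq), m$tau_iso_pf, tolerance = 1e-6)
  expect_true(all(tq >= 0))
})

test_that("force-velocity is Hill-like: zero at v_max, plateaued eccentric", {
  m <- bio_torque_model()
  # dorsiflexing velocity shortens the dorsiflexors
  expect_equal(max_bio_torque(0, m$v_max, "df", m), 0, tolerance = 1e-9)
  iso <- max_bio_torque(0, 0, "df", m)
  ecc <- max_bio_torque(0, -5000, "df", m)
  expect_lt(ecc / iso, m$ecc_plateau + 1e-6)
  expect_gt(ecc / iso, 1)
  # concentric torque decreases monotonically with shortening speed
  v <- seq(0, m$v_max, by = 50)
  expect_true(all(diff(max_bio_torque(0, v, "df", m)) < 0))
})

test_that("passive torque is zero in the neutral zone and restores beyond it", {
  m <- bio_torque_model()
  inside <- seq(m$passive_onset_pf, m$passive_onset_df, by = 0.5)
  expect_true(all(passive_structure_torque(inside, m) == 0))
  expect_lt(passive_structure_torque(9, m), 0)   # near DF end: plantar-flexing
  expect_gt(passive_structure_torque(-18, m), 0) # near PF end: dorsiflexing
  # grows with displacement
  expect_gt(abs(passive_structure_torque(10, m)),
            abs(passive_structure_torque(7, m)))
})

test_that("zero muscle activity leaves exactly the virtual impedance", {
  # inside the passive neutral zone the only torque is -k (angle - theta_ref)
  out <- command_torque(0, 0, 4, 0)
  expect_equal(out$tau_total, -0.45 * 4)
  expect_equal(out$tau_active, 0)
  expect_equal(out$tau_passive, 0)
  # damping term: -b * velocity
  out_v <- command_torque(0, 0, 0, 100)
  expect_equal(out_v$tau_total, -0.02 * 100)
})

test_that("maximal intent at maximal error commands the biological bound", {
  # test model with a flat force-length curve so the bound is tau_iso
  m <- bio_torque_model(fl_width_df = 1e6, fl_width_pf = 1e6,
                        passive_scale = 0, k_virtual = 0, b_virtual = 0)
  # full-span DF error: theta_ref at +10, angle at -20
  out <- command_torque(10, 1, -20, 0, m)
  expect_equal(out$tau_active, m$tau_iso_df, tolerance = 1e-9)
  # half error scales linearly
  out_half <- command_torque(-5, 1, 10, 0, m)
  expect_equal(out_half$tau_active, -m$tau_iso_pf / 2, tolerance = 1e-9)
})

test_that("active torque sign follows the error and scales with impedance level", {
  out_df <- command_torque(8, 0.6, 0, 0)
  out_pf <- command_torque(-8, 0.6, 0, 0)
  expect_gt(out_df$tau_active, 0)
  expect_lt(out_pf$tau_active, 0)
  expect_equal(command_torque(8, 0.3, 0, 0)$tau_active,
               out_df$tau_active / 2, tolerance = 1e-9)
})

test_that("commanded torque saturates at the device limit and flags it", {
  m <- bio_torque_model(tau_iso_pf = 5000)
  out <- command_torque(-20, 1, 10, 0, m)
  expect_equal(abs(out$tau_total), m$tau_limit)
  expect_true(out$saturated)
  expect_false(command_torque(0, 0, 1, 0)$saturated)
})

test_that("controller hard-faults on non-finite input and out-of-range impedance", {
  expect_error(command_torque(NaN, 0.5, 0, 0), "NaN")
  expect_error(command_torque(0, 1.5, 0, 0), "mu_z")
  expect_error(command_torque(0, -0.1, 0, 0), "mu_z")
})

test_that("torque components always sum to the pre-saturation total", {
  set.seed(7)
  out <- command_torque(runif(200, -20, 10), runif(200), runif(200, -20, 10),
                        runif(200, -1000, 1000))
  pre <- out$tau_active + out$tau_passive + out$tau_virtual
  recomputed <- pmin(pmax(pre, -162), 162)
  expect_equal(out$tau_total, recomputed, tolerance = 1e-12)
})
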