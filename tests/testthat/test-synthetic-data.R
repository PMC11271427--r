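# Synthetic generators: archetype validation, EMG synthesis, phantom
# cycles, gait trials, and the cohort table.

test_that("archetype specification validates and derives biomimeticness", {
  expect_error(archetype_spec("AMI", afferent_level = Inf), "finite")
  expect_error(archetype_spec("AMI", 5, gait_biomimeticness = 1.2), "0, 1")
  expect_error(archetype_spec("XYZ", 5))
  sp <- archetype_spec("AMI", afferent_level = 6)
  expect_equal(sp$gait_biomimeticness, 0.5)
  expect_equal(archetype_spec("CTL", -1.3)$gait_biomimeticness, 0)
  expect_equal(archetype_spec("AMI", 15)$gait_biomimeticness, 1)
})

test_that("raw EMG generation is seeded-deterministic and validates profiles", {
  prof <- boxcar_profile(n_cycles = 1)
  e1 <- generate_emg(prof, 2000, noise_sd = 0.05, seed = 9)
  e2 <- generate_emg(prof, 2000, noise_sd = 0.05, seed = 9)
  e3 <- generate_emg(prof, 2000, noise_sd = 0.05, seed = 10)
  expect_identical(e1$ch1, e2$ch1)
  expect_false(identical(e1$ch1, e3$ch1))
  bad <- prof; bad$ch1[1] <- 1.5
  expect_error(generate_emg(bad, 2000), "\\[0, 1\\]")
})

test_that("raw EMG power concentrates in the 90-330 Hz pass-band", {
  prof <- boxcar_profile(n_cycles = 2, duty = 1)  # constant-on modulation
  e <- generate_emg(prof, 2000, noise_sd = 0, seed = 11)
  sp <- stats::spec.pgram(e$ch1, plot = FALSE, taper = 0)
  f <- sp$freq * 2000
  inband <- sum(sp$spec[f >= 90 & f <= 330])
  outband <- sum(sp$spec[f < 60 | f > 360])
  expect_gt(inband / (inband + outband), 0.95)
})

test_that("phantom cycles deliver the requested counts and coupled strains", {
  sp <- archetype_spec("AMI", 10.5, noise_sd = 0, seed = 8)
  ph <- generate_phantom_cycles(sp, n_cycles = 10)
  tab <- table(ph$fascicle$movement[!duplicated(
    paste(ph$fascicle$movement, ph$fascicle$cycle))])
  expect_equal(unname(tab[["df"]]), 10)
  expect_equal(unname(tab[["pf"]]), 10)
  # anti-phase coupling: agonist shortens while antagonist lengthens
  df1 <- ph$fascicle[ph$fascicle$movement == "df" & ph$fascicle$cycle == 1, ]
  mid <- df1$cycle_pct == 50
  expect_lt(df1$strain_ta[mid], 0)
  expect_gt(df1$strain_gas[mid], 0)
})

test_that("control archetype strains vary more across cycles than AMI strains", {
  plateau_sd <- function(group, seed) {
    sp <- archetype_spec(group, 4, noise_sd = 0, seed = seed)
    ph <- generate_phantom_cycles(sp, n_cycles = 10)
    d <- ph$fascicle[ph$fascicle$movement == "df" & ph$fascicle$cycle_pct == 50, ]
    sd(d$strain_gas) / max(abs(mean(d$strain_gas)), 1e-12)
  }
  expect_gt(plateau_sd("CTL", 12), 2 * plateau_sd("AMI", 12))
})

test_that("an unachievable afferent target fails with a domain error", {
  sp <- archetype_spec("AMI", 500, gait_biomimeticness = 1, seed = 1)
  expect_error(generate_phantom_cycles(sp), "achievable")
})

test_that("net work increases monotonically with gait biomimeticness", {
  nw <- vapply(seq(0, 1, by = 0.2), function(b) {
    sp <- archetype_spec("AMI", 12 * b, gait_biomimeticness = b,
                         noise_sd = 0, seed = 3)
    net_work(normalize_cycle(generate_gait_trial(sp, n_cycles = 1))[[1]])
  }, numeric(1))
  expect_true(all(diff(nw) > 0))
})

test_that("biomimetic gait injects net positive work, non-biomimetic dissipates", {
  mk <- function(b) {
    sp <- archetype_spec("AMI", 12 * b, gait_biomimeticness = b,
                         noise_sd = 0, seed = 3)
    normalize_cycle(generate_gait_trial(sp, n_cycles = 1))[[1]]
  }
  hi <- torque_angle_loop(mk(1)); lo <- torque_angle_loop(mk(0))
  expect_equal(hi$direction, "ccw")
  expect_gt(hi$area, 0.1)
  expect_equal(lo$direction, "cw")
  expect_lte(lo$area, 0)
})

test_that("kinematic symmetry degrades as biomimeticness falls", {
  lek <- vapply(c(1, 0.5, 0), function(b) {
    sp <- archetype_spec("AMI", 12 * b, gait_biomimeticness = b,
                         noise_sd = 0, seed = 3)
    kin <- generate_gait_trial(sp, n_cycles = 1)$kinematics
    sym <- lek_symmetry(
      kin[, c("pct", "ankle", "knee", "hip")],
      stats::setNames(kin[, c("pct", "ankle_contra", "knee_contra",
                              "hip_contra")],
                      c("pct", "ankle", "knee", "hip")))
    sym$lek_symmetry[1]
  }, numeric(1))
  expect_true(all(diff(lek) < 0))
  expect_equal(lek[1], 100, tolerance = 0.5)
})

test_that("stair descent shows a larger weight acceptance than level loading response", {
  sp <- archetype_spec("AMI", 10.5, noise_sd = 0, seed = 5)
  cyd <- normalize_cycle(generate_gait_trial(sp, "stair_down"))[[1]]
  cyl <- normalize_cycle(generate_gait_trial(sp, "level_max"))[[1]]
  wa <- segment_stair_events(cyd, direction = "descent")
  lr <- segment_level_events(cyl)
  expect_gt(wa$excursion_deg[wa$event == "WA"],
            lr$excursion_deg[lr$event == "LR"])
})

test_that("cohort tables embody the configured afferent-function slopes", {
  co <- generate_cohort(n_per_group = 25, noise = 0.02, seed = 14)
  slopes <- attr(co, "slopes")
  fit <- lm(peak_power ~ afferent, data = co)
  expect_equal(unname(coef(fit)[2]), slopes$peak_power$m, tolerance = 0.02)
  # AMI afferents sit above CTL afferents by construction
  expect_gt(min(co$afferent[co$group == "AMI"]),
            max(co$afferent[co$group == "CTL"]))
})

test_that("cohort generation validates its arguments", {
  expect_error(generate_cohort(n_per_group = 1))
  expect_error(generate_cohort(afferent_range = c(5, 5)), "width")
})
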