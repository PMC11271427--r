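# Synthetic-data generators: every input the physical study measured (raw
# EMG, fascicle strain, joint trajectories, cohort tables) with controllable
# archetype parameters and seeds, so the downstream pipeline is fully
# testable without participant data.

#' Archetype specification for a synthetic subject
#'
#' Describes one synthetic subject: cohort label (`AMI` surgical
#' agonist-antagonist interface, or `CTL` standard amputation), the target
#' agonist-antagonist afferent statistic (Imp/s), how biomimetic the gait
#' waveforms are (`gait_biomimeticness` in `[0, 1]`: 1 gives a
#' counterclockwise torque-angle loop injecting net positive work, 0 a
#' clockwise dissipative loop), relative additive noise, and a seed.
#'
#' When `gait_biomimeticness` is `NULL` it defaults to
#' `clip(afferent_level / 12, 0, 1)`, emulating the observed coupling between
#' afferent magnitude (non-biomimetic ~ -1.3 Imp/s up to high ~ 12 Imp/s)
#' and gait biomimeticness.
#'
#' @param group_label `"AMI"` or `"CTL"`.
#' @param afferent_level Target agonist-antagonist afferent, Imp/s (finite;
#'   may be negative for non-biomimetic behaviour).
#' @param gait_biomimeticness Scalar in `[0, 1]` or `NULL` (derived).
#' @param noise_sd Relative amplitude of additive noise (default 0.02).
#' @param seed Integer seed.
#' @return A `bg_archetype` list.
#' @export
archetype_spec <- function(group_label = c("AMI", "CTL"),
                           afferent_level = 10.5,
                           gait_biomimeticness = NULL,
                           noise_sd = 0.02, seed = 1L) {
  group_label <- match.arg(group_label)
  if (!is.finite(afferent_level)) {
    stop("afferent_level must be finite", call. = FALSE)
  }
  if (is.null(gait_biomimeticness)) {
    gait_biomimeticness <- clip(afferent_level / 12, 0, 1)
  }
  if (!is.finite(gait_biomimeticness) ||
      gait_biomimeticness < 0 || gait_biomimeticness > 1) {
    stop("gait_biomimeticness must lie in [0, 1]", call. = FALSE)
  }
  stopifnot(noise_sd >= 0, is.finite(seed))
  structure(list(group_label = group_label,
                 afferent_level = afferent_level,
                 gait_biomimeticness = gait_biomimeticness,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "bg_archetype")
}

# Band-limited unit-RMS carrier confined to the EMG pass-band.
emg_carrier_ <- function(n, sample_rate, filt = NULL) {
  if (is.null(filt)) filt <- design_bandpass(sample_rate)
  g <- apply_fir(rnorm(n), filt)
  g / sqrt(mean(g^2))
}

#' Generate raw surface EMG from an activation profile
#'
#' Amplitude-modulates a band-limited Gaussian carrier (confined to the
#' 90-330 Hz pass-band) by the commanded activation profile, and adds
#' out-of-band interference - mains hum at 50 Hz and wide-band noise -
#' scaled by `noise_sd`, so the envelope chain's filter specifications are
#' genuinely exercised. The envelope recovered by [emg_envelope()] matches
#' the commanded profile on plateaus away from filter edge transients.
#'
#' @param profile Data frame with `time_s` plus one activation column per
#'   muscle (values in `[0, 1]`), or a numeric vector for a single channel.
#' @param sample_rate Sampling rate, Hz (>= 2000).
#' @param noise_sd Relative amplitude of additive interference.
#' @param seed Integer seed (same seed and profile give identical signals).
#' @return Tibble with `time_s` and one raw EMG column per muscle.
#' @export
generate_emg <- function(profile, sample_rate = 2000, noise_sd = 0, seed = 1L) {
  if (is.numeric(profile)) {
    profile <- tibble::tibble(
      time_s = (seq_along(profile) - 1) / sample_rate,
      ch1 = profile)
  }
  stopifnot(is.data.frame(profile), "time_s" %in% names(profile),
            sample_rate >= 2000)
  chans <- setdiff(names(profile), "time_s")
  for (ch in chans) {
    if (!all(is.finite(profile[[ch]]))) {
      stop(sprintf("non-finite activation profile in channel `%s`", ch),
           call. = FALSE)
    }
    if (any(profile[[ch]] < 0 | profile[[ch]] > 1)) {
      stop(sprintf("profile values in channel `%s` must lie in [0, 1]", ch),
           call. = FALSE)
    }
  }
  n <- nrow(profile)
  filt <- design_bandpass(sample_rate)
  with_seed_(seed, {
    out <- tibble::tibble(time_s = profile$time_s)
    for (ch in chans) {
      x <- profile[[ch]] * emg_carrier_(n, sample_rate, filt)
      if (noise_sd > 0) {
        hum <- sin(2 * pi * 50 * profile$time_s + runif(1, 0, 2 * pi))
        x <- x + noise_sd * hum + noise_sd * rnorm(n)
      }
      out[[ch]] <- x
    }
    out
  })
}

# Smoothstep ramp 0 -> 1 on [0, 1].
smoothstep_ <- function(x) {
  x <- clip(x, 0, 1)
  x * x * (3 - 2 * x)
}

# Phantom-cycle strain waveform: smooth rise over 0-25 % of the cycle,
# plateau over 25-75 %, return over 75-100 %.
phantom_shape_ <- function(pct) {
  smoothstep_(pct / 25) - smoothstep_((pct - 75) / 25)
}

# Mean DF + PF phantom traces for antagonist plateau strain `x` (agonist
# strain is -x), with the group's EMG co-activation; used both by the
# generator and by its internal calibration loop.
phantom_mean_traces_ <- function(x, coact) {
  pct <- seq(0, 100, by = 1)
  s <- phantom_shape_(pct)
  list(
    df = tibble::tibble(cycle_pct = pct,
                        strain_ta = -x * s, strain_gas = x * s,
                        env_ta = s, env_gas = coact * s,
                        movement = "df"),
    pf = tibble::tibble(cycle_pct = pct,
                        strain_ta = x * s, strain_gas = -x * s,
                        env_ta = coact * s, env_gas = s,
                        movement = "pf")
  )
}

# Agonist-antagonist statistic produced by coupling amplitude x.
phantom_statistic_ <- function(x, coact, params) {
  tr <- phantom_mean_traces_(x, coact)
  est <- estimate_afferents(rbind(tr$df, tr$pf), params = params)
  agonist_antagonist_afferent(est)
}

#' Generate phantom dorsiflexion/plantar-flexion cycles
#'
#' Emits `n_cycles` maximal phantom DF and `n_cycles` maximal PF cycles of
#' paired TA/GAS fascicle strain (dimensionless, positive = lengthening) and
#' EMG. For the AMI archetype the antagonist lengthens while the agonist
#' shortens (coupled, anti-phase); for the CTL archetype strains are small
#' or same-sign with higher cycle-to-cycle variance, and the EMG carries
#' antagonist co-activation. The strain coupling amplitude is calibrated by
#' a root solve so that the downstream agonist-antagonist afferent statistic
#' (with `params`) equals the archetype's `afferent_level`.
#'
#' @param spec A `bg_archetype`.
#' @param n_cycles Number of cycles per movement direction (default 10).
#' @param params Spindle parameters ([spindle_params()]) used for the
#'   calibration loop.
#' @param cycle_duration Movement cycle duration, s (default 2).
#' @return List of class `bg_phantom`: `fascicle` (tibble: `cycle`,
#'   `movement`, `cycle_pct`, `strain_ta`, `strain_gas`, `env_ta`,
#'   `env_gas`), `emg` (raw 2 kHz EMG tibble with `movement`, `cycle`), and
#'   `coupling` (the solved plateau strain).
#' @export
generate_phantom_cycles <- function(spec, n_cycles = 10,
                                    params = spindle_params(),
                                    cycle_duration = 2) {
  stopifnot(inherits(spec, "bg_archetype"), n_cycles >= 1)
  coact <- if (spec$group_label == "CTL") 0.3 else 0.05
  f <- function(x) phantom_statistic_(x, coact, params) - spec$afferent_level
  x <- tryCatch(stats::uniroot(f, c(-0.3, 0.3), tol = 1e-8)$root,
                error = function(e) stop(
                  "afferent_level outside the achievable range for this archetype",
                  call. = FALSE))
  cyc_sd <- if (spec$group_label == "CTL") 0.25 else 0.05
  pct <- seq(0, 100, by = 1)
  with_seed_(spec$seed, {
    fas <- purrr::map_dfr(c("df", "pf"), function(mv) {
      purrr::map_dfr(seq_len(n_cycles), function(k) {
        base <- phantom_mean_traces_(x * (1 + rnorm(1, 0, cyc_sd)), coact)[[mv]]
        base$strain_ta <- base$strain_ta + spec$noise_sd * abs(x) * rnorm(101)
        base$strain_gas <- base$strain_gas + spec$noise_sd * abs(x) * rnorm(101)
        tibble::tibble(cycle = k, base)
      })
    })
    emg <- purrr::map_dfr(c("df", "pf"), function(mv) {
      prof_t <- seq(0, n_cycles * cycle_duration - 1 / 2000, by = 1 / 2000)
      p <- (prof_t %% cycle_duration) / cycle_duration * 100
      s <- phantom_shape_(p)
      prof <- tibble::tibble(
        time_s = prof_t,
        ta = clip(if (mv == "df") s else coact * s, 0, 1),
        gas = clip(if (mv == "pf") s else coact * s, 0, 1))
      e <- generate_emg(prof, 2000, noise_sd = spec$noise_sd,
                        seed = spec$seed + (mv == "pf"))
      tibble::tibble(movement = mv,
                     cycle = as.integer(floor(prof_t / cycle_duration)) + 1L,
                     e)
    })
    structure(list(fascicle = fas, emg = emg, coupling = x, spec = spec),
              class = "bg_phantom")
  })
}

#' Generate one synthetic gait trial
#'
#' Builds a full trial for one condition: ipsilateral (bionic) ankle angle
#' and mass-normalized torque from the condition's parametric waveform
#' family, contralateral ankle/knee/hip from a fixed normative template,
#' raw EMG consistent with the condition's activation profiles, and
#' sampling metadata. `gait_biomimeticness = 1` produces a counterclockwise
#' torque-angle loop with positive net work for level walking;
#' `0` produces a clockwise, dissipative loop (torque collapses onto a
#' damping law). Ipsilateral knee/hip deviate from the normative template in
#' proportion to `1 - gait_biomimeticness`, so kinematic symmetry degrades
#' as biomimeticness falls.
#'
#' @param spec A `bg_archetype`.
#' @param condition Condition label (see [gait_conditions()]).
#' @param n_cycles Number of gait cycles (default 3).
#' @param body_mass Subject mass, kg.
#' @return A `bg_trial` list: `kinematics` (tibble at 1 kHz: `time_s`,
#'   `cycle`, `pct`, `ankle`, `knee`, `hip`, `ankle_contra`, `knee_contra`,
#'   `hip_contra`), `kinetics` (`time_s`, `cycle`, `pct`, `torque`, `power`
#'   in mass-normalized units), `emg` (raw 2 kHz), `condition`, `speed`,
#'   `stance_end_pct`, `cycle_duration_s`, `mass`, `spec`.
#' @export
generate_gait_trial <- function(spec, condition = "level_max", n_cycles = 3,
                                body_mass = 70) {
  stopifnot(inherits(spec, "bg_archetype"))
  condition <- match_condition_(condition)
  pars <- condition_pars_(condition)
  b <- spec$gait_biomimeticness
  dur <- pars$duration
  n <- as.integer(round(n_cycles * dur * 1000))
  t_s <- (seq_len(n) - 1) / 1000
  pct <- (t_s %% dur) / dur * 100
  with_seed_(spec$seed, {
    smooth_noise <- function(sd_abs) {
      if (sd_abs <= 0) return(numeric(n))
      z <- stats::filter(rnorm(n), rep(1 / 50, 50), circular = TRUE)
      as.numeric(z) / sd(as.numeric(z)) * sd_abs
    }
    angle <- condition_angle_(condition, pct, b) + smooth_noise(spec$noise_sd * 8)
    omega <- grad_(angle, t_s) * pi / 180            # rad/s
    tau_bio <- pars$kscale * condition_torque_bio_(condition, pct)
    # The non-biomimetic controller damps along its stereotyped stiff-ankle
    # (base) trajectory; using the base-component velocity keeps net work
    # monotone in biomimeticness (no damping x excursion-amplitude coupling).
    omega_base <- grad_(condition_angle_(condition, pct, 0), t_s) * pi / 180
    tau_damp <- -0.12 * omega_base                   # Nm s/kg damping law
    torque <- (1 - b) * tau_damp + b * tau_bio +
      smooth_noise(spec$noise_sd * 0.15)
    power <- torque * omega
    nk <- normative_lek_(pct)
    dev_knee <- (1 - b) * (6 - 10 * gbump_(pct, 72, 11))
    dev_hip <- (1 - b) * (4 + 5 * gbump_(pct, 50, 20))
    kinematics <- tibble::tibble(
      time_s = t_s,
      cycle = as.integer(floor(t_s / dur)) + 1L,
      pct = pct,
      ankle = angle, knee = nk$knee + dev_knee, hip = nk$hip + dev_hip,
      ankle_contra = nk$ankle, knee_contra = nk$knee, hip_contra = nk$hip
    )
    kinetics <- tibble::tibble(
      time_s = t_s, cycle = kinematics$cycle, pct = pct,
      torque = torque, power = power
    )
    prof_t <- seq(0, n_cycles * dur - 1 / 2000, by = 1 / 2000)
    prof_p <- (prof_t %% dur) / dur * 100
    act <- condition_activation_(condition, prof_p, b)
    emg <- generate_emg(tibble::tibble(time_s = prof_t, ta = act$ta,
                                       gas = act$gas),
                        2000, noise_sd = spec$noise_sd, seed = spec$seed)
    structure(
      list(kinematics = kinematics, kinetics = kinetics, emg = emg,
           condition = condition, speed = pars$speed,
           stance_end_pct = condition_stance_end(condition),
           cycle_duration_s = dur, mass = body_mass, spec = spec),
      class = "bg_trial"
    )
  })
}

#' Generate a synthetic cohort table
#'
#' Emits a subject-by-metric table embodying a configured linear relation
#' between the agonist-antagonist afferent statistic and each functional
#' metric, with Gaussian noise - the ground truth for parameter-recovery
#' tests of the cohort statistics. Per-group afferent levels are drawn
#' uniformly over `afferent_range` for the AMI group and shifted down by the
#' range width for the CTL group (emulating augmented vs non-augmented
#' cohorts).
#'
#' @param n_per_group Subjects per cohort (>= 2; default emulates a 7 + 7
#'   two-arm design).
#' @param afferent_range AMI afferent range, Imp/s (nonzero width).
#' @param slope_spec Named list of per-metric `list(m = slope, b = intercept)`
#'   against afferent level. Defaults cover `peak_power` (W/kg), `net_work`
#'   (J/kg), `speed` (m/s) and `lek_symmetry` (%).
#' @param noise Residual standard deviation, as a fraction of each metric's
#'   slope-induced range (default 0.1).
#' @param seed Integer seed.
#' @param include_trials If `TRUE`, attach a generated phantom-cycle set and
#'   level-walking trial per subject (slower; default `FALSE`).
#' @return Tibble: `subject`, `group`, `afferent` plus one column per metric
#'   (attribute `slopes` records the generating relation). With
#'   `include_trials`, a list-column `trial` and `phantom` are added.
#' @export
generate_cohort <- function(n_per_group = 7,
                            afferent_range = c(8, 13),
                            slope_spec = NULL, noise = 0.1, seed = 1L,
                            include_trials = FALSE) {
  stopifnot(n_per_group >= 2)
  if (diff(range(afferent_range)) <= 0) {
    stop("afferent_range must have nonzero width", call. = FALSE)
  }
  if (is.null(slope_spec)) {
    slope_spec <- list(
      peak_power = list(m = 0.10, b = 0.70),
      net_work = list(m = 0.018, b = -0.02),
      speed = list(m = 0.042, b = 1.26),
      lek_symmetry = list(m = 1.1, b = 72)
    )
  }
  width <- diff(range(afferent_range))
  with_seed_(seed, {
    aff_ami <- runif(n_per_group, afferent_range[1], afferent_range[2])
    aff_ctl <- runif(n_per_group, afferent_range[1] - 2 * width,
                     afferent_range[2] - 2 * width)
    tab <- tibble::tibble(
      subject = sprintf("S%02d", seq_len(2 * n_per_group)),
      group = rep(c("AMI", "CTL"), each = n_per_group),
      afferent = c(aff_ami, aff_ctl)
    )
    for (metric in names(slope_spec)) {
      sp <- slope_spec[[metric]]
      scale <- abs(sp$m) * width * 2
      tab[[metric]] <- sp$b + sp$m * tab$afferent +
        rnorm(nrow(tab), 0, noise * max(scale, .Machine$double.eps))
    }
    if (include_trials) {
      specs <- purrr::map2(tab$group, seq_len(nrow(tab)), function(g, i) {
        archetype_spec(g, afferent_level = tab$afferent[i],
                       seed = seed + i)
      })
      tab$phantom <- purrr::map(specs, generate_phantom_cycles, n_cycles = 3)
      tab$trial <- purrr::map(specs, generate_gait_trial,
                              condition = "level_max", n_cycles = 2)
    }
    attr(tab, "slopes") <- slope_spec
    tab
  })
}
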