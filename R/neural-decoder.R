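# Decoder: TA/GAS activations -> equilibrium angle theta_ref and impedance
# level mu_z, with per-subject calibration against maximal phantom DF/PF.

#' Calibrate the two-muscle decoder
#'
#' Solves for the weighting coefficients `w_ta`, `w_gas` such that the
#' plateau-mean weighted activation difference during a maximal phantom
#' dorsiflexion (DF) trial maps to the prosthetic DF limit (+10 deg) and the
#' maximal plantar flexion (PF) trial maps to the PF limit (-20 deg). The
#' impedance normalizers `mu_norm_df` / `mu_norm_pf` are the plateau-mean
#' weighted activation sums of the corresponding trial, so the calibration
#' activations themselves reach `mu_z = 1`.
#'
#' Plateaus are the samples where the trial's agonist activation is at or
#' above `plateau_frac` of its maximum; each trial must hold its plateau for
#' at least `min_plateau_s`.
#'
#' @param max_df_trial,max_pf_trial Data frames with `time_s`, `ta`, `gas`
#'   activation columns recorded during maximal phantom DF and PF.
#' @param rom_df,rom_pf Prosthetic range-of-motion limits, deg (DF positive);
#'   defaults +10 and -20.
#' @param plateau_frac Fraction of the agonist maximum defining the plateau.
#' @param min_plateau_s Minimum sustained plateau duration, s.
#' @return A `bg_decoder_calibration`: list with `w_ta`, `w_gas` (deg per
#'   unit activation), `mu_norm_df`, `mu_norm_pf`, `rom_df`, `rom_pf`, and
#'   the plateau means.
#' @export
calibrate_decoder <- function(max_df_trial, max_pf_trial,
                              rom_df = 10, rom_pf = -20,
                              plateau_frac = 0.9, min_plateau_s = 0.5) {
  stopifnot(rom_df > 0, rom_pf < 0)
  plateau_mean <- function(trial, agonist) {
    stopifnot(is.data.frame(trial), all(c("time_s", "ta", "gas") %in% names(trial)))
    sr <- 1 / stats::median(diff(trial$time_s))
    keep <- trial[[agonist]] >= plateau_frac * max(trial[[agonist]])
    if (sum(keep) < min_plateau_s * sr) {
      stop(sprintf(
        "no sustained plateau (>= %.1f s at >= %d%% of max %s activation) in trial",
        min_plateau_s, round(100 * plateau_frac), agonist), call. = FALSE)
    }
    c(ta = mean(trial$ta[keep]), gas = mean(trial$gas[keep]))
  }
  m_df <- plateau_mean(max_df_trial, "ta")
  m_pf <- plateau_mean(max_pf_trial, "gas")
  A <- rbind(c(m_df["ta"], -m_df["gas"]),
             c(m_pf["ta"], -m_pf["gas"]))
  d <- det(A)
  scale <- max(abs(A)) ^ 2
  if (!is.finite(d) || abs(d) < 1e-6 * max(scale, .Machine$double.eps)) {
    stop(paste0(
      "calibration failure: DF and PF activation patterns are indistinct ",
      sprintf("(plateau means DF ta=%.3f gas=%.3f, PF ta=%.3f gas=%.3f)",
              m_df["ta"], m_df["gas"], m_pf["ta"], m_pf["gas"])), call. = FALSE)
  }
  w <- solve(A, c(rom_df, rom_pf))
  mu_df <- w[1] * m_df["ta"] + w[2] * m_df["gas"]
  mu_pf <- w[1] * m_pf["ta"] + w[2] * m_pf["gas"]
  if (mu_df <= 0 || mu_pf <= 0) {
    stop("calibration failure: nonpositive impedance normalizer", call. = FALSE)
  }
  structure(
    list(w_ta = unname(w[1]), w_gas = unname(w[2]),
         mu_norm_df = unname(mu_df), mu_norm_pf = unname(mu_pf),
         rom_df = rom_df, rom_pf = rom_pf,
         plateau_df = m_df, plateau_pf = m_pf),
    class = "bg_decoder_calibration"
  )
}

#' @export
print.bg_decoder_calibration <- function(x, ...) {
  cat("<bg_decoder_calibration>\n")
  cat(sprintf("  w_ta  = %.3f deg/unit   w_gas = %.3f deg/unit\n", x$w_ta, x$w_gas))
  cat(sprintf("  mu_norm_df = %.3f   mu_norm_pf = %.3f\n", x$mu_norm_df, x$mu_norm_pf))
  cat(sprintf("  ROM [%+.0f, %+.0f] deg\n", x$rom_pf, x$rom_df))
  invisible(x)
}

# Critically damped second-order low-pass (two cascaded exact one-pole
# stages with pole at the cut-off), magnitude 1/2 at the cut-off frequency.
second_order_lowpass_ <- function(x, sample_rate, fc = 6, y0 = x[1]) {
  a <- exp(-2 * pi * fc / sample_rate)
  n <- length(x)
  y1 <- numeric(n); y2 <- numeric(n)
  p1 <- y0; p2 <- y0
  for (i in seq_len(n)) {
    p1 <- a * p1 + (1 - a) * x[i]
    p2 <- a * p2 + (1 - a) * p1
    y2[i] <- p2
  }
  y2
}

#' Decode the equilibrium angle command
#'
#' `theta_ref` is the weighted activation difference
#' `w_ta * a_ta - w_gas * a_gas`, clipped to the prosthetic range of motion,
#' then smoothed by a critically damped second-order low-pass filter with a
#' 6 Hz cut-off (zero overshoot to steps; magnitude 1/2 at the cut-off).
#' Clipping precedes filtering so the filtered command respects the actuator
#' limits without post-filter discontinuities.
#'
#' @param a_ta,a_gas Activation traces in `[0, 1]`, common sampling.
#' @param calib A `bg_decoder_calibration`.
#' @param sample_rate Sampling rate, Hz.
#' @param fc Filter cut-off, Hz (default 6).
#' @param init Initial filter state, deg (default 0: neutral at power-on).
#' @return `theta_ref` trace in deg, within `[rom_pf, rom_df]`.
#' @export
compute_theta_ref <- function(a_ta, a_gas, calib, sample_rate, fc = 6,
                              init = 0) {
  stopifnot(inherits(calib, "bg_decoder_calibration"),
            length(a_ta) == length(a_gas))
  assert_finite_(a_ta, "a_ta"); assert_finite_(a_gas, "a_gas")
  raw <- clip(calib$w_ta * a_ta - calib$w_gas * a_gas,
              calib$rom_pf, calib$rom_df)
  second_order_lowpass_(raw, sample_rate, fc = fc, y0 = init)
}

#' Decode the impedance modulation level
#'
#' `mu_z = clip((w_ta * a_ta + w_gas * a_gas) / mu_norm_dir, 0, 1)` where the
#' normalizer is direction specific (separate values for DF and PF
#' actuation, reflecting different DF/PF motor coordination).
#'
#' @inheritParams compute_theta_ref
#' @param direction `"df"` or `"pf"`, scalar or per-sample.
#' @return `mu_z` trace in `[0, 1]`.
#' @export
compute_mu_z <- function(a_ta, a_gas, calib, direction = "df") {
  stopifnot(inherits(calib, "bg_decoder_calibration"),
            length(a_ta) == length(a_gas),
            all(direction %in% c("df", "pf")))
  ws <- calib$w_ta * a_ta + calib$w_gas * a_gas
  norm <- ifelse(direction == "df", calib$mu_norm_df, calib$mu_norm_pf)
  clip(ws / norm, 0, 1)
}

#' Decode both control variables from an activation table
#'
#' Convenience wrapper producing per-sample `theta_ref` and `mu_z`. When the
#' measured ankle angle is supplied, the `mu_z` normalizer direction follows
#' the sign of the instantaneous angle error `delta = theta_ref - angle`,
#' with a hysteresis band (`hysteresis_deg`) holding the previous direction
#' near `delta = 0` to avoid normalizer chattering.
#'
#' @param activations Data frame with `time_s`, `ta`, `gas` activations.
#' @param calib A `bg_decoder_calibration`.
#' @param angle Optional measured ankle angle trace, deg (same length).
#' @param sample_rate Sampling rate, Hz; inferred from `time_s` if `NULL`.
#' @param hysteresis_deg Direction-switch hysteresis half-width, deg.
#' @param fc Equilibrium-angle filter cut-off, Hz.
#' @return Tibble with `time_s`, `theta_ref`, `mu_z`, `direction`.
#' @export
decode_intent <- function(activations, calib, angle = NULL,
                          sample_rate = NULL, hysteresis_deg = 0.5, fc = 6) {
  stopifnot(is.data.frame(activations),
            all(c("time_s", "ta", "gas") %in% names(activations)))
  if (is.null(sample_rate)) {
    sample_rate <- 1 / stats::median(diff(activations$time_s))
  }
  th <- compute_theta_ref(activations$ta, activations$gas, calib, sample_rate,
                          fc = fc)
  if (is.null(angle)) {
    dir <- ifelse(th >= 0, "df", "pf")
  } else {
    stopifnot(length(angle) == length(th))
    delta <- th - angle
    dir <- character(length(delta))
    prev <- if (delta[1] >= 0) "df" else "pf"
    for (i in seq_along(delta)) {
      if (delta[i] > hysteresis_deg) prev <- "df"
      else if (delta[i] < -hysteresis_deg) prev <- "pf"
      dir[i] <- prev
    }
  }
  tibble::tibble(
    time_s = activations$time_s,
    theta_ref = th,
    mu_z = compute_mu_z(activations$ta, activations$gas, calib, dir),
    direction = dir
  )
}
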