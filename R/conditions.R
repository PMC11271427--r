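# Gait condition templates: parametric waveform families (sums of Gaussian
# bumps on normative templates) for ankle angle, mass-normalized torque,
# muscle activation profiles, and external-load schedules. These are
# statistical emulations of typical prosthetic gait, not a validated
# forward-dynamics model.

#' Supported gait condition labels
#'
#' @return Character vector of the closed set of condition labels.
#' @export
gait_conditions <- function() {
  c("level_slow", "level_moderate", "level_max",
    "slope_up", "slope_down", "stair_up", "stair_down",
    "obstacle", "unperturbed_baseline")
}

match_condition_ <- function(condition) {
  if (!is.character(condition) || length(condition) != 1L ||
      !(condition %in% gait_conditions())) {
    stop("unknown condition; valid labels: ",
         paste(gait_conditions(), collapse = ", "), call. = FALSE)
  }
  condition
}

# Gaussian bump on the percent-cycle axis.
gbump_ <- function(p, center, width) exp(-((p - center) / width)^2)

#' Stance end for a condition
#'
#' @param condition Condition label.
#' @return Stance end as percent of the gait cycle.
#' @export
condition_stance_end <- function(condition) {
  condition <- match_condition_(condition)
  if (condition %in% c("stair_up", "stair_down")) 60 else 62
}

# speed (m/s), cycle duration (s) and kinetic scale per condition
condition_pars_ <- function(condition) {
  switch(condition,
    level_slow = list(speed = 0.98, duration = 1.25, kscale = 0.55),
    level_moderate = list(speed = 1.25, duration = 1.10, kscale = 0.80),
    level_max = list(speed = 1.78, duration = 0.95, kscale = 1.00),
    slope_up = list(speed = 1.10, duration = 1.15, kscale = 1.10),
    slope_down = list(speed = 1.10, duration = 1.15, kscale = 0.70),
    stair_up = list(speed = 0.60, duration = 1.40, kscale = 0.95),
    stair_down = list(speed = 0.60, duration = 1.40, kscale = 0.90),
    obstacle = list(speed = 0.94, duration = 1.20, kscale = 0.85),
    unperturbed_baseline = list(speed = 0.94, duration = 1.20, kscale = 0.85)
  )
}

# Ankle angle template, deg (DF positive): base component (non-biomimetic,
# stiff ankle) plus a biomimeticness-scaled component carrying the loading
# response, mid-stance dorsiflexion, push-off and foot-clearance features.
condition_angle_ <- function(condition, p, b) {
  base <- -2 * gbump_(p, 8, 6) + 2.5 * gbump_(p, 45, 18) - 3 * gbump_(p, 63, 9)
  extra <- switch(condition,
    stair_up = 6 * gbump_(p, 20, 14) - 12 * gbump_(p, 58, 7) +
      5 * gbump_(p, 82, 9),
    stair_down = 18 * gbump_(p, 30, 18) - 20 * gbump_(p, 78, 12),
    slope_up = -2.5 * gbump_(p, 8, 4) + 9.5 * gbump_(p, 45, 13) -
      11 * gbump_(p, 63, 9) + 5 * gbump_(p, 80, 9),
    slope_down = -3.5 * gbump_(p, 8, 4) + 6 * gbump_(p, 45, 13) -
      10 * gbump_(p, 63, 9) + 3.5 * gbump_(p, 80, 9),
    obstacle = -2.5 * gbump_(p, 8, 4) + 7.5 * gbump_(p, 45, 13) -
      11 * gbump_(p, 63, 9) + 8 * gbump_(p, 80, 10),
    # level walking and unperturbed baseline
    -2.5 * gbump_(p, 8, 4) + 7.5 * gbump_(p, 45, 13) -
      11 * gbump_(p, 63, 9) + 4 * gbump_(p, 80, 8)
  )
  base + b * extra
}

# Biological torque template, Nm/kg (DF positive; stance plantarflexor
# torque is negative). Stair descent carries an early eccentric
# weight-acceptance burst; stair ascent a concentric pull-up burst.
condition_torque_bio_ <- function(condition, p) {
  switch(condition,
    stair_down = -0.9 * gbump_(p, 18, 12) - 0.25 * gbump_(p, 45, 12),
    stair_up = -0.8 * gbump_(p, 45, 14),
    slope_up = -0.85 * gbump_(p, 52, 14),
    slope_down = -0.55 * gbump_(p, 50, 13),
    -0.75 * gbump_(p, 52, 13)
  )
}

# Muscle activation profiles in [0, 1]: TA at heel strike and through swing,
# GAS through mid/late stance.
condition_activation_ <- function(condition, p, b = 1) {
  ta <- clip(0.45 * gbump_(p, 4, 5) + (0.35 + 0.35 * b) * gbump_(p, 82, 12), 0, 1)
  gas <- clip((0.5 + 0.4 * b) * gbump_(p, 50, 14), 0, 1)
  tibble::tibble(pct = p, ta = ta, gas = gas)
}

#' External ground-torque schedule for a condition
#'
#' Ground contact is replayed as a mass-normalized dorsiflexing torque over
#' the stance phase (the ground reaction tends to dorsiflex the ankle as the
#' body progresses over the foot), zero in swing.
#'
#' @param condition Condition label.
#' @return Function mapping percent cycle (vectorized) to Nm/kg.
#' @export
condition_load_schedule <- function(condition) {
  condition <- match_condition_(condition)
  se <- condition_stance_end(condition)
  amp <- condition_pars_(condition)$kscale * 1.3
  force(se); force(amp)
  function(pct) {
    x <- clip(pct / se, 0, 1)
    ifelse(pct < se, amp * sin(pi * x)^2 * (0.4 + 0.6 * x), 0)
  }
}

# Normative contralateral lower-extremity templates, deg.
normative_lek_ <- function(p) {
  tibble::tibble(
    pct = p,
    ankle = condition_angle_("level_max", p, 1),
    knee = 8 + 12 * gbump_(p, 15, 10) + 55 * gbump_(p, 72, 11),
    hip = 25 * cos(2 * pi * p / 100) + 5
  )
}
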