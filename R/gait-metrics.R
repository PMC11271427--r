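# Per-trial gait biomechanics: cycle normalization, event kinematics, peak
# power, net work, torque-angle loops, range of motion, kinematic symmetry,
# and perturbation-response metrics.

GRID_N <- 1001L  # fixed cycle grid, 0.1 % resolution

#' Construct a normalized gait cycle
#'
#' @param angle,torque Numeric traces on the fixed 1001-point grid (deg,
#'   Nm/kg). `power` (W/kg) is recomputed from torque and angular velocity
#'   if missing.
#' @param power Optional power trace, W/kg.
#' @param stance_end_pct Stance end, percent of cycle (in (0, 100)).
#' @param duration_s Cycle duration, s.
#' @param mass Subject mass, kg.
#' @param condition Condition label.
#' @return Tibble of class `bg_gait_cycle` with columns `pct`, `angle`,
#'   `torque`, `power` and attributes `stance_end_pct`, `duration_s`,
#'   `mass`, `condition`.
#' @export
gait_cycle <- function(angle, torque, power = NULL, stance_end_pct = 62,
                       duration_s = 1, mass = 70, condition = "level_max") {
  stopifnot(length(angle) == GRID_N, length(torque) == GRID_N,
            stance_end_pct > 0, stance_end_pct < 100, duration_s > 0,
            mass > 0)
  pct <- seq(0, 100, length.out = GRID_N)
  if (is.null(power)) {
    t_s <- pct / 100 * duration_s
    power <- torque * grad_(angle, t_s) * pi / 180
  }
  out <- tibble::tibble(pct = pct, angle = angle, torque = torque,
                        power = power)
  attr(out, "stance_end_pct") <- stance_end_pct
  attr(out, "duration_s") <- duration_s
  attr(out, "mass") <- mass
  attr(out, "condition") <- condition
  class(out) <- c("bg_gait_cycle", class(out))
  out
}

#' Normalize a recorded trial into per-cycle gait cycles
#'
#' Splits a trial into gait cycles (using its `cycle` column or supplied
#' bounds), resamples angle and torque onto the fixed 1001-point percent
#' grid, divides torque (and hence power and work) by subject mass when the
#' trial torque is in Nm, and recomputes power from the resampled traces.
#'
#' @param trial Data frame with `time_s`, `angle`, `torque` and either a
#'   `cycle` column or none (then `bounds` is required). A `bg_trial` from
#'   [generate_gait_trial()] or a tibble from [simulate_gait()] is accepted
#'   directly.
#' @param bounds Optional numeric vector of cycle start times, s.
#' @param mass Subject mass, kg (defaults to the trial's attribute, else 70).
#' @param mass_normalized Is the trial torque already in Nm/kg? Defaults to
#'   `TRUE` for generated/simulated trials.
#' @param stance_end_pct Stance end, percent (defaults to the trial's
#'   attribute, else 62).
#' @param condition Condition label override.
#' @return List of `bg_gait_cycle` objects, one per complete cycle.
#' @export
normalize_cycle <- function(trial, bounds = NULL, mass = NULL,
                            mass_normalized = TRUE, stance_end_pct = NULL,
                            condition = NULL) {
  if (inherits(trial, "bg_trial")) {
    df <- dplyr::left_join(
      trial$kinematics[, c("time_s", "cycle", "ankle")],
      trial$kinetics[, c("time_s", "torque")], by = "time_s")
    names(df)[names(df) == "ankle"] <- "angle"
    if (is.null(mass)) mass <- trial$mass
    if (is.null(stance_end_pct)) stance_end_pct <- trial$stance_end_pct
    if (is.null(condition)) condition <- trial$condition
  } else {
    df <- trial
    if (is.null(mass)) mass <- attr(trial, "mass") %||% 70
    if (is.null(stance_end_pct)) {
      stance_end_pct <- attr(trial, "stance_end_pct") %||% 62
    }
    if (is.null(condition)) {
      condition <- attr(trial, "condition") %||% "level_max"
    }
  }
  stopifnot(all(c("time_s", "angle", "torque") %in% names(df)), mass > 0)
  if (!is.null(bounds)) {
    df$cycle <- findInterval(df$time_s, bounds)
    df <- df[df$cycle >= 1 & df$time_s < max(bounds), ]
  }
  if (!"cycle" %in% names(df)) {
    stop("trial has no `cycle` column and no `bounds` were supplied",
         call. = FALSE)
  }
  cycles <- split(df, df$cycle)
  cycles <- cycles[vapply(cycles, nrow, integer(1)) >= 2L]
  purrr::map(unname(cycles), function(d) {
    dur <- diff(range(d$time_s)) + stats::median(diff(d$time_s))
    if (dur < 0.2) stop("cycle shorter than 0.2 s rejected as spurious",
                        call. = FALSE)
    p_in <- (d$time_s - min(d$time_s)) / dur * 100
    pct <- seq(0, 100, length.out = GRID_N)
    ang <- approx(p_in, d$angle, pct, rule = 2)$y
    trq <- approx(p_in, d$torque, pct, rule = 2)$y
    if (!mass_normalized) trq <- trq / mass
    gait_cycle(ang, trq, stance_end_pct = stance_end_pct, duration_s = dur,
               mass = mass, condition = condition)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# signed excursion between two landmark indices, with direction label
excursion_row_ <- function(event, x, pct, i_from, i_to) {
  if (is.na(i_from) || is.na(i_to)) {
    return(tibble::tibble(event = event, excursion_deg = NA_real_,
                          direction = NA_character_, from_pct = NA_real_,
                          to_pct = NA_real_, absent = TRUE))
  }
  d <- x[i_to] - x[i_from]
  tibble::tibble(event = event, excursion_deg = abs(d),
                 direction = if (d >= 0) "df" else "pf",
                 from_pct = pct[i_from], to_pct = pct[i_to], absent = FALSE)
}

#' Segment level-walking / slope gait events
#'
#' Event excursions from the average ankle angle cycle, following the
#' landmark definitions: heel strike (HS) by PF from initial ground contact
#' to the first local PF maximum during stance; loading response (LR) by DF
#' from that point to the maximum DF during stance; push-off (PO) by PF from
#' the stance DF maximum to the angle at the end of stance; foot clearance
#' (FC) by DF from the end of stance to the end of swing. A missing landmark
#' (e.g. no PF local maximum in stance) flags the affected events absent
#' rather than fabricating them.
#'
#' @param cycle A `bg_gait_cycle`, or a numeric angle trace on the fixed
#'   grid.
#' @param stance_end_pct Stance end, percent (taken from the cycle if
#'   omitted).
#' @return Tibble: `event`, `excursion_deg` (magnitude), `direction`
#'   (`"df"`/`"pf"`), `from_pct`, `to_pct`, `absent`.
#' @export
segment_level_events <- function(cycle, stance_end_pct = NULL) {
  x <- if (is.data.frame(cycle)) cycle$angle else cycle
  stance_end_pct <- stance_end_pct %||% attr(cycle, "stance_end_pct") %||% 62
  pct <- seq(0, 100, length.out = length(x))
  stance <- which(pct <= stance_end_pct)
  ex <- local_extrema_(x[stance])
  i_pfmax <- if (length(ex$minima)) ex$minima[1] else NA_integer_
  i_dfmax <- stance[which.max(x[stance])]
  i_se <- max(stance)
  i_end <- length(x)
  flat <- length(unique(x)) == 1L
  if (flat) {
    i_pfmax <- 1L; i_dfmax <- 1L
  }
  out <- dplyr::bind_rows(
    excursion_row_("HS", x, pct, 1L, i_pfmax),
    excursion_row_("LR", x, pct, i_pfmax, i_dfmax),
    excursion_row_("PO", x, pct, i_dfmax, i_se),
    excursion_row_("FC", x, pct, i_se, i_end)
  )
  if (flat) out$absent <- TRUE
  out
}

#' Segment stair gait events
#'
#' Stair descent: weight acceptance (WA) by DF from initial contact to the
#' stance DF maximum; forward continuance / foot placement (FCo) by PF from
#' the stance DF maximum to the end of swing. Stair ascent: WA as for
#' descent; pull-up (PU) and foot clearance (FC) computed as PO and FC of
#' level walking.
#'
#' @inheritParams segment_level_events
#' @param direction `"descent"` or `"ascent"`.
#' @return Tibble as in [segment_level_events()].
#' @export
segment_stair_events <- function(cycle, stance_end_pct = NULL,
                                 direction = c("descent", "ascent")) {
  direction <- match.arg(direction)
  x <- if (is.data.frame(cycle)) cycle$angle else cycle
  stance_end_pct <- stance_end_pct %||% attr(cycle, "stance_end_pct") %||% 60
  pct <- seq(0, 100, length.out = length(x))
  stance <- which(pct <= stance_end_pct)
  i_dfmax <- stance[which.max(x[stance])]
  # a stance DF maximum must rise above initial contact to count
  if (x[i_dfmax] <= x[1] + .Machine$double.eps^0.5) i_dfmax <- NA_integer_
  i_se <- max(stance)
  i_end <- length(x)
  if (direction == "descent") {
    dplyr::bind_rows(
      excursion_row_("WA", x, pct, 1L, i_dfmax),
      excursion_row_("FCo", x, pct, i_dfmax, i_end)
    )
  } else {
    dplyr::bind_rows(
      excursion_row_("WA", x, pct, 1L, i_dfmax),
      excursion_row_("PU", x, pct, i_dfmax, i_se),
      excursion_row_("FC", x, pct, i_se, i_end)
    )
  }
}

#' Peak power of a gait cycle
#'
#' Extremum of the requested sign over the cycle (positive peak for all
#' conditions except stair descent, which uses the negative peak); 0 when no
#' sample of that sign exists.
#'
#' @param cycle A `bg_gait_cycle`, or a numeric power trace (W/kg).
#' @param mode `"positive"` or `"negative"`.
#' @return Peak power, W/kg (signed).
#' @export
peak_power <- function(cycle, mode = c("positive", "negative")) {
  mode <- match.arg(mode)
  p <- if (is.data.frame(cycle)) cycle$power else cycle
  if (mode == "positive") {
    if (!any(p > 0)) 0 else max(p)
  } else {
    if (!any(p < 0)) 0 else min(p)
  }
}

#' Net work over a cycle window
#'
#' Trapezoidal time-integral of the mass-normalized power over a percent
#' window of the cycle (full cycle for walking; the weight-acceptance and
#' pull-up windows for stair descent and ascent).
#'
#' @param cycle A `bg_gait_cycle`.
#' @param window Numeric length-2 percent range, default `c(0, 100)`.
#' @return Net work, J/kg.
#' @export
net_work <- function(cycle, window = c(0, 100)) {
  stopifnot(inherits(cycle, "bg_gait_cycle"))
  if (window[2] <= window[1] || any(window < 0) || any(window > 100)) {
    stop("window must be an increasing range within [0, 100]", call. = FALSE)
  }
  keep <- cycle$pct >= window[1] & cycle$pct <= window[2]
  t_s <- cycle$pct[keep] / 100 * attr(cycle, "duration_s")
  trapz_(t_s, cycle$power[keep])
}

#' Torque-angle loop direction and area
#'
#' Signed shoelace area of the closed (angle, torque) curve, with the angle
#' in radians so the area is in J/kg. Counterclockwise traversal gives
#' positive area, equal to the net positive work injected over the cycle;
#' clockwise traversal dissipates energy. A loop whose endpoints differ by
#' more than `tol` (in either coordinate's range fraction) is closed by a
#' straight segment and flagged.
#'
#' @param cycle A `bg_gait_cycle`.
#' @param tol Endpoint mismatch tolerance as a fraction of each coordinate's
#'   range (default 0.05).
#' @return Tibble with `direction` (`"ccw"`/`"cw"`), `area` (J/kg) and
#'   `closed` (endpoint flag).
#' @export
torque_angle_loop <- function(cycle, tol = 0.05) {
  stopifnot(inherits(cycle, "bg_gait_cycle"))
  th <- cycle$angle * pi / 180
  ta <- cycle$torque
  gap_th <- abs(th[length(th)] - th[1]) / max(diff(range(th)), .Machine$double.eps)
  gap_ta <- abs(ta[length(ta)] - ta[1]) / max(diff(range(ta)), .Machine$double.eps)
  closed <- gap_th <= tol && gap_ta <= tol
  # shoelace on the closed polygon (trapezoid form of the line integral)
  x <- c(th, th[1]); y <- c(ta, ta[1])
  area <- sum((x[-1] - x[-length(x)]) * (y[-1] + y[-length(y)])) / 2
  tibble::tibble(direction = if (area >= 0) "ccw" else "cw",
                 area = area, closed = closed)
}

#' Lower-extremity kinematic symmetry
#'
#' Per-joint symmetry index (SI): the cycle-integrated absolute difference
#' between contralateral and ipsilateral trajectories, normalized by the
#' mean cycle-integrated absolute excursion of the two limbs, times 100.
#' The SI is averaged across ankle, knee and hip, and symmetry is reported
#' as `100 - SI` (%): 100 iff the limbs' trajectories are identical,
#' symmetric under exchanging the limbs, decreasing in any offset.
#'
#' @param ipsi,contra Data frames with `pct` plus joint angle columns
#'   (default joints `ankle`, `knee`, `hip`), deg, on a common grid.
#' @param joints Joint column names to use.
#' @return Tibble of class `bg_symmetry`: per-joint `si` rows plus
#'   `lek_symmetry` (%) attribute columns `si_mean`, `lek_symmetry`.
#' @export
lek_symmetry <- function(ipsi, contra, joints = c("ankle", "knee", "hip")) {
  missing_j <- setdiff(joints, intersect(names(ipsi), names(contra)))
  if (length(missing_j)) {
    stop("missing joint columns: ", paste(missing_j, collapse = ", "),
         "; present: ",
         paste(intersect(names(ipsi), names(contra)), collapse = ", "),
         call. = FALSE)
  }
  stopifnot(nrow(ipsi) == nrow(contra))
  p <- if ("pct" %in% names(ipsi)) ipsi$pct else seq(0, 100, length.out = nrow(ipsi))
  si <- vapply(joints, function(j) {
    xi <- ipsi[[j]]; xp <- contra[[j]]
    num <- trapz_(p, abs(xp - xi))
    den <- mean(c(trapz_(p, abs(xi)), trapz_(p, abs(xp))))
    if (den <= .Machine$double.eps) {
      if (num <= .Machine$double.eps) 0 else 100
    } else {
      100 * num / den
    }
  }, numeric(1))
  out <- tibble::tibble(joint = joints, si = unname(si))
  out$lek_symmetry <- 100 - mean(si)
  class(out) <- c("bg_symmetry", class(out))
  out
}

#' Range of motion of a trajectory
#'
#' Difference between the maximum and minimum of the average trajectory
#' (maximum DF minus maximum PF for the ankle; flexion minus extension for
#' proximal joints).
#'
#' @param trajectory Numeric angle trace, deg.
#' @return Range of motion, deg.
#' @export
rom <- function(trajectory) {
  assert_finite_(trajectory, "trajectory")
  max(trajectory) - min(trajectory)
}

# peak swing dorsiflexion of one cycle
swing_df_peak_ <- function(cycle) {
  se <- attr(cycle, "stance_end_pct") %||% 62
  max(cycle$angle[cycle$pct > se])
}

#' Obstacle-crossing swing kinematics change
#'
#' Average increase in swing-phase dorsiflexion peak of the bionic ankle for
#' perturbed (obstacle-crossing) cycles relative to unperturbed walking;
#' negative values indicate an absent or inverted response.
#'
#' @param perturbed,unperturbed Lists of `bg_gait_cycle` objects.
#' @return Mean swing DF increase, deg.
#' @export
obstacle_swing_delta <- function(perturbed, unperturbed) {
  pk <- function(cycles) vapply(cycles, swing_df_peak_, numeric(1))
  mean(pk(perturbed)) - mean(pk(unperturbed))
}

#' Recovery-step propulsion metrics
#'
#' Peak positive power and full-cycle net work of the recovery step after an
#' obstacle crossing (delegates to [peak_power()] and [net_work()]).
#'
#' @param cycle A `bg_gait_cycle` for the recovery step.
#' @return Tibble with `peak_power` (W/kg) and `net_work` (J/kg).
#' @export
recovery_step_metrics <- function(cycle) {
  tibble::tibble(peak_power = peak_power(cycle, "positive"),
                 net_work = net_work(cycle))
}
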