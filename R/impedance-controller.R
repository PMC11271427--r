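# Impedance controller: (theta_ref, mu_z, joint state) -> ankle torque,
# bounded by biological maximal torque, plus passive-structure restoring
# torque and virtual stiffness/damping, saturated at the device limit.

#' Biological torque model for the prosthetic ankle
#'
#' Bundles the direction-specific maximal-torque curves (Gaussian
#' force-length over joint angle, Hill-type force-velocity with an eccentric
#' plateau), the passive-structure restoring-torque curve, the virtual
#' impedance gains, the device torque limit (162 Nm) and the range of motion
#' (+10 deg DF to -20 deg PF). All parameters are configurable; defaults are
#' in the physiological range for the adult human ankle.
#'
#' @param tau_iso_df,tau_iso_pf Peak isometric torque toward DF / PF, Nm.
#' @param fl_opt_df,fl_opt_pf Optimal joint angle of the force-length curve
#'   per direction, deg.
#' @param fl_width_df,fl_width_pf Gaussian force-length width, deg.
#' @param v_max Maximal shortening velocity in joint space, deg/s.
#' @param fv_shape Hill force-velocity shape factor (curvature).
#' @param ecc_plateau Eccentric force-velocity plateau (multiple of
#'   isometric), default 1.4.
#' @param passive_onset_df,passive_onset_pf Angles where passive-structure
#'   torque engages (neutral zone boundaries), deg.
#' @param passive_scale Passive torque scale, Nm.
#' @param passive_rate Passive torque exponential rate, 1/deg.
#' @param k_virtual Virtual stiffness, Nm/deg (default 0.45).
#' @param b_virtual Virtual damping, Nm s/deg (default 0.02).
#' @param tau_limit Device saturation torque, Nm (default 162).
#' @param rom_df,rom_pf Range-of-motion limits, deg.
#' @return A `bg_torque_model` list.
#' @export
bio_torque_model <- function(tau_iso_df = 45, tau_iso_pf = 180,
                             fl_opt_df = 0, fl_opt_pf = 5,
                             fl_width_df = 30, fl_width_pf = 35,
                             v_max = 600, fv_shape = 0.25, ecc_plateau = 1.4,
                             passive_onset_df = 5, passive_onset_pf = -12,
                             passive_scale = 0.5, passive_rate = 0.5,
                             k_virtual = 0.45, b_virtual = 0.02,
                             tau_limit = 162, rom_df = 10, rom_pf = -20) {
  stopifnot(tau_iso_df > 0, tau_iso_pf > 0, v_max > 0, fv_shape > 0,
            ecc_plateau >= 1, tau_limit > 0, rom_df > 0, rom_pf < 0,
            passive_onset_pf < passive_onset_df,
            k_virtual >= 0, b_virtual >= 0)
  structure(
    list(tau_iso_df = tau_iso_df, tau_iso_pf = tau_iso_pf,
         fl_opt_df = fl_opt_df, fl_opt_pf = fl_opt_pf,
         fl_width_df = fl_width_df, fl_width_pf = fl_width_pf,
         v_max = v_max, fv_shape = fv_shape, ecc_plateau = ecc_plateau,
         passive_onset_df = passive_onset_df,
         passive_onset_pf = passive_onset_pf,
         passive_scale = passive_scale, passive_rate = passive_rate,
         k_virtual = k_virtual, b_virtual = b_virtual,
         tau_limit = tau_limit, rom_df = rom_df, rom_pf = rom_pf),
    class = "bg_torque_model"
  )
}

# force-length factor in [0, 1], = 1 at the optimal angle
fl_factor_ <- function(angle, opt, width) exp(-((angle - opt) / width)^2)

# Hill force-velocity factor: 1 at zero velocity, 0 at v_max shortening,
# plateau `ecc` for lengthening.
fv_factor_ <- function(shortening, v_max, shape, ecc) {
  f <- ifelse(
    shortening >= 0,
    pmax(0, (1 - shortening / v_max) / (1 + shortening / (shape * v_max))),
    ecc - (ecc - 1) * exp(shortening / (0.1 * v_max))
  )
  pmax(f, 0)
}

#' Maximal biological ankle torque at a joint state
#'
#' `tau_iso_peak x fl(angle) x fv(velocity)` for the commanded direction.
#' Shortening velocity is the joint velocity signed toward the commanded
#' direction (DF torque: dorsiflexing velocity shortens the dorsiflexors).
#'
#' @param angle Joint angle, deg (DF positive).
#' @param velocity Joint angular velocity, deg/s.
#' @param direction `"df"` or `"pf"` (vectorized).
#' @param model A `bg_torque_model`.
#' @return Nonnegative maximal torque magnitude, Nm.
#' @export
max_bio_torque <- function(angle, velocity, direction, model = bio_torque_model()) {
  stopifnot(inherits(model, "bg_torque_model"),
            all(direction %in% c("df", "pf")))
  df <- direction == "df"
  tau0 <- ifelse(df, model$tau_iso_df, model$tau_iso_pf)
  fl <- fl_factor_(angle,
                   ifelse(df, model$fl_opt_df, model$fl_opt_pf),
                   ifelse(df, model$fl_width_df, model$fl_width_pf))
  shortening <- ifelse(df, velocity, -velocity)
  fv <- fv_factor_(shortening, model$v_max, model$fv_shape, model$ecc_plateau)
  tau0 * fl * fv
}

#' Passive-structure restoring torque
#'
#' Torque contribution of passive biological structures (ligaments, joint
#' capsule): zero inside the neutral zone, growing exponentially toward the
#' range-of-motion ends, with sign opposing the displacement (plantar-flexing
#' near the DF limit, dorsiflexing near the PF limit).
#'
#' @inheritParams max_bio_torque
#' @return Restoring torque, Nm.
#' @export
passive_structure_torque <- function(angle, model = bio_torque_model()) {
  stopifnot(inherits(model, "bg_torque_model"))
  k <- model$passive_scale
  r <- model$passive_rate
  tau <- numeric(length(angle))
  up <- angle > model$passive_onset_df
  dn <- angle < model$passive_onset_pf
  tau[up] <- -k * (exp(r * (angle[up] - model$passive_onset_df)) - 1)
  tau[dn] <- k * (exp(r * (model$passive_onset_pf - angle[dn])) - 1)
  tau
}

# Scalar/vector core without tibble overhead; returns a list of components.
command_torque_ <- function(theta_ref, mu_z, angle, velocity, model) {
  delta <- theta_ref - angle
  dir <- ifelse(delta >= 0, "df", "pf")
  delta_span <- model$rom_df - model$rom_pf
  delta_norm <- clip(abs(delta) / delta_span, 0, 1)
  tau_active <- sign(delta) * mu_z * delta_norm *
    max_bio_torque(angle, velocity, dir, model)
  tau_virtual <- -model$k_virtual * (angle - theta_ref) -
    model$b_virtual * velocity
  tau_passive <- passive_structure_torque(angle, model)
  pre <- tau_active + tau_passive + tau_virtual
  total <- clip(pre, -model$tau_limit, model$tau_limit)
  list(tau_total = total, tau_active = tau_active,
       tau_passive = tau_passive, tau_virtual = tau_virtual,
       saturated = abs(pre) > model$tau_limit)
}

#' Compute the commanded ankle torque
#'
#' The active component scales the maximal biological torque at the measured
#' joint state by `mu_z * delta_norm`, where `delta = theta_ref - angle` and
#' `delta_norm` is `|delta|` divided by the full range-of-motion span (the
#' maximal achievable error), clipped to `[0, 1]` - so maximal intent
#' (`mu_z = 1`, maximal `delta`) commands exactly the biological bound.
#' Virtual stiffness (0.45 Nm/deg on `angle - theta_ref`) and damping
#' (0.02 Nm s/deg on velocity) guarantee stability under zero muscle
#' activity; passive-structure torque is added, and the total is saturated
#' at the 162 Nm device limit.
#'
#' @param theta_ref Equilibrium angle command, deg.
#' @param mu_z Impedance modulation level in `[0, 1]`.
#' @param angle,velocity Measured joint state (deg, deg/s).
#' @param model A `bg_torque_model`.
#' @return Tibble with `tau_total`, `tau_active`, `tau_passive`,
#'   `tau_virtual` (Nm; components sum to the pre-saturation total) and
#'   `saturated`.
#' @export
command_torque <- function(theta_ref, mu_z, angle, velocity,
                           model = bio_torque_model()) {
  stopifnot(inherits(model, "bg_torque_model"))
  if (!all(is.finite(theta_ref), is.finite(mu_z), is.finite(angle),
           is.finite(velocity))) {
    stop("command_torque: non-finite input; the controller must never emit NaN torque",
         call. = FALSE)
  }
  if (any(mu_z < 0 | mu_z > 1)) {
    stop("mu_z must lie in [0, 1]", call. = FALSE)
  }
  tibble::as_tibble(command_torque_(theta_ref, mu_z, angle, velocity, model))
}
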