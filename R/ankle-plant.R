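# Minimal ankle/foot plant closing the loop around the controller:
# single rotational inertia, hard stops at the range-of-motion ends, and a
# phase-scheduled external (ground) torque replayed as a function of
# percent gait cycle.

#' Ankle plant configuration
#'
#' @param inertia Rotational inertia of foot + prosthesis about the ankle,
#'   kg m^2 (default 0.05, consistent with a ~2.4 kg ankle-foot device).
#' @param body_mass Subject body mass, kg (used to scale mass-normalized
#'   external load schedules).
#' @param timestep Integration step, s (at most 1 ms).
#' @param v_limit Divergence guard: simulation aborts if |velocity| exceeds
#'   this bound, deg/s.
#' @param rom_df,rom_pf Hard-stop angles, deg.
#' @return A `bg_plant` list.
#' @export
plant_config <- function(inertia = 0.05, body_mass = 70, timestep = 1e-3,
                         v_limit = 1e4, rom_df = 10, rom_pf = -20) {
  stopifnot(inertia > 0, body_mass > 0, timestep <= 1e-3, timestep > 0,
            v_limit > 0, rom_df > 0, rom_pf < 0)
  structure(list(inertia = inertia, body_mass = body_mass,
                 timestep = timestep, v_limit = v_limit,
                 rom_df = rom_df, rom_pf = rom_pf),
            class = "bg_plant")
}

#' Advance the ankle plant one step
#'
#' Semi-implicit Euler update of (angle, velocity) under the net torque,
#' with hard stops at the range-of-motion ends (angle clamped, velocity
#' zeroed when pushing outward).
#'
#' @param state List or numeric with `angle` (deg) and `velocity` (deg/s).
#' @param tau_command Commanded joint torque, Nm.
#' @param tau_external External (ground) torque, Nm.
#' @param plant A `bg_plant`.
#' @param dt Step length, s (defaults to `plant$timestep`; must not exceed it).
#' @return List with updated `angle` and `velocity`.
#' @export
step_dynamics <- function(state, tau_command, tau_external = 0,
                          plant = plant_config(), dt = plant$timestep) {
  stopifnot(inherits(plant, "bg_plant"), dt <= plant$timestep)
  acc <- (tau_command + tau_external) / plant$inertia * (180 / pi)
  v <- state$velocity + acc * dt
  if (abs(v) > plant$v_limit) {
    stop(sprintf(
      "plant divergence: |velocity| = %.0f deg/s exceeds the %.0f deg/s bound",
      abs(v), plant$v_limit), call. = FALSE)
  }
  a <- state$angle + v * dt
  if (a >= plant$rom_df) { a <- plant$rom_df; v <- min(v, 0) }
  if (a <= plant$rom_pf) { a <- plant$rom_pf; v <- max(v, 0) }
  list(angle = a, velocity = v)
}

#' Simulate closed-loop gait cycles
#'
#' Runs raw EMG through the envelope/activation chain, decodes
#' (`theta_ref`, `mu_z`) per sample, closes the loop through the impedance
#' controller and the plant at 1 kHz, and replays the condition's external
#' ground-torque schedule as a function of percent cycle.
#'
#' @param emg Raw EMG data frame (`time_s`, `ta`, `gas`) covering
#'   `n_cycles * cycle_duration` seconds.
#' @param calib A `bg_decoder_calibration`.
#' @param model A `bg_torque_model`.
#' @param plant A `bg_plant`.
#' @param condition Gait condition label (see [gait_conditions()]).
#' @param n_cycles Number of gait cycles to simulate.
#' @param cycle_duration Cycle duration, s.
#' @param load_schedule Function `pct -> Nm/kg` external torque; defaults to
#'   the condition's built-in schedule.
#' @param seed Optional integer seed (reserved for stochastic schedules;
#'   the default simulation is deterministic given its inputs).
#' @param emg_cal Optional envelope calibration passed to [emg_envelope()].
#' @return Tibble (one row per 1 kHz sample): `time_s`, `cycle`, `pct`,
#'   `angle` (deg), `velocity` (deg/s), `torque` (commanded, Nm/kg),
#'   `power` (W/kg), `external` (Nm/kg), `theta_ref`, `mu_z`. Attributes:
#'   `stance_end_pct`, `mass`, `condition`, `cycle_duration_s`.
#' @export
simulate_gait <- function(emg, calib, model = bio_torque_model(),
                          plant = plant_config(), condition = "level_max",
                          n_cycles = 3, cycle_duration = 1,
                          load_schedule = NULL, seed = NULL, emg_cal = NULL) {
  cond <- match.arg(condition, gait_conditions())
  if (is.null(load_schedule)) load_schedule <- condition_load_schedule(cond)
  with_seed_(seed, {
    env <- emg_envelope(emg, cal = emg_cal)
    act <- muscle_activation(env)
    # resample activations to the 1 kHz control grid
    n <- as.integer(round(n_cycles * cycle_duration * 1000))
    t_ctrl <- (seq_len(n) - 1L) / 1000
    a_ta <- approx(act$time_s, act$ta, t_ctrl, rule = 2)$y
    a_gas <- approx(act$time_s, act$gas, t_ctrl, rule = 2)$y
    theta_ref <- compute_theta_ref(a_ta, a_gas, calib, 1000)
    pct <- (t_ctrl %% cycle_duration) / cycle_duration * 100
    ext <- load_schedule(pct) * plant$body_mass
    angle <- numeric(n); vel <- numeric(n)
    tau <- numeric(n); mu <- numeric(n)
    st <- list(angle = 0, velocity = 0)
    dir_prev <- "df"
    for (i in seq_len(n)) {
      delta <- theta_ref[i] - st$angle
      if (delta > 0.5) dir_prev <- "df" else if (delta < -0.5) dir_prev <- "pf"
      mu[i] <- compute_mu_z(a_ta[i], a_gas[i], calib, dir_prev)
      cmd <- command_torque_(theta_ref[i], mu[i], st$angle, st$velocity, model)
      tau[i] <- cmd$tau_total
      st <- step_dynamics(st, tau[i], ext[i], plant, dt = 1e-3)
      angle[i] <- st$angle; vel[i] <- st$velocity
    }
    out <- tibble::tibble(
      time_s = t_ctrl,
      cycle = as.integer(floor(t_ctrl / cycle_duration)) + 1L,
      pct = pct,
      angle = angle, velocity = vel,
      torque = tau / plant$body_mass,
      power = tau * vel * pi / 180 / plant$body_mass,
      external = ext / plant$body_mass,
      theta_ref = theta_ref, mu_z = mu
    )
    attr(out, "stance_end_pct") <- condition_stance_end(cond)
    attr(out, "mass") <- plant$body_mass
    attr(out, "condition") <- cond
    attr(out, "cycle_duration_s") <- cycle_duration
    out
  })
}
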