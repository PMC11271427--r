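# Type II muscle-spindle afferent estimation from fascicle strain and EMG,
# and the agonist-antagonist afferent statistic.

#' Type II muscle-spindle model parameters
#'
#' Additive length/velocity/activation firing-rate model for secondary
#' (type II) spindle afferents. Type II endings are predominantly length
#' sensitive, so the defaults weight the strain term heavily and the
#' strain-rate term lightly. The defaults are calibrated once so that a
#' full-range biologically intact strain excursion (plateau strain 0.25)
#' yields a steady antagonist rate of about 60 Imp/s.
#'
#' @param baseline Resting discharge, Imp/s.
#' @param k_len Length sensitivity, Imp/s per unit strain.
#' @param k_vel Velocity sensitivity, Imp/s per (unit strain/s)^`p`.
#' @param p Velocity power-law exponent.
#' @param k_act Activation (EMG envelope) sensitivity, Imp/s per unit.
#' @return A `bg_spindle_params` list.
#' @export
spindle_params <- function(baseline = 10, k_len = 200, k_vel = 2, p = 0.5,
                           k_act = 10) {
  stopifnot(baseline >= 0, k_len >= 0, k_vel >= 0, p > 0, k_act >= 0)
  structure(list(baseline = baseline, k_len = k_len, k_vel = k_vel, p = p,
                 k_act = k_act),
            class = "bg_spindle_params")
}

#' Spindle firing rate from strain, strain rate and activation
#'
#' `rate = max(0, baseline + k_len * strain
#'   + k_vel * sign(strain_rate) * |strain_rate|^p + k_act * emg)`.
#' Strain is dimensionless (positive = lengthening, as a fraction of optimal
#' fascicle length); the rate is rectified at zero.
#'
#' @param strain Strain trace on the cycle grid.
#' @param strain_rate Strain rate, 1/s (same grid).
#' @param emg_envelope Normalized EMG envelope in `[0, 1]` (same grid).
#' @param params A `bg_spindle_params`.
#' @return Nonnegative firing-rate trace, Imp/s.
#' @export
spindle_rate <- function(strain, strain_rate, emg_envelope,
                         params = spindle_params()) {
  stopifnot(inherits(params, "bg_spindle_params"))
  n <- length(strain)
  if (length(strain_rate) != n || length(emg_envelope) != n) {
    stop("strain, strain_rate and emg_envelope must share one cycle grid",
         call. = FALSE)
  }
  assert_finite_(strain, "strain")
  pmax(0, params$baseline + params$k_len * strain +
         params$k_vel * sign(strain_rate) * abs(strain_rate)^params$p +
         params$k_act * emg_envelope)
}

#' Steady-state afferent rate over the 25-75 % window
#'
#' Arithmetic mean of the rate trace over cycle grid points between 25 %
#' and 75 % of the movement cycle, inclusive (the steady state of a maximal
#' phantom movement).
#'
#' @param rate_trace Firing-rate trace, Imp/s.
#' @param cycle_pct Percent-cycle grid (default the fixed 101-point grid).
#' @return Steady-state mean rate, Imp/s.
#' @export
steady_state_afferent <- function(rate_trace,
                                  cycle_pct = seq(0, 100, length.out = length(rate_trace))) {
  stopifnot(length(rate_trace) == length(cycle_pct))
  keep <- cycle_pct >= 25 & cycle_pct <= 75
  mean(rate_trace[keep])
}

# Strain rate: central differences on the cycle grid after 5-point moving
# average smoothing (ultrasound-derived strain traces are noisy).
strain_rate_ <- function(strain, cycle_pct, cycle_duration) {
  sm <- stats::filter(strain, rep(1 / 5, 5), sides = 2)
  sm <- as.numeric(sm)
  # fill filter edges with the raw values
  sm[is.na(sm)] <- strain[is.na(sm)]
  t_s <- cycle_pct / 100 * cycle_duration
  grad_(sm, t_s)
}

#' Estimate per-muscle afferents from averaged phantom traces
#'
#' Runs the spindle model on cycle-averaged TA/GAS fascicle strain and EMG
#' envelope traces for the phantom DF and PF movements and computes each
#' muscle's steady-state rate and movement role (in DF the TA is the
#' shortening agonist and the GAS the lengthening antagonist; in PF the
#' converse).
#'
#' @param fascicle Data frame with columns `cycle_pct`, `strain_ta`,
#'   `strain_gas`, `env_ta`, `env_gas`, `movement` (`"df"`/`"pf"`); multiple
#'   cycles (a `cycle` column) are averaged first.
#' @param params A `bg_spindle_params`.
#' @param cycle_duration Movement cycle duration in seconds (default 2),
#'   used to convert per-cycle strain to strain rate.
#' @return Tibble of class `bg_afferents`: one row per muscle x movement
#'   with `role` (`agonist_shortening` / `antagonist_lengthening`) and
#'   `steady_mean` (Imp/s); attribute `rate_traces` holds the full traces.
#' @export
estimate_afferents <- function(fascicle, params = spindle_params(),
                               cycle_duration = 2) {
  need <- c("cycle_pct", "strain_ta", "strain_gas", "env_ta", "env_gas",
            "movement")
  if (!all(need %in% names(fascicle))) {
    stop("fascicle must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  avg <- fascicle |>
    dplyr::group_by(.data$movement, .data$cycle_pct) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(
      c("strain_ta", "strain_gas", "env_ta", "env_gas")), mean),
      .groups = "drop")
  traces <- list()
  rows <- purrr::map_dfr(c("df", "pf"), function(mv) {
    d <- dplyr::arrange(dplyr::filter(avg, .data$movement == mv),
                        .data$cycle_pct)
    if (!nrow(d)) stop("missing movement `", mv, "` in fascicle data",
                       call. = FALSE)
    purrr::map_dfr(c("ta", "gas"), function(mu) {
      s <- d[[paste0("strain_", mu)]]
      sr <- strain_rate_(s, d$cycle_pct, cycle_duration)
      rate <- spindle_rate(s, sr, d[[paste0("env_", mu)]], params)
      traces[[paste(mv, mu, sep = "_")]] <<- rate
      agonist <- (mv == "df" && mu == "ta") || (mv == "pf" && mu == "gas")
      tibble::tibble(
        movement = mv, muscle = mu,
        role = if (agonist) "agonist_shortening" else "antagonist_lengthening",
        steady_mean = steady_state_afferent(rate, d$cycle_pct))
    })
  })
  structure(rows, rate_traces = traces,
            class = c("bg_afferents", class(rows)))
}

#' Agonist-antagonist muscle afferent statistic
#'
#' The bandwidth of residual muscle afferent signaling: the difference
#' between the antagonistic (lengthening) and agonistic (shortening)
#' steady-state afferents of the TA/GAS pair, averaged over the two phantom
#' movements. Negative values indicate non-biomimetic behaviour (the
#' nominal agonist's afferent increased).
#'
#' @param estimates A `bg_afferents` table from [estimate_afferents()], or
#'   any data frame with `movement`, `role`, `steady_mean`.
#' @return Scalar statistic, Imp/s.
#' @export
agonist_antagonist_afferent <- function(estimates) {
  need <- c("movement", "role", "steady_mean")
  if (!all(need %in% names(estimates))) {
    stop("estimates must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  per_mv <- vapply(c("df", "pf"), function(mv) {
    d <- estimates[estimates$movement == mv, ]
    ant <- d$steady_mean[d$role == "antagonist_lengthening"]
    ago <- d$steady_mean[d$role == "agonist_shortening"]
    if (!length(ant) || !length(ago)) {
      stop("movement `", mv, "` is missing an agonist or antagonist role",
           call. = FALSE)
    }
    mean(ant) - mean(ago)
  }, numeric(1))
  mean(per_mv)
}
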