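---
title: "Methods: EMG-driven impedance control and gait biomechanics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: EMG-driven impedance control and gait biomechanics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bionicgait)
```

This vignette documents the models implemented in `bionicgait`, the
assumptions behind them, and the parameter defaults. The package simulates
and analyses continuous neural control of a powered ankle prosthesis driven
by residual-muscle electromyography (EMG), in subjects whose residual
tibialis anterior (TA, dorsiflexor) and lateral gastrocnemius (GAS, plantar
flexor) remain mechanically coupled — an agonist–antagonist configuration in
which contracting one muscle stretches the other and regenerates
proprioceptive (muscle spindle) signaling.

## 1. EMG envelope extraction

Raw surface EMG is processed in five stages by `emg_envelope()`:

1. **Band-pass filtering** (`design_bandpass()`, `apply_fir()`). A linear-
   phase FIR filter designed by the Parks–McClellan equiripple method:
   stop-bands 0–60 Hz (motion artifact, mains hum) and above 360 Hz,
   pass-band 90–330 Hz, order 198 at the nominal 2 kHz sampling rate, with
   the stop-bands weighted 8:1 against the pass-band. The achieved response
   is verified at design time (at most −60 dB at 45 and 400 Hz, within 3 dB
   of unity across 110–310 Hz) and the design errors if it misses either
   check. Application compensates the constant group delay, so filtering is
   zero-phase.
2. **Rectification** (absolute value).
3. **Cumulative histogram filtering** (`cumulative_histogram_filter()`): each
   sample is replaced by its strict rank within a trailing window (default
   5 s, 128 amplitude bins) — the fraction of recent samples strictly below
   it. This adapts the gain to slow drifts in electrode contact. It is a
   *rank* transform: absolute amplitude within a stationary window is
   deliberately discarded, so downstream normalization operates on occupancy
   statistics, not volts. Consequences for testing are discussed in §8.
4. **RMS smoothing** (`rms_envelope()`, 200 ms moving window, reflect-padded
   at the edges).
5. **Min–max normalization** (`normalize_envelope()`) to a calibration range;
   by default the range observed after the rank filter's warm-up period.

`muscle_activation()` then applies bilinear activation dynamics: activation
tracks the envelope with a 10 ms time constant when rising and 40 ms when
falling, reflecting calcium kinetics of activation versus deactivation.

## 2. Neural decoding

`calibrate_decoder()` solves a 2×2 linear system so that plateau-mean
activations from a maximal phantom dorsiflexion trial map to the prosthesis
dorsiflexion limit (+10°) and maximal plantar flexion to −20°. Plateaus are
samples at ≥ 90 % of the trial's maximum agonist activation, held for at
least 0.5 s. Indistinct DF/PF patterns (singular system) abort calibration
with diagnostics rather than emitting unstable weights.

Per sample, `decode_intent()` computes:

* the **equilibrium angle** θ_ref = w_ta·a_ta − w_gas·a_gas, clipped to the
  range of motion and smoothed by a critically damped second-order 6 Hz
  low-pass (no overshoot to steps; gain 1/2 at the cut-off);
* the **impedance level** μ_Z = clip((w_ta·a_ta + w_gas·a_gas)/μ_norm, 0, 1),
  with direction-specific normalizers so the calibration trials themselves
  reach μ_Z = 1;
* the normalizer **direction** from the sign of the angle error δ = θ_ref −
  angle, with a 0.5° hysteresis band to prevent chattering near δ = 0.

## 3. Impedance control

`command_torque()` composes, in Nm:

| component | law | default parameters |
|---|---|---|
| active | sign(δ) · μ_Z · (|δ|/30°) · τ_iso · fl(angle) · fv(velocity) | τ_iso 45 Nm DF / 180 Nm PF |
| force–length fl | Gaussian over angle | optimum 0° DF / 5° PF, width 30° / 35° |
| force–velocity fv | Hill curve, eccentric plateau | v_max 600°/s, shape 0.25, plateau 1.4 |
| passive | exponential outside the neutral zone [−12°, +5°] | scale 0.5 Nm, rate 0.5 /° |
| virtual spring | −0.45 Nm/° · (angle − θ_ref) | guarantees stability at zero activity |
| virtual damper | −0.02 Nm·s/° · velocity | |
| saturation | clip at ±162 Nm | device limit |

The |δ|/30° factor normalizes the angle error by the full range-of-motion
span, so maximal intent (μ_Z = 1 at maximal error) commands exactly the
biological bound. Non-finite inputs are a hard fault: the controller refuses
to emit NaN torque.

## 4. Ankle plant and closed-loop simulation

`step_dynamics()` integrates a single rotational inertia (0.05 kg·m²,
consistent with a ~2.4 kg ankle–foot device) by semi-implicit Euler at
1 kHz, with hard stops at the range-of-motion ends and a divergence guard.
`simulate_gait()` closes the loop: raw EMG → envelope → activation →
(θ_ref, μ_Z) → torque → plant, with ground contact replayed as a
mass-normalized dorsiflexing torque schedule over the stance phase.

## 5. Muscle-spindle afferents

`spindle_rate()` implements an additive type II (secondary ending) model:

rate = max(0, baseline + k_len·strain + k_vel·sign(ṡ)|ṡ|^p + k_act·EMG)

with defaults baseline 10 Imp/s, k_len 200 Imp/s per unit strain, k_vel 2,
p 0.5, k_act 10. Type II endings are predominantly length-sensitive, hence
the heavy strain weighting. The defaults are anchored so a biologically
intact full-range excursion (plateau strain 0.25) yields a steady antagonist
rate of 60 Imp/s. The **agonist–antagonist afferent statistic**
(`agonist_antagonist_afferent()`) is the antagonist-minus-agonist
steady-state rate (mean over the central 25–75 % of the movement cycle),
averaged over phantom dorsiflexion and plantar flexion: positive when the
antagonist stretches while the agonist shortens (coupled residual muscles),
near zero or negative without coupling.

## 6. Gait biomechanics

Trials are resampled per cycle onto a fixed 1001-point percent grid
(`normalize_cycle()`); cycles shorter than 0.2 s are rejected as spurious.
Metrics follow standard conventions:

* **events**: level/slope — heel strike, loading response, push-off, foot
  clearance from the stance plantar-flexion minimum and dorsiflexion
  maximum; stairs — weight acceptance, forward continuance (descent) or
  pull-up and foot clearance (ascent). Missing landmarks are flagged
  `absent`, never fabricated.
* **peak power**: signed extremum (negative peak for stair descent).
* **net work**: trapezoidal time-integral of mass-normalized power over a
  percent window (weight-acceptance window 0–35 % for stair descent,
  pull-up window 30–60 % for ascent).
* **torque–angle loop** (`torque_angle_loop()`): shoelace area with the
  angle in radians; the energy-generating traversal is labelled `ccw` and
  its area equals the net work.
* **kinematic symmetry** (`lek_symmetry()`): 100 − mean symmetry index over
  ankle, knee and hip, where each joint's index is the cycle-integrated
  absolute inter-limb difference normalized by the mean absolute excursion.

## 7. Synthetic data

Because participant data are restricted, every measured input is emulated
(`generate_emg()`, `generate_phantom_cycles()`, `generate_gait_trial()`,
`generate_cohort()`) from archetype specifications (`archetype_spec()`):
cohort label (AMI: surgically coupled residual muscles; CTL: standard
amputation), target afferent level, and a gait-biomimeticness parameter
b ∈ [0, 1] that defaults to clip(afferent/12, 0, 1).

* Phantom fascicle strains are anti-phase smoothstep plateaus whose coupling
  amplitude is solved by root-finding so the downstream afferent statistic
  equals the archetype's target; CTL archetypes get small couplings, high
  cycle-to-cycle variance, and EMG co-activation.
* Gait waveforms are sums of Gaussian bumps on the percent-cycle axis: a
  stiff-ankle base component plus b-scaled biomimetic features (loading
  response, mid-stance dorsiflexion, push-off, foot clearance). Torque is
  (1−b) times a damping law along the base trajectory plus b times a
  biological push-off torque template. This construction makes net work
  continuous and monotone in b, with b = 1 an energy-injecting
  counterclockwise work loop and b = 0 a dissipative clockwise one.
* Cohort tables embody configured linear afferent–function relations with
  Gaussian noise — ground truth for parameter-recovery tests of the
  statistics (slope-interval coverage, type-I error of the normality-gated
  comparison).

## 8. Testing a rank transform, and other limitations

The cumulative histogram filter destroys absolute amplitude: a constant
signal of any level maps to rank 0. Round-trip tests therefore use cyclic
activation profiles (period ≪ window) so the trailing window's amplitude
mixture is stationary and plateau ranks are reproducible; tolerance on the
recovered envelope is ±0.05 away from filter edge transients.

Other limitations, by design:

* The plant is a single inertia without foot–ground contact geometry; ground
  reaction is replayed as a phase-scheduled torque, not computed from
  contact mechanics.
* Waveform families are statistical emulations of typical prosthetic gait,
  not a validated forward-dynamics model; they are intended as test
  substrates with controllable ground truth.
* The spindle model is algebraic (no fusimotor dynamics, no history
  dependence).
* Muscle curve parameters are literature-informed defaults, all
  configurable through `bio_torque_model()` and `spindle_params()`.

Typical problem sizes: trials of 2–10 gait cycles at 1 kHz (10³–10⁴
samples), EMG at 2 kHz, cohorts of 7 + 7 subjects; everything runs in
seconds on one CPU.

## 9. Worked example

```{r, eval = FALSE}
library(bionicgait)

# synthetic subject with strong afferent signaling
spec <- archetype_spec("AMI", afferent_level = 10.5, seed = 1)

# afferents from phantom movements
ph <- generate_phantom_cycles(spec)
agonist_antagonist_afferent(estimate_afferents(ph$fascicle))

# gait metrics for maximal-speed level walking
cycle <- normalize_cycle(generate_gait_trial(spec, "level_max"))[[1]]
torque_angle_loop(cycle)
net_work(cycle)

# cohort statistics
cohort <- generate_cohort(seed = 1)
pearson_with_ci(cohort, afferent, peak_power)
pca_composite(cohort[, c("group", "peak_power", "net_work", "speed",
                         "lek_symmetry")])
```
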