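---
title: "Methods: anticipatory torque analysis for precision-grip lifting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: anticipatory torque analysis for precision-grip lifting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prehension)
```

## The problem and the model

A participant lifts a visually symmetric T-shaped object whose centre of
mass (CoM) is concealed to one side. The object (mass 936 g, grip width
`d` = 82 mm, grip-surface depth 8 mm) carries an external torque of
250 N mm about the frontal-plane roll axis. Lifting it without tilt
requires an anticipatory *compensatory torque* at lift onset,

$$M_{Com} = LF_{diff}\cdot d/2 + GF_{mean}\cdot COP_{diff},$$

where the digits can realise the torque through asymmetric lift-force
sharing (`LF_diff`), asymmetric digit placement (`COP_diff`), or both. The
centre of pressure of each digit is estimated from its transducer's
frontal-plane torque as `COP = (Tx − LF·t)/GF` with surface depth `t`; this
is undefined when `GF ≤ 0`, which the code treats as an error rather than
propagating infinities. The decomposition identity
`M_Com = LF_diff·d/2 + GF_mean·COP_diff` is exact by construction and is
asserted to machine precision in the tests.

Sessions alternate the CoM side in runs. The trials immediately after a
side switch carry the interference signature: the longer the preceding
run, the more strongly the now-obsolete plan intrudes, depressing the first
post-switch `M_Com`.

## Trial schedules

`build_schedule()` expands a design into an ordered trial plan. Five runs
of each length (1, 3, 5) precede a switch; post-switch runs have equal
length (*matched* design, 91 trials: 45 pre + 46 post) or a single trial
(*unmatched*, 60 trials: 45 + 15). Two details of the expansion were
genuinely open and are package decisions:

- **The 46th post-switch trial.** The matched totals (45 + 46) exceed the
  15 symmetric run pairs by one trial. We prepend a session-initial lift on
  the starting side and label it post-switch with no preceding run
  (`run_length = NA`). It is the only labelling that reproduces the printed
  totals; the trial is excluded from all repetition analyses.
- **Run-length order** within a session is shuffled per subject under the
  schedule seed, with each length constrained to appear exactly `n_sets`
  times. A fixed order would confound run length with session time.
- After a switch the next pre-switch run continues on the side the switch
  established; pre-run sides therefore alternate through the session.

## The synthetic-data generator

No raw recordings are distributed for this paradigm, so `simulate_trial()`
synthesises physically consistent recordings that make every downstream
stage testable. Channel profiles are smooth logistic segments (analytic,
hence effectively band-limited well below the 5 Hz filter cutoff, so
scripted event times survive filtering to sub-sample accuracy):

- grip force rises logistically (time constant 80 ms) after grasp contact
  to a 16 N plateau per digit;
- net lift force ramps (time constant 60 ms) through the 0.2 N load-onset
  threshold and the object weight, overshoots by 15%, and settles exactly
  on the weight for the hold, so the hold-phase force implies the object
  mass;
- digit torques are synthesised as `Tx = COP·GF + LF·t` — the algebraic
  inverse of the COP estimator — which makes zero-noise metric recovery
  exact and the inverse problem well-posed;
- the object-height marker (150 Hz) rises to the 110 mm target after lift
  onset;
- Gaussian sensor noise is added per channel, then floor quantization at
  the transducer resolutions (0.03 N, 0.015 N, 0.375 N mm), mimicking
  least-significant-bit truncation. Setting resolutions and noise SDs to 0
  (`sensor_spec_ideal()`) disables both.

**Interference model.** Each trial has a planned torque magnitude: the
practised baseline `baseline_mcom_gain × 250 N mm` on pre-switch trials
(default gain 0.9 — trained subjects undershoot slightly); on the first
post-switch trial the magnitude drops by `interference_slope_nmm`
(default 15 N mm) per pre-switch repetition, recovering geometrically
(×0.5 per position) over later post-switch trials; the session-initial
novel lift is planned at 60% of baseline. Trial-to-trial noise
(SD 40 N mm) and a subject offset (SD 25 N mm) are added. `memory_split`
(default 0.6) partitions the planned torque between digit placement and
lift-force sharing. These magnitudes are free parameters of the generator:
the paradigm's group means are published only graphically, so the defaults
were chosen once as plausible for trained adults and are not calibrated to
any printed value.

**Sign convention.** Planned torque sign is fixed per subject by starting
side (left-start positive). This makes the mirror property exact — a
right-start subject simulated with the same seed is the algebraic negation
of its left-start twin — and makes the standard analysis rule (multiply
right-start subjects' `M_Com`, `LF_diff`, `COP_diff` by −1, once) restore
identical cohorts, which the tests verify.

The generator does **not** emulate reach trajectories, slips, failed
lifts, fatigue, or learning curves within pre-switch runs; passing tests
therefore demonstrate correctness of the measurement pipeline and
calibration of the statistics under this stochastic model, not robustness
to every artefact of real recordings (`run_pipeline()` does, however, drop
and log trials whose event detection fails, the expected failure mode of
real data).

## Signal processing

Forces and kinematics are filtered with a fourth-order low-pass Butterworth
at 5 Hz. Application is forward–backward (`zero_phase = TRUE` default) so
event times are not lag-shifted; this doubles the effective attenuation
order. Because naive forward–backward application has large zero-state
edge transients, each pass starts from the filter's steady state for an
input held at the first sample, with odd-reflection padding — the standard
edge handling of mature filtfilt implementations. Derivatives are central
differences (one-sided at the endpoints). The 150 Hz marker channel is
linearly interpolated onto the 500 Hz force clock (its grid does not
subdivide the 2 ms force grid), clamping outside the kinematic range.
Whether kinematics should be filtered at all was unstated in the source
paradigm; the pipeline filters both.

## Event detection

- *Reaction time*: go beep to home-button release (timestamps).
- *Grasp contact*: first sample with **both** digits above 0.2 N — a grasp
  requires opposition; the alternative single-digit and summed readings of
  the threshold are strictly earlier and would admit one-finger touches.
- *Load onset*: earliest sample exceeding 0.2 N net lift force followed by
  20 strictly increasing samples on the filtered channel ("consistent
  increase" is well-defined on the smooth filtered signal; ties resolve to
  the earliest index).
- *Lift onset*: the net lift force reaching the object weight. The
  crossing is located by linear interpolation between the bracketing
  samples rather than rounded to the grid: at 500 Hz the channels still
  have appreciable slope at lift-off, and grid rounding alone contributes
  up to ~1 N mm of torque error. A kinematic alternative (marker height
  leaving rest) is available via `lift_from = "marker"` but is coarser at
  150 Hz.

Lift-onset metrics are instantaneous values of the filtered channels
linearly interpolated at the detected (sub-sample) onset time.

## Grip–lift coupling

`r(τ) = cor(GF_rate(t+τ), LF_rate(t))` on a 2.5 ms lag grid from −100 to
+100 ms (81 lags). The printed 2.5 ms step does not align with the 2 ms
sample period, so both rate channels are linearly interpolated onto the
lag grid. The data window is the load phase (load onset to lift onset) —
the source specifies the *lag* range, not the data window, and the load
phase is where both rates are active. The peak is the maximum *signed*
correlation. Lag sign convention: positive lag means the grip-force rate
is delayed relative to the lift-force rate; a copy delayed by 10 ms peaks
at +10 ms, which the tests verify by exhaustive scan.

## Statistics

Repetition enters as a two-level within factor (1 vs 3, and separately
1 vs 5), matching the paired framing of the paradigm and reproducing its
degrees of freedom: two cohorts of 20 and 30 subjects give a within-effect
df of (1, 48). Familiarity (matched vs unmatched) is the between factor.
The ANOVA is fitted with `stats::aov` and an `Error(subject/within)`
stratum; the between effect is tested against the between-subject
residual, the within effect and interaction against the subject × within
residual. With two within levels sphericity corrections are moot and none
are applied. Partial eta squared uses each effect's own error term;
`partial_eta_squared_from_f()` is the algebraically identical F-based
form. Pairwise contrasts are paired t tests against run length 1 with
Bonferroni scaling (`min(1, m·p)`). Subjects missing a within level are
excluded with a warning; outcomes are subject cell means over the five
first-post-switch trials per run length (trial-level modelling is a
possible alternative; averaging is the convention adopted).

## Calibration studies

Two Monte-Carlo suites validate the inference chain end to end, using the
generator's planned-metrics fast path (`time_series = FALSE` plus
`truth_metrics()`): the same schedules and stochastic model without
waveform synthesis, whose fidelity the zero-noise pipeline-recovery tests
establish separately. With no planted effect the repetition test rejects
at 5% ± 2% over 1,000 simulated two-cohort experiments (8 + 8 subjects —
the null rejection rate of the exact F test does not depend on cohort
size); rejection rates rise monotonically across interference slopes
0–12 N mm/trial, and a planted 25 N mm/trial effect is detected by both
Bonferroni contrasts in ≥ 90% of 200 cohorts of 10 + 10.

## Numerical choices and degenerate inputs

- All randomness derives from integer seeds; per-subject and per-trial
  seeds are fixed affine hashes of the master seed modulo 2³¹ − 1, so any
  subset of a cohort reproduces independently.
- Quantization is floor-to-resolution after noise injection; grip force is
  clamped at zero first (transducers report non-negative normal force).
- A degenerate ANOVA stratum (all values equal) reports F = 0, p = 1
  rather than 0/0.
- Zero-variance coupling channels, thresholds never crossed, negative
  reaction times, `GF = 0` with nonzero lift force, and sub-minimum-length
  filter inputs all raise typed errors naming the offending quantity.

## Known limitations

- Event-time round-trips are guaranteed to one force sample (2 ms) only
  for the smooth synthetic profiles; real recordings with sharper
  transients will show larger filter-induced shifts.
- The reach component is simulated as timestamps only; no spatial
  trajectory model.
- The generator's interference effect sizes are assumptions, not fits to
  published group means; analyses of real cohorts should treat the
  simulated power figures as illustrative.
- Yaw torques are ignored (the apparatus geometry makes them negligible),
  and release/replace phases are not analysed.
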