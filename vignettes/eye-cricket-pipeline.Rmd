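---
title: "Methods: stimulus model, synthetic oculomotor data, and the analysis pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stimulus model, synthetic oculomotor data, and the analysis pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gazepred)
```

This vignette documents the models, parameter choices and numerical
decisions behind `gazepred`, in the spirit of a methods section: what is
assumed, what is tunable, and what the tests do and do not establish.

## 1. The kinematic stimulus model

All positions live on a one-dimensional signed axis in degrees of visual
angle, cross at the origin, positive toward the target's start side.
Degrees and seconds are canonical; screen millimetres are only a *view*
through the exact tangent conversion `deg_to_mm()` at a 1.2 m viewing
distance. The reason for making degrees canonical is that the published
millimetre figures for this kind of setup are typically rounded small-angle
approximations (at 1.2 m one degree subtends ≈ 20.9 mm, so "20 mm = 2°"
style statements cannot all be exact simultaneously); the degree values are
the quantities every analysis threshold is defined in.

A trial is a piecewise-constant-velocity trajectory: stationary at 14°
until `motion_onset` (1 s), 4°/s for 1 s to 10° eccentricity at
`change_onset`, then the condition speed *v* until (and past) TTC =
`change_onset` + 10/*v*. Occlusion at `change_onset + occlusion` switches
visibility off but not motion. TTC is defined as centre-on-centre
coincidence: a 4°-wide circle "completely overlapping" a 4°-wide cross
aligns the centres. Under these definitions the per-condition table

```{r}
stimulus_table()
```

is an analytic identity: eccentricity at occlusion `10 − v·t_occ`,
remaining time `(10 − v·t_occ)/v`, monitoring time `max(0, t_occ − 0.3)`.
The conservation identity `v·(time to TTC) + v·t_occ = 10` holds for every
design and is enforced by property tests.

**Quasi-randomization.** Trial order is drawn by sequential sampling
proportional to remaining cell counts, disallowing a fourth consecutive
trial of the same speed, with restarts on dead ends (a plain shuffle of 240
trials violates the run-length bound almost surely). The procedure is the
simplest one that (i) satisfies the stated constraint, (ii) is a
deterministic function of the seed, and (iii) leaves the cell histogram
seed-invariant. Sides are balanced within each speed × occlusion cell.

## 2. The synthetic oculomotor generator

The generator exists because raw human gaze recordings for this paradigm
are not publicly available: it produces labelled data *of the kind* the
apparatus would produce, so the detection/scoring/statistics chain can be
validated by parameter recovery. Its defaults emulate the described rig
and cohort:

| parameter | default | rationale |
|---|---|---|
| `sample_rate` | 200 Hz | the 5 ms gaze-vector update of the rig; the camera's 220 Hz is selectable, but all analysis windows are specified in time, not samples |
| `pursuit_gain` | 0.95 | typical steady-state pursuit gain just below 1 |
| `pursuit_latency` | 0.15 s | classic pursuit onset latency |
| `detection_latency_mean/sd` | 0.30 / 0.05 s | saccadic/button response latency to the perturbation |
| `main_sequence_slope` | 30 (°/s)/° | peak velocity 30× amplitude; with the raised-cosine profile every saccade lasts 2/30 ≈ 67 ms |
| `fixation_noise_sd`, `pursuit_noise_sd` | 0.2°, 0.1° | slow AR(1) drift, correlation time `noise_tau` = 0.3 s, bounded by the tracker's stated ~0.5° accuracy |
| `measurement_noise_sd` | 0.02° | white per-sample tracker noise at the resolution scale |
| `miss_rate`, `false_alarm_rate` | 0.05 | perceptual errors producing incorrect trials |
| `invalid_trial_rate` | 0.3 | matches the reported ~70% valid-trial proportions (27/40, 22/30, 25/30) |
| `ttc_bias_gain`, `ttc_response_sd` | 1, 0.2 s | unbiased TTC press model with Gaussian timing noise |

Two modelling choices deserve emphasis:

* **Noise is slow, not white.** Oculomotor drift is modelled as a
  stationary AR(1) process; naive white positional noise of 0.1–0.2° at
  200 Hz would imply implausible >10°/s velocity noise and swamp the 22°/s
  detection threshold. The white component is kept at the tracker's
  resolution scale. Consequence: detection operates at a realistic
  signal-to-noise ratio, and false positives are rare by construction of
  the *noise model*, not of the detector.
* **Raised-cosine saccades.** The velocity profile
  `v(t) = Vp/2·(1 − cos(2πt/D))` is smooth, integrates exactly to the
  commanded amplitude, and is fully determined by the main-sequence slope.
  Its onset is gradual (zero velocity *and* acceleration at t = 0), which
  makes threshold-crossing detection *late* by a computable margin — see
  §5.

Invalid trials carry a slow linear gaze drift (peak 4.5–6°, random sign)
during the pursuit phase, so they violate the 3° criterion the way real
non-compliant trials do (drift, not blinks; blinks are not modelled). The
TTC press is `change_onset + 10/(v_perceived · ttc_bias_gain) + noise`;
gains above 1 press too early, below 1 too late. Optionally
(`speed_update_time > 0`) the perceived speed is blended toward the
pre-change 4°/s for responses initiated before the percept updates, which
couples early saccades to old-speed extrapolation: 3°/s trials are then
pressed too early (positive slope of relative TTC on RT) and 5°/s trials
too late (negative slope) — a qualitative, sign-only emulation of
saccadic-suppression accounts.

What the generator does **not** emulate: blinks, glissades, catch-up
saccade sequences, torsion, 2-D curved trajectories, or the actual human
effect sizes. Passing recovery tests therefore demonstrate that the
pipeline measures what the generator encodes — not that it would reproduce
any particular human dataset.

## 3. Event detection

`compute_velocity()` uses central differences and a second-order
Butterworth low-pass at 60 Hz applied forward–backward (zero-phase), with
odd-reflection padding to suppress edge transients. Zero-phase filtering
was chosen so detected event times are unbiased; a causal filter would
systematically delay onsets. The filter has unit DC gain, so constant
velocities pass unchanged (a 4°/s ramp is recovered to <1e-6).

`detect_saccades()` takes maximal runs of samples with 2-D speed above
22°/s, merges runs closer than 20 ms, then discards runs spanning less
than 10 ms. Merge-before-discard is deliberate: noise can split one
saccade into two supra-threshold runs, and discarding first could delete
half of a real event. The 10/20 ms values are not part of the reference
analysis; they are conservative de-noising defaults and configurable.
Velocity is the 2-D magnitude (the horizontal-only alternative is not
used); onset/offset are the first/last supra-threshold samples, and the
16 ms/70 ms pursuit-exclusion margins are anchored at the detected onset
and offset.

## 4. Trial scoring

Validity applies the 3° criterion strictly (`> 3°` invalidates) to the
phase-appropriate distance: gaze-to-circle from motion onset until the
response saccade or occlusion (whichever is first, i.e. while the visible
target is being tracked), and gaze-to-cross from saccade landing (plus a
70 ms settling allowance) until the TTC press in the saccade task. In the
pursuit task validity is enforced through occlusion only — the analogous
criterion after occlusion would punish correct extrapolation.

A *qualifying* saccade is initiated after change onset and lands within 3°
of the cross (reusing the pipeline's only spatial threshold, since no
separate landing criterion is standard). Correctness is the truth table:
perturbation ∧ qualifying saccade, or catch ∧ no qualifying saccade; a
cross-directed saccade initiated *before* the change onset marks the trial
incorrect (anticipation), since a response-time measure presupposes
post-change initiation. In the pursuit task the perturbation button press
substitutes for the saccade, symmetrically. TTC errors are scored on
correct trials only: signed `press − TTC` and the relative measure
`100·(press − change_onset)/(TTC − change_onset)` (0% at change onset,
100% at the true TTC), which is affine in press time and origin-invariant.

Participants with fewer than 10 valid trials in any speed × occlusion cell
are excluded before the statistics. Applied literally, this rule is
incompatible with 10-trial catch cells at any realistic invalid-trial
rate; cohort-level demonstrations therefore use the first experiment's
design (40-trial cells), where the rule behaves as intended. The threshold
is a parameter (`min_valid`) for users who want the laxer variant.

## 5. Statistics

`rm_anova()` computes the within-subject decomposition on participant ×
cell means: each effect is tested against its participant-by-effect
interaction. Greenhouse–Geisser ε is estimated per effect from the
covariance of the orthonormalized condition contrasts,
`ε = tr(M)²/(k·tr(M²))` with `M = C'SC`; corrected dfs are `ε·df`. The
correction is applied by default to *every* effect (`correction = "GG"`),
the conservative reading of "applied when sphericity is violated" — a
2-level factor has ε = 1 identically, so nothing changes where sphericity
cannot fail. Effect sizes are partial η² = SS/(SS + SS_error). The
implementation is cross-checked in the tests against `stats::aov` error
strata and the paired-t equivalence (F = t² at 2 levels, to 1e-10), and
its null behaviour against a 1000-replicate type-I simulation (iid cells,
uncorrected p, α = 0.05 within the binomial interval).

Post-hoc contrasts are paired t tests with Holm adjustment by default
(`stats::p.adjust`); Bonferroni is available because both conventions
coexist in practice. The exploratory `rt_ttc_regression()` fits OLS of
relative TTC on response time per speed condition on valid correct trials.

## 6. Numerical choices and degenerate inputs

* Geometry that puts occlusion at or past contact (`10 − v·t_occ ≤ 0`) is
  rejected, as are non-positive speeds/delays, with messages naming the
  field.
* Sampling must be uniform to 1e-6 relative tolerance; velocity needs ≥ 5
  samples; a sample rate too low to put two samples inside a saccade is
  rejected.
* The design shuffler retries up to `max_tries` (200) before declaring a
  custom cell configuration infeasible.
* All simulation entry points take a seed and restore the caller's RNG
  state; equal seeds are bit-identical.

## 7. Known limitations

* **Threshold-crossing RT bias.** The fixed-threshold onset definition is
  structurally late for smooth profiles: a raised-cosine saccade of ~9°
  crosses 22°/s about 6 ms after true onset, and taking the first
  supra-threshold *sample* at 200 Hz adds on average half a sample
  (2.5 ms). Pipeline saccadic RTs therefore overestimate the generating
  detection latency by roughly 6–9 ms. This is within the pipeline's
  ±10 ms onset-accuracy budget but is visible in cohort means, whose
  standard errors are far smaller; recovery of the latency *mean* to
  within sampling error alone should not be expected from this estimator.
* Only horizontal target motion is modelled; vertical gaze carries noise
  but no signal.
* The generator's behavioural parameters are plausible-by-literature, not
  fitted to any dataset; all human effect sizes are out of reach by
  design, and generator-driven tests assert signs and orderings only.
* Problem sizes in the tests and the acceptance script — 200-trial
  detection batches, one 12 × 240 cohort, 1000 small-table null
  replicates — were chosen as the smallest sizes at which the stochastic
  assertions are stable.
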