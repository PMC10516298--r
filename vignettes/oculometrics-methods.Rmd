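---
title: "Methods: from 60 Hz gaze traces to clinical associations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from 60 Hz gaze traces to clinical associations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oculometrics)
```

## The problem

Eye movements are controlled by a widely distributed cortical–subcortical
network, and their kinematics degrade measurably in multiple sclerosis:
fixation becomes unstable, pro-saccades slow down and start later,
anti-saccade errors become more frequent, and smooth-pursuit gain drops.
Tablet-based eye tracking makes these measurements cheap enough for
routine use, but at a price: ~60 Hz sampling and roughly half a degree of
accuracy, far from research-grade infrared trackers. `oculometrics`
implements a complete analysis chain for such data — a four-task battery
(fixation, pro-saccade, anti-saccade, step–ramp pursuit) reduced to a
canonical set of twenty oculomotor parameters per participant, related
to clinical status (EDSS, SDMT and the BICAMS/MSFC composites) by a
Spearman/Benjamini–Hochberg screen, a high/low-EDSS contrast and partial
least squares regression with feature selection.

Because no patient recordings ship with the package, a synthetic cohort
generator with *planted ground truth* is a first-class component: every
downstream stage is validated by round-tripping known parameters through
the full pipeline.

## The synthetic cohort

A latent severity variable $s \sim \mathcal N(0,1)$ drives everything.
Clinical scores are monotone functions of $s$ plus noise, with marginals
matched to a typical MS cohort (EDSS mean 3.5 and SD 2, quantized to 0.5
steps and clipped to $[0,10]$; SDMT mean ~50; log-normal timed tests with
heavy right tails). The planted oculomotor truth moves with $s$ in the
directions the clinical literature reports: higher severity means longer
latencies, lower saturation peak velocity, larger fixation scatter, more
intrusions, more anti-saccade errors and lower pursuit gain. Effect maps
are plain lists (`default_effect_map()`, `default_clinical_map()`), so a
study with different couplings is a configuration change, not a code
change.

Gaze traces are rendered additively:

* **Saccades** follow a logistic position ramp
  $s(t) = A\,\sigma(k(t - t_m))$ whose peak velocity $Ak/4$ is pinned to
  the main sequence $V_p = \eta\,(1 - e^{-A/c})$ (defaults
  $\eta = 500$ deg/s, $c = 6$ deg). The generator and the downstream fit
  share this family, which makes parameter recovery exactly
  identifiable. Logged onsets/offsets bracket the 1–99% traversal.
* **Fixational drift** is an Ornstein–Uhlenbeck process with the planted
  stationary covariance $(\sigma_x, \sigma_y, \rho)$ and a correlation
  time of 1 s. The correlation time matters: i.i.d. scatter at 60 Hz
  would be white noise with enormous sample-to-sample velocity, and a
  sub-second correlation time still implies drift speeds of ~6 deg/s,
  several times faster than physiological drift. At 1 s the typical
  drift speed is 2–3 deg/s.
* **Intrusions** are square-wave-jerk pairs (outgoing saccade, 200 ms
  plateau, return saccade), the canonical MS-relevant intrusion
  morphology; the planted rate counts individual saccades, so pairs are
  generated at half that rate.
* **Pursuit** runs at the planted gain; a catch-up saccade fires
  whenever the positional error reaches the planted threshold (2 deg by
  default) and lands the eye the planted lag behind the target. The
  realized catch-up rate is therefore emergent, not a dial.
* **Sensor noise** is white Gaussian per axis. The parameter is the
  device precision convention — RMS sample-to-sample distance — with
  default 0.33 deg; the implied per-axis SD is 0.33/2. An optional
  constant bias models the 0.47 deg accuracy figure. Blinks are
  Poisson-timed 100–300 ms invalid runs.

What the simulator does **not** emulate: pupil signals, head motion,
calibration drift, anticipatory or express saccades, saccadic curvature,
asymmetric up/down pursuit, and any non-stationarity over a session.
Green round-trip tests therefore certify the *extraction pipeline*, not
the realism of any specific patient population.

## Preprocessing

Invalid runs no longer than 75 ms (a dropped frame or two) are linearly
interpolated and flagged; longer runs (blinks) are masked together with
a 50 ms guard margin. The sensor's `valid` flag is never overwritten —
the analysis mask lives in a separate `usable` column, which makes
artifact removal idempotent.

Velocity comes from a local-quadratic (Savitzky–Golay-style) fit over a
5-sample window, computed on the actual timestamps so irregular spacing
is handled exactly; the filter is exact on linear ramps and quadratics.
At 60 Hz this filter *cannot* report true peak velocities: a 10-degree
saccade lasts ~57 ms, about 3.4 samples, and the window's response to
the noiseless waveform peaks at roughly 40% of the analytic 405.6 deg/s.
That attenuation is the reason the pipeline fits a parametric waveform
at all — the trace-level velocity drives detection, and the fit restores
the kinematics.

## Saccade detection

Detection is adaptive-threshold in velocity space. The noise scale is
estimated robustly (median absolute deviation of speed with the Gaussian
consistency factor, iterated once after excluding first-pass events) and
the peak threshold is $\lambda\hat\sigma$ with $\lambda = 5$. A
candidate must exceed the peak threshold, is extended down to the
hysteresis (onset) threshold at $\lambda\hat\sigma/2$, must hold at
least 2 samples there (17 ms), is merged with neighbours closer than
33 ms, and must displace the eye by at least 0.5 deg.

The dual-threshold design is forced by the sampling rate. With
precision 0.33 deg RMS-S2S the per-axis velocity noise after the
5-sample filter is ~3.1 deg/s, while the filtered peak response of a
1-degree saccade is ~18 deg/s — about 5.7 noise SDs. A single threshold
high enough to keep false alarms below 0.1/s sits where second-sample
coverage of 1-degree saccades becomes unreliable; requiring the peak
only at the high threshold and the duration at the low one keeps both
sensitivity (≥0.95 at ≥1 deg) and the false-alarm budget. Sub-degree
events are deliberately out of scope: this class of tracker does not
capture microsaccades, and the 0.5 deg amplitude floor enforces that.

Detected onsets are hysteresis crossings and run ~2 samples early
(within the smoothing window); the event window is deliberately **not**
extended to the nearest local speed minimum, because at 60 Hz that walk
absorbs drift wander into the event and biases onsets by tens of
milliseconds. Latency-grade onsets come from the waveform fit.

## Waveform fitting

Each event is refit by bounded least squares
(Levenberg–Marquardt) of the position projected on the principal
displacement axis to $s_0 + A\,\sigma(k(t - t_m))$, with 3 samples of
context on each side. The refined onset is the ramp's 1% point; on
simulated saccades its median error is below a millisecond. The fit
reports $V_p = Ak/4$; because a single saccade constrains only $V_p$,
not $\eta$ and $c$ separately (they enter the template only through
$V_p$), the event carries $c$ at its configured default (6 deg) and
$\eta$ back-solved so that $V_p = \eta(1 - e^{-A/c})$ holds exactly —
estimating $\eta$ and $c$ jointly is meaningful only across many
saccades (`plot_main_sequence()`). Fits with RMSE above 0.75 deg fall
back to non-parametric estimates and stay flagged unfitted.

## The twenty parameters

* **Fixation (3)** — BCEA95 under a bivariate-Gaussian model,
  $2\pi(-\ln 0.05)\,\sigma_x\sigma_y\sqrt{1-\rho^2}$, from
  intrusion-free samples (the first second of each 7 s trial is skipped
  as the refixation transient; trials with <1 s of usable data are
  excluded); intrusion rate (detected saccades ≥0.5 deg per analysed
  second, both saccades of a square-wave pair counting separately); and
  pooled intrusion amplitude.
* **Pro-saccade (4 × 2 eccentricity classes)** — latency of the primary
  (first ≥1 deg) saccade inside an 80–800 ms acceptance window,
  time-to-target (first entry into a 2 deg radius held 100 ms — half the
  short-eccentricity spacing), fitted peak velocity, and amplitude gain
  (amplitude over target eccentricity, vertical targets using their 6/12
  deg eccentricities).
* **Anti-saccade (5, plus an optional 21st)** — the first ≥1 deg
  horizontal saccade in the window classifies the trial (toward the cue:
  error; away: correct; no qualifying saccade: invalid); error rate over
  non-invalid trials; correction rate over errors; per-class latencies;
  time-to-correct (onset-to-onset); and time-to-target (cue onset to the
  end of the final saccade landing in the correct hemifield), carried as
  an optional extra column because it behaves like a headline parameter
  even though it falls outside the canonical twenty.
* **Pursuit (4)** — after desaccading (excising detected events with a
  one-sample pad), velocity gain is the mean along-target velocity over
  target speed; the averaging window starts at a sustained movement
  onset (five consecutive samples above a quarter of target speed — a
  single supra-threshold sample is routinely produced by noise) and
  trims the filter half-window at both ends, where the smoothed velocity
  blends into the stationary epochs; lag is the mean gaze–target
  distance; proportion of time in pursuit is pursuit time over pursuit
  plus saccade time; catch-up saccades are co-directional detected
  events summed over the four trials.

Missingness is structural and explicit: a participant with no error
trials has no correction rate, and every profile has exactly the
canonical columns.

## Clinical composites and associations

BICAMS is the mean of cohort-internal z-scores of SDMT, RAVLT and
BVMT-R; the modified MSFC averages z(SDMT), z(−T25FW) and z(1/9HPT) so
that higher is always better. z-scores use the sample-SD convention
(n−1); external norm tables can be supplied. Zero-variance components
are an error naming the component.

The association screen computes Spearman's ρ (average ranks) on
pairwise-complete observations — parameter missingness is structural, so
listwise deletion would discard good pairs — with exact permutation
p-values below ten pairs and the t-approximation otherwise.
Benjamini–Hochberg control is applied within each outcome's family of
parameters (the more conservative global option is available); the
choice is recorded in the result's metadata. The EDSS contrast z-scores
each parameter against the whole cohort, splits at EDSS ≤ 4 versus
≥ 4.5, and uses two-sided Mann–Whitney tests (exact below 20 per group
when untied).

## PLS regression and feature selection

`fit_pls()` is PLS1 by NIPALS with internally standardized predictors;
with as many components as full-rank predictors it reproduces ordinary
least squares to machine precision, which the tests assert against
`lm()` and against an independent PLS implementation. The component
count minimizes 5-fold cross-validated MSE with seeded fold shuffling
and ties broken toward fewer components. Note that with correlated
sample columns the CV-MSE minimizer is usually larger than the number of
planted directions even in noise-free data — the first NIPALS direction
absorbs sample cross-covariances — so the selector is specified as the
minimizer, not as a dimension estimator.

Feature selection searches subsets of the twenty(+1) parameters with age
appended to every candidate model, complete cases scoped per subset (a
gap in an unused parameter never costs a participant), and in-sample R²
as the selection metric; adjusted R² and the selected subset's CV-R² are
reported alongside. A fully exhaustive search over 21 candidates is
~2×10⁶ subsets times cross-validation and is not a desk-scale
computation, so the default pipeline caps the subset size at 8 and
offers greedy forward search; any non-exhaustive search is flagged in
the result and in the run metadata. Standardized coefficients are
$b_j\,\mathrm{sd}(x_j)/\mathrm{sd}(y)$ and contribution weights are
their normalized absolute values.

## Numerical and scale choices

Degenerate inputs have defined behaviour: all-invalid recordings,
all-invalid trials, empty subgroups and zero-variance columns raise
named errors or produce flagged/missing results rather than silent
numbers. All randomness flows from explicit seeds through
`withr::with_seed()`, and identical configurations reproduce outputs
byte for byte.

Test problem sizes were chosen to make the checks statistically sharp at
desk scale: 100 fixation trials for detector operating characteristics,
a 60-participant cohort for end-to-end recovery (tolerances fixed in
advance: 10 ms mean latency, 0.05 gain, 10% peak velocity, 0.05 pursuit
gain, 0.1/s intrusion rate, 0.05 error rate), 1000 random p-vectors
against a brute-force step-up oracle, 100 seeded replicates of planted
3-of-12 feature recovery, and 200 null replicates for the
false-discovery calibration.

## Limitations

The simulator is the package's own model of the data; agreement with it
bounds implementation error, not device or population error. Parameters
whose planted value does not map one-to-one onto the trace (pursuit lag
away from catch-ups, intrusion amplitude under detector truncation,
BCEA under slow drift within finite trials) are recovered with known,
documented biases rather than exactly. The PLS stage produces inference
models; nothing here validates out-of-sample clinical prediction, and
the in-sample R² of a selected model is optimistic by construction —
compare it with the reported CV-R².
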