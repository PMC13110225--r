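---
title: "Methods: event-locked multimodal neuromonitoring analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: event-locked multimodal neuromonitoring analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

After aneurysmal subarachnoid hemorrhage (SAH), a subset of patients with
delayed cerebral ischemia (DCI) progress to irreversible infarction.
Invasive multimodal neuromonitoring — intracranial pressure (ICP), mean
arterial pressure (MAP), brain tissue oxygen tension (PtiO2), cerebral
microdialysis (lactate, pyruvate, glutamate, glycerol), and the pressure
reactivity index (PRx) — produces continuous physiological data around
that transition. `dcimon` implements the full analysis chain for such
data, locked to the time of radiological infarct detection:

1. **signals** — PRx computation and hourly, event-aligned aggregation of
   all modalities;
2. **trends** — population trajectory estimation with penalized-spline
   GAMs, derivative-based trough/peak detection, and paired 24-hour
   window comparisons;
3. **features** — rolling-window feature engineering over a 73-hour
   peri-detection window;
4. **classify** — a patient-level stratified Random Forest with impurity
   importances and TreeSHAP attributions;
5. **synth** — a calibrated synthetic cohort generator so that every stage
   is testable, end to end, without patient data.

## Signal processing

**PRx.** The pressure reactivity index is the moving Pearson correlation
between 10-second averages of MAP and ICP over a 5-minute sliding window
(30 grid slots) advancing by 60 s, i.e. 80% window overlap. A window
yields a value only when at least 15 slots (50%) hold a complete MAP/ICP
pair *and* both windowed variances are positive. Degenerate (zero
variance) windows are emitted as gaps rather than zeros: a correlation is
undefined there, and imputing 0 would bias hourly means toward intact
autoregulation. The window kernel is implemented in C++ with a two-pass
(centred) sum so results agree with the textbook correlation formula to
machine precision.

**Artifact filtering.** Monitoring ranges are not part of any printed
protocol; we use conventional neuro-ICU plausibility bounds
(ICP −10 to 100 mmHg, MAP 20 to 250 mmHg, PtiO2 0 to 150 mmHg),
overridable per call. Removed samples become gaps, never sentinels.

**Hourly table.** All modalities are summarised into half-open hourly
bins `[h, h+1)`. Signals (MAP, ICP, PtiO2, PRx) use the mean; skewed
microdialysis analytes and the lactate/pyruvate ratio (LPR) use the
median. In practice microdialysis bins contain at most one bedside sample,
so the analyte statistic is moot; the choice matters only for
high-frequency channels. Event time is indexed so that `rel_hour` 0 is the
hour containing the detection instant. Control patients have no detection
event; three anchoring policies are provided — the median detection hour
of the infarction group (default, used by the classification stage),
180 h post ictus (noon of the eighth post-ictus day, the trajectory-era
convention), and an explicit per-patient anchor. The wording "12:00 am of
the eighth day" is ambiguous between midnight and noon; we implement the
day-8 anchor at 180 h and keep the policy switch so either convention can
be examined.

**Inclusion filter.** Multivariate analyses require ≥ 30% of the expected
hourly microdialysis bins (glutamate or glycerol, whichever is better
covered) within the 73-hour analysis window.

## Trajectory estimation (trends)

One population GAM is fitted per variable and group by pooling all
patients' hourly values — matching a single predicted curve per cohort —
with a thin-plate regression spline of event time, basis dimension 20 and
smoothing by (fast) REML. Residual autocorrelation is handled by a
two-step AR(1) correction: fit, estimate the lag-1 correlation from
consecutive-hour residual pairs within patients, refit with that AR(1)
working correlation (capped at |phi| ≤ 0.95; disabled when the estimate is
negligible). A continuous-time autoregressive structure is underdetermined
for unevenly observed hourly data, so the discrete lag-1 working
correlation is used instead.

Fits are evaluated on a 0.1-hour grid over the ten days around detection
(`rel_hour` in [−120, 120] intersected with the data support) — the
window the trajectory analysis examines. Derivatives are central finite
differences of the fitted mean on that grid: basis-agnostic, with error
bounded by the grid spacing, reported per hour and per day.

The **trough** is the lowest fitted value over the pre-detection interval,
and the **peak** the highest fitted value from the trough onward; exact
ties break toward the time closest to detection. Per-patient medians over
the 24-hour windows centred on the *cohort* trough and peak (cohort-level
centres, consistent with defining extrema on the population curve first)
feed a paired comparison; a patient contributes only when both windows
hold at least 6 hourly values. PtiO2 typically lacks a clear
post-detection peak, so its second window is the pooled five-day
post-detection interval `[0, 120)` h.

**Wilcoxon signed-rank test.** The paired comparison uses a signed-rank
test with an exact null: zeros dropped, midranks for ties, and for up to
25 non-zero pairs the exact distribution of the positive-rank sum over all
`2^n` sign assignments via generating-function convolution (doubled ranks
make midranks integral). Beyond that, a normal approximation with
continuity and tie corrections. The exact path is authored here because
the standard implementation falls back to the approximation whenever ties
or zeros occur; tests cross-check both the full-enumeration oracle and
`stats::wilcox.test` in the untied case.

## Feature engineering

Within the 73-hour analysis window (48 h before to 24 h after detection),
each of PtiO2, PRx, glutamate and glycerol contributes four features per
patient-hour: the instantaneous hourly value, rolling means over the
preceding 6 and 12 hours, and a 6-hour OLS slope — 16 features in all.

* "Preceding six hours" is implemented as the half-open window `(t−6, t]`
  *including* the current hour: excluding it would make "instantaneous"
  and "mean" disjoint summaries of recent history. A flag provides the
  exclusive reading.
* The slope is an OLS fit rather than an endpoint difference, so interior
  missingness does not destroy it.
* Coverage rules are not printed anywhere; we require 50% of the window's
  slots for means and 3 points for slopes, both overridable.
* Rolling windows may reach back before the analysis window (history is
  legitimate context) but never forward — anti-leakage is asserted by
  perturbing future values and checking invariance.

## Classification

Patients are split 80/20 at the patient level with stratification by
outcome; per class the test set gets `round(0.2 · class size)` patients,
which yields the 55/14 split for a 24/45 cohort. The forest uses 100
trees, balanced class weights, maximum depth 10, minimum 20 samples to
split, minimum 10 per leaf (ranger backend, single-threaded for
reproducibility). Metrics (AUC by the Mann–Whitney rank formulation with
ties counted one half, accuracy, sensitivity on the infarction class,
specificity on the control class at threshold 0.5) are observation-level,
with a patient-level mean-score view as a secondary report.

Missing features are imputed with per-feature medians computed on training
rows only. Surrogate splits — the CART device for traversing a tree when
the primary split variable is missing — are not available in common
Random-Forest implementations, including the backend used here; the
`missing_policy = "native"` option is reserved and rejected with an
explanatory error rather than silently approximated.

Feature importance is the mean decrease in impurity, normalized to sum to
one. Per-prediction attributions use path-dependent TreeSHAP implemented
in C++ over the extracted tree structures, with node covers obtained by
routing the training data through each tree. Local accuracy (base value
plus attributions equals the predicted probability) is exact and tested to
1e-6; brute-force Shapley values over feature subsets serve as the oracle
on small forests.

## The synthetic cohort generator

The generator emulates the study conditions: 24 infarction patients and 45
no-DCI controls; infarct detection at a median of 7.5 days post ictus
(IQR 5.8–11.0), modelled lognormal matched to those quantiles (only these
summaries are available); MAP/ICP/PtiO2 signals at 10-s resolution from
ictus to five days after detection; microdialysis every 3 h, escalating to
hourly while the concurrent PtiO2 hourly mean is below 20 mmHg or the
latest measured LPR exceeds 40; multiplicative lognormal assay/biology
noise (mean 1, CV 0.4) on analytes; AR(1) noise (sd 4 mmHg, phi 0.5) on
PtiO2; a 3-hour all-modality transport gap centred on detection; and 10%
record-level MCAR deletions.

Latent trajectories are anchored to the population extrema of the study
cohort: a glutamate surge peaking at 22.2 µmol/L around day +0.5 with
rise/fall slopes of 11.27/−10.15 µmol/L/day (asymmetric Gaussian, widths
derived from the slope of a Gaussian limb, `sigma = A/(slope·sqrt(e))`);
glycerol rising to 190.8 µmol/L at day +1 and staying elevated; PtiO2
declining to 15.7 mmHg a day before detection then rising; PRx moving from
a trough of −0.078 near day −3 to a peak of 0.215 near day +1.5; ICP
peaking near 25 mmHg. Values the study does not print (the glutamate
baseline 8 µmol/L, the glycerol pre-event plateau 75 µmol/L, the ICP
trough level) are physiologically plausible design constants, fixed here.
Monotone shape-preserving piecewise cubics (Fritsch–Carlson slopes, zero
derivative at extremum knots) interpolate way-point profiles so anchored
extrema are attained exactly without overshoot. The PRx profile follows
the per-patient-median trough/peak rather than the alternative printed
GAM peak of 0.267 — the paired difference of 0.293 is the sharper
calibration target, and a single latent curve cannot match both.

**Between-patient heterogeneity and population calibration.** Patients
differ by a lognormal amplitude multiplier (mean 1, CV 0.2) on deviations
from baseline, and by a shared Gaussian extremum-time jitter (sd 12 h) —
one draw per patient, shifting all biomarkers together, as a single
ischemic event would. Time jitter has a consequence that is easy to miss:
averaging curves with jittered extrema *attenuates* the population
extremum (a Gaussian bump of width ~0.8 d convolved with N(0, 0.5 d)
loses ~15% of its height), and when the two limbs of an extremum have
unequal curvature it also *shifts* the population extremum toward the
shallower limb (the brain-oxygen valley, with its gentle decline and steep
post-detection recovery, moves roughly 17 hours earlier under 12-hour
jitter). Naively anchoring per-patient curves to the printed extrema would
therefore make the cohort-level GAM systematically undershoot the extrema
and misplace them. The generator instead calibrates at the population
level: each profile receives (i) a one-time time shift so the
jitter-convolved (population-average) trajectory attains its extremum at
the anchored time, and (ii) a one-time rescaling of deviations from
baseline so it attains the anchored value there. The shift is independent
of the rescaling (scaling deviations does not move an argmin), both are
computed from the profile and the jitter kernel alone, and both reduce to
the identity when jitter is disabled — the noiseless tests rely on this.
For PRx, whose anchors are themselves 24-hour-window medians, the
calibration kernel additionally includes the 24-hour window average, the
shift averages the trough and peak displacements, and the rescaling
preserves the anchored trough-to-peak contrast.

MAP/ICP pairs are coupled slow waves: per 10-s step a shared deviate `z`
and independent deviate `w` give `MAP = mu_MAP + a·z` and
`ICP = mu_ICP + b·(rho·z + sqrt(1−rho²)·w)`, so the windowed correlation
tracks the latent PRx target `rho`. No attempt is made to simulate pulse
or respiratory waveform morphology, drainage events, or vasopressor
responses; the slow-wave substrate is white at 10 s, which is sufficient
for the correlation estimator but does not reproduce the spectral
structure of real slow waves. Randomness is split per patient and per
modality from the master seed, so generation is reproducible regardless
of evaluation order.

**What passing recovery tests shows — and what it does not.** Recovery of
the anchored extrema demonstrates that the pipeline is unbiased under the
generator's assumptions (mean-one multiplicative noise, symmetric timing
jitter, MCAR missingness). Real monitoring data violate several of these:
missingness correlates with clinical state, noise is not mean-one within
patients, probe location matters, and trajectories are not shared shapes
scaled per patient. Synthetic recovery is therefore a necessary software
check, not clinical validation.

## Numerical and design choices

* Thin-plate basis dimension 20 (reduced automatically when the data
  have fewer unique hours); REML smoothing; fast-REML divergence on
  degenerate zero-residual inputs falls back to `gam`/REML, then GCV, and
  an exactly constant response short-circuits to the analytic constant
  fit.
* Grid spacing 0.1 h bounds the extremum-location error; trough/peak ties
  break toward detection.
* The lognormal noise CV parameterisation is mean-preserving
  (`meanlog = −sdlog²/2`), so hourly means and GAM estimates are unbiased
  for the latent trajectory.
* Stage outputs are plain CSV/JSON for diffability; the pipeline manifest
  records configuration and content hashes, and reruns are
  byte-reproducible at fixed seeds.
* Problem sizes: the recovery protocol uses ten replicate cohorts of 69
  patients with ~2.6 M 10-s samples per patient-channel; unit tests use
  scaled-down cohorts (4/5 patients, 2.5-day detection) that exercise the
  identical code paths.

## Known limitations

* The AR(1) correction is a discrete-time working correlation, not the
  continuous-time process a mixed-effects formulation would use; with
  strongly patient-clustered residuals the estimated phi partly absorbs
  between-patient variance.
* Cohort-level trough/peak centres are used for the paired windows; a
  per-patient-extremum variant is deliberately not implemented (the
  population-curve reading is the consistent one here).
* The classifier reports observation-level metrics; patient-hours are not
  independent, so these metrics are optimistic relative to patient-level
  generalisation — the patient-level mean-score view is provided for that
  reason.
* `evaluate_profile` extrapolates way-point profiles as constants beyond
  the outer knots; trajectories outside the simulated span are flat by
  construction.
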