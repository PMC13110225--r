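# dcimon

Event-locked analysis of invasive multimodal neuromonitoring around
delayed cerebral ischemia (DCI) related infarction after aneurysmal
subarachnoid hemorrhage — for neurocritical-care researchers working with
continuous ICP/MAP/PtiO2 monitoring, cerebral microdialysis, and
cerebrovascular pressure reactivity.

The package implements the full chain from raw pressure signals to a
patient-level classifier:

* **PRx** — the pressure reactivity index, computed as a moving Pearson
  correlation between 10-second averages of mean arterial and intracranial
  pressure over a 5-minute window advancing by 60 s (80% overlap, 50%
  missing-data limit):
  `PRx(t) = corr( MAP_10s , ICP_10s )` over the window centred at `t`.
* **Event-locked hourly tables** — artifact filtering, block averaging,
  lactate/pyruvate ratio (LPR), and hourly aggregation of every modality,
  re-indexed so hour 0 contains the infarct-detection instant (controls
  are anchored at the infarction group's median detection hour or at 180 h
  post ictus).
* **Population trajectories** — penalized thin-plate-spline GAMs
  (`value ~ s(rel_hour)`, REML, two-step AR(1) residual correction) per
  variable and group, first-derivative slope curves, trough/peak detection
  on the fitted mean, and paired 24-hour trough-vs-peak window comparisons
  with an exact Wilcoxon signed-rank test.
* **Rolling features** — for PtiO2, PRx, glutamate and glycerol over the
  73-hour analysis window (−48 h … +24 h around detection): instantaneous
  value, 6-h and 12-h preceding means, 6-h OLS slope (16 features).
* **Classification** — patient-level stratified 80/20 split, a
  100-tree Random Forest (balanced class weights, depth ≤ 10, ≥ 20 samples
  per split, ≥ 10 per leaf), rank-formulation AUC, impurity importances,
  and exact path-dependent TreeSHAP attributions (C++).
* **Synthetic cohorts** — a generator calibrated to the study's printed
  trajectory extrema (glutamate peak 22.2 µmol/L, glycerol peak
  190.8 µmol/L, PtiO2 trough 15.7 mmHg, PRx trough/peak −0.078/0.215),
  with correlated MAP/ICP slow waves, escalating microdialysis schedules,
  skewed noise, transport gaps and MCAR missingness — so the whole
  pipeline is testable without patient data.

## Worked example

```r
library(dcimon)

co      <- generate_cohort(generator_config(seed = 1))   # 69 patients
hourly  <- build_hourly(co)                              # PRx, LPR, hourly bins
aligned <- align_to_anchor(hourly, co$patients)          # rel_hour 0 = detection

glu <- analyze_trend(aligned, co$patients, "glutamate")
glu$extrema
#> <trough_peak: trough 7.813 @ -120.0 h, peak 21.3 @ +10.3 h>

prx <- analyze_trend(aligned, co$patients, "PRx")
prx$paired
#> <paired windows: n = 22, median difference 0.3084, V = 253, p = 4.768e-07>
```

The glutamate trajectory of the infarction group peaks at ~21.3 µmol/L
(this cohort's estimate of the 22.2 µmol/L population anchor) roughly
half a day after infarct detection, and the paired per-patient 24-hour
window medians around the PRx trough and peak differ by ~0.31 with a
clearly significant signed-rank test — impaired pressure reactivity after
infarction.

Classification on the same cohort:

```r
ft    <- engineer_features(aligned, co$patients)
sp    <- patient_split(co$patients, seed = 1)            # 55 train / 14 test
model <- train_rf(ft[ft$patient_id %in% sp$train, ], rf_config(seed = 1))
evaluate_model(model, ft[ft$patient_id %in% sp$test, ])
#> <model_report: AUC 1.000, accuracy 1.000, sensitivity 1.000, specificity 1.000 (n = 1022)>
head(feature_importance(model), 3)
#>  PtiO2_mean12   PtiO2_mean6 PtiO2_instant
#>     0.3098193     0.2726702     0.1829750
```

On synthetic cohorts the two groups are cleanly separable (the generator's
latent PtiO2/PRx/glutamate trajectories differ systematically between
groups), so the classifier saturates; the interesting checks are the
split arithmetic, the anti-leakage guarantees, the AUC/importance/SHAP
oracles, and the trajectory recovery above — not the headline AUC.

A full run (`run_pipeline(pipeline_config(), "out/")`, or
`exec/dcimon run --out out/ --seed 1`) writes `patients.csv`,
`microdialysis.csv`, `hourly.csv`, `features.csv`, `trends.json`,
`report.json`, `shap_summary.csv` and a `manifest.json` with configuration
and content hashes; reruns at the same seed are byte-identical.

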