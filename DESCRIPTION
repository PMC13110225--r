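Package: dcimon
Title: Peri-Infarction Multimodal Neuromonitoring Analysis for Delayed
    Cerebral Ischemia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An event-locked analysis pipeline for invasive multimodal
    neuromonitoring data recorded around delayed cerebral ischemia (DCI)
    related infarction after aneurysmal subarachnoid hemorrhage. Computes
    the pressure reactivity index (PRx) from 10-second averages of arterial
    and intracranial pressure, aggregates all modalities (PRx, intracranial
    pressure, brain tissue oxygenation, cerebral microdialysis analytes)
    into infarct-detection-aligned hourly tables, estimates population
    trajectories with penalized-spline generalized additive models and
    locates their troughs and peaks via first derivatives, compares paired
    24-hour trough/peak windows with exact Wilcoxon signed-rank tests,
    engineers rolling-window features over a 73-hour peri-detection window,
    and classifies patients with a patient-level stratified Random Forest
    including impurity importances and TreeSHAP attributions. A calibrated
    synthetic cohort generator emulates the study conditions so that every
    stage is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    mgcv,
    ranger,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
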