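# Shared fixtures: built in code, sized for fast unit tests.

# A small, fast cohort: short monitoring span, few patients.
small_config <- function(seed = 42, ...) {
  generator_config(
    n_infarction = 4, n_nodci = 5,
    detection_day_median = 2.5, detection_day_iqr = c(2.2, 2.9),
    post_detection_d = 2, seed = seed, ...)
}

# Noise-free, jitter-free configuration: latent trajectories pass through
# untouched, so downstream stages can be checked against evaluate_profile.
noiseless_config <- function(seed = 7, ...) {
  generator_config(
    n_infarction = 1, n_nodci = 0,
    detection_day_median = 2.5, detection_day_iqr = c(2.5, 2.5),
    post_detection_d = 2,
    md_noise_cv = 0, ptio2_noise_sd = 0,
    between_patient_amp_cv = 0, peak_time_jitter_sd = 0,
    mcar_rate = 0, transport_gap_h = 0, seed = seed, ...)
}

cached_small_cohort <- local({
  value <- NULL
  function() {
    if (is.null(value)) value <<- generate_cohort(small_config())
    value
  }
})

cached_small_aligned <- local({
  value <- NULL
  function() {
    if (is.null(value)) {
      co <- cached_small_cohort()
      value <<- align_to_anchor(build_hourly(co), co$patients)
    }
    value
  }
})

# Hand-built aligned hourly rows for one patient/variable.
hourly_rows <- function(patient_id, variable, rel_hours, values) {
  tibble::tibble(patient_id = patient_id, variable = variable,
                 rel_hour = as.integer(rel_hours), value = values)
}

# Separable two-class feature table for classifier tests: `signal` shifts
# by `delta` for infarction patients; remaining features are noise.
toy_features <- function(n_patients = 20, hours_per_patient = 20,
                         delta = 5, noise_sd = 1, seed = 1) {
  set.seed(seed)
  ids <- sprintf("T%02d", seq_len(n_patients))
  groups <- rep(c("infarction", "no_dci"), length.out = n_patients)
  rows <- lapply(seq_len(n_patients), function(i) {
    shift <- if (groups[i] == "infarction") delta else 0
    out <- tibble::tibble(
      patient_id = ids[i],
      rel_hour = seq_len(hours_per_patient) - 10L)
    for (f in feature_columns()) {
      out[[f]] <- rnorm(hours_per_patient, sd = noise_sd)
    }
    out$PtiO2_instant <- out$PtiO2_instant + shift
    out$label <- factor(groups[i], levels = c("no_dci", "infarction"))
    out
  })
  dplyr::bind_rows(rows)
}

toy_patients <- function(features) {
  dplyr::distinct(features, id = .data$patient_id,
                  group = as.character(.data$label))
}

# Pearson correlation by the textbook direct-sum formula (independent
# oracle for the PRx kernel).
pearson_oracle <- function(x, y) {
  n <- length(x)
  num <- sum(x * y) - sum(x) * sum(y) / n
  den <- sqrt((sum(x^2) - sum(x)^2 / n) * (sum(y^2) - sum(y)^2 / n))
  num / den
}

# Exhaustive signed-rank null: two-sided p over all 2^n sign assignments.
wilcoxon_enum_oracle <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.numeric(signs %*% r)
  p_le <- mean(w_all <= w_obs + 1e-9)
  p_ge <- mean(w_all >= w_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}
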