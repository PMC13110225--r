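#' Clip an aligned hourly table to the 73-hour analysis window
#'
#' Retains rows with `rel_hour` between 48 hours before and 24 hours after
#' infarct detection (73 integer hours inclusive).
#'
#' @param aligned Aligned hourly table ([align_to_anchor()]).
#' @param window `c(lo, hi)` in relative hours.
#' @return The clipped table.
#' @export
clip_analysis_window <- function(aligned, window = c(-48, 24)) {
  aligned[aligned$rel_hour >= window[1] & aligned$rel_hour <= window[2], ,
          drop = FALSE]
}

#' Rolling mean over the preceding hours
#'
#' For each evaluation hour `t`, the mean of the observations in the
#' half-open preceding window `(t - window_h, t]` (the current hour's value
#' included; set `include_current = FALSE` for the exclusive reading). The
#' value is emitted only when at least `min_frac * window_h` of the window's
#' hourly slots are observed.
#'
#' @param hours Integer observation hours (one patient's series).
#' @param values Observed values at `hours`.
#' @param window_h Window length, hours (6 or 12 in the feature set).
#' @param min_frac Minimum observed fraction of window slots.
#' @param eval_hours Hours at which to evaluate (default the observation
#'   hours).
#' @param include_current Include the current hour in the window.
#' @return Numeric vector aligned with `eval_hours` (`NA` = not emitted).
#' @export
rolling_mean <- function(hours, values, window_h, min_frac = 0.5,
                         eval_hours = hours, include_current = TRUE) {
  check_number(window_h, "window_h", lower = 1)
  ok <- !is.na(values)
  hours <- hours[ok]
  values <- values[ok]
  vapply(eval_hours, function(t) {
    upper <- if (include_current) t else t - 1
    sel <- hours > t - window_h & hours <= upper
    if (sum(sel) >= min_frac * window_h) mean(values[sel]) else NA_real_
  }, numeric(1))
}

#' Rolling slope over the preceding hours
#'
#' Ordinary least-squares slope of value against time over the preceding
#' `window_h`-hour window `(t - window_h, t]`, in units per hour; robust to
#' interior missingness. Emitted only with at least `min_obs` observations
#' in the window.
#'
#' @inheritParams rolling_mean
#' @param min_obs Minimum observations in the window.
#' @return Numeric vector of slopes aligned with `eval_hours`.
#' @export
rolling_slope <- function(hours, values, window_h = 6, min_obs = 3,
                          eval_hours = hours, include_current = TRUE) {
  ok <- !is.na(values)
  hours <- hours[ok]
  values <- values[ok]
  vapply(eval_hours, function(t) {
    upper <- if (include_current) t else t - 1
    sel <- hours > t - window_h & hours <= upper
    if (sum(sel) < min_obs) return(NA_real_)
    tt <- hours[sel]
    vv <- values[sel]
    stt <- sum((tt - mean(tt))^2)
    if (stt <= 0) return(NA_real_)
    sum((tt - mean(tt)) * (vv - mean(vv))) / stt
  }, numeric(1))
}

#' Biomarkers entering the classification feature set
#' @return Character vector.
#' @export
feature_biomarkers <- function() c("PtiO2", "PRx", "glutamate", "glycerol")

#' Engineer the patient-hour feature table
#'
#' Builds the 16-column feature table over the 73-hour analysis window:
#' for each of brain tissue oxygenation (PtiO2), pressure reactivity (PRx),
#' glutamate and glycerol, the instantaneous hourly value, rolling means
#' over the preceding 6 and 12 hours, and the 6-hour OLS slope. Rolling
#' features may draw on observations preceding the analysis window, never
#' on later hours, and never on other patients. A row is emitted for every
#' patient-hour with at least one observed feature; unobserved features
#' stay missing (no imputation at this stage).
#'
#' @param aligned Aligned hourly table covering (at least) the analysis
#'   window; earlier hours improve rolling-feature coverage at the window
#'   start.
#' @param patients Patient table with `id` and `group` (the class label).
#' @param window Analysis window, relative hours.
#' @param mean_min_frac Coverage rule for rolling means.
#' @param slope_min_obs Coverage rule for rolling slopes.
#' @param include_current Include the current hour in rolling windows.
#' @return Tibble `(patient_id, rel_hour, <16 features>, label)`.
#' @export
engineer_features <- function(aligned, patients, window = c(-48, 24),
                              mean_min_frac = 0.5, slope_min_obs = 3,
                              include_current = TRUE) {
  bio <- feature_biomarkers()
  rows <- aligned[aligned$variable %in% bio, , drop = FALSE]
  labels <- setNames(patients$group, patients$id)
  pts <- unique(rows$patient_id)
  missing_label <- setdiff(pts, patients$id)
  if (length(missing_label) > 0) {
    stop_dcimon("no class label for patient(s): %s",
                paste(missing_label, collapse = ", "))
  }
  eval_hours <- seq(window[1], window[2])
  per_patient <- lapply(split(rows, rows$patient_id), function(d) {
    out <- tibble::tibble(patient_id = d$patient_id[1],
                          rel_hour = as.integer(eval_hours))
    for (b in bio) {
      db <- d[d$variable == b & !is.na(d$value), ]
      dbw <- db[db$rel_hour >= window[1] & db$rel_hour <= window[2], ]
      inst <- rep(NA_real_, length(eval_hours))
      inst[match(dbw$rel_hour, eval_hours)] <- dbw$value
      out[[paste0(b, "_instant")]] <- inst
      out[[paste0(b, "_mean6")]] <- rolling_mean(
        db$rel_hour, db$value, 6, mean_min_frac, eval_hours, include_current)
      out[[paste0(b, "_mean12")]] <- rolling_mean(
        db$rel_hour, db$value, 12, mean_min_frac, eval_hours, include_current)
      out[[paste0(b, "_slope6")]] <- rolling_slope(
        db$rel_hour, db$value, 6, slope_min_obs, eval_hours, include_current)
    }
    out
  })
  feat <- dplyr::bind_rows(per_patient)
  fcols <- feature_columns()
  has_any <- rowSums(!is.na(as.matrix(feat[, fcols]))) > 0
  feat <- feat[has_any, , drop = FALSE]
  feat$label <- factor(labels[feat$patient_id],
                       levels = c("no_dci", "infarction"))
  feat
}

#' Names of the 16 engineered feature columns
#' @return Character vector of length 16.
#' @export
feature_columns <- function() {
  as.vector(t(outer(feature_biomarkers(),
                    c("instant", "mean6", "mean12", "slope6"),
                    paste, sep = "_")))
}
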