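#' Trajectory analysis for one variable
#'
#' Convenience wrapper running the trend stage for a single variable:
#' filters the aligned hourly table to one group, fits the population GAM
#' ([fit_gam()]), computes the derivative, locates the trough and peak
#' ([find_trough_peak()]), extracts per-patient 24-hour windows and runs
#' the paired Wilcoxon comparison.
#'
#' @param aligned Aligned hourly table.
#' @param patients Patient table (`id`, `group`).
#' @param variable Variable name (e.g. `"PRx"`).
#' @param group Group whose trajectory is analysed.
#' @param fit_range Event-time range (hours) of data entering the fit;
#'   the default spans the ten days around detection that the trajectory
#'   analysis examines.
#' @param basis_dim,ar1 Passed to [fit_gam()].
#' @param trough_search Trough search interval (pre-detection by default).
#' @param peak_search Peak search interval; `NULL` = trough to grid end.
#' @param width_h,min_obs Passed to [extract_paired_windows()].
#' @param peak_window Optional explicit second window (e.g. `c(0, 120)` for
#'   the pooled post-detection PtiO2 comparison).
#' @return List of class `trend_result`: `fit`, `extrema`, `derivative`,
#'   `pairs`, `paired`.
#' @export
analyze_trend <- function(aligned, patients, variable,
                          group = "infarction",
                          fit_range = c(-120, 120), basis_dim = 20,
                          ar1 = TRUE, trough_search = c(-240, 0),
                          peak_search = NULL, width_h = 24, min_obs = 6,
                          peak_window = NULL) {
  ids <- patients$id[patients$group == group]
  rows <- aligned[aligned$variable == variable &
                    aligned$patient_id %in% ids &
                    aligned$rel_hour >= fit_range[1] &
                    aligned$rel_hour <= fit_range[2], ]
  fit <- fit_gam(rows, variable = variable, group = group,
                 basis_dim = basis_dim, ar1 = ar1, grid_range = fit_range)
  tp <- find_trough_peak(fit, trough_search = trough_search,
                         peak_search = peak_search)
  deriv <- derivative(fit)
  pairs <- extract_paired_windows(rows, tp$trough_time_h, tp$peak_time_h,
                                  width_h = width_h, min_obs = min_obs,
                                  peak_window = peak_window)
  paired <- if (nrow(pairs) > 0) paired_window_test(pairs) else NULL
  structure(
    list(variable = variable, group = group, fit = fit, extrema = tp,
         derivative = deriv, pairs = pairs, paired = paired),
    class = "trend_result")
}

#' @export
print.trend_result <- function(x, ...) {
  cat(sprintf("<trend_result: %s / %s>\n", x$variable, x$group))
  print(x$extrema)
  if (!is.null(x$paired)) print(x$paired)
  invisible(x)
}

#' Full pipeline configuration
#'
#' @param generator A [generator_config()].
#' @param anchor_policy Control-group anchoring policy
#'   (see [align_to_anchor()]).
#' @param trend_variables Variables analysed in the trend stage.
#' @param basis_dim,ar1 GAM settings.
#' @param fit_range Event-time range for trajectory fits, hours.
#' @param feature_window Analysis window for feature engineering, hours.
#' @param apply_md_filter Apply the microdialysis inclusion filter before
#'   classification.
#' @param rf An [rf_config()].
#' @param split_seed Seed of the patient-level split.
#' @param write_signals Also write the (large) raw signal table.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(generator = generator_config(),
                            anchor_policy = "median_detection",
                            trend_variables = c("PRx", "PtiO2", "glutamate",
                                                "glycerol", "ICP", "LPR"),
                            basis_dim = 20, ar1 = TRUE,
                            fit_range = c(-120, 120),
                            feature_window = c(-48, 24),
                            apply_md_filter = TRUE,
                            rf = rf_config(),
                            split_seed = 1L,
                            write_signals = FALSE) {
  structure(
    list(generator = generator, anchor_policy = anchor_policy,
         trend_variables = trend_variables, basis_dim = basis_dim,
         ar1 = ar1, fit_range = fit_range,
         feature_window = feature_window,
         apply_md_filter = apply_md_filter, rf = rf,
         split_seed = as.integer(split_seed),
         write_signals = write_signals),
    class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes simulate, signals, trends, features and classify in sequence
#' and writes every stage output plus a manifest (configuration hash, stage
#' seeds, row counts, content hash) to `out_dir` as plain delimited text
#' and JSON. A rerun with the same configuration produces identical
#' outputs and manifest hashes.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Writable output directory.
#' @param quiet Suppress stage progress messages.
#' @return Invisibly, a list with all stage results and the manifest.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir, quiet = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(out_dir, 2) != 0) {
    stop_dcimon("output directory '%s' is not writable", out_dir)
  }
  say <- function(...) if (!quiet) message(sprintf(...))
  stage <- function(name, expr) {
    t0 <- Sys.time()
    out <- tryCatch(expr, error = function(e) {
      stop_dcimon("stage '%s' failed: %s", name, conditionMessage(e))
    })
    say("[%s] done in %.1f s", name,
        as.numeric(difftime(Sys.time(), t0, units = "secs")))
    out
  }

  cohort <- stage("simulate", generate_cohort(config$generator))
  aligned <- stage("signals", {
    hourly <- build_hourly(cohort)
    align_to_anchor(hourly, cohort$patients, config$anchor_policy)
  })
  trends <- stage("trends", {
    lapply(setNames(nm = config$trend_variables), function(v) {
      pw <- if (v == "PtiO2") c(0, 120) else NULL
      tryCatch(
        analyze_trend(aligned, cohort$patients, v, group = "infarction",
                      fit_range = config$fit_range,
                      basis_dim = config$basis_dim, ar1 = config$ar1,
                      peak_window = pw),
        dcimon_error = function(e) NULL)
    })
  })
  features <- stage("features", {
    engineer_features(aligned, cohort$patients,
                      window = config$feature_window)
  })
  classify <- stage("classify", {
    pts <- cohort$patients
    if (config$apply_md_filter) {
      keep <- md_inclusion_filter(aligned, window = config$feature_window)
      pts <- pts[pts$id %in% keep, ]
    }
    rows <- features[features$patient_id %in% pts$id, ]
    split <- patient_split(pts, seed = config$split_seed)
    train_rows <- rows[rows$patient_id %in% split$train, ]
    test_rows <- rows[rows$patient_id %in% split$test, ]
    model <- train_rf(train_rows, config$rf)
    report <- evaluate_model(model, test_rows)
    shap <- shap_summary(model, test_rows)
    list(split = split, model = model, report = report,
         importance = feature_importance(model), shap = shap,
         n_train_obs = nrow(train_rows), n_test_obs = nrow(test_rows),
         n_patients = nrow(pts))
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("dcimon")),
    config_hash = rlang::hash(config),
    seed = config$generator$seed,
    n_patients = nrow(cohort$patients),
    n_infarction = sum(cohort$patients$group == "infarction"),
    n_signal_rows = nrow(cohort$signals),
    n_md_rows = nrow(cohort$microdialysis),
    n_hourly_rows = nrow(aligned),
    n_feature_rows = nrow(features),
    n_feature_columns = length(feature_columns()),
    analysis_window_h = diff(config$feature_window) + 1,
    n_classified_patients = classify$n_patients,
    n_train_patients = length(classify$split$train),
    n_test_patients = length(classify$split$test),
    metrics = classify$report[c("auc", "accuracy", "sensitivity",
                                "specificity")],
    content_hash = rlang::hash(list(aligned, features,
                                    classify$report$auc,
                                    classify$importance)))

  stage("write", {
    write_cohort(cohort, out_dir, signals = isTRUE(config$write_signals))
    write.csv(aligned, file.path(out_dir, "hourly.csv"), row.names = FALSE)
    write.csv(features, file.path(out_dir, "features.csv"),
              row.names = FALSE)
    trends_json <- lapply(trends, function(tr) {
      if (is.null(tr)) return(NULL)
      list(variable = tr$variable, group = tr$group,
           grid_h = tr$fit$grid_h, mean = tr$fit$mean, se = tr$fit$se,
           derivative_per_d = tr$derivative$slope_per_d,
           trough = tr$extrema[c("trough_time_h", "trough_value")],
           peak = tr$extrema[c("peak_time_h", "peak_value")],
           paired = if (!is.null(tr$paired)) {
             tr$paired[c("n_pairs", "median_difference", "statistic",
                         "p_value")]
           })
    })
    jsonlite::write_json(trends_json, file.path(out_dir, "trends.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    jsonlite::write_json(
      list(metrics = classify$report[c("auc", "accuracy", "sensitivity",
                                       "specificity", "n_obs")],
           importance = as.list(classify$importance),
           split = classify$split[c("train", "test", "seed")],
           rf = unclass(config$rf)),
      file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
    write.csv(classify$shap$summary,
              file.path(out_dir, "shap_summary.csv"), row.names = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    NULL
  })

  invisible(list(cohort = cohort, aligned = aligned, trends = trends,
                 features = features, classify = classify,
                 manifest = manifest))
}
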