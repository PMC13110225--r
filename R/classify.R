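#' Patient-level stratified train/test split
#'
#' Splits the cohort at the patient level (never at the observation level,
#' so no patient's hours leak across the split) with stratification by
#' outcome class: per class the test set receives
#' `round((1 - train_fraction) * class size)` patients sampled without
#' replacement. A 24/45 cohort at 80/20 therefore yields 55 training and 14
#' test patients (5 infarction + 9 control in the test set) for every seed.
#'
#' @param patients Patient table with `id` and `group`.
#' @param train_fraction Fraction of each class assigned to training.
#' @param seed Integer seed.
#' @return List of class `split_spec` with `train` and `test` id vectors.
#' @export
patient_split <- function(patients, train_fraction = 0.8, seed = 1L) {
  check_number(train_fraction, "train_fraction", lower = 1e-9, upper = 1)
  test_ids <- character(0)
  for (g in unique(patients$group)) {
    ids <- patients$id[patients$group == g]
    if (length(ids) < 2) {
      stop_dcimon("class '%s' has fewer than 2 patients", g)
    }
    n_test <- round((1 - train_fraction) * length(ids))
    picked <- with_seed(seed + match(g, sort(unique(patients$group))),
                        sample(ids, n_test))
    test_ids <- c(test_ids, picked)
  }
  structure(
    list(train = setdiff(patients$id, test_ids), test = sort(test_ids),
         seed = as.integer(seed), train_fraction = train_fraction,
         stratified = TRUE),
    class = "split_spec")
}

#' Random-Forest configuration
#'
#' The classifier hyperparameters: 100 trees, balanced class weights,
#' maximum depth 10, minimum 20 samples to split a node, minimum 10 samples
#' per leaf. Missing features are imputed with per-feature medians computed
#' on the training rows only (`"train_median_impute"`); the `"native"`
#' policy is reserved for missing-aware split implementations and is not
#' provided by the ranger backend.
#'
#' @param n_trees,max_depth,min_samples_split,min_samples_leaf Tree
#'   ensemble regularization.
#' @param class_weight `"balanced"` or `"none"`.
#' @param missing_policy Missing-feature handling.
#' @param threshold Probability threshold for the positive (infarction)
#'   class when computing sensitivity/specificity.
#' @param seed Integer seed for bootstrap and split randomness.
#' @return An `rf_config` list.
#' @export
rf_config <- function(n_trees = 100, class_weight = c("balanced", "none"),
                      max_depth = 10, min_samples_split = 20,
                      min_samples_leaf = 10,
                      missing_policy = c("train_median_impute", "native"),
                      threshold = 0.5, seed = 1L) {
  class_weight <- match.arg(class_weight)
  missing_policy <- match.arg(missing_policy)
  check_count(n_trees, "n_trees")
  check_count(max_depth, "max_depth")
  check_count(min_samples_split, "min_samples_split")
  check_count(min_samples_leaf, "min_samples_leaf")
  check_number(threshold, "threshold", lower = 1e-9, upper = 1 - 1e-9)
  structure(
    list(n_trees = as.integer(n_trees), class_weight = class_weight,
         max_depth = as.integer(max_depth),
         min_samples_split = as.integer(min_samples_split),
         min_samples_leaf = as.integer(min_samples_leaf),
         missing_policy = missing_policy, threshold = threshold,
         seed = as.integer(seed)),
    class = "rf_config")
}

feature_matrix <- function(rows, fcols) {
  m <- as.matrix(rows[, fcols])
  storage.mode(m) <- "double"
  m
}

impute_with <- function(m, medians) {
  for (j in seq_len(ncol(m))) {
    miss <- is.na(m[, j])
    if (any(miss)) m[miss, j] <- medians[j]
  }
  m
}

#' Train the patient-hour Random-Forest classifier
#'
#' Fits a probability forest (ranger backend) of CART-style trees on the
#' engineered feature rows, honouring the depth/split/leaf limits and
#' balanced class weights of the configuration. Per-feature imputation
#' medians are computed on the supplied (training) rows only and stored in
#' the model, so no test-derived statistic can enter training. Training is
#' deterministic under the configuration seed.
#'
#' @param rows Training feature rows ([engineer_features()] output,
#'   restricted to training patients).
#' @param config An [rf_config()].
#' @return A `dcimon_rf` model object.
#' @export
train_rf <- function(rows, config = rf_config()) {
  stopifnot(inherits(config, "rf_config"))
  fcols <- intersect(feature_columns(), names(rows))
  if (length(fcols) == 0) {
    fcols <- setdiff(names(rows), c("patient_id", "rel_hour", "label"))
  }
  label <- droplevels(rows$label)
  if (nlevels(label) < 2) {
    stop_dcimon("training data contain a single class ('%s')",
                levels(label)[1])
  }
  label <- factor(as.character(label), levels = c("no_dci", "infarction"))
  if (config$missing_policy == "native") {
    stop_dcimon(paste0(
      "missing_policy 'native' (missing-aware splits) is not supported by ",
      "the ranger backend; use 'train_median_impute'"))
  }
  m <- feature_matrix(rows, fcols)
  medians <- apply(m, 2, median, na.rm = TRUE)
  medians[!is.finite(medians)] <- 0
  m <- impute_with(m, medians)
  cw <- if (config$class_weight == "balanced") {
    tab <- table(label)
    as.numeric(sum(tab) / (length(tab) * tab))[match(levels(label),
                                                     names(tab))]
  } else {
    c(1, 1)
  }
  d <- data.frame(m)
  d$.label <- label
  fit <- ranger::ranger(
    dependent.variable.name = ".label", data = d,
    num.trees = config$n_trees, probability = TRUE,
    max.depth = config$max_depth,
    min.node.size = config$min_samples_split,
    min.bucket = config$min_samples_leaf,
    class.weights = cw, importance = "impurity",
    seed = config$seed, num.threads = 1)
  structure(
    list(fit = fit, feature_names = fcols, medians = medians,
         config = config, levels = levels(label), positive = "infarction",
         train_matrix = m, train_patients = unique(rows$patient_id)),
    class = "dcimon_rf")
}

#' @export
print.dcimon_rf <- function(x, ...) {
  cat(sprintf("<dcimon_rf: %d trees, %d features, %d training rows>\n",
              x$config$n_trees, length(x$feature_names),
              nrow(x$train_matrix)))
  invisible(x)
}

#' Predicted infarction probability for feature rows
#'
#' @param model A [train_rf()] model.
#' @param rows Feature rows.
#' @return Numeric vector of probabilities for the infarction class.
#' @export
predict_prob <- function(model, rows) {
  stopifnot(inherits(model, "dcimon_rf"))
  m <- impute_with(feature_matrix(rows, model$feature_names), model$medians)
  pr <- predict(model$fit, data = data.frame(m),
                num.threads = 1)$predictions
  as.numeric(pr[, model$positive])
}

#' Area under the ROC curve (rank formulation)
#'
#' AUC via the Mann-Whitney rank statistic with ties counted one half,
#' equal to the exhaustive pairwise win fraction over all
#' positive/negative score pairs.
#'
#' @param scores Numeric classifier scores.
#' @param labels Logical or factor; `TRUE`/`"infarction"` = positive.
#' @return AUC in `[0, 1]`; `NA` if only one class is present.
#' @export
auc_rank <- function(scores, labels) {
  pos <- if (is.logical(labels)) labels else labels == "infarction"
  n1 <- sum(pos)
  n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Evaluate a trained classifier on held-out rows
#'
#' Observation-level (patient-hour) metrics: AUC by the rank formulation,
#' plus accuracy, sensitivity (recall on the infarction class) and
#' specificity (recall on the control class) at the configured probability
#' threshold. A patient-level secondary view aggregates the mean score per
#' patient.
#'
#' @param model A [train_rf()] model.
#' @param rows Held-out feature rows (with `label`).
#' @param threshold Probability threshold (default from the model config).
#' @return List of class `model_report`: `auc`, `accuracy`, `sensitivity`,
#'   `specificity`, `n_obs`, `threshold`, `patient_scores`.
#' @export
evaluate_model <- function(model, rows, threshold = NULL) {
  if (nrow(rows) == 0) stop_dcimon("no rows to evaluate")
  if (is.null(threshold)) threshold <- model$config$threshold
  p <- predict_prob(model, rows)
  truth <- rows$label == model$positive
  pred <- p >= threshold
  metrics <- list(
    auc = auc_rank(p, truth),
    accuracy = mean(pred == truth),
    sensitivity = if (any(truth)) mean(pred[truth]) else NA_real_,
    specificity = if (any(!truth)) mean(!pred[!truth]) else NA_real_)
  patient_scores <- tibble::tibble(patient_id = rows$patient_id,
                                   score = p, truth = truth) |>
    dplyr::summarise(mean_score = mean(.data$score),
                     truth = .data$truth[1], .by = "patient_id")
  structure(
    c(metrics,
      list(n_obs = nrow(rows), threshold = threshold,
           patient_scores = patient_scores,
           patient_auc = auc_rank(patient_scores$mean_score,
                                  patient_scores$truth))),
    class = "model_report")
}

#' @export
print.model_report <- function(x, ...) {
  cat(sprintf(paste0(
    "<model_report: AUC %.3f, accuracy %.3f, sensitivity %.3f, ",
    "specificity %.3f (n = %d)>\n"),
    x$auc, x$accuracy, x$sensitivity, x$specificity, x$n_obs))
  invisible(x)
}

#' Mean-decrease-in-impurity feature importances
#'
#' Per-feature mean impurity decrease across the forest, normalized to sum
#' to one.
#'
#' @param model A [train_rf()] model.
#' @return Named numeric vector (sums to 1), decreasing.
#' @export
feature_importance <- function(model) {
  stopifnot(inherits(model, "dcimon_rf"))
  imp <- ranger::importance(model$fit)
  imp <- pmax(imp, 0)
  sort(imp / sum(imp), decreasing = TRUE)
}
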