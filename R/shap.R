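# Extract a forest into the flat array encoding consumed by the C++
# TreeSHAP kernel. Leaf values are scaled by 1/n_trees so the ensemble
# prediction is the plain sum over trees; covers come from routing the
# training matrix through each tree.
extract_forest <- function(model) {
  stopifnot(inherits(model, "dcimon_rf"))
  fit <- model$fit
  n_trees <- fit$num.trees
  lapply(seq_len(n_trees), function(t) {
    ti <- ranger::treeInfo(fit, t)
    pred_col <- grep(paste0("^pred(iction)?\\.", model$positive, "$"),
                     names(ti), value = TRUE)[1]
    if (is.na(pred_col)) {
      stop_dcimon("cannot locate leaf probabilities for class '%s'",
                  model$positive)
    }
    left <- ifelse(is.na(ti$leftChild), -1L, as.integer(ti$leftChild))
    right <- ifelse(is.na(ti$rightChild), -1L, as.integer(ti$rightChild))
    feat <- match(ti$splitvarName, model$feature_names) - 1L
    feat[is.na(feat)] <- -1L
    thr <- ifelse(is.na(ti$splitval), 0, ti$splitval)
    value <- ti[[pred_col]]
    value <- ifelse(is.na(value), 0, value) / n_trees
    cover <- as.numeric(route_counts_cpp(left, right, feat, thr,
                                         model$train_matrix))
    list(left = left, right = right, feature = feat,
         threshold = as.numeric(thr), value = as.numeric(value),
         cover = cover)
  })
}

#' TreeSHAP attributions for the infarction probability
#'
#' Path-dependent TreeSHAP attributions of the predicted infarction-class
#' probability: per row and per feature, an additive contribution such that
#' the base value (the cover-weighted expected forest output over the
#' training distribution) plus the row's attributions equals the row's
#' predicted probability exactly (local accuracy). Features never used in
#' any split receive exactly zero attribution.
#'
#' @param model A [train_rf()] model (tree ensemble; other model types are
#'   rejected).
#' @param rows Feature rows to explain (missing features are imputed with
#'   the model's training medians, matching prediction).
#' @return List of class `shap_result`: `base_value`, `phi` (matrix rows x
#'   features), `prediction` (vector `base_value + rowSums(phi)`), and
#'   `summary`, a long tibble `(feature, value, phi)` for beeswarm-style
#'   summaries.
#' @export
shap_summary <- function(model, rows) {
  if (!inherits(model, "dcimon_rf")) {
    stop_dcimon("shap_summary requires a tree-ensemble model (dcimon_rf)")
  }
  X <- impute_with(feature_matrix(rows, model$feature_names), model$medians)
  forest <- extract_forest(model)
  res <- treeshap_cpp(forest, X)
  phi <- res$phi
  colnames(phi) <- model$feature_names
  summary <- tibble::tibble(
    feature = rep(model$feature_names, each = nrow(X)),
    value = as.vector(X),
    phi = as.vector(phi))
  structure(
    list(base_value = res$base, phi = phi,
         prediction = res$base + rowSums(phi), summary = summary),
    class = "shap_result")
}

#' @export
print.shap_result <- function(x, ...) {
  ord <- sort(colMeans(abs(x$phi)), decreasing = TRUE)
  cat(sprintf("<shap_result: %d rows, base value %.4f>\n",
              nrow(x$phi), x$base_value))
  cat("  top mean |phi|:\n")
  top <- head(ord, 5)
  for (i in seq_along(top)) {
    cat(sprintf("    %-18s %.4f\n", names(top)[i], top[i]))
  }
  invisible(x)
}
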