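test_that("stratified patient split reproduces the 55/14 arithmetic for
           every seed", {
  patients <- tibble::tibble(
    id = sprintf("P%02d", 1:69),
    group = c(rep("infarction", 24), rep("no_dci", 45)))
  for (seed in c(1, 2, 17, 123, 99991)) {
    sp <- patient_split(patients, seed = seed)
    expect_length(sp$train, 55)
    expect_length(sp$test, 14)
    test_groups <- patients$group[match(sp$test, patients$id)]
    expect_equal(sum(test_groups == "infarction"), 5)
    expect_equal(sum(test_groups == "no_dci"), 9)
    expect_length(intersect(sp$train, sp$test), 0)
    expect_setequal(c(sp$train, sp$test), patients$id)
  }
  # symmetric 10-patient case: 8 train, 1 test per class
  p10 <- tibble::tibble(id = letters[1:10],
                        group = rep(c("infarction", "no_dci"), each = 5))
  sp10 <- patient_split(p10, seed = 3)
  expect_length(sp10$train, 8)
  expect_length(sp10$test, 2)
  # determinism
  expect_identical(patient_split(p10, seed = 5), patient_split(p10, seed = 5))
  expect_error(patient_split(tibble::tibble(id = "x", group = "infarction")),
               "fewer than 2")
})

test_that("a separable feature yields AUC 1 and null labels sit near 0.5", {
  ft <- toy_features(delta = 8)
  patients <- toy_patients(ft)
  sp <- patient_split(patients, seed = 1)
  model <- train_rf(ft[ft$patient_id %in% sp$train, ], rf_config(seed = 1))
  rep_sep <- evaluate_model(model, ft[ft$patient_id %in% sp$test, ])
  expect_equal(rep_sep$auc, 1)
  expect_equal(rep_sep$sensitivity, 1)
  expect_equal(rep_sep$specificity, 1)

  # permuted labels: test AUC stays in the null band across seeds
  aucs <- vapply(1:10, function(s) {
    ftp <- toy_features(delta = 0, seed = 100 + s)
    spp <- patient_split(toy_patients(ftp), seed = s)
    m <- train_rf(ftp[ftp$patient_id %in% spp$train, ], rf_config(seed = s))
    evaluate_model(m, ftp[ftp$patient_id %in% spp$test, ])$auc
  }, numeric(1))
  expect_true(all(aucs >= 0.35 & aucs <= 0.65))
  expect_error(train_rf(ft[ft$label == "infarction", ]), "single class")
})

test_that("AUC matches the exhaustive pairwise oracle and tie convention", {
  expect_equal(auc_rank(c(0.9, 0.8, 0.1, 0.2), c(TRUE, TRUE, FALSE, FALSE)),
               1)
  expect_equal(auc_rank(rep(0.4, 6), rep(c(TRUE, FALSE), 3)), 0.5)
  expect_equal(auc_rank(c(0.8, 0.4, 0.6, 0.2), c(TRUE, TRUE, FALSE, FALSE)),
               0.75) # 3 wins of 4 pairs
  # property: agreement with brute-force pair counting
  set.seed(31)
  for (rep in 1:20) {
    n <- sample(5:40, 1)
    scores <- round(runif(n), 2) # ties likely
    labs <- runif(n) > 0.5
    if (length(unique(labs)) < 2) next
    pos <- scores[labs]
    neg <- scores[!labs]
    pairs <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
    expect_equal(auc_rank(scores, labs), mean(pairs), tolerance = 1e-12)
  }
  expect_true(is.na(auc_rank(c(0.2, 0.3), c(TRUE, TRUE))))
})

test_that("impurity importances normalize to one and rank signal above
           noise", {
  ft <- toy_features(delta = 6)
  sp <- patient_split(toy_patients(ft), seed = 2)
  model <- train_rf(ft[ft$patient_id %in% sp$train, ], rf_config(seed = 2))
  imp <- feature_importance(model)
  expect_equal(sum(imp), 1, tolerance = 1e-9)
  expect_true(all(imp >= 0))
  expect_equal(names(imp)[1], "PtiO2_instant") # the separating feature
  expect_gt(imp["PtiO2_instant"], max(imp[names(imp) != "PtiO2_instant"]))
})

test_that("training is deterministic, patient-levelled, and leak-free", {
  ft <- toy_features(delta = 2, noise_sd = 2)
  patients <- toy_patients(ft)
  sp <- patient_split(patients, seed = 4)
  train_rows <- ft[ft$patient_id %in% sp$train, ]
  test_rows <- ft[ft$patient_id %in% sp$test, ]
  m1 <- train_rf(train_rows, rf_config(seed = 9))
  m2 <- train_rf(train_rows, rf_config(seed = 9))
  probe <- test_rows
  expect_identical(predict_prob(m1, probe), predict_prob(m2, probe))
  # replacing all TEST rows by noise changes no training artifact
  noised <- test_rows
  for (f in feature_columns()) noised[[f]] <- rnorm(nrow(noised), 100, 50)
  m3 <- train_rf(train_rows, rf_config(seed = 9))
  expect_identical(predict_prob(m1, probe), predict_prob(m3, probe))
  expect_identical(m1$medians, m3$medians) # imputation from training only
  # train/test patient ids are disjoint by construction
  expect_length(intersect(unique(train_rows$patient_id),
                          unique(test_rows$patient_id)), 0)
})

test_that("imputation medians come from training rows and `native` policy
           is rejected", {
  ft <- toy_features(delta = 3)
  ft$PRx_instant[seq(1, nrow(ft), by = 3)] <- NA
  sp <- patient_split(toy_patients(ft), seed = 6)
  train_rows <- ft[ft$patient_id %in% sp$train, ]
  model <- train_rf(train_rows, rf_config(seed = 6))
  expect_equal(model$medians[["PRx_instant"]],
               median(train_rows$PRx_instant, na.rm = TRUE))
  expect_error(train_rf(train_rows, rf_config(missing_policy = "native")),
               "native")
})
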