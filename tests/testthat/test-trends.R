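make_rows <- function(f, patients = 6, hours = seq(-120, 120, by = 2),
                      noise_sd = 0, seed = 3) {
  set.seed(seed)
  dplyr::bind_rows(lapply(seq_len(patients), function(i) {
    tibble::tibble(patient_id = sprintf("P%02d", i), rel_hour = hours,
                   value = f(hours) + rnorm(length(hours), sd = noise_sd))
  }))
}

test_that("GAM reproduces a constant and recovers a smooth polynomial", {
  rows <- make_rows(function(h) rep(0.170, length(h)))
  fit <- fit_gam(rows, "PRx", "no_dci")
  expect_lt(max(abs(fit$mean - 0.170)), 1e-8)
  expect_true(all(fit$se >= 0))
  expect_equal(length(fit$mean), length(fit$grid_h))

  quad <- function(h) (h / 24)^2
  fitq <- fit_gam(make_rows(quad), "x", "g")
  interior <- fitq$grid_h > -100 & fitq$grid_h < 100
  rel_err <- abs(fitq$mean[interior] - quad(fitq$grid_h[interior])) /
    pmax(1, abs(quad(fitq$grid_h[interior])))
  expect_lt(max(rel_err), 0.01)
  # insufficient data errors name the variable and group
  expect_error(fit_gam(rows[1:10, ], "PRx", "infarction"),
               "PRx/infarction")
})

test_that("trajectory derivative is exact for constants and lines", {
  fitc <- fit_gam(make_rows(function(h) rep(5, length(h))), "c", "g")
  dc <- derivative(fitc)
  expect_lt(max(abs(dc$slope_per_h)), 1e-8)
  m <- 0.25
  fitl <- fit_gam(make_rows(function(h) m * h), "l", "g")
  dl <- derivative(fitl)
  interior <- dl$grid_h > -110 & dl$grid_h < 110
  expect_lt(max(abs(dl$slope_per_h[interior] - m)), 1e-6)
  expect_equal(dl$slope_per_d, dl$slope_per_h * 24)
})

test_that("the fitted glutamate surge slope matches the latent profile's
           maximum rise", {
  # noiseless hourly samples of the latent glutamate profile; the fitted
  # trajectory's maximum rising slope should approach the closed-form
  # Gaussian-limb maximum (smoothing attenuates it slightly)
  prof <- default_profiles("infarction")$glutamate
  hours <- seq(-120, 120)
  rows <- dplyr::bind_rows(lapply(1:4, function(i) {
    tibble::tibble(patient_id = sprintf("P%02d", i), rel_hour = hours,
                   value = evaluate_profile(prof, hours / 24))
  }))
  fit <- fit_gam(rows, "glutamate", "infarction")
  max_rise <- max(derivative(fit)$slope_per_d)
  expect_lt(abs(max_rise - 11.27) / 11.27, 0.15)
})

test_that("trough/peak detection matches analytic extrema and boundaries", {
  # parabola with minimum at -36 h
  fitp <- fit_gam(make_rows(function(h) ((h + 36) / 50)^2), "p", "g")
  tp <- find_trough_peak(fitp, trough_search = c(-120, 0))
  expect_equal(tp$trough_time_h, -36, tolerance = 0.5)
  expect_lte(tp$trough_value, tp$peak_value)
  # monotone increasing: trough at left edge, peak at right edge
  fitm <- fit_gam(make_rows(function(h) h / 100), "m", "g")
  tpm <- find_trough_peak(fitm, trough_search = c(-120, 0))
  expect_equal(tpm$trough_time_h, -120, tolerance = 0.2)
  expect_equal(tpm$peak_time_h, 120, tolerance = 0.2)
  expect_error(find_trough_peak(fitm, trough_search = c(500, 600)),
               "empty")
})

test_that("trough/peak times are shift-invariant and ties break toward 0", {
  base <- make_rows(function(h) ((h + 36) / 50)^2)
  fit1 <- fit_gam(base, "p", "g")
  shifted <- dplyr::mutate(base, value = value + 42)
  fit2 <- fit_gam(shifted, "p", "g")
  tp1 <- find_trough_peak(fit1, trough_search = c(-120, 0))
  tp2 <- find_trough_peak(fit2, trough_search = c(-120, 0))
  expect_equal(tp1$trough_time_h, tp2$trough_time_h)
  expect_equal(tp2$trough_value, tp1$trough_value + 42, tolerance = 1e-6)
  # exact tie on a flat fit resolves to the time nearest detection
  fitc <- fit_gam(make_rows(function(h) rep(1, length(h))), "c", "g")
  tpc <- find_trough_peak(fitc, trough_search = c(-120, 0))
  expect_equal(tpc$trough_time_h, 0)
})

test_that("paired 24-h windows take per-patient medians with the coverage
           rule and the post-detection override", {
  rows <- dplyr::bind_rows(
    hourly_rows("A", "PRx", -60:40, rep(10, 101)),
    hourly_rows("B", "PRx", c(-40, -39, -38), c(1, 2, 3)),
    hourly_rows("C", "PRx", -60:40, c(rep(2, 50), rep(8, 51))))
  pairs <- extract_paired_windows(rows, trough_time_h = -36,
                                  peak_time_h = 12)
  expect_equal(sort(pairs$patient_id), c("A", "C"))
  a <- pairs[pairs$patient_id == "A", ]
  expect_equal(c(a$trough_median, a$peak_median), c(10, 10))
  # B had only 3 observations in the trough window: excluded
  expect_false("B" %in% pairs$patient_id)
  # median robust to outliers
  rows_out <- dplyr::bind_rows(
    hourly_rows("D", "x", -47:-43, c(1, 2, 3, 4, 100)),
    hourly_rows("D", "x", 8:12, c(5, 6, 7, 8, 9)))
  p_out <- extract_paired_windows(rows_out, -45, 12, min_obs = 5)
  expect_equal(p_out$trough_median, 3)
  expect_equal(p_out$peak_median, 7)
  # explicit post-detection window override
  p_ov <- extract_paired_windows(
    hourly_rows("E", "PtiO2", -60:119, c(rep(15, 60), rep(30, 120))),
    trough_time_h = -24, peak_time_h = 2, peak_window = c(0, 120))
  expect_equal(p_ov$peak_median, 30)
  expect_equal(p_ov$n_peak, 120L)
})

test_that("window medians are invariant to observation order", {
  rows <- hourly_rows("A", "x", -47:-24, rnorm(24))
  shuffled <- rows[sample(nrow(rows)), ]
  p1 <- extract_paired_windows(rows, -36, 0)
  p2 <- extract_paired_windows(shuffled, -36, 0)
  expect_equal(p1$trough_median, p2$trough_median)
})

test_that("exact Wilcoxon agrees with full sign enumeration", {
  # fixed example: pairs (1,2),(1,3),(1,4),(2,6),(3,7),(4,9)
  x <- c(2, 3, 4, 6, 7, 9)
  y <- c(1, 1, 1, 2, 3, 4)
  w <- paired_wilcoxon(x, y)
  expect_equal(w$p_value, wilcoxon_enum_oracle(x - y), tolerance = 1e-12)
  expect_equal(w$method, "exact")
  # property: agreement across random paired integer data (with ties and
  # zeros) for every n <= 10
  set.seed(202)
  for (rep in 1:50) {
    n <- sample(2:10, 1)
    d <- sample(-5:5, n, replace = TRUE)
    if (all(d == 0)) d[1] <- 1
    got <- paired_wilcoxon(d)
    expect_equal(got$p_value, wilcoxon_enum_oracle(d), tolerance = 1e-12,
                 info = paste("d =", paste(d, collapse = ",")))
  }
})

test_that("Wilcoxon handles degenerate input and matches stats::wilcox.test
           when the latter is exact", {
  ident <- paired_wilcoxon(c(3, 5, 7), c(3, 5, 7))
  expect_equal(ident$p_value, 1)
  expect_equal(ident$statistic, 0)
  expect_equal(ident$median_difference, 0)
  set.seed(77)
  for (rep in 1:20) {
    n <- sample(4:12, 1)
    d <- round(rnorm(n, sd = 3), 4) # continuous: no ties, no zeros
    ref <- stats::wilcox.test(d, exact = TRUE)
    got <- paired_wilcoxon(d)
    expect_equal(got$statistic, unname(ref$statistic))
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-12)
  }
  # large-n branch: normal approximation close to the exact DP
  set.seed(8)
  d <- rnorm(40) + 0.3
  approx_p <- paired_wilcoxon(d)$p_value
  exact_p <- paired_wilcoxon(d, exact_limit = 40)$p_value
  expect_lt(abs(approx_p - exact_p), 0.01)
})
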