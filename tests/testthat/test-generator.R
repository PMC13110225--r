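test_that("cohort counts, determinism, and basic invariants hold", {
  co <- cached_small_cohort()
  expect_equal(nrow(co$patients), 9)
  expect_equal(sum(co$patients$group == "infarction"), 4)
  expect_true(all(co$microdialysis$concentration >= 0))
  # strictly increasing timestamps per patient and channel
  by_series <- split(co$signals$t_s,
                     paste(co$signals$patient_id, co$signals$channel))
  expect_true(all(vapply(by_series, function(t) all(diff(t) > 0),
                         logical(1))))
  # same seed: byte-identical; different seed: different noise
  co2 <- generate_cohort(small_config())
  expect_identical(co$signals, co2$signals)
  expect_identical(co$microdialysis, co2$microdialysis)
  co3 <- generate_cohort(small_config(seed = 43))
  expect_false(identical(co$signals$value, co3$signals$value))
})

test_that("noiseless generation reproduces the latent profiles exactly", {
  co <- generate_cohort(noiseless_config())
  pat <- co$patients[1, ]
  prof <- default_profiles("infarction")
  md <- co$microdialysis
  glu <- md[md$analyte == "glutamate", ]
  latent <- evaluate_profile(prof$glutamate,
                             (glu$t_h - pat$detection_time_h) / 24)
  expect_equal(glu$concentration, latent, tolerance = 1e-12)
  # PtiO2 with zero noise equals its latent trajectory
  pt <- co$signals[co$signals$channel == "PtiO2", ]
  latent_pt <- evaluate_profile(prof$PtiO2,
                                (pt$t_s / 3600 - pat$detection_time_h) / 24)
  expect_equal(pt$value, latent_pt, tolerance = 1e-12)
})

test_that("coupled slow waves deliver the target windowed correlation", {
  # rho = 1: every complete window correlates perfectly
  w1 <- generate_coupled_slow_waves(1, n_samples = 300, seed = 1)
  p1 <- prx(w1$map, w1$icp)
  expect_true(all(abs(p1$value - 1) < 1e-12))
  # rho = 0 over many windows: mean PRx near 0 (Monte-Carlo tolerance)
  n <- 6 * 10000 + 30
  w0 <- generate_coupled_slow_waves(0, n_samples = n, seed = 2)
  p0 <- prx(w0$map, w0$icp)
  expect_gt(nrow(p0), 9999)
  expect_lt(abs(mean(p0$value)), 0.02)
  # rho = 0.5: mean PRx within 0.03 (small-sample r bias < 0.01)
  w5 <- generate_coupled_slow_waves(0.5, n_samples = n, seed = 3)
  p5 <- prx(w5$map, w5$icp)
  expect_lt(abs(mean(p5$value) - 0.5), 0.03)
  expect_error(generate_coupled_slow_waves(1.2, 100), "-1, 1")
})

test_that("microdialysis sampling follows the escalating schedule", {
  hours <- 0:23
  latent <- tibble::tibble(t_h = hours, lactate = 3000, pyruvate = 100,
                           glutamate = 22.2, glycerol = 80)
  # noiseless, no escalation: every 3 h over 24 h = 8 samples per analyte
  md <- sample_microdialysis(latent, md_noise_cv = 0, seed = 1)
  expect_equal(sum(md$analyte == "glutamate"), 8)
  expect_equal(unique(md$concentration[md$analyte == "glutamate"]), 22.2)
  # hypoxia escalation: PtiO2 < 20 densifies to hourly
  md2 <- sample_microdialysis(latent, ptio2_hourly = rep(15, 24),
                              md_noise_cv = 0, seed = 1)
  expect_equal(sum(md2$analyte == "glutamate"), 24)
  # LPR > 40 escalation: the trigger follows the measured ratio
  latent_hi <- dplyr::mutate(latent, lactate = 4500)
  md3 <- sample_microdialysis(latent_hi, md_noise_cv = 0, seed = 1)
  expect_equal(sum(md3$analyte == "glutamate"), 24) # armed from hour 0 on
  expect_error(sample_microdialysis(latent, md_noise_cv = -0.1), ">= 0")
})

test_that("mean-one lognormal noise preserves the latent mean", {
  x <- dcimon:::rlnorm_mean1(1e5, 0.4)
  expect_lt(abs(mean(100 * x) - 100), 1)
  expect_lt(abs(sd(x) / mean(x) - 0.4), 0.01)
})

test_that("missingness removes the transport gap and MCAR fraction", {
  df <- tibble::tibble(i = 1:10000)
  t_h <- seq_len(nrow(df))
  expect_identical(apply_missingness(df, t_h, anchor_h = NA,
                                     transport_gap_h = 0, mcar_rate = 0),
                   df)
  out <- apply_missingness(df, t_h, anchor_h = 5000, transport_gap_h = 3,
                           mcar_rate = 0)
  expect_false(any(abs(t_h[out$i] - 5000) < 1.5))
  out2 <- apply_missingness(df, t_h, anchor_h = NA, mcar_rate = 0.1,
                            seed = 9)
  expect_lt(abs(nrow(out2) / nrow(df) - 0.9), 0.01)
})

test_that("generated hypoxic hours carry hourly microdialysis density", {
  # pre-missingness cohort: the escalation schedule is driven by the
  # generated PtiO2 hourly means before any record deletion
  co <- generate_cohort(small_config(mcar_rate = 0, transport_gap_h = 0))
  sig <- co$signals[co$signals$channel == "PtiO2", ]
  md <- co$microdialysis
  for (pid in unique(co$patients$id)) {
    s <- sig[sig$patient_id == pid, ]
    hourly <- tapply(s$value, floor(s$t_s / 3600), mean)
    hypoxic_hours <- as.numeric(names(hourly))[hourly < 20]
    glu_hours <- md$t_h[md$patient_id == pid & md$analyte == "glutamate"]
    expect_true(all(hypoxic_hours %in% glu_hours))
  }
})
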