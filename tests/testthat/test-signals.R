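test_that("artifact filter removes implausible samples only", {
  sig <- tibble::tibble(
    patient_id = "P01",
    channel = rep("ICP", 100),
    t_s = seq(0, by = 10, length.out = 100),
    value = c(rep(12, 93), rep(-50, 7)))
  out <- artifact_filter(sig)
  expect_equal(nrow(out), 93)
  expect_true(all(out$value == 12))
  sig$value <- rep(12, 100)
  expect_identical(artifact_filter(sig), sig)
  one <- tibble::tibble(channel = "ICP", value = 300)
  expect_equal(nrow(artifact_filter(one)), 0)
  expect_error(artifact_filter(tibble::tibble(channel = "EEG", value = 1)),
               "EEG")
})

test_that("block averaging respects the half-open bins and coverage rule", {
  s <- tibble::tibble(t_s = 0:9, value = rep(80, 10))
  out <- block_average(s, block_s = 10, dt_s = 1)
  expect_equal(out$value, 80)
  expect_equal(out$t_s, 0)
  # ramp 1..10 -> mean 5.5
  s2 <- tibble::tibble(t_s = 0:9, value = 1:10)
  expect_equal(block_average(s2, 10, 1)$value, 5.5)
  # 4 of 10 nominal samples: below the 50% rule, block absent
  s3 <- tibble::tibble(t_s = c(0, 1, 2, 3), value = 1:4)
  expect_equal(nrow(block_average(s3, 10, 1)), 0)
  # 5 of 10 is enough
  s4 <- tibble::tibble(t_s = 0:4, value = rep(2, 5))
  expect_equal(block_average(s4, 10, 1)$value, 2)
})

test_that("PRx equals the textbook Pearson correlation on complete windows", {
  m <- (1:30)
  i <- (1:30)^2
  map <- tibble::tibble(t_s = seq(0, by = 10, length.out = 30), value = m)
  icp <- tibble::tibble(t_s = seq(0, by = 10, length.out = 30), value = i)
  p <- prx(map, icp)
  expect_equal(nrow(p), 1)
  expect_equal(p$value, pearson_oracle(m, i), tolerance = 1e-14)
  expect_equal(p$n_valid, 30L)
  expect_equal(p$t_s, 150) # centre of [0, 300)
})

test_that("PRx handles perfect linearity, sign, sparsity, degeneracy", {
  t10 <- seq(0, by = 10, length.out = 30)
  set.seed(5)
  m <- 90 + rnorm(30)
  map <- tibble::tibble(t_s = t10, value = m)
  expect_equal(prx(map, tibble::tibble(t_s = t10, value = 2 * m + 1))$value,
               1, tolerance = 1e-12)
  expect_equal(prx(map, tibble::tibble(t_s = t10, value = -m))$value,
               -1, tolerance = 1e-12)
  # 14 valid pairs: below the 50% missing-data limit, no value
  icp14 <- tibble::tibble(t_s = t10[1:14], value = m[1:14] + 1)
  expect_equal(nrow(prx(map, icp14)), 0)
  # 15 valid pairs: emitted
  icp15 <- tibble::tibble(t_s = t10[1:15], value = seq(1, 8, length.out = 15))
  expect_equal(nrow(prx(map, icp15)), 1)
  # zero-variance window yields no value, not zero
  flat <- tibble::tibble(t_s = t10, value = rep(12, 30))
  expect_equal(nrow(prx(map, flat)), 0)
  # off-grid timestamps are rejected
  expect_error(prx(tibble::tibble(t_s = c(0, 13), value = 1:2),
                   tibble::tibble(t_s = c(0, 10), value = 1:2)), "grid")
})

test_that("PRx is invariant to positive affine maps and window centres
           advance by 60 s", {
  t10 <- seq(0, by = 10, length.out = 96) # 4 windows
  set.seed(11)
  m <- 90 + cumsum(rnorm(96))
  i <- 12 + 0.4 * m + rnorm(96)
  map <- tibble::tibble(t_s = t10, value = m)
  icp <- tibble::tibble(t_s = t10, value = i)
  p0 <- prx(map, icp)
  expect_equal(diff(p0$t_s), rep(60, nrow(p0) - 1))
  p_scaled <- prx(dplyr::mutate(map, value = 3 * value + 7), icp)
  expect_equal(p0$value, p_scaled$value, tolerance = 1e-12)
  p_flip <- prx(dplyr::mutate(map, value = -2 * value), icp)
  expect_equal(p0$value, -p_flip$value, tolerance = 1e-12)
})

test_that("lactate/pyruvate ratio handles units and the undefined case", {
  expect_equal(compute_lpr(3000, 100), 30)
  expect_equal(compute_lpr(4000, 100), 40)
  expect_true(is.na(compute_lpr(3000, 0)))
  expect_true(is.na(compute_lpr(3000, -1)))
  expect_equal(compute_lpr(c(3000, 4000), c(100, 0)), c(30, NA))
})

test_that("hourly aggregation uses half-open bins and the chosen statistic", {
  x <- tibble::tibble(t_h = seq(0, 0.99, length.out = 12), value = 16)
  expect_equal(hourly_aggregate(x, "mean")$value, 16)
  expect_equal(hourly_aggregate(x, "median")$value, 16)
  x2 <- tibble::tibble(t_h = c(0.2, 0.8), value = c(0.1, 0.3))
  expect_equal(hourly_aggregate(x2, "mean")$value, 0.2)
  x3 <- tibble::tibble(t_h = c(2.1, 2.5, 2.9), value = c(1, 1, 10))
  expect_equal(hourly_aggregate(x3, "median")$value, 1)
  expect_equal(hourly_aggregate(x3, "mean")$value, 4)
  expect_equal(hourly_aggregate(x3, "mean")$abs_hour, 2)
  # bin boundary: sample at exactly t = 1 belongs to bin 1
  x4 <- tibble::tibble(t_h = c(0.5, 1), value = c(1, 9))
  expect_equal(hourly_aggregate(x4, "mean")$abs_hour, c(0, 1))
  expect_error(hourly_aggregate(x4, "mode"), "mode")
  # idempotence on already-hourly input
  h1 <- hourly_aggregate(x3, "mean")
  h2 <- hourly_aggregate(
    dplyr::rename(h1, t_h = "abs_hour"), "mean")
  expect_equal(h2$value, h1$value)
})

test_that("anchor alignment maps detection hour to rel_hour 0 per policy", {
  patients <- tibble::tibble(
    id = c("A", "B"), group = c("infarction", "no_dci"),
    detection_time_h = c(100.6, NA), anchor_h = c(100.6, 100.6))
  hourly <- tibble::tibble(
    patient_id = rep(c("A", "B"), each = 3),
    variable = "ICP",
    abs_hour = c(100, 52, 101, 180, 181, 100),
    value = 1:6)
  al <- align_to_anchor(hourly, patients, "median_detection")
  a <- al[al$patient_id == "A", ]
  expect_equal(a$rel_hour[a$value == 1], 0L)  # detection hour
  expect_equal(a$rel_hour[a$value == 2], -48L)
  b <- al[al$patient_id == "B", ]
  expect_equal(b$rel_hour[b$value == 4], 80L) # anchored at floor(100.6)
  # day-8 policy: anchor 180 h post ictus
  al8 <- align_to_anchor(hourly, patients, "day8_noon")
  b8 <- al8[al8$patient_id == "B", ]
  expect_equal(b8$rel_hour[b8$value == 4], 0L)
  expect_equal(b8$rel_hour[b8$value == 6], -80L)
  # missing detection time for an infarction patient is an error
  bad <- patients
  bad$detection_time_h[1] <- NA
  expect_error(align_to_anchor(hourly, bad), "detection time")
})

test_that("the hourly table equals the composition of the reference
           operations", {
  co <- cached_small_cohort()
  got <- build_hourly(co)
  # reference path: artifact filter -> block average -> PRx -> hourly
  sig <- block_average(artifact_filter(co$signals), block_s = 10, dt_s = 10)
  for (pid in co$patients$id[c(1, 5)]) {
    for (chan in c("MAP", "ICP", "PtiO2")) {
      s <- sig[sig$patient_id == pid & sig$channel == chan, ]
      ref <- hourly_aggregate(
        tibble::tibble(t_h = s$t_s / 3600, value = s$value), "mean")
      g <- got[got$patient_id == pid & got$variable == chan, ]
      expect_equal(g$abs_hour, ref$abs_hour)
      expect_equal(g$value, ref$value, tolerance = 1e-12)
    }
    sm <- sig[sig$patient_id == pid & sig$channel == "MAP", ]
    si <- sig[sig$patient_id == pid & sig$channel == "ICP", ]
    p <- prx(sm[, c("t_s", "value")], si[, c("t_s", "value")])
    ref_prx <- hourly_aggregate(
      tibble::tibble(t_h = p$t_s / 3600, value = p$value), "mean")
    g <- got[got$patient_id == pid & got$variable == "PRx", ]
    expect_equal(g$value, ref_prx$value, tolerance = 1e-12)
    # microdialysis analytes aggregate by median at bedside sample times
    md <- co$microdialysis
    glu <- md[md$patient_id == pid & md$analyte == "glutamate", ]
    ref_glu <- hourly_aggregate(
      tibble::tibble(t_h = glu$t_h, value = glu$concentration), "median")
    g <- got[got$patient_id == pid & got$variable == "glutamate", ]
    expect_equal(g$value, ref_glu$value, tolerance = 1e-12)
  }
})

test_that("microdialysis inclusion filter applies the 30% / 73-hour rule", {
  mk <- function(pid, variable, n) {
    hourly_rows(pid, variable, seq_len(n) - 40, rep(5, n))
  }
  # 22 of 73 hours = 0.301 >= 0.30: retained
  aligned <- dplyr::bind_rows(
    mk("keep22", "glutamate", 22),
    mk("drop10", "glutamate", 10),
    dplyr::bind_rows(mk("glyc30", "glutamate", 10),
                     mk("glyc30", "glycerol", 30)))
  kept <- md_inclusion_filter(aligned)
  expect_true("keep22" %in% kept)
  expect_false("drop10" %in% kept)
  expect_true("glyc30" %in% kept) # max over analytes decides
  # 21 of 73 = 0.288: excluded
  expect_false("keep21" %in% md_inclusion_filter(
    mk("keep21", "glutamate", 21)))
  # no data at all: excluded
  expect_length(md_inclusion_filter(aligned[0, ]), 0)
})
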