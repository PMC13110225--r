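#' Synthetic cohort generator configuration
#'
#' Bundles every knob of the synthetic aneurysmal-SAH monitoring cohort:
#' group sizes, infarct-detection timing, latent trajectory profiles, noise
#' levels, microdialysis sampling schedule, and missingness. The defaults
#' reproduce the study conditions: 24 infarction patients and 45 no-DCI
#' controls, infarct detection at a median of 7.5 days post ictus
#' (IQR 5.8-11.0, lognormal matched by moments), 10-second signal sampling,
#' 3-hourly microdialysis escalating to hourly during metabolic
#' deterioration (brain tissue hypoxia PtiO2 < 20 mmHg or
#' lactate/pyruvate ratio > 40), multiplicative lognormal microdialysis
#' noise (mean 1, CV 0.4), AR(1) brain-oxygen probe noise, correlated
#' MAP/ICP slow waves whose windowed correlation tracks the latent PRx
#' trajectory, mean-one lognormal between-patient amplitude heterogeneity,
#' Gaussian extremum-time jitter (sd 12 h), a 3-hour transport gap around
#' detection, and 10% missing-completely-at-random deletions.
#'
#' @param n_infarction,n_nodci Group sizes.
#' @param detection_day_median Median infarct-detection lag, days post ictus.
#' @param detection_day_iqr Length-2 interquartile range of the lag (days).
#' @param profiles Named list with elements `infarction` and `no_dci`, each a
#'   named list of [trajectory_profile()]s (see [default_profiles()]).
#' @param md_noise_cv Coefficient of variation of the multiplicative
#'   lognormal (mean-one) microdialysis assay/biology noise.
#' @param ptio2_noise_sd Marginal SD (mmHg) of the AR(1) PtiO2 noise.
#' @param ptio2_ar1_phi AR(1) coefficient of the PtiO2 noise at signal
#'   resolution.
#' @param icp_noise_sd,map_noise_sd Slow-wave amplitudes (mmHg) of the
#'   coupled ICP and MAP series.
#' @param between_patient_amp_cv CV of the lognormal (mean-one) per-patient
#'   amplitude multiplier applied to deviations from baseline.
#' @param peak_time_jitter_sd Between-patient extremum-time jitter, hours.
#' @param md_interval_h Routine microdialysis sampling interval, hours.
#' @param escalation_interval_h Sampling interval during metabolic
#'   deterioration, hours; must divide `md_interval_h`.
#' @param mcar_rate Per-record missing-completely-at-random deletion rate.
#' @param transport_gap_h Width (hours) of the all-modality gap centred on
#'   the detection/anchor time, emulating imaging-related transport.
#' @param signal_dt_s Signal sampling interval in seconds (10 s is the
#'   resolution the PRx computation consumes; 1 s exercises block
#'   averaging).
#' @param post_detection_d Days of monitoring simulated beyond detection.
#' @param seed Master integer seed; all randomness derives from it via
#'   per-patient, per-modality streams ([seed_streams()]).
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_infarction = 24,
                             n_nodci = 45,
                             detection_day_median = 7.5,
                             detection_day_iqr = c(5.8, 11.0),
                             profiles = list(infarction = default_profiles("infarction"),
                                             no_dci = default_profiles("no_dci")),
                             md_noise_cv = 0.4,
                             ptio2_noise_sd = 4,
                             ptio2_ar1_phi = 0.5,
                             icp_noise_sd = 2,
                             map_noise_sd = 5,
                             between_patient_amp_cv = 0.2,
                             peak_time_jitter_sd = 12,
                             md_interval_h = 3,
                             escalation_interval_h = 1,
                             mcar_rate = 0.1,
                             transport_gap_h = 3,
                             signal_dt_s = 10,
                             post_detection_d = 5,
                             seed = 1L) {
  check_count(n_infarction, "n_infarction", lower = 0L)
  check_count(n_nodci, "n_nodci", lower = 0L)
  if (n_infarction + n_nodci < 1L) stop_dcimon("cohort must have >= 1 patient")
  check_number(detection_day_median, "detection_day_median", lower = 0.1)
  check_number(md_noise_cv, "md_noise_cv", lower = 0)
  check_number(ptio2_noise_sd, "ptio2_noise_sd", lower = 0)
  check_number(ptio2_ar1_phi, "ptio2_ar1_phi", lower = -0.999, upper = 0.999)
  check_number(icp_noise_sd, "icp_noise_sd", lower = 0)
  check_number(map_noise_sd, "map_noise_sd", lower = 0)
  check_number(between_patient_amp_cv, "between_patient_amp_cv", lower = 0)
  check_number(peak_time_jitter_sd, "peak_time_jitter_sd", lower = 0)
  check_number(mcar_rate, "mcar_rate", lower = 0, upper = 1)
  check_number(transport_gap_h, "transport_gap_h", lower = 0)
  check_number(signal_dt_s, "signal_dt_s", lower = 0.5)
  check_number(md_interval_h, "md_interval_h", lower = 0.5)
  check_number(escalation_interval_h, "escalation_interval_h", lower = 0.5)
  if (md_interval_h %% escalation_interval_h != 0) {
    stop_dcimon("md_interval_h must be a multiple of escalation_interval_h")
  }
  check_count(seed, "seed", lower = 0L)
  structure(
    list(n_infarction = as.integer(n_infarction), n_nodci = as.integer(n_nodci),
         detection_day_median = detection_day_median,
         detection_day_iqr = detection_day_iqr,
         profiles = profiles,
         md_noise_cv = md_noise_cv,
         ptio2_noise_sd = ptio2_noise_sd, ptio2_ar1_phi = ptio2_ar1_phi,
         icp_noise_sd = icp_noise_sd, map_noise_sd = map_noise_sd,
         between_patient_amp_cv = between_patient_amp_cv,
         peak_time_jitter_sd = peak_time_jitter_sd,
         md_interval_h = md_interval_h,
         escalation_interval_h = escalation_interval_h,
         mcar_rate = mcar_rate, transport_gap_h = transport_gap_h,
         signal_dt_s = signal_dt_s, post_detection_d = post_detection_d,
         seed = as.integer(seed)),
    class = "generator_config"
  )
}

# lognormal with mean 1 and coefficient of variation cv
rlnorm_mean1 <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

# lognormal detection-day distribution matched by moments to a printed
# median and IQR (median fixes meanlog; the IQR ratio fixes sdlog)
detection_day_params <- function(median_d, iqr_d) {
  list(meanlog = log(median_d),
       sdlog = log(iqr_d[2] / iqr_d[1]) / (2 * qnorm(0.75)))
}

#' Generate coupled MAP/ICP slow-wave series with a target correlation
#'
#' Emits paired mean arterial pressure and intracranial pressure samples on
#' a regular grid whose expected windowed Pearson correlation equals the
#' supplied target `rho` at each step: a shared standard deviate `z` and an
#' independent deviate `w` give `MAP = map_mean + map_sd * z` and
#' `ICP = icp_mean + icp_sd * (rho * z + sqrt(1 - rho^2) * w)`. This is the
#' substrate on which the pressure reactivity index (PRx) is computed
#' downstream.
#'
#' @param rho Target correlation, scalar or one value per sample; in
#'   `[-1, 1]`.
#' @param n_samples Number of samples (ignored when `rho` is a vector).
#' @param dt_s Sampling interval, seconds.
#' @param map_mean,icp_mean Mean levels (mmHg); `icp_mean` may be a vector.
#' @param map_sd,icp_sd Slow-wave amplitudes (mmHg).
#' @param t0_s Time of the first sample, seconds.
#' @param seed Integer seed.
#' @return List with tibbles `map` and `icp`, columns `t_s`, `value`.
#' @export
generate_coupled_slow_waves <- function(rho, n_samples = length(rho),
                                        dt_s = 10, map_mean = 90,
                                        icp_mean = 15, map_sd = 5,
                                        icp_sd = 2, t0_s = 0, seed = 1L) {
  if (any(!is.finite(rho)) || any(abs(rho) > 1)) {
    stop_dcimon("`rho` must lie in [-1, 1]")
  }
  if (length(rho) == 1L) rho <- rep(rho, n_samples)
  n <- length(rho)
  t_s <- t0_s + (seq_len(n) - 1) * dt_s
  zw <- with_seed(seed, matrix(rnorm(2 * n), ncol = 2))
  z <- zw[, 1]
  w <- zw[, 2]
  map <- map_mean + map_sd * z
  icp <- icp_mean + icp_sd * (rho * z + sqrt(pmax(0, 1 - rho^2)) * w)
  list(map = tibble::tibble(t_s = t_s, value = map),
       icp = tibble::tibble(t_s = t_s, value = icp))
}

#' Sample microdialysis analytes on an escalating bedside schedule
#'
#' Draws bedside microdialysis measurements from latent hourly analyte
#' trajectories. Samples are taken every `md_interval_h` hours under
#' standard conditions and densified to `escalation_interval_h` during
#' metabolic deterioration: hours whose concurrent PtiO2 hourly mean is
#' below 20 mmHg, or following a measured lactate/pyruvate ratio above 40.
#' Measured concentrations carry multiplicative lognormal noise (mean 1,
#' CV `md_noise_cv`) and are clipped at zero.
#'
#' @param latent Data frame with integer column `t_h` (hours post ictus) and
#'   one column per analyte (`lactate`, `pyruvate`, `glutamate`,
#'   `glycerol`) holding the latent hourly concentration (umol/L).
#' @param ptio2_hourly Optional numeric vector aligned with `latent$t_h`:
#'   the concurrent PtiO2 hourly mean (mmHg); `NA` disables the hypoxia
#'   trigger for that hour.
#' @param md_interval_h,escalation_interval_h Routine and escalated
#'   sampling intervals, hours.
#' @param md_noise_cv Noise CV (>= 0).
#' @param hypoxia_threshold PtiO2 escalation trigger, mmHg.
#' @param lpr_threshold Lactate/pyruvate ratio escalation trigger.
#' @param seed Integer seed.
#' @return Tibble `(t_h, analyte, concentration)` in long format.
#' @export
sample_microdialysis <- function(latent, ptio2_hourly = NULL,
                                 md_interval_h = 3, escalation_interval_h = 1,
                                 md_noise_cv = 0.4,
                                 hypoxia_threshold = 20, lpr_threshold = 40,
                                 seed = 1L) {
  if (md_noise_cv < 0) stop_dcimon("md_noise_cv must be >= 0")
  analytes <- intersect(MD_ANALYTES, names(latent))
  if (length(analytes) == 0L) stop_dcimon("`latent` has no analyte columns")
  hours <- latent$t_h
  n <- length(hours)
  if (is.null(ptio2_hourly)) ptio2_hourly <- rep(NA_real_, n)
  # pre-draw noise on the full hourly grid so the emitted values at a given
  # hour do not depend on the escalation path taken to reach it
  noise <- with_seed(seed,
    matrix(rlnorm_mean1(n * length(analytes), md_noise_cv), nrow = n,
           dimnames = list(NULL, analytes)))

  routine <- hours %% md_interval_h == 0
  escalation_grid <- hours %% escalation_interval_h == 0
  hypoxic <- !is.na(ptio2_hourly) & ptio2_hourly < hypoxia_threshold

  emit <- logical(n)
  lpr_state <- FALSE # latest measured LPR exceeded the threshold
  for (i in seq_len(n)) {
    emit[i] <- routine[i] || (escalation_grid[i] && (hypoxic[i] || lpr_state))
    if (emit[i] && all(c("lactate", "pyruvate") %in% analytes)) {
      lac <- latent$lactate[i] * noise[i, "lactate"]
      pyr <- latent$pyruvate[i] * noise[i, "pyruvate"]
      lpr_state <- is.finite(lac / pyr) && pyr > 0 && lac / pyr > lpr_threshold
    }
  }

  idx <- which(emit)
  out <- lapply(analytes, function(a) {
    tibble::tibble(t_h = as.numeric(hours[idx]), analyte = a,
                   concentration = pmax(0, latent[[a]][idx] * noise[idx, a]))
  })
  dplyr::arrange(dplyr::bind_rows(out), .data$t_h, .data$analyte)
}

#' Apply transport-gap and MCAR missingness to a record table
#'
#' Removes (i) an all-modality gap of `transport_gap_h` hours centred on the
#' anchor time, emulating imaging-related patient transport around infarct
#' detection, and (ii) independent missing-completely-at-random deletions at
#' rate `mcar_rate`. Missing records are absent rows, never sentinel values.
#'
#' @param x Data frame of records.
#' @param time_h Numeric vector, time of each record in hours (same length
#'   as `nrow(x)`).
#' @param anchor_h Centre of the transport gap, hours (NA = no gap).
#' @param transport_gap_h Gap width in hours.
#' @param mcar_rate Deletion probability per record, in `[0, 1]`.
#' @param seed Integer seed.
#' @return `x` with the removed rows dropped; the input is not modified.
#' @export
apply_missingness <- function(x, time_h, anchor_h = NA, transport_gap_h = 3,
                              mcar_rate = 0.1, seed = 1L) {
  stopifnot(length(time_h) == nrow(x))
  check_number(mcar_rate, "mcar_rate", lower = 0, upper = 1)
  keep <- rep(TRUE, nrow(x))
  if (!is.na(anchor_h) && transport_gap_h > 0) {
    keep <- keep & !(abs(time_h - anchor_h) < transport_gap_h / 2)
  }
  if (mcar_rate > 0) {
    keep <- keep & with_seed(seed, runif(nrow(x)) >= mcar_rate)
  }
  x[keep, , drop = FALSE]
}

#' Generate a synthetic multimodal neuromonitoring cohort
#'
#' Produces a full synthetic cohort under a [generator_config()]: a patient
#' table, 10-second MAP/ICP/PtiO2 signal series from ictus to five days
#' after detection, and scheduled microdialysis samples. Each patient's
#' latent trajectories are the group profiles with a per-patient lognormal
#' amplitude multiplier on deviations from baseline and a Gaussian
#' extremum-time jitter shared across modalities (the same ischemic event
#' shifts all biomarkers together). Deviations are rescaled once per group
#' and biomarker so that the population-average trajectory — what a cohort
#' GAM estimates — hits the anchored extrema despite the jitter smearing
#' individual curves (see the methods vignette). Generation is byte-for-byte
#' deterministic under a fixed seed.
#'
#' @param config A [generator_config()].
#' @return A list of class `dcimon_cohort` with tibbles `patients`
#'   (`id`, `group`, `detection_time_h`, `anchor_h`), `signals`
#'   (`patient_id`, `channel`, `t_s`, `value`), `microdialysis`
#'   (`patient_id`, `t_h`, `analyte`, `concentration`), and the `config`.
#' @export
generate_cohort <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  n_inf <- config$n_infarction
  n_ctl <- config$n_nodci
  n_total <- n_inf + n_ctl
  master <- seed_streams(config$seed, 2)
  patient_seeds <- seed_streams(master[2], max(n_total, 1L))

  dd <- detection_day_params(config$detection_day_median,
                             config$detection_day_iqr)
  detection_h <- if (n_inf > 0) {
    with_seed(master[1], rlnorm(n_inf, dd$meanlog, dd$sdlog)) * 24
  } else {
    numeric(0)
  }
  pseudo_anchor <- if (n_inf > 0) median(detection_h) else
    config$detection_day_median * 24

  groups <- c(rep("infarction", n_inf), rep("no_dci", n_ctl))
  ids <- sprintf("P%02d", seq_len(n_total))
  anchors <- c(detection_h, rep(pseudo_anchor, n_ctl))
  patients <- tibble::tibble(
    id = ids, group = groups,
    detection_time_h = c(detection_h, rep(NA_real_, n_ctl)),
    anchor_h = anchors)

  jitter_sd_d <- config$peak_time_jitter_sd / 24
  biomarkers <- c("glutamate", "glycerol", "lactate", "pyruvate",
                  "PtiO2", "PRx", "ICP", "MAP")
  # population calibration (time shift + deviation scale); PRx anchors are
  # 24-h window medians, so its kernel includes the window average in
  # addition to the jitter
  calib <- lapply(c(infarction = "infarction", no_dci = "no_dci"), function(g) {
    lapply(setNames(nm = biomarkers), function(b) {
      calibrate_profile(config$profiles[[g]][[b]], jitter_sd_d,
                        window_d = if (b == "PRx") 1 else 0)
    })
  })

  sig_list <- vector("list", n_total)
  md_list <- vector("list", n_total)
  dt <- config$signal_dt_s

  for (i in seq_len(n_total)) {
    g <- groups[i]
    prof <- config$profiles[[g]]
    ps <- seed_streams(patient_seeds[i], 5)
    het <- with_seed(ps[1], {
      amps <- rlnorm_mean1(length(biomarkers), config$between_patient_amp_cv)
      jit <- rnorm(1, sd = jitter_sd_d)
      list(amps = setNames(amps, biomarkers), jitter_d = jit)
    })
    anchor_h <- anchors[i]
    curve <- function(b, t_rel_d) {
      p <- prof[[b]]
      cb <- calib[[g]][[b]]
      p$baseline + het$amps[[b]] * cb$k *
        (evaluate_profile(p, t_rel_d - cb$delta - het$jitter_d) -
           p$baseline)
    }

    span_s <- (anchor_h + config$post_detection_d * 24) * 3600
    t_s <- seq(0, span_s, by = dt)
    t_rel_d <- (t_s / 3600 - anchor_h) / 24

    rho <- pmin(0.999, pmax(-0.999, curve("PRx", t_rel_d)))
    waves <- generate_coupled_slow_waves(
      rho, dt_s = dt,
      map_mean = curve("MAP", t_rel_d), icp_mean = curve("ICP", t_rel_d),
      map_sd = config$map_noise_sd, icp_sd = config$icp_noise_sd,
      seed = ps[2])

    ptio2_latent <- curve("PtiO2", t_rel_d)
    ptio2 <- ptio2_latent
    if (config$ptio2_noise_sd > 0) {
      innov_sd <- config$ptio2_noise_sd * sqrt(1 - config$ptio2_ar1_phi^2)
      ar_noise <- with_seed(ps[3], as.numeric(
        stats::filter(rnorm(length(t_s), sd = innov_sd),
                      config$ptio2_ar1_phi, method = "recursive")))
      ptio2 <- ptio2 + ar_noise
    }

    sig <- tibble::tibble(
      patient_id = ids[i],
      channel = rep(SIGNAL_CHANNELS, each = length(t_s)),
      t_s = rep(t_s, times = 3),
      value = c(waves$map$value, waves$icp$value, ptio2))

    hours <- 0:floor(span_s / 3600)
    latent_md <- tibble::tibble(t_h = hours)
    for (a in MD_ANALYTES) {
      latent_md[[a]] <- curve(a, (hours - anchor_h) / 24)
    }
    hb <- floor(t_s / 3600)
    pt_sums <- rowsum(ptio2, hb, reorder = TRUE)
    pt_n <- rowsum(rep(1, length(hb)), hb, reorder = TRUE)
    pt_means <- setNames(pt_sums[, 1] / pt_n[, 1], rownames(pt_sums))
    ptio2_hourly <- as.numeric(pt_means[as.character(hours)])
    md <- sample_microdialysis(
      latent_md, ptio2_hourly = ptio2_hourly,
      md_interval_h = config$md_interval_h,
      escalation_interval_h = config$escalation_interval_h,
      md_noise_cv = config$md_noise_cv, seed = ps[4])
    md$patient_id <- ids[i]

    # transport gap around detection plus record-level MCAR, all modalities
    miss_seeds <- seed_streams(ps[5], 2)
    sig <- apply_missingness(sig, sig$t_s / 3600, anchor_h,
                             config$transport_gap_h, config$mcar_rate,
                             seed = miss_seeds[1])
    md <- apply_missingness(md, md$t_h, anchor_h,
                            config$transport_gap_h, config$mcar_rate,
                            seed = miss_seeds[2])

    sig_list[[i]] <- sig
    md_list[[i]] <- md[, c("patient_id", "t_h", "analyte", "concentration")]
  }

  col <- function(lst, nm) unlist(lapply(lst, `[[`, nm), use.names = FALSE)
  structure(
    list(patients = patients,
         signals = tibble::tibble(
           patient_id = col(sig_list, "patient_id"),
           channel = col(sig_list, "channel"),
           t_s = col(sig_list, "t_s"),
           value = col(sig_list, "value")),
         microdialysis = dplyr::bind_rows(md_list),
         config = config),
    class = "dcimon_cohort"
  )
}

#' @export
print.dcimon_cohort <- function(x, ...) {
  cat(sprintf("<dcimon_cohort: %d patients (%d infarction / %d no-DCI)>\n",
              nrow(x$patients), sum(x$patients$group == "infarction"),
              sum(x$patients$group == "no_dci")))
  cat(sprintf("  signals: %s rows; microdialysis: %s rows\n",
              format(nrow(x$signals), big.mark = ","),
              format(nrow(x$microdialysis), big.mark = ",")))
  invisible(x)
}

#' Write / read a cohort as delimited text tables
#'
#' `write_cohort()` writes `patients.csv`, `signals.csv` and
#' `microdialysis.csv` (UTF-8, header row, one record per line; missing =
#' absent row). `read_cohort()` reads them back.
#'
#' @param cohort A `dcimon_cohort`.
#' @param dir Output directory (created if needed).
#' @param signals Whether to write the (large) raw signal table.
#' @return `write_cohort()` the directory, invisibly; `read_cohort()` a
#'   `dcimon_cohort` (without config).
#' @export
write_cohort <- function(cohort, dir, signals = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(cohort$patients, file.path(dir, "patients.csv"),
            row.names = FALSE)
  if (signals) {
    write.csv(cohort$signals, file.path(dir, "signals.csv"),
              row.names = FALSE)
  }
  write.csv(cohort$microdialysis, file.path(dir, "microdialysis.csv"),
            row.names = FALSE)
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  out <- list(
    patients = tibble::as_tibble(
      read.csv(file.path(dir, "patients.csv"))),
    microdialysis = tibble::as_tibble(
      read.csv(file.path(dir, "microdialysis.csv"))))
  sig_path <- file.path(dir, "signals.csv")
  out$signals <- if (file.exists(sig_path)) {
    tibble::as_tibble(read.csv(sig_path))
  } else {
    NULL
  }
  structure(out, class = "dcimon_cohort")
}
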