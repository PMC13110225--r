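#' Default plausibility ranges for artifact filtering
#'
#' Conventional neuro-ICU plausibility bounds (mmHg) used to strip
#' calibration artifacts and signal disruptions; out-of-range samples
#' become gaps, never sentinel values.
#'
#' @return Named list of `c(lower, upper)` per channel.
#' @export
artifact_ranges <- function() {
  list(ICP = c(-10, 100), MAP = c(20, 250), PtiO2 = c(0, 150))
}

#' Remove implausible samples from a signal table
#'
#' @param signals Tibble with columns `channel`, `value` (and typically
#'   `patient_id`, `t_s`).
#' @param ranges Plausibility bounds, see [artifact_ranges()].
#' @return The table with out-of-range samples dropped.
#' @export
artifact_filter <- function(signals, ranges = artifact_ranges()) {
  chans <- unique(signals$channel)
  unknown <- setdiff(chans, names(ranges))
  if (length(unknown) > 0) {
    stop_dcimon("unknown channel(s): %s", paste(unknown, collapse = ", "))
  }
  lo <- unlist(lapply(ranges, `[`, 1))[signals$channel]
  hi <- unlist(lapply(ranges, `[`, 2))[signals$channel]
  keep <- is.finite(signals$value) & signals$value >= lo & signals$value <= hi
  signals[keep, , drop = FALSE]
}

#' Average a signal into fixed-width time blocks
#'
#' Aggregates raw samples into half-open blocks `[k*block_s, (k+1)*block_s)`
#' by arithmetic mean. A block is emitted only when it contains at least
#' `min_frac` of its nominal number of samples (`block_s / dt_s`); sparser
#' blocks become gaps. The pressure reactivity computation consumes
#' 10-second block means of MAP and ICP.
#'
#' @param signals Tibble with columns `t_s`, `value` and optional grouping
#'   columns `patient_id`, `channel`.
#' @param block_s Block width, seconds.
#' @param dt_s Nominal sampling interval of the input, seconds.
#' @param min_frac Minimum fraction of nominal samples per block.
#' @return Tibble on the block grid; `t_s` is the block start time.
#' @export
block_average <- function(signals, block_s = 10, dt_s = 1, min_frac = 0.5) {
  check_number(block_s, "block_s", lower = 1e-9)
  expected <- block_s / dt_s
  grp <- intersect(c("patient_id", "channel"), names(signals))
  if (dt_s == block_s) {
    # input already on the block grid: one sample per block, snap times
    out <- signals[, c(grp, "t_s", "value")]
    out$t_s <- floor(out$t_s / block_s) * block_s
    return(out)
  }
  out <- signals |>
    dplyr::mutate(.block = floor(.data$t_s / block_s)) |>
    dplyr::summarise(value = mean(.data$value), .n = dplyr::n(),
                     .by = dplyr::all_of(c(grp, ".block"))) |>
    dplyr::filter(.data$.n >= min_frac * expected) |>
    dplyr::mutate(t_s = .data$.block * block_s) |>
    dplyr::select(dplyr::all_of(c(grp, "t_s", "value"))) |>
    dplyr::arrange(dplyr::across(dplyr::all_of(c(grp, "t_s"))))
  out
}

#' Pressure reactivity index from 10-second MAP/ICP averages
#'
#' Computes PRx as a moving Pearson correlation between paired 10-second
#' averages of mean arterial pressure and intracranial pressure over a
#' 5-minute sliding window (30 grid slots) advancing by 60 s (80% overlap).
#' A window yields a value only if at least `min_valid` slots (default 15,
#' the 50% missing-data limit) have both channels present and both windowed
#' variances are positive; degenerate or sparse windows become gaps rather
#' than zeros.
#'
#' @param map,icp Tibbles with columns `t_s`, `value` for one patient, both
#'   on the same regular `dt_s` grid (gaps = absent rows).
#' @param dt_s Grid interval, seconds.
#' @param window_s Window width, seconds.
#' @param step_s Window advance, seconds.
#' @param min_valid Minimum complete pairs per window.
#' @return Tibble `(t_s, value, n_valid)`; `t_s` is the window centre.
#' @export
prx <- function(map, icp, dt_s = 10, window_s = 300, step_s = 60,
                min_valid = 15) {
  for (s in list(map, icp)) {
    if (any(s$t_s %% dt_s != 0)) {
      stop_dcimon("series timestamps are not on the common %g-s grid", dt_s)
    }
  }
  width <- as.integer(round(window_s / dt_s))
  step <- as.integer(round(step_s / dt_s))
  k0 <- min(map$t_s[1], icp$t_s[1]) / dt_s
  k1 <- max(max(map$t_s), max(icp$t_s)) / dt_s
  n <- as.integer(k1 - k0 + 1)
  x <- rep(NA_real_, n)
  y <- rep(NA_real_, n)
  x[map$t_s / dt_s - k0 + 1] <- map$value
  y[icp$t_s / dt_s - k0 + 1] <- icp$value
  res <- rolling_pearson_cpp(x, y, width, step, as.integer(min_valid))
  tibble::tibble(
    t_s = (k0 + res$start + width / 2) * dt_s,
    value = res$r,
    n_valid = res$n_valid)
}

#' Lactate-to-pyruvate ratio
#'
#' `LPR = lactate / pyruvate` (both umol/L, ratio dimensionless), the
#' marker of anaerobic versus aerobic energy production; values above 40
#' indicate metabolic deterioration. Non-positive pyruvate yields a missing
#' value (the ratio is undefined), not an error.
#'
#' @param lactate,pyruvate Concentrations in umol/L.
#' @return Numeric vector of ratios, `NA` where pyruvate is non-positive.
#' @export
compute_lpr <- function(lactate, pyruvate) {
  ifelse(is.finite(pyruvate) & pyruvate > 0, lactate / pyruvate, NA_real_)
}

#' Aggregate a variable into hourly bins
#'
#' Summarises observations into half-open hourly bins `[h, h+1)` using the
#' chosen statistic; bins with no observations are absent. High-frequency
#' signals are summarised by their mean and skewed microdialysis analytes
#' by their median by default (see [default_hourly_stats()]).
#'
#' @param x Tibble with columns `t_h` (hours), `value`, and optional
#'   grouping columns `patient_id`, `variable`.
#' @param stat `"mean"` or `"median"`.
#' @return Tibble with `abs_hour` (integer bin start) and `value`.
#' @export
hourly_aggregate <- function(x, stat = c("mean", "median")) {
  if (is.character(stat) && length(stat) == 1L &&
      !stat %in% c("mean", "median")) {
    stop_dcimon("unknown hourly statistic '%s'", stat)
  }
  stat <- match.arg(stat)
  f <- if (stat == "mean") mean else median
  grp <- intersect(c("patient_id", "variable"), names(x))
  x |>
    dplyr::mutate(abs_hour = floor(.data$t_h)) |>
    dplyr::summarise(value = f(.data$value),
                     .by = dplyr::all_of(c(grp, "abs_hour"))) |>
    dplyr::arrange(dplyr::across(dplyr::all_of(c(grp, "abs_hour"))))
}

#' Default hourly summary statistic per variable
#'
#' Mean for the continuously sampled signals (MAP, ICP, PtiO2, PRx), median
#' for the skewed microdialysis analytes and their ratio.
#'
#' @return Named character vector.
#' @export
default_hourly_stats <- function() {
  c(MAP = "mean", ICP = "mean", PtiO2 = "mean", PRx = "mean",
    lactate = "median", pyruvate = "median", glutamate = "median",
    glycerol = "median", LPR = "median")
}

#' Build the event-aligned hourly table for a cohort
#'
#' Runs the full signal stage: artifact filtering, 10-s block averaging,
#' PRx moving correlation, lactate/pyruvate ratio computation, and hourly
#' aggregation of every modality into one long table of
#' `(patient_id, variable, abs_hour, value)` rows. Use [align_to_anchor()]
#' to convert absolute hours into event time.
#'
#' @param cohort A `dcimon_cohort` (or a list with `signals` and
#'   `microdialysis` tibbles).
#' @param stats Named statistic per variable, see [default_hourly_stats()].
#' @param dt_s Raw signal sampling interval, seconds.
#' @return Hourly tibble in absolute hours.
#' @export
build_hourly <- function(cohort, stats = default_hourly_stats(),
                         dt_s = NULL) {
  if (is.null(dt_s)) {
    dt_s <- if (!is.null(cohort$config)) cohort$config$signal_dt_s else 10
  }
  sig_hourly <- hourly_from_signals(cohort$signals, dt_s, stats)

  md <- cohort$microdialysis
  md_rows <- md |>
    dplyr::transmute(patient_id = .data$patient_id,
                     variable = .data$analyte, t_h = .data$t_h,
                     value = .data$concentration)
  lpr_rows <- md |>
    tidyr::pivot_wider(names_from = "analyte",
                       values_from = "concentration") |>
    dplyr::filter(!is.na(.data$lactate), !is.na(.data$pyruvate)) |>
    dplyr::mutate(value = compute_lpr(.data$lactate, .data$pyruvate)) |>
    dplyr::filter(!is.na(.data$value)) |>
    dplyr::transmute(patient_id = .data$patient_id, variable = "LPR",
                     t_h = .data$t_h, value = .data$value)

  md_long <- dplyr::bind_rows(md_rows, lpr_rows)
  md_hourly <- dplyr::bind_rows(
    lapply(split(md_long, md_long$variable), function(d) {
      st <- stats[[d$variable[1]]]
      if (is.null(st)) st <- "median"
      hourly_aggregate(d, stat = st)
    }))

  dplyr::bind_rows(sig_hourly, md_hourly) |>
    dplyr::arrange(.data$patient_id, .data$variable, .data$abs_hour)
}

# Signal-side hourly aggregation on contiguous per-patient blocks: same
# semantics as artifact_filter + block_average + prx + hourly_aggregate,
# evaluated with vector arithmetic to keep large cohorts inside desk-scale
# memory/time. (The composed operations remain the reference semantics and
# the unit tests assert agreement.)
hourly_from_signals <- function(signals, dt_s, stats) {
  ranges <- artifact_ranges()
  stat_fun <- function(variable) {
    st <- stats[[variable]]
    if (is.null(st)) st <- "mean"
    if (st == "mean") mean else median
  }
  runs <- rle(signals$patient_id)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  out <- vector("list", length(runs$values))
  for (k in seq_along(runs$values)) {
    pid <- runs$values[k]
    idx <- starts[k]:ends[k]
    ch <- signals$channel[idx]
    tt <- signals$t_s[idx]
    vv <- signals$value[idx]
    unknown <- setdiff(unique(ch), names(ranges))
    if (length(unknown) > 0) {
      stop_dcimon("unknown channel(s): %s", paste(unknown, collapse = ", "))
    }
    blocks <- list()
    rows <- list()
    for (channel in unique(ch)) {
      sel <- ch == channel
      t_c <- tt[sel]
      v_c <- vv[sel]
      rng <- ranges[[channel]]
      keep <- is.finite(v_c) & v_c >= rng[1] & v_c <= rng[2]
      t_c <- t_c[keep]
      v_c <- v_c[keep]
      if (length(t_c) == 0) next
      if (dt_s != 10) {
        b <- floor(t_c / 10)
        cnt <- rowsum(rep(1, length(b)), b, reorder = TRUE)
        sums <- rowsum(v_c, b, reorder = TRUE)
        ok <- cnt[, 1] >= 0.5 * (10 / dt_s)
        t_c <- as.numeric(rownames(cnt))[ok] * 10
        v_c <- (sums[, 1] / cnt[, 1])[ok]
      }
      blocks[[channel]] <- list(t_s = t_c, value = v_c)
      f <- stat_fun(channel)
      h <- floor(t_c / 3600)
      agg <- if (identical(f, mean)) {
        s <- rowsum(v_c, h, reorder = TRUE)
        n <- rowsum(rep(1, length(h)), h, reorder = TRUE)
        setNames(s[, 1] / n[, 1], rownames(s))
      } else {
        tapply(v_c, h, f)
      }
      rows[[channel]] <- tibble::tibble(
        patient_id = pid, variable = channel,
        abs_hour = as.numeric(names(agg)), value = as.numeric(agg))
    }
    if (!is.null(blocks$MAP) && !is.null(blocks$ICP)) {
      p <- prx(tibble::as_tibble(blocks$MAP), tibble::as_tibble(blocks$ICP),
               dt_s = 10)
      if (nrow(p) > 0) {
        f <- stat_fun("PRx")
        h <- floor(p$t_s / 3600)
        agg <- tapply(p$value, h, f)
        rows$PRx <- tibble::tibble(
          patient_id = pid, variable = "PRx",
          abs_hour = as.numeric(names(agg)), value = as.numeric(agg))
      }
    }
    out[[k]] <- dplyr::bind_rows(rows)
  }
  dplyr::bind_rows(out)
}

#' Align an hourly table to the infarct-detection anchor
#'
#' Re-indexes hourly bins to event time: `rel_hour` 0 is the hour containing
#' the detection instant (infarction patients are always anchored at their
#' own detection hour). Control (no-DCI) patients are anchored per policy:
#' `"median_detection"` (default) uses the median detection hour of the
#' infarction group; `"day8_noon"` anchors at 180 h post ictus (noon of the
#' eighth post-ictus day); `"per_patient_detection"` requires an `anchor_h`
#' per patient. Rows outside `rel_hour` in `[-240, 120]` are dropped.
#'
#' @param hourly Output of [build_hourly()] (columns `patient_id`,
#'   `variable`, `abs_hour`, `value`).
#' @param patients Patient table with `id`, `group`, `detection_time_h`
#'   (and `anchor_h` for the per-patient policy).
#' @param anchor_policy Anchoring policy for the control group.
#' @param rel_range Retained event-time range in hours.
#' @return Hourly tibble with `rel_hour` replacing `abs_hour`.
#' @export
align_to_anchor <- function(hourly, patients,
                            anchor_policy = c("median_detection", "day8_noon",
                                              "per_patient_detection"),
                            rel_range = c(-240, 120)) {
  anchor_policy <- match.arg(anchor_policy)
  inf <- patients[patients$group == "infarction", ]
  if (nrow(inf) > 0 && anyNA(inf$detection_time_h)) {
    stop_dcimon("missing detection time for infarction patient(s): %s",
                paste(inf$id[is.na(inf$detection_time_h)], collapse = ", "))
  }
  anchor <- numeric(nrow(patients))
  is_inf <- patients$group == "infarction"
  anchor[is_inf] <- floor(patients$detection_time_h[is_inf])
  ctl_anchor <- switch(anchor_policy,
    median_detection = {
      if (nrow(inf) == 0) stop_dcimon(
        "median_detection policy needs at least one infarction patient")
      floor(median(inf$detection_time_h))
    },
    day8_noon = 7 * 24 + 12,
    per_patient_detection = NA)
  if (anchor_policy == "per_patient_detection") {
    if (!"anchor_h" %in% names(patients)) {
      stop_dcimon("per_patient_detection policy requires an `anchor_h` column")
    }
    anchor[!is_inf] <- floor(patients$anchor_h[!is_inf])
  } else {
    anchor[!is_inf] <- ctl_anchor
  }
  amap <- setNames(anchor, patients$id)
  hourly |>
    dplyr::mutate(rel_hour = as.integer(.data$abs_hour -
                                          amap[.data$patient_id])) |>
    dplyr::filter(.data$rel_hour >= rel_range[1],
                  .data$rel_hour <= rel_range[2]) |>
    dplyr::select(-"abs_hour") |>
    dplyr::relocate("patient_id", "variable", "rel_hour", "value")
}

#' Microdialysis data-density inclusion filter
#'
#' A patient is retained when at least `min_frac` of the expected hourly
#' microdialysis bins in the analysis window carry a value for glutamate or
#' glycerol (the better-covered analyte counts).
#'
#' @param aligned Aligned hourly table ([align_to_anchor()]).
#' @param window Analysis window in relative hours (default the 73-hour
#'   window from -48 to +24).
#' @param min_frac Minimum observed fraction (default 0.30).
#' @param analytes Analytes eligible to satisfy the criterion.
#' @return Character vector of retained patient ids.
#' @export
md_inclusion_filter <- function(aligned, window = c(-48, 24),
                                min_frac = 0.30,
                                analytes = c("glutamate", "glycerol")) {
  check_number(min_frac, "min_frac", lower = 1e-12, upper = 1)
  n_expected <- window[2] - window[1] + 1
  counts <- aligned |>
    dplyr::filter(.data$variable %in% analytes,
                  .data$rel_hour >= window[1], .data$rel_hour <= window[2],
                  !is.na(.data$value)) |>
    dplyr::distinct(.data$patient_id, .data$variable, .data$rel_hour) |>
    dplyr::count(.data$patient_id, .data$variable)
  if (nrow(counts) == 0) return(character(0))
  ok <- counts |>
    dplyr::summarise(frac = max(.data$n) / n_expected,
                     .by = "patient_id") |>
    dplyr::filter(.data$frac >= min_frac)
  sort(unique(ok$patient_id))
}
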