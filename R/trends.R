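#' Fit a population trajectory GAM for one variable and group
#'
#' Estimates the cohort-level event-time trajectory of one variable by
#' pooling all patients' hourly observations and fitting a penalized
#' thin-plate regression spline of value on relative hour, with the
#' smoothing parameter selected by (fast) REML. Residual temporal
#' autocorrelation is handled by a two-step AR(1) correction: the model is
#' fitted once, a lag-1 autocorrelation is estimated from consecutive-hour
#' residual pairs within patients, and the model is refitted with that
#' AR(1) working correlation (disable with `ar1 = FALSE`). Predictions and
#' pointwise 95% confidence bands are evaluated on a 0.1-hour grid over the
#' data support intersected with `grid_range`.
#'
#' @param rows Tibble with columns `patient_id`, `rel_hour`, `value` for a
#'   single variable and group (e.g. a filtered [align_to_anchor()] table).
#' @param variable,group Labels carried into the fit (used in messages and
#'   downstream reports).
#' @param basis_dim Spline basis dimension (upper bound on the effective
#'   degrees of freedom; reduced automatically when the data have fewer
#'   unique hours).
#' @param ar1 Apply the two-step AR(1) residual correction.
#' @param grid_range Prediction grid limits, relative hours.
#' @param grid_dh Prediction grid spacing, hours.
#' @param ci_mult Confidence-band multiplier (1.96 for 95%).
#' @return An object of class `gam_fit`: the mgcv fit plus `grid_h`,
#'   `mean`, `se`, `ci_lo`, `ci_hi`, the estimated AR(1) coefficient
#'   `ar1_phi`, and metadata.
#' @export
fit_gam <- function(rows, variable = "value", group = "all",
                    basis_dim = 20, ar1 = TRUE,
                    grid_range = c(-240, 120), grid_dh = 0.1,
                    ci_mult = 1.96) {
  rows <- rows[is.finite(rows$value) & is.finite(rows$rel_hour), ]
  span <- diff(range(rows$rel_hour))
  if (nrow(rows) < 50 || span < 48) {
    stop_dcimon("insufficient data to fit %s/%s: %d observations over %.0f h",
                variable, group, nrow(rows), span)
  }
  d <- rows[order(rows$patient_id, rows$rel_hour), ]
  n_unique <- length(unique(d$rel_hour))
  k <- max(5L, min(as.integer(basis_dim), n_unique - 1L))

  if (sd(d$value) < 1e-10) {
    # degenerate case: a constant response has a constant smooth
    return(constant_gam_fit(d, variable, group, grid_range, grid_dh, k))
  }
  spline_fit <- function(rho = NULL, ar_start = NULL) {
    # fREML can diverge on zero-residual (exactly representable) inputs;
    # fall back to gam/REML, then GCV
    tryCatch(
      if (is.null(rho)) {
        mgcv::bam(value ~ s(rel_hour, bs = "tp", k = k), data = d,
                  method = "fREML")
      } else {
        mgcv::bam(value ~ s(rel_hour, bs = "tp", k = k), data = d,
                  method = "fREML", rho = rho, AR.start = ar_start)
      },
      error = function(e) tryCatch(
        mgcv::gam(value ~ s(rel_hour, bs = "tp", k = k), data = d,
                  method = "REML"),
        error = function(e2) mgcv::gam(
          value ~ s(rel_hour, bs = "tp", k = k), data = d,
          method = "GCV.Cp")))
  }
  fit0 <- spline_fit()
  phi <- 0
  fit <- fit0
  if (isTRUE(ar1)) {
    r <- stats::residuals(fit0)
    same_pat <- d$patient_id[-1] == d$patient_id[-nrow(d)]
    lag1 <- diff(d$rel_hour) == 1
    idx <- which(same_pat & lag1)
    if (length(idx) >= 10 && sd(r) > 1e-10) {
      phi <- suppressWarnings(stats::cor(r[idx], r[idx + 1]))
      if (!is.finite(phi)) phi <- 0
      phi <- max(-0.95, min(0.95, phi))
      if (abs(phi) > 0.05) {
        fit <- spline_fit(rho = phi, ar_start = !duplicated(d$patient_id))
      }
    }
  }

  lo <- max(grid_range[1], min(d$rel_hour))
  hi <- min(grid_range[2], max(d$rel_hour))
  grid_h <- seq(lo, hi, by = grid_dh)
  pr <- predict(fit, newdata = data.frame(rel_hour = grid_h), se.fit = TRUE)
  structure(
    list(variable = variable, group = group, fit = fit,
         basis_dim = k, smoothing_param = as.numeric(fit$sp),
         ar1_phi = phi, n_obs = nrow(d),
         grid_h = grid_h, mean = as.numeric(pr$fit),
         se = as.numeric(pr$se.fit),
         ci_lo = as.numeric(pr$fit - ci_mult * pr$se.fit),
         ci_hi = as.numeric(pr$fit + ci_mult * pr$se.fit)),
    class = "gam_fit")
}

# Exact fit for a constant response: mean = the constant, se from the
# intercept-only model.
constant_gam_fit <- function(d, variable, group, grid_range, grid_dh, k) {
  lo <- max(grid_range[1], min(d$rel_hour))
  hi <- min(grid_range[2], max(d$rel_hour))
  grid_h <- seq(lo, hi, by = grid_dh)
  mu <- mean(d$value)
  se <- sd(d$value) / sqrt(nrow(d))
  structure(
    list(variable = variable, group = group, fit = NULL,
         basis_dim = k, smoothing_param = Inf, ar1_phi = 0,
         n_obs = nrow(d), grid_h = grid_h,
         mean = rep(mu, length(grid_h)), se = rep(se, length(grid_h)),
         ci_lo = rep(mu - 1.96 * se, length(grid_h)),
         ci_hi = rep(mu + 1.96 * se, length(grid_h))),
    class = "gam_fit")
}

#' @export
print.gam_fit <- function(x, ...) {
  cat(sprintf("<gam_fit: %s / %s>\n", x$variable, x$group))
  cat(sprintf("  n = %d, k = %d, AR(1) phi = %.3f, grid [%g, %g] h\n",
              x$n_obs, x$basis_dim, x$ar1_phi, min(x$grid_h), max(x$grid_h)))
  invisible(x)
}

#' First derivative of a fitted trajectory
#'
#' Central finite differences of the fitted mean on the prediction grid
#' (one-sided at the ends); basis-agnostic, with error bounded by the grid
#' spacing. Units are variable units per hour; the per-day column is the
#' same slope scaled by 24.
#'
#' @param fit A [fit_gam()] object.
#' @return Tibble `(grid_h, slope_per_h, slope_per_d)`.
#' @export
derivative <- function(fit) {
  stopifnot(inherits(fit, "gam_fit"))
  g <- fit$grid_h
  m <- fit$mean
  n <- length(g)
  dh <- g[2] - g[1]
  sl <- numeric(n)
  sl[1] <- (m[2] - m[1]) / dh
  sl[n] <- (m[n] - m[n - 1]) / dh
  if (n > 2) sl[2:(n - 1)] <- (m[3:n] - m[1:(n - 2)]) / (2 * dh)
  tibble::tibble(grid_h = g, slope_per_h = sl, slope_per_d = sl * 24)
}

#' Locate the trough and peak of a fitted trajectory
#'
#' The trough is the lowest fitted value on the trough search interval
#' (default the pre-detection period `[-240, 0]` h); the peak is the
#' highest fitted value from the trough onward (default up to +120 h).
#' Ties are broken toward the time closest to detection.
#'
#' @param fit A [fit_gam()] object.
#' @param trough_search,peak_search Search intervals in relative hours;
#'   `peak_search = NULL` means `[trough_time, 120]`.
#' @return A list of class `trough_peak` with `trough_time_h`,
#'   `trough_value`, `peak_time_h`, `peak_value`.
#' @export
find_trough_peak <- function(fit, trough_search = c(-240, 0),
                             peak_search = NULL) {
  stopifnot(inherits(fit, "gam_fit"))
  pick <- function(values, grid, decreasing) {
    target <- if (decreasing) max(values) else min(values)
    cand <- which(abs(values - target) <= 1e-12 * max(1, abs(target)))
    cand[which.min(abs(grid[cand]))]
  }
  in_t <- fit$grid_h >= trough_search[1] & fit$grid_h <= trough_search[2]
  if (!any(in_t)) stop_dcimon("empty trough search interval")
  gt <- fit$grid_h[in_t]
  vt <- fit$mean[in_t]
  it <- pick(vt, gt, decreasing = FALSE)
  trough_time <- gt[it]
  trough_value <- vt[it]

  if (is.null(peak_search)) peak_search <- c(trough_time, 120)
  in_p <- fit$grid_h >= peak_search[1] & fit$grid_h <= peak_search[2]
  if (!any(in_p)) stop_dcimon("empty peak search interval")
  gp <- fit$grid_h[in_p]
  vp <- fit$mean[in_p]
  ip <- pick(vp, gp, decreasing = TRUE)

  structure(
    list(trough_time_h = trough_time, trough_value = trough_value,
         peak_time_h = gp[ip], peak_value = vp[ip],
         trough_search = trough_search, peak_search = peak_search),
    class = "trough_peak")
}

#' @export
print.trough_peak <- function(x, ...) {
  cat(sprintf("<trough_peak: trough %.4g @ %+.1f h, peak %.4g @ %+.1f h>\n",
              x$trough_value, x$trough_time_h, x$peak_value, x$peak_time_h))
  invisible(x)
}

#' Per-patient medians of 24-hour windows around the trough and peak
#'
#' For each patient, takes the median of the variable over the 24-hour
#' window centred on the cohort trough and the window centred on the cohort
#' peak (`[centre - width/2, centre + width/2)`); a patient contributes a
#' pair only when both windows hold at least `min_obs` hourly values. For
#' trajectories without a clear post-detection peak (brain tissue oxygen),
#' `peak_window` can override the second window with an explicit interval
#' such as the pooled 5-day post-detection window `c(0, 120)`.
#'
#' @param rows Aligned hourly rows for one variable (columns `patient_id`,
#'   `rel_hour`, `value`).
#' @param trough_time_h,peak_time_h Window centres, relative hours.
#' @param width_h Window width (hours).
#' @param min_obs Minimum observations per window.
#' @param peak_window Optional explicit `c(lo, hi)` for the second window.
#' @return Tibble `(patient_id, trough_median, peak_median, n_trough,
#'   n_peak)`, one row per contributing patient.
#' @export
extract_paired_windows <- function(rows, trough_time_h, peak_time_h,
                                   width_h = 24, min_obs = 6,
                                   peak_window = NULL) {
  check_number(width_h, "width_h", lower = 1e-9)
  tw <- c(trough_time_h - width_h / 2, trough_time_h + width_h / 2)
  pw <- if (is.null(peak_window)) {
    c(peak_time_h - width_h / 2, peak_time_h + width_h / 2)
  } else {
    peak_window
  }
  win_stat <- function(d, w) {
    v <- d$value[d$rel_hour >= w[1] & d$rel_hour < w[2] & !is.na(d$value)]
    c(md = median(v), n = length(v))
  }
  out <- lapply(split(rows, rows$patient_id), function(d) {
    a <- win_stat(d, tw)
    b <- win_stat(d, pw)
    tibble::tibble(patient_id = d$patient_id[1],
                   trough_median = a[["md"]], peak_median = b[["md"]],
                   n_trough = as.integer(a[["n"]]),
                   n_peak = as.integer(b[["n"]]))
  })
  res <- dplyr::bind_rows(out)
  res[res$n_trough >= min_obs & res$n_peak >= min_obs, , drop = FALSE]
}

#' Paired trough-versus-peak comparison
#'
#' Runs the exact Wilcoxon signed-rank test ([paired_wilcoxon()]) on the
#' per-patient window medians from [extract_paired_windows()].
#'
#' @param pairs Output of [extract_paired_windows()].
#' @return List of class `paired_window_result`: `n_pairs`,
#'   `median_difference` (peak minus trough), `statistic`, `p_value`, and
#'   the pairs table.
#' @export
paired_window_test <- function(pairs) {
  w <- paired_wilcoxon(pairs$peak_median, pairs$trough_median)
  structure(
    list(n_pairs = nrow(pairs),
         median_difference = w$median_difference,
         statistic = w$statistic, p_value = w$p_value, pairs = pairs),
    class = "paired_window_result")
}

#' @export
print.paired_window_result <- function(x, ...) {
  cat(sprintf(
    "<paired windows: n = %d, median difference %.4g, V = %g, p = %.4g>\n",
    x$n_pairs, x$median_difference, x$statistic, x$p_value))
  invisible(x)
}

#' Wilcoxon signed-rank test for paired data with an exact null
#'
#' Two-sided signed-rank test of paired differences. Zero differences are
#' dropped; midranks handle ties. For `n <= exact_limit` non-zero pairs the
#' p-value comes from the exact null distribution of the positive-rank sum
#' under all `2^n` sign assignments (computed by generating-function
#' convolution over the observed, possibly tied, ranks); beyond that a
#' normal approximation with continuity and tie corrections is used. The
#' two-sided p-value is `min(1, 2 * min(P(W <= w), P(W >= w)))`.
#'
#' @param x,y Paired samples (`y = NULL` treats `x` as differences).
#' @param exact_limit Largest n for the exact null.
#' @return List with `statistic` (positive-rank sum `V`), `p_value`,
#'   `n_pairs` (non-zero pairs), `median_difference` (median of all paired
#'   differences, zeros included), and `method`.
#' @export
paired_wilcoxon <- function(x, y = NULL, exact_limit = 25) {
  d <- if (is.null(y)) x else x - y
  d <- d[is.finite(d)]
  if (length(d) == 0) stop_dcimon("no finite paired differences")
  med_diff <- median(d)
  dz <- d[d != 0]
  n <- length(dz)
  if (n == 0) {
    return(list(statistic = 0, p_value = 1, n_pairs = 0,
                median_difference = med_diff, method = "degenerate"))
  }
  r <- rank(abs(dz))
  w <- sum(r[dz > 0])
  if (n <= exact_limit) {
    # exact null: distribution of the positive-rank sum over all 2^n sign
    # assignments; doubled ranks make midranks integral
    r2 <- as.integer(round(2 * r))
    probs <- c(1)
    for (ri in r2) {
      padded <- c(probs, rep(0, ri))
      shifted <- c(rep(0, ri), probs)
      probs <- (padded + shifted) / 2
    }
    w2 <- as.integer(round(2 * w))
    cdf_le <- sum(probs[seq_len(w2 + 1)])
    cdf_ge <- sum(probs[(w2 + 1):length(probs)])
    p <- min(1, 2 * min(cdf_le, cdf_ge))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "normal approximation"
  }
  list(statistic = w, p_value = p, n_pairs = n,
       median_difference = med_diff, method = method)
}
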