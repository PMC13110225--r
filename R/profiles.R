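#' Latent biomarker trajectory profiles
#'
#' A `trajectory_profile` describes the latent, noise-free time course of one
#' biomarker in event time (days relative to infarct detection; negative =
#' before detection). Three functional forms are supported:
#'
#' * `"asym_gaussian"` — baseline plus a Gaussian bump with different rise
#'   and fall widths: `baseline + (extremum - baseline) *
#'   exp(-(t - t0)^2 / (2 sigma^2))` with `sigma = rise_scale_d` for `t < t0`
#'   and `fall_scale_d` afterwards. Used for transient surges such as the
#'   peri-infarction glutamate excursion.
#' * `"knot_interpolant"` — a shape-preserving monotone piecewise cubic
#'   (Fritsch-Carlson) through supplied `(time_d, value)` knots, constant
#'   beyond the outermost knots. Used for trajectories printed as a sequence
#'   of plateau / trough / peak way-points (glycerol, PtiO2, PRx, ICP).
#' * `"constant"` — flat at `baseline`.
#'
#' @param form One of `"asym_gaussian"`, `"knot_interpolant"`, `"constant"`.
#' @param baseline Resting level, in the biomarker's own units.
#' @param extremum_value Value at the defining extremum (peak or trough).
#' @param extremum_time_d Time of the extremum, days relative to detection.
#' @param rise_scale_d,fall_scale_d Gaussian widths (days) of the rising and
#'   falling limbs; must be positive for `asym_gaussian`.
#' @param knots Two-column matrix or data frame `(time_d, value)`, strictly
#'   increasing in time, for `knot_interpolant`.
#' @param ref_time_d,ref_value Optional secondary anchor (e.g. the trough of
#'   a trough-then-peak trajectory). When present, population calibration
#'   preserves the contrast `extremum_value - ref_value` between the two
#'   anchors rather than the primary deviation from baseline alone.
#' @return An object of class `trajectory_profile`.
#' @examples
#' p <- trajectory_profile("asym_gaussian", baseline = 8, extremum_value = 22.2,
#'                         extremum_time_d = 0.5, rise_scale_d = 0.764,
#'                         fall_scale_d = 0.849)
#' evaluate_profile(p, 0.5) # exactly 22.2
#' @export
trajectory_profile <- function(form = c("asym_gaussian", "knot_interpolant", "constant"),
                               baseline,
                               extremum_value = baseline,
                               extremum_time_d = 0,
                               rise_scale_d = NULL,
                               fall_scale_d = NULL,
                               knots = NULL,
                               ref_time_d = NULL,
                               ref_value = NULL) {
  if (is.character(form) && length(form) == 1L &&
      !form %in% c("asym_gaussian", "knot_interpolant", "constant")) {
    stop_dcimon("unknown trajectory form '%s'", form)
  }
  form <- match.arg(form)
  check_number(baseline, "baseline")
  check_number(extremum_value, "extremum_value")
  check_number(extremum_time_d, "extremum_time_d")
  if (form == "asym_gaussian") {
    check_number(rise_scale_d, "rise_scale_d")
    check_number(fall_scale_d, "fall_scale_d")
    if (rise_scale_d <= 0 || fall_scale_d <= 0) {
      stop_dcimon("rise_scale_d and fall_scale_d must be > 0")
    }
  }
  if (form == "knot_interpolant") {
    knots <- as.data.frame(knots)
    names(knots) <- c("time_d", "value")
    if (nrow(knots) < 2L) stop_dcimon("knot_interpolant needs at least 2 knots")
    if (any(diff(knots$time_d) <= 0)) {
      stop_dcimon("knot times must be strictly increasing")
    }
  }
  structure(
    list(form = form, baseline = baseline,
         extremum_value = extremum_value, extremum_time_d = extremum_time_d,
         rise_scale_d = rise_scale_d, fall_scale_d = fall_scale_d,
         knots = knots, ref_time_d = ref_time_d, ref_value = ref_value),
    class = "trajectory_profile"
  )
}

#' Evaluate a trajectory profile
#'
#' @param profile A [trajectory_profile()].
#' @param t_rel_d Numeric vector of times, days relative to detection.
#' @return Numeric vector of profile values at `t_rel_d`.
#' @export
evaluate_profile <- function(profile, t_rel_d) {
  if (!inherits(profile, "trajectory_profile")) {
    stop_dcimon("`profile` must be a trajectory_profile")
  }
  if (!all(is.finite(t_rel_d))) stop_dcimon("`t_rel_d` must be finite")
  switch(profile$form,
    constant = rep(profile$baseline, length(t_rel_d)),
    asym_gaussian = {
      t0 <- profile$extremum_time_d
      sigma <- ifelse(t_rel_d < t0, profile$rise_scale_d, profile$fall_scale_d)
      profile$baseline + (profile$extremum_value - profile$baseline) *
        exp(-(t_rel_d - t0)^2 / (2 * sigma^2))
    },
    knot_interpolant = {
      k <- profile$knots
      # constant extrapolation beyond the outer knots
      pchip_eval(k$time_d, k$value,
                 pmin(pmax(t_rel_d, min(k$time_d)), max(k$time_d)))
    }
  )
}

#' @export
print.trajectory_profile <- function(x, ...) {
  cat(sprintf("<trajectory_profile: %s>\n", x$form))
  cat(sprintf("  baseline %.4g, extremum %.4g at day %+.2f\n",
              x$baseline, x$extremum_value, x$extremum_time_d))
  if (x$form == "asym_gaussian") {
    cat(sprintf("  rise/fall scales %.3g / %.3g d\n",
                x$rise_scale_d, x$fall_scale_d))
  }
  if (x$form == "knot_interpolant") {
    cat(sprintf("  %d knots over [%g, %g] d\n", nrow(x$knots),
                min(x$knots$time_d), max(x$knots$time_d)))
  }
  invisible(x)
}

# Shape-preserving monotone piecewise-cubic interpolation with
# Fritsch-Carlson (PCHIP) slopes: zero derivative at local-extremum knots,
# so peak/trough knot values are attained exactly with no overshoot.
# (stats::splinefun's "monoH.FC" keeps a nonzero slope where the secant
# changes sign, which overshoots peak knots.)
pchip_slopes <- function(x, y) {
  n <- length(x)
  h <- diff(x)
  d <- diff(y) / h
  m <- numeric(n)
  if (n == 2) return(rep(d, 2))
  for (i in 2:(n - 1)) {
    if (d[i - 1] * d[i] <= 0) {
      m[i] <- 0
    } else {
      w1 <- 2 * h[i] + h[i - 1]
      w2 <- h[i] + 2 * h[i - 1]
      m[i] <- (w1 + w2) / (w1 / d[i - 1] + w2 / d[i])
    }
  }
  edge <- function(h1, h2, d1, d2) {
    s <- ((2 * h1 + h2) * d1 - h1 * d2) / (h1 + h2)
    if (sign(s) != sign(d1)) 0
    else if (sign(d1) != sign(d2) && abs(s) > 3 * abs(d1)) 3 * d1
    else s
  }
  m[1] <- edge(h[1], h[2], d[1], d[2])
  m[n] <- edge(h[n - 1], h[n - 2], d[n - 1], d[n - 2])
  m
}

pchip_eval <- function(x, y, t) {
  m <- pchip_slopes(x, y)
  i <- pmin(pmax(findInterval(t, x), 1L), length(x) - 1L)
  h <- x[i + 1] - x[i]
  s <- (t - x[i]) / h
  h00 <- (1 + 2 * s) * (1 - s)^2
  h10 <- s * (1 - s)^2
  h01 <- s^2 * (3 - 2 * s)
  h11 <- s^2 * (s - 1)
  h00 * y[i] + h10 * h * m[i] + h01 * y[i + 1] + h11 * h * m[i + 1]
}

# Smooth a profile's deviation-from-baseline with the between-patient
# timing-jitter kernel (Gaussian sd `jitter_sd_d` days), optionally composed
# with a centred moving-average window of `window_d` days (used for
# quantities whose printed anchors are 24-h window medians, e.g. PRx).
# Returns the smoothed profile value at time `t_d`.
smoothed_profile_value <- function(profile, t_d, jitter_sd_d, window_d = 0) {
  offsets <- 0
  weights <- 1
  if (jitter_sd_d > 0) {
    offsets <- seq(-4, 4, length.out = 81) * jitter_sd_d
    weights <- dnorm(offsets, sd = jitter_sd_d)
    weights <- weights / sum(weights)
  }
  if (window_d > 0) {
    u <- seq(-window_d / 2, window_d / 2, length.out = 25)
    offsets <- rep(offsets, each = length(u)) + rep(u, times = length(offsets))
    weights <- rep(weights / length(u), each = length(u))
  }
  sum(weights * evaluate_profile(profile, t_d - offsets))
}

# Location of the smoothed profile's extremum near an anchor: argmin when
# the anchored value lies below baseline, argmax otherwise.
smoothed_argext <- function(profile, anchor_time_d, anchor_value,
                            jitter_sd_d, window_d) {
  tt <- seq(anchor_time_d - 3, anchor_time_d + 3, by = 0.02)
  vv <- vapply(tt, smoothed_profile_value, numeric(1), profile = profile,
               jitter_sd_d = jitter_sd_d, window_d = window_d)
  if (anchor_value < profile$baseline) tt[which.min(vv)] else
    tt[which.max(vv)]
}

# Population calibration of a latent profile against the between-patient
# timing-jitter kernel. Jitter smears the population-average trajectory,
# which (i) attenuates extrema and (ii) shifts their location toward the
# shallower limb when curvature is asymmetric. The calibration returns
#   delta - a time shift applied to per-patient curves so the smeared
#           population extremum sits at the anchored time, and
#   k     - a scale on deviations from baseline so the smeared population
#           trajectory attains the anchored extremum value there (for
#           profiles with a secondary anchor, k preserves the anchored
#           contrast between the two extrema instead).
# Both are identities (delta 0, k 1) without jitter, so noiseless
# generation reproduces the anchored profiles exactly.
calibrate_profile <- function(profile, jitter_sd_d, window_d = 0) {
  none <- list(delta = 0, k = 1)
  if (profile$form == "constant") return(none)
  if (jitter_sd_d <= 0 && window_d <= 0) return(none)
  delta <- profile$extremum_time_d -
    smoothed_argext(profile, profile$extremum_time_d,
                    profile$extremum_value, jitter_sd_d, window_d)
  if (!is.null(profile$ref_time_d)) {
    delta_ref <- profile$ref_time_d -
      smoothed_argext(profile, profile$ref_time_d, profile$ref_value,
                      jitter_sd_d, window_d)
    delta <- (delta + delta_ref) / 2
    target <- profile$extremum_value - profile$ref_value
    got <- smoothed_profile_value(profile,
                                  profile$extremum_time_d - delta,
                                  jitter_sd_d, window_d) -
      smoothed_profile_value(profile, profile$ref_time_d - delta,
                             jitter_sd_d, window_d)
  } else {
    target <- profile$extremum_value - profile$baseline
    got <- smoothed_profile_value(profile,
                                  profile$extremum_time_d - delta,
                                  jitter_sd_d, window_d) - profile$baseline
  }
  k <- if (abs(target) < .Machine$double.eps || abs(got) < 1e-12) 1 else
    target / got
  list(delta = delta, k = k)
}

# Back-compatible value-only calibration factor (delta ignored).
calibration_factor <- function(profile, jitter_sd_d, window_d = 0) {
  calibrate_profile(profile, jitter_sd_d, window_d)$k
}

#' Default latent trajectory profiles
#'
#' The calibration table anchoring the synthetic cohort generator: one
#' profile per biomarker and outcome group. Infarction-group anchors follow
#' the population trajectory extrema and maximum slopes of the study cohort
#' (glutamate peak 22.2 umol/L around day +0.5 with rise/fall slopes
#' 11.27 / -10.15 umol/L/day; glycerol peak 190.8 umol/L at day +1 remaining
#' elevated; PtiO2 trough 15.7 mmHg one day before detection rising post
#' detection; PRx trough -0.078 about day -3 and peak 0.215 around day +1.5;
#' ICP peaking near 25 mmHg around day +1). Control-group (no-DCI) profiles
#' are flat or gently peaked (glutamate ~11 umol/L, PtiO2 ~21 mmHg, PRx
#' ~0.170, ICP ~16 mmHg, glycerol peaking at 98.3 umol/L). Lactate and
#' pyruvate are constants whose ratio gives a lactate/pyruvate ratio of ~34
#' (infarction) and ~30 (controls). Unprinted baselines (glutamate 8 umol/L,
#' glycerol 75 umol/L pre-event plateau, ICP trough level) are package design
#' choices documented in the methods vignette.
#'
#' @param group `"infarction"` or `"no_dci"`.
#' @return Named list of [trajectory_profile()] objects, one per biomarker
#'   (`glutamate`, `glycerol`, `lactate`, `pyruvate`, `PtiO2`, `PRx`, `ICP`,
#'   `MAP`).
#' @export
default_profiles <- function(group = c("infarction", "no_dci")) {
  group <- match.arg(group)
  if (group == "infarction") {
    list(
      glutamate = trajectory_profile("asym_gaussian", baseline = 8,
        extremum_value = 22.2, extremum_time_d = 0.5,
        rise_scale_d = 0.764, fall_scale_d = 0.849),
      glycerol = trajectory_profile("knot_interpolant", baseline = 75,
        extremum_value = 190.8, extremum_time_d = 1,
        knots = cbind(c(-5, -1, 1, 5), c(75, 90, 190.8, 160))),
      lactate = trajectory_profile("constant", baseline = 3400),
      pyruvate = trajectory_profile("constant", baseline = 100),
      PtiO2 = trajectory_profile("knot_interpolant", baseline = 17,
        extremum_value = 15.7, extremum_time_d = -1,
        knots = cbind(c(-5, -1, 4), c(17, 15.7, 30))),
      PRx = trajectory_profile("knot_interpolant", baseline = 0.17,
        extremum_value = 0.215, extremum_time_d = 1.5,
        knots = cbind(c(-10, -3, 1.5, 5), c(0.17, -0.078, 0.215, 0.10)),
        ref_time_d = -3, ref_value = -0.078),
      ICP = trajectory_profile("knot_interpolant", baseline = 16,
        extremum_value = 25, extremum_time_d = 1,
        knots = cbind(c(-10, -1.5, 1, 5), c(16, 14, 25, 18))),
      MAP = trajectory_profile("constant", baseline = 90)
    )
  } else {
    list(
      glutamate = trajectory_profile("constant", baseline = 11),
      glycerol = trajectory_profile("asym_gaussian", baseline = 60,
        extremum_value = 98.3, extremum_time_d = 0,
        rise_scale_d = 3, fall_scale_d = 3),
      lactate = trajectory_profile("constant", baseline = 3000),
      pyruvate = trajectory_profile("constant", baseline = 100),
      PtiO2 = trajectory_profile("constant", baseline = 21),
      PRx = trajectory_profile("constant", baseline = 0.170),
      ICP = trajectory_profile("constant", baseline = 16),
      MAP = trajectory_profile("constant", baseline = 90)
    )
  }
}
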