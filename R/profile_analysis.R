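#' @title Compaction-profile metrics
#' @name profile_analysis
#' @description Extraction of dwell window, residual punch velocity during
#'   dwell, compression time and stress prolongation from measured or
#'   simulated compaction profiles.
NULL

#' Detect the dwell window of a profile
#'
#' The dwell window is the maximal contiguous time interval over which the
#' punch separation stays within `separation_tolerance` of its minimum,
#' i.e. while the punch head flat passes under the lowest point of the
#' compression roller.
#'
#' @param profile A [compaction_profile()] with at least 10 samples.
#' @param separation_tolerance Separation band above the minimum (mm).
#'   The default 0.01 mm (10 um) is on the order of punch-position sensor
#'   resolution.
#' @return Numeric length-2 vector `c(start, end)` in ms, with attributes
#'   `indices` (sample index range) and `width` (ms): the plateau width
#'   estimate extending half a sampling step beyond the bounding samples on
#'   each side, whose quantisation error is at most one sampling step. A
#'   single-sample (zero-length) interval is returned with a warning,
#'   flagging a degenerate profile without a plateau.
#' @export
detect_dwell_window <- function(profile, separation_tolerance = 0.01) {
  stopifnot(inherits(profile, "compaction_profile"))
  if (nrow(profile) < 10L)
    stop("detect_dwell_window: profile must have at least 10 samples")
  if (separation_tolerance <= 0)
    stop("detect_dwell_window: separation_tolerance must be > 0")
  ok <- profile$separation <= min(profile$separation) + separation_tolerance
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  best <- runs[which.max(r$lengths[runs])]
  i0 <- starts[best]; i1 <- ends[best]
  if (i1 == i0)
    warning("detect_dwell_window: degenerate profile, single-sample dwell window")
  dt <- profile$time[2] - profile$time[1]
  structure(c(profile$time[i0], profile$time[i1]), indices = c(i0, i1),
            width = profile$time[i1] - profile$time[i0] + dt)
}

#' Residual punch velocity during the dwell window
#'
#' Least-squares slope of punch separation versus time over the dwell
#' window. Negative values indicate that the punches keep approaching each
#' other during the nominal dwell phase, the hallmark of
#' compaction-simulator execution at short dwell times.
#'
#' @param profile A [compaction_profile()].
#' @param window Time interval `c(start, end)` in ms; defaults to
#'   [detect_dwell_window()] on the profile.
#' @param smooth_window Optional odd integer; if given, a centred moving
#'   average of that many samples is applied to the separation before
#'   fitting (for noisy high-speed profiles). Default off.
#' @param conf_level Confidence level of the reported interval.
#' @return Signed speed (mm/s) with attributes `std_error` (mm/s),
#'   `conf_int` (mm/s, `conf_level` two-sided) and `n`.
#' @export
residual_dwell_velocity <- function(profile, window = NULL,
                                    smooth_window = NULL, conf_level = 0.95) {
  stopifnot(inherits(profile, "compaction_profile"))
  if (is.null(window)) window <- detect_dwell_window(profile)
  sel <- profile$time >= window[1] - 1e-12 & profile$time <= window[2] + 1e-12
  t <- profile$time[sel]
  y <- profile$separation[sel]
  if (!is.null(smooth_window)) {
    y <- profile$separation
    k <- as.integer(smooth_window)
    if (k %% 2L != 1L || k < 3L)
      stop("residual_dwell_velocity: smooth_window must be an odd integer >= 3")
    y <- stats::filter(y, rep(1 / k, k), sides = 2)
    y <- as.numeric(y)[sel]
    keep <- !is.na(y)
    t <- t[keep]; y <- y[keep]
  }
  if (length(t) < 3L)
    stop("residual_dwell_velocity: window must contain at least 3 samples")
  fit <- stats::lm(y ~ t)
  slope <- unname(stats::coef(fit)[2]) * 1e3          # mm/ms -> mm/s
  se <- unname(sqrt(diag(stats::vcov(fit)))[2]) * 1e3
  ci <- unname(stats::confint(fit, "t", level = conf_level)) * 1e3
  structure(slope, std_error = se, conf_int = as.numeric(ci), n = length(t))
}

#' Compression time above a stress threshold
#'
#' Total time during which the axial stress is at or above a given fraction
#' of its peak. Crossing times are linearly interpolated between samples.
#'
#' @param profile A [compaction_profile()] with a stress channel.
#' @param stress_threshold_fraction Fraction of peak stress in (0, 1)
#'   defining the threshold. The default 0.10 is robust to baseline noise.
#' @return Duration (ms).
#' @export
compression_time <- function(profile, stress_threshold_fraction = 0.10) {
  stopifnot(inherits(profile, "compaction_profile"))
  if (is.null(profile$stress))
    stop("compression_time: profile has no stress channel")
  f <- stress_threshold_fraction
  if (f <= 0 || f >= 1)
    stop("compression_time: stress_threshold_fraction must be in (0, 1)")
  s <- profile$stress
  peak <- max(s)
  if (peak <= 0) stop("compression_time: all-zero stress, no peak")
  thr <- f * peak
  t <- profile$time
  above <- s >= thr
  total <- 0
  for (i in seq_len(length(t) - 1L)) {
    dt <- t[i + 1L] - t[i]
    if (above[i] && above[i + 1L]) {
      total <- total + dt
    } else if (above[i] != above[i + 1L]) {
      frac <- (thr - s[i]) / (s[i + 1L] - s[i])
      total <- total + if (above[i]) frac * dt else (1 - frac) * dt
    }
  }
  total
}

#' Relative prolongation of a simulator profile versus its press reference
#'
#' Ratio of compression times (duration above a common relative stress
#' threshold) minus one: a value of 0.2 means the simulator holds the powder
#' under stress 20\% longer than the rotary press it replays.
#'
#' @param cs_profile,press_profile [compaction_profile()]s carrying stress.
#' @param stress_threshold_fraction Threshold fraction passed to
#'   [compression_time()] for both profiles.
#' @return Dimensionless fraction (0.2 = 20\% prolongation).
#' @export
prolongation <- function(cs_profile, press_profile,
                         stress_threshold_fraction = 0.10) {
  compression_time(cs_profile, stress_threshold_fraction) /
    compression_time(press_profile, stress_threshold_fraction) - 1
}

#' Summary metrics of a compaction profile
#'
#' @param profile A [compaction_profile()].
#' @param reference Optional reference [compaction_profile()] (e.g. the
#'   rotary-press profile a simulator replayed) for the prolongation metric.
#' @param separation_tolerance Passed to [detect_dwell_window()].
#' @param stress_threshold_fraction Passed to [compression_time()].
#' @return A list of class `profile_metrics` with elements `dwell_time`
#'   (ms), `compression_time` (ms or `NA` without stress), `peak_stress`
#'   (MPa or `NA`), `residual_dwell_velocity` (mm/s) and
#'   `prolongation_vs_reference` (fraction or `NA`).
#' @export
profile_metrics <- function(profile, reference = NULL,
                            separation_tolerance = 0.01,
                            stress_threshold_fraction = 0.10) {
  win <- detect_dwell_window(profile, separation_tolerance)
  has_stress <- !is.null(profile$stress)
  out <- list(
    dwell_time = unname(attr(win, "width")),
    compression_time = if (has_stress)
      compression_time(profile, stress_threshold_fraction) else NA_real_,
    peak_stress = if (has_stress) max(profile$stress) else NA_real_,
    residual_dwell_velocity = as.numeric(
      residual_dwell_velocity(profile, win)),
    prolongation_vs_reference = if (!is.null(reference))
      prolongation(profile, reference, stress_threshold_fraction) else NA_real_)
  class(out) <- "profile_metrics"
  out
}

#' @export
print.profile_metrics <- function(x, ...) {
  cat("Profile metrics:\n")
  cat(sprintf("  dwell time            %8.3f ms\n", x$dwell_time))
  if (!is.na(x$compression_time))
    cat(sprintf("  compression time      %8.3f ms\n", x$compression_time))
  if (!is.na(x$peak_stress))
    cat(sprintf("  peak stress           %8.2f MPa\n", x$peak_stress))
  cat(sprintf("  residual dwell vel.   %+8.4f mm/s\n",
              x$residual_dwell_velocity))
  if (!is.na(x$prolongation_vs_reference))
    cat(sprintf("  prolongation vs ref.  %+8.2f %%\n",
                100 * x$prolongation_vs_reference))
  invisible(x)
}

#' @export
as.data.frame.profile_metrics <- function(x, ...) {
  data.frame(dwell_time_ms = x$dwell_time,
             compression_time_ms = x$compression_time,
             peak_stress_MPa = x$peak_stress,
             residual_dwell_velocity_mm_s = x$residual_dwell_velocity,
             prolongation_vs_reference = x$prolongation_vs_reference)
}
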