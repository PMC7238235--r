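#' @title Punch kinematics of rotary presses
#' @name kinematics
#' @description Punch displacement-over-time profiles generated from
#'   geometric machine data (pitch circle, compression roller, punch head
#'   flat), and the deviated execution of those profiles by a compaction
#'   simulator.
NULL

#' Compaction profile container
#'
#' A uniformly sampled time series of punch positions (and optionally axial
#' stress) for one compaction event. Punch positions are face positions
#' relative to the die mid-plane, so `separation = upper_pos - lower_pos` is
#' the gap between the punch faces.
#'
#' @param time Time (ms), strictly increasing, uniform step.
#' @param upper_pos Upper punch face position (mm).
#' @param lower_pos Lower punch face position (mm).
#' @param stress Optional axial stress (MPa), non-negative.
#' @param source One of `"rotary_press"`, `"cs_simulated"`, `"measured"`.
#' @return A data frame of class `compaction_profile` with columns `time`,
#'   `upper_pos`, `lower_pos`, `separation` and optionally `stress`.
#' @export
compaction_profile <- function(time, upper_pos, lower_pos, stress = NULL,
                               source = c("rotary_press", "cs_simulated",
                                          "measured")) {
  source <- match.arg(source)
  n <- length(time)
  if (n < 2L) stop("compaction_profile: need at least 2 samples")
  if (length(upper_pos) != n || length(lower_pos) != n ||
      (!is.null(stress) && length(stress) != n))
    stop("compaction_profile: all series must have equal length")
  dt <- diff(time)
  if (any(dt <= 0)) stop("compaction_profile: time must be strictly increasing")
  if (max(abs(dt - dt[1])) > 1e-9 * max(abs(time)))
    stop("compaction_profile: time step must be uniform")
  sep <- upper_pos - lower_pos
  if (any(sep < -1e-12)) stop("compaction_profile: separation must be >= 0")
  if (!is.null(stress) && any(stress < -1e-12))
    stop("compaction_profile: stress must be >= 0 where present")
  df <- data.frame(time = time, upper_pos = upper_pos, lower_pos = lower_pos,
                   separation = sep)
  if (!is.null(stress)) df$stress <- stress
  structure(df, class = c("compaction_profile", "data.frame"),
            source = source)
}

#' @export
print.compaction_profile <- function(x, ...) {
  cat(sprintf("Compaction profile [%s]: %d samples, %.4g ms step, %.4g ms span\n",
              attr(x, "source"), nrow(x), x$time[2] - x$time[1],
              x$time[nrow(x)] - x$time[1]))
  cat(sprintf("  separation %.4g .. %.4g mm", min(x$separation),
              max(x$separation)))
  if (!is.null(x$stress)) cat(sprintf(", peak stress %.4g MPa", max(x$stress)))
  cat("\n")
  invisible(x)
}

#' @export
plot.compaction_profile <- function(x, y, which = c("separation", "stress"),
                                    ...) {
  which <- match.arg(which)
  if (which == "stress" && is.null(x$stress))
    stop("profile has no stress channel")
  ylab <- if (which == "stress") "stress (MPa)" else "punch separation (mm)"
  graphics::plot(x$time, x[[which]], type = "l", xlab = "time (ms)",
                 ylab = ylab, ...)
  invisible(x)
}

#' Horizontal punch speed on the pitch circle
#'
#' @param press A [press_geometry()].
#' @param n_t Turret rotation frequency (min^-1).
#' @return Speed (m/s): `pi * pitch_circle_diameter * n_t / 60`.
#' @export
#' @examples
#' p <- press_geometry("demo", 0.5, 10, 0.2, 0.0094, 0.016, 90, 36)
#' horizontal_velocity(p, 60)  # pi * 0.5 m/s
horizontal_velocity <- function(press, n_t) {
  validate_press_geometry(press)
  if (n_t <= 0) stop("horizontal_velocity: n_t must be > 0")
  pi * press$pitch_circle_diameter * n_t / 60
}

#' Theoretical dwell time
#'
#' Time during which the punch head flat passes under the lowest point of
#' the compression roller: head flat length over horizontal pitch-circle
#' speed.
#'
#' @inheritParams horizontal_velocity
#' @return Dwell time (ms).
#' @export
dwell_time <- function(press, n_t) {
  1e3 * press$head_flat_length / horizontal_velocity(press, n_t)
}

#' Simulate a punch displacement profile from machine geometry
#'
#' Builds the piecewise displacement profile of the roller/punch-head
#' contact: a circular-arc approach while the curved head rim is under the
#' roller, a flat plateau (the dwell phase) while the head flat passes under
#' the roller's lowest point, and the mirror-image retraction. Upper and
#' lower punches move symmetrically, each contributing half of the
#' penetration; the punch separation therefore runs from `penetration_depth`
#' (fully open within the modelled window) down to 0 at the dwell plateau.
#'
#' @inheritParams horizontal_velocity
#' @param penetration_depth Total punch approach depth to simulate (mm);
#'   must be reachable, i.e. at most the roller-contact depth limit
#'   `1e3 * (roller radius + head radius)`.
#' @param sampling_step Sampling step (ms). The default 0.1 ms resolves the
#'   shortest production-scale dwell times (~12.5 ms) with more than 100
#'   points.
#' @param margin Fraction of extra flat lead-in/out time added on either side
#'   of the roller contact.
#' @param min_separation Punch separation at full penetration (mm), i.e. the
#'   in-die tablet thickness at peak stress; the separation runs from
#'   `min_separation + penetration_depth` down to `min_separation`.
#' @return A [compaction_profile()] with `source = "rotary_press"` and
#'   attributes `turret_frequency`, `press_name`, `dwell_time_ms`,
#'   `penetration_depth_mm` and `min_separation_mm`.
#' @export
simulate_displacement <- function(press, n_t, penetration_depth,
                                  sampling_step = 0.1, margin = 0.2,
                                  min_separation = 2) {
  validate_press_geometry(press)
  if (sampling_step <= 0) stop("simulate_displacement: sampling_step must be > 0")
  if (penetration_depth <= 0)
    stop("simulate_displacement: penetration_depth must be > 0")
  R <- press$roller_diameter / 2 + press$head_radius   # m, effective radius
  zp <- penetration_depth * 1e-3                       # m
  if (zp > R)
    stop("simulate_displacement: penetration_depth exceeds the roller-contact ",
         "depth limit of ", format(1e3 * R), " mm")
  v <- horizontal_velocity(press, n_t)                 # m/s
  lf <- press$head_flat_length                         # m
  u_max <- sqrt(zp * (2 * R - zp))                     # roller-contact half-width
  half_x <- (u_max + lf / 2) * (1 + margin)            # m, half window
  dt_s <- sampling_step * 1e-3
  k <- ceiling(half_x / v / dt_s)
  t_s <- seq.int(-k, k) * dt_s                         # symmetric sample times
  u <- abs(v * t_s)                                    # |x| of head centre
  w <- pmax(0, u - lf / 2)
  z <- ifelse(w >= u_max, zp, R - sqrt(pmax(0, R^2 - w^2)))
  z <- pmin(z, zp)                                     # m, retract distance
  if (min_separation < 0)
    stop("simulate_displacement: min_separation must be >= 0")
  sep_mm <- 1e3 * z + min_separation
  prof <- compaction_profile(time = (t_s - t_s[1]) * 1e3,
                             upper_pos = sep_mm / 2, lower_pos = -sep_mm / 2,
                             source = "rotary_press")
  attr(prof, "turret_frequency") <- n_t
  attr(prof, "press_name") <- press$name
  attr(prof, "dwell_time_ms") <- dwell_time(press, n_t)
  attr(prof, "penetration_depth_mm") <- penetration_depth
  attr(prof, "min_separation_mm") <- min_separation
  prof
}

#' Apply the compaction-simulator execution deviations to a profile
#'
#' Transforms an ideal rotary-press profile into the profile a compaction
#' simulator actually executes: (i) the time axis is prolonged by a stress-
#' and speed-dependent stretch factor, (ii) the punches keep approaching each
#' other during the dwell phase with a residual velocity whose magnitude
#' grows as the dwell time shrinks, and (iii) optional additive sensor-like
#' noise on the punch separation. See [cs_deviation_model()] for the
#' deviation parameters.
#'
#' The stretch factor is evaluated from the profile's peak stress (stress
#' channel if present, else the `target_stress` attribute) and its
#' `turret_frequency` attribute; any stress channel is stretched in time
#' along with the positions.
#'
#' @param profile A [compaction_profile()] with `source = "rotary_press"`.
#' @param deviation A [cs_deviation_model()].
#' @return A [compaction_profile()] with `source = "cs_simulated"`.
#' @export
apply_cs_execution <- function(profile, deviation) {
  stopifnot(inherits(profile, "compaction_profile"))
  if (!identical(attr(profile, "source"), "rotary_press"))
    stop("apply_cs_execution: profile source must be 'rotary_press'")
  stopifnot(inherits(deviation, "cs_deviation_model"))
  sigma <- if (!is.null(profile$stress)) max(profile$stress)
           else attr(profile, "target_stress")
  if (is.null(sigma)) sigma <- 0
  n_t <- attr(profile, "turret_frequency")
  if (is.null(n_t)) n_t <- 0
  s <- max(1, 1 + deviation$prolongation_coeff_stress * sigma +
              deviation$prolongation_coeff_speed * n_t)

  t0 <- profile$time
  dt <- t0[2] - t0[1]
  t_new <- seq.int(0, floor(s * (t0[length(t0)] - t0[1]) / dt + 1e-9)) * dt + t0[1]
  interp <- function(y) stats::approx(t0, y, xout = t_new / s, rule = 2)$y
  up <- interp(profile$upper_pos)
  lo <- interp(profile$lower_pos)
  stress <- if (!is.null(profile$stress)) interp(profile$stress) else NULL
  sep <- up - lo

  # residual punch approach during dwell: v_res = -kappa / dwell_time
  kappa <- deviation$residual_velocity_coeff
  if (kappa > 0) {
    idx <- which(sep <= min(sep) + 1e-9)
    i0 <- min(idx); i1 <- max(idx)
    if (i1 > i0) {
      dwell_ms <- t_new[i1] - t_new[i0]
      v_res <- kappa / dwell_ms                 # mm/s, closing
      closing <- v_res * dwell_ms * 1e-3        # mm reached at end of dwell
      ramp <- numeric(length(t_new))
      ramp[i0:i1] <- (t_new[i0:i1] - t_new[i0]) / dwell_ms
      if (i1 < length(t_new))                   # release back to 0 on retraction
        ramp[(i1 + 1):length(t_new)] <-
          1 - (t_new[(i1 + 1):length(t_new)] - t_new[i1]) /
              (t_new[length(t_new)] - t_new[i1])
      delta <- closing * ramp
      up <- up - delta / 2
      lo <- lo + delta / 2
    }
  }

  if (deviation$noise_sd_per_speed > 0) {
    sd <- deviation$noise_sd_per_speed * n_t
    noise <- .with_seed(deviation$seed, stats::rnorm(length(t_new), 0, sd))
    up <- up + noise / 2
    lo <- lo - noise / 2
    # keep the container invariant separation >= 0
    neg <- (up - lo) < 0
    if (any(neg)) { mid <- (up[neg] + lo[neg]) / 2; up[neg] <- mid; lo[neg] <- mid }
  }

  out <- compaction_profile(time = t_new, upper_pos = up, lower_pos = lo,
                            stress = stress, source = "cs_simulated")
  for (a in c("turret_frequency", "press_name", "dwell_time_ms",
              "penetration_depth_mm", "min_separation_mm", "target_stress"))
    attr(out, a) <- attr(profile, a)
  attr(out, "stretch_factor") <- s
  out
}

# run expr under a local RNG state seeded with `seed` (NULL = current stream)
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Read / write profile CSV files
#'
#' The profile CSV dialect has a header row and comma-separated columns
#' `time_ms`, `upper_pos_mm`, `lower_pos_mm` and optionally `stress_MPa`.
#'
#' @param path File path.
#' @param source Source tag to attach on read (files do not carry one).
#' @return `read_profile()` returns a [compaction_profile()];
#'   `write_profile()` invisibly returns `path`.
#' @export
read_profile <- function(path, source = "measured") {
  df <- utils::read.csv(path, check.names = FALSE)
  need <- c("time_ms", "upper_pos_mm", "lower_pos_mm")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("read_profile: missing column(s): ", paste(miss, collapse = ", "))
  compaction_profile(time = df$time_ms, upper_pos = df$upper_pos_mm,
                     lower_pos = df$lower_pos_mm,
                     stress = df[["stress_MPa"]], source = source)
}

#' @rdname read_profile
#' @param profile A [compaction_profile()].
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "compaction_profile"))
  out <- data.frame(time_ms = profile$time, upper_pos_mm = profile$upper_pos,
                    lower_pos_mm = profile$lower_pos)
  if (!is.null(profile$stress)) out$stress_MPa <- profile$stress
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
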