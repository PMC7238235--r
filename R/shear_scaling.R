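#' @title Feed-frame shear-number scaling
#' @name shear_scaling
#' @description Shear numbers quantifying the cumulative shear exposure of a
#'   lubricated powder blend in the feed frame of a rotary press, their
#'   adapted form for a single-station compaction simulator, the ideal
#'   filling time of a feed system, and the paddle-frequency matching solver
#'   that equates shear histories across machines.
NULL

#' Ideal filling time of a feed system
#'
#' Feed-system volume times bulk density over mass flow: the residence time
#' of the powder in the feed frame assuming no dead volumes and constant
#' bulk density. Used as a rough estimate of the mean residence time, and as
#' the time scale on which shear-driven tensile-strength changes approach
#' their equilibrium.
#'
#' @param feeder A [feeder_geometry()].
#' @param op An [operating_point()] with a positive `mass_flow` (kg/s).
#' @return Filling time (s).
#' @export
#' @examples
#' f <- feeder_geometry(0.1, 4, 0.002, 0.4, 1e-3, 500)
#' op <- operating_point(20, 20, 150, 5e-4, mass_flow = 5e-3)
#' ideal_filling_time(f, op)  # 100 s
ideal_filling_time <- function(feeder, op) {
  validate_feeder_geometry(feeder)
  stopifnot(inherits(op, "operating_point"))
  if (!is.finite(op$mass_flow) || op$mass_flow <= 0)
    stop("ideal_filling_time: operating point must carry a positive mass_flow")
  feeder$feed_volume * feeder$bulk_density / op$mass_flow
}

.shear_number <- function(press, feeder, op, machine, correction_factor) {
  validate_press_geometry(press)
  validate_feeder_geometry(feeder)
  stopifnot(inherits(op, "operating_point"))
  intensity <- pi * feeder$paddle_diameter * feeder$n_spokes / feeder$clearance
  residence <- (feeder$holdup_mass / (op$tablet_weight * press$n_dies))^2
  frequency <- (op$paddle_frequency / op$turret_frequency)^2
  structure(list(value = intensity * residence * frequency * correction_factor,
                 shear_intensity_term = intensity,
                 residence_term = residence,
                 frequency_term = frequency,
                 correction_factor = correction_factor,
                 machine = machine,
                 paddle_frequency = op$paddle_frequency,
                 turret_frequency = op$turret_frequency),
            class = "shear_number")
}

#' Shear number of a rotary-press feed frame
#'
#' Dimensionless index of the cumulative shear exposure of the powder in a
#' rotary-press feed frame:
#' \deqn{SN = \frac{\pi d_p k_s}{c} \left(\frac{m}{w k_d}\right)^2
#'       \left(\frac{n_p}{n_t}\right)^2}
#' combining the shear rate/intensity (paddle tip speed over clearance), the
#' shear frequency (spokes passing per rotation) and the squared residence
#' time of the powder in the feed frame. Lengths and masses enter in SI
#' units; the frequency ratio is unit-free. Absolute magnitudes (typically
#' 1E6 to 1E9 at practical settings) depend on this convention; comparisons
#' and ratios do not.
#'
#' @param press A [press_geometry()] (supplies `k_d`).
#' @param feeder A [feeder_geometry()] (supplies `d_p`, `k_s`, `c`, `m`).
#' @param op An [operating_point()] (supplies `n_p`, `n_t`, `w`).
#' @return An object of class `shear_number`: a list with `value` and its
#'   factor decomposition `shear_intensity_term`, `residence_term`,
#'   `frequency_term`, `correction_factor` (1 for a rotary press).
#' @export
shear_number_rotary <- function(press, feeder, op) {
  .shear_number(press, feeder, op, "rotary_press", correction_factor = 1)
}

#' Compaction-simulator-adapted shear number
#'
#' Adaptation of the rotary-press shear number to a single-station
#' compaction simulator whose paddle feeder (i) is only actuated during the
#' filling time corresponding to the simulated press's fill angle, and (ii)
#' shears the powder destined for its single die as often as the multiple
#' dies under a rotary feed frame would withdraw it:
#' \deqn{SN_{C} = \frac{\pi d_p k_s}{c} \left(\frac{m}{w k_d}\right)^2
#'       \left(\frac{n_p}{n_t}\,
#'       \frac{\varphi_{fill}^2}{360^\circ\,\varphi_{dies}}\right)^2}
#' `k_d`, the fill angle and the die-spacing angle come from the SIMULATED
#' rotary press; paddle geometry and hold-up come from the simulator's own
#' feeder.
#'
#' @param press_simulated [press_geometry()] of the simulated rotary press.
#' @param cs_feeder [feeder_geometry()] of the compaction simulator.
#' @param op An [operating_point()]; `paddle_frequency` is the simulator's
#'   paddle frequency, `turret_frequency` the simulated turret frequency.
#' @return An object of class `shear_number` with the angular correction
#'   factor \eqn{(\varphi_{fill}^2/(360 \varphi_{dies}))^2} populated.
#' @export
shear_number_cs <- function(press_simulated, cs_feeder, op) {
  corr <- (press_simulated$fill_angle^2 /
             (360 * press_simulated$die_spacing_angle))^2
  .shear_number(press_simulated, cs_feeder, op, "compaction_simulator", corr)
}

#' @export
print.shear_number <- function(x, ...) {
  cat(sprintf("Shear number [%s]: %.4g\n", x$machine, x$value))
  cat(sprintf("  shear intensity  pi*dp*ks/c   = %.4g\n", x$shear_intensity_term))
  cat(sprintf("  residence^2      (m/(w*kd))^2 = %.4g\n", x$residence_term))
  cat(sprintf("  frequency^2      (np/nt)^2    = %.4g\n", x$frequency_term))
  cat(sprintf("  correction factor             = %.4g\n", x$correction_factor))
  invisible(x)
}

#' Match the simulator paddle frequency to a rotary press's shear history
#'
#' Solves for the compaction-simulator paddle frequency at which the
#' simulator-adapted shear number equals the rotary press's shear number at
#' a given operating point. The closed form
#' \deqn{n_{p,CS} = n_{p,press} \sqrt{B_{press}/B_{CS}}\,
#'       \frac{360^\circ\,\varphi_{dies}}{\varphi_{fill}^2}, \quad
#'       B = \frac{\pi d_p k_s}{c} \left(\frac{m}{w k_d}\right)^2}
#' is independent of the tablet weight `w` and of the turret frequency,
#' which cancel between the two machines.
#'
#' @param press [press_geometry()] of the rotary press to be simulated.
#' @param press_feeder [feeder_geometry()] of the rotary press.
#' @param cs_feeder [feeder_geometry()] of the compaction simulator.
#' @param op_press [operating_point()] of the rotary press run.
#' @param rounding_step Machine step the result is rounded to (min^-1).
#'   Default 4 min^-1.
#' @return Matched paddle frequency (min^-1), rounded to `rounding_step`,
#'   with attributes `unrounded` (min^-1) and `target_sn` (the rotary shear
#'   number being matched).
#' @export
#' @examples
#' xl100 <- load_fixture("XL100")
#' cs <- load_fixture("StylOne")
#' op <- operating_point(20, 60, 150, 7.25e-4)
#' match_paddle_frequency(xl100$press, xl100$feeder, cs$feeder, op)  # 128
match_paddle_frequency <- function(press, press_feeder, cs_feeder, op_press,
                                   rounding_step = 4) {
  target <- shear_number_rotary(press, press_feeder, op_press)
  if (!is.finite(target$value) || target$value <= 0)
    stop("match_paddle_frequency: target rotary shear number must be finite and > 0")
  if (rounding_step <= 0)
    stop("match_paddle_frequency: rounding_step must be > 0")
  b <- function(f) pi * f$paddle_diameter * f$n_spokes / f$clearance *
    (f$holdup_mass / (op_press$tablet_weight * press$n_dies))^2
  np_cs <- op_press$paddle_frequency * sqrt(b(press_feeder) / b(cs_feeder)) *
    360 * press$die_spacing_angle / press$fill_angle^2
  structure(round(np_cs / rounding_step) * rounding_step,
            unrounded = np_cs, target_sn = target$value)
}
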