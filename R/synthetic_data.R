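#' @title Synthetic process-data generators
#' @name synthetic_data
#' @description Generators for everything needed to exercise the toolkit
#'   without measured data: paired rotary-press / compaction-simulator
#'   stress-time profiles including the simulator-specific execution
#'   deviations, and tensile-strength responses of lubricated powder blends
#'   to feed-frame shear exposure for ductile, intermediate, brittle and
#'   visco-plastic deformation classes.
NULL

#' Compaction-simulator deviation model
#'
#' Parametric description of how a compaction simulator's executed profile
#' deviates from the ideal rotary-press profile it replays. The time-stretch
#' factor is `max(1, 1 + prolongation_coeff_stress * stress +
#' prolongation_coeff_speed * n_t)`; with the defaults it is exactly 1.20 at
#' 300 MPa and a simulated turret speed of 20 min^-1, grows with stress,
#' shrinks with speed, and stays >= 1 over the supported operating grid
#' (50-300 MPa x 20-60 min^-1, minimum 1.005). The residual punch approach
#' during dwell has velocity `-residual_velocity_coeff / dwell_time`, so
#' shorter dwells see faster residual closing (defaults: -0.5 mm/s at a
#' 50 ms dwell, -2 mm/s at 12.5 ms).
#'
#' @param prolongation_coeff_stress Stretch-factor slope per MPa of peak
#'   stress. Default 7e-4.
#' @param prolongation_coeff_speed Stretch-factor slope per min^-1 of
#'   simulated turret frequency (negative). Default -5e-4.
#' @param residual_velocity_coeff Residual-closing coefficient kappa
#'   (mm ms/s): closing velocity magnitude is kappa / dwell_time. The total
#'   closing over one dwell is kappa/1000 mm regardless of dwell time.
#'   Default 25 (25 um closing).
#' @param noise_sd_per_speed Additive Gaussian separation noise, standard
#'   deviation in mm per min^-1 of turret frequency. Default 0 (off).
#' @param seed Integer seed for the noise draw; `NULL` uses the current RNG
#'   stream.
#' @return An object of class `cs_deviation_model`.
#' @export
cs_deviation_model <- function(prolongation_coeff_stress = 7e-4,
                               prolongation_coeff_speed = -5e-4,
                               residual_velocity_coeff = 25,
                               noise_sd_per_speed = 0,
                               seed = NULL) {
  if (residual_velocity_coeff < 0)
    stop("cs_deviation_model: residual_velocity_coeff must be >= 0")
  if (noise_sd_per_speed < 0)
    stop("cs_deviation_model: noise_sd_per_speed must be >= 0")
  structure(list(prolongation_coeff_stress = prolongation_coeff_stress,
                 prolongation_coeff_speed = prolongation_coeff_speed,
                 residual_velocity_coeff = residual_velocity_coeff,
                 noise_sd_per_speed = noise_sd_per_speed,
                 seed = seed),
            class = "cs_deviation_model")
}

#' Identity deviation model (simulator executes the profile perfectly)
#' @rdname cs_deviation_model
#' @export
cs_deviation_identity <- function() {
  cs_deviation_model(0, 0, 0, 0, NULL)
}

#' Material shear-response model
#'
#' Parametric model of the relative tensile strength of a lubricated blend
#' as a function of its feed-frame shear exposure. The equilibrium response
#' is a log-logistic decay between an unsheared reference strength and a
#' fully-overlubricated floor; the approach to equilibrium over process
#' runtime is exponential with the ideal filling time as time constant.
#'
#' @param deformation_class `"ductile"`, `"intermediate"`, `"brittle"` or
#'   `"viscoplastic"`.
#' @param sigma_ref Unsheared tensile strength (MPa) at the reference
#'   compaction stress.
#' @param sigma_floor Fully-sheared floor strength (MPa), `<= sigma_ref`.
#'   Equal to `sigma_ref` for a flat (shear-insensitive) response.
#' @param sn50 Shear number at which half the strength loss has occurred.
#' @param hill Hill exponent (steepness of the decay on a log-SN axis).
#' @param ref_stress Reference compaction stress (MPa) at which `sigma_ref`
#'   is defined; tensile strength scales proportionally with compaction
#'   stress around it (linear tabletability through the origin).
#' @param dwell_sensitivity Fractional strength change per natural-log unit
#'   of dwell time relative to `dwell_ref_ms`; nonzero only for
#'   visco-plastic (starch-like) materials.
#' @param dwell_ref_ms Reference dwell time (ms) for the visco-plastic term.
#' @return An object of class `material_response` with an additional
#'   `tabletability_slope` field (`sigma_ref / ref_stress`, MPa/MPa).
#' @export
material_response <- function(deformation_class = c("ductile", "intermediate",
                                                    "brittle", "viscoplastic"),
                              sigma_ref, sigma_floor, sn50, hill,
                              ref_stress = 150, dwell_sensitivity = 0,
                              dwell_ref_ms = 40) {
  deformation_class <- match.arg(deformation_class)
  if (sigma_floor > sigma_ref)
    stop("material_response: sigma_floor must be <= sigma_ref")
  if (sn50 <= 0) stop("material_response: sn50 must be > 0")
  if (hill <= 0) stop("material_response: hill must be > 0")
  if (deformation_class == "brittle" && sigma_floor != sigma_ref)
    stop("material_response: the brittle class has a flat response ",
         "(sigma_floor must equal sigma_ref)")
  if (dwell_sensitivity != 0 && deformation_class != "viscoplastic")
    stop("material_response: dwell_sensitivity is only meaningful for the ",
         "viscoplastic class")
  structure(list(deformation_class = deformation_class,
                 sigma_ref = sigma_ref, sigma_floor = sigma_floor,
                 sn50 = sn50, hill = hill, ref_stress = ref_stress,
                 tabletability_slope = sigma_ref / ref_stress,
                 dwell_sensitivity = dwell_sensitivity,
                 dwell_ref_ms = dwell_ref_ms),
            class = "material_response")
}

#' Packaged material presets
#'
#' Four synthetic material presets emulating the shear sensitivity of
#' lubricated (1 wt.-\% magnesium stearate) pharmaceutical excipient
#' classes: `"ductile"` (microcrystalline-cellulose-like, strong
#' overlubrication), `"intermediate"` (lactose-like, moderate),
#' `"brittle"` (anhydrous-dicalcium-phosphate-like, insensitive: fracture
#' during compaction creates lubricant-free surfaces), and
#' `"viscoplastic"` (starch-like, dwell-time sensitive rather than
#' shear-sensitive). The ductile and intermediate decay parameters are
#' jointly calibrated against the packaged machine fixtures so that, at a
#' simulated XL100 operating point, the ductile preset loses ~70\% and the
#' intermediate preset ~30\% of its stress-normalised strength between
#' paddle frequencies of 10 and 272 min^-1, and the ductile
#' simulator-to-press strength ratio at uncorrected convenient-filling
#' settings is ~35\%.
#'
#' @param name Preset name (case-insensitive); aliases `"MCC"`,
#'   `"lactose"`, `"DCP"`, `"starch"` are accepted.
#' @return A [material_response()].
#' @export
material_preset <- function(name) {
  key <- switch(tolower(name),
                "ductile" = , "mcc" = "ductile",
                "intermediate" = , "lactose" = "intermediate",
                "brittle" = , "dcp" = "brittle",
                "viscoplastic" = , "starch" = "viscoplastic",
                stop("material_preset: unknown preset '", name, "'"))
  switch(key,
    ductile = material_response("ductile", sigma_ref = 5.0, sigma_floor = 0.5,
                                sn50 = 3.00e6, hill = 0.462),
    intermediate = material_response("intermediate", sigma_ref = 2.0,
                                     sigma_floor = 1.0, sn50 = 6.79e7,
                                     hill = 1.0),
    brittle = material_response("brittle", sigma_ref = 1.5, sigma_floor = 1.5,
                                sn50 = 1e7, hill = 1.0),
    viscoplastic = material_response("viscoplastic", sigma_ref = 2.5,
                                     sigma_floor = 2.5, sn50 = 1e7, hill = 1.0,
                                     dwell_sensitivity = 0.08))
}

#' Equilibrium tensile strength under shear exposure
#'
#' Log-logistic decay
#' \eqn{\sigma(SN) = \sigma_{floor} + (\sigma_{ref} - \sigma_{floor}) /
#' (1 + (SN/SN_{50})^h)}: monotone non-increasing in the shear number, equal
#' to `sigma_ref` at SN = 0 and to the midpoint at SN = SN50.
#'
#' @param mat A [material_response()].
#' @param sn Shear number(s), >= 0.
#' @return Tensile strength (MPa) at the reference compaction stress.
#' @export
equilibrium_tensile_strength <- function(mat, sn) {
  stopifnot(inherits(mat, "material_response"))
  if (any(sn < 0)) stop("equilibrium_tensile_strength: sn must be >= 0")
  mat$sigma_floor + (mat$sigma_ref - mat$sigma_floor) /
    (1 + (sn / mat$sn50)^mat$hill)
}

#' Tensile strength over process runtime
#'
#' Exponential relaxation from a starting strength towards the equilibrium
#' strength at the given shear number, with the feed system's ideal filling
#' time as time constant — the strength plateaus in the range of the ideal
#' filling time, once feed-frame influx, efflux and lubricant dispersion
#' balance.
#'
#' @inheritParams equilibrium_tensile_strength
#' @param runtime Process runtime (s), >= 0.
#' @param t_f Ideal filling time (s), see [ideal_filling_time()].
#' @param sigma_start Strength of the pre-blended, unsheared state (MPa);
#'   defaults to `mat$sigma_ref`.
#' @return Tensile strength (MPa) at the reference compaction stress.
#' @export
runtime_tensile_strength <- function(mat, sn, runtime, t_f,
                                     sigma_start = mat$sigma_ref) {
  stopifnot(inherits(mat, "material_response"))
  if (any(runtime < 0)) stop("runtime_tensile_strength: runtime must be >= 0")
  if (t_f <= 0) stop("runtime_tensile_strength: t_f must be > 0")
  sigma_eq <- equilibrium_tensile_strength(mat, sn)
  sigma_eq + (sigma_start - sigma_eq) * exp(-runtime / t_f)
}

#' Sample a batch of synthetic tablet measurements
#'
#' Draws `n` tablet records whose breaking forces imply tensile strengths
#' with mean [runtime_tensile_strength()] scaled proportionally from the
#' material's reference compaction stress to the operating point's target
#' stress, with multiplicative log-normal noise of a given coefficient of
#' variation. For the visco-plastic class the mean is additionally
#' multiplied by `1 + dwell_sensitivity * log(dwell_ms / dwell_ref_ms)`.
#'
#' @inheritParams runtime_tensile_strength
#' @param op An [operating_point()]; supplies the compaction stress and the
#'   tablet weight (used to pick the tablet diameter).
#' @param n Number of tablets.
#' @param cv Coefficient of variation of the multiplicative strength noise.
#' @param seed Integer seed; identical seeds give identical batches.
#' @param diameter Tablet diameter (mm); default picks 9, 11.28 or 14 mm,
#'   whichever standard round euro-D size is nearest to the tablet weight
#'   (300, 450, 725 mg).
#' @param apparent_density Out-of-die apparent tablet density (g/cm^3) used
#'   to derive the thickness from the tablet weight.
#' @param true_density True material density recorded on the records
#'   (g/cm^3).
#' @param dwell_ms Dwell time (ms) of the compaction, used only by the
#'   visco-plastic class.
#' @return A [tablet_records()] table with `n` rows.
#' @export
sample_tablet_batch <- function(mat, op, sn, runtime, t_f, n = 10, cv = 0.05,
                                seed = NULL, sigma_start = mat$sigma_ref,
                                diameter = NULL, apparent_density = 1.3,
                                true_density = 1.55, dwell_ms = NULL) {
  stopifnot(inherits(mat, "material_response"), inherits(op, "operating_point"))
  if (n < 1L) stop("sample_tablet_batch: n must be >= 1")
  if (cv < 0) stop("sample_tablet_batch: cv must be >= 0")
  mu <- runtime_tensile_strength(mat, sn, runtime, t_f, sigma_start) *
    op$target_stress / mat$ref_stress
  if (mat$dwell_sensitivity != 0 && !is.null(dwell_ms))
    mu <- mu * (1 + mat$dwell_sensitivity * log(dwell_ms / mat$dwell_ref_ms))
  if (is.null(diameter)) {
    sizes <- c(9, 11.28, 14); weights <- c(3.0e-4, 4.5e-4, 7.25e-4)
    diameter <- sizes[which.min(abs(weights - op$tablet_weight))]
  }
  mass_mg <- op$tablet_weight * 1e6
  thickness <- mass_mg / (apparent_density * pi * (diameter / 2)^2)  # mm
  sigma <- if (cv > 0) {
    sdlog <- sqrt(log(1 + cv^2))
    mu * .with_seed(seed, exp(stats::rnorm(n, -sdlog^2 / 2, sdlog)))
  } else rep(mu, n)
  tablet_records(diameter = diameter, thickness = thickness,
                 breaking_force = sigma * pi * thickness * diameter / 2,
                 mass = mass_mg, true_density = true_density,
                 compaction_stress = op$target_stress)
}

#' Displacement-to-stress material law for synthetic profiles
#'
#' Power-law mapping from relative punch penetration to axial stress,
#' \eqn{\sigma = \sigma_{full} (d / d_{max})^k}, used to paint a stress
#' channel onto simulated displacement profiles. A purely phenomenological
#' stand-in for in-die compression behaviour; the exponent controls how
#' sharply stress rises near minimum separation.
#'
#' @param exponent Power-law exponent `k` > 0.
#' @param sigma_at_full_penetration Stress (MPa) at full penetration.
#' @return An object of class `stress_material_law`.
#' @export
stress_material_law <- function(exponent = 3, sigma_at_full_penetration) {
  if (exponent <= 0) stop("stress_material_law: exponent must be > 0")
  if (sigma_at_full_penetration <= 0)
    stop("stress_material_law: sigma_at_full_penetration must be > 0")
  structure(list(exponent = exponent,
                 sigma_at_full_penetration = sigma_at_full_penetration),
            class = "stress_material_law")
}

.apply_stress_law <- function(profile, law) {
  pen <- attr(profile, "penetration_depth_mm")
  base <- attr(profile, "min_separation_mm")
  if (is.null(base)) base <- min(profile$separation)
  depth <- pmax(0, pen - (profile$separation - base)) / pen
  law$sigma_at_full_penetration * depth^law$exponent
}

#' Generate a paired rotary-press / simulator stress-time profile
#'
#' Simulates the rotary-press displacement profile from machine geometry,
#' paints stress onto it through a [stress_material_law()], then produces
#' the compaction simulator's deviated execution of the same profile via
#' [apply_cs_execution()] and recomputes its stress from the deviated
#' displacement. The simulator stress is rescaled so both profiles reach
#' exactly the same peak stress, mirroring force-calibrated replay; the
#' residual punch approach then shows up as stress rising over the dwell
#' phase rather than as a higher peak.
#'
#' @param press A [press_geometry()].
#' @param op An [operating_point()]; `target_stress` (50-300 MPa) and
#'   `turret_frequency` (20-70 min^-1) should lie on the supported grid.
#' @param law A [stress_material_law()]; defaults to exponent 3 with
#'   `sigma_at_full_penetration = op$target_stress`.
#' @param deviation A [cs_deviation_model()].
#' @param penetration_depth,sampling_step Passed to
#'   [simulate_displacement()].
#' @return A list with elements `rotary` and `cs`, both
#'   [compaction_profile()]s carrying stress.
#' @export
generate_profile_pair <- function(press, op, law = NULL,
                                  deviation = cs_deviation_model(),
                                  penetration_depth = 3, sampling_step = 0.1) {
  stopifnot(inherits(op, "operating_point"))
  if (is.null(law)) law <- stress_material_law(3, op$target_stress)
  rot <- simulate_displacement(press, op$turret_frequency, penetration_depth,
                               sampling_step)
  attr(rot, "target_stress") <- op$target_stress
  rot_stress <- .apply_stress_law(rot, law)
  cs <- apply_cs_execution(rot, deviation)
  cs_stress <- .apply_stress_law(cs, law)
  cs_stress <- cs_stress * max(rot_stress) / max(cs_stress)

  rotary <- compaction_profile(rot$time, rot$upper_pos, rot$lower_pos,
                               stress = rot_stress, source = "rotary_press")
  cs_out <- compaction_profile(cs$time, cs$upper_pos, cs$lower_pos,
                               stress = cs_stress, source = "cs_simulated")
  for (a in c("turret_frequency", "press_name", "dwell_time_ms",
              "penetration_depth_mm", "min_separation_mm", "target_stress")) {
    attr(rotary, a) <- attr(rot, a)
    attr(cs_out, a) <- attr(cs, a)
  }
  attr(cs_out, "stretch_factor") <- attr(cs, "stretch_factor")
  list(rotary = rotary, cs = cs_out)
}
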