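#' @title Tablet property calculations
#' @name tablet_props
#' @description Diametral-compression tensile strength, out-of-die porosity,
#'   stress-normalised tensile strength and tabletability-curve assembly for
#'   flat-faced round tablets.
NULL

#' Tablet measurement table
#'
#' Builds a validated table of tablet measurements. All arguments are
#' recycled to a common length.
#'
#' @param diameter Tablet diameter (mm).
#' @param thickness Tablet thickness/height (mm).
#' @param breaking_force Diametral breaking force (N).
#' @param mass Tablet mass (mg), optional.
#' @param true_density True (skeletal) density of the material (g/cm^3),
#'   optional.
#' @param compaction_stress Peak compaction stress the tablet was made at
#'   (MPa), optional.
#' @return A data frame of class `tablet_records`.
#' @export
tablet_records <- function(diameter, thickness, breaking_force,
                           mass = NA_real_, true_density = NA_real_,
                           compaction_stress = NA_real_) {
  df <- data.frame(diameter = diameter, thickness = thickness,
                   breaking_force = breaking_force, mass = mass,
                   true_density = true_density,
                   compaction_stress = compaction_stress)
  if (any(df$diameter <= 0) || any(df$thickness <= 0))
    stop("tablet_records: diameter and thickness must be > 0")
  if (any(df$breaking_force < 0))
    stop("tablet_records: breaking_force must be >= 0")
  if (any(df$mass <= 0, na.rm = TRUE) || any(df$true_density <= 0, na.rm = TRUE))
    stop("tablet_records: mass and true_density must be > 0 where present")
  if (any(df$compaction_stress <= 0, na.rm = TRUE))
    stop("tablet_records: compaction_stress must be > 0 where present")
  class(df) <- c("tablet_records", "data.frame")
  df
}

#' Diametral-compression tensile strength
#'
#' Fell-Newton tensile strength of flat-faced round tablets,
#' \eqn{\sigma_t = 2F / (\pi h_t d_t)}, in MPa when the breaking force is in
#' N and the dimensions in mm.
#'
#' @param records A [tablet_records()] table.
#' @return Numeric vector of tensile strengths (MPa), one per record.
#' @export
#' @examples
#' r <- tablet_records(10, 4, 100)
#' tensile_strength(r)  # 2*100/(pi*4*10) = 1.5915 MPa
tensile_strength <- function(records) {
  stopifnot(inherits(records, "tablet_records"))
  2 * records$breaking_force / (pi * records$thickness * records$diameter)
}

#' Out-of-die tablet porosity
#'
#' Porosity from the envelope (apparent) density of the measured tablet and
#' the true density of the material:
#' \eqn{\epsilon = 1 - m / (\rho_{true} \pi (d_t/2)^2 h_t)}. With mass in
#' mg, dimensions in mm and true density in g/cm^3 the units cancel.
#'
#' @param records A [tablet_records()] table with `mass` and `true_density`.
#' @return Numeric vector of porosities (fraction). Values below 0 (apparent
#'   density exceeding true density, i.e. inconsistent inputs) are returned
#'   as-is with a warning.
#' @export
porosity <- function(records) {
  stopifnot(inherits(records, "tablet_records"))
  if (any(is.na(records$mass)) || any(is.na(records$true_density)))
    stop("porosity: records must carry mass and true_density")
  vol <- pi * (records$diameter / 2)^2 * records$thickness  # mm^3
  eps <- 1 - records$mass / (records$true_density * vol)
  if (any(eps < 0))
    warning("porosity: apparent density exceeds true density for ",
            sum(eps < 0), " record(s)")
  eps
}

#' Stress-normalised tensile strength
#'
#' Tensile strength divided by the peak compaction stress the tablet was
#' produced at. Used to exclude die-filling-efficiency effects (a lower fill
#' mass lowers both the reached stress and the strength) and isolate the
#' lubricant-dispersion effect on bonding; this assumes tensile strength and
#' compaction stress correlate well over the stress range in question.
#'
#' @param records A [tablet_records()] table with `compaction_stress`.
#' @return Numeric vector (MPa/MPa).
#' @export
normalize_by_stress <- function(records) {
  stopifnot(inherits(records, "tablet_records"))
  if (any(is.na(records$compaction_stress)) ||
      any(records$compaction_stress <= 0))
    stop("normalize_by_stress: records must carry a positive compaction_stress")
  tensile_strength(records) / records$compaction_stress
}

#' Assemble a tabletability curve
#'
#' Groups tablet records by compaction stress (within a tolerance) and
#' returns mean, standard deviation and count of tensile strength per
#' stress level, sorted by ascending stress.
#'
#' @param records A [tablet_records()] table with `compaction_stress`.
#' @param grouping_tolerance Absolute stress tolerance (MPa) within which
#'   records belong to one curve point; `NULL` (default) uses 5\% of the
#'   group's first stress, accommodating press-to-press stress scatter.
#' @return A data frame of class `tabletability_curve` with columns
#'   `compaction_stress` (group mean, MPa), `tensile_strength_mean`,
#'   `tensile_strength_sd` (MPa) and `n`.
#' @export
build_tabletability <- function(records, grouping_tolerance = NULL) {
  stopifnot(inherits(records, "tablet_records"))
  if (nrow(records) == 0L) stop("build_tabletability: empty input")
  if (any(is.na(records$compaction_stress)))
    stop("build_tabletability: records must carry compaction_stress")
  ord <- order(records$compaction_stress)
  stress <- records$compaction_stress[ord]
  sigma <- tensile_strength(records)[ord]
  group <- integer(length(stress))
  g <- 1L; ref <- stress[1]
  for (i in seq_along(stress)) {
    tol <- if (is.null(grouping_tolerance)) 0.05 * ref else grouping_tolerance
    if (stress[i] - ref > tol) { g <- g + 1L; ref <- stress[i] }
    group[i] <- g
  }
  agg <- function(x, f) as.numeric(tapply(x, group, f))
  out <- data.frame(compaction_stress = agg(stress, mean),
                    tensile_strength_mean = agg(sigma, mean),
                    tensile_strength_sd = agg(sigma, function(v)
                      if (length(v) > 1L) stats::sd(v) else 0),
                    n = as.integer(agg(sigma, length)))
  class(out) <- c("tabletability_curve", "data.frame")
  out
}

#' @export
print.tabletability_curve <- function(x, ...) {
  cat("Tabletability curve (", nrow(x), " stress level(s)):\n", sep = "")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
plot.tabletability_curve <- function(x, y, ...) {
  graphics::plot(x$compaction_stress, x$tensile_strength_mean, type = "b",
                 pch = 16, xlab = "compaction stress (MPa)",
                 ylab = "tensile strength (MPa)", ...)
  graphics::arrows(x$compaction_stress,
                   x$tensile_strength_mean - x$tensile_strength_sd,
                   x$compaction_stress,
                   x$tensile_strength_mean + x$tensile_strength_sd,
                   angle = 90, code = 3, length = 0.03)
  invisible(x)
}

#' Read / write tablet measurement CSV files
#'
#' Column dialect: `diameter_mm`, `thickness_mm`, `breaking_force_N` and
#' optionally `mass_mg`, `true_density_g_cm3`, `compaction_stress_MPa`.
#'
#' @param path File path.
#' @return `read_tablet_table()` returns a [tablet_records()] table;
#'   `write_tablet_table()` invisibly returns `path`.
#' @export
read_tablet_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  need <- c("diameter_mm", "thickness_mm", "breaking_force_N")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("read_tablet_table: missing column(s): ", paste(miss, collapse = ", "))
  opt <- function(col) if (col %in% names(df)) df[[col]] else NA_real_
  tablet_records(diameter = df$diameter_mm, thickness = df$thickness_mm,
                 breaking_force = df$breaking_force_N,
                 mass = opt("mass_mg"), true_density = opt("true_density_g_cm3"),
                 compaction_stress = opt("compaction_stress_MPa"))
}

#' @rdname read_tablet_table
#' @param records A [tablet_records()] table.
#' @export
write_tablet_table <- function(records, path) {
  stopifnot(inherits(records, "tablet_records"))
  out <- data.frame(diameter_mm = records$diameter,
                    thickness_mm = records$thickness,
                    breaking_force_N = records$breaking_force,
                    mass_mg = records$mass,
                    true_density_g_cm3 = records$true_density,
                    compaction_stress_MPa = records$compaction_stress)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
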