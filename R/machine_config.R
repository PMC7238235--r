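#' @title Machine geometry definitions and fixture I/O
#' @name machine_config
#' @description Typed definitions of rotary-press and compaction-simulator
#'   geometry, feed-frame geometry and operating points, plus JSON/YAML
#'   fixture files for the packaged machines (XL100, XL400, StylOne).
NULL

.press_fields <- c("name", "pitch_circle_diameter", "n_dies", "roller_diameter",
                   "head_flat_length", "head_radius", "fill_angle",
                   "die_spacing_angle")
.feeder_fields <- c("paddle_diameter", "n_spokes", "clearance", "holdup_mass",
                    "feed_volume", "bulk_density")

#' Rotary-press geometry
#'
#' Geometry of a rotary tablet press (or of the press a compaction simulator
#' replays): turret pitch circle, compression roller, punch head and the
#' angular layout of the feed-frame window and die stations. All lengths in
#' metres, angles in degrees.
#'
#' @param name Machine label.
#' @param pitch_circle_diameter Turret pitch-circle diameter (m).
#' @param n_dies Number of installed dies / punch pairs (`k_d`).
#' @param roller_diameter Main compression roller diameter (m).
#' @param head_flat_length Punch head flat length (m); sets the dwell time.
#' @param head_radius Punch head edge radius of curvature (m).
#' @param fill_angle Angle of the turret circle covered by the feed-frame
#'   filling window (degrees).
#' @param die_spacing_angle Angular spacing between adjacent installed dies
#'   (degrees). For an under-tooled turret this refers to the installed punch
#'   set, i.e. `360 / n_dies`.
#' @return An object of class `press_geometry`.
#' @export
#' @examples
#' press_geometry("demo", 0.5, 10, 0.2, 0.0094, 0.016, 90, 36)
press_geometry <- function(name, pitch_circle_diameter, n_dies, roller_diameter,
                           head_flat_length, head_radius, fill_angle,
                           die_spacing_angle) {
  x <- list(name = as.character(name),
            pitch_circle_diameter = as.numeric(pitch_circle_diameter),
            n_dies = as.integer(n_dies),
            roller_diameter = as.numeric(roller_diameter),
            head_flat_length = as.numeric(head_flat_length),
            head_radius = as.numeric(head_radius),
            fill_angle = as.numeric(fill_angle),
            die_spacing_angle = as.numeric(die_spacing_angle))
  class(x) <- "press_geometry"
  validate_press_geometry(x)
}

#' @rdname press_geometry
#' @param x A `press_geometry` object.
#' @export
validate_press_geometry <- function(x) {
  stopifnot(inherits(x, "press_geometry"))
  for (f in setdiff(.press_fields, "name"))
    if (!is.finite(x[[f]])) stop("press_geometry: field '", f, "' must be finite")
  lens <- c("pitch_circle_diameter", "roller_diameter", "head_flat_length",
            "head_radius")
  for (f in lens)
    if (x[[f]] <= 0) stop("press_geometry: field '", f, "' must be > 0")
  if (x$n_dies < 1L) stop("press_geometry: field 'n_dies' must be >= 1")
  if (x$fill_angle <= 0 || x$fill_angle > 360)
    stop("press_geometry: field 'fill_angle' must be in (0, 360]")
  if (x$die_spacing_angle <= 0 || x$die_spacing_angle > 360)
    stop("press_geometry: field 'die_spacing_angle' must be in (0, 360]")
  x
}

#' Feed-frame geometry
#'
#' Paddle-wheel geometry and powder hold-up of a feed system, either of a
#' rotary press or of a compaction simulator.
#'
#' @param paddle_diameter Paddle-wheel diameter `d_p` (m).
#' @param n_spokes Number of paddle spokes `k_s`.
#' @param clearance Clearance between spokes and feeder base `c` (m).
#' @param holdup_mass Powder mass held in the feed frame `m` (kg).
#' @param feed_volume Feed-system volume `V_R` (m^3).
#' @param bulk_density Powder bulk density `rho_b` (kg/m^3).
#' @return An object of class `feeder_geometry`.
#' @export
feeder_geometry <- function(paddle_diameter, n_spokes, clearance, holdup_mass,
                            feed_volume, bulk_density) {
  x <- list(paddle_diameter = as.numeric(paddle_diameter),
            n_spokes = as.integer(n_spokes),
            clearance = as.numeric(clearance),
            holdup_mass = as.numeric(holdup_mass),
            feed_volume = as.numeric(feed_volume),
            bulk_density = as.numeric(bulk_density))
  class(x) <- "feeder_geometry"
  validate_feeder_geometry(x)
}

#' @rdname feeder_geometry
#' @param x A `feeder_geometry` object.
#' @export
validate_feeder_geometry <- function(x) {
  stopifnot(inherits(x, "feeder_geometry"))
  for (f in .feeder_fields)
    if (!is.finite(x[[f]])) stop("feeder_geometry: field '", f, "' must be finite")
  for (f in c("paddle_diameter", "clearance", "holdup_mass", "feed_volume",
              "bulk_density"))
    if (x[[f]] <= 0) stop("feeder_geometry: field '", f, "' must be > 0")
  if (x$n_spokes < 1L) stop("feeder_geometry: field 'n_spokes' must be >= 1")
  if (x$holdup_mass > x$feed_volume * x$bulk_density + 1e-12)
    stop("feeder_geometry: holdup_mass exceeds feed_volume * bulk_density")
  x
}

#' Operating point of a tableting run
#'
#' @param turret_frequency Turret (die-table) rotation frequency `n_t`
#'   (min^-1); for a compaction simulator, the simulated turret frequency.
#' @param paddle_frequency Feeder paddle rotation frequency `n_p` (min^-1).
#' @param target_stress Target peak compaction stress (MPa).
#' @param tablet_weight Weight of one tablet `w` (kg).
#' @param mass_flow Powder mass flow through the feed system (kg/s); required
#'   only for filling-time computations. Defaults to `NA`.
#' @return An object of class `operating_point`.
#' @export
operating_point <- function(turret_frequency, paddle_frequency, target_stress,
                            tablet_weight, mass_flow = NA_real_) {
  x <- list(turret_frequency = as.numeric(turret_frequency),
            paddle_frequency = as.numeric(paddle_frequency),
            target_stress = as.numeric(target_stress),
            tablet_weight = as.numeric(tablet_weight),
            mass_flow = as.numeric(mass_flow))
  class(x) <- "operating_point"
  if (x$turret_frequency <= 0) stop("operating_point: turret_frequency must be > 0")
  if (x$paddle_frequency < 0) stop("operating_point: paddle_frequency must be >= 0")
  if (x$target_stress <= 0) stop("operating_point: target_stress must be > 0")
  if (x$tablet_weight <= 0) stop("operating_point: tablet_weight must be > 0")
  x
}

#' Machine fixture: press plus feed frame
#'
#' @param press A [press_geometry()].
#' @param feeder A [feeder_geometry()].
#' @param kind `"rotary_press"` or `"compaction_simulator"`. A compaction
#'   simulator has exactly one die position under its feeder, so
#'   `press$n_dies` must be 1.
#' @param provenance Optional free-text note on where the numbers come from.
#' @return An object of class `machine_fixture`.
#' @export
machine_fixture <- function(press, feeder, kind = c("rotary_press",
                                                    "compaction_simulator"),
                            provenance = NULL) {
  kind <- match.arg(kind)
  validate_press_geometry(press)
  validate_feeder_geometry(feeder)
  if (kind == "compaction_simulator" && press$n_dies != 1L)
    stop("machine_fixture: a compaction_simulator has exactly one die ",
         "position under the feeder (press$n_dies must be 1)")
  structure(list(press = press, feeder = feeder, kind = kind,
                 provenance = provenance),
            class = "machine_fixture")
}

.fixture_path <- function(name) {
  system.file("extdata", "fixtures", paste0(name, ".json"),
              package = "tabscale", mustWork = FALSE)
}

#' Load a machine fixture
#'
#' Loads a packaged fixture by id (`"XL100"`, `"XL400"`, `"StylOne"`) or any
#' fixture config file (JSON, or YAML when the \pkg{yaml} package is
#' available). All geometry invariants are checked and unknown fields are
#' rejected.
#'
#' @param name_or_path Fixture id or path to a config file.
#' @return A validated [machine_fixture()].
#' @export
#' @examples
#' xl100 <- load_fixture("XL100")
#' xl100$press$n_dies  # 4 installed punch pairs
load_fixture <- function(name_or_path) {
  path <- name_or_path
  if (!file.exists(path)) {
    packaged <- .fixture_path(name_or_path)
    if (!nzchar(packaged) || !file.exists(packaged))
      stop("load_fixture: no file or packaged fixture named '", name_or_path, "'")
    path <- packaged
  }
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("load_fixture: the 'yaml' package is required for YAML fixtures")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  .fixture_from_list(raw, path)
}

.fixture_from_list <- function(raw, path = "<config>") {
  known_top <- c("kind", "press", "feeder", "provenance")
  extra <- setdiff(names(raw), known_top)
  if (length(extra))
    stop("fixture '", path, "': unknown field(s): ", paste(extra, collapse = ", "))
  for (f in c("kind", "press", "feeder"))
    if (is.null(raw[[f]])) stop("fixture '", path, "': missing field '", f, "'")
  ep <- setdiff(names(raw$press), .press_fields)
  if (length(ep))
    stop("fixture '", path, "': unknown press field(s): ", paste(ep, collapse = ", "))
  ef <- setdiff(names(raw$feeder), .feeder_fields)
  if (length(ef))
    stop("fixture '", path, "': unknown feeder field(s): ", paste(ef, collapse = ", "))
  miss <- c(setdiff(.press_fields, names(raw$press)),
            setdiff(.feeder_fields, names(raw$feeder)))
  if (length(miss))
    stop("fixture '", path, "': missing field(s): ", paste(miss, collapse = ", "))
  machine_fixture(press = do.call(press_geometry, raw$press),
                  feeder = do.call(feeder_geometry, raw$feeder),
                  kind = raw$kind,
                  provenance = raw$provenance)
}

#' Save a machine fixture
#'
#' Writes a fixture as a JSON (or YAML) config file; [load_fixture()] on the
#' result reproduces the fixture exactly.
#'
#' @param fixture A [machine_fixture()].
#' @param path Output file path (`.json`, `.yml` or `.yaml`).
#' @return Invisibly, `path`.
#' @export
save_fixture <- function(fixture, path) {
  stopifnot(inherits(fixture, "machine_fixture"))
  validate_press_geometry(fixture$press)
  validate_feeder_geometry(fixture$feeder)
  out <- list(kind = fixture$kind,
              press = unclass(fixture$press),
              feeder = unclass(fixture$feeder))
  if (!is.null(fixture$provenance)) out$provenance <- fixture$provenance
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("save_fixture: the 'yaml' package is required for YAML fixtures")
    yaml::write_yaml(out, path)
  } else {
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' @export
print.press_geometry <- function(x, ...) {
  cat("Press geometry:", x$name, "\n")
  cat(sprintf("  pitch circle %.4g m, %d dies, roller %.4g m\n",
              x$pitch_circle_diameter, x$n_dies, x$roller_diameter))
  cat(sprintf("  head flat %.3g mm, head radius %.3g mm\n",
              1e3 * x$head_flat_length, 1e3 * x$head_radius))
  cat(sprintf("  fill angle %.4g deg, die spacing %.4g deg\n",
              x$fill_angle, x$die_spacing_angle))
  invisible(x)
}

#' @export
print.feeder_geometry <- function(x, ...) {
  cat("Feeder geometry:\n")
  cat(sprintf("  paddle %.4g m, %d spokes, clearance %.3g mm\n",
              x$paddle_diameter, x$n_spokes, 1e3 * x$clearance))
  cat(sprintf("  hold-up %.4g kg in %.4g L (bulk density %.4g kg/m3)\n",
              x$holdup_mass, 1e3 * x$feed_volume, x$bulk_density))
  invisible(x)
}

#' @export
print.machine_fixture <- function(x, ...) {
  cat("Machine fixture [", x$kind, "]\n", sep = "")
  print(x$press)
  print(x$feeder)
  if (!is.null(x$provenance)) cat("Provenance:", x$provenance, "\n")
  invisible(x)
}
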