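# small builders used across test files

demo_press <- function(pitch = 0.5, n_dies = 10, roller = 0.2,
                       head_flat = 9.42e-3, head_radius = 0.016,
                       fill_angle = 90, die_spacing = 36, name = "demo") {
  press_geometry(name, pitch, n_dies, roller, head_flat, head_radius,
                 fill_angle, die_spacing)
}

demo_feeder <- function(paddle = 0.1, spokes = 4, clearance = 0.002,
                        holdup = 0.4, volume = 1e-3, density = 500) {
  feeder_geometry(paddle, spokes, clearance, holdup, volume, density)
}

# a random but valid press geometry (draws from the caller's RNG stream)
random_press <- function() {
  press_geometry("rand",
                 pitch_circle_diameter = runif(1, 0.2, 0.6),
                 n_dies = sample(3:30, 1),
                 roller_diameter = runif(1, 0.15, 0.3),
                 head_flat_length = runif(1, 0.006, 0.016),
                 head_radius = runif(1, 0.01, 0.03),
                 fill_angle = runif(1, 60, 140),
                 die_spacing_angle = runif(1, 10, 90))
}

# triangular stress pulse profile: rises 0 -> peak -> 0 over `base` ms
triangle_profile <- function(base = 40, peak = 100, dt = 0.1, pad = 10) {
  t <- seq(0, base + 2 * pad, by = dt)
  s <- pmax(0, peak * (1 - abs(t - pad - base / 2) / (base / 2)))
  sep <- 5 - 4 * s / peak  # separation shrinking with stress, stays > 0
  compaction_profile(t, sep / 2, -sep / 2, stress = s, source = "measured")
}
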