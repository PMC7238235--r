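test_that("dwell window detection handles plateaus, ramps and wide tolerances", {
  prof <- simulate_displacement(demo_press(), 40, 3)
  win <- detect_dwell_window(prof, 1e-9)
  expect_lt(abs(attr(win, "width") - dwell_time(demo_press(), 40)), 0.1 + 1e-9)

  # monotone ramp, tight tolerance: degenerate single-sample window
  t <- seq(0, 5, by = 0.1)
  ramp <- compaction_profile(t, 5 - 0.5 * t, rep(0, length(t)),
                             source = "measured")
  expect_warning(w <- detect_dwell_window(ramp, 1e-6), "degenerate")
  expect_identical(diff(range(w)), 0)

  # tolerance wider than the profile amplitude: whole profile
  w_all <- detect_dwell_window(ramp, 100)
  expect_equal(w_all, range(t), ignore_attr = TRUE)

  expect_error(detect_dwell_window(ramp, 0), "tolerance")
  short <- compaction_profile(0:5, rep(1, 6), rep(0, 6), source = "measured")
  expect_error(detect_dwell_window(short), "at least 10 samples")
})

test_that("residual dwell velocity recovers constructed slopes and sign", {
  t <- seq(0, 20, by = 0.1)
  flat <- compaction_profile(t, rep(2, length(t)), rep(0, length(t)),
                             source = "measured")
  # (suppressed: lm warns about the noise-free, perfectly linear oracle data)
  v_flat <- suppressWarnings(residual_dwell_velocity(flat, range(t)))
  expect_equal(as.numeric(v_flat), 0, tolerance = 1e-12)

  # 10 um decrease over 20 ms -> -0.5 mm/s, negative = punches approaching
  sep <- 2 - 0.010 * t / 20
  lin <- compaction_profile(t, sep / 2, -sep / 2, source = "measured")
  v_lin <- suppressWarnings(residual_dwell_velocity(lin, range(t)))
  expect_equal(as.numeric(v_lin), -0.5, tolerance = 1e-9)

  expect_error(residual_dwell_velocity(lin, c(0, 0.1)), "at least 3 samples")
})

test_that("residual velocity is invariant to separation offset and time shift", {
  set.seed(7)
  t <- seq(0, 20, by = 0.1)
  sep <- 2 - 0.3e-3 * t + rnorm(length(t), 0, 1e-3)
  a <- compaction_profile(t, sep / 2, -sep / 2, source = "measured")
  b <- compaction_profile(t + 100, (sep + 1) / 2, -(sep + 1) / 2,
                          source = "measured")
  va <- residual_dwell_velocity(a, range(t))
  vb <- residual_dwell_velocity(b, range(t) + 100)
  expect_equal(as.numeric(va), as.numeric(vb), tolerance = 1e-9)
})

test_that("noisy linear-dwell slope is recovered within the fit's confidence band", {
  set.seed(11)
  t <- seq(0, 40, by = 0.1)
  true_slope <- -0.8  # mm/s
  sep <- 3 + true_slope * 1e-3 * t + rnorm(length(t), 0, 2e-3)
  prof <- compaction_profile(t, sep / 2, -sep / 2, source = "measured")
  v <- residual_dwell_velocity(prof, range(t))
  ci <- attr(v, "conf_int")
  expect_true(ci[1] <= true_slope && true_slope <= ci[2])
})

test_that("moving-average pre-smoothing leaves the underlying slope intact", {
  set.seed(13)
  t <- seq(0, 40, by = 0.1)
  sep <- 3 - 0.5e-3 * t + rnorm(length(t), 0, 5e-3)
  prof <- compaction_profile(t, sep / 2, -sep / 2, source = "measured")
  v <- residual_dwell_velocity(prof, range(t), smooth_window = 9)
  expect_equal(as.numeric(v), -0.5, tolerance = 0.15)
})

test_that("compression time follows pulse geometry and threshold limits", {
  prof <- triangle_profile(base = 40, peak = 100)
  expect_equal(compression_time(prof, 0.5), 20, tolerance = 1e-9)
  expect_equal(compression_time(prof, 1e-9), 40, tolerance = 1e-3)

  zero <- compaction_profile(0:20, rep(1, 21), rep(0, 21),
                             stress = rep(0, 21), source = "measured")
  expect_error(compression_time(zero), "no peak")
  nostress <- compaction_profile(0:20, rep(1, 21), rep(0, 21),
                                 source = "measured")
  expect_error(compression_time(nostress), "no stress channel")
  expect_error(compression_time(prof, 0), "threshold_fraction")
})

test_that("prolongation is zero on identity and antisymmetric for stretched pairs", {
  prof <- triangle_profile()
  expect_identical(prolongation(prof, prof), 0)

  t2 <- seq(0, max(prof$time) * 1.2, by = 0.1)
  stretched <- compaction_profile(
    t2, approx(prof$time * 1.2, prof$upper_pos, t2, rule = 2)$y,
    approx(prof$time * 1.2, prof$lower_pos, t2, rule = 2)$y,
    stress = approx(prof$time * 1.2, prof$stress, t2, rule = 2)$y,
    source = "cs_simulated")
  p_ab <- prolongation(stretched, prof)
  p_ba <- prolongation(prof, stretched)
  expect_equal(p_ab, 0.20, tolerance = 1e-3)
  expect_identical(sign(p_ab), -sign(p_ba))
})

test_that("profile metrics assemble consistently and export flat", {
  op <- operating_point(20, 0, 150, 7.25e-4)
  pair <- generate_profile_pair(load_fixture("XL100")$press, op)
  m <- profile_metrics(pair$cs, reference = pair$rotary)
  expect_s3_class(m, "profile_metrics")
  expect_lte(m$dwell_time, m$compression_time)
  expect_equal(m$peak_stress, 150)
  expect_lt(m$residual_dwell_velocity, 0)
  expect_gt(m$prolongation_vs_reference, 0)
  df <- as.data.frame(m)
  expect_identical(nrow(df), 1L)
  expect_equal(df$prolongation_vs_reference, m$prolongation_vs_reference)
})
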