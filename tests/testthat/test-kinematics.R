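test_that("horizontal velocity and dwell time follow the pitch-circle geometry", {
  p <- demo_press(pitch = 0.5)
  v <- horizontal_velocity(p, 60)
  expect_equal(v, pi * 0.5)
  expect_equal(horizontal_velocity(p, 120), 2 * v)  # linear in n_t
  # l_f = 9.42 mm at 1.5708 m/s -> 6.0 ms
  expect_equal(dwell_time(p, 60), 9.42e-3 / (pi * 0.5) * 1e3, tolerance = 1e-12)
  expect_equal(dwell_time(p, 60), 5.997, tolerance = 1e-3)
  expect_equal(dwell_time(p, 30), 2 * dwell_time(p, 60))  # inverse in n_t
})

test_that("XL400 fixture reproduces the theoretical production-scale dwell time", {
  xl400 <- load_fixture("XL400")
  expect_equal(dwell_time(xl400$press, 60), 12.5, tolerance = 1e-3)
})

test_that("simulated displacement profiles have the constructed geometry", {
  p <- demo_press()
  prof <- simulate_displacement(p, 40, penetration_depth = 3)
  # symmetric about the midpoint
  expect_equal(prof$separation, rev(prof$separation), tolerance = 1e-9)
  # separation range equals the requested penetration depth
  expect_equal(max(prof$separation) - min(prof$separation), 3,
               tolerance = 1e-12)
  # plateau width matches the closed-form dwell time to one sampling step
  win <- detect_dwell_window(prof, 1e-9)
  expect_lt(abs(attr(win, "width") - dwell_time(p, 40)), 0.1 + 1e-9)
  # curved head engages before the flat: contact longer than plateau
  contact <- range(prof$time[prof$separation < max(prof$separation) - 1e-9])
  expect_gt(diff(contact), attr(win, "width"))
})

test_that("plateau width tracks the closed form across random geometries", {
  set.seed(42)
  for (i in 1:10) {
    p <- random_press()
    n_t <- runif(1, 20, 70)
    step <- 0.1
    prof <- simulate_displacement(p, n_t, penetration_depth = runif(1, 1, 4),
                                  sampling_step = step)
    win <- detect_dwell_window(prof, 1e-9)
    expect_lt(abs(attr(win, "width") - dwell_time(p, n_t)), step + 1e-9)
  }
})

test_that("profiles at different turret speeds are time-rescalings of one another", {
  p <- demo_press()
  a <- simulate_displacement(p, 20, 3, sampling_step = 0.2)
  b <- simulate_displacement(p, 40, 3, sampling_step = 0.1)
  # same sample count; normalising time by 1/n_t makes the curves coincide
  expect_identical(nrow(a), nrow(b))
  expect_equal(a$separation, b$separation, tolerance = 1e-9)
})

test_that("unreachable penetration depth and bad steps are rejected", {
  p <- demo_press(roller = 0.2, head_radius = 0.016)
  expect_error(simulate_displacement(p, 40, penetration_depth = 1e3),
               "depth limit")
  expect_error(simulate_displacement(p, 40, 3, sampling_step = 0),
               "sampling_step")
})

test_that("identity deviation model reproduces the input profile", {
  prof <- simulate_displacement(demo_press(), 40, 3)
  attr(prof, "target_stress") <- 300
  out <- apply_cs_execution(prof, cs_deviation_identity())
  expect_equal(out$time, prof$time)
  expect_equal(out$separation, prof$separation)
  expect_identical(attr(out, "source"), "cs_simulated")
  expect_error(apply_cs_execution(out, cs_deviation_identity()), "source")
})

test_that("a pure time stretch prolongs the stress duration accordingly", {
  prof <- triangle_profile()
  attr(prof, "source") <- "rotary_press"
  attr(prof, "turret_frequency") <- 0
  # stretch factor 1.2 from the stress coefficient alone: peak is 100 MPa
  dev <- cs_deviation_model(prolongation_coeff_stress = 0.2 / 100,
                            prolongation_coeff_speed = 0,
                            residual_velocity_coeff = 0)
  out <- apply_cs_execution(prof, dev)
  expect_equal(compression_time(out, 0.5) / compression_time(prof, 0.5),
               1.2, tolerance = 1e-3)
})

test_that("residual-velocity deviation makes separation decrease over the dwell", {
  prof <- simulate_displacement(demo_press(), 40, 3)
  dev <- cs_deviation_model(0, 0, residual_velocity_coeff = 25)
  out <- apply_cs_execution(prof, dev)
  win0 <- detect_dwell_window(prof, 1e-9)
  sel <- out$time >= win0[1] & out$time <= win0[2]
  expect_true(all(diff(out$separation[sel]) < 0))
})

test_that("profile CSV round-trips through the documented dialect", {
  prof <- triangle_profile()
  path <- withr::local_tempfile(fileext = ".csv")
  write_profile(prof, path)
  header <- readLines(path, n = 1)
  expect_identical(header, "time_ms,upper_pos_mm,lower_pos_mm,stress_MPa")
  back <- read_profile(path)
  expect_equal(back$separation, prof$separation)
  expect_equal(back$stress, prof$stress)
})

test_that("malformed profile containers are rejected", {
  expect_error(compaction_profile(c(0, 1, 1.5), c(1, 1, 1), c(0, 0, 0)),
               "uniform")
  expect_error(compaction_profile(c(0, 1, 2), c(0, 0, 0), c(1, 1, 1)),
               "separation")
  expect_error(compaction_profile(c(0, 1), c(1, 1), c(0, 0),
                                  stress = c(-5, 0)), "stress")
})
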