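test_that("ideal filling time is volume times density over mass flow", {
  f <- demo_feeder(volume = 1e-3, density = 500)
  op <- operating_point(20, 20, 150, 5e-4, mass_flow = 5e-3)
  expect_equal(ideal_filling_time(f, op), 100)
  op2 <- operating_point(20, 20, 150, 5e-4, mass_flow = 1e-2)
  expect_equal(ideal_filling_time(f, op2), 50)  # inverse in mass flow
  expect_error(ideal_filling_time(f, operating_point(20, 20, 150, 5e-4)),
               "mass_flow")
})

test_that("rotary shear number matches hand arithmetic and scaling laws", {
  press <- demo_press(n_dies = 10)
  feeder <- demo_feeder(paddle = 0.1, spokes = 4, clearance = 0.002,
                        holdup = 0.5)
  op <- operating_point(20, 20, 150, 5e-4)
  sn <- shear_number_rotary(press, feeder, op)
  # (pi*0.1*4/0.002) * (0.5/(5e-4*10))^2 * 1 = 6.283e6
  expect_equal(sn$value, pi * 0.1 * 4 / 0.002 * 100^2, tolerance = 1e-12)
  expect_equal(sn$value, 6.283e6, tolerance = 1e-4)

  op0 <- operating_point(20, 0, 150, 5e-4)
  expect_identical(shear_number_rotary(press, feeder, op0)$value, 0)

  op2 <- operating_point(20, 40, 150, 5e-4)
  expect_equal(shear_number_rotary(press, feeder, op2)$value, 4 * sn$value)
})

test_that("shear number equals the product of its decomposition terms", {
  set.seed(3)
  for (i in 1:20) {
    press <- random_press()
    feeder <- demo_feeder(paddle = runif(1, 0.05, 0.2),
                          spokes = sample(2:6, 1),
                          clearance = runif(1, 5e-4, 5e-3),
                          holdup = runif(1, 0.05, 0.4))
    op <- operating_point(runif(1, 10, 80), runif(1, 0, 300),
                          150, runif(1, 2e-4, 1e-3))
    for (sn in list(shear_number_rotary(press, feeder, op),
                    shear_number_cs(press, feeder, op))) {
      prod_terms <- sn$shear_intensity_term * sn$residence_term *
        sn$frequency_term * sn$correction_factor
      expect_equal(sn$value, prod_terms, tolerance = 1e-12)
      expect_true(all(unlist(sn[c("shear_intensity_term", "residence_term",
                                  "frequency_term", "correction_factor")]) >= 0))
    }
  }
})

test_that("shear number is invariant under joint frequency scaling", {
  press <- demo_press(); feeder <- demo_feeder()
  a <- shear_number_rotary(press, feeder, operating_point(20, 30, 150, 5e-4))
  b <- shear_number_rotary(press, feeder, operating_point(60, 90, 150, 5e-4))
  expect_equal(a$value, b$value, tolerance = 1e-12)
})

test_that("CS correction factor follows the fill/die-spacing angles", {
  feeder <- demo_feeder()
  op <- operating_point(20, 20, 150, 5e-4)
  # phi_fill = 60, phi_dies = 12.4 -> (3600/4464)^2 = 0.6504
  press <- demo_press(fill_angle = 60, die_spacing = 12.4)
  sn <- shear_number_cs(press, feeder, op)
  expect_equal(sn$correction_factor, (3600 / 4464)^2, tolerance = 1e-12)
  expect_equal(sn$correction_factor, 0.6504, tolerance = 1e-4)

  # phi_fill^2 = 360 * phi_dies makes the correction vanish
  press_id <- demo_press(fill_angle = 120, die_spacing = 40)
  expect_equal(shear_number_cs(press_id, feeder, op)$value,
               shear_number_rotary(press_id, feeder, op)$value,
               tolerance = 1e-12)
})

test_that("uncorrected parametric transfer overstates the CS shear number by orders", {
  xl100 <- load_fixture("XL100")
  rot <- shear_number_rotary(xl100$press, xl100$feeder,
                             operating_point(20, 20, 150, 3.0e-4))
  cs_uncorr <- shear_number_rotary(xl100$press, xl100$feeder,
                                   operating_point(20, 272, 150, 3.0e-4))
  expect_equal(log10(cs_uncorr$value / rot$value), log10((272 / 20)^2),
               tolerance = 1e-12)
  expect_gt(rot$value, 1e6)       # practical settings land in the 1E6-1E9 band
  expect_lt(rot$value, 1e9)
})

test_that("paddle matching is weight-invariant, rounds to machine steps and round-trips", {
  xl100 <- load_fixture("XL100")
  cs <- load_fixture("StylOne")
  for (w in c(3.0e-4, 7.25e-4)) {
    op <- operating_point(20, 60, 150, w)
    m <- match_paddle_frequency(xl100$press, xl100$feeder, cs$feeder, op)
    expect_equal(as.numeric(m), 128)
    # round trip: the unrounded frequency reproduces the rotary shear number
    op_cs <- operating_point(20, attr(m, "unrounded"), 150, w)
    sn_cs <- shear_number_cs(xl100$press, cs$feeder, op_cs)
    expect_equal(sn_cs$value, attr(m, "target_sn"), tolerance = 1e-9)
  }

  # identical feeders and vanishing correction: identity mapping
  press_id <- demo_press(fill_angle = 120, die_spacing = 40)
  f <- demo_feeder()
  op <- operating_point(20, 37, 150, 5e-4)
  m_id <- match_paddle_frequency(press_id, f, f, op, rounding_step = 1)
  expect_equal(attr(m_id, "unrounded"), 37, tolerance = 1e-12)

  expect_error(match_paddle_frequency(xl100$press, xl100$feeder, cs$feeder,
                                      operating_point(20, 0, 150, 5e-4)),
               "finite and > 0")
})
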