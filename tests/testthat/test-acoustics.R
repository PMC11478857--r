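# Closed-form acoustic algebra: polynomial, impedances, reflection,
# and the speed / attenuation estimators.

test_that("water speed-of-sound polynomial evaluates correctly and guards its range", {
  poly <- marczak_polynomial()
  expect_identical(water_speed_of_sound(0), poly$coefficients[1])
  # independent direct summation at 20 degC
  direct <- sum(poly$coefficients * 20^(0:5))
  expect_equal(water_speed_of_sound(20), direct)
  expect_equal(water_speed_of_sound(20), 1482.38, tolerance = 1e-5)
  expect_error(water_speed_of_sound(-10), "validity range")
  expect_error(water_speed_of_sound(96), "validity range")
  expect_error(marczak_polynomial(coefficients = 1:5), "six")
})

test_that("acoustic impedance is density times speed and inputs are validated", {
  expect_equal(acoustic_impedance(plexiglas()), 1170 * 2760)
  expect_equal(acoustic_impedance(water_medium(20)), 998.2 * 1482.38,
               tolerance = 1e-5)
  expect_error(acoustic_medium("bad", 0, 1500), "density")
  expect_error(acoustic_medium("bad", 1000, -1), "speed_of_sound")
})

test_that("reflection coefficient is signed, antisymmetric, and matches the buffer-water value", {
  w <- water_medium(20)
  p <- plexiglas()
  expect_equal(reflection_coefficient(w, w), 0)
  expect_equal(reflection_coefficient(p, w), -0.3715, tolerance = 1e-3)
  # antisymmetry over random media pairs
  withr::with_seed(1, {
    for (i in 1:25) {
      a <- acoustic_medium("a", runif(1, 500, 3000), runif(1, 300, 6000))
      b <- acoustic_medium("b", runif(1, 500, 3000), runif(1, 300, 6000))
      expect_equal(reflection_coefficient(a, b),
                   -reflection_coefficient(b, a))
      expect_lt(abs(reflection_coefficient(a, b)), 1)
    }
  })
})

test_that("two-way transmission factor equals T12*T21 and handles limits", {
  expect_equal(two_way_transmission_factor(0), 1)
  expect_equal(two_way_transmission_factor(1), 0)
  expect_equal(two_way_transmission_factor(-1), 0)
  expect_equal(two_way_transmission_factor(-0.3715), 0.8620, tolerance = 1e-4)
  expect_error(two_way_transmission_factor(1.2), "<=")
  # brute-force identity: 1 - R^2 = (2 Z2/(Z1+Z2)) * (2 Z1/(Z1+Z2))
  withr::with_seed(2, {
    for (i in 1:50) {
      z1 <- runif(1, 1e5, 1e7); z2 <- runif(1, 1e5, 1e7)
      r <- (z2 - z1) / (z2 + z1)
      expect_equal(two_way_transmission_factor(r),
                   (2 * z2 / (z1 + z2)) * (2 * z1 / (z1 + z2)))
    }
  })
})

test_that("speed_from_tof inverts the forward time-of-flight relation", {
  c_w <- water_speed_of_sound(20)
  expect_equal(speed_from_tof(2 * 0.0375 / c_w, 0.0375), c_w)
  # anchored to the reported 1 wt% speed
  expect_equal(speed_from_tof(2 * 0.0375 / 1488.86, 0.0375), 1488.86)
  expect_equal(speed_from_tof(50.594e-6, 0.0375), 1482.38, tolerance = 0.01)
  expect_error(speed_from_tof(0, 0.0375), "positive")
  expect_error(speed_from_tof(1e-5, -1), "positive")
})

test_that("water-reference diameter calibration is the inverse map and linear in TOF", {
  c_w <- water_speed_of_sound(20)
  tof_w <- 2 * 0.0375 / c_w
  expect_equal(diameter_from_water_reference(tof_w, 20), 0.0375)
  expect_equal(diameter_from_water_reference(50.594e-6, 20), 0.0375,
               tolerance = 1e-4)
  expect_equal(diameter_from_water_reference(2 * tof_w, 20), 2 * 0.0375)
  expect_error(diameter_from_water_reference(tof_w, -10), "validity")
})

test_that("C0 calibration is definitional and independent of the assumed buffer attenuation", {
  expect_equal(calibrate_C0(-0.3715, -0.3715), 1)
  expect_error(calibrate_C0(-0.3715, 0), "nonzero")
  expect_error(calibrate_C0(0.3715, -0.3715), "sign")
  # route via the incident-amplitude form: A0 = A1/(e^(-2 aB dB) R12),
  # C0 = A0 e^(-2 aB dB) must agree for any aB, dB
  withr::with_seed(3, {
    for (i in 1:20) {
      aB <- runif(1, 0, 200); dB <- runif(1, 0.005, 0.05)
      A1 <- -runif(1, 0.01, 1); R12 <- -runif(1, 0.05, 0.95)
      A0 <- A1 / (exp(-2 * aB * dB) * R12)
      expect_equal(A0 * exp(-2 * aB * dB), calibrate_C0(A1, R12))
    }
  })
})

test_that("attenuation estimator matches derived fixed points and rejects bad input", {
  # zero-attenuation fixed point: A2 built with alpha = 0
  A2_0 <- 0.3715 * (1 - 0.3715^2)
  expect_equal(attenuation_from_amplitudes(-0.3715, A2_0, 1, 0.0375), 0,
               tolerance = 1e-12)
  expect_equal(attenuation_from_amplitudes(-0.3715, 0.22009, 1, 0.0375), 5.0,
               tolerance = 1e-3)
  expect_error(attenuation_from_amplitudes(-0.3715, -0.1, 1, 0.0375),
               "positive")
  expect_error(attenuation_from_amplitudes(0.3715, 0.22, 1, 0.0375),
               "log argument")
})

test_that("calibrated and reflection-coefficient forms of the estimator are equivalent", {
  d <- 0.0375
  withr::with_seed(4, {
    for (i in 1:30) {
      C0 <- runif(1, 0.1, 5)
      R12 <- -runif(1, 0.05, 0.9)
      A1 <- C0 * R12
      A2 <- runif(1, 0.01, 0.9) * abs(A1)
      via_C0 <- attenuation_from_amplitudes(A1, A2, C0, d)
      via_R12 <- log(-A1 * (1 - R12^2) / A2) / (2 * d)
      expect_equal(via_C0, via_R12)
      # the general two-interface oracle reduces to the same value when
      # R23 = -R12 (signed second echo has opposite sign to the first)
      via_general <- attenuation_general(A1, -sign(A1) * A2, R12, -R12, d)
      expect_equal(via_general, via_C0)
    }
  })
})

test_that("forward amplitude model round-trips through the estimator over an attenuation grid", {
  d <- 0.0375
  C0 <- 0.427
  R12 <- -0.3715272
  A1 <- C0 * R12
  for (alpha in c(0, 0.5, 2, 5, 10, 20)) {
    A2 <- abs(C0 * (1 - R12^2) * (-R12) * exp(-2 * alpha * d))
    rec <- attenuation_from_amplitudes(A1, A2, C0, d)
    expect_equal(rec, alpha, tolerance = 1e-10)
  }
})

test_that("neper/decibel conversion is the standard factor and invertible", {
  expect_equal(np_to_db(1), 8.6859, tolerance = 1e-4)
  expect_equal(db_to_np(np_to_db(3.7)), 3.7)
})
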