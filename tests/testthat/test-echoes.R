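# Echo detection, water-reference calibration, and per-sample estimation.

test_that("echo features scale linearly with amplitude and TOF is scale/offset invariant", {
  rec <- simulate_record(water20, std_geometry, std_buffer, std_pulse,
                         noise_sd = 0)
  f0 <- detect_echoes(rec, std_geometry, std_buffer)
  scaled <- rec
  scaled$samples <- 3.7 * rec$samples
  f1 <- detect_echoes(scaled, std_geometry, std_buffer)
  expect_equal(f1$tof, f0$tof)
  expect_equal(f1$A1_magnitude, 3.7 * f0$A1_magnitude)
  expect_equal(f1$A2_magnitude, 3.7 * f0$A2_magnitude)
  # DC offset is removed by detrending before extremum picking
  shifted <- rec
  shifted$samples <- rec$samples + 0.5
  f2 <- detect_echoes(shifted, std_geometry, std_buffer)
  expect_equal(f2$tof, f0$tof)
  expect_equal(f2$A1_magnitude, f0$A1_magnitude, tolerance = 1e-6)
})

test_that("records without echoes raise a no-echo error", {
  noise_only <- withr::with_seed(6, {
    waveform_record(stats::rnorm(7200, sd = 1e-4), sampling_rate = 1e8)
  })
  expect_error(detect_echoes(noise_only, std_geometry, std_buffer),
               "no echo")
})

test_that("window handling guards edges and overlap", {
  rec <- simulate_record(water20, std_geometry, std_buffer, std_pulse,
                         noise_sd = 0)
  expect_error(detect_echoes(rec, std_geometry, std_buffer,
                             first_window = c(5e-6, 2e-5),
                             second_window = c(1.2e-5, 7e-5)),
               "overlap")
  # a window ending right at the first echo leaves no room for the segment
  expect_error(detect_echoes(rec, std_geometry, std_buffer,
                             window_length = 30000),
               "edge")
})

test_that("water calibration recovers the vessel diameter within one sample period", {
  refs <- make_records(water20, n = 5)
  cal <- calibrate_from_water(refs, std_geometry, std_buffer)
  c_w <- water_speed_of_sound(20)
  tol_d <- c_w / std_pulse$sampling_rate / 2  # one TOF sample in distance
  expect_lt(abs(cal$diameter - 0.0375), tol_d)
  expect_equal(cal$R12_reference,
               reflection_coefficient(std_buffer, water20))
  expect_gt(cal$C0, 0)
  expect_error(calibrate_from_water(list()), "non-empty")
})

test_that("calibrated C0 equals the simulator common factor times the analytic burst gain", {
  # windowed-DFT oracle: for a gaussian-enveloped tone burst the
  # carrier-bin magnitude (2/N normalization) is amplitude * sum(env)/N
  refs <- make_records(water20, n = 3)
  cal <- calibrate_from_water(refs, std_geometry, std_buffer)
  common <- refs[[1]]$truth$common_factor
  sigma_samples <- std_pulse$duration / 6 * std_pulse$sampling_rate
  gain <- sqrt(2 * pi) * sigma_samples / 300
  expect_equal(cal$C0, common * gain, tolerance = 0.01)
})

test_that("estimates are invariant to buffer attenuation and excitation amplitude at fixed product", {
  med <- acoustic_medium("s", 998.2, 1488.86, 3)
  run_chain <- function(alphaB, A0) {
    geo <- vessel_geometry(0.0375, 0.017, alphaB)
    pulse <- pulse_parameters(amplitude = A0)
    cal <- calibrate_from_water(make_records(water20, n = 3, pulse = pulse,
                                             geometry = geo),
                                geo, std_buffer)
    est <- estimate_sample(make_records(med, n = 3, pulse = pulse,
                                        geometry = geo),
                           cal, geo, std_buffer)
    c(est$speed_of_sound, est$attenuation, cal$C0)
  }
  # alpha_B 25 -> 50 halves exp(-2 aB dB); A0 compensates to fix the product
  base <- run_chain(25, 1)
  comp <- run_chain(50, exp(2 * (50 - 25) * 0.017))
  expect_equal(comp, base, tolerance = 1e-9)
})

test_that("noiseless pipeline recovers speed and attenuation near the 1 wt% anchor", {
  med <- acoustic_medium("s", 998.2, 1488.86, 3)
  est <- estimate_sample(make_records(med, n = 3), std_calibration,
                         std_geometry, std_buffer)
  expect_lt(abs(est$speed_of_sound - 1488.86), 0.1)
  expect_lt(abs(est$attenuation - 3), 0.05)
})

test_that("noiseless recovery holds over a grid of speeds and attenuations", {
  dt <- 1 / std_pulse$sampling_rate
  d <- std_geometry$sample_path_diameter
  for (c_true in c(1470, 1485, 1500)) {
    for (alpha_true in c(0, 5, 20)) {
      med <- acoustic_medium("g", 998.2, c_true, alpha_true)
      est <- estimate_sample(make_records(med, n = 1), std_calibration,
                             std_geometry, std_buffer)
      # TOF quantization in both the measurement and the calibration
      tol_c <- 2 * c_true^2 * dt / (2 * d)
      expect_lt(abs(est$speed_of_sound - c_true), tol_c)
      expect_lt(abs(est$attenuation - alpha_true),
                max(0.01 * alpha_true, 0.02))
    }
  }
})

test_that("increasing true attenuation decreases A2 and increases the estimate monotonically", {
  alphas <- c(1, 4, 8, 14, 20)
  a2 <- numeric(0)
  est <- numeric(0)
  for (a in alphas) {
    med <- acoustic_medium("m", 998.2, 1485, a)
    rec <- simulate_record(med, std_geometry, std_buffer, std_pulse,
                           noise_sd = 0)
    f <- detect_echoes(rec, std_geometry, std_buffer)
    a2 <- c(a2, f$A2_magnitude)
    s <- estimate_sample(list(rec), std_calibration, std_geometry, std_buffer)
    est <- c(est, s$attenuation)
  }
  expect_true(all(diff(a2) < 0))
  expect_true(all(diff(est) > 0))
})

test_that("a single record yields zero SDs and is flagged", {
  est <- estimate_sample(make_records(water20, n = 1), std_calibration,
                         std_geometry, std_buffer)
  expect_equal(est$n_records, 1L)
  expect_true(est$single_record)
  expect_identical(est$sd_speed, 0)
  expect_identical(est$sd_attenuation, 0)
})

test_that("per-record failures abort by default and are excluded under the omit policy", {
  good <- make_records(water20, n = 2)
  bad <- withr::with_seed(7, {
    waveform_record(stats::rnorm(7200, sd = 1e-4), sampling_rate = 1e8)
  })
  recs <- c(good, list(bad))
  expect_error(estimate_sample(recs, std_calibration, std_geometry,
                               std_buffer),
               "omit")
  expect_warning(
    est <- estimate_sample(recs, std_calibration, std_geometry, std_buffer,
                           on_error = "omit"),
    "excluded")
  expect_equal(est$n_records, 2L)
})

test_that("temperature mismatch between sample and calibration warns", {
  warm <- make_records(water20, n = 1, temperature = 21.5)
  expect_warning(
    estimate_sample(warm, std_calibration, std_geometry, std_buffer),
    "temperature")
})
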