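#' Locate the two echoes and extract their spectral amplitudes
#'
#' Implements the time/frequency analysis of one pulse-echo record: the
#' record is mean-detrended, the first reflection is located as the global
#' maximum M1 inside the first search window, the second reflection as the
#' global minimum M2 inside the second window (the second echo is
#' phase-inverted, so its global minimum corresponds to the first echo's
#' global maximum and the difference `M2_time - M1_time` is the time of
#' flight through the sample). A `window_length`-sample segment centered on
#' each extremum is transformed with the DFT and the magnitude at the bin
#' nearest the carrier is taken as the echo amplitude (A1, A2). Magnitudes
#' are normalized by `2 / window_length` so a full-window tone of amplitude
#' `a` yields magnitude `a`; only ratios of magnitudes enter the attenuation
#' estimator, so the normalization is cosmetic.
#'
#' Default search windows follow the expected geometry: the first window is
#' 0.5--1.5 times the buffer round-trip delay `2*d_B/c_buffer`, and the
#' second window is `M1_time` plus 0.5--1.5 times the expected time of
#' flight `2*d/expected_speed`. Both are overridable.
#'
#' @param record A [waveform_record()].
#' @param geometry A [vessel_geometry()] (used for the default windows).
#' @param buffer Buffer [acoustic_medium()] (used for the default windows).
#' @param expected_speed Rough expected sample speed of sound in m/s used
#'   only to center the second search window; default 1480 covers aqueous
#'   samples generously (window spans roughly 990--2960 m/s).
#' @param window_length DFT segment length in samples (default 300).
#' @param carrier Carrier frequency in Hz at which magnitudes are read.
#' @param first_window,second_window Optional explicit time intervals (s)
#'   overriding the defaults; the second window is absolute, not relative to
#'   M1.
#' @param noise_floor Minimum admissible extremum amplitude. `NULL` (default)
#'   estimates it as 5 standard deviations of the pre-echo quiet segment
#'   (first quarter of the buffer delay). An extremum below the floor raises
#'   a "no echo" error.
#' @return An object of class `echo_features`: `M1_time`, `M1_value`,
#'   `M2_time`, `M2_value`, `tof`, `A1_magnitude`, `A2_magnitude`.
#' @export
detect_echoes <- function(record, geometry = default_geometry(),
                          buffer = plexiglas(), expected_speed = 1480,
                          window_length = 300, carrier = 2e6,
                          first_window = NULL, second_window = NULL,
                          noise_floor = NULL) {
  stopifnot(inherits(record, "waveform_record"))
  fs <- record$sampling_rate
  dt <- 1 / fs
  x <- record$samples - mean(record$samples)  # DC detrend
  n <- length(x)
  t_end <- (n - 1) * dt

  expected_delay <- 2 * geometry$buffer_diameter / buffer$speed_of_sound
  expected_tof <- 2 * geometry$sample_path_diameter / expected_speed

  if (is.null(first_window)) {
    first_window <- c(0.5, 1.5) * expected_delay
  }
  w1 <- window_indices(first_window, dt, n)

  if (is.null(noise_floor)) {
    quiet <- x[seq_len(max(2L, floor(0.25 * expected_delay / dt)))]
    noise_floor <- 5 * stats::sd(quiet)
  }

  i1 <- w1[which.max(x[w1])]
  if (x[i1] <= noise_floor) {
    stop("no echo found: first-reflection peak below the noise floor")
  }

  if (is.null(second_window)) {
    second_window <- (i1 - 1) * dt + c(0.5, 1.5) * expected_tof
  }
  second_window[2] <- min(second_window[2], t_end)
  if (second_window[1] >= second_window[2]) {
    stop("second search window lies outside the record")
  }
  w2 <- window_indices(second_window, dt, n)
  if (length(intersect(w1, w2)) > 0) {
    stop("search windows overlap")
  }

  i2 <- w2[which.min(x[w2])]
  if (-x[i2] <= noise_floor) {
    stop("no echo found: second-reflection peak below the noise floor")
  }
  if (i2 <= i1) stop("second reflection precedes the first")

  half <- window_length %/% 2
  for (i in c(i1, i2)) {
    if (i - half < 1L || i + (window_length - half - 1L) > n) {
      stop("echo extremum within half a window of the record edge")
    }
  }
  seg1 <- x[(i1 - half):(i1 + window_length - half - 1L)]
  seg2 <- x[(i2 - half):(i2 + window_length - half - 1L)]

  k <- round(carrier * window_length * dt)  # bin nearest the carrier
  A1 <- 2 * Mod(stats::fft(seg1))[k + 1L] / window_length
  A2 <- 2 * Mod(stats::fft(seg2))[k + 1L] / window_length

  structure(
    list(M1_time = (i1 - 1) * dt, M1_value = x[i1],
         M2_time = (i2 - 1) * dt, M2_value = x[i2],
         tof = (i2 - i1) * dt,
         A1_magnitude = A1, A2_magnitude = A2),
    class = "echo_features"
  )
}

window_indices <- function(window, dt, n) {
  i_lo <- max(1L, floor(window[1] / dt) + 1L)
  i_hi <- min(n, ceiling(window[2] / dt) + 1L)
  if (i_lo >= i_hi) stop("search window lies outside the record")
  i_lo:i_hi
}

#' @export
print.echo_features <- function(x, ...) {
  cat(sprintf(
    "<echo_features> M1 @ %.4f us (%.4g), M2 @ %.4f us (%.4g), TOF = %.4f us\n",
    x$M1_time * 1e6, x$M1_value, x$M2_time * 1e6, x$M2_value, x$tof * 1e6))
  cat(sprintf("  A1 = %.5g, A2 = %.5g (carrier-bin DFT magnitudes)\n",
              x$A1_magnitude, x$A2_magnitude))
  invisible(x)
}

#' Water-reference calibration
#'
#' Turns a set of water records at known temperature into the calibration
#' constants of the cell: the vessel diameter
#' `d = mean(TOF_w) * c_w(T) / 2` (with `c_w` from the temperature
#' polynomial) and the amplitude constant `C0 = A1_water / R12`, where
#' `R12` is the buffer--water reflection coefficient computed from the known
#' material properties and `A1_water` is the mean first-echo magnitude with
#' the sign of `R12` applied (for water against Plexiglas the interface
#' inverts, so the signed amplitude is negative). Neither the buffer
#' attenuation nor the excitation amplitude is needed: only their product
#' enters, and it is absorbed into C0.
#'
#' @param records List of water [waveform_record()]s at a common temperature.
#' @param geometry A [vessel_geometry()]; only the buffer fields and the
#'   nominal diameter (for search windows) are used.
#' @param buffer Buffer [acoustic_medium()].
#' @param poly A [marczak_polynomial()].
#' @param ... Passed to [detect_echoes()].
#' @return An object of class `us_calibration`: `diameter`, `C0`,
#'   `R12_reference`, `temperature`, `n_records`.
#' @export
calibrate_from_water <- function(records, geometry = default_geometry(),
                                 buffer = plexiglas(),
                                 poly = marczak_polynomial(), ...) {
  if (!is.list(records) || length(records) == 0L) {
    stop("'records' must be a non-empty list of waveform records")
  }
  temps <- vapply(records, function(r) r$temperature, numeric(1))
  if (diff(range(temps)) > 0.5) {
    warning("reference record temperatures span more than 0.5 degC")
  }
  temperature <- mean(temps)
  c_w <- water_speed_of_sound(temperature, poly)
  water <- water_medium(temperature, poly = poly)

  feats <- lapply(records, detect_echoes, geometry = geometry,
                  buffer = buffer, expected_speed = c_w, ...)
  tofs <- vapply(feats, function(f) f$tof, numeric(1))
  a1s <- vapply(feats, function(f) f$A1_magnitude, numeric(1))

  d <- mean(tofs) * c_w / 2
  R12 <- reflection_coefficient(buffer, water)
  C0 <- calibrate_C0(sign(R12) * mean(a1s), R12)

  structure(
    list(diameter = d, C0 = C0, R12_reference = R12,
         temperature = temperature, n_records = length(records)),
    class = "us_calibration"
  )
}

#' @export
print.us_calibration <- function(x, ...) {
  cat(sprintf(
    "<us_calibration> d = %.4f mm, C0 = %.5g, R12(ref) = %.4f, T = %.1f degC (n = %d)\n",
    1000 * x$diameter, x$C0, x$R12_reference, x$temperature, x$n_records))
  invisible(x)
}

#' Per-sample speed of sound and attenuation estimate
#'
#' Processes every record of one sample: per record, the speed of sound is
#' `c = 2 * d / TOF` and the attenuation coefficient is the calibrated
#' estimator [attenuation_from_amplitudes()] applied to the signed
#' first-echo magnitude (sign taken from the calibration's reference
#' reflection coefficient) and the second-echo magnitude. Estimates are
#' computed per record and then averaged, so the reported standard
#' deviations are the record-to-record measurement spread.
#'
#' @param records Non-empty list of [waveform_record()]s of one sample.
#' @param calibration A `us_calibration` from [calibrate_from_water()].
#' @param geometry,buffer Passed to [detect_echoes()] for search windows.
#' @param on_error `"abort"` (default): any per-record failure aborts the
#'   sample; `"omit"`: failing records are dropped with a warning.
#' @param ... Passed to [detect_echoes()].
#' @return An object of class `sample_estimate`: `sample_id`, `wt_pct`,
#'   `replicate`, `speed_of_sound`, `attenuation`, `sd_speed`,
#'   `sd_attenuation`, `n_records`, plus the per-record feature table
#'   `records`.
#' @export
estimate_sample <- function(records, calibration,
                            geometry = default_geometry(),
                            buffer = plexiglas(),
                            on_error = c("abort", "omit"), ...) {
  on_error <- match.arg(on_error)
  if (!is.list(records) || length(records) == 0L) {
    stop("'records' must be a non-empty list of waveform records")
  }
  stopifnot(inherits(calibration, "us_calibration"))

  temps <- vapply(records, function(r) r$temperature, numeric(1))
  if (any(abs(temps - calibration$temperature) > 0.5)) {
    warning(sprintf(
      "record temperature differs from calibration temperature (%.1f degC) by more than 0.5 degC",
      calibration$temperature))
  }

  d <- calibration$diameter
  sgn <- sign(calibration$R12_reference)
  rows <- vector("list", length(records))
  failures <- character(0)
  for (i in seq_along(records)) {
    r <- records[[i]]
    res <- tryCatch({
      f <- detect_echoes(r, geometry = geometry, buffer = buffer, ...)
      data.frame(
        sample_id = r$sample_id, wt_pct = r$wt_pct,
        replicate = r$replicate, record_index = r$record_index,
        tof_s = f$tof, a1_mag = f$A1_magnitude, a2_mag = f$A2_magnitude,
        c_mps = speed_from_tof(f$tof, d),
        alpha_npm = attenuation_from_amplitudes(
          sgn * f$A1_magnitude, f$A2_magnitude, calibration$C0, d),
        stringsAsFactors = FALSE)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      msg <- sprintf("record %d: %s", i, conditionMessage(res))
      if (on_error == "abort") {
        stop("sample estimation failed (", msg,
             "); use on_error = \"omit\" to drop failing records")
      }
      failures <- c(failures, msg)
    } else {
      rows[[i]] <- res
    }
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(failures) > 0) {
    warning(sprintf("excluded %d failing record(s): %s", length(failures),
                    paste(failures, collapse = "; ")))
  }
  if (length(rows) == 0L) stop("all records failed echo detection")
  per_record <- do.call(rbind, rows)

  n <- nrow(per_record)
  structure(
    list(sample_id = per_record$sample_id[1],
         wt_pct = per_record$wt_pct[1],
         replicate = per_record$replicate[1],
         speed_of_sound = mean(per_record$c_mps),
         attenuation = mean(per_record$alpha_npm),
         sd_speed = if (n > 1) stats::sd(per_record$c_mps) else 0,
         sd_attenuation = if (n > 1) stats::sd(per_record$alpha_npm) else 0,
         n_records = n, single_record = n == 1L,
         records = per_record),
    class = "sample_estimate"
  )
}

#' @export
print.sample_estimate <- function(x, ...) {
  cat(sprintf(
    "<sample_estimate> %s: c = %.3f +/- %.3f m/s, alpha = %.4f +/- %.4f Np/m (n = %d)\n",
    x$sample_id, x$speed_of_sound, x$sd_speed, x$attenuation,
    x$sd_attenuation, x$n_records))
  invisible(x)
}
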