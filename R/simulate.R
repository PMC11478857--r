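#' Excitation pulse parameters
#'
#' The transducer excitation is modeled as an `n_cycles` sine tone burst at
#' the carrier frequency. By default the burst carries a Gaussian envelope:
#' a strictly enveloped burst has a unique global extremum per echo, which the
#' extremum-based time-of-flight picker requires (a flat rectangular burst
#' makes every carrier cycle an equally tall peak, so the picked extremum is
#' degenerate and hops between cycles under noise). A `rectangular` envelope
#' is available for experimentation.
#'
#' @param center_frequency Carrier frequency in Hz (default 2 MHz).
#' @param n_cycles Number of carrier cycles in the burst (default 4).
#' @param amplitude Initial wave amplitude A0 (arbitrary units, > 0).
#' @param envelope `"gaussian"` (default) or `"rectangular"`.
#' @param sampling_rate Sampling rate in Hz; must be at least 10 times the
#'   carrier. Default 100 MHz (50 samples per carrier cycle); the physical
#'   instrument recorded at 1 GHz, available by setting this parameter.
#' @return An object of class `pulse_parameters`.
#' @export
pulse_parameters <- function(center_frequency = 2e6, n_cycles = 4,
                             amplitude = 1,
                             envelope = c("gaussian", "rectangular"),
                             sampling_rate = 100e6) {
  envelope <- match.arg(envelope)
  if (!is.numeric(center_frequency) || center_frequency <= 0) {
    stop("'center_frequency' must be positive")
  }
  if (!is.numeric(n_cycles) || n_cycles < 1) stop("'n_cycles' must be >= 1")
  if (!is.numeric(amplitude) || amplitude <= 0) {
    stop("'amplitude' (A0) must be positive")
  }
  if (!is.numeric(sampling_rate) || sampling_rate < 10 * center_frequency) {
    stop("'sampling_rate' must be at least 10 x the carrier frequency ",
         "(undersampling)")
  }
  structure(
    list(center_frequency = center_frequency, n_cycles = n_cycles,
         amplitude = amplitude, envelope = envelope,
         sampling_rate = sampling_rate,
         duration = n_cycles / center_frequency),
    class = "pulse_parameters"
  )
}

# Unit-amplitude burst evaluated at times tau (s) since burst onset.
# Zero outside [0, duration].
burst_shape <- function(tau, pulse) {
  s <- sin(2 * pi * pulse$center_frequency * tau)
  inside <- tau >= 0 & tau <= pulse$duration
  if (pulse$envelope == "gaussian") {
    tc <- pulse$duration / 2
    sigma <- pulse$duration / 6
    s <- s * exp(-(tau - tc)^2 / (2 * sigma^2))
  }
  s * inside
}

#' Waveform record
#'
#' One sampled pulse-echo voltage trace plus acquisition metadata. The
#' simulator attaches the generating ground truth (`truth`), which the file
#' format preserves so that parameter-recovery tests can use it as an oracle.
#'
#' @param samples Numeric vector of sampled amplitudes; must be finite.
#' @param sampling_rate Sampling rate in Hz.
#' @param temperature Sample temperature in degC.
#' @param sample_id,replicate,record_index Provenance labels.
#' @param wt_pct Optional yeast concentration in wt%.
#' @param truth Optional list with elements `speed_of_sound` (m/s) and
#'   `attenuation` (Np/m) carried for testing; `NULL` for real data.
#' @return An object of class `waveform_record`.
#' @export
waveform_record <- function(samples, sampling_rate, temperature = 20,
                            sample_id = "sample", replicate = 1L,
                            record_index = 1L, wt_pct = NA_real_,
                            truth = NULL) {
  if (!is.numeric(samples) || length(samples) < 2L || any(!is.finite(samples))) {
    stop("'samples' must be a finite numeric vector")
  }
  if (!is.numeric(sampling_rate) || sampling_rate <= 0) {
    stop("'sampling_rate' must be positive")
  }
  structure(
    list(samples = as.numeric(samples), sampling_rate = sampling_rate,
         temperature = temperature, sample_id = sample_id,
         replicate = as.integer(replicate),
         record_index = as.integer(record_index),
         wt_pct = wt_pct, truth = truth),
    class = "waveform_record"
  )
}

#' @export
print.waveform_record <- function(x, ...) {
  cat(sprintf(
    "<waveform_record> %s (rep %d, rec %d): %d samples @ %.3g MHz, T = %.1f degC\n",
    x$sample_id, x$replicate, x$record_index, length(x$samples),
    x$sampling_rate / 1e6, x$temperature))
  if (!is.null(x$truth)) {
    cat(sprintf("  truth: c = %.4f m/s, alpha = %.4f Np/m\n",
                x$truth$speed_of_sound, x$truth$attenuation))
  }
  invisible(x)
}

#' Simulate one pulse-echo waveform record
#'
#' Builds the two-echo record the measurement cell produces: the excitation
#' burst travels down the Plexiglas buffer rod, partially reflects at the
#' buffer--sample interface (first echo, signed amplitude
#' `A0 * exp(-2*alpha_B*d_B) * R12`), and the transmitted part crosses the
#' sample, reflects at the sample--reflector interface, and returns (second
#' echo, delayed by `TOF = 2*d/c`, amplitude carrying the two-way
#' transmission factor `1 - R12^2`, the reflector reflection `R23 = -R12`,
#' and the sample attenuation `exp(-2*alpha*d)`). Because the reflector is
#' the same Plexiglas as the buffer, `R23 = -R12` and the second echo is
#' phase-inverted relative to the first. White Gaussian noise with standard
#' deviation `noise_sd` times the first-echo peak is added.
#'
#' @param sample An [acoustic_medium()] for the sample (medium 2); its
#'   `speed_of_sound` and `attenuation` are the ground truth.
#' @param geometry A [vessel_geometry()].
#' @param buffer An [acoustic_medium()] for the buffer rod; by construction
#'   the reflector is the same material.
#' @param pulse A [pulse_parameters()].
#' @param noise_sd Noise standard deviation relative to the first-echo peak
#'   amplitude (dimensionless). Default 0.001; see the methods vignette for
#'   how this reproduces the instrument's reported measurement precision.
#' @param seed Optional integer seed for reproducible noise. The caller's RNG
#'   state is restored on exit.
#' @param temperature Temperature in degC stored in the record metadata.
#' @param sample_id,replicate,record_index,wt_pct Provenance labels.
#' @return A [waveform_record()] whose `truth` holds the generating
#'   `speed_of_sound`, `attenuation`, `tof`, `buffer_delay`, `common_factor`
#'   (`A0 * exp(-2*alpha_B*d_B)`) and `R12`.
#' @examples
#' rec <- simulate_record(water_medium(20), default_geometry(), plexiglas(),
#'                        pulse_parameters(), noise_sd = 0, seed = 1)
#' rec
#' @export
simulate_record <- function(sample, geometry, buffer,
                            pulse = pulse_parameters(), noise_sd = 0.001,
                            seed = NULL, temperature = 20,
                            sample_id = "sample", replicate = 1L,
                            record_index = 1L, wt_pct = NA_real_) {
  stopifnot(inherits(sample, "acoustic_medium"),
            inherits(geometry, "vessel_geometry"),
            inherits(buffer, "acoustic_medium"),
            inherits(pulse, "pulse_parameters"))
  if (!is.numeric(noise_sd) || length(noise_sd) != 1L || noise_sd < 0) {
    stop("'noise_sd' must be a single non-negative number")
  }

  fs <- pulse$sampling_rate
  dt <- 1 / fs
  d <- geometry$sample_path_diameter
  buffer_delay <- 2 * geometry$buffer_diameter / buffer$speed_of_sound
  tof <- 2 * d / sample$speed_of_sound

  # echo separability: the sample transit must exceed the burst duration by
  # at least a factor of two, or the two echoes smear into each other
  if (tof < 2 * pulse$duration) {
    stop(sprintf(
      "echoes overlap: TOF (%.3g us) < 2 x pulse duration (%.3g us)",
      tof * 1e6, pulse$duration * 1e6))
  }
  if (buffer_delay < 2 * pulse$duration) {
    stop("buffer round-trip delay too short to separate the first echo ",
         "from the excitation")
  }

  common <- pulse$amplitude * exp(-2 * geometry$buffer_attenuation *
                                    geometry$buffer_diameter)
  R12 <- reflection_coefficient(buffer, sample)
  A1_signed <- common * R12
  # R23 = -R12 (reflector material = buffer material)
  A2_signed <- common * two_way_transmission_factor(R12) * (-R12) *
    exp(-2 * sample$attenuation * d)

  total_t <- 1.1 * (buffer_delay + tof + pulse$duration)
  n <- ceiling(total_t * fs)
  t <- (seq_len(n) - 1) * dt

  echo1 <- A1_signed * burst_shape(t - buffer_delay, pulse)
  echo2 <- A2_signed * burst_shape(t - buffer_delay - tof, pulse)
  x <- echo1 + echo2

  if (noise_sd > 0) {
    if (!is.null(seed)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        old_seed <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old_seed, envir = globalenv()),
                add = TRUE)
      }
      set.seed(seed)
    }
    peak1 <- max(abs(echo1))
    x <- x + stats::rnorm(n, sd = noise_sd * peak1)
  }

  waveform_record(
    samples = x, sampling_rate = fs, temperature = temperature,
    sample_id = sample_id, replicate = replicate,
    record_index = record_index, wt_pct = wt_pct,
    truth = list(speed_of_sound = sample$speed_of_sound,
                 attenuation = sample$attenuation, tof = tof,
                 buffer_delay = buffer_delay, common_factor = common,
                 R12 = R12)
  )
}
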