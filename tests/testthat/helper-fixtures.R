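# Shared fixtures: the study cell, a fast reduced design, and small
# record-set builders used across test files.

std_geometry <- default_geometry()
std_buffer <- plexiglas()
std_pulse <- pulse_parameters()  # 2 MHz, 4 cycles, gaussian, 100 MHz

water20 <- water_medium(20)

# n noiseless (or noisy) records of a medium, indexed for provenance
make_records <- function(medium, n = 3, noise_sd = 0, pulse = std_pulse,
                         geometry = std_geometry, buffer = std_buffer,
                         seed = NULL, ...) {
  maybe_seeded <- function(expr) {
    if (is.null(seed)) expr else withr::with_seed(seed, expr)
  }
  maybe_seeded(lapply(seq_len(n), function(i) {
    simulate_record(medium, geometry, buffer, pulse, noise_sd = noise_sd,
                    record_index = i, ...)
  }))
}

# water calibration reused by several files (noiseless; deterministic)
std_calibration <- calibrate_from_water(make_records(water20, n = 3),
                                        std_geometry, std_buffer)

small_design <- function(seed = 11L) {
  gradient_design(concentrations = c(0, 0.5, 1), replicates = 2,
                  records_per_sample = 3, seed = seed)
}

# mixture median oracle, independent of the package internals
mixture_median_oracle <- function(medians, log_sds, weights) {
  cdf <- function(x) {
    sum(weights * stats::plnorm(x, meanlog = log(medians), sdlog = log_sds))
  }
  stats::uniroot(function(x) cdf(x) - 0.5, lower = 0.05, upper = 500,
                 tol = 1e-12)$root
}
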