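#' Run a full concentration-gradient experiment in memory
#'
#' Streams the complete simulate -> calibrate -> process chain for one
#' strain: simulates a water reference and calibrates the cell, then
#' simulates each (concentration x replicate) sample's records and estimates
#' its speed of sound and attenuation, discarding each waveform after
#' processing so the full default design (11 x 3 x 30 records) stays small
#' in memory. Deterministic for a fixed design seed.
#'
#' @param profile A [strain_profile()].
#' @param design A [gradient_design()].
#' @param geometry A [vessel_geometry()].
#' @param buffer Buffer/reflector [acoustic_medium()].
#' @param pulse A [pulse_parameters()].
#' @param temperature Temperature in degC (calibration and samples).
#' @param reference_records Number of water-reference records for
#'   calibration (default: the design's records per sample).
#' @param noise_sd Waveform noise level; defaults to the profile's.
#' @param verbose Print progress.
#' @return An object of class `gradient_experiment` with elements
#'   `strain`, `design`, `calibration`, `estimates` (data frame: one row per
#'   concentration x replicate with estimated and true values) and
#'   `per_record` (per-record feature table).
#' @export
run_gradient_experiment <- function(profile, design = gradient_design(),
                                    geometry = default_geometry(),
                                    buffer = plexiglas(),
                                    pulse = pulse_parameters(),
                                    temperature = 20,
                                    reference_records = design$records_per_sample,
                                    noise_sd = profile$noise_relative_sd,
                                    verbose = FALSE) {
  stopifnot(inherits(profile, "strain_profile"),
            inherits(design, "gradient_design"))
  truth <- gradient_truth(profile, design)
  out <- with_preserved_seed(design$seed, {
    water <- water_medium(temperature)
    refs <- lapply(seq_len(reference_records), function(i) {
      simulate_record(water, geometry, buffer, pulse, noise_sd = noise_sd,
                      temperature = temperature, sample_id = "water_ref",
                      record_index = i)
    })
    calibration <- calibrate_from_water(refs, geometry, buffer)
    if (verbose) print(calibration)

    est_rows <- vector("list", nrow(truth))
    rec_rows <- vector("list", nrow(truth))
    for (i in seq_len(nrow(truth))) {
      med <- sample_medium(profile, truth$wt_pct[i])
      recs <- lapply(seq_len(design$records_per_sample), function(r) {
        simulate_record(med, geometry, buffer, pulse, noise_sd = noise_sd,
                        temperature = temperature,
                        sample_id = truth$sample_id[i],
                        replicate = truth$replicate[i], record_index = r,
                        wt_pct = truth$wt_pct[i])
      })
      est <- estimate_sample(recs, calibration, geometry, buffer)
      est_rows[[i]] <- data.frame(
        strain = profile$strain_name, sample_id = est$sample_id,
        wt_pct = est$wt_pct, replicate = est$replicate,
        cells_per_ml = truth$cells_per_ml[i],
        c_mps = est$speed_of_sound, alpha_npm = est$attenuation,
        sd_c_mps = est$sd_speed, sd_alpha_npm = est$sd_attenuation,
        n_records = est$n_records,
        c_true_mps = truth$c_true_mps[i],
        alpha_true_npm = truth$alpha_true_npm[i],
        stringsAsFactors = FALSE)
      rec_rows[[i]] <- est$records
      if (verbose) {
        message(sprintf("  %s: c = %.3f m/s, alpha = %.4f Np/m",
                        est$sample_id, est$speed_of_sound, est$attenuation))
      }
    }
    list(calibration = calibration,
         estimates = do.call(rbind, est_rows),
         per_record = do.call(rbind, rec_rows))
  })
  structure(
    list(strain = profile$strain_name, design = design,
         calibration = out$calibration, estimates = out$estimates,
         per_record = out$per_record),
    class = "gradient_experiment"
  )
}

#' @export
print.gradient_experiment <- function(x, ...) {
  cat(sprintf("<gradient_experiment> %s: %d samples, %d records\n",
              x$strain, nrow(x$estimates), nrow(x$per_record)))
  print(x$calibration)
  invisible(x)
}

#' @export
summary.gradient_experiment <- function(object, ...) {
  reg <- gradient_analysis(object)
  cat(sprintf("Gradient experiment, strain %s\n", object$strain))
  print(object$calibration)
  print(reg)
  max_rel_sd <- max(object$estimates$sd_alpha_npm / object$estimates$alpha_npm,
                    object$estimates$sd_c_mps / object$estimates$c_mps)
  cat(sprintf("max relative SD across samples: %.3f%%\n", 100 * max_rel_sd))
  invisible(reg)
}

#' @export
plot.gradient_experiment <- function(x, ...) {
  est <- x$estimates
  agg <- stats::aggregate(est[c("alpha_npm", "c_mps")],
                          by = list(wt_pct = est$wt_pct), mean)
  sds <- stats::aggregate(est[c("alpha_npm", "c_mps")],
                          by = list(wt_pct = est$wt_pct), stats::sd)
  old <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(old))
  error_bars <- function(x0, y, s) {
    ok <- s > 0  # zero-length bars (noiseless runs) are not drawn
    if (any(ok)) {
      # bars below device resolution are harmless; silence the arrows nag
      suppressWarnings(
        graphics::arrows(x0[ok], (y - s)[ok], x0[ok], (y + s)[ok],
                         angle = 90, code = 3, length = 0.03))
    }
  }
  graphics::plot(agg$wt_pct, agg$alpha_npm, pch = 19,
                 xlab = "concentration (wt%)",
                 ylab = "attenuation coefficient (Np/m)", main = x$strain)
  error_bars(agg$wt_pct, agg$alpha_npm, sds$alpha_npm)
  graphics::abline(stats::lm(alpha_npm ~ wt_pct, data = agg), lty = 2)
  graphics::plot(agg$wt_pct, agg$c_mps, pch = 19,
                 xlab = "concentration (wt%)", ylab = "speed of sound (m/s)",
                 main = x$strain)
  error_bars(agg$wt_pct, agg$c_mps, sds$c_mps)
  graphics::abline(stats::lm(c_mps ~ wt_pct, data = agg), lty = 2)
  invisible(x)
}

#' Simulate the three-sample phase comparison for one strain
#'
#' Emulates the Ringer solution vs 1 wt% suspension vs filtrate comparison:
#' the Ringer baseline has the profile's 0 wt% properties, the suspension
#' the 1 wt% properties, and the filtrate (cells removed, solutes retained)
#' keeps the baseline attenuation but an elevated speed of sound between
#' Ringer and suspension. Returns per-replicate estimates ready for
#' [anova_tukey()].
#'
#' @param profile A [strain_profile()].
#' @param calibration A `us_calibration`; if `NULL` a fresh noiseless-free
#'   water calibration is run.
#' @param replicates Replicates per phase.
#' @param records_per_sample Records per replicate.
#' @param filtrate_speed_fraction Fraction of the 0-to-1 wt% speed increase
#'   retained by the filtrate (soluble substances only); default 0.6.
#' @param geometry,buffer,pulse,temperature As in [run_gradient_experiment()].
#' @param seed Integer seed.
#' @return A list with data frame `estimates` (columns `phase`, `replicate`,
#'   `alpha_npm`, `c_mps`) and the `calibration` used.
#' @export
simulate_phase_comparison <- function(profile, calibration = NULL,
                                      replicates = 3, records_per_sample = 30,
                                      filtrate_speed_fraction = 0.6,
                                      geometry = default_geometry(),
                                      buffer = plexiglas(),
                                      pulse = pulse_parameters(),
                                      temperature = 20, seed = 7L) {
  stopifnot(inherits(profile, "strain_profile"))
  c0 <- eval_affine(profile$c_map, 0)
  c1 <- eval_affine(profile$c_map, 1)
  a0 <- eval_affine(profile$alpha_map, 0)
  a1 <- eval_affine(profile$alpha_map, 1)
  media <- list(
    ringer = acoustic_medium("ringer", WATER_DENSITY_20C, c0, a0),
    suspension = acoustic_medium("suspension", WATER_DENSITY_20C, c1, a1),
    filtrate = acoustic_medium(
      "filtrate", WATER_DENSITY_20C,
      c0 + filtrate_speed_fraction * (c1 - c0), a0))
  with_preserved_seed(seed, {
    if (is.null(calibration)) {
      water <- water_medium(temperature)
      refs <- lapply(seq_len(records_per_sample), function(i) {
        simulate_record(water, geometry, buffer, pulse,
                        noise_sd = profile$noise_relative_sd,
                        temperature = temperature, sample_id = "water_ref",
                        record_index = i)
      })
      calibration <- calibrate_from_water(refs, geometry, buffer)
    }
    rows <- list()
    for (phase in names(media)) {
      for (rep_i in seq_len(replicates)) {
        recs <- lapply(seq_len(records_per_sample), function(r) {
          simulate_record(media[[phase]], geometry, buffer, pulse,
                          noise_sd = profile$noise_relative_sd,
                          temperature = temperature,
                          sample_id = paste0(phase, "_r", rep_i),
                          replicate = rep_i, record_index = r)
        })
        est <- estimate_sample(recs, calibration, geometry, buffer)
        rows[[length(rows) + 1L]] <- data.frame(
          phase = phase, replicate = rep_i,
          alpha_npm = est$attenuation, c_mps = est$speed_of_sound,
          stringsAsFactors = FALSE)
      }
    }
    list(estimates = do.call(rbind, rows), calibration = calibration)
  })
}
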