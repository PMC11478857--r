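#' Strain profile: synthetic ground truth for one yeast strain
#'
#' A strain profile defines the linear maps from yeast concentration (wt%)
#' to true speed of sound, attenuation coefficient and cell count, the
#' two-component lognormal particle-size mixture, and the waveform noise
#' level. These are the quantities the gradient experiment assumes and the
#' analysis chain is meant to recover.
#'
#' @param strain_name Character label.
#' @param alpha_map,c_map,cellcount_map Named numeric vectors
#'   `c(intercept =, slope =)` mapping wt% to Np/m, m/s and cells/mL
#'   respectively. `alpha_map` must be non-negative and `c_map` positive on
#'   the whole 0--1 wt% range.
#' @param psd List with `medians` (two component medians, um), `log_sds`
#'   (two geometric standard deviations on the log scale) and `weights`
#'   (volume weights summing to 1).
#' @param noise_relative_sd Waveform noise level relative to the first-echo
#'   peak.
#' @return An object of class `strain_profile`.
#' @seealso [make_strain_profiles()] for the three shipped presets.
#' @export
strain_profile <- function(strain_name, alpha_map, c_map, cellcount_map,
                           psd, noise_relative_sd = 0.001) {
  for (nm in c("alpha_map", "c_map", "cellcount_map")) {
    m <- get(nm)
    if (!is.numeric(m) || length(m) != 2L ||
        !all(c("intercept", "slope") %in% names(m)) || any(!is.finite(m))) {
      stop(sprintf("'%s' must be c(intercept =, slope =) with finite values",
                   nm))
    }
  }
  w_grid <- c(0, 1)
  if (any(eval_affine(alpha_map, w_grid) < 0)) {
    stop("'alpha_map' must be non-negative on [0, 1] wt%")
  }
  if (any(eval_affine(c_map, w_grid) <= 0)) {
    stop("'c_map' must be positive on [0, 1] wt%")
  }
  if (!is.list(psd) || !all(c("medians", "log_sds", "weights") %in% names(psd))) {
    stop("'psd' must be a list with medians, log_sds, weights")
  }
  if (abs(sum(psd$weights) - 1) > 1e-8) stop("psd weights must sum to 1")
  if (any(psd$medians <= 0) || any(psd$log_sds <= 0)) {
    stop("psd medians and log_sds must be positive")
  }
  structure(
    list(strain_name = strain_name, alpha_map = alpha_map, c_map = c_map,
         cellcount_map = cellcount_map, psd = psd,
         noise_relative_sd = noise_relative_sd),
    class = "strain_profile"
  )
}

eval_affine <- function(map, w) unname(map["intercept"] + map["slope"] * w)

#' @export
print.strain_profile <- function(x, ...) {
  cat(sprintf("<strain_profile> %s\n", x$strain_name))
  cat(sprintf("  c(w)     = %.2f + %.2f w  m/s\n",
              x$c_map["intercept"], x$c_map["slope"]))
  cat(sprintf("  alpha(w) = %.2f + %.2f w  Np/m\n",
              x$alpha_map["intercept"], x$alpha_map["slope"]))
  cat(sprintf("  cells(w) = %.3g + %.3g w  cells/mL\n",
              x$cellcount_map["intercept"], x$cellcount_map["slope"]))
  cat(sprintf("  psd: medians %s um, weights %s, noise %.4f\n",
              paste(signif(x$psd$medians, 3), collapse = "/"),
              paste(x$psd$weights, collapse = "/"), x$noise_relative_sd))
  invisible(x)
}

# Volume-weighted CDF of the two-component lognormal mixture.
psd_mixture_cdf <- function(x, psd) {
  F1 <- stats::plnorm(x, meanlog = log(psd$medians[1]), sdlog = psd$log_sds[1])
  F2 <- stats::plnorm(x, meanlog = log(psd$medians[2]), sdlog = psd$log_sds[2])
  psd$weights[1] * F1 + psd$weights[2] * F2
}

# Analytic volume-weighted median of the mixture.
psd_mixture_median <- function(psd) {
  stats::uniroot(function(x) psd_mixture_cdf(x, psd) - 0.5,
                 lower = 0.05, upper = 500, tol = 1e-10)$root
}

# Solve the primary-component median so the mixture median equals x50.
solve_primary_median <- function(x50, secondary_median, log_sds, weights) {
  if (weights[2] == 0) return(x50)
  f <- function(m1) {
    psd_mixture_cdf(x50, list(medians = c(m1, secondary_median),
                              log_sds = log_sds, weights = weights)) - 0.5
  }
  stats::uniroot(f, lower = 0.1, upper = 100, tol = 1e-10)$root
}

#' Strain presets for the three commercial yeasts
#'
#' Returns profiles for the baker's strain (S. cerevisiae), the
#' top-fermenting wheat-beer strain WB-06, and the bottom-fermenting lager
#' strain W 34/70, anchored to the study's printed values:
#' \itemize{
#'   \item S. cerevisiae speed of sound at 1.0 wt% = 1488.86 m/s;
#'   \item cell counts at 1.0 wt% of 204, 307 and 152 x 10^6 cells/mL
#'     (affine through the origin: only the maxima are reported);
#'   \item volume-weighted median cell diameters (x50) of 5.73, 4.61 and
#'     5.80 um; the two top-fermenting strains carry a secondary lognormal
#'     component centered at 20 um (cell clusters), the lager strain is
#'     unimodal with the narrowest primary mode (hence the tallest peak).
#' }
#' All remaining numbers (speed and attenuation slopes, Ringer baseline,
#' component spreads and weights) are synthetic: they are chosen to
#' reproduce the qualitative ordering of the study's figures (comparable
#' attenuation at 1 wt% for all strains; S. cerevisiae clearly fastest,
#' WB-06 slowest) but are not reported values. The 0.0 wt% baseline is
#' Ringer solution, modeled as water at 20 degC plus a small positive speed
#' offset for the electrolytes.
#'
#' @param ringer_speed Speed of sound of the 0 wt% Ringer baseline, m/s.
#' @param ringer_attenuation Attenuation of the Ringer baseline, Np/m (the
#'   effective per-length system baseline, not pure-water absorption alone).
#' @param noise_relative_sd Waveform noise level for all presets.
#' @return Named list of three [strain_profile()] objects
#'   (`s_cerevisiae`, `wb06`, `w3470`).
#' @examples
#' profs <- make_strain_profiles()
#' eval_c <- function(p, w) p$c_map[["intercept"]] + p$c_map[["slope"]] * w
#' eval_c(profs$s_cerevisiae, 1)  # 1488.86
#' @export
make_strain_profiles <- function(ringer_speed = 1483.5,
                                 ringer_attenuation = 2.0,
                                 noise_relative_sd = 0.001) {
  mk_psd <- function(x50, log_sds, weights, secondary_median = 20) {
    m1 <- solve_primary_median(x50, secondary_median, log_sds, weights)
    list(medians = c(m1, secondary_median), log_sds = log_sds,
         weights = weights, target_x50 = x50)
  }
  list(
    s_cerevisiae = strain_profile(
      "S. cerevisiae",
      alpha_map = c(intercept = ringer_attenuation, slope = 12.0),
      c_map = c(intercept = ringer_speed, slope = 1488.86 - ringer_speed),
      cellcount_map = c(intercept = 0, slope = 204e6),
      psd = mk_psd(5.73, log_sds = c(0.32, 0.25), weights = c(0.88, 0.12)),
      noise_relative_sd = noise_relative_sd),
    wb06 = strain_profile(
      "WB-06",
      alpha_map = c(intercept = ringer_attenuation, slope = 12.8),
      c_map = c(intercept = ringer_speed, slope = 4.4),
      cellcount_map = c(intercept = 0, slope = 307e6),
      psd = mk_psd(4.61, log_sds = c(0.34, 0.25), weights = c(0.90, 0.10)),
      noise_relative_sd = noise_relative_sd),
    w3470 = strain_profile(
      "W 34/70",
      alpha_map = c(intercept = ringer_attenuation, slope = 12.4),
      c_map = c(intercept = ringer_speed, slope = 4.8),
      cellcount_map = c(intercept = 0, slope = 152e6),
      psd = mk_psd(5.80, log_sds = c(0.28, 0.25), weights = c(1, 0)),
      noise_relative_sd = noise_relative_sd)
  )
}

#' Acoustic medium of a suspension at a given concentration
#'
#' Evaluates a strain profile's affine maps at `wt_pct` and wraps the result
#' as an [acoustic_medium()]. The suspension density is held at the water
#' value (dilute suspensions, <= 1 wt%).
#'
#' @param profile A [strain_profile()].
#' @param wt_pct Concentration in wt%, within 0--1.
#' @param density Suspension density, kg/m^3.
#' @return An `acoustic_medium`.
#' @export
sample_medium <- function(profile, wt_pct, density = WATER_DENSITY_20C) {
  stopifnot(inherits(profile, "strain_profile"))
  if (!is.numeric(wt_pct) || length(wt_pct) != 1L || wt_pct < 0 || wt_pct > 1) {
    stop("'wt_pct' must be a single value in [0, 1]")
  }
  acoustic_medium(sprintf("%s_%.1fwt", profile$strain_name, wt_pct),
                  density = density,
                  speed_of_sound = eval_affine(profile$c_map, wt_pct),
                  attenuation = eval_affine(profile$alpha_map, wt_pct))
}

#' Concentration-gradient experiment design
#'
#' The study design: 11 concentrations from 0.0 to 1.0 wt% in 0.1 steps,
#' technical triplicates, 30 records per sample.
#'
#' @param concentrations Concentrations in wt%, each within `[0, 1]`.
#' @param replicates Technical replicates per concentration.
#' @param records_per_sample Waveform records per replicate.
#' @param seed Integer seed making the generated dataset reproducible.
#' @return An object of class `gradient_design`.
#' @export
gradient_design <- function(concentrations = seq(0, 1, by = 0.1),
                            replicates = 3, records_per_sample = 30,
                            seed = 20L) {
  if (!is.numeric(concentrations) || length(concentrations) < 1L ||
      any(concentrations < 0) || any(concentrations > 1)) {
    stop("'concentrations' must lie within [0, 1] wt%")
  }
  if (replicates < 1 || records_per_sample < 1) {
    stop("'replicates' and 'records_per_sample' must be >= 1")
  }
  structure(
    list(concentrations = concentrations, replicates = as.integer(replicates),
         records_per_sample = as.integer(records_per_sample),
         seed = as.integer(seed)),
    class = "gradient_design"
  )
}

#' @export
print.gradient_design <- function(x, ...) {
  cat(sprintf(
    "<gradient_design> %d concentrations x %d replicates x %d records = %d records (seed %d)\n",
    length(x$concentrations), x$replicates, x$records_per_sample,
    length(x$concentrations) * x$replicates * x$records_per_sample, x$seed))
  invisible(x)
}

#' Ground-truth table of a gradient design under a strain profile
#'
#' One row per (concentration, replicate) sample with the true speed of
#' sound, attenuation and cell count implied by the profile's maps.
#'
#' @param profile A [strain_profile()].
#' @param design A [gradient_design()].
#' @return A data frame with columns `sample_id`, `wt_pct`, `replicate`,
#'   `c_true_mps`, `alpha_true_npm`, `cells_per_ml`.
#' @export
gradient_truth <- function(profile, design) {
  grid <- expand.grid(replicate = seq_len(design$replicates),
                      wt_pct = design$concentrations)
  grid <- grid[order(grid$wt_pct, grid$replicate), , drop = FALSE]
  data.frame(
    sample_id = sprintf("%s_wt%04.1f_r%d", gsub("[ /.]", "", profile$strain_name),
                        grid$wt_pct, grid$replicate),
    wt_pct = grid$wt_pct,
    replicate = grid$replicate,
    c_true_mps = eval_affine(profile$c_map, grid$wt_pct),
    alpha_true_npm = eval_affine(profile$alpha_map, grid$wt_pct),
    cells_per_ml = eval_affine(profile$cellcount_map, grid$wt_pct),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Generate a full gradient dataset of waveform records
#'
#' Simulates every record of the design (concentrations x replicates x
#' records per sample) under the profile's ground-truth maps and noise
#' level. Deterministic for a fixed design seed.
#'
#' For the full default design this holds ~1000 waveforms in memory; the
#' streaming pipeline [run_gradient_experiment()] processes records one at a
#' time instead and is preferred for full-size runs.
#'
#' @param profile A [strain_profile()].
#' @param design A [gradient_design()].
#' @param geometry A [vessel_geometry()].
#' @param buffer Buffer/reflector [acoustic_medium()].
#' @param pulse A [pulse_parameters()].
#' @param temperature Temperature in degC.
#' @return A list with `records` (list of [waveform_record()]) and `truth`
#'   (the [gradient_truth()] data frame).
#' @export
generate_gradient_dataset <- function(profile, design,
                                      geometry = default_geometry(),
                                      buffer = plexiglas(),
                                      pulse = pulse_parameters(),
                                      temperature = 20) {
  stopifnot(inherits(profile, "strain_profile"),
            inherits(design, "gradient_design"))
  truth <- gradient_truth(profile, design)
  records <- vector("list", nrow(truth) * design$records_per_sample)
  k <- 0L
  with_preserved_seed(design$seed, {
    for (i in seq_len(nrow(truth))) {
      med <- sample_medium(profile, truth$wt_pct[i])
      for (r in seq_len(design$records_per_sample)) {
        k <- k + 1L
        records[[k]] <- simulate_record(
          med, geometry, buffer, pulse,
          noise_sd = profile$noise_relative_sd, seed = NULL,
          temperature = temperature, sample_id = truth$sample_id[i],
          replicate = truth$replicate[i], record_index = r,
          wt_pct = truth$wt_pct[i])
      }
    }
  })
  list(records = records, truth = truth)
}

# Run `expr` under set.seed(seed), restoring the caller's RNG state.
with_preserved_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Default particle-size bin grid
#'
#' Sixty logarithmically spaced bins from 0.7 to 70 um, covering the yeast
#' single-cell and cluster modes the way a laser-diffraction size table does.
#'
#' @return Numeric vector of 61 bin edges in um.
#' @export
default_psd_bins <- function() {
  exp(seq(log(0.7), log(70), length.out = 61))
}

#' Binned particle-size distribution
#'
#' @param bin_edges Increasing positive bin edges in um (length nbins + 1).
#' @param volume_density Volume density per bin in %, non-negative; must sum
#'   to 100 within tolerance unless `normalize = TRUE`.
#' @param normalize If `TRUE`, rescale densities to sum to 100.
#' @return An object of class `psd`.
#' @export
particle_size_distribution <- function(bin_edges, volume_density,
                                       normalize = FALSE) {
  if (!is.numeric(bin_edges) || length(bin_edges) < 2L ||
      any(bin_edges <= 0) || any(diff(bin_edges) <= 0)) {
    stop("'bin_edges' must be increasing and positive")
  }
  if (length(volume_density) != length(bin_edges) - 1L ||
      any(volume_density < 0) || any(!is.finite(volume_density))) {
    stop("'volume_density' must be non-negative with one value per bin")
  }
  s <- sum(volume_density)
  if (s <= 0) stop("degenerate distribution: zero total volume density")
  if (normalize) {
    volume_density <- 100 * volume_density / s
  } else if (abs(s - 100) > 1e-6) {
    stop("volume densities must sum to 100% (or pass normalize = TRUE)")
  }
  structure(list(bin_edges = bin_edges, volume_density = volume_density),
            class = "psd")
}

#' @export
print.psd <- function(x, ...) {
  cat(sprintf("<psd> %d bins, %.3g--%.3g um, x50 = %.3f um\n",
              length(x$volume_density), min(x$bin_edges), max(x$bin_edges),
              compute_x50(x)))
  invisible(x)
}

#' Generate a binned volume-density particle-size distribution
#'
#' Bins the profile's two-component lognormal mixture onto a size grid,
#' either analytically (exact bin masses from the mixture CDF) or by drawing
#' virtual particles from the volume-weighted distribution and histogramming
#' them.
#'
#' @param profile A [strain_profile()].
#' @param bin_edges Increasing positive bin edges in um.
#' @param mode `"analytic"` (default) or `"sampled"`.
#' @param n_particles Number of virtual particles in sampled mode.
#' @param seed Optional seed for sampled mode.
#' @return A [particle_size_distribution()] in % summing to 100.
#' @export
generate_psd <- function(profile, bin_edges = default_psd_bins(),
                         mode = c("analytic", "sampled"),
                         n_particles = 1e5, seed = NULL) {
  stopifnot(inherits(profile, "strain_profile"))
  mode <- match.arg(mode)
  psd <- profile$psd
  if (mode == "analytic") {
    mass <- diff(psd_mixture_cdf(bin_edges, psd))
  } else {
    mass <- with_preserved_seed(if (is.null(seed)) 1L else seed, {
      comp <- sample.int(2L, n_particles, replace = TRUE, prob = psd$weights)
      x <- stats::rlnorm(n_particles, meanlog = log(psd$medians)[comp],
                         sdlog = psd$log_sds[comp])
      x <- x[x >= min(bin_edges) & x <= max(bin_edges)]
      graphics::hist(x, breaks = bin_edges, plot = FALSE)$counts
    })
  }
  particle_size_distribution(bin_edges, as.numeric(mass), normalize = TRUE)
}
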