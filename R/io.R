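#' Write / read a waveform record as delimited text
#'
#' One file per record: '#'-prefixed `key=value` header lines
#' (`sampling_rate_hz`, `temperature_c`, `sample_id`, `replicate`,
#' `record_index`, optional `wt_pct`, `truth_c_mps`, `truth_alpha_npm`)
#' followed by one amplitude per line. The round trip preserves all fields
#' to full double precision.
#'
#' @param record A [waveform_record()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_waveform <- function(record, path) {
  stopifnot(inherits(record, "waveform_record"))
  hdr <- c(
    sprintf("# sampling_rate_hz=%.17g", record$sampling_rate),
    sprintf("# temperature_c=%.17g", record$temperature),
    sprintf("# sample_id=%s", record$sample_id),
    sprintf("# replicate=%d", record$replicate),
    sprintf("# record_index=%d", record$record_index))
  if (!is.na(record$wt_pct)) {
    hdr <- c(hdr, sprintf("# wt_pct=%.17g", record$wt_pct))
  }
  if (!is.null(record$truth)) {
    hdr <- c(hdr,
             sprintf("# truth_c_mps=%.17g", record$truth$speed_of_sound),
             sprintf("# truth_alpha_npm=%.17g", record$truth$attenuation))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines(sprintf("%.17g", record$samples), con)
  invisible(path)
}

#' @rdname write_waveform
#' @export
read_waveform <- function(path) {
  if (!file.exists(path)) stop("waveform file not found: ", path)
  lines <- readLines(path)
  is_hdr <- startsWith(lines, "#")
  kv <- sub("^#\\s*", "", lines[is_hdr])
  keys <- sub("=.*$", "", kv)
  vals <- sub("^[^=]*=", "", kv)
  meta <- stats::setNames(as.list(vals), keys)
  need <- c("sampling_rate_hz", "temperature_c", "sample_id", "replicate",
            "record_index")
  if (!all(need %in% keys)) {
    stop("waveform header missing required keys: ",
         paste(setdiff(need, keys), collapse = ", "))
  }
  truth <- NULL
  if (all(c("truth_c_mps", "truth_alpha_npm") %in% keys)) {
    truth <- list(speed_of_sound = as.numeric(meta$truth_c_mps),
                  attenuation = as.numeric(meta$truth_alpha_npm))
  }
  waveform_record(
    samples = as.numeric(lines[!is_hdr]),
    sampling_rate = as.numeric(meta$sampling_rate_hz),
    temperature = as.numeric(meta$temperature_c),
    sample_id = meta$sample_id,
    replicate = as.integer(meta$replicate),
    record_index = as.integer(meta$record_index),
    wt_pct = if ("wt_pct" %in% keys) as.numeric(meta$wt_pct) else NA_real_,
    truth = truth)
}

#' Write / read a dataset manifest
#'
#' CSV with columns `path`, `strain`, `sample_id`, `wt_pct`, `replicate`,
#' `record_index`; '#'-prefixed comment lines may carry provenance
#' metadata (e.g. the config hash) and are ignored on read.
#'
#' @param manifest Data frame with the columns above.
#' @param path Output path.
#' @param comments Optional character vector written as '# ' comment lines.
#' @return `path` invisibly / the manifest data frame.
#' @export
write_manifest <- function(manifest, path, comments = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(comments)) writeLines(paste("#", comments), con)
  utils::write.csv(manifest, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Write / read sample-estimate tables
#'
#' CSV round trip for the per-sample estimates table produced by the
#' processing stage (and, via `write_records_csv`, the per-record feature
#' table with columns `sample_id`, `wt_pct`, `replicate`, `record_index`,
#' `tof_s`, `a1_mag`, `a2_mag`, `c_mps`, `alpha_npm`).
#'
#' @param estimates Data frame of estimates.
#' @param path File path.
#' @param comments Optional '#' comment lines (e.g. calibration constants).
#' @return `path` invisibly / the data frame.
#' @export
write_estimates <- function(estimates, path, comments = character(0)) {
  write_manifest(estimates, path, comments)
}

#' @rdname write_estimates
#' @export
read_estimates <- function(path) read_manifest(path)

#' Write / read a binned particle-size distribution
#'
#' CSV with columns `bin_lower_um`, `bin_upper_um`, `volume_density_pct`.
#'
#' @param psd A [particle_size_distribution()].
#' @param path File path.
#' @return `path` invisibly / a `psd` object.
#' @export
write_psd_csv <- function(psd, path) {
  stopifnot(inherits(psd, "psd"))
  df <- data.frame(bin_lower_um = utils::head(psd$bin_edges, -1),
                   bin_upper_um = psd$bin_edges[-1],
                   volume_density_pct = psd$volume_density)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_psd_csv
#' @export
read_psd_csv <- function(path) {
  if (!file.exists(path)) stop("PSD file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("bin_lower_um", "bin_upper_um", "volume_density_pct")
  if (!all(need %in% names(df))) {
    stop("PSD file must have columns ", paste(need, collapse = ", "))
  }
  if (any(abs(df$bin_lower_um[-1] - utils::head(df$bin_upper_um, -1)) > 1e-9)) {
    stop("PSD bins must be contiguous")
  }
  particle_size_distribution(c(df$bin_lower_um[1], df$bin_upper_um),
                             df$volume_density_pct, normalize = TRUE)
}

#' Read and validate an experiment configuration
#'
#' YAML configuration with sections `geometry` (`sample_path_diameter_m`,
#' `buffer_diameter_m`, `buffer_attenuation_npm`), `buffer` and `reflector`
#' (`density_kgm3`, `speed_of_sound_mps`), `pulse` (`center_frequency_hz`,
#' `n_cycles`, `envelope`, `sampling_rate_hz`, `amplitude`), `design`
#' (`concentrations_wt`, `replicates`, `records_per_sample`, `seed`),
#' `profiles` (names of shipped presets), `noise_relative_sd`, and
#' `temperature_c`. The reflector must be the same material as the buffer:
#' the attenuation estimator assumes the sample--reflector reflection
#' coefficient is the negative of the buffer--sample one, which holds only
#' for equal materials.
#'
#' @param path Path to a YAML config file.
#' @return A list of validated, instantiated components: `geometry`,
#'   `buffer`, `pulse`, `design`, `profiles`, `temperature`,
#'   `noise_relative_sd`, `config_md5`.
#' @export
read_experiment_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  need_top <- c("geometry", "buffer", "reflector", "pulse", "design",
                "profiles")
  missing <- setdiff(need_top, names(cfg))
  if (length(missing)) {
    stop("config missing section(s): ", paste(missing, collapse = ", "))
  }
  if (!identical(cfg$buffer, cfg$reflector)) {
    stop("config invalid: reflector material must equal buffer material ",
         "(the attenuation estimator assumes R23 = -R12, which requires ",
         "identical buffer and reflector)")
  }
  # YAML 1.1 only recognizes exponents written as "1.0e+08"; be lenient and
  # coerce numeric-looking strings such as "1.0e8"
  num <- function(x) if (is.character(x)) as.numeric(x) else x
  g <- cfg$geometry
  geometry <- vessel_geometry(num(g$sample_path_diameter_m),
                              num(g$buffer_diameter_m),
                              num(g$buffer_attenuation_npm))
  buffer <- acoustic_medium("buffer", num(cfg$buffer$density_kgm3),
                            num(cfg$buffer$speed_of_sound_mps),
                            num(cfg$buffer$attenuation_npm %||% 0))
  p <- cfg$pulse
  pulse <- pulse_parameters(
    center_frequency = num(p$center_frequency_hz %||% 2e6),
    n_cycles = num(p$n_cycles %||% 4),
    amplitude = num(p$amplitude %||% 1),
    envelope = p$envelope %||% "gaussian",
    sampling_rate = num(p$sampling_rate_hz %||% 100e6))
  dsg <- cfg$design
  design <- gradient_design(
    concentrations = as.numeric(unlist(dsg$concentrations_wt %||%
                                         seq(0, 1, by = 0.1))),
    replicates = num(dsg$replicates %||% 3),
    records_per_sample = num(dsg$records_per_sample %||% 30),
    seed = num(dsg$seed %||% 20L))
  presets <- make_strain_profiles(
    noise_relative_sd = cfg$noise_relative_sd %||% 0.001)
  unknown <- setdiff(unlist(cfg$profiles), names(presets))
  if (length(unknown)) {
    stop("unknown profile preset(s): ", paste(unknown, collapse = ", "),
         " (available: ", paste(names(presets), collapse = ", "), ")")
  }
  list(geometry = geometry, buffer = buffer, pulse = pulse, design = design,
       profiles = presets[unlist(cfg$profiles)],
       temperature = cfg$temperature_c %||% 20,
       noise_relative_sd = cfg$noise_relative_sd %||% 0.001,
       config_md5 = unname(tools::md5sum(path)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Pipeline stage: simulate a dataset to waveform files
#'
#' Simulates the configured gradient dataset for every configured strain
#' plus a water-reference set, writing one text file per record and CSV
#' manifests (dataset and reference) stamped with the config hash.
#'
#' @param config Path to a YAML config, or the list from
#'   [read_experiment_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with `manifest_path` and
#'   `reference_manifest_path`.
#' @export
cli_simulate <- function(config, out_dir) {
  if (is.character(config)) config <- read_experiment_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wf_dir <- file.path(out_dir, "waveforms")
  dir.create(wf_dir, showWarnings = FALSE)

  rows <- list()
  ref_rows <- list()
  with_preserved_seed(config$design$seed, {
    water <- water_medium(config$temperature)
    for (i in seq_len(config$design$records_per_sample)) {
      rec <- simulate_record(water, config$geometry, config$buffer,
                             config$pulse,
                             noise_sd = config$noise_relative_sd,
                             temperature = config$temperature,
                             sample_id = "water_ref", record_index = i)
      p <- file.path(wf_dir, sprintf("water_ref_%03d.txt", i))
      write_waveform(rec, p)
      ref_rows[[i]] <- data.frame(path = p, strain = "water",
                                  sample_id = "water_ref", wt_pct = NA,
                                  replicate = 1L, record_index = i,
                                  stringsAsFactors = FALSE)
    }
    for (pname in names(config$profiles)) {
      profile <- config$profiles[[pname]]
      truth <- gradient_truth(profile, config$design)
      for (i in seq_len(nrow(truth))) {
        med <- sample_medium(profile, truth$wt_pct[i])
        for (r in seq_len(config$design$records_per_sample)) {
          rec <- simulate_record(
            med, config$geometry, config$buffer, config$pulse,
            noise_sd = config$noise_relative_sd,
            temperature = config$temperature,
            sample_id = truth$sample_id[i], replicate = truth$replicate[i],
            record_index = r, wt_pct = truth$wt_pct[i])
          p <- file.path(wf_dir, sprintf("%s_%03d.txt", truth$sample_id[i], r))
          write_waveform(rec, p)
          rows[[length(rows) + 1L]] <- data.frame(
            path = p, strain = profile$strain_name,
            sample_id = truth$sample_id[i], wt_pct = truth$wt_pct[i],
            replicate = truth$replicate[i], record_index = r,
            stringsAsFactors = FALSE)
        }
      }
    }
  })
  comments <- sprintf("config_md5=%s", config$config_md5 %||% "unknown")
  manifest_path <- file.path(out_dir, "manifest.csv")
  ref_path <- file.path(out_dir, "reference_manifest.csv")
  write_manifest(do.call(rbind, rows), manifest_path, comments)
  write_manifest(do.call(rbind, ref_rows), ref_path, comments)
  invisible(list(manifest_path = manifest_path,
                 reference_manifest_path = ref_path))
}

#' Pipeline stage: process waveform files into estimates
#'
#' Reads the dataset and water-reference manifests, calibrates from the
#' reference records, estimates every sample, and writes the per-record
#' feature table (`records.csv`), the per-sample estimates
#' (`estimates.csv`) and a processing log (`process.log`) that records the
#' calibration constants and any exclusions.
#'
#' @param manifest_path Dataset manifest CSV from [cli_simulate()].
#' @param reference_manifest_path Water-reference manifest CSV.
#' @param out_dir Output directory.
#' @param geometry,buffer Cell description used for echo search windows and
#'   the reference reflection coefficient.
#' @param on_error Per-record failure policy, see [estimate_sample()].
#' @return Invisibly, the path of the estimates CSV.
#' @export
cli_process <- function(manifest_path, reference_manifest_path, out_dir,
                        geometry = default_geometry(), buffer = plexiglas(),
                        on_error = "abort") {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- read_manifest(manifest_path)
  ref_manifest <- read_manifest(reference_manifest_path)
  missing <- c(manifest$path, ref_manifest$path)
  missing <- missing[!file.exists(missing)]
  if (length(missing)) {
    stop("manifest references missing waveform file(s): ",
         paste(utils::head(missing, 3), collapse = ", "))
  }
  log_lines <- c(sprintf("processing %d records, %d reference records",
                         nrow(manifest), nrow(ref_manifest)))
  refs <- lapply(ref_manifest$path, read_waveform)
  cal <- calibrate_from_water(refs, geometry, buffer)
  log_lines <- c(log_lines, sprintf(
    "calibration: d=%.6g m, C0=%.6g, R12=%.6g, T=%.2f degC (n=%d)",
    cal$diameter, cal$C0, cal$R12_reference, cal$temperature, cal$n_records))

  keys <- unique(manifest[c("strain", "sample_id")])
  est_rows <- list(); rec_rows <- list()
  for (i in seq_len(nrow(keys))) {
    sub <- manifest[manifest$sample_id == keys$sample_id[i], , drop = FALSE]
    recs <- lapply(sub$path, read_waveform)
    est <- withCallingHandlers(
      estimate_sample(recs, cal, geometry, buffer, on_error = on_error),
      warning = function(w) {
        log_lines <<- c(log_lines, sprintf("%s: %s", keys$sample_id[i],
                                           conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
    est_rows[[i]] <- data.frame(
      strain = keys$strain[i], sample_id = est$sample_id,
      wt_pct = est$wt_pct, replicate = est$replicate,
      c_mps = est$speed_of_sound, alpha_npm = est$attenuation,
      sd_c_mps = est$sd_speed, sd_alpha_npm = est$sd_attenuation,
      n_records = est$n_records, stringsAsFactors = FALSE)
    rec_rows[[i]] <- est$records
    log_lines <- c(log_lines, sprintf(
      "%s: c=%.4f m/s alpha=%.5f Np/m (n=%d)", est$sample_id,
      est$speed_of_sound, est$attenuation, est$n_records))
  }
  cal_comment <- sprintf("calibration d_m=%.10g C0=%.10g R12=%.10g",
                         cal$diameter, cal$C0, cal$R12_reference)
  est_path <- file.path(out_dir, "estimates.csv")
  write_estimates(do.call(rbind, est_rows), est_path, cal_comment)
  write_estimates(do.call(rbind, rec_rows),
                  file.path(out_dir, "records.csv"), cal_comment)
  writeLines(log_lines, file.path(out_dir, "process.log"))
  invisible(est_path)
}

#' Pipeline stage: study-level analysis and report
#'
#' Reads a per-sample estimates table (optionally several strains) and
#' particle-size CSVs, fits the four gradient regressions per strain,
#' computes x50 per PSD, and writes `regressions.csv`, `x50.csv`, a
#' machine-readable `summary.json` and a plain-text `report.txt`. If the
#' estimates carry a `phase` column (Ringer / suspension / filtrate), the
#' three-phase ANOVA + Tukey-Kramer comparison with compact letters is
#' added per strain.
#'
#' @param estimates_path Estimates CSV from [cli_process()] (needs a
#'   `cells_per_ml` column for the cell-count regressions; if absent those
#'   are skipped).
#' @param psd_paths Named character vector of PSD CSV paths (names = strain).
#' @param out_dir Output directory.
#' @param alpha_level Significance level for group comparisons.
#' @return Invisibly, the summary list written to `summary.json`.
#' @export
cli_analyze <- function(estimates_path, psd_paths = NULL, out_dir,
                        alpha_level = 0.05) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  est <- read_estimates(estimates_path)
  if (nrow(est) == 0L) stop("estimates table is empty")
  if (!"strain" %in% names(est)) est$strain <- "unknown"

  reg_rows <- list()
  report <- character(0)
  summary_list <- list(regressions = list(), x50_um = list())
  for (strain in unique(est$strain)) {
    sub <- est[est$strain == strain, , drop = FALSE]
    if (!"cells_per_ml" %in% names(sub)) {
      # cell-count map is ground-truth metadata; without it only the wt%
      # regressions are possible
      sub$cells_per_ml <- NA_real_
    }
    if (length(unique(sub$wt_pct)) >= 3) {
      regs <- if (all(is.na(sub$cells_per_ml))) {
        agg <- stats::aggregate(sub[c("alpha_npm", "c_mps")],
                                by = list(wt_pct = sub$wt_pct), mean)
        list(alpha_vs_wt = fit_linear(agg$wt_pct, agg$alpha_npm),
             c_vs_wt = fit_linear(agg$wt_pct, agg$c_mps))
      } else {
        gradient_analysis(sub)
      }
      for (nm in names(regs)) {
        reg_rows[[length(reg_rows) + 1L]] <- data.frame(
          strain = strain, regression = nm, slope = regs[[nm]]$slope,
          intercept = regs[[nm]]$intercept,
          r_squared = regs[[nm]]$r_squared, n = regs[[nm]]$n,
          stringsAsFactors = FALSE)
        report <- c(report, sprintf("%s %s: R^2 = %.4f", strain, nm,
                                    regs[[nm]]$r_squared))
      }
      summary_list$regressions[[strain]] <-
        lapply(regs, function(r) list(slope = r$slope,
                                      intercept = r$intercept,
                                      r_squared = r$r_squared, n = r$n))
    }
    if ("phase" %in% names(sub) && length(unique(sub$phase)) >= 2) {
      for (response in c("alpha_npm", "c_mps")) {
        gr <- split(sub[[response]], sub$phase)
        cmp <- anova_tukey(gr, alpha_level = alpha_level)
        report <- c(report, sprintf(
          "%s %s phases: ANOVA p = %.3g; letters: %s", strain, response,
          cmp$anova_p,
          paste(names(cmp$letters), cmp$letters, sep = "=", collapse = " ")))
        summary_list$phase_comparison[[strain]][[response]] <-
          list(anova_p = cmp$anova_p, letters = as.list(cmp$letters))
      }
    }
  }
  if (length(reg_rows)) {
    utils::write.csv(do.call(rbind, reg_rows),
                     file.path(out_dir, "regressions.csv"), row.names = FALSE)
  }
  if (!is.null(psd_paths)) {
    x50_rows <- list()
    for (i in seq_along(psd_paths)) {
      strain <- names(psd_paths)[i] %||% basename(psd_paths[i])
      p <- read_psd_csv(psd_paths[i])
      x50 <- compute_x50(p)
      x50_rows[[i]] <- data.frame(strain = strain, x50_um = x50,
                                  stringsAsFactors = FALSE)
      summary_list$x50_um[[strain]] <- x50
      report <- c(report, sprintf("%s: x50 = %.3f um", strain, x50))
    }
    utils::write.csv(do.call(rbind, x50_rows), file.path(out_dir, "x50.csv"),
                     row.names = FALSE)
  }
  summary_list$n_regressions <- length(reg_rows)
  jsonlite::write_json(summary_list, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(report, file.path(out_dir, "report.txt"))
  invisible(summary_list)
}

#' Validate a pipeline summary against the shipped schema
#'
#' Checks the required top-level fields and their types as declared in the
#' JSON schema shipped at `inst/extdata/summary-schema.json`.
#'
#' @param summary_path Path to a `summary.json` produced by [cli_analyze()].
#' @return `TRUE` invisibly; errors describe the first violation.
#' @export
validate_summary <- function(summary_path) {
  schema <- jsonlite::read_json(
    system.file("extdata", "summary-schema.json", package = "sonoyeast"))
  s <- jsonlite::read_json(summary_path)
  for (field in unlist(schema$required)) {
    if (is.null(s[[field]])) stop("summary missing required field: ", field)
  }
  for (field in names(schema$properties)) {
    if (!is.null(s[[field]])) {
      type <- schema$properties[[field]]$type
      ok <- switch(type,
                   object = is.list(s[[field]]),
                   integer = is.numeric(s[[field]]),
                   number = is.numeric(s[[field]]),
                   TRUE)
      if (!ok) stop(sprintf("summary field '%s' is not of type %s",
                            field, type))
    }
  }
  invisible(TRUE)
}

#' Run the full demo experiment
#'
#' One-command end-to-end run of the default study design: for each of the
#' three strain presets, simulate and process the full gradient (11
#' concentrations x 3 replicates x 30 records at 100 MHz sampling), fit the
#' gradient regressions, generate and summarize the particle-size
#' distributions, and write estimates, regressions, x50 table, a JSON
#' summary and a text report into `out_dir`.
#'
#' @param out_dir Output directory.
#' @param seed Base integer seed.
#' @param design A [gradient_design()]; its seed is replaced by `seed`.
#' @param verbose Print progress.
#' @return Invisibly, the summary list (also written as JSON).
#' @export
run_demo <- function(out_dir, seed = 20L, design = gradient_design(),
                     verbose = TRUE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  profiles <- make_strain_profiles()
  est_all <- list()
  psd_paths <- character(0)
  for (i in seq_along(profiles)) {
    pname <- names(profiles)[i]
    if (verbose) message("running gradient for ", pname)
    design$seed <- as.integer(seed + i)
    exp_i <- run_gradient_experiment(profiles[[pname]], design)
    est_all[[pname]] <- exp_i$estimates
    psd_path <- file.path(out_dir, paste0("psd_", pname, ".csv"))
    write_psd_csv(generate_psd(profiles[[pname]]), psd_path)
    psd_paths[pname] <- psd_path
  }
  est_path <- file.path(out_dir, "estimates.csv")
  write_estimates(do.call(rbind, est_all), est_path)
  out <- cli_analyze(est_path, psd_paths, out_dir)
  if (verbose) {
    message("wrote ", file.path(out_dir, "summary.json"))
  }
  invisible(out)
}
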