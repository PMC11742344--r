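#' Downcore index profile of a cube
#'
#' Collapses per-pixel index maps to a depth series: for each trough, the
#' mean and standard deviation of the index across each row's unmasked
#' pixels, on a depth axis derived from the pixel size (row 1 = core top at
#' depth 0; depth increases downcore in steps of one pixel). At ~80 um per
#' pixel this resolves sub-millimetre (seasonal, varve-scale) pigment
#' laminae.
#'
#' @param cube A calibrated [hsi_cube()].
#' @param troughs A [trough_definition()] or list of them.
#' @param mask Optional logical rows x cols ROI mask.
#' @return A data.frame with `row`, `depth_mm`, and per trough
#'   `mean_<name>` and `sd_<name>` columns; fully masked rows give `NA`.
#' @export
downcore_profile <- function(cube, troughs, mask = NULL) {
  stopifnot(inherits(cube, "hsi_cube"))
  if (inherits(troughs, "trough_definition")) troughs <- list(troughs)
  if (length(troughs) < 1L) stop("need at least one trough", call. = FALSE)
  d <- dim(cube$values)
  mask <- check_mask(mask, d[1:2])
  out <- data.frame(row = seq_len(d[1]),
                    depth_mm = (seq_len(d[1]) - 1) * cube$pixel_size_um / 1000)
  for (tr in troughs) {
    map <- index_map(cube, tr)
    map[!mask] <- NA_real_
    mu <- apply(map, 1, function(v) {
      v <- v[is.finite(v)]
      if (length(v) == 0L) NA_real_ else mean(v)
    })
    sdv <- apply(map, 1, function(v) {
      v <- v[is.finite(v)]
      if (length(v) < 2L) NA_real_ else stats::sd(v)
    })
    n_blank <- sum(is.na(mu))
    if (n_blank > 0) {
      message(sprintf("downcore_profile: %d fully masked row(s) for %s",
                      n_blank, tr$name))
    }
    out[[paste0("mean_", tr$name)]] <- mu
    out[[paste0("sd_", tr$name)]] <- sdv
  }
  out
}

#' Default pipeline configuration
#'
#' The configuration reproduces the study conditions of the two synthetic
#' spiking experiments and the interference experiment: three sediment
#' matrices, cumulative phycocyanin spikes of 0/50/100/150 ug, chlorophyll
#' a spikes of 0/5/10/15/20 ug at a fixed 150 ug phycocyanin load, 8 x 8
#' pixel aliquot cubes on a 2 nm axis.
#'
#' @param seed Integer master seed; every random draw in the run flows
#'   from it.
#' @param output_dir Directory the run writes into.
#' @return A nested list understood by [run_pipeline()].
#' @export
default_pipeline_config <- function(seed = 1L, output_dir = "phycoscan_run") {
  list(
    seed = as.integer(seed),
    output_dir = output_dir,
    simulation = list(
      matrices = c("organic", "clastic", "crm"),
      noise_sd = 0.01,
      pc_masses = c(0, 50, 100, 150),
      chla_masses = c(0, 5, 10, 15, 20),
      interference_pc_mass = 150,
      interference_matrix = "organic",
      shape = c(8, 8),
      wavelength = list(from = 400, to = 1000, by = 2)
    ),
    troughs = "conservative",
    calibration = list(folds = 10, denominator = "mean"),
    write_cubes = FALSE
  )
}

# field-by-field schema check; collects every violation before stopping
validate_pipeline_config <- function(config) {
  problems <- character(0)
  need <- function(ok, msg) if (!ok) problems <<- c(problems, msg)
  need(is.list(config), "config: must be a list")
  if (!is.list(config)) {
    stop(paste(problems, collapse = "; "), call. = FALSE)
  }
  need(!is.null(config$seed) && is.finite(as.numeric(config$seed)),
       "seed: required integer")
  need(is.character(config$output_dir %||% NULL) &&
         length(config$output_dir) == 1L, "output_dir: required string")
  sim <- config$simulation
  need(is.list(sim), "simulation: required section")
  if (is.list(sim)) {
    need(all(sim$matrices %in% c("organic", "clastic", "crm")),
         "simulation.matrices: must be subset of organic/clastic/crm")
    need(length(sim$matrices) >= 1, "simulation.matrices: at least one")
    need(is.numeric(sim$pc_masses) && !is.unsorted(sim$pc_masses),
         "simulation.pc_masses: non-decreasing numeric")
    need(is.numeric(sim$chla_masses) && !is.unsorted(sim$chla_masses),
         "simulation.chla_masses: non-decreasing numeric")
    need(is.numeric(sim$interference_pc_mass) && sim$interference_pc_mass > 0,
         "simulation.interference_pc_mass: positive number")
    need(is.null(sim$interference_matrix) ||
           sim$interference_matrix %in% c("organic", "clastic", "crm"),
         "simulation.interference_matrix: one of organic/clastic/crm")
    need(is.numeric(sim$noise_sd) && sim$noise_sd >= 0,
         "simulation.noise_sd: non-negative number")
    need(length(sim$shape) == 2 && all(sim$shape >= 4),
         "simulation.shape: two integers >= 4")
    wl <- sim$wavelength
    need(is.list(wl) && all(c("from", "to", "by") %in% names(wl)),
         "simulation.wavelength: needs from/to/by")
  }
  need(is.character(config$troughs %||% NULL) &&
         config$troughs %in% c("conservative", "downcore"),
       "troughs: 'conservative' or 'downcore'")
  if (length(problems) > 0) {
    stop("invalid pipeline config:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  }
  invisible(config)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full synthetic spiking pipeline
#'
#' Executes simulate -> calibrate indices -> normalise -> calibration
#' regressions -> interference analysis -> downcore profile, writing a
#' deterministic directory of CSV/JSON artifacts plus a run manifest
#' (config hash, seed, versions). Running the same configuration and seed
#' twice yields byte-identical CSV outputs.
#'
#' @param config A config list as from [default_pipeline_config()], or a
#'   path to a YAML/JSON file with the same structure.
#' @param output_dir Optional override of `config$output_dir`.
#' @return Invisibly, a list with the output directory, the spike series,
#'   calibration table and interference summary.
#' @export
run_pipeline <- function(config = default_pipeline_config(),
                         output_dir = NULL) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.json$", config, ignore.case = TRUE)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  if (!is.null(output_dir)) config$output_dir <- output_dir
  validate_pipeline_config(config)
  sim <- config$simulation
  out <- config$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed)
  wl <- seq(sim$wavelength$from, sim$wavelength$to, by = sim$wavelength$by)
  troughs <- default_troughs(config$troughs)
  chlorin <- setdiff(names(troughs), "RABD620")
  specs <- default_matrix_specs(noise_sd = sim$noise_sd, seed = seed)
  specs <- specs[sim$matrices]
  folds <- config$calibration$folds %||% 10
  denom <- config$calibration$denominator %||% "mean"

  log_lines <- c(sprintf("stage=init seed=%d matrices=%s", seed,
                         paste(sim$matrices, collapse = ",")))

  # --- spiking experiment: one PC series per matrix ------------------
  series_all <- list()
  calib_rows <- list()
  last_cube <- NULL
  for (m in names(specs)) {
    spec <- specs[[m]]
    plan <- spike_plan("PC", sim$pc_masses)
    res <- simulate_spiking_cubes(spec, plan, shape = sim$shape,
                                  wavelength = wl, seed = seed)
    if (isTRUE(config$write_cubes)) {
      for (i in seq_along(res$cubes)) {
        write_envi(res$cubes[[i]],
                   file.path(out, sprintf("cube_%s_step%d.dat", m, i - 1L)))
      }
    }
    ss <- normalize_series(spike_series(res$cubes, plan$masses,
                                        troughs$RABD620,
                                        matrix_name = m, pigment = "PC"))
    series_all[[m]] <- data.frame(matrix = m, pigment = "PC",
                                  mass_ug = ss$mass_ug, index = ss$index,
                                  index_normalized = ss$index_normalized)
    rep <- withCallingHandlers(
      build_calibration_report(ss, folds = folds, seed = seed,
                               denominator = denom),
      warning = function(w) {
        log_lines <<- c(log_lines, sprintf("stage=calibrate matrix=%s note=%s",
                                           m, conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
    md <- rep$model
    calib_rows[[m]] <- data.frame(matrix = m, slope = md$slope,
                                  intercept = md$intercept,
                                  r_squared = md$r_squared,
                                  p_value = md$p_value, n = md$n,
                                  rmsep_percent = md$rmsep_percent,
                                  folds = md$folds,
                                  significant = rep$significant)
    last_cube <- res$cubes[[length(res$cubes)]]
    log_lines <- c(log_lines,
                   sprintf("stage=spike matrix=%s steps=%d masked_pixels=0",
                           m, length(res$cubes)))
  }
  spike_tab <- do.call(rbind, series_all)
  rownames(spike_tab) <- NULL
  write_csv_stable(spike_tab, file.path(out, "spike_series.csv"))

  # pooled model over every matrix and step
  pooled <- fit_calibration(spike_tab$mass_ug, spike_tab$index_normalized)
  pooled_rm <- withCallingHandlers(
    rmsep_cv(spike_tab$mass_ug, spike_tab$index_normalized,
             folds = folds, seed = seed, denominator = denom),
    warning = function(w) {
      log_lines <<- c(log_lines, sprintf("stage=calibrate matrix=pooled note=%s",
                                         conditionMessage(w)))
      invokeRestart("muffleWarning")
    })
  calib_rows$pooled <- data.frame(matrix = "pooled", slope = pooled$slope,
                                  intercept = pooled$intercept,
                                  r_squared = pooled$r_squared,
                                  p_value = pooled$p_value, n = pooled$n,
                                  rmsep_percent = as.numeric(pooled_rm),
                                  folds = attr(pooled_rm, "folds"),
                                  significant = pooled$p_value < 0.05)
  calib_tab <- do.call(rbind, calib_rows)
  rownames(calib_tab) <- NULL
  write_csv_stable(calib_tab, file.path(out, "calibration.csv"))
  jsonlite::write_json(calib_tab, file.path(out, "calibration.json"),
                       dataframe = "rows", digits = NA, pretty = TRUE)

  # --- interference experiment ---------------------------------------
  int_matrix <- sim$interference_matrix %||% names(specs)[1]
  int_spec <- default_matrix_specs(noise_sd = sim$noise_sd,
                                   seed = seed)[[int_matrix]]
  iser <- simulate_interference_series(
    int_spec, pc_mass = sim$interference_pc_mass,
    chla_masses = sim$chla_masses, shape = sim$shape, wavelength = wl,
    seed = seed,
    troughs = c(default_troughs("conservative")))
  write_csv_stable(
    data.frame(step = iser$step, chla_mass_ug = iser$chla_mass_ug,
               rabd620 = iser$rabd620, rabd675 = iser$rabd675,
               mass_ratio = iser$mass_ratio, index_ratio = iser$index_ratio),
    file.path(out, "interference.csv"))
  curve <- masking_curve(iser)
  reg <- interference_regression(iser)
  thr <- detectability_threshold(int_spec,
                                 pc_mass = sim$interference_pc_mass,
                                 chla_grid = pmax(iser$chla_mass_ug, 0.001),
                                 wavelength = wl)
  jsonlite::write_json(
    list(matrix = int_matrix, pc_mass_ug = sim$interference_pc_mass,
         rabd620_slope = reg$slope, slope_sign = reg$slope_sign,
         spearman_rho = attr(curve, "spearman_rho"),
         monotone_decreasing = attr(curve, "monotone_decreasing"),
         threshold_reached = thr$reached,
         threshold_ug = if (thr$reached) thr$threshold_ug else "not reached"),
    file.path(out, "interference_summary.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_lines <- c(log_lines, sprintf("stage=interference matrix=%s steps=%d",
                                    int_matrix, nrow(iser)))

  # --- downcore profile of the final, fully spiked cube ---------------
  prof <- downcore_profile(last_cube, troughs[c("RABD620", chlorin)])
  write_csv_stable(prof, file.path(out, "downcore_profile.csv"))

  # --- manifest and log ----------------------------------------------
  cfg_path <- file.path(out, "config.json")
  jsonlite::write_json(config, cfg_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  manifest <- list(seed = seed,
                   config_md5 = unname(tools::md5sum(cfg_path)),
                   package = "phycoscan",
                   package_version =
                     as.character(utils::packageVersion("phycoscan")),
                   r_version = R.version.string,
                   outputs = c("spike_series.csv", "calibration.csv",
                               "calibration.json", "interference.csv",
                               "interference_summary.json",
                               "downcore_profile.csv", "config.json",
                               "run_log.txt"))
  jsonlite::write_json(manifest, file.path(out, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  writeLines(log_lines, file.path(out, "run_log.txt"))

  invisible(list(output_dir = out, spike_series = spike_tab,
                 calibration = calib_tab, interference = iser,
                 downcore = prof))
}

# deterministic CSV writer: fixed column order, '.' decimal separator,
# no row names, LF line endings
write_csv_stable <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.csv(df, con, row.names = FALSE, eol = "\n")
  invisible(path)
}
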