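#' Chlorophyll a to phycocyanin mass ratio
#'
#' @param chla_mass,pc_mass Pigment masses in ug; `pc_mass` must be > 0.
#' @return `chla_mass / pc_mass` (reported to two decimals in summaries).
#' @export
mass_ratio <- function(chla_mass, pc_mass) {
  if (any(pc_mass <= 0)) stop("`pc_mass` must be > 0", call. = FALSE)
  if (any(chla_mass < 0)) stop("`chla_mass` must be >= 0", call. = FALSE)
  chla_mass / pc_mass
}

#' Simulate a chlorophyll a interference series
#'
#' Emulates the interference experiment: sediment pre-loaded with a fixed
#' phycocyanin mass is spiked with increasing chlorophyll a, each step is
#' scanned, and the ROI-mean RABD620 and RABD675 are recorded. Because the
#' two absorption troughs overlap in the 600-700 nm range, a growing
#' chlorophyll a trough depresses the right shoulder of the phycocyanin
#' window and drags RABD620 down even though the phycocyanin load never
#' changes.
#'
#' @param spec A [matrix_spec()].
#' @param pc_mass Constant phycocyanin load in ug (default 150).
#' @param chla_masses Non-decreasing chlorophyll a masses in ug
#'   (default `c(0, 5, 10, 15, 20)`).
#' @param shape,wavelength,seed Passed to [simulate_spiking_cubes()].
#' @param troughs List with `RABD620` and `RABD675` [trough_definition()]s
#'   (default [default_troughs()]).
#' @return An `interference_series` data.frame: `step`, `chla_mass_ug`,
#'   `rabd620`, `rabd675`, `mass_ratio`, `index_ratio`; attributes
#'   `pc_mass` and `matrix`.
#' @export
simulate_interference_series <- function(spec, pc_mass = 150,
                                         chla_masses = c(0, 5, 10, 15, 20),
                                         shape = c(8, 8),
                                         wavelength = seq(400, 1000, by = 2),
                                         seed = spec$seed,
                                         troughs = default_troughs()) {
  if (pc_mass <= 0) stop("`pc_mass` must be > 0", call. = FALSE)
  plan <- spike_plan("ChlA", chla_masses)
  sim <- simulate_spiking_cubes(spec, plan, shape = shape,
                                wavelength = wavelength,
                                fixed_pc_mass = pc_mass, seed = seed)
  r620 <- vapply(sim$cubes,
                 function(cb) roi_mean(index_map(cb, troughs$RABD620)),
                 numeric(1))
  r675 <- vapply(sim$cubes,
                 function(cb) roi_mean(index_map(cb, troughs$RABD675)),
                 numeric(1))
  structure(data.frame(step = seq_along(chla_masses) - 1L,
                       chla_mass_ug = as.numeric(chla_masses),
                       rabd620 = r620, rabd675 = r675,
                       mass_ratio = mass_ratio(as.numeric(chla_masses), pc_mass),
                       index_ratio = r620 / r675),
            class = c("interference_series", "data.frame"),
            pc_mass = pc_mass, matrix = spec$name)
}

#' Regression of RABD620 on chlorophyll a mass at fixed phycocyanin
#'
#' Tests the linearity (and, crucially, the sign) of the RABD620 response
#' to chlorophyll a spiking while the phycocyanin load is constant. With
#' overlapping troughs the slope is negative: added chlorophyll a makes
#' the phycocyanin index underestimate phycocyanin.
#'
#' @param series An `interference_series` from
#'   [simulate_interference_series()] (or any data.frame with
#'   `chla_mass_ug` and `rabd620` columns, >= 3 steps).
#' @return A `calibration_model` (see [fit_calibration()]) with an extra
#'   `slope_sign` element (-1, 0 or 1).
#' @export
interference_regression <- function(series) {
  if (!all(c("chla_mass_ug", "rabd620") %in% names(series))) {
    stop("`series` needs `chla_mass_ug` and `rabd620` columns", call. = FALSE)
  }
  model <- fit_calibration(series$chla_mass_ug, series$rabd620)
  model$slope_sign <- sign(model$slope)
  model
}

#' Masking curve: index ratio against mass ratio
#'
#' Pairs the Chl a/PC mass ratio with the RABD620/RABD675 index ratio per
#' spiking step and reports the Spearman rank correlation between them. A
#' decreasing curve (rho near -1) means a growing chlorophyll a trough
#' progressively masks the phycocyanin trough.
#'
#' @param series An `interference_series` (>= 2 steps).
#' @return A data.frame (`mass_ratio`, `index_ratio`) with attributes
#'   `spearman_rho` and `monotone_decreasing`.
#' @export
masking_curve <- function(series) {
  if (!all(c("mass_ratio", "index_ratio") %in% names(series))) {
    stop("`series` needs `mass_ratio` and `index_ratio` columns",
         call. = FALSE)
  }
  if (nrow(series) < 2L) stop("need at least 2 steps", call. = FALSE)
  rho <- stats::cor(series$mass_ratio, series$index_ratio,
                    method = "spearman")
  structure(data.frame(mass_ratio = series$mass_ratio,
                       index_ratio = series$index_ratio),
            spearman_rho = rho,
            monotone_decreasing = all(diff(series$index_ratio) < 0))
}

#' Chlorophyll a mass at which the phycocyanin trough disappears
#'
#' Sweeps a grid of chlorophyll a masses at fixed phycocyanin load and
#' reports the smallest mass at which the continuum-removed noiseless
#' spectrum no longer has a local minimum inside the phycocyanin window —
#' the point where the chlorophyll a shoulder has swallowed the 620 nm
#' trough entirely.
#'
#' @param spec A [matrix_spec()].
#' @param pc_mass Fixed phycocyanin mass in ug (>= 0).
#' @param chla_grid Increasing chlorophyll a masses in ug to test.
#' @param pc_window Wavelength window (nm) searched for the local minimum
#'   (default 600-640).
#' @param wavelength Band centres in nm.
#' @param hull_window Window for continuum removal.
#' @return List with `threshold_ug` (smallest masking mass, or `NA` if not
#'   reached on the grid), `reached` (logical) and `grid` (data.frame:
#'   chla_mass_ug, has_local_min).
#' @export
detectability_threshold <- function(spec, pc_mass, chla_grid,
                                    pc_window = c(600, 640),
                                    wavelength = seq(400, 1000, by = 2),
                                    hull_window = c(550, 850)) {
  stopifnot(inherits(spec, "matrix_spec"))
  if (is.unsorted(chla_grid, strictly = TRUE)) {
    stop("`chla_grid` must be strictly increasing", call. = FALSE)
  }
  bg <- make_background(spec, wavelength)
  has_min <- vapply(chla_grid, function(m) {
    s <- apply_pigment_troughs(bg, pc_mass = pc_mass, chla_mass = m,
                               spec = spec)
    cr <- continuum_removed(s, window = hull_window)
    has_local_min(cr, pc_window)
  }, logical(1))
  first_gone <- which(!has_min)[1]
  list(threshold_ug = if (is.na(first_gone)) NA_real_ else chla_grid[first_gone],
       reached = !is.na(first_gone),
       grid = data.frame(chla_mass_ug = as.numeric(chla_grid),
                         has_local_min = has_min))
}

# TRUE when the continuum-removed spectrum has an interior local minimum
# whose band lies inside `window` (neighbours may sit outside it)
has_local_min <- function(cr, window) {
  v <- cr$reflectance
  wl <- cr$wavelength
  n <- length(v)
  if (n < 3L) return(FALSE)
  i <- 2:(n - 1)
  local_min <- v[i] < v[i - 1] & v[i] <= v[i + 1]
  any(local_min & wl[i] >= window[1] & wl[i] <= window[2])
}
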