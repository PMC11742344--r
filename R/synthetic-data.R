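#' Describe a synthetic sediment matrix
#'
#' A matrix spec captures how one sediment type turns spiked pigment mass
#' into spectral signal: a smooth background reflectance continuum, a
#' per-pigment sensitivity (absorbance units per ug of pigment on the
#' aliquot), the width of each pigment's Gaussian absorption trough, and
#' per-pixel instrument noise. Organic, clastic and dried certified
#' reference material (CRM) sediments respond with different sensitivities
#' and baselines — the matrix effect.
#'
#' @param name One of `"organic"`, `"clastic"`, `"crm"`.
#' @param background_knots Two-column matrix or data.frame (wavelength nm,
#'   reflectance in (0, 1\]) defining the trough-free baseline.
#' @param sensitivity_pc,sensitivity_chla,sensitivity_bphe Absorbance units
#'   per ug of phycocyanin, chlorophyll a and bacteriopheophytin a.
#' @param trough_sigma_pc,trough_sigma_chla,trough_sigma_bphe Gaussian
#'   trough standard deviations in nm.
#' @param noise_sd Per-pixel, per-band i.i.d. Gaussian reflectance noise.
#' @param visibility Fraction of the spiked mass optically visible at the
#'   sediment surface (pigment solution soaked into pores is invisible to
#'   the scanner); 1 means all of it.
#' @param seed Integer seed attached to the spec; simulation functions use
#'   it unless given their own.
#' @return An object of class `matrix_spec`.
#' @seealso [default_matrix_specs()] for the three stock sediment classes.
#' @export
matrix_spec <- function(name = c("organic", "clastic", "crm"),
                        background_knots,
                        sensitivity_pc, sensitivity_chla,
                        sensitivity_bphe = 0.004,
                        trough_sigma_pc = 12, trough_sigma_chla = 10,
                        trough_sigma_bphe = 15,
                        noise_sd = 0.01, visibility = 1, seed = 1L) {
  name <- match.arg(name)
  kn <- as.matrix(background_knots)
  if (ncol(kn) != 2L || nrow(kn) < 2L) {
    stop("`background_knots` needs >= 2 rows of (wavelength, reflectance)",
         call. = FALSE)
  }
  if (any(kn[, 2] <= 0) || any(kn[, 2] > 1)) {
    stop("background reflectance must lie in (0, 1]", call. = FALSE)
  }
  if (is.unsorted(kn[, 1], strictly = TRUE)) {
    stop("knot wavelengths must be strictly increasing", call. = FALSE)
  }
  sens <- c(sensitivity_pc, sensitivity_chla, sensitivity_bphe)
  if (any(sens < 0)) stop("sensitivities must be >= 0", call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  if (visibility < 0 || visibility > 1) {
    stop("`visibility` must lie in [0, 1]", call. = FALSE)
  }
  structure(list(name = name, background_knots = kn,
                 sensitivity_pc = sensitivity_pc,
                 sensitivity_chla = sensitivity_chla,
                 sensitivity_bphe = sensitivity_bphe,
                 trough_sigma_pc = trough_sigma_pc,
                 trough_sigma_chla = trough_sigma_chla,
                 trough_sigma_bphe = trough_sigma_bphe,
                 noise_sd = noise_sd, visibility = visibility,
                 seed = as.integer(seed)),
            class = "matrix_spec")
}

#' Stock sediment-matrix specifications
#'
#' Three matrix classes mirroring a sediment spiking experiment: wet
#' organic gyttja (dark baseline, strongest index response per ug), wet
#' clastic silt/clay (brighter, weakest response — pigment solution drains
#' into pores), and dry homogenised CRM (brightest, steep response). The
#' baselines are concave, trough-free continua.
#'
#' @param noise_sd Per-pixel reflectance noise shared by all three specs.
#' @param seed Seed stored on each spec.
#' @return Named list of three [matrix_spec()] objects.
#' @export
default_matrix_specs <- function(noise_sd = 0.01, seed = 1L) {
  knots <- list(
    organic = cbind(c(400, 550, 700, 1000), c(0.15, 0.25, 0.32, 0.40)),
    clastic = cbind(c(400, 550, 700, 1000), c(0.30, 0.45, 0.52, 0.60)),
    crm     = cbind(c(400, 550, 700, 1000), c(0.40, 0.58, 0.66, 0.74))
  )
  sens_pc <- c(organic = 0.004, clastic = 0.002, crm = 0.006)
  out <- lapply(names(knots), function(nm) {
    matrix_spec(nm, knots[[nm]],
                sensitivity_pc = sens_pc[[nm]], sensitivity_chla = 0.010,
                noise_sd = noise_sd, seed = seed)
  })
  names(out) <- names(knots)
  out
}

#' Trough-free background spectrum of a sediment matrix
#'
#' Interpolates the spec's baseline knots linearly onto the wavelength
#' axis. A concave, monotone knot sequence yields a continuum with no local
#' absorption troughs, so its continuum-removed version is identically 1.
#'
#' @param spec A [matrix_spec()].
#' @param wavelength Band centres in nm (covering 400-1000 nm for the
#'   stock specs).
#' @return An [hsi_spectrum()] with reflectance in (0, 1\].
#' @export
make_background <- function(spec, wavelength) {
  stopifnot(inherits(spec, "matrix_spec"))
  check_axis(wavelength)
  kn <- spec$background_knots
  if (min(kn[, 1]) < min(wavelength) || max(kn[, 1]) > max(wavelength)) {
    stop("background knot wavelengths fall outside the axis", call. = FALSE)
  }
  r <- stats::approx(kn[, 1], kn[, 2], xout = wavelength, method = "linear",
                     rule = 2)$y
  hsi_spectrum(wavelength, r)
}

# Gaussian trough centres (nm) for the three modelled pigments
TROUGH_CENTRES <- c(pc = 620, chla = 673, bphe = 845)

#' Imprint pigment absorption troughs on a background spectrum
#'
#' Absorbance scales with pigment amount (Beer-Lambert logic), so each
#' pigment contributes a Gaussian absorbance trough
#' `A_p(lambda) = sensitivity_p * mass_p * exp(-(lambda - centre_p)^2 / (2 sigma_p^2))`
#' centred at 620 nm (phycocyanin), 673 nm (chlorophyll a) and 845 nm
#' (bacteriopheophytin a). Reflectance follows the transmittance
#' convention `R = background * 10^(-A)`, clipped to (0, 1\].
#'
#' @param background An [hsi_spectrum()] as from [make_background()].
#' @param pc_mass,chla_mass,bphe_mass Pigment masses in ug (>= 0).
#' @param spec A [matrix_spec()] providing sensitivities, sigmas and
#'   visibility.
#' @param centres Named numeric, trough centres in nm (defaults
#'   `c(pc = 620, chla = 673, bphe = 845)`).
#' @return An [hsi_spectrum()].
#' @export
apply_pigment_troughs <- function(background, pc_mass = 0, chla_mass = 0,
                                  bphe_mass = 0, spec,
                                  centres = TROUGH_CENTRES) {
  stopifnot(inherits(background, "hsi_spectrum"), inherits(spec, "matrix_spec"))
  masses <- c(pc = pc_mass, chla = chla_mass, bphe = bphe_mass)
  if (any(masses < 0)) stop("pigment masses must be >= 0", call. = FALSE)
  hsi_spectrum(background$wavelength,
               clip_reflectance(background$reflectance *
                                  10^(-trough_absorbance(background$wavelength,
                                                         masses, spec, centres))))
}

# summed Gaussian absorbance A(lambda) for given pigment masses
trough_absorbance <- function(wavelength, masses, spec, centres = TROUGH_CENTRES) {
  sens <- c(pc = spec$sensitivity_pc, chla = spec$sensitivity_chla,
            bphe = spec$sensitivity_bphe)
  sigma <- c(pc = spec$trough_sigma_pc, chla = spec$trough_sigma_chla,
             bphe = spec$trough_sigma_bphe)
  a <- numeric(length(wavelength))
  for (p in names(centres)) {
    m <- spec$visibility * masses[[p]]
    if (m > 0 && sens[[p]] > 0) {
      a <- a + sens[[p]] * m *
        exp(-(wavelength - centres[[p]])^2 / (2 * sigma[[p]]^2))
    }
  }
  a
}

# keep reflectance in (0, 1]; floor avoids exact zeros that would break
# ratio indices; preserves array dimensions
clip_reflectance <- function(r, floor = 1e-6) {
  r[r < floor] <- floor
  r[r > 1] <- 1
  r
}

#' Define a spiking plan
#'
#' @param pigment `"PC"` or `"ChlA"`.
#' @param masses Cumulative pigment masses in ug per spiking step,
#'   non-negative and non-decreasing. Typical plans: `c(0, 50, 100, 150)`
#'   ug PC, `c(0, 20, 30, 62.6)` ug PC, or `c(0, 5, 10, 15, 20)` ug Chl a.
#' @param mixed_at_final_step Whether the standard was mixed into the
#'   sediment at the last step (metadata only; the optical model is
#'   unchanged).
#' @return An object of class `spike_plan`.
#' @export
spike_plan <- function(pigment = c("PC", "ChlA"), masses,
                       mixed_at_final_step = FALSE) {
  pigment <- match.arg(pigment)
  masses <- as.numeric(masses)
  if (length(masses) < 1L || any(masses < 0) ||
      is.unsorted(masses, strictly = FALSE)) {
    stop("`masses` must be non-negative and non-decreasing", call. = FALSE)
  }
  structure(list(pigment = pigment, masses = masses,
                 mixed_at_final_step = isTRUE(mixed_at_final_step)),
            class = "spike_plan")
}

#' Simulate the cube sequence of a spiking experiment
#'
#' Produces one hyperspectral cube per cumulative spiking step: the
#' matrix background, the pigment troughs for that step's mass (plus any
#' fixed co-occurring pigment), and i.i.d. Gaussian pixel noise added after
#' trough application. The ground-truth table records the noiseless trough
#' absorbance at each pigment's centre band, identical for every pixel of a
#' homogeneous aliquot.
#'
#' @param spec A [matrix_spec()].
#' @param plan A [spike_plan()].
#' @param shape Integer length-2, rows x cols of each cube (>= 4 x 4).
#' @param wavelength Band centres in nm (default 2 nm sampling, 400-1000).
#' @param fixed_pc_mass,fixed_chla_mass Constant pigment load present at
#'   every step, e.g. `fixed_pc_mass = 150` while spiking Chl a in an
#'   interference experiment.
#' @param seed Integer; defaults to `spec$seed`. Identical
#'   (spec, plan, seed) give bit-identical cubes.
#' @return List with `cubes` (list of [hsi_cube()], one per step) and
#'   `truth` (data.frame: step, pigment, cumulative_mass_ug, matrix, seed,
#'   true_a620, true_a673, true_a845).
#' @export
simulate_spiking_cubes <- function(spec, plan, shape = c(8, 8),
                                   wavelength = seq(400, 1000, by = 2),
                                   fixed_pc_mass = 0, fixed_chla_mass = 0,
                                   seed = spec$seed) {
  stopifnot(inherits(spec, "matrix_spec"), inherits(plan, "spike_plan"))
  shape <- as.integer(shape)
  if (length(shape) != 2L || any(shape < 4L)) {
    stop("`shape` must be at least 4 x 4", call. = FALSE)
  }
  bg <- make_background(spec, wavelength)
  nb <- length(wavelength)
  steps <- seq_along(plan$masses)
  cubes <- vector("list", length(steps))
  truth <- data.frame(step = steps - 1L, pigment = plan$pigment,
                      cumulative_mass_ug = plan$masses, matrix = spec$name,
                      seed = as.integer(seed),
                      true_a620 = NA_real_, true_a673 = NA_real_,
                      true_a845 = NA_real_)
  withr::with_seed(as.integer(seed), {
    for (i in steps) {
      masses <- c(pc = fixed_pc_mass, chla = fixed_chla_mass, bphe = 0)
      masses[[if (plan$pigment == "PC") "pc" else "chla"]] <-
        masses[[if (plan$pigment == "PC") "pc" else "chla"]] + plan$masses[i]
      a <- trough_absorbance(wavelength, masses, spec)
      clean <- clip_reflectance(bg$reflectance * 10^(-a))
      vals <- array(rep(clean, each = prod(shape)), dim = c(shape, nb))
      if (spec$noise_sd > 0) {
        vals <- clip_reflectance(vals + stats::rnorm(length(vals),
                                                     sd = spec$noise_sd))
      }
      cubes[[i]] <- hsi_cube(vals, wavelength)
      ac <- trough_absorbance(TROUGH_CENTRES, masses, spec)
      truth$true_a620[i] <- ac[1]
      truth$true_a673[i] <- ac[2]
      truth$true_a845[i] <- ac[3]
    }
  })
  list(cubes = cubes, truth = truth)
}

#' Simulate a Beer-Lambert spectrophotometer series
#'
#' Absorbance of a pigment standard dilution series:
#' `A_i = alpha * L * c_i` with `c_i` converted from ug/ml to g/l, plus
#' optional Gaussian noise. With `noise_sd = 0` the series is an exact
#' Beer-Lambert line through the origin.
#'
#' @param concentrations_ug_ml Non-negative concentrations in ug/ml.
#' @param alpha Specific extinction coefficient in l g^-1 cm^-1 (default
#'   88.15, chlorophyll a in 100% acetone).
#' @param L Optical path length in cm.
#' @param noise_sd Gaussian absorbance noise; requires `seed` when > 0.
#' @param seed Integer seed for the noise draw.
#' @return Numeric vector of absorbances.
#' @export
simulate_absorbance_series <- function(concentrations_ug_ml, alpha = 88.15,
                                       L = 1, noise_sd = 0, seed = NULL) {
  conc <- as.numeric(concentrations_ug_ml)
  if (any(conc < 0)) stop("concentrations must be >= 0", call. = FALSE)
  if (alpha <= 0 || L <= 0) stop("`alpha` and `L` must be > 0", call. = FALSE)
  a <- alpha * L * conc / 1000  # ug/ml == mg/l == 1e-3 g/l
  if (noise_sd > 0) {
    if (is.null(seed)) {
      stop("`seed` is required when `noise_sd` > 0 (no global random state)",
           call. = FALSE)
    }
    a <- a + withr::with_seed(as.integer(seed),
                              stats::rnorm(length(a), sd = noise_sd))
  }
  a
}
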