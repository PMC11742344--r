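#' Calibrate raw digital numbers to 0-1 reflectance
#'
#' Scales a raw cube between the dark reference (closed aperture, total
#' absorbance, 0) and the white reference (BaSO4 panel, total reflectance,
#' 1): `R = (raw - dark) / (white - dark)`. Sensor noise can push values
#' slightly outside \[0, 1\]; these are clipped.
#'
#' @param raw An [hsi_cube()] of raw values.
#' @param white,dark Reference frames: either a numeric vector of length
#'   `bands` (one value per band), a cols x bands matrix (one value per
#'   across-core pixel and band), or an array with the cube's dimensions.
#' @return A calibrated [hsi_cube()] with values in \[0, 1\].
#' @export
calibrate_reflectance <- function(raw, white, dark) {
  stopifnot(inherits(raw, "hsi_cube"))
  d <- dim(raw$values)
  white_a <- expand_frame(white, d, "white")
  dark_a <- expand_frame(dark, d, "dark")
  denom <- white_a - dark_a
  bad <- apply(denom == 0, 3, any)
  if (any(bad)) {
    stop(sprintf(
      "white and dark references coincide in band(s) %s (%.6g nm ...)",
      paste(utils::head(which(bad), 5), collapse = ", "),
      raw$wavelength[which(bad)[1]]), call. = FALSE)
  }
  refl <- (raw$values - dark_a) / denom
  refl[refl < 0] <- 0
  refl[refl > 1] <- 1
  hsi_cube(refl, raw$wavelength, raw$pixel_size_um)
}

# broadcast a reference frame to the full cube shape
expand_frame <- function(frame, d, what) {
  if (is.array(frame) && length(dim(frame)) == 3L) {
    if (!identical(dim(frame), d)) {
      stop(sprintf("`%s` array must match the cube dimensions", what),
           call. = FALSE)
    }
    return(frame)
  }
  if (is.matrix(frame)) {
    if (!identical(dim(frame), d[2:3])) {
      stop(sprintf("`%s` matrix must be cols x bands", what), call. = FALSE)
    }
    return(aperm(array(frame, dim = c(d[2], d[3], d[1])), c(3, 1, 2)))
  }
  if (is.numeric(frame) && length(frame) == d[3]) {
    return(aperm(array(frame, dim = c(d[3], d[1], d[2])), c(2, 3, 1)))
  }
  stop(sprintf("`%s` must be a band vector, cols x bands matrix, or full array",
               what), call. = FALSE)
}

#' Upper convex hull of a spectrum (the continuum)
#'
#' Fits the continuum over the top of a reflectance spectrum as straight
#' line segments connecting local spectral maxima — the upper convex hull
#' of the (wavelength, reflectance) points — evaluated at every band in the
#' window. The hull dominates the spectrum everywhere and touches it at the
#' window endpoints and at hull vertices.
#'
#' @param spectrum An [hsi_spectrum()].
#' @param window Length-2 numeric, wavelength interval in nm over which the
#'   hull is fitted. The default 550-850 nm brackets the phycocyanin,
#'   chlorin and bacteriopheophytin troughs while avoiding noisy edge
#'   bands.
#' @return An [hsi_spectrum()] holding hull values at the window's bands.
#' @export
continuum_hull <- function(spectrum, window = c(550, 850)) {
  stopifnot(inherits(spectrum, "hsi_spectrum"))
  sel <- window_bands(spectrum$wavelength, window)
  wl <- spectrum$wavelength[sel]
  r <- spectrum$reflectance[sel]
  hv <- upper_hull_values(wl, r)
  hsi_spectrum(wl, hv)
}

#' Continuum-removed spectrum
#'
#' Divides reflectance by its upper convex hull, normalising out the
#' background signal unrelated to specific absorption features. Values lie
#' in (0, 1\]; the continuum-removed trough depth at band b is
#' `1 - R(b)/hull(b)`. The operation is idempotent.
#'
#' @inheritParams continuum_hull
#' @return An [hsi_spectrum()] of `R/hull` values over the window bands.
#' @export
continuum_removed <- function(spectrum, window = c(550, 850)) {
  hull <- continuum_hull(spectrum, window)
  sel <- window_bands(spectrum$wavelength, window)
  r <- spectrum$reflectance[sel]
  if (any(r <= 0)) {
    stop("spectrum must be strictly positive inside the window", call. = FALSE)
  }
  hsi_spectrum(hull$wavelength, r / hull$reflectance)
}

# band indices inside a wavelength window; requires >= 3 bands in-window
window_bands <- function(wavelength, window) {
  if (length(window) != 2L || anyNA(window) || window[1] >= window[2]) {
    stop("`window` must be an increasing length-2 wavelength interval",
         call. = FALSE)
  }
  sel <- which(wavelength >= window[1] & wavelength <= window[2])
  if (length(sel) < 3L) {
    stop(sprintf("window [%.6g, %.6g] nm covers %d band(s); at least 3 required",
                 window[1], window[2], length(sel)), call. = FALSE)
  }
  sel
}

# Andrew monotone-chain upper hull, evaluated at every input wavelength.
# Collinear middle points are dropped, so a tie in reflectance keeps the
# earlier band as the segment vertex.
upper_hull_values <- function(wl, r) {
  n <- length(wl)
  hull <- integer(n)
  m <- 0L
  for (i in seq_len(n)) {
    while (m >= 2L) {
      k <- hull[m - 1L]
      j <- hull[m]
      # drop j unless (k, j, i) makes a strict clockwise (convex-up) turn
      cross <- (wl[j] - wl[k]) * (r[i] - r[k]) - (r[j] - r[k]) * (wl[i] - wl[k])
      if (cross >= 0) m <- m - 1L else break
    }
    m <- m + 1L
    hull[m] <- i
  }
  hull <- hull[seq_len(m)]
  if (length(hull) == 1L) return(r)
  stats::approx(wl[hull], r[hull], xout = wl, method = "linear")$y
}
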