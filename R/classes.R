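#' Construct a spectrum on a wavelength axis
#'
#' A spectrum pairs a strictly increasing wavelength axis (nm) with one
#' reflectance (or absorbance-derived) value per band. Calibrated
#' reflectance lies in \[0, 1\]; 1 approximates total reflectance against a
#' BaSO4 white standard and 0 total absorbance (closed-aperture dark
#' reference).
#'
#' @param wavelength Numeric vector of band centres in nm, strictly
#'   increasing.
#' @param reflectance Numeric vector of the same length.
#' @return An object of class `hsi_spectrum`: a list with elements
#'   `wavelength` and `reflectance`.
#' @examples
#' s <- hsi_spectrum(seq(400, 1000, by = 2), rep(0.6, 301))
#' @export
hsi_spectrum <- function(wavelength, reflectance) {
  wavelength <- as.numeric(wavelength)
  reflectance <- as.numeric(reflectance)
  if (length(wavelength) != length(reflectance)) {
    stop("`wavelength` and `reflectance` must have equal length", call. = FALSE)
  }
  check_axis(wavelength)
  structure(list(wavelength = wavelength, reflectance = reflectance),
            class = "hsi_spectrum")
}

#' @export
print.hsi_spectrum <- function(x, ...) {
  cat(sprintf("<hsi_spectrum> %d bands, %.1f-%.1f nm, reflectance [%.4g, %.4g]\n",
              length(x$wavelength), min(x$wavelength), max(x$wavelength),
              min(x$reflectance), max(x$reflectance)))
  invisible(x)
}

#' Construct a hyperspectral cube
#'
#' A cube is a rows x cols x bands reflectance array sharing one wavelength
#' axis. Rows run downcore (row 1 = core top, depth increases with row
#' index); columns run across-core.
#'
#' @param values Numeric array with dimensions rows x cols x bands.
#' @param wavelength Band centres in nm, strictly increasing, length equal
#'   to the third array dimension.
#' @param pixel_size_um Edge length of a pixel in micrometres (default 80,
#'   a typical core-scanner resolution).
#' @return An object of class `hsi_cube`.
#' @export
hsi_cube <- function(values, wavelength, pixel_size_um = 80) {
  if (!is.array(values) || length(dim(values)) != 3L) {
    stop("`values` must be a rows x cols x bands array", call. = FALSE)
  }
  wavelength <- as.numeric(wavelength)
  check_axis(wavelength)
  if (dim(values)[3] != length(wavelength)) {
    stop("third array dimension must match the wavelength axis length",
         call. = FALSE)
  }
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      !is.finite(pixel_size_um) || pixel_size_um <= 0) {
    stop("`pixel_size_um` must be a single positive number", call. = FALSE)
  }
  structure(list(values = values, wavelength = wavelength,
                 pixel_size_um = as.numeric(pixel_size_um)),
            class = "hsi_cube")
}

#' @export
print.hsi_cube <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<hsi_cube> %d rows x %d cols x %d bands (%.1f-%.1f nm), pixel %g um\n",
              d[1], d[2], d[3], min(x$wavelength), max(x$wavelength),
              x$pixel_size_um))
  invisible(x)
}

#' Extract one pixel of a cube as a spectrum
#'
#' @param cube An [hsi_cube()].
#' @param row,col Pixel coordinates (1-based; row 1 is the core top).
#' @return An [hsi_spectrum()].
#' @export
cube_spectrum <- function(cube, row, col) {
  stopifnot(inherits(cube, "hsi_cube"))
  d <- dim(cube$values)
  if (row < 1 || row > d[1] || col < 1 || col > d[2]) {
    stop("pixel coordinates outside the cube", call. = FALSE)
  }
  hsi_spectrum(cube$wavelength, cube$values[row, col, ])
}

#' Mean spectrum of a cube over a region of interest
#'
#' @param cube An [hsi_cube()].
#' @param mask Optional logical rows x cols matrix; `TRUE` pixels enter the
#'   mean. `NULL` averages all pixels.
#' @return An [hsi_spectrum()] of per-band means.
#' @export
cube_mean_spectrum <- function(cube, mask = NULL) {
  stopifnot(inherits(cube, "hsi_cube"))
  mask <- check_mask(mask, dim(cube$values)[1:2])
  vals <- matrix(cube$values, nrow = prod(dim(cube$values)[1:2]))
  hsi_spectrum(cube$wavelength, colMeans(vals[as.vector(mask), , drop = FALSE]))
}

# strictly increasing finite axis
check_axis <- function(wavelength) {
  if (length(wavelength) < 1L || anyNA(wavelength) || any(!is.finite(wavelength))) {
    stop("wavelength axis must be finite and non-empty", call. = FALSE)
  }
  if (length(wavelength) > 1L && any(diff(wavelength) <= 0)) {
    stop("wavelength axis must be strictly increasing", call. = FALSE)
  }
  invisible(wavelength)
}

# normalise a mask argument to a logical matrix with >= 1 TRUE pixel
check_mask <- function(mask, shape) {
  if (is.null(mask)) {
    mask <- matrix(TRUE, shape[1], shape[2])
  }
  if (!is.logical(mask) || !identical(dim(mask), as.integer(shape))) {
    stop("`mask` must be a logical matrix matching the spatial shape",
         call. = FALSE)
  }
  if (!any(mask)) stop("mask selects no pixels", call. = FALSE)
  mask
}

#' Snap a wavelength to the nearest band index
#'
#' Nearest band centre wins; an exact tie between two neighbours snaps to
#' the lower band.
#'
#' @param wavelength Axis in nm (strictly increasing).
#' @param target Wavelength in nm to snap.
#' @return Integer band index.
#' @export
snap_band <- function(wavelength, target) {
  check_axis(wavelength)
  if (target < min(wavelength) || target > max(wavelength)) {
    stop(sprintf("wavelength %.6g nm is outside the axis [%.6g, %.6g]",
                 target, min(wavelength), max(wavelength)), call. = FALSE)
  }
  which.min(abs(wavelength - target))  # which.min takes the first = lower band
}
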