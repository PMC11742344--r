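#' Define an absorption trough for index computation
#'
#' A trough is fixed by three wavelengths: the left and right continuum
#' endpoints and the trough minimum. On a given axis they snap to the
#' nearest band centres (exact ties to the lower band); the band-step
#' counts `X_left = min_band - left_band` and `X_right = right_band -
#' min_band` weight the two endpoints in the relative absorbance band
#' depth.
#'
#' @param name Label, e.g. `"RABD620"`.
#' @param lambda_left,lambda_min,lambda_right Wavelengths in nm with
#'   `lambda_left < lambda_min < lambda_right`.
#' @return An object of class `trough_definition`.
#' @seealso [default_troughs()] for the stock pigment profiles.
#' @export
trough_definition <- function(name, lambda_left, lambda_min, lambda_right) {
  if (!(lambda_left < lambda_min && lambda_min < lambda_right)) {
    stop("need lambda_left < lambda_min < lambda_right", call. = FALSE)
  }
  structure(list(name = as.character(name), lambda_left = lambda_left,
                 lambda_min = lambda_min, lambda_right = lambda_right),
            class = "trough_definition")
}

#' Stock trough profiles
#'
#' Conservative, non-overlapping trough windows: the phycocyanin window
#' (600-640 nm) and the chlorin window (650-700 nm) share no band, so
#' RABD620 reflects phycocyanin only and not a mixed signal with
#' chlorophyll a — at the cost of underestimating absolute trough depth.
#' `RABD660` is the broader total-chlorin profile used for downcore
#' work; `RABD845` targets bacteriopheophytin a.
#'
#' @param profile `"conservative"` (RABD620 + RABD675, disjoint windows) or
#'   `"downcore"` (RABD620 + RABD660).
#' @return Named list of [trough_definition()] objects.
#' @export
default_troughs <- function(profile = c("conservative", "downcore")) {
  profile <- match.arg(profile)
  all <- list(
    RABD620 = trough_definition("RABD620", 600, 620, 640),
    RABD675 = trough_definition("RABD675", 650, 673, 700),
    RABD660 = trough_definition("RABD660", 650, 660, 690),
    RABD845 = trough_definition("RABD845", 800, 845, 880)
  )
  if (profile == "conservative") all[c("RABD620", "RABD675")]
  else all[c("RABD620", "RABD660")]
}

# snap a trough's three wavelengths to band indices on an axis
trough_bands <- function(wavelength, trough) {
  i_left <- snap_band(wavelength, trough$lambda_left)
  i_min <- snap_band(wavelength, trough$lambda_min)
  i_right <- snap_band(wavelength, trough$lambda_right)
  if (!(i_left < i_min && i_min < i_right)) {
    stop(sprintf("trough %s collapses on this axis (bands %d/%d/%d)",
                 trough$name, i_left, i_min, i_right), call. = FALSE)
  }
  list(left = i_left, min = i_min, right = i_right)
}

#' Relative absorbance band depth (RABD) of one spectrum
#'
#' The two-endpoint continuum at the trough minimum, divided by the
#' measured reflectance there:
#' \deqn{RABD_{min} = \frac{(X_{right} R_{left} + X_{left} R_{right}) /
#'   (X_{right} + X_{left})}{R_{min}}}
#' A flat spectrum gives exactly 1; a deeper trough gives a larger value.
#'
#' @param spectrum An [hsi_spectrum()] of calibrated reflectance.
#' @param trough A [trough_definition()].
#' @param float_min If `TRUE`, the minimum band floats to the deepest band
#'   inside the trough window instead of the fixed centre band.
#' @return A single positive number.
#' @export
rabd <- function(spectrum, trough, float_min = FALSE) {
  stopifnot(inherits(spectrum, "hsi_spectrum"),
            inherits(trough, "trough_definition"))
  b <- trough_bands(spectrum$wavelength, trough)
  r <- spectrum$reflectance
  i_min <- b$min
  if (float_min) {
    inside <- (b$left + 1L):(b$right - 1L)
    i_min <- inside[which.min(r[inside])]
  }
  r_min <- r[i_min]
  if (is.na(r_min) || r_min <= 0) {
    stop("reflectance at the trough minimum must be > 0", call. = FALSE)
  }
  x_left <- i_min - b$left
  x_right <- b$right - i_min
  ((x_right * r[b$left] + x_left * r[b$right]) / (x_right + x_left)) / r_min
}

#' Relative absorbance band area (RABA) of one spectrum
#'
#' Integrated relative reflectance deficit below the trough's endpoint
#' chord: `sum over bands left..right of (C_i - R_i) / C_i`, where `C` is
#' the straight line from (lambda_left, R_left) to (lambda_right, R_right).
#' A spectrum lying on its chord gives 0; the ratio form makes the area
#' invariant to rescaling the whole spectrum.
#'
#' @inheritParams rabd
#' @return A single number (>= 0 for a genuine trough).
#' @export
raba <- function(spectrum, trough) {
  stopifnot(inherits(spectrum, "hsi_spectrum"),
            inherits(trough, "trough_definition"))
  b <- trough_bands(spectrum$wavelength, trough)
  idx <- b$left:b$right
  wl <- spectrum$wavelength[idx]
  r <- spectrum$reflectance[idx]
  chord <- r[1] + (r[length(r)] - r[1]) *
    (wl - wl[1]) / (wl[length(wl)] - wl[1])
  if (any(chord <= 0)) {
    stop("endpoint chord must be strictly positive across the window",
         call. = FALSE)
  }
  sum((chord - r) / chord)
}

#' Per-pixel index map of a cube
#'
#' Applies [rabd()] (or [raba()]) to every pixel of a calibrated cube,
#' preserving the spatial shape. Pixels where the index is undefined
#' (non-positive reflectance at the minimum band or on the chord) are
#' masked as `NA` and counted in a message.
#'
#' @param cube A calibrated [hsi_cube()].
#' @param trough A [trough_definition()].
#' @param method `"rabd"` or `"raba"`.
#' @param float_min Passed to [rabd()].
#' @return A rows x cols numeric matrix of class `pigment_index_map` with
#'   attributes `trough` (the trough name) and `pixel_size_um`.
#' @export
index_map <- function(cube, trough, method = c("rabd", "raba"),
                      float_min = FALSE) {
  stopifnot(inherits(cube, "hsi_cube"), inherits(trough, "trough_definition"))
  method <- match.arg(method)
  b <- trough_bands(cube$wavelength, trough)
  v <- cube$values
  if (method == "rabd") {
    if (float_min) {
      inside <- (b$left + 1L):(b$right - 1L)
      slab <- v[, , inside, drop = FALSE]
      imin_rel <- apply(slab, c(1, 2), which.min)
      i_min <- inside[imin_rel]
      r_min <- matrix(slab[cbind(as.vector(row(imin_rel)),
                                 as.vector(col(imin_rel)),
                                 as.vector(imin_rel))], nrow(imin_rel))
      x_left <- matrix(i_min - b$left, nrow(imin_rel))
      x_right <- matrix(b$right - i_min, nrow(imin_rel))
    } else {
      r_min <- v[, , b$min]
      x_left <- b$min - b$left
      x_right <- b$right - b$min
    }
    out <- ((x_right * v[, , b$left] + x_left * v[, , b$right]) /
              (x_right + x_left)) / r_min
    out[!is.finite(out) | r_min <= 0] <- NA_real_
  } else {
    idx <- b$left:b$right
    wl <- cube$wavelength[idx]
    w <- (wl - wl[1]) / (wl[length(wl)] - wl[1])
    r_left <- v[, , b$left]
    r_right <- v[, , b$right]
    out <- matrix(0, dim(v)[1], dim(v)[2])
    bad <- matrix(FALSE, dim(v)[1], dim(v)[2])
    for (k in seq_along(idx)) {
      chord <- r_left + (r_right - r_left) * w[k]
      bad <- bad | chord <= 0
      out <- out + (chord - v[, , idx[k]]) / chord
    }
    out[bad | !is.finite(out)] <- NA_real_
  }
  n_bad <- sum(is.na(out))
  if (n_bad > 0) {
    message(sprintf("index_map: %d pixel(s) masked (undefined %s)", n_bad,
                    toupper(method)))
  }
  structure(out, class = c("pigment_index_map", "matrix", "array"),
            trough = trough$name, pixel_size_um = cube$pixel_size_um)
}

#' Mean index over a region of interest
#'
#' Arithmetic mean of all finite, unmasked pixel indices — the sample
#' statistic reported per spiking step (one value for the whole spiked
#' sediment area).
#'
#' @param map A matrix as returned by [index_map()].
#' @param mask Optional logical matrix of the same shape; `TRUE` pixels
#'   enter the mean.
#' @return A single number.
#' @export
roi_mean <- function(map, mask = NULL) {
  if (!is.matrix(map)) stop("`map` must be a matrix", call. = FALSE)
  mask <- check_mask(mask, dim(map))
  vals <- map[mask]
  vals <- vals[is.finite(vals)]
  if (length(vals) == 0L) {
    stop("no finite index values inside the mask", call. = FALSE)
  }
  mean(vals)
}

#' Build a spike series from a cube sequence
#'
#' Computes the ROI-mean index for each spiking step's cube and pairs it
#' with the cumulative pigment mass.
#'
#' @param cubes List of calibrated [hsi_cube()]s, one per step.
#' @param masses Cumulative pigment masses in ug, one per cube.
#' @param trough A [trough_definition()].
#' @param mask Optional ROI mask shared by all cubes.
#' @param matrix_name,pigment Metadata labels carried on the result.
#' @return A `spike_series` data.frame with columns `step`, `mass_ug`,
#'   `index` (and after [normalize_series()], `index_normalized`).
#' @export
spike_series <- function(cubes, masses, trough, mask = NULL,
                         matrix_name = NA_character_, pigment = NA_character_) {
  if (length(cubes) != length(masses)) {
    stop("`cubes` and `masses` must have equal length", call. = FALSE)
  }
  idx <- vapply(cubes, function(cb) roi_mean(index_map(cb, trough), mask),
                numeric(1))
  structure(data.frame(step = seq_along(masses) - 1L, mass_ug = as.numeric(masses),
                       index = idx),
            class = c("spike_series", "data.frame"),
            matrix = matrix_name, pigment = pigment, trough = trough$name)
}

#' Normalise a spike series by its unspiked baseline
#'
#' Divides every step's ROI-mean index by the step-0 (unspiked sediment)
#' value, removing inter-matrix baseline differences:
#' `normalized_i = index_i / index_0`, so `normalized_0 = 1` exactly. The
#' operation is idempotent.
#'
#' @param series A `spike_series` data.frame (needs a `mass_ug == 0` step
#'   with positive index).
#' @return The series with an `index_normalized` column.
#' @export
normalize_series <- function(series) {
  if (!is.data.frame(series) || !all(c("mass_ug", "index") %in% names(series))) {
    stop("`series` must have `mass_ug` and `index` columns", call. = FALSE)
  }
  i0 <- which(series$mass_ug == 0)
  if (length(i0) == 0L) {
    stop("series has no unspiked (mass 0) step to normalise by", call. = FALSE)
  }
  base <- if ("index_normalized" %in% names(series)) {
    series$index_normalized[i0[1]]
  } else {
    series$index[i0[1]]
  }
  if (!is.finite(base) || base <= 0) {
    stop("unspiked baseline index must be > 0", call. = FALSE)
  }
  series$index_normalized <-
    (if ("index_normalized" %in% names(series)) series$index_normalized
     else series$index) / base
  series
}

#' Ratio of two index maps' ROI means
#'
#' `mean(map_a) / mean(map_b)` over a shared region of interest, e.g.
#' RABD620/RABD675 to gauge how far the chlorophyll a trough masks the
#' phycocyanin trough.
#'
#' @param map_a,map_b Index maps of identical shape.
#' @param mask Optional shared ROI mask.
#' @return A single number.
#' @export
index_ratio <- function(map_a, map_b, mask = NULL) {
  if (!identical(dim(map_a), dim(map_b))) {
    stop("maps must share one spatial shape", call. = FALSE)
  }
  denom <- roi_mean(map_b, mask)
  if (denom == 0) stop("denominator ROI mean is zero", call. = FALSE)
  roi_mean(map_a, mask) / denom
}
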