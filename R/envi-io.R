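#' Write a hyperspectral cube as an ENVI raster
#'
#' Writes the standard ENVI pair: an ASCII header (`<path>.hdr`) carrying
#' samples/lines/bands, data type, interleave and the wavelength list, and
#' a flat binary body at `path`. Data type 5 (64-bit IEEE float, the
#' default) round-trips R doubles bit-exactly; type 4 (32-bit float) is
#' also supported.
#'
#' @param cube An [hsi_cube()].
#' @param path Output file for the binary body; the header is written to
#'   `paste0(path, ".hdr")`.
#' @param interleave `"bsq"` (band sequential), `"bil"` (band interleaved
#'   by line) or `"bip"` (band interleaved by pixel).
#' @param data_type ENVI data type code: 5 (float64, default) or 4
#'   (float32).
#' @return `path`, invisibly.
#' @export
write_envi <- function(cube, path, interleave = c("bsq", "bil", "bip"),
                       data_type = 5) {
  stopifnot(inherits(cube, "hsi_cube"))
  interleave <- match.arg(interleave)
  if (!data_type %in% c(4, 5)) {
    stop("supported ENVI data types: 4 (float32), 5 (float64)", call. = FALSE)
  }
  d <- dim(cube$values)
  # ENVI orders: bsq sample->line->band, bil sample->band->line,
  # bip band->sample->line; R arrays are [line, sample, band] column-major
  perm <- switch(interleave, bsq = c(2, 1, 3), bil = c(2, 3, 1),
                 bip = c(3, 2, 1))
  body <- as.vector(aperm(cube$values, perm))
  hdr <- c(
    "ENVI",
    sprintf("samples = %d", d[2]),
    sprintf("lines = %d", d[1]),
    sprintf("bands = %d", d[3]),
    "header offset = 0",
    "file type = ENVI Standard",
    sprintf("data type = %d", as.integer(data_type)),
    sprintf("interleave = %s", interleave),
    "byte order = 0",
    "wavelength units = Nanometers",
    sprintf("pixel size um = %.10g", cube$pixel_size_um),
    sprintf("wavelength = {%s}",
            paste(sprintf("%.10g", cube$wavelength), collapse = ", "))
  )
  writeLines(hdr, paste0(path, ".hdr"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(body, con, size = if (data_type == 5) 8L else 4L, endian = "little")
  invisible(path)
}

#' Read an ENVI raster as a hyperspectral cube
#'
#' Parses the ASCII header next to the binary body and reconstructs the
#' cube; `write_envi()` followed by `read_envi()` is the identity on
#' values, wavelength axis and pixel size (for data type 5). Errors are
#' classed conditions: `envi_header_missing`, `envi_missing_wavelength`,
#' `envi_unknown_interleave`, `envi_unsupported_type`,
#' `envi_size_mismatch`.
#'
#' @param path Path to the binary body (header expected at
#'   `paste0(path, ".hdr")`, falling back to `<path-sans-ext>.hdr`).
#' @return An [hsi_cube()].
#' @export
read_envi <- function(path) {
  hdr_path <- paste0(path, ".hdr")
  if (!file.exists(hdr_path)) {
    hdr_path <- paste0(tools::file_path_sans_ext(path), ".hdr")
  }
  if (!file.exists(hdr_path)) {
    envi_stop("envi_header_missing", "no ENVI header found for '%s'", path)
  }
  h <- parse_envi_header(hdr_path)
  need <- c("samples", "lines", "bands", "data type", "interleave")
  miss <- setdiff(need, names(h))
  if (length(miss) > 0) {
    envi_stop("envi_header_missing", "header lacks field(s): %s",
              paste(miss, collapse = ", "))
  }
  if (!"wavelength" %in% names(h)) {
    envi_stop("envi_missing_wavelength", "header has no wavelength list")
  }
  samples <- as.integer(h$samples)
  lines <- as.integer(h$lines)
  bands <- as.integer(h$bands)
  dtype <- as.integer(h$`data type`)
  interleave <- tolower(h$interleave)
  wl <- as.numeric(strsplit(h$wavelength, ",")[[1]])
  if (length(wl) != bands) {
    envi_stop("envi_missing_wavelength",
              "wavelength list length %d does not match %d bands",
              length(wl), bands)
  }
  if (!interleave %in% c("bsq", "bil", "bip")) {
    envi_stop("envi_unknown_interleave", "unknown interleave '%s'", interleave)
  }
  if (!dtype %in% c(4L, 5L)) {
    envi_stop("envi_unsupported_type", "unsupported ENVI data type %d", dtype)
  }
  size <- if (dtype == 5L) 8L else 4L
  n <- samples * lines * bands
  expected <- as.numeric(n) * size
  actual <- file.size(path)
  if (is.na(actual) || actual != expected) {
    envi_stop("envi_size_mismatch",
              "body size mismatch: expected %.0f bytes (%d x %d x %d x %d), found %.0f",
              expected, lines, samples, bands, size,
              ifelse(is.na(actual), 0, actual))
  }
  con <- file(path, "rb")
  on.exit(close(con))
  body <- readBin(con, what = "double", n = n, size = size, endian = "little")
  dims <- switch(interleave,
                 bsq = c(samples, lines, bands),
                 bil = c(samples, bands, lines),
                 bip = c(bands, samples, lines))
  inv <- switch(interleave, bsq = c(2, 1, 3), bil = c(3, 1, 2),
                bip = c(3, 2, 1))
  values <- aperm(array(body, dim = dims), inv)
  px <- if ("pixel size um" %in% names(h)) as.numeric(h$`pixel size um`) else 80
  hsi_cube(values, wl, px)
}

envi_stop <- function(code, fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...), class = c(code, "envi_error")))
}

# key = value header parser; {...} values may span lines
parse_envi_header <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  out <- list()
  # braced (possibly multi-line) entries first, then scalars
  m <- gregexpr("([a-zA-Z][a-zA-Z0-9 ]*?)\\s*=\\s*\\{([^}]*)\\}", txt)[[1]]
  if (m[1] != -1) {
    for (i in seq_along(m)) {
      piece <- substr(txt, m[i], m[i] + attr(m, "match.length")[i] - 1)
      key <- trimws(sub("=.*", "", piece))
      val <- gsub("\\s+", " ", sub(".*\\{", "", sub("\\}\\s*$", "", piece)))
      out[[tolower(key)]] <- trimws(val)
    }
    txt <- gsub("([a-zA-Z][a-zA-Z0-9 ]*?)\\s*=\\s*\\{[^}]*\\}", "", txt)
  }
  for (line in strsplit(txt, "\n")[[1]]) {
    if (!grepl("=", line, fixed = TRUE)) next
    key <- tolower(trimws(sub("=.*", "", line)))
    val <- trimws(sub("^[^=]*=", "", line))
    if (nzchar(key) && nzchar(val)) out[[key]] <- val
  }
  out
}
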