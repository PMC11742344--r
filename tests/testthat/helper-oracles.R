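# Independent brute-force oracles and small fixture builders shared by the
# suite. These deliberately avoid the package's own code paths.

# O(n^2) chord oracle for the upper convex hull: the hull value at a band
# is the maximum over all chords between band pairs that span it (a chord
# from a band to itself reproduces the point).
oracle_upper_hull <- function(wl, r) {
  n <- length(wl)
  h <- r
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      sel <- i:j
      line <- r[i] + (r[j] - r[i]) * (wl[sel] - wl[i]) / (wl[j] - wl[i])
      h[sel] <- pmax(h[sel], line)
    }
  }
  h
}

# textbook sum-formula OLS, independent of stats::lm
oracle_ols <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  sxx <- sum(x^2); sxy <- sum(x * y)
  slope <- (n * sxy - sx * sy) / (n * sxx - sx^2)
  intercept <- mean(y) - slope * mean(x)
  fitted <- intercept + slope * x
  sse <- sum((y - fitted)^2)
  sst <- sum((y - mean(y))^2)
  se_slope <- sqrt(sse / (n - 2) / sum((x - mean(x))^2))
  tval <- slope / se_slope
  list(slope = slope, intercept = intercept, r_squared = 1 - sse / sst,
       p_value = 2 * stats::pt(abs(tval), df = n - 2, lower.tail = FALSE))
}

# flat spectrum fixture
flat_spectrum <- function(value = 0.6, wl = seq(400, 1000, by = 2)) {
  hsi_spectrum(wl, rep(value, length(wl)))
}

# homogeneous cube: every pixel carries `spectrum`
homogeneous_cube <- function(spectrum, rows = 4, cols = 4) {
  nb <- length(spectrum$wavelength)
  vals <- array(rep(spectrum$reflectance, each = rows * cols),
                dim = c(rows, cols, nb))
  hsi_cube(vals, spectrum$wavelength)
}

# noise-free organic matrix spec used across the suite
quiet_spec <- function(name = "organic", ...) {
  sp <- default_matrix_specs(noise_sd = 0)[[name]]
  extra <- list(...)
  for (nm in names(extra)) sp[[nm]] <- extra[[nm]]
  sp
}
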