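test_that("RABD reproduces hand-evaluated trough arithmetic", {
  flat <- flat_spectrum(0.7, seq(600, 640, by = 10))
  t_sym <- trough_definition("t", 600, 620, 640)
  expect_identical(rabd(flat, t_sym), 1)

  s1 <- hsi_spectrum(seq(600, 640, by = 10), c(0.8, 0.9, 0.5, 0.9, 0.78))
  expect_equal(rabd(s1, t_sym), ((2 * 0.8 + 2 * 0.78) / 4) / 0.5)  # 1.58

  # asymmetric counts: X_left = 1, X_right = 3
  s2 <- hsi_spectrum(seq(600, 650, by = 10), c(0.9, 1.0, 0.45, 0.5, 0.55, 0.6))
  t_asym <- trough_definition("t", 610, 620, 650)
  expect_equal(rabd(s2, t_asym), ((3 * 1.0 + 1 * 0.6) / 4) / 0.45)  # 2.0

  expect_error(rabd(hsi_spectrum(seq(600, 640, 10), c(0.8, 0.7, 0, 0.7, 0.8)),
                    t_sym), "> 0")
  expect_error(rabd(flat_spectrum(0.7, seq(700, 740, 10)), t_sym), "outside")
})

test_that("RABD deepens strictly as the minimum drops, and float_min finds it", {
  t_sym <- trough_definition("t", 600, 620, 640)
  wl <- seq(600, 640, by = 10)
  vals <- seq(0.65, 0.1, by = -0.05)
  r_prev <- -Inf
  for (rmin in rev(vals)) {
    r <- rabd(hsi_spectrum(wl, c(0.8, 0.75, rmin, 0.75, 0.8)), t_sym)
    expect_gt(r, 1)
    if (is.finite(r_prev)) expect_gt(r_prev, r)
    r_prev <- r
  }
  # deepest point off-centre: the floating minimum picks 630 nm
  s <- hsi_spectrum(wl, c(0.8, 0.7, 0.6, 0.4, 0.8))
  expect_equal(rabd(s, t_sym, float_min = TRUE),
               ((1 * 0.8 + 3 * 0.8) / 4) / 0.4)
  expect_gt(rabd(s, t_sym, float_min = TRUE), rabd(s, t_sym))
})

test_that("RABA integrates the relative chord deficit", {
  t_sym <- trough_definition("t", 600, 620, 640)
  wl <- seq(600, 640, by = 10)
  # spectrum on its chord
  expect_equal(raba(hsi_spectrum(wl, seq(0.8, 0.78, length.out = 5)), t_sym), 0)

  s <- hsi_spectrum(wl, c(0.8, 0.75, 0.5, 0.72, 0.78))
  hand <- 0 + 0.045 / 0.795 + 0.29 / 0.79 + 0.065 / 0.785 + 0
  expect_equal(raba(s, t_sym), hand)

  # scale invariance
  s_k <- hsi_spectrum(wl, 3.7 * s$reflectance)
  expect_equal(raba(s_k, t_sym), raba(s, t_sym))
})

test_that("index maps preserve shape and respond to spiking", {
  sp <- quiet_spec()
  tr <- default_troughs()$RABD620
  wl <- seq(400, 1000, by = 2)
  bg <- make_background(sp, wl)
  spiked <- apply_pigment_troughs(bg, pc_mass = 100, spec = sp)

  m_flat <- index_map(homogeneous_cube(bg, 5, 6), tr)
  expect_equal(dim(m_flat), c(5, 6))
  expect_equal(as.vector(m_flat), rep(rabd(bg, tr), 30))

  m_spiked <- index_map(homogeneous_cube(spiked, 5, 6), tr)
  expect_gt(roi_mean(m_spiked), roi_mean(m_flat))

  # raba map agrees with the single-spectrum value on homogeneous cubes
  m_area <- index_map(homogeneous_cube(spiked, 5, 6), tr, method = "raba")
  expect_equal(as.vector(m_area), rep(raba(spiked, tr), 30))
})

test_that("undefined pixels are masked and counted", {
  sp <- quiet_spec()
  wl <- seq(400, 1000, by = 2)
  bg <- make_background(sp, wl)
  cube <- homogeneous_cube(bg, 4, 4)
  i620 <- snap_band(wl, 620)
  cube$values[1, 1:2, i620] <- 0  # dead pixels at the minimum band
  tr <- default_troughs()$RABD620
  expect_message(map <- index_map(cube, tr), "2 pixel")
  expect_equal(sum(is.finite(map)), 14)
  expect_equal(roi_mean(map), rabd(bg, tr))
})

test_that("ROI mean matches its brute-force definition", {
  expect_equal(roi_mean(matrix(1.3, 3, 3)), 1.3)
  expect_equal(roi_mean(matrix(c(1.2, 1.4), 1, 2)), 1.3)
  withr::with_seed(5, {
    m <- matrix(runif(48, 1, 3), 6, 8)
    mask <- matrix(runif(48) > 0.4, 6, 8)
    expect_equal(roi_mean(m, mask), sum(m[mask]) / sum(mask))
  })
  expect_error(roi_mean(matrix(1, 2, 2), matrix(FALSE, 2, 2)), "no pixels")
})

test_that("series normalisation divides by the unspiked baseline", {
  ser <- structure(data.frame(step = 0:2, mass_ug = c(0, 50, 100),
                              index = c(1.05, 1.10, 1.21)),
                   class = c("spike_series", "data.frame"))
  out <- normalize_series(ser)
  expect_equal(out$index_normalized, c(1.05, 1.10, 1.21) / 1.05)
  expect_identical(out$index_normalized[1], 1)
  # idempotent
  expect_equal(normalize_series(out)$index_normalized, out$index_normalized)
  # all-equal series normalises to all ones
  ser$index <- rep(1.2, 3)
  expect_equal(normalize_series(ser)$index_normalized, rep(1, 3))
  ser$mass_ug <- c(10, 50, 100)
  expect_error(normalize_series(ser), "unspiked")
})

test_that("index ratios behave as constructed", {
  a <- matrix(1.3, 4, 4)
  expect_equal(index_ratio(a, a), 1)
  expect_equal(index_ratio(0.61 * a, a), 0.61)
  expect_error(index_ratio(a, matrix(0, 4, 4)), "zero")
  expect_error(index_ratio(a, matrix(1, 3, 3)), "shape")
})

test_that("conservative pigment windows share no band", {
  tr <- default_troughs("conservative")
  wl <- seq(400, 1000, by = 2)
  pc_bands <- seq(snap_band(wl, tr$RABD620$lambda_left),
                  snap_band(wl, tr$RABD620$lambda_right))
  ch_bands <- seq(snap_band(wl, tr$RABD675$lambda_left),
                  snap_band(wl, tr$RABD675$lambda_right))
  expect_length(intersect(pc_bands, ch_bands), 0)
})

test_that("pixel-first ROI statistics differ from mean-spectrum indices on
           heterogeneous cubes but agree on homogeneous ones", {
  sp <- quiet_spec()
  wl <- seq(400, 1000, by = 2)
  tr <- default_troughs()$RABD620
  bg <- make_background(sp, wl)
  spiked <- apply_pigment_troughs(bg, pc_mass = 150, spec = sp)

  homog <- homogeneous_cube(spiked, 4, 4)
  expect_equal(roi_mean(index_map(homog, tr)),
               rabd(cube_mean_spectrum(homog), tr))

  # half the pixels unspiked, half heavily spiked: the mean of per-pixel
  # ratios is not the ratio at the mean spectrum (Jensen gap)
  hetero <- homogeneous_cube(spiked, 4, 4)
  hetero$values[, 1:2, ] <- homogeneous_cube(bg, 4, 4)$values[, 1:2, ]
  pixel_first <- roi_mean(index_map(hetero, tr))
  spectrum_first <- rabd(cube_mean_spectrum(hetero), tr)
  expect_gt(abs(pixel_first - spectrum_first), 1e-3)
})
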