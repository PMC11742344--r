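make_test_cube <- function(rows = 4, cols = 4, bands = 10, seed = 99) {
  withr::with_seed(seed, {
    hsi_cube(array(runif(rows * cols * bands), c(rows, cols, bands)),
             seq(500, by = 10, length.out = bands))
  })
}

test_that("ENVI round-trips are bit-exact in every interleave", {
  cube <- make_test_cube()
  for (il in c("bsq", "bil", "bip")) {
    path <- withr::local_tempfile(fileext = ".dat")
    write_envi(cube, path, interleave = il)
    back <- read_envi(path)
    expect_identical(back$values, cube$values)
    expect_identical(back$wavelength, cube$wavelength)
    expect_identical(back$pixel_size_um, cube$pixel_size_um)
  }
})

test_that("corrupt or incomplete ENVI files raise classed errors", {
  cube <- make_test_cube()
  path <- withr::local_tempfile(fileext = ".dat")
  write_envi(cube, path)

  # truncated body: the message names expected and found byte counts
  body <- readBin(path, "raw", file.size(path))
  writeBin(body[1:100], path)
  err <- expect_error(read_envi(path), class = "envi_size_mismatch")
  expect_match(conditionMessage(err), "1280")
  expect_match(conditionMessage(err), "100")
  writeBin(body, path)

  hdr_path <- paste0(path, ".hdr")
  hdr <- readLines(hdr_path)

  writeLines(sub("interleave = bsq", "interleave = weird", hdr), hdr_path)
  expect_error(read_envi(path), class = "envi_unknown_interleave")

  writeLines(hdr[!grepl("^wavelength =", hdr)], hdr_path)
  expect_error(read_envi(path), class = "envi_missing_wavelength")

  file.remove(hdr_path)
  expect_error(read_envi(path), class = "envi_header_missing")
})

test_that("float32 ENVI output rereads within single precision", {
  cube <- make_test_cube()
  path <- withr::local_tempfile(fileext = ".dat")
  write_envi(cube, path, data_type = 4)
  back <- read_envi(path)
  expect_equal(back$values, cube$values, tolerance = 1e-6)
})

test_that("downcore profiles collapse rows at the right depths", {
  sp <- quiet_spec()
  wl <- seq(400, 1000, by = 2)
  tr <- default_troughs("downcore")
  bg <- make_background(sp, wl)
  rich <- apply_pigment_troughs(bg, pc_mass = 150, spec = sp)

  # row-constant cube: profile equals per-row single-spectrum indices
  nb <- length(wl)
  rows <- 6; cols <- 5
  vals <- array(NA_real_, c(rows, cols, nb))
  row_spectra <- list()
  for (i in seq_len(rows)) {
    s <- apply_pigment_troughs(bg, pc_mass = 25 * (i - 1), spec = sp)
    row_spectra[[i]] <- s
    vals[i, , ] <- matrix(s$reflectance, cols, nb, byrow = TRUE)
  }
  cube <- hsi_cube(vals, wl)
  prof <- downcore_profile(cube, tr$RABD620)
  expect_equal(prof$mean_RABD620,
               vapply(row_spectra, rabd, numeric(1),
                      trough = tr$RABD620))
  expect_equal(prof$sd_RABD620, rep(0, rows))

  # alternating phycocyanin-rich / poor laminae give a period-2 profile
  lam <- array(NA_real_, c(8, 4, nb))
  for (i in 1:8) {
    s <- if (i %% 2 == 1) rich else bg
    lam[i, , ] <- matrix(s$reflectance, 4, nb, byrow = TRUE)
  }
  varve <- hsi_cube(lam, wl)
  vp <- downcore_profile(varve, tr$RABD620)
  expect_equal(vp$mean_RABD620[seq(1, 8, 2)], rep(vp$mean_RABD620[1], 4))
  expect_equal(vp$mean_RABD620[seq(2, 8, 2)], rep(vp$mean_RABD620[2], 4))
  expect_gt(vp$mean_RABD620[1], vp$mean_RABD620[2])

  # depth axis: 100 rows at 80 um span 0 - 7.92 mm
  big <- hsi_cube(array(0.5, c(100, 4, 5)), seq(600, 640, 10),
                  pixel_size_um = 80)
  dp <- downcore_profile(big, tr$RABD620)
  expect_equal(range(dp$depth_mm), c(0, 7.92))

  # fully masked rows surface as NA
  mask <- matrix(TRUE, 8, 4); mask[3, ] <- FALSE
  expect_message(vm <- downcore_profile(varve, tr$RABD620, mask = mask),
                 "fully masked")
  expect_true(is.na(vm$mean_RABD620[3]))
})

test_that("pipeline configs are validated field by field", {
  cfg <- default_pipeline_config(seed = 1, output_dir = withr::local_tempdir())
  cfg$troughs <- "bogus"
  cfg$simulation$pc_masses <- c(100, 0)
  err <- expect_error(run_pipeline(cfg), "invalid pipeline config")
  expect_match(conditionMessage(err), "troughs")
  expect_match(conditionMessage(err), "pc_masses")
})

test_that("the pipeline emits its declared artifacts and a manifest", {
  out <- file.path(withr::local_tempdir(), "run")
  cfg <- default_pipeline_config(seed = 21, output_dir = out)
  cfg$simulation$matrices <- "organic"
  cfg$simulation$shape <- c(4, 4)
  res <- suppressMessages(run_pipeline(cfg))
  expect_true(all(file.exists(file.path(out, c(
    "spike_series.csv", "calibration.csv", "calibration.json",
    "interference.csv", "interference_summary.json",
    "downcore_profile.csv", "config.json", "run_manifest.json",
    "run_log.txt")))))
  man <- jsonlite::read_json(file.path(out, "run_manifest.json"))
  expect_equal(man$seed, 21)
  expect_match(man$config_md5, "^[0-9a-f]{32}$")
  expect_equal(nrow(res$spike_series), 4)
})

test_that("a YAML config file drives the same run as the in-memory list", {
  dir <- withr::local_tempdir()
  cfg <- default_pipeline_config(seed = 9, output_dir = file.path(dir, "a"))
  cfg$simulation$matrices <- "clastic"
  cfg$simulation$shape <- c(4, 4)
  yml <- file.path(dir, "cfg.yaml")
  yaml::write_yaml(cfg, yml)
  r1 <- suppressMessages(run_pipeline(cfg))
  r2 <- suppressMessages(run_pipeline(yml, output_dir = file.path(dir, "b")))
  expect_equal(r2$spike_series, r1$spike_series)
})
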