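test_that("Beer-Lambert inversion round-trips the simulator", {
  expect_equal(beer_lambert_concentration(0), 0)
  expect_equal(beer_lambert_concentration(0.8815, alpha = 88.15, L = 1), 0.01)
  conc <- c(0, 5, 20, 60, 100)  # ug/ml
  a <- simulate_absorbance_series(conc, alpha = 88.15, L = 1)
  expect_equal(beer_lambert_concentration(a, 88.15, 1) * 1000, conc)
  expect_error(beer_lambert_concentration(0.5, alpha = 0), "> 0")
  expect_error(beer_lambert_concentration(-0.1), ">= 0")
})

test_that("the two-wavelength phycocyanin equation evaluates and floors", {
  expect_equal(pc_concentration_bennett_bogorad(0, 0), 0)
  expect_equal(pc_concentration_bennett_bogorad(0.534, 0), 0.1)
  expect_equal(pc_concentration_bennett_bogorad(0.474, 1.0), 0)
  expect_warning(pc_concentration_bennett_bogorad(0.1, 1.0), "floored")
  expect_error(pc_concentration_bennett_bogorad(-0.1), ">= 0")
})

test_that("OLS fit recovers exact lines and matches the sum-formula oracle", {
  x <- seq(0, 12, by = 2)
  fit <- suppressWarnings(fit_calibration(x, 2 * x + 1))
  expect_equal(fit$slope, 2)
  expect_equal(fit$intercept, 1)
  expect_equal(fit$r_squared, 1)
  expect_equal(fit$n, 7)

  withr::with_seed(31, {
    for (k in 1:20) {
      xr <- runif(12, 0, 50)
      yr <- 0.3 + 0.02 * xr + rnorm(12, sd = 0.5)
      got <- fit_calibration(xr, yr)
      want <- oracle_ols(xr, yr)
      expect_equal(got$slope, want$slope, tolerance = 1e-10)
      expect_equal(got$intercept, want$intercept, tolerance = 1e-10)
      expect_equal(got$r_squared, want$r_squared, tolerance = 1e-10)
      expect_equal(got$p_value, want$p_value, tolerance = 1e-10)
    }
  })

  expect_error(fit_calibration(rep(1, 5), 1:5), "constant")
  expect_error(fit_calibration(1:2, 1:2), "3 points")
})

test_that("fitted slopes are unbiased over repeated noisy series", {
  s_true <- 0.5
  x <- seq(0, 10, length.out = 24)
  sigma <- 0.2
  slopes <- vapply(1:500, function(seed) {
    y <- s_true * x + 1 +
      withr::with_seed(seed, rnorm(24, sd = sigma))
    fit_calibration(x, y)$slope
  }, numeric(1))
  se_slope <- sigma / sqrt(sum((x - mean(x))^2))
  expect_lt(abs(mean(slopes) - s_true), 2 * se_slope)
})

test_that("R-squared degrades with noise in expectation", {
  x <- seq(0, 10, length.out = 24)
  mean_r2 <- function(sd) {
    mean(vapply(1:100, function(seed) {
      y <- 0.5 * x + withr::with_seed(seed + 7000, rnorm(24, sd = sd))
      fit_calibration(x, y)$r_squared
    }, numeric(1)))
  }
  r2_lo <- mean_r2(0.1)
  r2_hi <- mean_r2(1.0)
  expect_gt(r2_lo, r2_hi)
})

test_that("cross-validated RMSEP is zero on a line, seeded, and order-free", {
  x <- seq(0, 100, length.out = 20)
  y <- 0.01 * x + 0.2
  expect_lt(as.numeric(rmsep_cv(x, y, folds = 10, seed = 1)), 1e-10)

  withr::with_seed(17, yn <- y + rnorm(20, sd = 0.05))
  r1 <- rmsep_cv(x, yn, folds = 10, seed = 3)
  r2 <- rmsep_cv(x, yn, folds = 10, seed = 3)
  expect_identical(r1, r2)

  # shuffling the input pairs leaves the estimate unchanged
  perm <- withr::with_seed(8, sample(20))
  expect_equal(as.numeric(rmsep_cv(x[perm], yn[perm], folds = 10, seed = 3)),
               as.numeric(r1))

  # different fold seeds move the estimate (so the seed really drives folds)
  expect_false(isTRUE(all.equal(as.numeric(r1),
                                as.numeric(rmsep_cv(x, yn, 10, seed = 4)))))
})

test_that("RMSEP falls as measurement noise falls", {
  conc <- seq(0, 100, length.out = 20)
  mean_rmsep <- function(sd) {
    mean(vapply(1:50, function(seed) {
      a <- simulate_absorbance_series(conc, noise_sd = sd, seed = seed)
      as.numeric(rmsep_cv(conc, a, folds = 10, seed = seed))
    }, numeric(1)))
  }
  expect_gt(mean_rmsep(0.05), mean_rmsep(0.005))
})

test_that("small series fall back to leave-one-out with a warning", {
  x <- c(0, 50, 100, 150)
  y <- c(1, 1.4, 1.9, 2.5)
  expect_warning(r <- rmsep_cv(x, y, folds = 10, seed = 1), "leave-one-out")
  expect_equal(attr(r, "folds"), 4L)
  expect_error(rmsep_cv(x, y, folds = 10, seed = 1, reduce_folds = FALSE),
               "below")
})

test_that("calibration reports regress normalised index on mass", {
  ser <- structure(data.frame(step = 0:3, mass_ug = c(0, 50, 100, 150),
                              index = c(1.2, 1.32, 1.44, 1.56)),
                   class = c("spike_series", "data.frame"))
  rep <- suppressWarnings(build_calibration_report(ser, seed = 1))
  expect_equal(rep$model$r_squared, 1)
  expect_lt(rep$model$p_value, 0.05)
  expect_true(rep$significant)
  expect_equal(rep$model$slope, (1.56 / 1.2 - 1) / 150)
  expect_equal(rep$residuals$residual, rep(0, 4), tolerance = 1e-12)
  expect_lt(rep$model$rmsep_percent, 1e-8)
})

test_that("three-point noisy series are usually non-significant", {
  x <- c(0, 50, 100)
  rejections <- vapply(1:200, function(seed) {
    y <- 1 + 0.001 * x + withr::with_seed(seed + 300, rnorm(3, sd = 0.05))
    fit_calibration(x, y)$p_value < 0.05
  }, logical(1))
  expect_lt(mean(rejections), 0.5)
})

test_that("pooled multi-matrix series give one model over all points", {
  x <- rep(c(0, 50, 100, 150), 3)
  y <- 1 + 0.004 * x + rep(c(0, 0.02, -0.02), each = 4)
  fit <- fit_calibration(x, y)
  expect_equal(fit$n, 12)
  expect_equal(fit$slope, oracle_ols(x, y)$slope, tolerance = 1e-10)
})
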