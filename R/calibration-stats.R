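#' Beer-Lambert concentration from absorbance
#'
#' Inverts `A = alpha * L * c`: `c = A / (alpha * L)` in g/l.
#'
#' @param A Absorbance (dimensionless, >= 0). Vectorised.
#' @param alpha Specific extinction coefficient in l g^-1 cm^-1 (default
#'   88.15, chlorophyll a in 100% acetone).
#' @param L Optical path length in cm.
#' @return Concentration(s) in g/l.
#' @export
beer_lambert_concentration <- function(A, alpha = 88.15, L = 1) {
  if (alpha <= 0 || L <= 0) stop("`alpha` and `L` must be > 0", call. = FALSE)
  if (any(A < 0)) stop("absorbance must be >= 0", call. = FALSE)
  A / (alpha * L)
}

#' Phycocyanin concentration from a two-wavelength absorbance reading
#'
#' Spectrophotometric phycocyanin concentration from absorbance at 620 nm
#' with an allophycocyanin correction at 652 nm:
#' `PC (mg/ml) = (A620 - k * A652) / d`, with the standard coefficients
#' `k = 0.474` and `d = 5.34`. A negative numerator (correction exceeding
#' the 620 nm signal) is floored at 0 with a warning.
#'
#' @param A620,A652 Absorbances at 620 and 652 nm (>= 0). Vectorised.
#' @param k,d Equation coefficients; exposed for alternative published
#'   variants.
#' @return Concentration(s) in mg/ml.
#' @export
pc_concentration_bennett_bogorad <- function(A620, A652 = 0, k = 0.474,
                                             d = 5.34) {
  if (any(A620 < 0) || any(A652 < 0)) {
    stop("absorbances must be >= 0", call. = FALSE)
  }
  pc <- (A620 - k * A652) / d
  if (any(pc < 0)) {
    warning("negative phycocyanin concentration floored at 0 ",
            "(A652 correction exceeds A620)", call. = FALSE)
    pc[pc < 0] <- 0
  }
  pc
}

#' Ordinary least-squares calibration fit
#'
#' Fits `y = intercept + slope * x` by OLS and reports the slope, the
#' intercept, R-squared, the two-sided t-test p-value of the slope
#' (t distribution, n - 2 df) and n. RMSEP is filled in by [rmsep_cv()] or
#' [build_calibration_report()].
#'
#' @param x Predictor (concentration or spiked mass), not constant, n >= 3.
#' @param y Response (absorbance or normalised index).
#' @return An object of class `calibration_model`: a list with `slope`,
#'   `intercept`, `r_squared`, `p_value`, `n`, `rmsep_percent` (`NA` until
#'   computed), `folds` (`NA`).
#' @export
fit_calibration <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x)
  if (n != length(y)) stop("`x` and `y` must have equal length", call. = FALSE)
  if (n < 3L) stop("need at least 3 points for a calibration fit", call. = FALSE)
  if (stats::sd(x) == 0) stop("`x` is constant; no slope estimable", call. = FALSE)
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  co <- stats::coef(sm)
  structure(list(slope = unname(co["x", "Estimate"]),
                 intercept = unname(co["(Intercept)", "Estimate"]),
                 r_squared = sm$r.squared,
                 p_value = unname(co["x", "Pr(>|t|)"]),
                 n = n, rmsep_percent = NA_real_, folds = NA_integer_),
            class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf(
    "<calibration_model> y = %.4g + %.4g x | R2 = %.4f, p = %.3g, n = %d",
    x$intercept, x$slope, x$r_squared, x$p_value, x$n))
  if (is.finite(x$rmsep_percent)) {
    cat(sprintf(", RMSEP = %.3g%% (%d-fold CV)", x$rmsep_percent, x$folds))
  }
  cat("\n")
  invisible(x)
}

#' Cross-validated root mean square error of prediction
#'
#' K-fold (default tenfold) cross-validation of the OLS calibration line:
#' points are assigned to folds by a seeded shuffle, each fold is predicted
#' from an OLS fit on the remaining points, and the pooled squared
#' prediction errors give `RMSEP% = 100 * sqrt(MSE) / denominator`.
#' Fold assignment is made on a canonical ordering of the (x, y) pairs, so
#' the result does not depend on the order the data arrive in. When n is
#' below the requested fold count, the folds reduce to n
#' (leave-one-out) with a warning, or an error if `reduce_folds = FALSE`.
#'
#' @param x,y Calibration points as in [fit_calibration()].
#' @param folds Number of CV folds (default 10).
#' @param seed Integer seed for the fold shuffle.
#' @param denominator `"mean"` (default; mean of all observed y), `"range"`
#'   or `"max"` — the normaliser turning RMSEP into a percentage.
#' @param reduce_folds Whether to fall back to leave-one-out when
#'   `n < folds`.
#' @return RMSEP as a percentage (single number, >= 0), with attribute
#'   `folds` = folds actually used.
#' @export
rmsep_cv <- function(x, y, folds = 10, seed = 1L,
                     denominator = c("mean", "range", "max"),
                     reduce_folds = TRUE) {
  denominator <- match.arg(denominator)
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x)
  if (n != length(y)) stop("`x` and `y` must have equal length", call. = FALSE)
  if (n < 3L) stop("need at least 3 points", call. = FALSE)
  folds <- as.integer(folds)
  if (n < folds) {
    if (!reduce_folds) {
      stop(sprintf("n = %d is below the %d requested folds", n, folds),
           call. = FALSE)
    }
    warning(sprintf("n = %d < %d folds; using leave-one-out", n, folds),
            call. = FALSE)
    folds <- n
  }
  ord <- order(x, y)  # canonical order: fold membership ignores input order
  xs <- x[ord]; ys <- y[ord]
  perm <- withr::with_seed(as.integer(seed), sample.int(n))
  fold_id <- integer(n)
  fold_id[perm] <- rep_len(seq_len(folds), n)
  sq_err <- numeric(n)
  for (f in seq_len(folds)) {
    held <- fold_id == f
    fit <- stats::lm(ys[!held] ~ xs[!held])
    pred <- stats::coef(fit)[1] + stats::coef(fit)[2] * xs[held]
    sq_err[held] <- (ys[held] - pred)^2
  }
  denom <- switch(denominator,
                  mean = mean(ys), range = diff(range(ys)), max = max(ys))
  if (!is.finite(denom) || denom == 0) {
    stop("RMSEP denominator is zero; choose another `denominator`",
         call. = FALSE)
  }
  structure(100 * sqrt(mean(sq_err)) / denom, folds = folds)
}

#' Calibration report for a spike series
#'
#' Regresses the normalised ROI-mean index on cumulative spiked mass,
#' attaches the cross-validated RMSEP, and flags non-significant fits
#' (p >= 0.05) — common for short 3-4 step spiking series.
#'
#' @param series A `spike_series` data.frame; normalised with
#'   [normalize_series()] if not already.
#' @param folds,seed,denominator Passed to [rmsep_cv()].
#' @return List with `model` (a `calibration_model`), `residuals`
#'   (data.frame: step, mass_ug, observed, fitted, residual) and
#'   `significant` (logical, p < 0.05).
#' @export
build_calibration_report <- function(series, folds = 10, seed = 1L,
                                     denominator = "mean") {
  if (!"index_normalized" %in% names(series)) {
    series <- normalize_series(series)
  }
  x <- series$mass_ug
  y <- series$index_normalized
  model <- fit_calibration(x, y)
  rm_pct <- rmsep_cv(x, y, folds = folds, seed = seed,
                     denominator = denominator)
  model$rmsep_percent <- as.numeric(rm_pct)
  model$folds <- attr(rm_pct, "folds")
  fitted <- model$intercept + model$slope * x
  list(model = model,
       residuals = data.frame(step = series$step, mass_ug = x, observed = y,
                              fitted = fitted, residual = y - fitted),
       significant = model$p_value < 0.05)
}
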