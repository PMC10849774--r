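## Logistic growth-curve fitting, exponential segment-length fitting, and
## the small fit-comparison statistics (MAPE, WMAPE, n-sigma test) plus the
## Damkohler utility.

#' Mean absolute percentage error
#'
#' `mean(|a_i - p_i| / a_i)`, as a fraction. Zero or negative actual values
#' are rejected (a zero actual makes the percentage error infinite).
#'
#' @param actual,predicted equal-length numeric vectors (length >= 1).
#' @return fraction (multiply by 100 for percent).
#' @export
mape <- function(actual, predicted) {
  if (length(actual) != length(predicted) || length(actual) < 1)
    stop("actual and predicted must have equal length >= 1")
  if (any(actual < 0)) stop("negative actual value at index ",
                            which(actual < 0)[1])
  z <- which(actual == 0)
  if (length(z)) stop("zero actual value at index ", z[1],
                      ": percentage error undefined")
  mean(abs(actual - predicted) / actual)
}

#' Weighted mean absolute percentage error
#'
#' `sum(|a_i - p_i|) / sum(a_i)`: each point is weighted by its share of the
#' total, which tames the small-value sensitivity of [mape()].
#'
#' @inheritParams mape
#' @return fraction.
#' @export
wmape <- function(actual, predicted) {
  if (length(actual) != length(predicted) || length(actual) < 1)
    stop("actual and predicted must have equal length >= 1")
  if (any(actual < 0)) stop("negative actual value at index ",
                            which(actual < 0)[1])
  s <- sum(actual)
  if (s == 0) stop("sum of actual values is zero")
  sum(abs(actual - predicted)) / s
}

#' n-sigma agreement test
#'
#' TRUE iff `|x1 - x2| <= n * sqrt(u1^2 + u2^2)`. TRUE means the two fitted
#' values are statistically compatible at n combined standard errors; FALSE
#' means one cannot assume they came from the same random process.
#'
#' @param x1,x2 fitted values.
#' @param u1,u2 their uncertainties (non-negative).
#' @param n number of sigmas (integer >= 1).
#' @return logical.
#' @export
n_sigma_test <- function(x1, u1, x2, u2, n) {
  if (u1 < 0 || u2 < 0) stop("uncertainties must be non-negative")
  if (n < 1) stop("n must be >= 1")
  abs(x1 - x2) <= n * sqrt(u1^2 + u2^2)
}

#' Damkohler number
#'
#' Ratio of the diffusion timescale `L^2 / D` to the reaction timescale
#' `1/k`: `Da = k * L^2 / D`. Values much greater than 1 indicate
#' diffusion-limited transport of the consumed species (here, VEGF uptake
#' by endothelial cells across the culture well).
#'
#' @param uptake_rate first-order uptake rate k (1/s).
#' @param length_scale system size (cm).
#' @param diffusivity diffusion constant (cm^2/s).
#' @return dimensionless Damkohler number.
#' @export
damkohler_number <- function(uptake_rate, length_scale, diffusivity) {
  if (uptake_rate <= 0 || length_scale <= 0 || diffusivity <= 0)
    stop("all inputs must be positive")
  uptake_rate * length_scale^2 / diffusivity
}

#' Fit a logistic growth curve by nonlinear least squares
#'
#' Fits `Y(t) = Y_max / (1 + exp(-k (t - t1)))` with positivity bounds on
#' `Y_max` and `k`. Initialization: `Y_max = 1.05 max(Y)`; `t1` = first day
#' the series crosses `max(Y)/2` (linear interpolation); `k` from the local
#' slope at that crossing via the midpoint identity `slope = Y_max k / 4`.
#' The derived onset `t0 = t1 - 2/k` (x-intercept of the inflection
#' tangent) and maximal rate `(dY/dt)_max = Y_max k / 4` are attached, as
#' are MAPE/WMAPE of the fit on the data points.
#'
#' @param series a [time_series()] (or data.frame with `day`, `value`),
#'   at least 4 points, not all equal.
#' @return a `logistic_fit`: `Y_max`, `k`, `t1`, `t0`, `rate_max`,
#'   standard errors (`se_Y_max`, `se_k`, `se_t1`), `mape`, `wmape`
#'   (NA when a zero value makes MAPE undefined), `converged`, `fitted`,
#'   `residuals`, and the initializer `init`. Non-convergence returns the
#'   object with `converged = FALSE` and parameters `NA`.
#' @export
fit_logistic <- function(series) {
  t <- series$day; y <- series$value
  ok <- is.finite(t) & is.finite(y)
  t <- t[ok]; y <- y[ok]
  if (length(y) < 4) stop("need at least 4 points")
  if (all(y == y[1])) stop("all values equal: logistic fit is degenerate")
  if (all(y == 0)) stop("all-zero series")
  ymax0 <- 1.05 * max(y)
  half <- max(y) / 2
  above <- which(y >= half)
  i <- above[1]
  if (i == 1) {
    t10 <- t[1]
    slope <- (y[min(2, length(y))] - y[1]) / (t[min(2, length(t))] - t[1] + 1e-12)
  } else {
    # linear interpolation of the crossing
    f <- (half - y[i - 1]) / (y[i] - y[i - 1])
    t10 <- t[i - 1] + f * (t[i] - t[i - 1])
    slope <- (y[i] - y[i - 1]) / (t[i] - t[i - 1])
  }
  k0 <- max(4 * abs(slope) / ymax0, 1e-3)
  init <- list(Y_max = ymax0, k = k0, t1 = t10)
  df <- data.frame(t = t, y = y)
  fit <- tryCatch(
    stats::nls(y ~ Y_max / (1 + exp(-k * (t - t1))), data = df,
               start = init, algorithm = "port",
               lower = c(Y_max = 1e-12, k = 1e-12, t1 = -Inf),
               control = stats::nls.control(maxiter = 200, warnOnly = FALSE)),
    error = function(e) e)
  out <- list(init = init, n = length(y), converged = FALSE,
              Y_max = NA_real_, k = NA_real_, t1 = NA_real_,
              t0 = NA_real_, rate_max = NA_real_,
              se_Y_max = NA_real_, se_k = NA_real_, se_t1 = NA_real_,
              mape = NA_real_, wmape = NA_real_,
              fitted = rep(NA_real_, length(y)), residuals = y - NA_real_,
              day = t, value = y)
  class(out) <- "logistic_fit"
  if (inherits(fit, "error")) {
    out$error <- conditionMessage(fit)
    p0 <- logistic_value(t, init$Y_max, init$k, init$t1)
    out$residuals <- y - p0
    return(out)
  }
  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, 3))
  pred <- logistic_value(t, cf[["Y_max"]], cf[["k"]], cf[["t1"]])
  out$converged <- TRUE
  out$Y_max <- cf[["Y_max"]]; out$k <- cf[["k"]]; out$t1 <- cf[["t1"]]
  out$t0 <- out$t1 - 2 / out$k
  out$rate_max <- out$Y_max * out$k / 4
  out$se_Y_max <- se[["Y_max"]]; out$se_k <- se[["k"]]; out$se_t1 <- se[["t1"]]
  out$fitted <- pred
  out$residuals <- y - pred
  out$mape <- tryCatch(mape(y, pred), error = function(e) NA_real_)
  out$wmape <- tryCatch(wmape(y, pred), error = function(e) NA_real_)
  out
}

#' @export
print.logistic_fit <- function(x, ...) {
  if (!x$converged) {
    cat("<logistic_fit: did not converge>\n")
  } else {
    cat(sprintf(
      "<logistic_fit Y_max = %.4g +/- %.2g, k = %.4g +/- %.2g /day, t1 = %.4g +/- %.2g d>\n",
      x$Y_max, x$se_Y_max, x$k, x$se_k, x$t1, x$se_t1))
    cat(sprintf("  onset t0 = %.4g d, (dY/dt)_max = %.4g /day, WMAPE = %.3g\n",
                x$t0, x$rate_max, x$wmape))
  }
  invisible(x)
}

#' Semi-log exponential fit from binned densities
#'
#' Ordinary least squares of `ln(density)` on bin centres; the
#' characteristic length is `l* = -1/slope` with its standard error
#' propagated from the slope (`se_l = se_slope / slope^2`). This is the
#' shared back end of [fit_exponential_pdf()] and doubles as the analytic
#' oracle path (exact bin densities of an exponential recover `l*` exactly,
#' since ln of binned exponential mass is linear in the bin centre).
#'
#' @param bin_centers_um bin centres (um), >= 2 values.
#' @param density strictly positive densities at those centres.
#' @param n sample count behind the densities (metadata).
#' @param bin_width_um bin width (metadata).
#' @param population segment population label (`"tip"`, `"bifurcating"`, ...).
#' @return an `exponential_fit`: `l_star_um`, `se_l_star_um`, `slope`,
#'   `se_slope`, `intercept`, `n`, `n_bins`, `valid` (FALSE when the slope
#'   is non-negative).
#' @export
fit_exponential_from_density <- function(bin_centers_um, density, n = NA,
                                         bin_width_um = NA,
                                         population = NA_character_) {
  keep <- density > 0
  x <- bin_centers_um[keep]; dn <- density[keep]
  if (length(x) < 2) stop("need at least 2 non-empty bins")
  fit <- stats::lm(log(dn) ~ x)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  se_slope <- if (length(x) > 2)
    unname(suppressWarnings(summary(fit))$coefficients[2, 2]) else NA_real_
  valid <- slope < 0
  out <- list(l_star_um = if (valid) -1 / slope else NA_real_,
              se_l_star_um = if (valid && is.finite(se_slope))
                se_slope / slope^2 else NA_real_,
              slope = slope, se_slope = se_slope, intercept = intercept,
              n = n, n_bins = length(x), bin_width_um = bin_width_um,
              population = population, valid = valid)
  class(out) <- "exponential_fit"
  out
}

#' Fit an exponential segment-length distribution
#'
#' Histograms the lengths with a fixed bin width starting at `min_length_um`
#' (the pruning cut, below which skeletonization over-produces short
#' segments), normalizes to a density, drops empty bins, and fits a line to
#' `ln P(l)` vs the bin centre by ordinary least squares.
#'
#' @param lengths_um segment lengths in um.
#' @param bin_width_um histogram bin width (default 25).
#' @param min_length_um lower cut (default 62.5); lengths below it are
#'   discarded before binning.
#' @param min_n minimum retained sample size (default 30).
#' @param min_density_frac bins whose density is below this fraction of the
#'   peak bin density are excluded from the fit (default 1/10, about 2.3
#'   e-foldings of decay). Far-tail bins sit on the discreteness floor:
#'   1-count bins survive while 0-count bins drop out, which flattens the
#'   observed tail and biases the characteristic length upward by ~25% at
#'   n = 1000. A relative-density cut removes most of that bias while
#'   keeping the fit exactly invariant under duplicating every sample.
#' @param population label stored in the fit.
#' @return an `exponential_fit` (see [fit_exponential_from_density()]).
#' @export
fit_exponential_pdf <- function(lengths_um, bin_width_um = 25,
                                min_length_um = 62.5, min_n = 30,
                                min_density_frac = 1 / 10,
                                population = NA_character_) {
  x <- lengths_um[is.finite(lengths_um) & lengths_um >= min_length_um]
  if (length(x) < min_n)
    stop("need at least ", min_n, " lengths above ", min_length_um, " um")
  idx <- floor((x - min_length_um) / bin_width_um)
  counts <- table(idx)
  centers <- min_length_um + (as.numeric(names(counts)) + 0.5) * bin_width_um
  density <- as.numeric(counts) / (length(x) * bin_width_um)
  keep <- density >= max(density) * min_density_frac
  if (sum(keep) < 2) keep <- rep(TRUE, length(counts))   # tiny samples: use all
  fit_exponential_from_density(centers[keep], density[keep], n = length(x),
                               bin_width_um = bin_width_um,
                               population = population)
}

#' @export
print.exponential_fit <- function(x, ...) {
  if (!x$valid) cat("<exponential_fit: invalid (non-negative slope)>\n")
  else cat(sprintf("<exponential_fit l* = %.4g +/- %.2g um (n = %s, %d bins)>\n",
                   x$l_star_um, x$se_l_star_um, as.character(x$n), x$n_bins))
  invisible(x)
}
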