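test_that("MAPE and WMAPE match their definitions and guard their domains", {
  expect_equal(mape(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(wmape(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(mape(c(1, 2), c(1.1, 1.8)), 0.10, tolerance = 1e-12)
  expect_equal(wmape(c(1, 2), c(1.1, 1.8)), 0.10, tolerance = 1e-12)
  # the small-value sensitivity the two metrics differ on
  expect_equal(mape(c(100, 1), c(100, 2)), 0.5)
  expect_equal(wmape(c(100, 1), c(100, 2)), 1 / 101, tolerance = 1e-12)

  expect_error(mape(c(1, 0, 2), c(1, 1, 2)), "index 2")
  expect_error(mape(c(1, -1), c(1, 1)), "negative")
  expect_error(wmape(c(1, -1), c(1, 1)), "negative")
  expect_error(mape(1:3, 1:2), "equal length")

  # with all-equal actual values the two metrics coincide
  a <- rep(5, 4); p <- c(4, 6, 5.5, 4.5)
  expect_equal(mape(a, p), wmape(a, p), tolerance = 1e-12)
})

test_that("the n-sigma test is symmetric, monotone, and matches arithmetic", {
  expect_true(n_sigma_test(10, 1, 12, 1, 3))    # 3*sqrt(2) > 2
  expect_false(n_sigma_test(10, 0.2, 12, 0.2, 3))
  expect_true(n_sigma_test(7, 0, 7, 0, 1))      # equal values always pass
  expect_false(n_sigma_test(1, 0, 2, 0, 100))   # sigma = 0, unequal
  expect_error(n_sigma_test(1, -1, 2, 1, 2), "non-negative")

  set.seed(7)
  for (i in 1:25) {
    x <- rnorm(2, 0, 5); u <- runif(2, 0, 2); n <- sample(1:5, 1)
    expect_identical(n_sigma_test(x[1], u[1], x[2], u[2], n),
                     n_sigma_test(x[2], u[2], x[1], u[1], n))
    if (n_sigma_test(x[1], u[1], x[2], u[2], n))
      expect_true(n_sigma_test(x[1], u[1], x[2], u[2], n + 1))
  }
})

test_that("the Damkohler number is k L^2 / D", {
  expect_equal(damkohler_number(1, 1, 1), 1)
  expect_equal(damkohler_number(1e-5, 1.6, 3e-7), 85.3333333, tolerance = 1e-7)
  expect_lt(damkohler_number(1e-5, 1.6, 3e-2), 1e-3)
  expect_error(damkohler_number(0, 1, 1), "positive")
})

test_that("logistic fitting recovers noiseless parameters and identities", {
  ts <- generate_logistic_series(4000, 1.2, 7, days = 0:14)
  fit <- fit_logistic(ts)
  expect_true(fit$converged)
  expect_equal(fit$Y_max, 4000, tolerance = 1e-6)
  expect_equal(fit$k, 1.2, tolerance = 1e-6)
  expect_equal(fit$t1, 7, tolerance = 1e-6)
  # exact derived identities
  expect_equal(fit$t0, fit$t1 - 2 / fit$k, tolerance = 1e-12)
  expect_equal(fit$rate_max, fit$Y_max * fit$k / 4, tolerance = 1e-12)
  expect_equal(fit$t0, 7 - 2 / 1.2, tolerance = 1e-5)
  expect_equal(fit$rate_max, 1200, tolerance = 1e-4)
  expect_lt(fit$wmape, 1e-8)
  # the fitted curve passes through Y_max/2 at t1
  expect_equal(logistic_value(fit$t1, fit$Y_max, fit$k, fit$t1),
               fit$Y_max / 2, tolerance = 1e-12)
  # rate_max equals the numerical maximum of dY/dt
  dY <- function(t) fit$Y_max * fit$k * exp(-fit$k * (t - fit$t1)) /
    (1 + exp(-fit$k * (t - fit$t1)))^2
  num_max <- stats::optimize(dY, c(0, 14), maximum = TRUE)$objective
  expect_equal(fit$rate_max, num_max, tolerance = 1e-9)

  expect_error(fit_logistic(time_series(0:2, c(1, 2, 3))), "at least 4")
  expect_error(fit_logistic(time_series(0:5, rep(2, 6))), "all values equal")
  expect_error(fit_logistic(time_series(0:5, rep(0, 6))), "all values equal|all-zero")
})

test_that("noisy logistic series recover the onset within half a day", {
  t0_true <- 7 - 2 / 1.2
  errs <- vapply(1:20, function(i) {
    ts <- generate_logistic_series(4000, 1.2, 7, days = 0:14,
                                   noise_sd = 200, rng_seed = 100 + i)
    fit <- fit_logistic(ts)
    if (!fit$converged) return(NA_real_)
    abs(fit$t0 - t0_true)
  }, numeric(1))
  expect_true(all(is.finite(errs)))
  expect_lt(median(errs), 0.5)
})

test_that("exponential fitting is exact on analytic densities", {
  # binned mass of Exponential(100) has ln density linear in the bin centre
  bw <- 25; lo <- 62.5
  edges <- seq(lo, 500, by = bw)
  centers <- edges[-length(edges)] + bw / 2
  dens <- (pexp(edges[-1], 1 / 100) - pexp(edges[-length(edges)], 1 / 100)) / bw
  fit <- fit_exponential_from_density(centers, dens)
  expect_equal(fit$slope, -0.01, tolerance = 1e-12)
  expect_equal(fit$l_star_um, 100, tolerance = 1e-9)
  expect_true(fit$valid)

  # a positive slope is flagged invalid, not an error
  bad <- fit_exponential_from_density(centers, rev(dens))
  expect_false(bad$valid)
  expect_true(is.na(bad$l_star_um))
})

test_that("exponential fitting recovers the scale from seeded draws", {
  set.seed(123)
  x <- rexp(1000, 1 / 100)
  fit <- fit_exponential_pdf(x, bin_width_um = 25, min_length_um = 62.5)
  expect_true(fit$valid)
  expect_lt(abs(fit$l_star_um - 100), 3 * fit$se_l_star_um)
  expect_equal(fit$slope, -1 / fit$l_star_um, tolerance = 1e-12)

  # density normalization: duplicating every sample changes nothing
  fit2 <- fit_exponential_pdf(c(x, x), bin_width_um = 25, min_length_um = 62.5)
  expect_equal(fit2$l_star_um, fit$l_star_um, tolerance = 1e-12)

  expect_error(fit_exponential_pdf(rep(100, 50)), "non-empty bins")
  expect_error(fit_exponential_pdf(rexp(10, 1 / 100)), "at least 30")
})
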