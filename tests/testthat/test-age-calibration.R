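make_cores <- function(gamma, sigma, depths = seq(2, 30, by = 2),
                       n_cores = 3, seed = 1) {
  set.seed(seed)
  purrr::map_dfr(seq_len(n_cores), function(k) {
    mu <- gamma[1] + gamma[2] * depths + gamma[3] * depths^2
    tibble::tibble(core_id = paste0("c", k), depth_cm = depths,
                   age_years = pmax(mu + stats::rnorm(length(depths), 0,
                                                      sigma), 0))
  })
}

test_that("noiseless quadratic data are recovered to numerical precision", {
  cores <- make_cores(c(5, 4, 0.1), sigma = 0)
  cal <- fit_age_calibration(cores, n_draws = 500, seed = 1)
  expect_equal(cal$gamma0, 5, tolerance = 1e-6)
  expect_equal(cal$gamma1, 4, tolerance = 1e-6)
  expect_equal(cal$gamma2, 0.1, tolerance = 1e-6)
  expect_lt(cal$sigma_eps, 1e-6)
  # degenerate calibration gives a degenerate age distribution
  ad <- age_distribution(cal, 10)
  expect_equal(ad$mean, 5 + 40 + 10, tolerance = 1e-6)
  expect_lt(ad$sd, 1e-6)
})

test_that("age constant over depth concentrates the slopes at zero", {
  cores <- make_cores(c(50, 0, 0), sigma = 0.5, seed = 3)
  cal <- suppressWarnings(fit_age_calibration(cores, n_draws = 2000, seed = 3))
  q1 <- stats::quantile(cal$posterior_draws$gamma1, c(0.025, 0.975))
  q2 <- stats::quantile(cal$posterior_draws$gamma2, c(0.025, 0.975))
  expect_true(q1[1] < 0 && q1[2] > 0)
  expect_true(q2[1] < 0 && q2[2] > 0)
})

test_that("too few distinct depths is an error", {
  cores <- tibble::tibble(core_id = "c1", depth_cm = c(1, 1, 2),
                          age_years = c(2, 3, 6))
  expect_error(fit_age_calibration(cores, n_draws = 200), "distinct depths")
})

test_that("age distribution mean matches a brute-force sampling oracle", {
  cores <- make_cores(c(0, 4.5, 0.04), sigma = 6, seed = 7)
  cal <- suppressWarnings(fit_age_calibration(cores, n_draws = 2000, seed = 7))
  ad <- age_distribution(cal, 20)
  draws <- ad$sample(2e5, seed = 8)
  expect_equal(ad$mean, mean(draws), tolerance = 0.01)
  expect_equal(ad$sd, stats::sd(draws), tolerance = 0.05)
  # quantile function inverts the CDF
  for (p in c(0.1, 0.5, 0.9)) {
    expect_equal(ad$cdf(ad$quantile(p)), p, tolerance = 1e-6)
    expect_equal(unname(stats::quantile(draws, p)), ad$quantile(p),
                 tolerance = 0.02)
  }
})

test_that("truncation at zero follows the truncated-normal median", {
  # single draw (0, 1, 0) with unit residual SD at depth 0: ages are
  # |N(0,1)|-like (normal truncated at 0), median = qnorm(0.75)
  cal <- calibration_from_truth(c(0, 1, 0), sigma_eps = 1, depth_grid = 0:10)
  ad <- age_distribution(cal, 0)
  expect_equal(ad$quantile(0.5), stats::qnorm(0.75), tolerance = 1e-6)
  # and a point-mass posterior at positive depth is the quadratic value
  cal0 <- calibration_from_truth(c(0, 1, 0), sigma_eps = 0, depth_grid = 0:10)
  ad0 <- age_distribution(cal0, 20)
  expect_equal(ad0$mean, 20)
  expect_equal(ad0$quantile(0.5), 20)
})

test_that("standardization is a numerical involution around the center", {
  cal <- tiny_cal()
  expect_equal(standardize_age(cal, cal$age_center), 0)
  expect_equal(standardize_age(cal, cal$age_center + cal$age_scale), 1)
  x <- c(-3.2, 0, 11, 250)
  expect_equal(destandardize_age(cal, standardize_age(cal, x)), x)
})

test_that("posterior predictive intervals widen relative to fixed coefficients", {
  cores <- make_cores(c(0, 4.5, 0.04), sigma = 6, seed = 9)
  cal <- suppressWarnings(fit_age_calibration(cores, n_draws = 2000, seed = 9))
  for (d in c(5, 15, 25)) {
    full <- age_distribution(cal, d)
    width_full <- full$quantile(0.975) - full$quantile(0.025)
    fixed <- calibration_from_truth(
      c(cal$gamma0, cal$gamma1, cal$gamma2), cal$sigma_eps, 0:30)
    adf <- age_distribution(fixed, d)
    width_fixed <- adf$quantile(0.975) - adf$quantile(0.025)
    expect_gte(width_full, width_fixed - 1e-6)
  }
})

test_that("predicted mean age is monotone in depth for non-negative slopes", {
  cal <- calibration_from_truth(c(2, 3, 0.02), sigma_eps = 4,
                                depth_grid = 0:40)
  means <- vapply(seq(0, 40, by = 2),
                  function(d) age_distribution(cal, d)$mean, numeric(1))
  expect_true(all(diff(means) >= 0))
})
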