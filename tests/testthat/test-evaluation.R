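test_that("WAIC matches the hand-computed two-draw case", {
  ll <- matrix(c(log(0.5), log(0.25)), nrow = 2, ncol = 1)
  w <- waic(ll)
  lppd <- log(0.375)
  p <- stats::var(c(log(0.5), log(0.25))) # (log 2)^2 / 2
  expect_equal(p, (log(2))^2 / 2)
  expect_equal(w$elpd_waic, lppd - p)
  expect_equal(w$p_waic, p)

  expect_error(waic(matrix(0, 1, 3)), "at least 2 draws")
})

test_that("identical draws collapse both criteria to the plain log-likelihood", {
  ll_row <- log(c(0.2, 0.5, 0.9, 0.04))
  ll <- matrix(ll_row, nrow = 50, ncol = 4, byrow = TRUE)
  w <- waic(ll)
  expect_equal(w$p_waic, 0)
  expect_equal(w$elpd_waic, sum(ll_row))
  l <- psis_loo(ll)
  expect_equal(l$elpd_loo, sum(ll_row), tolerance = 1e-10)
  expect_true(all(l$pointwise$pareto_k < 0.7))
})

test_that("criteria are equivariant under constant shifts (translation property)", {
  set.seed(1)
  ll <- matrix(stats::rnorm(200 * 7, -2, 0.7), 200, 7)
  c0 <- 1.37
  w0 <- waic(ll); w1 <- waic(ll + c0)
  expect_equal(w1$elpd_waic, w0$elpd_waic + 7 * c0, tolerance = 1e-10)
  expect_equal(w1$p_waic, w0$p_waic, tolerance = 1e-10)
  l0 <- psis_loo(ll); l1 <- psis_loo(ll + c0)
  expect_equal(l1$elpd_loo, l0$elpd_loo + 7 * c0, tolerance = 1e-10)
})

test_that("LOO penalizes at least as much as the in-sample density", {
  set.seed(2)
  ll <- matrix(stats::rnorm(400 * 10, -3, 1), 400, 10)
  l <- psis_loo(ll)
  lppd_i <- apply(ll, 2, function(v) {
    m <- max(v); m + log(mean(exp(v - m)))
  })
  expect_true(all(l$pointwise$elpd_loo <= lppd_i + 1e-10))
})

test_that("the Pareto tail fit recovers a known shape parameter", {
  set.seed(3)
  xi_true <- 0.25; sigma_true <- 1
  u <- stats::runif(4000)
  z <- sigma_true / xi_true * ((1 - u)^(-xi_true) - 1)
  fit <- marshseed:::gpd_fit_pwm(z)
  expect_equal(fit$xi, xi_true, tolerance = 0.1)
  expect_equal(fit$sigma, sigma_true, tolerance = 0.1)
  # and the exponential special case
  z0 <- stats::rexp(4000)
  expect_lt(abs(marshseed:::gpd_fit_pwm(z0)$xi), 0.1)
})

test_that("WAIC and PSIS-LOO agree on a well-behaved fit", {
  fit <- small_bb_fit()$fit
  w <- waic(fit); l <- psis_loo(fit)
  diff_i <- (w$pointwise$elpd_waic - l$pointwise$elpd_loo)
  tol <- max(1, stats::sd(diff_i) * sqrt(length(diff_i)))
  expect_lt(abs(w$elpd_waic - l$elpd_loo), 2 * tol)
  expect_lt(mean(l$pointwise$pareto_k > 0.7), 0.1)
})

test_that("comparing a fit with itself gives a zero difference", {
  fit <- small_bb_fit()$fit
  cmp <- compare_models(list(m_a = fit, m_b = fit))
  expect_equal(cmp$pairwise$elpd_diff, c(0, 0))
  expect_equal(cmp$pairwise$se_diff, c(0, 0))
  expect_true(all(cmp$table$tied_with_best))
})

test_that("replicates reproduce degenerate posteriors exactly", {
  trials <- dplyr::bind_rows(
    ref_trial_row("a", 12L, 3L, depth_cm = 5),
    ref_trial_row("b", 7L, 0L, depth_cm = 9, provenance = "LocB")
  )
  cal <- tiny_cal()

  sure <- fake_fit(trials, germ_model_spec("BIN",
                                           use_errors_in_variables = FALSE),
                   cal, list(beta0 = rep(50, 250)))
  y <- posterior_replicates(sure, seed = 1)
  expect_true(all(y == matrix(c(12L, 7L), 250, 2, byrow = TRUE)))

  zi <- fake_fit(trials, germ_model_spec("ZIB",
                                         use_errors_in_variables = FALSE),
                 cal, list(beta0 = rep(0, 250), alpha0 = rep(50, 250)))
  expect_true(all(posterior_replicates(zi, seed = 1) == 0))
})

test_that("replicate means match the analytic expectation at a fixed draw", {
  trials <- dplyr::bind_rows(
    ref_trial_row("a", 30L, 3L, depth_cm = 5),
    ref_trial_row("b", 90L, 0L, depth_cm = 5, provenance = "LocB")
  )
  cal <- calibration_from_truth(c(0, 1, 0), 0, rep(5, 2))
  p0 <- 0.3
  f <- fake_fit(trials, germ_model_spec("BIN",
                                        use_errors_in_variables = FALSE),
                cal, list(beta0 = rep(stats::qlogis(p0), 1000)))
  y <- posterior_replicates(f, seed = 2)
  means <- rowMeans(y)
  exp_mean <- mean(c(30, 90) * p0)
  mcse <- stats::sd(means) / sqrt(length(means))
  expect_lt(abs(mean(means) - exp_mean), 3 * mcse + 1e-9)
})

test_that("PPC covers a dataset drawn from the replicate distribution itself", {
  fit <- small_bb_fit()$fit
  reps <- posterior_replicates(fit, seed = 3, cap = 400)
  res <- ppc(reps[-5, , drop = FALSE], reps[5, ])
  expect_s3_class(res, "germ_ppc")
  expect_true(all(res$covered))
  expect_true(all(res$lower95 <= res$upper95))
  # observed values computed by the same statistic code path
  expect_equal(res$observed[res$statistic == "n_zero_groups"],
               sum(reps[5, ] == 0))
})

test_that("split R-hat behaves on iid, divergent and permuted chains", {
  set.seed(4)
  n <- 2000
  draws <- matrix(stats::rnorm(2 * n), ncol = 1)
  id <- rep(1:2, each = n)
  conv <- convergence(draws, chain_id = id)
  expect_gte(conv$rhat, 1)
  expect_lt(conv$rhat, 1.01)
  expect_gt(conv$ess_bulk, n / 2)

  # chains stuck at different constants: divergence reported as huge
  const <- matrix(c(rep(0, 100), rep(5, 100)), ncol = 1)
  expect_gt(convergence(const, chain_id = rep(1:2, each = 100))$rhat, 2)

  # permuting within each half-chain leaves split R-hat unchanged
  x <- stats::rnorm(2 * n)
  base <- convergence(matrix(x, ncol = 1), chain_id = id)
  perm <- x
  set.seed(5)
  for (blk in list(1:(n / 2), (n / 2 + 1):n, n + 1:(n / 2),
                   (n + n / 2 + 1):(2 * n))) {
    perm[blk] <- sample(perm[blk])
  }
  permuted <- convergence(matrix(perm, ncol = 1), chain_id = id)
  expect_equal(permuted$rhat, base$rhat)

  expect_error(convergence(draws, chain_id = rep(1, 2 * n)), "2 chains")
})
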