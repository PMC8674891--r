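point_mass_fit <- function(draws_list, n_draws = 400) {
  trials <- dplyr::bind_rows(
    ref_trial_row("a", 10L, 2L, depth_cm = 5),
    ref_trial_row("b", 10L, 1L, depth_cm = 9, provenance = "LocB")
  )
  cal <- calibration_from_truth(c(0, 10, 0), 0, seq(1, 29, 2))
  expanded <- lapply(draws_list, function(v) rep(v, n_draws))
  fake_fit(trials, germ_model_spec("BB", use_errors_in_variables = FALSE),
           cal, expanded)
}

test_that("an all-zero posterior predicts one half with a collapsed interval", {
  f <- point_mass_fit(list(beta0 = 0))
  pr <- predict_probability(f, list(std_age = 0, provenance = "none"))
  expect_equal(pr$median, 0.5)
  expect_equal(pr$lower95, 0.5)
  expect_equal(pr$upper95, 0.5)
})

test_that("point-mass posteriors reproduce inverse-logit closed forms", {
  f <- point_mass_fit(list(beta0 = 0, beta_age = -1))
  p0 <- predict_probability(f, list(std_age = 0, provenance = "none"))
  p1 <- predict_probability(f, list(std_age = 1, provenance = "none"))
  expect_equal(p0$median, 0.5)
  expect_equal(p1$median, stats::plogis(-1), tolerance = 1e-12)

  # ages in years route through the calibration standardization
  age <- destandardize_age(f$cal, 1)
  p1b <- predict_probability(f, list(age_years = age, provenance = "none"))
  expect_equal(p1b$median, stats::plogis(-1))

  expect_error(predict_probability(f, list(media = "volcanic_ash")),
               "unknown media level")
})

test_that("treatment marginal effects are hand-checkable at a point mass", {
  dlt <- -2
  f <- point_mass_fit(list(beta0 = 0.5, `beta[media:sand]` = dlt))
  at_level <- marginal_treatment_effect(f, "media", "sand",
                                        list(provenance = "none",
                                             age_years = f$cal$age_center))
  at_ref <- marginal_treatment_effect(f, "media", "sand_soil",
                                      list(provenance = "none",
                                           age_years = f$cal$age_center))
  expect_equal(at_level$median, stats::plogis(0.5 + dlt))
  expect_equal(at_ref$median, stats::plogis(0.5))
  # reference level equals the plain reference prediction
  plain <- predict_probability(f, list(provenance = "none",
                                       age_years = f$cal$age_center))
  expect_equal(at_ref$median, plain$median)
})

test_that("HPD intervals: point mass collapses, symmetric matches equal tails", {
  expect_equal(unname(hpd_interval(rep(3.2, 100), 0.9)), c(3.2, 3.2))
  set.seed(6)
  x <- stats::rnorm(20000)
  h <- hpd_interval(x, 0.95)
  q <- stats::quantile(x, c(0.025, 0.975), names = FALSE)
  expect_equal(unname(h), q, tolerance = 0.05)
  expect_lte(diff(unname(h)), diff(q) + 1e-12)
})

test_that("provenance deviations report ordered HPD intervals and shrinkage", {
  res <- small_bb_fit()
  pd <- provenance_deviations(res$fit)
  expect_true(all(pd$hpd95_lower <= pd$hpd90_lower))
  expect_true(all(pd$hpd90_upper <= pd$hpd95_upper))
  expect_true(all(pd$hpd90_lower <= pd$median & pd$median <= pd$hpd90_upper))

  # hierarchical shrinkage: posterior means are closer to zero on
  # average than raw per-location log-odds deviations
  tr <- res$sim$trials
  emp <- tr |>
    dplyr::group_by(.data$provenance) |>
    dplyr::summarise(lo = stats::qlogis((sum(.data$n_germinated) + 0.5) /
                                          (sum(.data$n_planted) + 1)),
                     .groups = "drop")
  emp_dev <- emp$lo - mean(emp$lo)
  expect_lt(mean(abs(pd$mean)), mean(abs(emp_dev)))
})

test_that("probability-scale location differences summarize correctly", {
  f <- point_mass_fit(list(beta0 = 0, `u[LocA]` = 1, `u[LocB]` = -1))
  d <- provenance_difference(f, "LocA", "LocB",
                             list(age_years = f$cal$age_center))
  expect_equal(d$median, stats::plogis(1) - stats::plogis(-1))
  expect_equal(d$lower95, d$upper95)
})

test_that("decay curves are monotone under an all-negative age slope", {
  f <- point_mass_fit(list(beta0 = 1, beta_age = -1.5))
  curve <- decay_curve(f, ages = seq(0, 200, by = 20),
                       weighting = "reference")
  expect_true(all(diff(curve$median) < 0))
  expect_true(all(curve$lower95 <= curve$median &
                    curve$median <= curve$upper95))
  expect_true(all(curve$lower95 >= 0 & curve$upper95 <= 1))

  weighted <- decay_curve(f, ages = seq(0, 200, by = 20),
                          weighting = "planted")
  expect_true(all(diff(weighted$median) < 0))
})
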