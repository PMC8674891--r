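validate_tetrazolium <- function(records) {
  stopifnot(all(c("trial_id", "depth_cm", "n_tested", "n_viable")
                %in% names(records)))
  if (any(records$n_viable < 0 | records$n_viable > records$n_tested)) {
    stop("n_viable must satisfy 0 <= n_viable <= n_tested", call. = FALSE)
  }
  if (any(records$n_tested < 1) || any(records$depth_cm < 0)) {
    stop("n_tested must be >= 1 and depth_cm non-negative", call. = FALSE)
  }
  tibble::as_tibble(records)
}

#' Binomial regression of residual seed viability on burial depth
#'
#' Tetrazolium staining gives a direct viability readout for seeds that
#' failed to germinate; regressing the viable fraction on depth asks
#' whether that residual viability decays down the profile. Fits a
#' maximum-likelihood logistic regression (`glm`, binomial family) of
#' viable/tested counts on depth and attaches a delta-method 95% Wald
#' confidence band on the probability scale. Depth, not calibrated age,
#' is the regressor by default; pass an [age_calibration] to regress on
#' mean predicted age instead.
#'
#' Complete separation (some depth threshold splitting viable from
#' inviable perfectly) is detected from exploding coefficients; the fit
#' is then flagged and refitted with a light data-augmentation penalty
#' (half a success and half a failure added at the extreme depths), which
#' keeps the estimate finite.
#'
#' @param records Data frame with `trial_id`, `depth_cm`, `n_tested`,
#'   `n_viable`.
#' @param cal Optional [age_calibration]; when supplied the regressor is
#'   the calibration's mean age at each record's depth (per 100 years,
#'   labelled in the output).
#' @return Object of class `viability_fit`: `coef` (intercept, slope),
#'   `vcov`, `regressor`, `separation` flag, `records`, and
#'   `curve(depths)` returning fitted probabilities with the 95% band.
#' @export
fit_viability_glm <- function(records, cal = NULL) {
  records <- validate_tetrazolium(records)
  if (length(unique(records$depth_cm)) < 2) {
    stop("need at least 2 distinct depths", call. = FALSE)
  }
  x <- records$depth_cm
  regressor <- "depth_cm"
  if (!is.null(cal)) {
    x <- quad_age(c(cal$gamma0, cal$gamma1, cal$gamma2), records$depth_cm)
    regressor <- "age_years"
  }
  dat <- data.frame(x = x, v = records$n_viable,
                    f = records$n_tested - records$n_viable)
  fit <- suppressWarnings(
    stats::glm(cbind(v, f) ~ x, family = stats::binomial(), data = dat)
  )
  separation <- !fit$converged || any(abs(stats::coef(fit)) > 15)
  if (separation) {
    aug <- rbind(dat,
                 data.frame(x = range(dat$x), v = 0.5, f = 0.5))
    fit <- suppressWarnings(
      stats::glm(cbind(v, f) ~ x, family = stats::binomial(), data = aug)
    )
  }
  cf <- stats::coef(fit)
  vc <- stats::vcov(fit)

  curve <- function(xnew) {
    eta <- cf[1] + cf[2] * xnew
    se <- sqrt(vc[1, 1] + 2 * xnew * vc[1, 2] + xnew^2 * vc[2, 2])
    tibble::tibble(
      x = xnew,
      probability = stats::plogis(eta),
      lower95 = stats::plogis(eta - 1.96 * se),
      upper95 = stats::plogis(eta + 1.96 * se)
    )
  }

  structure(list(
    coef = stats::setNames(as.numeric(cf), c("intercept", "slope")),
    vcov = vc, regressor = regressor, separation = separation,
    glm = fit, records = records, curve = curve,
    null_deviance = fit$null.deviance, deviance = fit$deviance
  ), class = "viability_fit")
}

#' @export
print.viability_fit <- function(x, ...) {
  se <- sqrt(diag(x$vcov))
  cat("<viability_fit> logit(p_viable) = ",
      format(x$coef[1], digits = 3), " + ",
      format(x$coef[2], digits = 3), " * ", x$regressor,
      "  (slope SE ", format(se[2], digits = 3), ")",
      if (x$separation) "  [separation: penalized refit]", "\n", sep = "")
  invisible(x)
}

#' Pooled viable fraction with an exact binomial interval
#'
#' Pools all tetrazolium records and reports the overall viable
#' proportion with a Clopper-Pearson 95% interval.
#'
#' @param records Data frame as in [fit_viability_glm()].
#' @return One-row tibble: `n_viable`, `n_tested`, `proportion`,
#'   `lower95`, `upper95`.
#' @export
overall_viable_fraction <- function(records) {
  records <- validate_tetrazolium(records)
  v <- sum(records$n_viable); n <- sum(records$n_tested)
  bt <- stats::binom.test(v, n)
  tibble::tibble(
    n_viable = v, n_tested = n, proportion = v / n,
    lower95 = bt$conf.int[1], upper95 = bt$conf.int[2]
  )
}
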