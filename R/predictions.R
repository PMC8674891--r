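#' Shortest-interval highest-posterior-density interval
#'
#' The narrowest contiguous interval of sorted draws containing the
#' requested posterior mass.
#'
#' @param x Numeric draws.
#' @param prob Mass to cover (e.g. 0.95).
#' @return Named numeric `c(lower, upper)`.
#' @export
hpd_interval <- function(x, prob = 0.95) {
  stopifnot(prob > 0, prob <= 1)
  x <- sort(x)
  n <- length(x)
  m <- max(1, ceiling(prob * n))
  if (m >= n) return(c(lower = x[1], upper = x[n]))
  widths <- x[(m + 1):n] - x[1:(n - m)]
  i <- which.min(widths)
  c(lower = x[i], upper = x[i + m])
}

# Per-draw u contribution for a provenance setting. "population"
# integrates over the random-intercept distribution with a seeded draw
# per posterior sample; a location label uses its posterior; "none" is 0.
u_term_draws <- function(fit, provenance, seed = 1) {
  d <- fit$draws
  if (identical(provenance, "none")) return(numeric(nrow(d)))
  if (identical(provenance, "population")) {
    set.seed(seed)
    return(stats::rnorm(nrow(d), 0, d[, "sigma_loc"]))
  }
  col <- paste0("u[", provenance, "]")
  if (!col %in% colnames(d)) {
    stop("unknown provenance: ", provenance, call. = FALSE)
  }
  d[, col]
}

profile_eta_draws <- function(fit, profile, seed = 1) {
  d <- fit$draws
  lv <- trial_levels()
  ref <- fit$spec$reference_levels
  cal <- fit$cal

  age <- profile$age_years
  if (is.null(age) && !is.null(profile$depth_cm)) {
    age <- quad_age(c(cal$gamma0, cal$gamma1, cal$gamma2), profile$depth_cm)
  }
  xs <- profile$std_age %||% standardize_age(cal, age %||% 0)

  eta <- d[, "beta0"] + d[, "beta_age"] * xs
  for (f in names(lv)) {
    level <- profile[[f]] %||% ref[[f]]
    if (!level %in% lv[[f]]) {
      stop("unknown ", f, " level: ", level, call. = FALSE)
    }
    if (level != ref[[f]]) {
      col <- paste0("beta[", f, ":", level, "]")
      eta <- eta + d[, col]
    }
  }
  prov <- profile$provenance %||% "population"
  if (length(fit$design$provenance_levels) > 1) {
    eta <- eta + u_term_draws(fit, prov, seed = seed)
  }
  eta
}

#' Posterior predicted germination probability at a covariate profile
#'
#' Inverse-logit of the linear predictor at the requested profile,
#' evaluated draw by draw and summarized by the median and equal-tailed
#' 95% interval. Age may be given in years (`age_years`), as a depth
#' (`depth_cm`, converted through the calibration quadratic), or directly
#' on the standardized scale (`std_age`); unspecified treatments sit at
#' their reference levels; `provenance` is a location label,
#' `"population"` (integrate over the random-intercept distribution) or
#' `"none"` (the global intercept).
#'
#' @param fit A [fit_germination()] object.
#' @param profile Named list of covariate settings.
#' @param seed Seed for the population-provenance integration.
#' @return One-row tibble of class `germ_prediction` with `median`,
#'   `lower95`, `upper95` and the profile settings; posterior draws kept
#'   in a list column.
#' @export
predict_probability <- function(fit, profile = list(), seed = 1) {
  p <- stats::plogis(profile_eta_draws(fit, profile, seed = seed))
  q <- stats::quantile(p, c(0.025, 0.5, 0.975), names = FALSE)
  ref <- fit$spec$reference_levels
  tibble::tibble(
    age_years = profile$age_years %||% NA_real_,
    depth_cm = profile$depth_cm %||% NA_real_,
    temperature = profile$temperature %||% ref[["temperature"]],
    media = profile$media %||% ref[["media"]],
    pretreated = profile$pretreated %||% ref[["pretreated"]],
    photoperiod = profile$photoperiod %||% ref[["photoperiod"]],
    provenance = profile$provenance %||% "population",
    median = q[2], lower95 = q[1], upper95 = q[3],
    draws = list(p)
  ) |>
    structure(class = c("germ_prediction", "tbl_df", "tbl", "data.frame"))
}

#' Marginal effect of one treatment level at reference conditions
#'
#' Predicted germination probability for modern (age 0) seeds with all
#' covariates at the reference profile except the stated treatment level,
#' i.e. the marginal treatment comparison of the fitted model.
#'
#' @param fit A [fit_germination()] object.
#' @param treatment One of `"temperature"`, `"media"`, `"pretreated"`,
#'   `"photoperiod"`.
#' @param level A declared level of that treatment.
#' @param reference_profile Base profile (default: reference levels, age
#'   0, population provenance).
#' @param seed Passed to [predict_probability()].
#' @return A `germ_prediction` row.
#' @export
marginal_treatment_effect <- function(fit, treatment, level,
                                      reference_profile = list(), seed = 1) {
  stopifnot(treatment %in% names(trial_levels()))
  profile <- reference_profile
  profile$age_years <- profile$age_years %||% 0
  profile[[treatment]] <- level
  predict_probability(fit, profile, seed = seed)
}

#' Posterior summaries of the provenance random intercepts
#'
#' Per-location posterior of the deviation from the global intercept
#' (logit scale), with 90% and 95% highest-posterior-density intervals
#' (shortest-interval method). Under the hierarchical prior these
#' deviations are shrunk toward zero relative to the raw per-location
#' log-odds.
#'
#' @param fit A [fit_germination()] object with more than one provenance.
#' @return Tibble of class `germ_provenance`: one row per location with
#'   posterior mean, median, and HPD bounds.
#' @export
provenance_deviations <- function(fit) {
  locs <- fit$design$provenance_levels
  if (length(locs) < 2) {
    stop("fit has no provenance random intercepts", call. = FALSE)
  }
  purrr::map_dfr(locs, function(l) {
    x <- fit$draws[, paste0("u[", l, "]")]
    h90 <- hpd_interval(x, 0.90)
    h95 <- hpd_interval(x, 0.95)
    tibble::tibble(
      provenance = l, mean = mean(x), median = stats::median(x),
      hpd90_lower = h90[["lower"]], hpd90_upper = h90[["upper"]],
      hpd95_lower = h95[["lower"]], hpd95_upper = h95[["upper"]]
    )
  }) |>
    structure(class = c("germ_provenance", "tbl_df", "tbl", "data.frame"))
}

#' Probability-scale difference between two provenances at a profile
#'
#' Per-draw difference in predicted germination probability between two
#' locations at an otherwise common covariate profile, summarized by the
#' median and equal-tailed 95% interval.
#'
#' @param fit A [fit_germination()] object.
#' @param provenance_a,provenance_b Location labels.
#' @param profile Shared covariate profile (default: modern seeds at
#'   reference conditions).
#' @return One-row tibble with `median`, `lower95`, `upper95`.
#' @export
provenance_difference <- function(fit, provenance_a, provenance_b,
                                  profile = list(age_years = 0)) {
  pa <- profile; pa$provenance <- provenance_a
  pb <- profile; pb$provenance <- provenance_b
  da <- stats::plogis(profile_eta_draws(fit, pa))
  db <- stats::plogis(profile_eta_draws(fit, pb))
  q <- stats::quantile(da - db, c(0.025, 0.5, 0.975), names = FALSE)
  tibble::tibble(provenance_a = provenance_a, provenance_b = provenance_b,
                 median = q[2], lower95 = q[1], upper95 = q[3])
}

#' Germination decay curve over seed age
#'
#' Predicted germination probability as a function of seed age, either at
#' the reference profile or averaged over the germination-trial
#' conditions present in the fitted data with weights proportional to the
#' number of seeds planted under each condition (so heavily used
#' conditions dominate, mirroring a planted-seed-weighted average).
#'
#' @param fit A [fit_germination()] object.
#' @param ages Age grid in years (default: 0 to the calibration's mean
#'   age at its deepest dated depth, 41 points).
#' @param weighting `"planted"` (seeds-planted-weighted average over
#'   observed conditions) or `"reference"` (reference profile,
#'   population provenance).
#' @param max_draws Cap on posterior draws used (evenly thinned).
#' @return Tibble of class `germ_decay` with `age_years`, `median`,
#'   `lower95`, `upper95`.
#' @export
decay_curve <- function(fit, ages = NULL,
                        weighting = c("planted", "reference"),
                        max_draws = 2000) {
  weighting <- match.arg(weighting)
  cal <- fit$cal
  if (is.null(ages)) {
    top <- quad_age(c(cal$gamma0, cal$gamma1, cal$gamma2),
                    max(cal$depth_range))
    ages <- seq(0, top, length.out = 41)
  }
  d <- fit$draws
  idx <- seq_len(nrow(d))
  if (nrow(d) > max_draws) idx <- round(seq(1, nrow(d), length.out = max_draws))
  d <- d[idx, , drop = FALSE]

  if (weighting == "reference") {
    out <- purrr::map_dfr(ages, function(a) {
      xs <- standardize_age(cal, a)
      eta <- d[, "beta0"] + d[, "beta_age"] * xs
      if ("sigma_loc" %in% colnames(d)) {
        set.seed(1)
        eta <- eta + stats::rnorm(nrow(d), 0, d[, "sigma_loc"])
      }
      q <- stats::quantile(stats::plogis(eta), c(0.025, 0.5, 0.975),
                           names = FALSE)
      tibble::tibble(age_years = a, median = q[2],
                     lower95 = q[1], upper95 = q[3])
    })
  } else {
    design <- fit$design
    bt <- d[, paste0("beta[", colnames(design$X), "]"), drop = FALSE]
    base <- d[, "beta0"] + bt %*% t(design$X)
    if (length(design$provenance_levels) > 1) {
      u <- d[, paste0("u[", design$provenance_levels, "]"), drop = FALSE]
      base <- base + u[, design$provenance_index, drop = FALSE]
    }
    w <- design$n_planted / sum(design$n_planted)
    out <- purrr::map_dfr(ages, function(a) {
      xs <- standardize_age(cal, a)
      pbar <- drop(stats::plogis(base + d[, "beta_age"] * xs) %*% w)
      q <- stats::quantile(pbar, c(0.025, 0.5, 0.975), names = FALSE)
      tibble::tibble(age_years = a, median = q[2],
                     lower95 = q[1], upper95 = q[3])
    })
  }
  structure(out, class = c("germ_decay", class(out)),
            weighting = weighting)
}
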