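#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @method tidy age_calibration
#' @export
tidy.age_calibration <- function(x, ...) {
  d <- x$posterior_draws
  purrr::map_dfr(names(d), function(nm) {
    v <- d[[nm]]
    q <- stats::quantile(v, c(0.025, 0.975), names = FALSE)
    tibble::tibble(term = nm, estimate = mean(v), std.error = stats::sd(v),
                   conf.low = q[1], conf.high = q[2])
  })
}

#' @method glance age_calibration
#' @export
glance.age_calibration <- function(x, ...) {
  tibble::tibble(
    n_obs = x$n_obs, n_draws = nrow(x$posterior_draws),
    sigma_eps = x$sigma_eps,
    age_center = x$age_center, age_scale = x$age_scale,
    min_depth = x$depth_range[1], max_depth = x$depth_range[2]
  )
}

#' Posterior summaries of a fitted germination model
#'
#' One row per parameter: posterior mean, SD, equal-tailed 95% interval,
#' split R-hat and bulk ESS. Latent ages are included; filter them out
#' with `latent = FALSE`.
#'
#' @param x A `germ_fit`.
#' @param latent Include `x_latent[...]` rows?
#' @param ... Unused.
#' @return A tibble.
#' @method tidy germ_fit
#' @export
tidy.germ_fit <- function(x, latent = TRUE, ...) {
  out <- purrr::map_dfr(colnames(x$draws), function(nm) {
    v <- x$draws[, nm]
    q <- stats::quantile(v, c(0.025, 0.975), names = FALSE)
    tibble::tibble(term = nm, estimate = mean(v), std.error = stats::sd(v),
                   conf.low = q[1], conf.high = q[2])
  })
  out <- dplyr::left_join(out,
    dplyr::rename(x$diagnostics, term = "parameter"), by = "term")
  if (!latent) out <- dplyr::filter(out, !grepl("^x_latent", .data$term))
  out
}

#' @method glance germ_fit
#' @export
glance.germ_fit <- function(x, ...) {
  core <- !grepl("^x_latent", x$diagnostics$parameter)
  w <- waic(x)
  tibble::tibble(
    family = x$spec$family,
    n_groups = length(x$design$y),
    n_draws = nrow(x$draws),
    chains = x$sampler_config$chains,
    elpd_waic = w$elpd_waic, p_waic = w$p_waic,
    max_rhat = max(x$diagnostics$rhat[core], na.rm = TRUE),
    min_ess_bulk = min(x$diagnostics$ess_bulk[core], na.rm = TRUE),
    flagged = x$flagged
  )
}

#' @method tidy germ_compare
#' @export
tidy.germ_compare <- function(x, ...) x$table

#' @method glance germ_compare
#' @export
glance.germ_compare <- function(x, ...) {
  tibble::tibble(preferred = x$preferred,
                 best_elpd_loo = max(x$table$elpd_loo),
                 n_models = nrow(x$table))
}

#' @method tidy viability_fit
#' @export
tidy.viability_fit <- function(x, ...) {
  se <- sqrt(diag(x$vcov))
  tibble::tibble(
    term = c("intercept", x$regressor),
    estimate = as.numeric(x$coef),
    std.error = as.numeric(se),
    statistic = as.numeric(x$coef / se),
    p.value = 2 * stats::pnorm(-abs(as.numeric(x$coef / se)))
  )
}

#' @method glance viability_fit
#' @export
glance.viability_fit <- function(x, ...) {
  tibble::tibble(
    null_deviance = x$null_deviance, deviance = x$deviance,
    n_records = nrow(x$records),
    n_tested = sum(x$records$n_tested),
    separation = x$separation
  )
}
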