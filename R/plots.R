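#' Plot posterior predictive check distributions
#'
#' One panel per summary statistic: the replicate distribution with the
#' observed value as a dashed line; a model that could plausibly generate
#' the data has every dashed line inside its distribution.
#'
#' @param object A [ppc()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot germ_ppc
#' @export
autoplot.germ_ppc <- function(object, ...) {
  long <- tidyr::unnest(
    dplyr::select(object, "statistic", "observed", "replicate_values"),
    "replicate_values")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$replicate_values)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey60") +
    ggplot2::geom_vline(ggplot2::aes(xintercept = .data$observed),
                        linetype = "dashed") +
    ggplot2::facet_wrap(~statistic, scales = "free") +
    ggplot2::labs(x = "replicate statistic", y = "count")
}

#' Plot the germination decay curve
#'
#' @param object A [decay_curve()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot germ_decay
#' @export
autoplot.germ_decay <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$age_years, y = .data$median)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower95,
                                      ymax = .data$upper95),
                         alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "seed age (years)",
                  y = "P(germination)",
                  title = paste0("Germination decay (",
                                 attr(object, "weighting"),
                                 "-weighted)"))
}

#' Plot provenance random-intercept deviations
#'
#' Points at the posterior mean with thick 90% and thin 95% HPD bars,
#' ordered by effect size.
#'
#' @param object A [provenance_deviations()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot germ_provenance
#' @export
autoplot.germ_provenance <- function(object, ...) {
  object <- dplyr::mutate(object,
    provenance = stats::reorder(.data$provenance, .data$mean))
  ggplot2::ggplot(object, ggplot2::aes(y = .data$provenance)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::geom_segment(ggplot2::aes(x = .data$hpd95_lower,
                                       xend = .data$hpd95_upper,
                                       yend = .data$provenance),
                          linewidth = 0.4) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$hpd90_lower,
                                       xend = .data$hpd90_upper,
                                       yend = .data$provenance),
                          linewidth = 1.2) +
    ggplot2::geom_point(ggplot2::aes(x = .data$mean), size = 2) +
    ggplot2::labs(x = "deviation from global intercept (logit)",
                  y = NULL)
}

#' Plot the viability-by-depth regression
#'
#' Observed per-record viable fractions (point size by seeds tested),
#' fitted mean curve, and the 95% confidence band.
#'
#' @param object A [fit_viability_glm()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot viability_fit
#' @export
autoplot.viability_fit <- function(object, ...) {
  r <- object$records
  xobs <- if (object$regressor == "depth_cm") r$depth_cm else
    stop("plotting supports the depth regressor", call. = FALSE)
  grid <- object$curve(seq(min(xobs), max(xobs), length.out = 100))
  pts <- tibble::tibble(x = xobs, p = r$n_viable / r$n_tested,
                        n = r$n_tested)
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$x)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower95,
                                      ymax = .data$upper95), alpha = 0.25) +
    ggplot2::geom_line(ggplot2::aes(y = .data$probability),
                       linewidth = 1) +
    ggplot2::geom_point(data = pts,
                        ggplot2::aes(y = .data$p, size = .data$n),
                        alpha = 0.6) +
    ggplot2::scale_size_area(max_size = 4) +
    ggplot2::labs(x = "depth (cm)", y = "P(viable | not germinated)",
                  size = "tested")
}
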