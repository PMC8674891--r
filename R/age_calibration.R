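quad_age <- function(gamma, depth) {
  gamma[1] + gamma[2] * depth + gamma[3] * depth^2
}

#' Fit the depth-to-age calibration from dated sediment cores
#'
#' Radioisotope dating of sediment cores yields depth/age pairs; seed age at
#' any depth is then interpolated with a quadratic regression
#' `age = gamma0 + gamma1 * depth + gamma2 * depth^2 + eps`,
#' `eps ~ Normal(0, sigma_eps^2)`, pooling all cores. The fit is Bayesian
#' with the standard noninformative prior (flat on the coefficients,
#' `p(sigma^2) ~ 1/sigma^2`), which is conjugate: the posterior is sampled
#' exactly (scaled inverse-chi-squared draw for the residual variance, then
#' a multivariate normal draw for the coefficients), so no MCMC is needed
#' and draws are i.i.d.
#'
#' The calibration also fixes the standardization constants used for the
#' age covariate in the germination models: the center and scale are the
#' mean and standard deviation of the posterior-mean predicted ages over
#' the observed depth grid, so "one standardized age unit" is one standard
#' deviation of age across the dated depths.
#'
#' @param records Data frame with columns `core_id`, `depth_cm`,
#'   `age_years` (years before collection, non-negative).
#' @param n_draws Number of posterior draws (>= 100).
#' @param seed Integer seed for reproducible draws.
#' @return An object of class `age_calibration`: posterior-mean
#'   coefficients `gamma0`, `gamma1`, `gamma2` and residual SD `sigma_eps`,
#'   a `posterior_draws` tibble, standardization constants `age_center`
#'   and `age_scale`, and the observed `depth_range`.
#' @export
fit_age_calibration <- function(records, n_draws = 4000, seed = NULL) {
  stopifnot(all(c("core_id", "depth_cm", "age_years") %in% names(records)))
  if (any(records$age_years < 0) || any(records$depth_cm < 0)) {
    stop("depths and ages must be non-negative", call. = FALSE)
  }
  if (n_draws < 100) stop("n_draws must be >= 100", call. = FALSE)
  depths <- records$depth_cm
  if (length(unique(depths)) < 4) {
    stop("need at least 4 distinct depths to fit a quadratic with ",
         "residual uncertainty", call. = FALSE)
  }
  nonmono <- records |>
    dplyr::arrange(.data$core_id, .data$depth_cm) |>
    dplyr::group_by(.data$core_id) |>
    dplyr::summarise(mono = !is.unsorted(.data$age_years), .groups = "drop")
  if (any(!nonmono$mono)) {
    warning("age decreases with depth within core(s): ",
            paste(nonmono$core_id[!nonmono$mono], collapse = ", "),
            " (possible dating noise or stratigraphic mixing)",
            call. = FALSE)
  }

  X <- cbind(1, depths, depths^2)
  y <- records$age_years
  qrX <- qr(X)
  if (qrX$rank < 3) stop("depth design is rank deficient", call. = FALSE)
  gamma_hat <- qr.coef(qrX, y)
  rss <- sum((y - X %*% gamma_hat)^2)
  df <- length(y) - 3
  XtX_inv <- chol2inv(qr.R(qrX))
  R_chol <- chol(XtX_inv + diag(1e-12, 3))

  if (!is.null(seed)) set.seed(seed)
  sigma2 <- rss / stats::rchisq(n_draws, df)
  z <- matrix(stats::rnorm(3 * n_draws), n_draws, 3)
  gammas <- sweep(z %*% R_chol, 1, sqrt(sigma2), `*`)
  gammas <- sweep(gammas, 2, gamma_hat, `+`)
  draws <- tibble::tibble(
    gamma0 = gammas[, 1], gamma1 = gammas[, 2], gamma2 = gammas[, 3],
    sigma_eps = sqrt(sigma2)
  )

  grid <- sort(unique(depths))
  post_gamma <- colMeans(gammas)
  mu_grid <- quad_age(post_gamma, grid)
  scale <- stats::sd(mu_grid)
  if (!is.finite(scale) || scale <= 0) scale <- 1

  structure(list(
    gamma0 = post_gamma[1], gamma1 = post_gamma[2], gamma2 = post_gamma[3],
    sigma_eps = mean(draws$sigma_eps),
    posterior_draws = draws,
    age_center = mean(mu_grid),
    age_scale = scale,
    depth_range = range(depths),
    n_obs = length(y)
  ), class = "age_calibration")
}

#' Construct a point-mass calibration from known coefficients
#'
#' For simulation studies the generating depth-to-age relationship is known
#' exactly; this wraps known coefficients in the same `age_calibration`
#' container (single posterior draw, standardization over a stated depth
#' grid) so that downstream code is agnostic to whether the calibration was
#' fitted or assumed.
#'
#' @param gamma Numeric length-3 vector `(gamma0, gamma1, gamma2)`.
#' @param sigma_eps Residual SD in years.
#' @param depth_grid Depths (cm) over which to compute the standardization
#'   constants.
#' @return An `age_calibration` object with a single posterior draw.
#' @export
calibration_from_truth <- function(gamma, sigma_eps, depth_grid) {
  mu_grid <- quad_age(gamma, depth_grid)
  scale <- stats::sd(mu_grid)
  if (!is.finite(scale) || scale <= 0) scale <- 1
  structure(list(
    gamma0 = gamma[1], gamma1 = gamma[2], gamma2 = gamma[3],
    sigma_eps = sigma_eps,
    posterior_draws = tibble::tibble(
      gamma0 = gamma[1], gamma1 = gamma[2], gamma2 = gamma[3],
      sigma_eps = sigma_eps
    ),
    age_center = mean(mu_grid),
    age_scale = scale,
    depth_range = range(depth_grid),
    n_obs = length(depth_grid)
  ), class = "age_calibration")
}

#' @export
print.age_calibration <- function(x, ...) {
  cat("<age_calibration> age = ",
      format(x$gamma0, digits = 3), " + ",
      format(x$gamma1, digits = 3), " d + ",
      format(x$gamma2, digits = 3), " d^2,  sigma_eps = ",
      format(x$sigma_eps, digits = 3), " yr\n",
      "  ", nrow(x$posterior_draws), " posterior draws; age center/scale = ",
      format(x$age_center, digits = 4), " / ",
      format(x$age_scale, digits = 4), " yr\n", sep = "")
  invisible(x)
}

#' Posterior age distribution of a seed at a given depth
#'
#' Mixes, over the calibration posterior draws, normal age distributions
#' centered on each draw's quadratic prediction with that draw's residual
#' SD, truncated below at zero (buried seeds cannot have negative age).
#' The returned object carries the mixture mean and SD plus a quantile
#' function and a reproducible sampler.
#'
#' @param cal An [age_calibration] object.
#' @param depth_cm Single non-negative depth.
#' @return Object of class `age_dist` with elements `mean`, `sd`,
#'   `quantile(p)`, `sample(n, seed)`, `depth_cm`.
#' @export
age_distribution <- function(cal, depth_cm) {
  stopifnot(inherits(cal, "age_calibration"), depth_cm >= 0,
            length(depth_cm) == 1)
  d <- cal$posterior_draws
  mu <- d$gamma0 + d$gamma1 * depth_cm + d$gamma2 * depth_cm^2
  s <- d$sigma_eps

  # per-component truncated-normal (at 0) moments
  deg <- s <= 0
  a <- ifelse(deg, -Inf, -mu / pmax(s, 1e-300))
  za <- stats::pnorm(a)
  lambda <- ifelse(deg, 0, stats::dnorm(a) / pmax(1 - za, 1e-300))
  comp_mean <- ifelse(deg, pmax(mu, 0), mu + s * lambda)
  comp_var <- ifelse(deg, 0, s^2 * (1 + a * lambda - lambda^2))
  mix_mean <- mean(comp_mean)
  mix_var <- mean(comp_var + comp_mean^2) - mix_mean^2

  cdf <- function(x) {
    vapply(x, function(xi) {
      if (xi <= 0) return(0)
      p <- ifelse(deg, as.numeric(xi >= mu),
                  (stats::pnorm((xi - mu) / pmax(s, 1e-300)) - za) /
                    pmax(1 - za, 1e-300))
      mean(pmin(pmax(p, 0), 1))
    }, numeric(1))
  }
  qf <- function(p) {
    vapply(p, function(pi) {
      stopifnot(pi >= 0, pi <= 1)
      hi <- max(comp_mean + 10 * sqrt(pmax(comp_var, 1e-12))) + 1
      if (all(deg)) {
        # discrete mixture of point masses
        return(stats::quantile(mu, probs = pi, type = 1, names = FALSE))
      }
      stats::uniroot(function(x) cdf(x) - pi, lower = 0, upper = hi,
                     extendInt = "upX", tol = 1e-8)$root
    }, numeric(1))
  }
  sampler <- function(n, seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    idx <- sample.int(length(mu), n, replace = TRUE)
    u <- stats::runif(n)
    m <- mu[idx]; sd_i <- s[idx]; za_i <- za[idx]
    ifelse(sd_i <= 0, pmax(m, 0),
           m + sd_i * stats::qnorm(za_i + u * (1 - za_i)))
  }

  structure(list(mean = mix_mean, sd = sqrt(pmax(mix_var, 0)),
                 quantile = qf, cdf = cdf, sample = sampler,
                 depth_cm = depth_cm),
            class = "age_dist")
}

#' @export
print.age_dist <- function(x, ...) {
  q <- x$quantile(c(0.025, 0.5, 0.975))
  cat("<age_dist> depth ", x$depth_cm, " cm: mean ",
      format(x$mean, digits = 4), " yr, sd ", format(x$sd, digits = 3),
      ", 95% [", format(q[1], digits = 4), ", ", format(q[3], digits = 4),
      "]\n", sep = "")
  invisible(x)
}

#' Standardize an age in years to calibration units
#'
#' `(age - age_center) / age_scale`; the inverse is [destandardize_age()].
#' Slopes in the germination models are per one standardized age unit,
#' i.e. per standard deviation of mean predicted age across the dated
#' depth grid.
#'
#' @param cal An [age_calibration] object.
#' @param age_years Numeric vector of ages in years.
#' @return Standardized ages.
#' @export
standardize_age <- function(cal, age_years) {
  (age_years - cal$age_center) / cal$age_scale
}

#' @rdname standardize_age
#' @param x Standardized age(s).
#' @export
destandardize_age <- function(cal, x) {
  x * cal$age_scale + cal$age_center
}

#' Read a dated-core CSV (columns `core_id,depth_cm,age_years`)
#'
#' @param path CSV path.
#' @return Tibble of dating records.
#' @export
read_core_dating <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  stopifnot(all(c("core_id", "depth_cm", "age_years") %in% names(x)))
  x
}
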