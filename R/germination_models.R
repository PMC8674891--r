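#' Default weakly informative priors for the germination models
#'
#' Normal(0, 2.5^2) on all logit-scale regression coefficients (intercept,
#' age slope, treatment dummies, zero-inflation coefficients),
#' Half-Normal(0, 1) on the provenance random-intercept SD, and, for the
#' beta-binomial precision, a uniform prior on the intraclass correlation
#' `rho = 1/(1 + phi)` (equivalently `p(phi) = 1/(1 + phi)^2`). The
#' coefficient priors are the conventional weakly informative defaults
#' for logit-scale regression. The precision prior is chosen so that the
#' binomial limit (`rho -> 0`, `phi -> Inf`) carries positive prior
#' density: a light-tailed prior on `phi` itself (e.g. an exponential)
#' would forbid that limit and spuriously penalize the beta-binomial in
#' model comparison whenever the data are not overdispersed. Exponential
#' (`phi = list(rate = ...)`) and log-normal
#' (`phi = list(meanlog = , sdlog = )`) alternatives remain available.
#' The coefficient priors can be switched to logistic
#' (`dist = "logistic"`; scale 1 on the intercept is equivalent to a
#' uniform prior on the reference-profile probability).
#'
#' @return Nested list of prior settings, overridable per block.
#' @export
default_priors <- function() {
  list(
    beta = list(dist = "normal", scale = 2.5),
    alpha = list(dist = "normal", scale = 2.5),
    sigma_loc = list(scale = 1),
    phi = list(dist = "icc_uniform")
  )
}

lprior_phi <- function(phi, prior) {
  if (!is.null(prior$rate)) {
    stats::dexp(phi, prior$rate, log = TRUE)
  } else if (!is.null(prior$meanlog)) {
    stats::dlnorm(phi, prior$meanlog, prior$sdlog, log = TRUE)
  } else {
    -2 * log1p(phi) # uniform on rho = 1/(1+phi)
  }
}

lprior_coef <- function(x, prior) {
  switch(prior$dist,
    normal = sum(stats::dnorm(x, 0, prior$scale, log = TRUE)),
    logistic = sum(stats::dlogis(x, 0, prior$scale, log = TRUE)),
    stop("unknown coefficient prior: ", prior$dist, call. = FALSE)
  )
}

#' Specify one of the four hierarchical germination models
#'
#' The four candidate likelihoods form a 2x2 grid: with/without
#' zero-inflation (ZI) and with/without beta-binomial overdispersion (OD).
#' `"BIN"` is the plain binomial (-ZI/-OD), `"ZIB"` zero-inflated binomial
#' (+ZI/-OD), `"BB"` beta-binomial (-ZI/+OD) and `"ZIBB"` zero-inflated
#' beta-binomial (+ZI/+OD). All four share the same mean structure:
#' logit(p) = intercept + age slope x standardized age + treatment dummies
#' + provenance random intercept. The zero-inflation probability is
#' intercept-only for ZIB and gains an age slope for ZIBB (testing whether
#' the excess-zero process itself ages).
#'
#' @param family `"BIN"`, `"ZIB"`, `"BB"` or `"ZIBB"`.
#' @param zero_inflation_age_slope Regress the zero-inflation logit on
#'   standardized age? Defaults on for ZIBB, off for ZIB.
#' @param use_errors_in_variables Treat the per-depth-slice seed age as a
#'   latent variable with the calibration posterior as its prior
#'   (default), rather than plugging in the calibration's mean age.
#' @param marginalize_calibration With errors-in-variables on, average the
#'   latent-age prior over the whole calibration posterior (a mixture
#'   prior, subsampled to at most 200 draws) instead of conditioning each
#'   chain on one random calibration draw.
#' @param priors See [default_priors()]; partial overrides allowed.
#' @param reference_levels See [default_reference_levels()].
#' @return Object of class `germ_model_spec`.
#' @export
germ_model_spec <- function(family = c("BB", "BIN", "ZIB", "ZIBB"),
                            zero_inflation_age_slope = NULL,
                            use_errors_in_variables = TRUE,
                            marginalize_calibration = FALSE,
                            priors = default_priors(),
                            reference_levels = default_reference_levels()) {
  family <- match.arg(family)
  zi <- family %in% c("ZIB", "ZIBB")
  if (is.null(zero_inflation_age_slope)) {
    zero_inflation_age_slope <- family == "ZIBB"
  }
  if (zero_inflation_age_slope && !zi) {
    stop("zero_inflation_age_slope is only meaningful for ZIB/ZIBB",
         call. = FALSE)
  }
  pr <- utils::modifyList(default_priors(), priors)
  structure(list(
    family = family,
    has_zi = zi,
    has_od = family %in% c("BB", "ZIBB"),
    zero_inflation_age_slope = zero_inflation_age_slope,
    use_errors_in_variables = use_errors_in_variables,
    marginalize_calibration = marginalize_calibration,
    priors = pr,
    reference_levels = reference_levels
  ), class = "germ_model_spec")
}

#' @export
print.germ_model_spec <- function(x, ...) {
  cat("<germ_model_spec> family ", x$family,
      if (x$has_zi) paste0(" (ZI", if (x$zero_inflation_age_slope)
        " with age slope", ")"),
      if (x$use_errors_in_variables) ", errors-in-variables age", "\n",
      sep = "")
  invisible(x)
}

#' Germination probabilities from the linear predictor
#'
#' `p_i = plogis(beta0 + beta_age * x_i + X_i beta_treat + u[loc(i)])`.
#' When the design has a single provenance the random intercept is
#' dropped (it would be confounded with the global intercept).
#'
#' @param params List with `beta0`, `beta_age`, `beta_treat` (length
#'   `ncol(design$X)`), `u` (length = number of provenances, ignored if 1).
#' @param design A [build_design()] object.
#' @param standardized_ages Standardized age per row (or per depth slice,
#'   recycled through `design$depth_interval` if named by interval).
#' @return Vector of probabilities.
#' @export
linear_predictor <- function(params, design, standardized_ages) {
  n <- length(design$y)
  xs <- if (length(standardized_ages) == n) standardized_ages
        else standardized_ages[as.character(design$depth_interval)]
  if (length(xs) != n) stop("standardized_ages has the wrong length",
                            call. = FALSE)
  bt <- params$beta_treat %||% numeric(ncol(design$X))
  if (length(bt) != ncol(design$X)) {
    stop("beta_treat must have one entry per design column", call. = FALSE)
  }
  eta <- params$beta0 + params$beta_age * xs + drop(design$X %*% bt)
  if (length(design$provenance_levels) > 1) {
    u <- params$u
    if (length(u) != length(design$provenance_levels)) {
      stop("u must have one entry per provenance", call. = FALSE)
    }
    eta <- eta + u[design$provenance_index]
  }
  stats::plogis(eta)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Build the static model context shared by log_posterior and the sampler.
model_context <- function(spec, design, cal, cal_draw = NULL,
                          n_marginal = 200) {
  occupied <- sort(unique(design$depth_interval))
  mids <- 2 * occupied - 1
  mids[design$depth_cm[match(occupied, design$depth_interval)] == 0] <- 0
  rows_by_interval <- lapply(occupied, function(d)
    which(design$depth_interval == d))
  L <- length(design$provenance_levels)
  rows_by_loc <- lapply(seq_len(L), function(l)
    which(design$provenance_index == l))

  pd <- cal$posterior_draws
  if (is.null(cal_draw)) {
    gam <- c(cal$gamma0, cal$gamma1, cal$gamma2)
    sig <- cal$sigma_eps
  } else {
    gam <- as.numeric(pd[cal_draw, c("gamma0", "gamma1", "gamma2")])
    sig <- pd$sigma_eps[cal_draw]
  }
  mu_d <- quad_age(gam, mids)
  mu_d[mids == 0] <- 0 # surface/greenhouse anchor

  marg <- NULL
  if (spec$marginalize_calibration && spec$use_errors_in_variables) {
    k <- min(n_marginal, nrow(pd))
    idx <- if (nrow(pd) <= k) seq_len(nrow(pd))
           else round(seq(1, nrow(pd), length.out = k))
    mu_k <- sapply(idx, function(i)
      quad_age(as.numeric(pd[i, c("gamma0", "gamma1", "gamma2")]), mids))
    mu_k[mids == 0, ] <- 0
    marg <- list(mu = mu_k, sigma = pd$sigma_eps[idx]) # mu: D x K
  }

  list(
    y = design$y, n = design$n_planted, X = design$X,
    lch = lchoose(design$n_planted, design$y),
    loc = design$provenance_index, L = L,
    use_u = L > 1,
    occupied = occupied, mids = mids,
    interval_pos = match(design$depth_interval, occupied),
    rows_by_interval = rows_by_interval, rows_by_loc = rows_by_loc,
    mu_d = mu_d, sigma_d = sig, marg = marg,
    center = cal$age_center, scale = cal$age_scale,
    spec = spec
  )
}

ctx_loglik <- function(ctx, rows, eta, zeta, phi) {
  p <- pmin(pmax(stats::plogis(eta), 1e-12), 1 - 1e-12)
  y <- ctx$y[rows]; n <- ctx$n[rows]
  base <- if (ctx$spec$has_od) {
    a <- p * phi; b <- (1 - p) * phi
    ctx$lch[rows] + lbeta(y + a, n - y + b) - lbeta(a, b)
  } else {
    stats::dbinom(y, n, p, log = TRUE)
  }
  if (ctx$spec$has_zi) {
    pi <- stats::plogis(zeta)
    out <- log1p(-pi) + base
    at0 <- y == 0
    if (any(at0)) {
      la <- log(pi[at0]); lb <- out[at0]
      m <- pmax(la, lb)
      out[at0] <- m + log(exp(la - m) + exp(lb - m))
    }
    out
  } else {
    base
  }
}

# Latent-age log prior; x in years. Separable normal per slice by default,
# or a calibration-posterior mixture when marginalizing.
lprior_latent <- function(ctx, x) {
  if (is.null(ctx$marg)) {
    sum(stats::dnorm(x, ctx$mu_d, ctx$sigma_d, log = TRUE))
  } else {
    A <- colSums(stats::dnorm(x, ctx$marg$mu,
                              rep(ctx$marg$sigma, each = length(x)),
                              log = TRUE))
    m <- max(A)
    m + log(mean(exp(A - m)))
  }
}

#' Joint log posterior density of a germination model
#'
#' Sum of the pointwise count log-likelihood under the specified family,
#' the log priors of all parameter blocks, and (with errors-in-variables)
#' the latent-age terms `x_latent[d] ~ Normal(mu_d, sigma_eps^2)` with
#' the depth-to-age mean and residual SD taken from the calibration
#' (posterior means by default, a specific posterior draw via `cal_draw`,
#' or the full posterior mixture when the spec marginalizes). Returns
#' `-Inf` (not an error) outside the support.
#'
#' @param params Named list: `beta0`, `beta_age`, `beta_treat`, `u`,
#'   `sigma_loc`, and per family `phi`, `alpha0`, `alpha1`, `x_latent`
#'   (years, one per occupied depth slice, in increasing slice order).
#' @param spec A [germ_model_spec()].
#' @param design A [build_design()] object.
#' @param cal An [age_calibration] object.
#' @param cal_draw Optional row index into the calibration posterior to
#'   condition on.
#' @return Scalar log posterior density (unnormalized).
#' @export
log_posterior <- function(params, spec, design, cal, cal_draw = NULL) {
  ctx <- model_context(spec, design, cal, cal_draw = cal_draw)
  pr <- spec$priors

  sigma_loc <- params$sigma_loc %||% 0
  if (ctx$use_u && (!is.finite(sigma_loc) || sigma_loc < 0)) return(-Inf)
  if (spec$has_od && (!is.finite(params$phi) || params$phi <= 0)) return(-Inf)

  xs_d <- if (spec$use_errors_in_variables) {
    (params$x_latent - ctx$center) / ctx$scale
  } else {
    (ctx$mu_d - ctx$center) / ctx$scale
  }
  xs <- xs_d[ctx$interval_pos]
  p <- linear_predictor(params, design, xs)
  eta <- stats::qlogis(p)
  zeta <- if (spec$has_zi) {
    params$alpha0 + (if (spec$zero_inflation_age_slope)
      params$alpha1 * xs else 0)
  } else NULL

  ll <- loglik_family(spec$family, ctx$y, ctx$n, p,
                      phi = params$phi,
                      pi = if (spec$has_zi) stats::plogis(zeta) else NULL)
  out <- sum(ll)
  out <- out + lprior_coef(c(params$beta0, params$beta_age,
                             params$beta_treat), pr$beta)
  if (ctx$use_u) {
    out <- out + sum(stats::dnorm(params$u, 0, sigma_loc, log = TRUE)) +
      stats::dnorm(sigma_loc, 0, pr$sigma_loc$scale, log = TRUE) + log(2)
  }
  if (spec$has_od) {
    out <- out + lprior_phi(params$phi, pr$phi)
  }
  if (spec$has_zi) {
    out <- out + lprior_coef(c(params$alpha0,
                               if (spec$zero_inflation_age_slope)
                                 params$alpha1), pr$alpha)
  }
  if (spec$use_errors_in_variables) {
    out <- out + lprior_latent(ctx, params$x_latent)
  }
  if (!is.finite(out)) -Inf else out
}

#' Fit a hierarchical germination model by MCMC
#'
#' Samples the joint posterior with an adaptive Metropolis-within-Gibbs
#' scheme: the fixed-effect block (intercept, age slope, treatment
#' dummies, zero-inflation coefficients) moves with a multivariate
#' random-walk proposal whose covariance adapts to the sampled history
#' during warmup; the provenance intercepts, the two variance-type
#' parameters (on log scale) and each latent age move with univariate
#' random walks whose step sizes adapt toward standard target acceptance
#' rates. Adaptation stops at the end of warmup, so retained draws come
#' from a fixed kernel. With errors-in-variables on, each chain
#' conditions on one random draw of the calibration posterior (or the
#' full mixture when the spec marginalizes), which propagates the dating
#' uncertainty into every coefficient.
#'
#' The default sampler configuration (3 chains, 10,000 iterations with
#' 2,000 warmup, thinning 3) mirrors the study-scale settings; scaled-down
#' configurations are appropriate for simulation work.
#'
#' @param trials Validated trial table, or a prebuilt [build_design()]
#'   object.
#' @param cal An [age_calibration] object.
#' @param spec A [germ_model_spec()].
#' @param chains Number of chains (>= 2).
#' @param iter Iterations per chain, including warmup.
#' @param warmup Warmup (adaptation) iterations discarded from the draws.
#' @param thin Thinning interval for retained draws.
#' @param seed Integer seed; fits with identical seeds are identical.
#' @return Object of class `germ_fit` with elements `draws` (matrix of
#'   retained draws x named parameters), `chain_id`, `pointwise_loglik`
#'   (draws x groups), `spec`, `design`, `cal`, `sampler_config`,
#'   `accept_rates`, `diagnostics` (split R-hat and bulk ESS via
#'   [convergence()]), and `flagged` (TRUE unless all R-hat < 1.01).
#' @export
fit_germination <- function(trials, cal, spec = germ_model_spec("BB"),
                            chains = 3, iter = 10000, warmup = 2000,
                            thin = 3, seed = 1) {
  stopifnot(inherits(cal, "age_calibration"),
            inherits(spec, "germ_model_spec"),
            chains >= 2, iter > warmup, warmup >= 1, thin >= 1)
  design <- if (inherits(trials, "germ_design")) trials
            else build_design(trials, spec$reference_levels)

  keep_per_chain <- floor((iter - warmup) / thin)
  if (keep_per_chain < 2) stop("too few retained iterations", call. = FALSE)

  chain_results <- lapply(seq_len(chains), function(ch) {
    run_chain(spec, design, cal, iter = iter, warmup = warmup, thin = thin,
              seed = seed, chain = ch)
  })

  draws <- do.call(rbind, lapply(chain_results, `[[`, "draws"))
  ll <- do.call(rbind, lapply(chain_results, `[[`, "loglik"))
  chain_id <- rep(seq_len(chains), each = keep_per_chain)
  accept <- rowMeans(sapply(chain_results, `[[`, "accept"))

  fit <- structure(list(
    draws = draws, chain_id = chain_id, pointwise_loglik = ll,
    spec = spec, design = design, cal = cal,
    sampler_config = list(chains = chains, iter = iter, warmup = warmup,
                          thin = thin, seed = seed),
    accept_rates = accept,
    cal_draws_used = vapply(chain_results, `[[`, numeric(1), "cal_draw")
  ), class = "germ_fit")

  fit$diagnostics <- convergence(fit)
  core <- !grepl("^x_latent", fit$diagnostics$parameter)
  fit$flagged <- any(fit$diagnostics$rhat[core] >= 1.01, na.rm = TRUE)
  fit
}

#' @rdname fit_germination
#' @export
sample_posterior <- fit_germination

#' @export
print.germ_fit <- function(x, ...) {
  cfg <- x$sampler_config
  cat("<germ_fit> family ", x$spec$family, ", ", nrow(x$draws),
      " draws (", cfg$chains, " chains x ", cfg$iter, " iter, warmup ",
      cfg$warmup, ", thin ", cfg$thin, ")\n", sep = "")
  core <- !grepl("^x_latent", x$diagnostics$parameter)
  cat("  max split R-hat (model parameters): ",
      format(max(x$diagnostics$rhat[core], na.rm = TRUE), digits = 4),
      if (x$flagged) "  ** CONVERGENCE FLAGGED (R-hat >= 1.01) **",
      "\n", sep = "")
  invisible(x)
}

# One MCMC chain. Returns retained draws, pointwise log-likelihoods,
# acceptance rates and the calibration draw index used.
run_chain <- function(spec, design, cal, iter, warmup, thin, seed, chain) {
  set.seed(as.integer((seed * 101 + chain) %% .Machine$integer.max))
  cal_draw <- if (spec$use_errors_in_variables &&
                  !spec$marginalize_calibration) {
    sample.int(nrow(cal$posterior_draws), 1)
  } else NA_real_
  ctx <- model_context(spec, design, cal,
                       cal_draw = if (is.na(cal_draw)) NULL else cal_draw)
  K <- ncol(ctx$X)
  D <- length(ctx$occupied)
  eiv <- spec$use_errors_in_variables
  pr <- spec$priors

  n_alpha <- if (spec$has_zi) 1 + spec$zero_inflation_age_slope else 0
  nf <- 2 + K + n_alpha # fixed-effect block size

  # --- initialization (jittered; retried if log posterior non-finite)
  init_state <- function() {
    list(
      betaf = c(stats::rnorm(2 + K, 0, 0.1),
                if (n_alpha > 0) stats::rnorm(n_alpha, 0, 0.1)),
      u = if (ctx$use_u) stats::rnorm(ctx$L, 0, 0.1) else numeric(0),
      lsl = log(0.5) + stats::rnorm(1, 0, 0.1),
      lphi = log(5) + stats::rnorm(1, 0, 0.1),
      x = if (eiv) ctx$mu_d + stats::rnorm(D, 0, max(ctx$sigma_d, 1) / 4)
          else ctx$mu_d
    )
  }

  xs_of <- function(x) (x - ctx$center) / ctx$scale

  # cached quantities given a state
  recache <- function(s) {
    xs_d <- xs_of(s$x)
    xs <- xs_d[ctx$interval_pos]
    eta_fix <- s$betaf[1] + drop(ctx$X %*% s$betaf[3:(2 + K)])
    eta <- eta_fix + s$betaf[2] * xs +
      (if (ctx$use_u) s$u[ctx$loc] else 0)
    zeta <- if (spec$has_zi) {
      s$betaf[2 + K + 1] +
        (if (spec$zero_inflation_age_slope) s$betaf[2 + K + 2] * xs else 0)
    } else NULL
    phi <- if (spec$has_od) exp(s$lphi) else NULL
    ll <- ctx_loglik(ctx, seq_along(ctx$y), eta, zeta, phi)
    list(xs_d = xs_d, xs_row = xs, eta = eta, zeta = zeta, ll = ll)
  }

  # rows touched by each fixed-effect coordinate (treatment dummies act
  # on their nonzero rows only)
  rows_of_coef <- lapply(seq_len(nf), function(j) {
    if (j <= 2 || j > 2 + K) seq_along(ctx$y)
    else which(ctx$X[, j - 2] != 0)
  })

  lp_fixed_prior <- function(betaf) {
    lprior_coef(betaf[1:(2 + K)], pr$beta) +
      if (n_alpha > 0) lprior_coef(betaf[(2 + K + 1):nf], pr$alpha) else 0
  }

  s <- NULL; cache <- NULL
  for (try in 1:20) {
    s <- init_state()
    cache <- recache(s)
    if (all(is.finite(cache$ll))) break
    if (try == 20) stop("non-finite log posterior at initialization ",
                        "(likelihood block)", call. = FALSE)
  }

  # --- adaptation state
  step_f <- 0.1 / sqrt(nf)          # global scale of fixed-effect block
  emp_mean <- s$betaf; emp_cov <- diag(0.01, nf); n_emp <- 0
  chol_prop <- diag(sqrt(0.01), nf)
  step_f1 <- rep(0.2, nf)           # coordinate-wise refinement steps
  step_shift <- 0.3                 # intercept/random-effect translation
  step_u <- rep(0.5, max(ctx$L, 1))
  step_sl <- 0.3; step_phi <- 0.3
  step_x <- rep(max(ctx$sigma_d, 1) / 2, D)
  acc <- c(fixed = 0, u = 0, sigma_loc = 0, phi = 0, x = 0)
  n_prop <- c(fixed = 0, u = 0, sigma_loc = 0, phi = 0, x = 0)

  keep <- floor((iter - warmup) / thin)
  par_names <- c(
    "beta0", "beta_age",
    paste0("beta[", colnames(ctx$X), "]"),
    if (n_alpha > 0) c("alpha0", if (n_alpha > 1) "alpha1"),
    if (ctx$use_u) paste0("u[", design$provenance_levels, "]"),
    if (ctx$use_u) "sigma_loc",
    if (spec$has_od) "phi",
    if (eiv) paste0("x_latent[", ctx$occupied, "]")
  )
  draws <- matrix(NA_real_, keep, length(par_names),
                  dimnames = list(NULL, par_names))
  ll_out <- matrix(NA_real_, keep, length(ctx$y))
  kept <- 0

  phi_now <- function() if (spec$has_od) exp(s$lphi) else NULL
  # Marginalizing over the calibration posterior is implemented by
  # augmentation: a draw indicator k with uniform prior and
  # x_d | k ~ N(mu_kd, sigma_k) is Gibbs-sampled from its exact
  # conditional each iteration, which mixes globally across calibration
  # draws and marginalizes to the mixture prior.
  mu_cur <- ctx$mu_d; sd_cur <- ctx$sigma_d

  for (t in seq_len(iter)) {
    adapting <- t <= warmup

    ## -- block 1: fixed effects (+ ZI coefficients), joint MVN walk
    prop <- s$betaf + step_f * drop(stats::rnorm(nf) %*% chol_prop)
    s2 <- s; s2$betaf <- prop
    cache2 <- recache(s2)
    lr <- sum(cache2$ll) - sum(cache$ll) +
      lp_fixed_prior(prop) - lp_fixed_prior(s$betaf)
    n_prop["fixed"] <- n_prop["fixed"] + 1
    a <- is.finite(lr) && log(stats::runif(1)) < lr
    if (a) { s <- s2; cache <- cache2; acc["fixed"] <- acc["fixed"] + 1 }
    if (adapting) {
      step_f <- exp(log(step_f) +
                      (min(1, exp(min(lr, 0))) - 0.234) / sqrt(t))
      n_emp <- n_emp + 1
      dlt <- s$betaf - emp_mean
      emp_mean <- emp_mean + dlt / n_emp
      emp_cov <- emp_cov + (tcrossprod(dlt, s$betaf - emp_mean) -
                              emp_cov) / n_emp
      if (n_emp > 50 && t %% 25 == 0) {
        cc <- 2.38^2 / nf * (emp_cov + diag(1e-8, nf))
        ch <- tryCatch(chol(cc), error = function(e) NULL)
        if (!is.null(ch)) chol_prop <- ch
      }
    }

    ## -- block 1b: coordinate-wise refinement of the fixed effects.
    ## Each coordinate only touches the rows its column acts on, so the
    ## likelihood update is restricted to those rows.
    for (jf in seq_len(nf)) {
      r <- rows_of_coef[[jf]]
      dlt <- stats::rnorm(1, 0, step_f1[jf])
      eta2 <- cache$eta[r]
      zeta2 <- if (spec$has_zi) cache$zeta[r] else NULL
      if (jf == 1) eta2 <- eta2 + dlt
      else if (jf == 2) eta2 <- eta2 + dlt * cache$xs_row[r]
      else if (jf <= 2 + K) eta2 <- eta2 + dlt * ctx$X[r, jf - 2]
      else if (jf == 2 + K + 1) zeta2 <- zeta2 + dlt
      else zeta2 <- zeta2 + dlt * cache$xs_row[r]
      prop <- s$betaf; prop[jf] <- prop[jf] + dlt
      ll2 <- ctx_loglik(ctx, r, eta2, zeta2, phi_now())
      lr <- sum(ll2) - sum(cache$ll[r]) +
        lp_fixed_prior(prop) - lp_fixed_prior(s$betaf)
      n_prop["fixed"] <- n_prop["fixed"] + 1
      if (is.finite(lr) && log(stats::runif(1)) < lr) {
        s$betaf <- prop
        cache$eta[r] <- eta2
        if (spec$has_zi) cache$zeta[r] <- zeta2
        cache$ll[r] <- ll2
        acc["fixed"] <- acc["fixed"] + 1
      }
      if (adapting) {
        step_f1[jf] <- exp(log(step_f1[jf]) +
                             (min(1, exp(min(lr, 0))) - 0.44) / sqrt(t))
      }
    }

    ## -- block 2: provenance intercepts, single-site
    if (ctx$use_u) {
      sl <- exp(s$lsl)
      for (l in seq_len(ctx$L)) {
        r <- ctx$rows_by_loc[[l]]
        du <- stats::rnorm(1, 0, step_u[l])
        lr <- stats::dnorm(s$u[l] + du, 0, sl, log = TRUE) -
          stats::dnorm(s$u[l], 0, sl, log = TRUE)
        if (length(r) > 0) {
          eta2 <- cache$eta[r] + du
          ll2 <- ctx_loglik(ctx, r, eta2,
                            if (spec$has_zi) cache$zeta[r] else NULL,
                            phi_now())
          lr <- lr + sum(ll2) - sum(cache$ll[r])
        }
        n_prop["u"] <- n_prop["u"] + 1
        if (is.finite(lr) && log(stats::runif(1)) < lr) {
          s$u[l] <- s$u[l] + du
          if (length(r) > 0) {
            cache$eta[r] <- eta2; cache$ll[r] <- ll2
          }
          acc["u"] <- acc["u"] + 1
        }
        if (adapting) {
          step_u[l] <- exp(log(step_u[l]) +
                             (min(1, exp(min(lr, 0))) - 0.44) / sqrt(t))
        }
      }

      ## -- block 3: log sigma_loc (prior-only conditional)
      lsl2 <- s$lsl + stats::rnorm(1, 0, step_sl)
      cond <- function(lsl) {
        slv <- exp(lsl)
        sum(stats::dnorm(s$u, 0, slv, log = TRUE)) +
          stats::dnorm(slv, 0, pr$sigma_loc$scale, log = TRUE) + lsl
      }
      lr <- cond(lsl2) - cond(s$lsl)
      n_prop["sigma_loc"] <- n_prop["sigma_loc"] + 1
      if (is.finite(lr) && log(stats::runif(1)) < lr) {
        s$lsl <- lsl2; acc["sigma_loc"] <- acc["sigma_loc"] + 1
      }
      if (adapting) {
        step_sl <- exp(log(step_sl) +
                         (min(1, exp(min(lr, 0))) - 0.44) / sqrt(t))
      }

      ## -- block 3b: joint translation of intercept vs provenance
      ## deviations (likelihood-invariant; breaks their posterior
      ## correlation, a standard hierarchical reparametrization move)
      dlt <- stats::rnorm(1, 0, step_shift)
      slv <- exp(s$lsl)
      lr <- lprior_coef(s$betaf[1] + dlt, pr$beta) -
        lprior_coef(s$betaf[1], pr$beta) +
        sum(stats::dnorm(s$u - dlt, 0, slv, log = TRUE)) -
        sum(stats::dnorm(s$u, 0, slv, log = TRUE))
      if (is.finite(lr) && log(stats::runif(1)) < lr) {
        s$betaf[1] <- s$betaf[1] + dlt
        s$u <- s$u - dlt
      }
      if (adapting) {
        step_shift <- exp(log(step_shift) +
                            (min(1, exp(min(lr, 0))) - 0.44) / sqrt(t))
      }
    }

    ## -- block 4: log phi (full-likelihood update)
    if (spec$has_od) {
      lphi2 <- s$lphi + stats::rnorm(1, 0, step_phi)
      ll2 <- ctx_loglik(ctx, seq_along(ctx$y), cache$eta, cache$zeta,
                        exp(lphi2))
      lr <- sum(ll2) - sum(cache$ll) +
        lprior_phi(exp(lphi2), pr$phi) - lprior_phi(exp(s$lphi), pr$phi) +
        lphi2 - s$lphi
      n_prop["phi"] <- n_prop["phi"] + 1
      if (is.finite(lr) && log(stats::runif(1)) < lr) {
        s$lphi <- lphi2; cache$ll <- ll2; acc["phi"] <- acc["phi"] + 1
      }
      if (adapting) {
        step_phi <- exp(log(step_phi) +
                          (min(1, exp(min(lr, 0))) - 0.44) / sqrt(t))
      }
    }

    ## -- block 5: latent ages, single-site (with a Gibbs update of the
    ## calibration-draw indicator when marginalizing)
    if (eiv) {
      if (!is.null(ctx$marg)) {
        A <- colSums(stats::dnorm(s$x, ctx$marg$mu,
                                  rep(ctx$marg$sigma, each = D),
                                  log = TRUE))
        k_cur <- sample.int(length(A), 1, prob = exp(A - max(A)))
        mu_cur <- ctx$marg$mu[, k_cur]
        sd_cur <- ctx$marg$sigma[k_cur]
      }
      b_age <- s$betaf[2]
      a_age <- if (spec$zero_inflation_age_slope) s$betaf[nf] else 0
      for (j in seq_len(D)) {
        r <- ctx$rows_by_interval[[j]]
        xj2 <- s$x[j] + stats::rnorm(1, 0, step_x[j])
        dpr <- stats::dnorm(xj2, mu_cur[j], sd_cur, log = TRUE) -
          stats::dnorm(s$x[j], mu_cur[j], sd_cur, log = TRUE)
        dxs <- (xj2 - s$x[j]) / ctx$scale
        eta2 <- cache$eta[r] + b_age * dxs
        zeta2 <- if (spec$has_zi) cache$zeta[r] + a_age * dxs else NULL
        ll2 <- ctx_loglik(ctx, r, eta2, zeta2, phi_now())
        lr <- dpr + sum(ll2) - sum(cache$ll[r])
        n_prop["x"] <- n_prop["x"] + 1
        if (is.finite(lr) && log(stats::runif(1)) < lr) {
          s$x[j] <- xj2
          cache$eta[r] <- eta2
          if (spec$has_zi) cache$zeta[r] <- zeta2
          cache$ll[r] <- ll2
          cache$xs_d[j] <- xs_of(xj2)
          cache$xs_row[r] <- cache$xs_d[j]
          acc["x"] <- acc["x"] + 1
        }
        if (adapting) {
          step_x[j] <- exp(log(step_x[j]) +
                             (min(1, exp(min(lr, 0))) - 0.44) / sqrt(t))
        }
      }
    }

    ## -- retain
    if (t > warmup && (t - warmup) %% thin == 0 && kept < keep) {
      kept <- kept + 1
      draws[kept, ] <- c(
        s$betaf[1:2], s$betaf[3:(2 + K)],
        if (n_alpha > 0) s$betaf[(2 + K + 1):nf],
        if (ctx$use_u) s$u,
        if (ctx$use_u) exp(s$lsl),
        if (spec$has_od) exp(s$lphi),
        if (eiv) s$x
      )
      ll_out[kept, ] <- cache$ll
    }
  }

  list(draws = draws, loglik = ll_out,
       accept = acc / pmax(n_prop, 1), cal_draw = cal_draw)
}
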