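col_log_mean_exp <- function(ll) {
  m <- apply(ll, 2, max)
  m + log(colMeans(exp(sweep(ll, 2, m))))
}

# Per-draw fitted germination probabilities (and zero-inflation
# probabilities) for every group, reconstructed from the stored draws.
fitted_probabilities <- function(fit) {
  d <- fit$draws
  design <- fit$design
  spec <- fit$spec
  ctx <- model_context(spec, design, fit$cal)
  S <- nrow(d); N <- length(ctx$y)
  K <- ncol(design$X)

  xs <- if (spec$use_errors_in_variables) {
    xl <- d[, paste0("x_latent[", ctx$occupied, "]"), drop = FALSE]
    ((xl - ctx$center) / ctx$scale)[, ctx$interval_pos, drop = FALSE]
  } else {
    matrix(rep((ctx$mu_d - ctx$center) / ctx$scale, each = S)[
      seq_len(S * length(ctx$mu_d))],
      S, length(ctx$mu_d))[, ctx$interval_pos, drop = FALSE]
  }
  bt <- d[, paste0("beta[", colnames(design$X), "]"), drop = FALSE]
  eta <- d[, "beta0"] + d[, "beta_age"] * xs + bt %*% t(design$X)
  if (ctx$use_u) {
    u <- d[, paste0("u[", design$provenance_levels, "]"), drop = FALSE]
    eta <- eta + u[, ctx$loc, drop = FALSE]
  }
  p <- stats::plogis(eta)
  pi <- NULL
  if (spec$has_zi) {
    zeta <- d[, "alpha0"] +
      if (spec$zero_inflation_age_slope) d[, "alpha1"] * xs else 0
    pi <- stats::plogis(zeta)
    if (!is.matrix(pi)) pi <- matrix(pi, S, N)
  }
  list(p = p, pi = pi, phi = if (spec$has_od) d[, "phi"] else NULL,
       n = ctx$n, y = ctx$y)
}

#' Simulate replicate datasets from the posterior
#'
#' For each retained draw, simulates one dataset of the same size and
#' structure as the observed one using only that draw's parameter values
#' (including its latent ages), i.e. the standard posterior predictive
#' replication scheme.
#'
#' @param fit A [fit_germination()] object.
#' @param seed Integer seed.
#' @param cap Optional maximum number of draws to use (evenly thinned);
#'   recorded in the result's `draws_used` attribute.
#' @return Integer matrix, draws x groups, of replicated germinant counts.
#' @export
posterior_replicates <- function(fit, seed = 1, cap = NULL) {
  fp <- fitted_probabilities(fit)
  S <- nrow(fp$p)
  idx <- seq_len(S)
  if (!is.null(cap) && cap < S) idx <- round(seq(1, S, length.out = cap))
  set.seed(seed)
  p <- fp$p[idx, , drop = FALSE]
  S2 <- nrow(p); N <- ncol(p)
  nmat <- matrix(fp$n, S2, N, byrow = TRUE)
  if (fit$spec$has_od) {
    a <- p * fp$phi[idx]; b <- (1 - p) * fp$phi[idx]
    pg <- matrix(stats::rbeta(S2 * N, a, b), S2, N)
    bad <- !is.finite(pg)
    pg[bad] <- p[bad]
    y <- matrix(stats::rbinom(S2 * N, nmat, pg), S2, N)
  } else {
    y <- matrix(stats::rbinom(S2 * N, nmat, p), S2, N)
  }
  if (fit$spec$has_zi) {
    z <- matrix(stats::rbinom(S2 * N, 1, fp$pi[idx, , drop = FALSE]), S2, N)
    y[z == 1] <- 0L
  }
  structure(y, draws_used = idx)
}

ppc_statistics <- list(
  mean_germ = function(y) mean(y),
  sd_germ = function(y) stats::sd(y),
  n_zero_groups = function(y) sum(y == 0)
)

#' Posterior predictive checks with three summary statistics
#'
#' Computes, for each replicate dataset and for the observed data via the
#' same code path, the mean germinant count across groups, its standard
#' deviation, and the number of zero-germinant groups. A model is
#' considered able to give rise to the data for a statistic when the
#' observed value falls inside the equal-tailed 95% interval of the
#' replicate distribution.
#'
#' @param replicates Matrix from [posterior_replicates()] (>= 200 rows
#'   recommended).
#' @param observed Observed germinant counts (one per group), or a
#'   validated trial table.
#' @return Tibble of class `germ_ppc`: one row per statistic with the
#'   replicate 2.5%/97.5% quantiles, observed value and coverage flag;
#'   replicate values are kept in a list column for plotting.
#' @export
ppc <- function(replicates, observed) {
  if (is.data.frame(observed)) observed <- validate_trials(observed)$n_germinated
  if (nrow(replicates) < 200) {
    warning("fewer than 200 replicates; PPC quantiles will be noisy",
            call. = FALSE)
  }
  purrr::map_dfr(names(ppc_statistics), function(nm) {
    f <- ppc_statistics[[nm]]
    rep_vals <- apply(replicates, 1, f)
    obs <- f(observed)
    q <- stats::quantile(rep_vals, c(0.025, 0.975), names = FALSE)
    tibble::tibble(
      statistic = nm,
      observed = obs,
      lower95 = q[1], upper95 = q[2],
      covered = obs >= q[1] & obs <= q[2],
      replicate_values = list(rep_vals)
    )
  }) |>
    structure(class = c("germ_ppc", "tbl_df", "tbl", "data.frame"))
}

#' Widely applicable information criterion from pointwise log-likelihoods
#'
#' `elpd_waic = sum_i log mean_s exp(ll_si) - sum_i var_s(ll_si)`, with the
#' log-mean-exp computed stably and the sample variance over draws as the
#' effective-parameter penalty.
#'
#' @param pointwise_loglik Draws x observations matrix, or a `germ_fit`.
#' @return List with `elpd_waic`, `p_waic`, and a `pointwise` tibble.
#' @export
waic <- function(pointwise_loglik) {
  ll <- if (inherits(pointwise_loglik, "germ_fit"))
    pointwise_loglik$pointwise_loglik else pointwise_loglik
  if (nrow(ll) < 2) stop("need at least 2 draws", call. = FALSE)
  if (any(!is.finite(ll))) stop("non-finite log-likelihood entries",
                                call. = FALSE)
  lppd_i <- col_log_mean_exp(ll)
  p_i <- apply(ll, 2, stats::var)
  list(elpd_waic = sum(lppd_i) - sum(p_i), p_waic = sum(p_i),
       pointwise = tibble::tibble(lppd = lppd_i, p_waic = p_i,
                                  elpd_waic = lppd_i - p_i))
}

# Probability-weighted-moment fit of the generalized Pareto distribution
# to exceedances z (Hosking & Wallis estimators). Returns shape xi and
# scale sigma; xi is later shrunk toward 0.5 with the standard weakly
# informative adjustment.
gpd_fit_pwm <- function(z) {
  z <- sort(z)
  m <- length(z)
  b0 <- mean(z)
  b1 <- mean(z * (1 - (seq_len(m) - 0.5) / m))
  if (!is.finite(b0) || b0 <= 0) return(list(xi = -1, sigma = 0))
  denom <- b0 - 2 * b1
  if (abs(denom) < .Machine$double.eps * b0) {
    return(list(xi = 10, sigma = b0)) # extremely heavy tail
  }
  xi <- (b0 - 4 * b1) / denom
  sigma <- b0 * (1 - xi)
  list(xi = xi, sigma = max(sigma, .Machine$double.eps))
}

qgpd <- function(p, xi, sigma) {
  if (abs(xi) < 1e-12) -sigma * log1p(-p)
  else sigma / xi * ((1 - p)^(-xi) - 1)
}

#' Pareto-smoothed importance-sampling leave-one-out cross-validation
#'
#' For each observation the importance ratios `exp(-ll_si)` are computed,
#' the largest 20% (capped at `3*sqrt(S)`) are replaced by expected order
#' statistics of a generalized Pareto distribution fitted to them by
#' probability-weighted moments (shape regularized toward 0.5 with the
#' usual `(M k + 10*0.5)/(M + 10)` adjustment, smoothed weights truncated
#' at the raw maximum), and the LOO predictive density is the
#' weight-normalized average of the pointwise likelihoods. Observations
#' with shape diagnostic `k > 0.7`, or with degenerate weights, are
#' flagged rather than dropped.
#'
#' @param pointwise_loglik Draws x observations matrix, or a `germ_fit`.
#' @return List with `elpd_loo`, `p_loo`, and a `pointwise` tibble
#'   (`elpd_loo`, `pareto_k`, `flagged`).
#' @export
psis_loo <- function(pointwise_loglik) {
  ll <- if (inherits(pointwise_loglik, "germ_fit"))
    pointwise_loglik$pointwise_loglik else pointwise_loglik
  if (any(!is.finite(ll))) stop("non-finite log-likelihood entries",
                                call. = FALSE)
  S <- nrow(ll); N <- ncol(ll)
  M <- ceiling(min(0.2 * S, 3 * sqrt(S)))
  lppd_i <- col_log_mean_exp(ll)

  res <- vapply(seq_len(N), function(i) {
    lw <- -ll[, i]
    lw <- lw - max(lw)
    w <- exp(lw)
    k_hat <- -1
    if (M >= 5 && stats::sd(w) > 0) {
      ord <- order(w)
      tail_idx <- ord[(S - M + 1):S]
      u <- w[ord[S - M]]
      z <- w[tail_idx] - u
      if (any(z > 0)) {
        fit <- gpd_fit_pwm(z)
        k_hat <- (M * fit$xi + 10 * 0.5) / (M + 10)
        sm <- u + qgpd((rank(w[tail_idx], ties.method = "first") - 0.5) / M,
                       fit$xi, fit$sigma)
        w[tail_idx] <- pmin(sm, max(w))
      }
    }
    lw_s <- log(w)
    denom <- max(lw_s) + log(sum(exp(lw_s - max(lw_s))))
    num_v <- lw_s + ll[, i]
    num <- max(num_v) + log(sum(exp(num_v - max(num_v))))
    c(elpd = num - denom, k = k_hat)
  }, numeric(2))

  elpd_i <- res["elpd", ]
  k <- res["k", ]
  list(
    elpd_loo = sum(elpd_i),
    p_loo = sum(lppd_i - elpd_i),
    pointwise = tibble::tibble(elpd_loo = elpd_i, pareto_k = k,
                               flagged = k > 0.7)
  )
}

n_parameter_blocks <- function(spec) 1 + spec$has_zi + spec$has_od

#' Compare fitted germination models by WAIC and PSIS-LOO
#'
#' Computes both criteria for each fit and all pairwise differences in
#' LOO expected log predictive density, with standard errors from the
#' pointwise difference vectors. Models whose difference from the
#' top-ranked model is within two standard errors are reported as
#' statistical ties; among ties the preferred model is the one with the
#' fewest likelihood components (base count model, zero-inflation,
#' overdispersion), i.e. the most parsimonious.
#'
#' @param fits Named list of [fit_germination()] objects fitted to the
#'   same observations in the same order.
#' @return Object of class `germ_compare`: `table` (per-model criteria,
#'   ranked), `pairwise` (elpd differences with SEs), and `preferred`.
#' @export
compare_models <- function(fits) {
  stopifnot(is.list(fits), length(fits) >= 1)
  if (is.null(names(fits)) || any(names(fits) == "")) {
    names(fits) <- vapply(fits, function(f) f$spec$family, character(1))
  }
  ns <- vapply(fits, function(f) ncol(f$pointwise_loglik), integer(1))
  if (length(unique(ns)) != 1) {
    stop("fits were made on different numbers of observations",
         call. = FALSE)
  }
  loos <- lapply(fits, psis_loo)
  waics <- lapply(fits, waic)

  tab <- tibble::tibble(
    model = names(fits),
    family = vapply(fits, function(f) f$spec$family, character(1)),
    elpd_loo = vapply(loos, `[[`, numeric(1), "elpd_loo"),
    p_loo = vapply(loos, `[[`, numeric(1), "p_loo"),
    elpd_waic = vapply(waics, `[[`, numeric(1), "elpd_waic"),
    p_waic = vapply(waics, `[[`, numeric(1), "p_waic"),
    max_pareto_k = vapply(loos, function(l) max(l$pointwise$pareto_k),
                          numeric(1)),
    n_blocks = vapply(fits, function(f) n_parameter_blocks(f$spec),
                      numeric(1))
  ) |>
    dplyr::arrange(dplyr::desc(.data$elpd_loo)) |>
    dplyr::mutate(rank = dplyr::row_number())

  pw <- tidyr::crossing(model_a = names(fits), model_b = names(fits)) |>
    dplyr::filter(.data$model_a != .data$model_b) |>
    dplyr::mutate(purrr::map2_dfr(.data$model_a, .data$model_b,
      function(a, b) {
        da <- loos[[a]]$pointwise$elpd_loo
        db <- loos[[b]]$pointwise$elpd_loo
        tibble::tibble(elpd_diff = sum(da - db),
                       se_diff = stats::sd(da - db) * sqrt(length(da)))
      }))

  best <- tab$model[1]
  tied <- tab |>
    dplyr::mutate(
      diff_best = .data$elpd_loo - .data$elpd_loo[1],
      se_best = purrr::map_dbl(.data$model, function(m) {
        if (m == best) return(0)
        pw$se_diff[pw$model_a == best & pw$model_b == m]
      }),
      tied_with_best = abs(.data$diff_best) <= 2 * .data$se_best +
        1e-12 | .data$model == best
    )
  preferred <- tied |>
    dplyr::filter(.data$tied_with_best) |>
    dplyr::arrange(.data$n_blocks, dplyr::desc(.data$elpd_loo)) |>
    dplyr::pull("model") |>
    dplyr::first()

  structure(list(table = tied, pairwise = pw, preferred = preferred),
            class = "germ_compare")
}

#' @export
print.germ_compare <- function(x, ...) {
  cat("<germ_compare> ranking by PSIS-LOO elpd:\n")
  print(dplyr::select(x$table, "model", "elpd_loo", "p_loo",
                      "elpd_waic", "diff_best", "tied_with_best"))
  cat("parsimony-preferred among statistical ties: ", x$preferred, "\n",
      sep = "")
  invisible(x)
}

rank_normalize <- function(x) {
  r <- rank(x, ties.method = "average")
  stats::qnorm((r - 3 / 8) / (length(x) + 1 / 4))
}

split_chain_matrix <- function(x, chain_id) {
  # x: draws vector; returns matrix iterations x (2 * chains), chains
  # split in half (odd lengths drop the middle draw)
  chains <- unique(chain_id)
  halves <- lapply(chains, function(ch) {
    v <- x[chain_id == ch]
    n2 <- floor(length(v) / 2)
    list(v[seq_len(n2)], v[(length(v) - n2 + 1):length(v)])
  })
  m <- unlist(halves, recursive = FALSE)
  sapply(m, identity)
}

rhat_ess_one <- function(x, chain_id) {
  sm <- split_chain_matrix(x, chain_id)
  n <- nrow(sm); m <- ncol(sm)
  if (n < 3) return(c(rhat = NA_real_, ess = NA_real_))
  z <- matrix(rank_normalize(as.vector(sm)), n, m)
  mu <- colMeans(z)
  W <- mean(apply(z, 2, stats::var))
  B <- n * stats::var(mu)
  if (!is.finite(W) || W == 0) {
    rhat <- if (is.finite(B) && B > 0) Inf else NA_real_
    return(c(rhat = rhat, ess = NA_real_))
  }
  var_plus <- (n - 1) / n * W + B / n
  rhat <- max(1, sqrt(var_plus / W)) # conventionally reported >= 1

  # bulk ESS via Geyer initial monotone positive sequence on the
  # rank-normalized splits
  acov <- sapply(seq_len(m), function(j) {
    a <- stats::acf(z[, j], lag.max = n - 1, type = "covariance",
                    plot = FALSE, demean = TRUE)$acf[, 1, 1]
    a
  })
  mean_acov <- rowMeans(acov)
  rho <- 1 - (W - mean_acov) / var_plus
  rho[1] <- 1
  # paired sums
  max_t <- 1
  t <- 1
  while (t + 2 <= length(rho)) {
    pair <- rho[t + 1] + rho[t + 2]
    if (pair < 0) break
    max_t <- t + 2
    t <- t + 2
  }
  rho_use <- if (max_t >= 2) rho[2:max_t] else numeric(0)
  if (length(rho_use) > 0) {
    # enforce monotone decreasing paired sums
    ps <- rho_use[seq(1, length(rho_use) - length(rho_use) %% 2, by = 2)] +
      rho_use[seq(2, length(rho_use), by = 2)][
        seq_len(floor(length(rho_use) / 2))]
    ps <- cummin(ps)
    tau <- 1 + 2 * sum(pmax(ps, 0))
  } else tau <- 1
  ess <- m * n / tau
  c(rhat = rhat, ess = min(ess, m * n))
}

#' Convergence diagnostics: split R-hat and bulk effective sample size
#'
#' Rank-normalized split-R-hat and bulk ESS per parameter. A fit is
#' flagged unless all model-parameter R-hats are below 1.01; constant
#' chains at different values report `Inf`.
#'
#' @param fit A `germ_fit`, or a draws matrix.
#' @param chain_id Integer chain label per draw (required when `fit` is a
#'   matrix).
#' @return Tibble with columns `parameter`, `rhat`, `ess_bulk`.
#' @export
convergence <- function(fit, chain_id = NULL) {
  if (inherits(fit, "germ_fit")) {
    draws <- fit$draws; chain_id <- fit$chain_id
  } else {
    draws <- as.matrix(fit)
    if (is.null(chain_id)) stop("chain_id required", call. = FALSE)
  }
  if (length(unique(chain_id)) < 2) {
    stop("convergence diagnostics need at least 2 chains", call. = FALSE)
  }
  out <- t(apply(draws, 2, rhat_ess_one, chain_id = chain_id))
  tibble::tibble(parameter = colnames(draws),
                 rhat = out[, "rhat"], ess_bulk = out[, "ess"])
}
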