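# Shared fixtures, built in code at test time.

ref_trial_row <- function(group_id = "g1", n_planted = 10L,
                          n_germinated = 3L, depth_cm = 5,
                          provenance = "LocA", temperature = "27C/15C",
                          media = "sand_soil", pretreated = "no",
                          photoperiod = "12L/12D") {
  tibble::tibble(group_id = group_id, n_planted = n_planted,
                 n_germinated = n_germinated, depth_cm = depth_cm,
                 provenance = provenance, temperature = temperature,
                 media = media, pretreated = pretreated,
                 photoperiod = photoperiod)
}

tiny_cal <- function() {
  calibration_from_truth(c(0, 4, 0.05), 5, seq(1, 29, by = 2))
}

# A minimal hand-built germ_fit whose "posterior" is whatever draws we
# say it is; used to test prediction/replication machinery against
# closed forms.
fake_fit <- function(trials, spec, cal, draws_list, chains = 2) {
  design <- build_design(trials, spec$reference_levels)
  cols <- c("beta0", "beta_age", paste0("beta[", colnames(design$X), "]"))
  if (spec$has_zi) {
    cols <- c(cols, "alpha0", if (spec$zero_inflation_age_slope) "alpha1")
  }
  if (length(design$provenance_levels) > 1) {
    cols <- c(cols, paste0("u[", design$provenance_levels, "]"),
              "sigma_loc")
  }
  if (spec$has_od) cols <- c(cols, "phi")
  S <- length(draws_list[[1]])
  draws <- matrix(0, S, length(cols), dimnames = list(NULL, cols))
  for (nm in names(draws_list)) draws[, nm] <- draws_list[[nm]]
  structure(list(
    draws = draws, chain_id = rep(seq_len(chains), length.out = S),
    pointwise_loglik = NULL, spec = spec, design = design, cal = cal,
    sampler_config = list(chains = chains, iter = S, warmup = 0, thin = 1,
                          seed = 1),
    diagnostics = tibble::tibble(parameter = cols, rhat = 1,
                                 ess_bulk = S),
    flagged = FALSE
  ), class = "germ_fit")
}

# One small, well-behaved beta-binomial fit on synthetic data, memoized
# across test files (several suites need a real posterior).
small_bb_fit <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    cfg <- study_preset(
      sparsity = list(max_start = 4, min_len = 4, max_len = 8,
                      p_include = 0.8, max_combos = 2))
    sim <- simulate_trials(cfg, seed = 11)
    spec <- germ_model_spec("BB", use_errors_in_variables = FALSE)
    fit <- fit_germination(sim$trials, cfg$calibration, spec,
                           chains = 2, iter = 2500, warmup = 800,
                           thin = 2, seed = 5)
    cache <<- list(fit = fit, sim = sim, cfg = cfg)
    cache
  }
})
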