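#' Configuration for the germination-trial data generator
#'
#' Describes a complete generating process for germination trials: the
#' count family and its true parameters, the depth-to-age truth, the
#' design structure (number of 2-cm depth slices, source locations,
#' treatment level sets), the per-group seed-count distribution, and the
#' sparsity pattern controlling which depth x location x treatment cells
#' are observed. All downstream simulators are pure functions of a config
#' and a seed.
#'
#' @param family Count family: `"BIN"`, `"ZIB"`, `"BB"` or `"ZIBB"`.
#' @param beta0 True intercept (logit scale).
#' @param beta_age True age slope per standardized age unit (logit scale).
#' @param beta_treat Named vector of treatment-dummy coefficients; names
#'   use the `factor:level` convention of [build_design()]. Missing
#'   dummies are taken as 0.
#' @param sigma_loc SD of the provenance random intercept.
#' @param phi Beta-binomial precision (BB/ZIBB families).
#' @param alpha0,alpha1 Zero-inflation intercept and age slope (logit
#'   scale; ZIB/ZIBB families; `alpha1` used by ZIBB).
#' @param gamma True depth-to-age quadratic coefficients (length 3).
#' @param sigma_eps True residual SD of the age calibration (years).
#' @param n_intervals Number of 2-cm depth slices available (slice `d`
#'   has midpoint `2 d - 1` cm).
#' @param locations Character vector of provenance labels.
#' @param reference_levels As in [default_reference_levels()].
#' @param seeds_per_group Length-2 range; group sizes are drawn
#'   log-uniformly between the two (mimicking the heavy right skew of
#'   seeds-per-cell in stratified collections).
#' @param sparsity List controlling imbalance: each field location
#'   occupies a contiguous run of depth slices (`max_start`, `min_len`,
#'   `max_len`), keeps each slice with probability `p_include`, and is
#'   observed under 1 to `max_combos` treatment combinations.
#' @param standardization_depths Depth grid (cm) defining the age
#'   standardization constants of the truth (see
#'   [calibration_from_truth()]).
#' @return Object of class `germ_generator_config`.
#' @export
generator_config <- function(family = c("BB", "BIN", "ZIB", "ZIBB"),
                             beta0 = -1.8,
                             beta_age = -1.3,
                             beta_treat = c(
                               "temperature:25C" = -0.4,
                               "temperature:30C" = 0.3,
                               "temperature:20C/15C" = -0.6,
                               "media:sand" = 0.2,
                               "media:growth_media" = -2.0,
                               "pretreated:yes" = -2.4,
                               "photoperiod:15L/9D" = 0.4,
                               "photoperiod:0L/24D" = -0.4),
                             sigma_loc = 0.7,
                             phi = 5,
                             alpha0 = -0.85,
                             alpha1 = 0.5,
                             gamma = c(0, 4.5, 0.04),
                             sigma_eps = 6,
                             n_intervals = 75,
                             locations = c("Kirkpatrick", "Corn Island",
                                           "Hog Island", "Virginia",
                                           "Bay Bridge", "Eastern Shore",
                                           "Blackwater", "Taylors Island",
                                           "Delaware Bay", "Sellman Creek",
                                           "Greenhouse"),
                             reference_levels = default_reference_levels(),
                             seeds_per_group = c(1, 600),
                             sparsity = list(max_start = 6, min_len = 5,
                                             max_len = 14, p_include = 0.7,
                                             max_combos = 4),
                             standardization_depths = seq(1, 35, by = 2)) {
  family <- match.arg(family)
  stopifnot(sigma_loc >= 0, phi > 0, length(gamma) == 3, sigma_eps >= 0,
            n_intervals >= 1, length(seeds_per_group) == 2,
            all(seeds_per_group >= 1))
  cal <- calibration_from_truth(gamma, sigma_eps, standardization_depths)
  structure(list(
    family = family, beta0 = beta0, beta_age = beta_age,
    beta_treat = beta_treat, sigma_loc = sigma_loc, phi = phi,
    alpha0 = alpha0, alpha1 = alpha1,
    gamma = gamma, sigma_eps = sigma_eps, calibration = cal,
    n_intervals = n_intervals, locations = locations,
    reference_levels = reference_levels,
    seeds_per_group = seeds_per_group, sparsity = sparsity
  ), class = "germ_generator_config")
}

#' Study-structured generator preset
#'
#' The default [generator_config()] with the structure of the motivating
#' study: 75 possible depth slices, 11 provenances (one of them modern
#' greenhouse accessions at the surface), four unbalanced treatment
#' factors, group sizes spanning three orders of magnitude, a beta-binomial
#' count process with an age slope of -1.3 per standardized age unit, a
#' provenance SD of 0.7 and precision 5, and a depth-to-age truth whose
#' dating example at 20 cm (mean about 106 yr, 95% range about
#' [94, 118]) mirrors a Pb-210 chronology of a mid-Atlantic brackish
#' marsh.
#'
#' @param family Count family (default beta-binomial).
#' @param ... Overrides passed to [generator_config()].
#' @return A `germ_generator_config`.
#' @export
study_preset <- function(family = "BB", ...) {
  generator_config(family = family, ...)
}

all_treatment_combos <- function(reference_levels) {
  lv <- trial_levels()
  combos <- expand.grid(temperature = lv$temperature, media = lv$media,
                        pretreated = lv$pretreated,
                        photoperiod = lv$photoperiod,
                        stringsAsFactors = FALSE)
  tibble::as_tibble(combos)
}

rtrunc_norm0 <- function(n, mean, sd) {
  if (all(sd <= 0)) return(pmax(mean, 0))
  lo <- stats::pnorm(0, mean, sd)
  stats::qnorm(lo + stats::runif(n) * (1 - lo), mean, sd)
}

#' Simulate dated sediment cores
#'
#' Draws per-core depth grids and ages on the configured quadratic with
#' truncated normal residual noise, emulating replicate radioisotope
#' chronologies from the same marsh.
#'
#' @param cfg A [generator_config()].
#' @param n_cores Number of cores.
#' @param depths_per_core Dated depths per core.
#' @param seed Integer seed.
#' @return Tibble of dating records (`core_id`, `depth_cm`, `age_years`).
#' @export
simulate_core_dating <- function(cfg, n_cores = 3, depths_per_core = 15,
                                 seed = 1) {
  stopifnot(n_cores >= 1, depths_per_core >= 1)
  set.seed(seed)
  purrr::map_dfr(seq_len(n_cores), function(k) {
    step <- 30 / depths_per_core
    depths <- seq(step, 30, length.out = depths_per_core) +
      (k - 1) * step / n_cores
    mu <- quad_age(cfg$gamma, depths)
    tibble::tibble(
      core_id = paste0("core", k),
      depth_cm = depths,
      age_years = rtrunc_norm0(length(depths), mu, cfg$sigma_eps)
    )
  })
}

#' Simulate a germination-trial dataset with known truth
#'
#' Realizes the full generating process: provenance random intercepts,
#' one latent seed age per occupied depth slice (drawn around the
#' quadratic truth), the sparsity pattern of which location x slice x
#' treatment cells exist, log-uniform group sizes, and counts from the
#' configured family. Greenhouse-labelled locations are placed at the
#' surface (depth 0, age 0).
#'
#' @param cfg A [generator_config()].
#' @param seed Integer seed.
#' @return List with `trials` (a validated trial tibble) and `truth`
#'   (sealed record of every latent quantity: `u`, per-slice latent ages,
#'   per-group probabilities, and the config parameters). Pipeline code
#'   should only ever consume `trials`.
#' @export
simulate_trials <- function(cfg, seed = 1) {
  stopifnot(inherits(cfg, "germ_generator_config"))
  set.seed(seed)
  sp <- cfg$sparsity
  combos <- all_treatment_combos(cfg$reference_levels)
  u <- stats::rnorm(length(cfg$locations), 0, cfg$sigma_loc)
  names(u) <- cfg$locations

  cells <- purrr::map_dfr(cfg$locations, function(loc) {
    if (grepl("Greenhouse", loc, ignore.case = TRUE)) {
      ivs <- 0L # surface
      nc <- sample(1:2, 1)
    } else {
      start <- sample.int(sp$max_start, 1)
      len <- sample(seq(sp$min_len, sp$max_len), 1)
      ivs <- intersect(start:(start + len - 1), seq_len(cfg$n_intervals))
      ivs <- ivs[stats::runif(length(ivs)) < sp$p_include]
      if (length(ivs) == 0) ivs <- start
      nc <- sample.int(sp$max_combos, 1)
    }
    ci <- sample.int(nrow(combos), nc)
    tidyr::crossing(provenance = loc, interval = ivs, combo = ci)
  })

  # one latent age per occupied depth slice, shared by all groups there
  occupied <- sort(unique(cells$interval[cells$interval > 0]))
  mids <- 2 * occupied - 1
  x_latent <- rtrunc_norm0(length(occupied),
                           quad_age(cfg$gamma, mids), cfg$sigma_eps)
  names(x_latent) <- occupied
  age_of <- function(iv) ifelse(iv == 0, 0, x_latent[as.character(iv)])

  lo <- log(cfg$seeds_per_group[1]); hi <- log(cfg$seeds_per_group[2])
  n_planted <- pmax(1L, as.integer(round(exp(stats::runif(nrow(cells), lo, hi)))))

  trt <- combos[cells$combo, ]
  trials <- dplyr::bind_cols(
    tibble::tibble(
      group_id = sprintf("g%04d", seq_len(nrow(cells))),
      n_planted = n_planted,
      depth_cm = ifelse(cells$interval == 0, 0, 2 * cells$interval - 1),
      provenance = cells$provenance
    ),
    trt
  )

  xs <- standardize_age(cfg$calibration, age_of(cells$interval))
  design <- build_design(
    dplyr::mutate(trials, n_germinated = 0L),
    cfg$reference_levels
  )
  bt <- stats::setNames(numeric(ncol(design$X)), colnames(design$X))
  keep <- intersect(names(cfg$beta_treat), names(bt))
  bt[keep] <- cfg$beta_treat[keep]
  eta <- cfg$beta0 + cfg$beta_age * xs +
    drop(design$X %*% bt) + u[trials$provenance]
  p <- stats::plogis(eta)
  pi <- if (cfg$family %in% c("ZIB", "ZIBB")) {
    stats::plogis(cfg$alpha0 +
                    (if (cfg$family == "ZIBB") cfg$alpha1 * xs else 0))
  } else NULL
  y <- rcounts_family(cfg$family, trials$n_planted, p, cfg$phi, pi)
  trials$n_germinated <- as.integer(y)
  trials <- validate_trials(trials[, trial_columns])

  list(
    trials = trials,
    truth = list(
      family = cfg$family, beta0 = cfg$beta0, beta_age = cfg$beta_age,
      beta_treat = bt, sigma_loc = cfg$sigma_loc, phi = cfg$phi,
      alpha0 = cfg$alpha0, alpha1 = cfg$alpha1, u = u,
      x_latent = x_latent, p = p, pi = pi,
      gamma = cfg$gamma, sigma_eps = cfg$sigma_eps,
      age_center = cfg$calibration$age_center,
      age_scale = cfg$calibration$age_scale,
      seed = seed
    )
  )
}

#' Simulate tetrazolium viability assay records
#'
#' Binomial draws from a logistic decay of viability with depth. The
#' defaults (intercept -0.72, slope -0.12 per cm, 470 seeds over 15
#' depths) give a pooled viable fraction near 10 percent, the order
#' observed when staining non-germinating seeds from a century-scale
#' seed bank.
#'
#' @param intercept,slope Logit-scale intercept and per-cm depth slope.
#' @param depths Depth grid (cm).
#' @param n_per_depth Seeds tested per depth (recycled).
#' @param seed Integer seed.
#' @return Tibble of records (`trial_id`, `depth_cm`, `n_tested`,
#'   `n_viable`).
#' @export
simulate_tetrazolium <- function(intercept = -0.72, slope = -0.12,
                                 depths = seq(1, 29, by = 2),
                                 n_per_depth = c(rep(32, 5), rep(31, 10)),
                                 seed = 1) {
  stopifnot(all(n_per_depth >= 1))
  set.seed(seed)
  n <- rep_len(n_per_depth, length(depths))
  p <- stats::plogis(intercept + slope * depths)
  tibble::tibble(
    trial_id = paste0("tz", seq_along(depths)),
    depth_cm = depths,
    n_tested = as.integer(n),
    n_viable = stats::rbinom(length(depths), n, p)
  )
}
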