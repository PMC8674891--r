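# marshseed

Hierarchical Bayesian analysis of germination trials on soil-stored
seeds from stratified marsh sediment.

Coastal marshes bury each year's seed rain under new sediment, building
century-deep, datable seed banks. Germination trials on seeds sieved
from dated core slices are the non-destructive way to estimate how
viability decays with age — but the counts are messy: most trial groups
produce zero germinants, group sizes span three orders of magnitude,
treatments and source marshes differ, and seed age is only known
through an uncertain depth-to-age calibration. `marshseed` is for
ecologists doing this kind of resurrection-ecology work: it fits and
compares four hierarchical count models of germination success and asks
whether the excess zeros are a separate (zero-inflation) process or
ordinary overdispersion.

The observation is y germinants of n planted in a *trial group* (shared
depth slice, provenance, treatment combination). All four models share

logit(p_i) = β₀ + β_age·x_d(i) + X_i β + u_ℓ(i),  u_ℓ ~ N(0, σ_loc²)

where x_d is the (standardized, latent) seed age of depth slice d with
the calibration posterior x ~ N(γ₀ + γ₁d + γ₂d², σ_ε²) as its prior
("errors in variables"), X are treatment dummies and u are provenance
random intercepts. The likelihood factorially adds zero-inflation (ZI)
and beta-binomial overdispersion (OD): BIN (−/−), ZIB (+/−), BB (−/+),
ZIBB (+/+). Fits are compared by posterior predictive checks on three
summary statistics (mean, SD, number of zero-count groups) and by
WAIC / PSIS-LOO. A separate module analyses tetrazolium staining of
non-germinating seeds (binomial GLM of viability on depth), and a
synthetic-data generator reproduces the whole study structure with
known truth so every stage is testable.

## Worked example

```r
library(marshseed)

# a study-structured synthetic dataset with known truth
cfg   <- study_preset()            # beta-binomial truth
sim   <- simulate_trials(cfg, seed = 3)
cores <- simulate_core_dating(cfg, seed = 3)

# depth -> age calibration (exact conjugate posterior)
cal <- fit_age_calibration(cores, n_draws = 4000, seed = 3)
age_distribution(cal, 20)
#> <age_dist> depth 20 cm: mean 104.3 yr, sd 4.76, 95% [94.95, 113.7]

# fit the beta-binomial model (scaled-down sampler settings)
fit <- fit_germination(sim$trials, cal, germ_model_spec("BB"),
                       chains = 2, iter = 2000, warmup = 800,
                       thin = 2, seed = 7)
dplyr::filter(tidy(fit, latent = FALSE),
              term %in% c("beta_age", "sigma_loc", "phi"))
#> # A tibble: 3 × 7
#>   term      estimate std.error conf.low conf.high  rhat ess_bulk
#>   <chr>        <dbl>     <dbl>    <dbl>     <dbl> <dbl>    <dbl>
#> 1 beta_age    -1.64      0.270   -2.20      -1.15  1.04     92.0
#> 2 sigma_loc    0.762     0.361    0.161      1.56  1.05     36.2
#> 3 phi          6.75      1.74     3.86     10.5    1.00    189.
```

A seed buried at 20 cm is estimated to be ~104 years old (95% interval
95–114 yr) under this simulated chronology. The fitted age slope is per
*standardized* age unit — here `cal$age_scale` ≈ 52 yr, so −1.6 logits
per 52 years of burial; always read slopes together with the scale the
calibration reports. `phi` ≈ 6.8 (95% CI [3.9, 10.5]) recovers the
generating precision 5, and 69% of the simulated groups have zero
germinants — heavy zero loading that the overdispersed model produces
without any zero-inflation term.

Model comparison and checking:

```r
fit_bin <- fit_germination(sim$trials, cal, germ_model_spec("BIN"),
                           chains = 2, iter = 2000, warmup = 800,
                           thin = 2, seed = 7)
cmp <- compare_models(list(BIN = fit_bin, BB = fit))
cmp$preferred            # "BB" on overdispersed data
ppc(posterior_replicates(fit_bin, seed = 1), sim$trials$n_germinated)
#>   statistic     observed lower95 upper95 covered
#> 1 mean_germ         7.03    6.59    7.49 TRUE
#> 2 sd_germ          25.9    23.1    26.9  TRUE
#> 3 n_zero_groups   126     100     115    FALSE
# the binomial fit reproduces the mean but misses the zero count

autoplot(decay_curve(fit))            # germination decay with age
autoplot(provenance_deviations(fit))  # random-intercept HPD bars
```

The packaged decade-by-location seed-count table is available via
`load_table2()` (10,588 seeds; its loader re-checks every printed
marginal total), and `run_pipeline(out_dir)` chains
calibrate → fit × 4 → PPC → compare → predict → viability on any
inputs, writing CSV artifacts plus a hash-and-seed manifest.

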