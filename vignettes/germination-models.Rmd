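---
title: "Hierarchical models of germination in soil-stored seed banks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical models of germination in soil-stored seed banks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(marshseed)
```

## The estimation problem

Tidal marshes accumulate sediment year after year, burying each season's
seed rain in a datable stratigraphic archive. Germination trials on seeds
sieved from dated core slices are the non-destructive way to ask how long
those seeds stay alive — but a trial's outcome (y germinants out of n
planted) confounds several processes: genuine viability decay with age,
the experimental conditions used to break dormancy, the seeds' source
marsh, dating uncertainty, and unmeasured seed-quality heterogeneity.
`marshseed` estimates viability decay while accounting for all of these,
and asks a model-structure question on the way: do the many zero-count
trials reflect a distinct excess-zero process (inviable groups), or
ordinary overdispersion?

The observation unit is a *trial group*: all seeds sharing one depth
slice, one provenance, and one treatment combination (temperature,
medium, pretreatment, photoperiod).

## Depth-to-age calibration

Radioisotope profiles of replicate cores give depth/age pairs, pooled
into a quadratic

$$x = \gamma_0 + \gamma_1 d + \gamma_2 d^2 + \epsilon,\qquad
\epsilon \sim \mathrm{N}(0, \sigma_\epsilon^2).$$

`fit_age_calibration()` samples the posterior exactly under the standard
noninformative prior (flat coefficients, $1/\sigma^2$): a scaled
inverse-$\chi^2$ draw for $\sigma^2$ and a conditional normal draw for
$\gamma$. This conjugate route was chosen over MCMC because it is exact,
instant, and trivially reproducible. `age_distribution()` then mixes,
over posterior draws, normal age distributions truncated below at zero
(buried seeds cannot be younger than the surface).

Ages enter the germination models *standardized*: centered and scaled by
the mean and SD of the posterior-mean predicted ages over the dated
depth grid. A slope of $-1.3$ therefore means "1.3 logits per standard
deviation of age across the dated profile" — roughly per 50–100 years
for a marsh accreting a few mm per year. The scale is reported with
every calibration (`age_scale`) because slopes are only interpretable
with it; the choice to standardize (rather than use raw years or
centuries) keeps coefficient priors comparable across covariates and is
stated explicitly wherever a slope is printed.

## The four count models

All four share the mean structure

$$\mathrm{logit}(p_i) = \beta_0 + \beta_{\mathrm{age}} x_{d(i)}
  + X_i \beta + u_{\ell(i)},\qquad u_\ell \sim \mathrm{N}(0, \sigma_{\mathrm{loc}}^2),$$

with treatment-dummy coding against a reference profile (27/15 °C,
sand/soil, untreated, 12 h light) and a provenance random intercept.
The factorial structure of the likelihoods is zero-inflation (ZI) ×
overdispersion (OD):

| family | likelihood | ZI | OD |
|---|---|---|---|
| `BIN` | binomial | – | – |
| `ZIB` | zero-inflated binomial | ✓ | – |
| `BB`  | beta-binomial | – | ✓ |
| `ZIBB`| zero-inflated beta-binomial | ✓ | ✓ |

The beta-binomial is parameterized by mean $p$ and precision $\phi$
(variance $np(1-p)\,[1 + (n-1)/(\phi+1)]$). Zero inflation adds a
structural-zero probability $\pi$ with
$\mathrm{logit}(\pi_i) = \alpha_0$ for `ZIB` and
$\alpha_0 + \alpha_1 x_{d(i)}$ for `ZIBB` — the latter asks whether the
excess-zero process itself ages. An experiment-assay random effect is
deliberately absent: in the motivating data it explained no appreciable
variation once treatments were controlled.

### Errors in variables

Seed age is not known, only its depth slice is. With
`use_errors_in_variables = TRUE` (the default), each occupied depth
slice gets a latent age with the calibration posterior as its prior, so
dating uncertainty widens every downstream interval. One latent age is
shared by all groups in a slice, matching how seeds were pooled by
slice. Each chain conditions on one random calibration draw (cheap, and
between-chain mixing integrates over draws); setting
`marginalize_calibration = TRUE` instead marginalizes the latent-age
prior over the whole calibration posterior (subsampled to 200 draws)
within every chain. The marginal prior is implemented by augmentation —
a calibration-draw indicator with a uniform prior, Gibbs-sampled from
its exact conditional every iteration — because under the plain mixture
prior single-site latent-age moves cannot switch the whole age vector
between calibration draws and the chain understates the dating
uncertainty. The latent-age prior is left untruncated normal — the
likelihood cares only about the standardized age, and truncation at
zero would bite only for surface slices where the prior SD already
dwarfs the age signal.

### Priors

Defaults (`default_priors()`, all overridable):

* coefficients (incl. zero-inflation): Normal(0, 2.5²) on the logit
  scale — the conventional weakly informative choice;
* provenance SD: Half-Normal(0, 1);
* beta-binomial precision: uniform on the intraclass correlation
  $\rho = 1/(1+\phi)$, i.e. $p(\phi) = (1+\phi)^{-2}$.

The precision prior deserves a note. The binomial is the
$\phi \to \infty$ boundary of the beta-binomial, and the model-selection
question "is there overdispersion?" is only answerable if the prior
gives that boundary real mass. A light-tailed prior on $\phi$ itself
(an exponential, say) makes $\phi > 10^3$ essentially impossible, so on
purely binomial data with large groups the beta-binomial would be
forced to stay visibly overdispersed and would lose predictive score
spuriously. Uniform-on-$\rho$ is the parameterization under which
"no overdispersion" is an ordinary parameter value, not an unreachable
limit.

### Sampling

`fit_germination()` runs an adaptive Metropolis-within-Gibbs sampler
written for this model family:

* a joint random-walk move over the fixed-effect block whose proposal
  covariance adapts to the sampled history (Haario-style), plus a
  coordinate-wise refinement sweep targeting 44% acceptance;
* single-site moves for provenance intercepts and latent ages, touching
  only the rows they act on;
* log-scale moves for $\sigma_{\mathrm{loc}}$ and $\phi$;
* a likelihood-invariant translation move trading the global intercept
  against all provenance deviations — the standard reparameterization
  trick for hierarchical intercepts, which removes their strong
  posterior correlation.

Adaptation stops at the end of warmup, so retained draws come from a
fixed kernel. Initialization is at zero coefficients, $\sigma = 0.5$,
$\phi = 5$, latent ages at calibration means, jittered per chain; a
non-finite starting log posterior is retried up to 20 times and then
reported as an initialization error. The default configuration
(3 chains × 10,000 iterations, 2,000 warmup, thinning 3) matches the
study-scale setting; the simulation studies in the test suite use 2
chains × 1,500–4,000 iterations, which the diagnostics show is enough
at those problem sizes. Every fit carries rank-normalized split R-hat
and bulk ESS for all parameters and is *flagged* (never silently
reported) if any model-parameter R-hat reaches 1.01.

A gradient-based sampler (NUTS) would be the field's default for this
model; the random-walk scheme was chosen because it is self-contained,
exactly reproducible under a seed, and fast enough at the problem sizes
the package targets (hundreds of groups, dozens of latent ages).

## Model checking and comparison

`posterior_replicates()` simulates one dataset per retained draw using
only that draw's parameters; `ppc()` compares three statistics between
replicates and data — mean germinant count, SD of germinant counts, and
the number of zero-germinant groups — using equal-tailed 95% intervals,
with the observed value computed by the same code path as the
replicates. These three statistics are the diagnostic trio for the
ZI/OD question: a binomial fit typically matches the mean but not the
spread or the zero count of overdispersed data, and a zero-inflated
binomial buys the zeros at the cost of the mean.

`waic()` and `psis_loo()` are computed from the stored pointwise
log-likelihood matrix. The PSIS implementation smooths the top
$\min(0.2S, 3\sqrt{S})$ importance ratios per observation with a
generalized Pareto fit by probability-weighted moments, regularizes the
shape by the usual $(Mk + 5)/(M + 10)$-style shrinkage toward 0.5,
truncates smoothed weights at the raw maximum, and reports $\hat k$,
flagging observations above 0.7. `compare_models()` reports pairwise
elpd differences with standard errors from the pointwise vectors; among
models within two standard errors of the best it *prefers the most
parsimonious* (fewest likelihood components), mirroring how a
practitioner reads such a table — ties are reported, not broken
silently.

## Predictions and the viability assay

`predict_probability()`, `marginal_treatment_effect()`,
`provenance_deviations()` (with shortest-interval HPD bars at 90/95%)
and `decay_curve()` summarize the fitted model on the probability
scale. The decay curve's `"planted"` weighting averages
condition-specific predictions with weights proportional to seeds
planted under each observed condition; the weighting is an explicit
choice (the natural alternative — equal weights per condition — is one
argument away) because condition-averaged "overall" curves are
otherwise ambiguous.

The tetrazolium module is deliberately plain: staining counts are a
direct viability readout, so `fit_viability_glm()` is a
maximum-likelihood binomial GLM of viable/tested on depth with a
delta-method Wald band, and `overall_viable_fraction()` is a pooled
proportion with a Clopper–Pearson interval. Depth, not calibrated age,
is the regressor by default (the assay question is about the profile,
not the chronology); an age-scale variant is available via the `cal`
argument. Complete separation is detected from exploding coefficients
and handled by a half-success/half-failure augmentation at the extreme
depths, flagged in the result.

## What the generator emulates — and what it does not

`study_preset()` encodes the study conditions the package is
tested under: 75 possible 2-cm depth slices, 11 provenances including
modern greenhouse accessions anchored at the surface (depth 0, age 0),
four treatment factors with the reference profile above, group sizes
log-uniform on 1–600 seeds, and severe imbalance — each location
occupies a random contiguous run of shallow-to-mid slices and only 1–4
treatment combinations. The depth-to-age truth
$(\gamma_0, \gamma_1, \gamma_2, \sigma_\epsilon) = (0, 4.5, 0.04, 6)$
makes a 20-cm seed about 106 years old with a 95% range near [94, 118],
matching a published Pb-210 chronology for this kind of marsh. The
count-model truth (age slope −1.3 per standardized age unit, provenance
SD 0.7, precision 5) yields a zero-germinant share of roughly 0.54–0.73
across seeds, bracketing the 59.1% observed in the motivating data; the
intercept (−1.8) was set so that this zero share and the
condition-averaged modern germination probability (~20%) land on the
study's values, and the treatment effects echo the reported ordering
(growth medium and pretreatment strongly negative, sand slightly
positive, mild temperature/photoperiod effects). The tetrazolium preset
(intercept −0.72, slope −0.12 per cm, 470 seeds) pools to about 10%
viable.

What passing tests on these simulations do **not** show: that real
germination data meet the model's assumptions. The generator draws
group sizes independently of depth (real collections plant more seeds
where more were found), uses a single shared depth-age law across
marshes (as the motivating analysis did, and as its authors flag as a
limitation), and contains no temporal genetic structure. Parameter
recovery here demonstrates correctness of the machinery, not realism of
the model.

## Numerical choices and problem sizes

* All pmfs are computed in log space (`lgamma`/`lbeta`, log-sum-exp at
  the zero-inflation mixture); probabilities are clamped to
  $[10^{-12}, 1-10^{-12}]$ inside likelihood evaluation only.
* The test suite's simulation studies use 100–350 groups per dataset,
  2 chains, and 1,200–4,000 iterations per fit — sizes at which a fit
  takes seconds to ~20 s and the full suite stays comfortably
  desk-scale while leaving the diagnostics unambiguous.
* HPD intervals use the shortest contiguous window on sorted draws;
  equal-tailed intervals elsewhere.
* Degenerate inputs: a single provenance drops the random intercept
  (it would be confounded with the global intercept); constant-age
  cores still calibrate (slopes concentrate at zero); a point-mass
  calibration (σ → 0) degenerates `age_distribution()` to the
  quadratic's value exactly.

## Known limitations

* The sampler is serial R; study-scale configurations (3 × 10,000 on
  ~300 groups with latent ages) take minutes, not seconds.
* PSIS-LOO with random-walk draws needs the stored draw count to be
  moderate (thousands); $\hat k$ flags are reported and should be
  respected.
* Zero inflation is modeled at the trial-group level (a whole group
  excess zero); a seed-level viability mixture is a different model and
  out of scope.
* The per-chain calibration-draw scheme understates dating uncertainty
  if very few chains are run; use more chains or
  `marginalize_calibration = TRUE` when the calibration posterior is
  wide.
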