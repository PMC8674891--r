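Package: marshseed
Title: Hierarchical Bayesian Models of Germination in Soil-Stored Seed Banks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating the viability of soil-stored seeds from
    germination trials of stratified seed-bank cores. Provides an
    errors-in-variables depth-to-age calibration from dated sediment cores,
    four hierarchical Bayesian count models of germination success (binomial,
    zero-inflated binomial, beta-binomial, and zero-inflated beta-binomial)
    with treatment fixed effects and a provenance random intercept, posterior
    predictive checks, WAIC and Pareto-smoothed importance-sampling
    leave-one-out model comparison, post-fit prediction surfaces, a binomial
    regression for tetrazolium viability assays, and a synthetic-data
    generator that emulates the unbalanced structure of multi-decade
    germination studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Roxygen: list(markdown = TRUE)
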