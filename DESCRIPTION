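Package: migrascale
Title: Cross-Scale Gravity Modelling of Migration Flows
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Fits fine-scale gravity-type spatial interaction models of
    human migration to origin-destination flows observed only at a coarser
    administrative level. Fine-unit migration proportions follow a
    logistic-linear model in distance, population, and socio-economic
    covariates; they are aggregated by population weighting into
    coarse-pair proportions that enter a binomial likelihood. Estimation
    is Bayesian, via adaptive random-walk Metropolis-Hastings with
    Gelman-Rubin convergence diagnostics, DIC-based forward covariate
    selection, and cross-scale validation by aggregation and uniform
    disaggregation of flows. Includes raster preprocessing primitives
    (neighbour-mean imputation, block resampling, zonal statistics,
    population-weighted centroids) and a synthetic multi-level landscape
    generator with known ground truth for end-to-end calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils
Suggests: testthat (>= 3.0.0), withr, yaml, optparse, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
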