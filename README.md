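# migrascale

Cross-scale gravity modelling of migration flows: fit a fine-scale
(municipality-level) spatial interaction model when origin–destination
migration counts are only observed at a coarser (department) level.

Human migration data from censuses are typically released between coarse
administrative units, while applications — epidemic seeding, service
planning, connectivity proxies — need fine-scale flows. `migrascale`
bridges the scales inside the likelihood: fine-pair migration proportions
follow a logistic-linear gravity model,

    logit(v_ij) = β0 + β1·DIST_ij + β2·POP_i + β3·POP_j + Σk βk·X_k,

they are aggregated by population weighting to coarse pairs,

    P_IJ = Σ_{i∈I} N_i Σ_{j∈J} v_ij / Σ_{i∈I} N_i,

and the observed coarse counts enter a binomial likelihood
`M_IJ ~ Binomial(n_I, P_IJ)` for `I ≠ J`, with `n_I` the origin's observed
(sampled) population. Estimation is Bayesian — adaptive random-walk
Metropolis–Hastings with Cauchy(0, 2.5) priors on standardized slopes
(Cauchy(0, 10) intercept), Gelman–Rubin convergence diagnostics, DIC-based
forward covariate selection — and validation works by aggregating fine
predictions upward and uniformly disaggregating coarse fits downward.

The package also provides the raster preprocessing primitives such
analyses need (neighbour-mean imputation, block resampling, zonal
statistics, urban proportions, population-weighted centroids) and a
synthetic nested-landscape generator with known ground truth, used
throughout the tests as the calibration bench.

## Worked example

Simulate a landscape of 8 departments × 6 municipalities with known
coefficients, observe a 10% sample of coarse flows, and refit:

```r
library(migrascale)

land <- generateLandscape(landscapeConfig(nCoarse = 8, finePerCoarse = 6,
                                          seed = 1))
sim  <- simulateFlows(land$units, land$adj, land$dist, defaultTrueBeta(),
                      fraction = 0.1, seed = 2)
fit  <- fitMigrationModel(land$units, land$adj, land$dist, sim$flows,
                          settings = mcmcSettings(nChains = 3,
                                                  nSteps = 20000, seed = 3))
fit$summary
#>   parameter      median       q2.5       q97.5      rhat
#> 1 Intercept -6.99874147 -7.0473824 -6.95150295 1.0063009
#> 2   DIST_ij -2.40305101 -2.4975422 -2.30821439 0.9997523
#> 3     POP_j -0.08648156 -0.3278918  0.08823119 1.0043630
#> 4     POP_i  0.16919687  0.1338287  0.20258873 1.0056706
```

The true vector was `(-7, -2.4, -0.12, 0.16)`: every coefficient is
recovered inside its 95% credible interval and all R-hat values sit at 1.
Columns mirror the usual coefficient-table shape (posterior median, 2.5%
and 97.5% quantiles, Gelman–Rubin statistic). Predicted fine flows can
then be aggregated and compared against the coarse observations:

```r
pred <- predictFlows(fit, land$units, samplingFraction = 0.1)
compareFlows(pred$coarseFlows, flowCounts(sim$flows))$r
#> [1] 0.9907988
```

a Pearson correlation on the `log10(x+1)` scale across the 56 ordered
department pairs. `forwardSelect()` grows the covariate set from the base
gravity model by DIC, and `runCommand()` (or the `inst/cli/migrascale`
script) wires the stages — simulate, fit, select, predict, validate,
diagnose — into seeded, byte-reproducible runs.

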