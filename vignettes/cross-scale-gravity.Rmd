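---
title: "Cross-scale gravity modelling of migration flows"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-scale gravity modelling of migration flows}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(migrascale)
```

## The problem

Migration flows are often observed only between coarse administrative units
(departments, provinces), while planning and epidemiological applications
need flows between fine units (municipalities). `migrascale` fits a
gravity-type spatial interaction model *at the fine scale* using only
coarse-scale observations, by carrying the fine-scale predictions through an
aggregation step inside the likelihood.

## The model

For each ordered pair of fine units $(i, j)$, the proportion of origin $i$'s
population migrating to $j$ over the study window follows a logistic-linear
model

$$\operatorname{logit}(v_{ij}) = \beta_0 + \beta_1 d_{ij} +
\beta_2 N_i + \beta_3 N_j + \textstyle\sum_k \beta_k X_k,$$

with $d_{ij}$ the Euclidean distance between population-weighted centroids,
$N_i, N_j$ origin and destination populations, and $X_k$ optional
covariates: per-capita economic product (`GECON`), urban population fraction
(`URBANPROP`), population percentile (`PERC`), tiny-population and
major-centre indicators (`TINY`, `MAJCEN`, strict decile thresholds), and
boundary contiguity (`CONT`). Fine-pair proportions aggregate to coarse
pairs by population weighting,

$$P_{IJ} = \frac{\sum_{i \in I} N_i \sum_{j \in J} v_{ij}}
                {\sum_{i \in I} N_i},$$

and the observed coarse counts enter a binomial likelihood,
$M_{IJ} \sim \mathrm{Binomial}(n_I, P_{IJ})$ for $I \neq J$, where $n_I$ is
the number of persons *observed* at origin $I$ (the census-sample count, not
the full population — the generator and the likelihood use the same
sampling fraction so the two sides agree). Destination counts from a common
origin are treated as independent binomials, not multinomial; consequently
$\sum_J P_{IJ}$ is unconstrained and the model is unconstrained at both the
origin and destination sides.

Two readings of the aggregation denominator are possible because the
printed form of the aggregation sums $N_i$ over both indices; dividing by
$\sum_{i\in I}\sum_{j\in J} N_i$ would scale $P_{IJ}$ by the number of
destination units. We use $\sum_{i \in I} N_i$, the only reading under
which $P_{IJ}$ is a proportion of $I$'s observed population; the literal
form is available behind `aggregateProportions(..., literalDenominator =
TRUE)` for auditability. Similarly, the combinatorial constant of the
likelihood is computed with log-gamma as
$\ln n_I! - \ln M_{IJ}! - \ln(n_I - M_{IJ})!$ (the binomial coefficient);
it never enters MCMC, where it cancels.

## Covariate scaling and priors

Continuous covariates are standardized to mean 0 and standard deviation
0.5, binary covariates centred to mean 0 with range 1, so slope magnitudes
are comparable and a common weakly-informative prior is meaningful:
independent Cauchy(0, 2.5) on slopes and Cauchy(0, 10) on the intercept.
Scaling is *fitted on the design rows* (each unit appears $n-1$ times), not
on the unit table, because that is where the regression sees the data; the
fitted transforms are stored (`@scalers`, `writeScaler()`) and reproduce
the standardized columns bit-identically at prediction time. Percentile
thresholds use the default linear-interpolation quantile and strict
inequalities, so equal populations flag neither `TINY` nor `MAJCEN`.

## Estimation

The posterior is sampled by adaptive Gaussian random-walk
Metropolis-Hastings. Default protocol: 5 chains × 150,000 steps, first half
burn-in, thinning every 10 (7,500 retained draws per chain). During burn-in
a global proposal factor is steered into a target acceptance band
(0.15–0.45) every 50 steps, and relative per-parameter scales track running
posterior standard deviations, with the accumulator reset halfway through
burn-in to discard the approach transient; all adaptation freezes at the
end of burn-in, preserving detailed balance in the retained part. Every
chain is bit-reproducible given its seed, and per-chain seeds derive
deterministically from one master seed.

**Initial conditions.** Aggregated census-scale counts make this posterior
extremely concentrated (coefficient standard deviations of order
$10^{-2}$). Starting vectors drawn from the prior lie thousands of
posterior standard deviations away, and a random walk cannot traverse that
distance within any reasonable burn-in — chains stall and the Gelman-Rubin
statistic explodes. `fitMigrationModel()` therefore starts each chain at a
jittered posterior mode (`mapInits()`: Nelder-Mead from a feasible
low-migration anchor, BFGS polish, then per-chain relative jitter), which
keeps starts overdispersed relative to the posterior while reachable
within burn-in. Prior-drawn starts remain available via `priorInits()`.

Convergence is assessed with the classic (non-split) Gelman-Rubin
potential scale reduction factor; model comparison uses DIC with
Spiegelhalter's effective parameter count
$p_D = \bar{D} - D(\bar\theta)$. Forward selection starts from the base
gravity specification (`DIST_ij`, `POP_j`, `POP_i`), adds the
lowest-DIC candidate each iteration, and stops when no candidate improves
DIC by more than 2 — the conventional "substantial" difference; the full trace
of every iteration is returned and serializable in the standard
iteration-table shape. Shortened chains during selection are legitimate
and configurable; a final refit at full settings is recommended.

## Numerical choices

* Inverse logit is clamped at $|\eta| \le 500$ so proportions never round
  to exactly 0 or 1; parameter values driving an aggregated $P_{IJ}$ out of
  $(0,1)$ score $-\infty$ in the sampler rather than erroring.
* `makeModelPosterior()` precomputes the pair-to-coarse-pair aggregation
  weights once; each posterior evaluation is then one dense
  matrix–vector product plus a grouped sum — a fraction of a millisecond
  for a few thousand pairs — and agrees with the reference composition
  `logPosterior()` to floating-point rounding.
* Raster imputation fills each missing cell with the mean of its
  non-missing Moore neighbours (truncated at borders), sweeping repeatedly
  so values propagate; it terminates whenever at least one cell is known
  and is idempotent on complete grids.
* Resampling is integer block replication (nearest neighbour, no
  smoothing); zonal means are unweighted cell means within the zone, since
  cell/boundary area weighting information is out of scope.
* DIC ties in forward selection break by candidate order; quantiles
  everywhere are linear-interpolation (default type 7).

## The synthetic landscape generator

`generateLandscape()` emulates the statistical structure of the real
inputs at desk scale: coarse units as 100 km planar cells, fine units at
uniform seed points within their cell, log-normal populations (median
~15,000, sdlog 1 — heavy-tailed like municipal populations), Beta(2, 2)
urban fractions, log-normal per-capita product (median ~6,000, sdlog 0.5),
and a 10% sampling fraction matching a 10% census sample. Contiguity is
the Delaunay tessellation of seed points (two units are contiguous iff
their Voronoi cells share a boundary), written in-package as a
brute-force empty-circumcircle test because the landscape sizes used here
(≤ 400 seed points) do not warrant a computational-geometry dependency.
`simulateFlows()` then runs the model generatively at known coefficients
(defaults follow the signs typical of fitted migration models: strong negative
distance, positive contiguity and destination urbanicity), and
`coarsenPartition()` merges contiguous fine units within coarse units into
connected intermediate groups, emulating intermediate census units.

What the generator does *not* emulate: realistic geography and projection
distortion, spatially autocorrelated covariates, multi-department
intermediate units, non-binomial overdispersion, and any misreporting
process. Passing recovery tests therefore demonstrates the correctness and
calibration of the machinery under the model's own assumptions, not
robustness to real-data violations of them (a multinomial mis-specification
toggle is deliberately out of scope here).

## Study sizes used in the tests

The recovery study uses 8 coarse × 6 fine units (2,256 ordered pairs),
sampling fraction 0.1, 3 chains × 20,000 steps, 20 replicates — sizes at
which the posterior is informative yet a full replicate study runs in a
few minutes. Selection recovery uses 6 × 4 landscapes with one truly
active candidate (`URBANPROP_j`, coefficient 0.8) among inert ones.

## A worked example

```{r example, eval = FALSE}
land <- generateLandscape(landscapeConfig(nCoarse = 8, finePerCoarse = 6,
                                          seed = 1))
sim <- simulateFlows(land$units, land$adj, land$dist, defaultTrueBeta(),
                     fraction = 0.1, seed = 2)
fit <- fitMigrationModel(land$units, land$adj, land$dist, sim$flows,
                         settings = mcmcSettings(nChains = 3,
                                                 nSteps = 20000, seed = 3))
fit$summary
pred <- predictFlows(fit, land$units, samplingFraction = 0.1)
compareFlows(pred$coarseFlows, flowCounts(sim$flows))$r
```

## Known limitations

* The likelihood treats destinations independently; when true row sums of
  $P$ approach 1 the generator refuses ("implausible truth") rather than
  renormalising.
* Within-coarse-unit fine pairs are predicted but excluded from the
  likelihood and between-group comparisons (the fitting domain is
  $I \neq J$), so those routes are extrapolations of the fitted surface.
* The classic Gelman-Rubin statistic is reported; split-chain or
  rank-normalized variants are out of scope.
* Distances are planar kilometres; geodesy and map projections are out of
  scope, and real coordinate inputs should be pre-projected.
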