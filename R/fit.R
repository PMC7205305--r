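# High-level fitting interface: one code path for the fine-, broad- and
# intermediate-scale approaches, parameterized by which level's design is
# built (the unit table handed in) and which level's flows the likelihood
# uses (the flows object plus optional partition).

#' Fit the cross-scale migration model
#'
#' Builds the standardized pair design for `spec` at the level of `units`,
#' compiles the aggregated binomial posterior against the observed coarse
#' flows, and samples it with multi-chain adaptive random-walk
#' Metropolis-Hastings. The broad-scale approach is the degenerate case
#' where each unit is its own coarse unit; the intermediate-scale approach
#' passes the matching intermediate-level units and flows.
#'
#' @param units a [UnitTable-class] at the modelling level.
#' @param adj contiguity matrix over the units (needed iff `CONT_ij` is in
#'   `spec`).
#' @param dist distance matrix over the units.
#' @param flows a [CoarseFlows-class] at the observation level.
#' @param spec covariate names; see [covariateCatalogue()].
#' @param settings an [mcmcSettings()] list.
#' @param partition optional named fine-to-group mapping when the
#'   observation level is not the units' coarse membership.
#' @param inits optional list of per-chain initial coefficient vectors;
#'   defaults to prior draws truncated to \eqn{|\beta| \le 5}.
#' @return list with `sample` (a [PosteriorSample-class]), `summary`
#'   (the [posteriorSummary()] table), `dic` (the [dic()] list), `design`,
#'   `model` (the compiled closures) and `spec`.
#' @export
fitMigrationModel <- function(units, adj = NULL, dist, flows,
                              spec = baseGravitySpec(),
                              settings = mcmcSettings(),
                              partition = NULL, inits = NULL) {
  design <- buildPairDesign(units, adj, dist, spec)
  scales <- priorScales(length(spec))
  model <- makeModelPosterior(design, flows, partition, scales)
  if (is.null(inits))
    inits <- mapInits(model$logPost, length(spec), settings$nChains,
                      seed = settings$seed)
  # guard: an init must not sit in a region of zero likelihood (some
  # aggregated proportion pushed to 1); pull offenders toward a feasible
  # anchor with a very negative intercept and zero slopes
  anchor <- c(-12, rep(0, length(spec)))
  inits <- lapply(inits, function(b) {
    for (k in 1:60) {
      if (is.finite(model$logPost(b))) return(b)
      b <- (b + anchor) / 2
    }
    anchor
  })
  sample <- runMultichain(model$logPost, model$deviance, inits, settings,
                          parNames = c("Intercept", spec))
  list(sample = sample, summary = posteriorSummary(sample),
       dic = dic(sample), design = design, model = model, spec = spec)
}

#' Mode-centred overdispersed chain initial values
#'
#' Locates the posterior mode by numerical optimization (Nelder-Mead from a
#' feasible low-migration anchor, polished by BFGS) and scatters one
#' starting vector per chain around it with a modest relative jitter. With
#' the very peaked posteriors aggregated census-scale counts produce, prior
#' draws start random walks thousands of posterior standard deviations from
#' the mode; mode-centred, overdispersed starts keep the Gelman-Rubin
#' diagnostic meaningful while letting every chain reach the typical set
#' during burn-in.
#'
#' @param logPost log-posterior function.
#' @param nCovariates number of slope parameters.
#' @param nChains number of chains.
#' @param seed integer seed for the jitter.
#' @param jitter relative jitter scale around the mode.
#' @return list of numeric vectors, one per chain.
#' @export
mapInits <- function(logPost, nCovariates, nChains, seed = 1L,
                     jitter = 0.02) {
  anchor <- c(-12, rep(0, nCovariates))
  fn <- function(b) {
    lp <- logPost(b)
    if (!is.finite(lp)) 1e12 else -lp
  }
  opt <- optim(anchor, fn, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-10))
  opt <- tryCatch(optim(opt$par, fn, method = "BFGS",
                        control = list(maxit = 200)),
                  error = function(e) opt)
  mode <- opt$par
  set.seed(.chainSeed(seed, 0))
  lapply(seq_len(nChains), function(ch)
    mode + rnorm(length(mode), 0, jitter * pmax(abs(mode), 1)))
}

#' Predict flows from a fitted model
#'
#' Evaluates the fine-pair proportions at the posterior median
#' coefficients, aggregates them, and converts both levels to expected
#' flows at the chosen sampling fraction.
#'
#' @param fitted the list returned by [fitMigrationModel()].
#' @param units the [UnitTable-class] the model was fitted on.
#' @param samplingFraction fraction of the population observed.
#' @return list with `beta` (posterior medians), `v` (fine proportions),
#'   `P` (coarse proportions), `fineFlows`, `coarseFlows`.
#' @export
predictFlows <- function(fitted, units, samplingFraction = 1) {
  beta <- fitted$summary$median
  v <- predictVij(beta, fitted$design)
  P <- aggregateProportions(v, units)
  fineFlows <- flowsFromProportions(v, units, samplingFraction)
  list(beta = setNames(beta, fitted$summary$parameter), v = v, P = P,
       fineFlows = fineFlows,
       coarseFlows = aggregateFlows(fineFlows, coarseIds(units)))
}
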