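# Bayesian estimation: adaptive per-parameter Gaussian random-walk
# Metropolis-Hastings, multi-chain orchestration, Gelman-Rubin convergence
# diagnostics, DIC, and posterior summaries.

#' Sampler settings
#'
#' Defaults follow the study protocol: 5 chains of 1.5e5 steps, the first
#' half discarded as burn-in, thinning every 10 steps. Proposal scales are
#' adapted in windows during burn-in toward the target acceptance band and
#' frozen afterwards (preserving detailed balance in the retained part).
#'
#' @param nChains number of chains.
#' @param nSteps Metropolis steps per chain.
#' @param burnInFraction fraction of each chain discarded, in (0, 1).
#' @param thin keep every `thin`-th post-burn-in draw.
#' @param seed master seed; per-chain seeds are derived deterministically.
#' @param adaptWindow steps per adaptation window during burn-in.
#' @param targetAccept acceptance-rate band `(low, high)` the adaptation
#'   steers into.
#' @param initScale initial per-parameter proposal standard deviation.
#' @return validated list of settings (class `mcmcSettings`).
#' @export
mcmcSettings <- function(nChains = 5, nSteps = 150000, burnInFraction = 0.5,
                         thin = 10, seed = 1L, adaptWindow = 50,
                         targetAccept = c(0.15, 0.45), initScale = 0.1) {
  stopifnot(nChains >= 1, nSteps >= 1, thin >= 1, adaptWindow >= 1,
            burnInFraction > 0, burnInFraction < 1,
            length(targetAccept) == 2, targetAccept[1] < targetAccept[2],
            initScale > 0)
  retained <- floor(nSteps * (1 - burnInFraction) / thin)
  if (retained < 10)
    stop("settings retain fewer than 10 draws per chain")
  structure(list(nChains = as.integer(nChains), nSteps = as.integer(nSteps),
                 burnInFraction = burnInFraction, thin = as.integer(thin),
                 seed = as.integer(seed), adaptWindow = as.integer(adaptWindow),
                 targetAccept = targetAccept, initScale = initScale,
                 retainedPerChain = retained),
            class = "mcmcSettings")
}

# deterministic per-chain seed derivation from the master seed
.chainSeed <- function(seed, chain) {
  as.integer((abs(as.numeric(seed)) * 131 + chain * 7919) %% 2147483629)
}

#' Run one adaptive random-walk Metropolis chain
#'
#' Joint Gaussian proposals with per-parameter standard deviations. During
#' burn-in the scales are adapted every `adaptWindow` steps: a global factor
#' is steered by the window acceptance rate toward the target band, and the
#' relative per-parameter scales track the running posterior standard
#' deviations. Adaptation freezes at the end of burn-in. The chain is fully
#' reproducible given its seed.
#'
#' @param logPost function: coefficient vector -> log posterior
#'   (may return `-Inf`).
#' @param init starting coefficient vector; `logPost(init)` must be finite.
#' @param settings an [mcmcSettings()] list.
#' @param seed chain seed (defaults to the settings master seed).
#' @return list with `draws` (retained draws, matrix), `logPost` (vector),
#'   `acceptRate` (post-burn-in acceptance rate) and `scales`
#'   (frozen proposal scales).
#' @export
rwMetropolisChain <- function(logPost, init, settings = mcmcSettings(),
                              seed = settings$seed) {
  p <- length(init)
  lp <- logPost(init)
  if (!is.finite(lp)) stop("log posterior not finite at init")
  if (settings$initScale <= 0) stop("zero proposal scale")
  set.seed(seed)
  nSteps <- settings$nSteps
  burn <- floor(nSteps * settings$burnInFraction)
  thin <- settings$thin
  nKeep <- settings$retainedPerChain
  draws <- matrix(NA_real_, nKeep, p)
  lps <- numeric(nKeep)
  beta <- as.numeric(init)
  scales <- rep(settings$initScale, p)
  gfac <- 1
  accWin <- 0L; accPost <- 0L; nPost <- 0L
  # Welford running moments for relative scale adaptation
  wm <- beta; ws <- numeric(p); wn <- 0
  kept <- 0L
  for (step in seq_len(nSteps)) {
    prop <- beta + rnorm(p, 0, gfac * scales)
    lpProp <- logPost(prop)
    if (is.finite(lpProp) && log(runif(1)) < lpProp - lp) {
      beta <- prop; lp <- lpProp
      accWin <- accWin + 1L
      if (step > burn) accPost <- accPost + 1L
    }
    if (step > burn) nPost <- nPost + 1L
    if (step <= burn) {
      # drop the early transient from the running moments so relative
      # scales reflect the stationary spread, not the approach path
      if (step == burn %/% 2) { wm <- beta; ws <- numeric(p); wn <- 0 }
      wn <- wn + 1
      d0 <- beta - wm
      wm <- wm + d0 / wn
      ws <- ws + d0 * (beta - wm)
      if (step %% settings$adaptWindow == 0L) {
        rate <- accWin / settings$adaptWindow
        if (rate > settings$targetAccept[2]) gfac <- gfac * 1.25
        else if (rate < settings$targetAccept[1]) gfac <- gfac * 0.8
        if (wn > 2 * p) {
          sdv <- sqrt(ws / (wn - 1))
          if (all(sdv > 0)) {
            # retarget relative scales, preserving the overall magnitude
            newScales <- sdv / exp(mean(log(sdv))) * exp(mean(log(scales)))
            scales <- newScales
          }
        }
        accWin <- 0L
      }
    } else if ((step - burn) %% thin == 0L && kept < nKeep) {
      kept <- kept + 1L
      draws[kept, ] <- beta
      lps[kept] <- lp
    }
  }
  list(draws = draws[seq_len(kept), , drop = FALSE],
       logPost = lps[seq_len(kept)],
       acceptRate = if (nPost > 0) accPost / nPost else NA_real_,
       scales = gfac * scales)
}

#' Run multiple chains and assemble a posterior sample
#'
#' Runs `settings$nChains` chains from distinct initial conditions, strips
#' burn-in, thins, evaluates the deviance on the retained draws, stacks the
#' chains and computes the per-parameter Gelman-Rubin statistic.
#'
#' @param logPost log-posterior function.
#' @param devFun deviance function (`-2` log-likelihood) used for DIC;
#'   evaluated on retained draws only.
#' @param inits list of starting vectors, one per chain (at least
#'   `nChains`).
#' @param settings an [mcmcSettings()] list.
#' @param parNames optional parameter names.
#' @return A [PosteriorSample-class].
#' @export
runMultichain <- function(logPost, devFun, inits, settings = mcmcSettings(),
                          parNames = NULL) {
  if (!is.list(inits)) inits <- list(inits)
  if (length(inits) < settings$nChains)
    stop("need one init per chain: ", settings$nChains, " required")
  p <- length(inits[[1]])
  if (is.null(parNames))
    parNames <- c("Intercept", paste0("beta", seq_len(p - 1)))
  chains <- lapply(seq_len(settings$nChains), function(ch)
    rwMetropolisChain(logPost, inits[[ch]], settings,
                      seed = .chainSeed(settings$seed, ch)))
  nKeep <- min(vapply(chains, function(ch) nrow(ch$draws), integer(1)))
  draws <- array(NA_real_, c(nKeep, settings$nChains, p),
                 dimnames = list(NULL, NULL, parNames))
  lp <- matrix(NA_real_, nKeep, settings$nChains)
  dev <- matrix(NA_real_, nKeep, settings$nChains)
  for (ch in seq_along(chains)) {
    draws[, ch, ] <- chains[[ch]]$draws[seq_len(nKeep), , drop = FALSE]
    lp[, ch] <- chains[[ch]]$logPost[seq_len(nKeep)]
    dev[, ch] <- apply(draws[, ch, , drop = FALSE], 1,
                       function(b) devFun(as.numeric(b)))
  }
  rh <- if (settings$nChains >= 2) {
    vapply(seq_len(p), function(k) .psrf(draws[, , k, drop = FALSE]), numeric(1))
  } else rep(NA_real_, p)
  names(rh) <- parNames
  new("PosteriorSample", draws = draws, logPost = lp, deviance = dev,
      rhat = rh, devFun = devFun,
      settings = unclass(settings))
}

# classic (non-split) potential scale reduction factor for one parameter;
# x: [iter, chain] or [iter, chain, 1]
.psrf <- function(x) {
  x <- matrix(x, nrow = dim(x)[1])
  n <- nrow(x); m <- ncol(x)
  if (n < 2 || m < 2) return(NA_real_)
  W <- mean(apply(x, 2, var))
  if (W == 0) stop("degenerate chains")
  Bn <- var(colMeans(x))             # B/n
  sqrt(((n - 1) / n * W + Bn) / W)
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Classic PSRF per parameter:
#' `sqrt(((n-1)/n * W + B/n) / W)` where `W` is the mean within-chain
#' variance and `B/n` the variance of the chain means. Values near 1
#' indicate the chains have mixed into the same distribution.
#'
#' @param sample a [PosteriorSample-class] with at least two chains, or a
#'   matrix `[iteration, chain]` for a single parameter.
#' @return named numeric vector of PSRF values.
#' @export
gelmanRubin <- function(sample) {
  if (is(sample, "PosteriorSample")) {
    d <- dim(sample@draws)
    if (d[2] < 2) stop("need at least 2 chains")
    out <- vapply(seq_len(d[3]), function(k)
      .psrf(sample@draws[, , k, drop = FALSE]), numeric(1))
    names(out) <- parameterNames(sample)
    out
  } else {
    .psrf(as.matrix(sample))
  }
}

#' Deviance Information Criterion
#'
#' `DIC = mean(D) + pD` with the effective number of parameters
#' `pD = mean(D) - D(posterior mean)` (Spiegelhalter's classic variant),
#' where `D` is the deviance `-2 log L` over the retained draws.
#'
#' @param sample a [PosteriorSample-class] carrying per-draw deviances and
#'   its deviance function.
#' @return list with `dic`, `pD`, `meanDeviance` and `devianceAtMean`.
#' @export
dic <- function(sample) {
  stopifnot(is(sample, "PosteriorSample"))
  Dbar <- mean(sample@deviance)
  thetaBar <- colMeans(posteriorDraws(sample))
  Dhat <- sample@devFun(as.numeric(thetaBar))
  if (!is.finite(Dhat)) stop("deviance not finite at the posterior mean")
  pD <- Dbar - Dhat
  list(dic = Dbar + pD, pD = pD, meanDeviance = Dbar, devianceAtMean = Dhat)
}

#' Posterior summary table
#'
#' Per-parameter median, central 95% credible interval (2.5% and 97.5%
#' linear-interpolation quantiles) and Gelman-Rubin statistic.
#'
#' @param sample a [PosteriorSample-class].
#' @return data.frame with columns `parameter`, `median`, `q2.5`, `q97.5`,
#'   `rhat`.
#' @export
posteriorSummary <- function(sample) {
  stopifnot(is(sample, "PosteriorSample"))
  X <- posteriorDraws(sample)
  if (nrow(X) == 0) stop("empty sample")
  qs <- t(apply(X, 2, quantile, probs = c(0.5, 0.025, 0.975), names = FALSE))
  data.frame(parameter = colnames(X), median = qs[, 1],
             q2.5 = qs[, 2], q97.5 = qs[, 3],
             rhat = as.numeric(sample@rhat), row.names = NULL)
}

#' Draw chain initial values from the prior
#'
#' Independent Cauchy(0, scale) draws truncated to `|beta| <= bound`, one
#' vector per chain, seeded deterministically from the master seed.
#'
#' @param nChains number of chains.
#' @param scales prior scales, intercept first.
#' @param seed master seed.
#' @param bound truncation bound.
#' @return list of numeric vectors.
#' @export
priorInits <- function(nChains, scales, seed = 1L, bound = 5) {
  set.seed(.chainSeed(seed, 0))
  lapply(seq_len(nChains), function(ch) {
    vapply(scales, function(s) {
      repeat {
        x <- rcauchy(1, 0, s)
        if (abs(x) <= bound) return(x)
      }
    }, numeric(1))
  })
}

#' Write posterior draws and a summary table as delimited text
#'
#' Draws: one row per retained draw with `chain`, `iteration`, the
#' parameters, `log_posterior` and `deviance`. Summary: the
#' [posteriorSummary()] table.
#'
#' @param sample a [PosteriorSample-class].
#' @param drawsPath,summaryPath file paths.
#' @param header optional `#`-prefixed comment lines.
#' @export
writePosterior <- function(sample, drawsPath, summaryPath, header = NULL) {
  stopifnot(is(sample, "PosteriorSample"))
  d <- dim(sample@draws)
  df <- data.frame(
    chain = rep(seq_len(d[2]), each = d[1]),
    iteration = rep(seq_len(d[1]), times = d[2]))
  flat <- matrix(aperm(sample@draws, c(1, 2, 3)), d[1] * d[2], d[3])
  colnames(flat) <- dimnames(sample@draws)[[3]]
  df <- cbind(df, flat,
              log_posterior = as.vector(sample@logPost),
              deviance = as.vector(sample@deviance))
  for (path in c(drawsPath, summaryPath)) {
    con <- file(path, "w")
    if (!is.null(header)) writeLines(paste0("# ", header), con)
    tab <- if (path == drawsPath) df else posteriorSummary(sample)
    suppressWarnings(write.table(tab, con, sep = "\t", quote = FALSE,
                                 row.names = FALSE))
    close(con)
  }
  invisible(drawsPath)
}
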