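# A standard normal / bivariate normal target gives the sampler a known
# stationary distribution to recover.

test_that("settings arithmetic retains the documented number of draws", {
  s <- mcmcSettings(nChains = 5, nSteps = 150000, burnInFraction = 0.5,
                    thin = 10)
  expect_equal(s$retainedPerChain, 7500)
  expect_equal(s$retainedPerChain * s$nChains, 37500)
  expect_error(mcmcSettings(nSteps = 100, thin = 50), "fewer than 10")
})

test_that("chains are bit-identical under a fixed seed", {
  lp <- function(b) -0.5 * sum(b^2)
  s <- mcmcSettings(nChains = 1, nSteps = 2000, seed = 42)
  c1 <- rwMetropolisChain(lp, c(0.5, -0.5), s)
  c2 <- rwMetropolisChain(lp, c(0.5, -0.5), s)
  expect_identical(c1$draws, c2$draws)
  expect_identical(c1$logPost, c2$logPost)
  expect_error(rwMetropolisChain(lp, c(Inf, 0), s), "finite")
})

test_that("the sampler recovers a standard normal target", {
  lp <- function(b) -0.5 * b^2
  s <- mcmcSettings(nChains = 1, nSteps = 50000, seed = 7, initScale = 1)
  ch <- rwMetropolisChain(lp, 0.3, s)
  x <- ch$draws[, 1]
  # Monte-Carlo standard error via batch means
  nb <- 50
  bm <- tapply(x, rep(seq_len(nb), each = length(x) / nb), mean)
  se <- sd(bm) / sqrt(nb)
  expect_lt(abs(mean(x)), 3 * se)
  expect_lt(abs(var(x) - 1), 0.1)
  # post-burn-in acceptance rate sits in the adaptation band
  expect_gt(ch$acceptRate, 0.15)
  expect_lt(ch$acceptRate, 0.45)
})

test_that("multi-chain runs strip burn-in, thin, and stack correctly", {
  lp <- function(b) -0.5 * sum(b^2)
  dev <- function(b) sum(b^2)
  s <- mcmcSettings(nChains = 3, nSteps = 3000, thin = 10, seed = 9)
  ps <- runMultichain(lp, dev, list(c(0, 0), c(1, 1), c(-1, 1)), s,
                      parNames = c("a", "b"))
  expect_s4_class(ps, "PosteriorSample")
  expect_equal(nDraws(ps), floor(3000 * 0.5 / 10))
  expect_equal(nChains(ps), 3)
  expect_equal(parameterNames(ps), c("a", "b"))
  expect_equal(dim(posteriorDraws(ps)), c(3 * 150, 2))
  expect_true(all(is.finite(ps@rhat)))
  expect_error(runMultichain(lp, dev, list(c(0, 0)), s), "one init per chain")
  # single chain: sampling valid, R-hat unavailable
  s1 <- mcmcSettings(nChains = 1, nSteps = 2000, seed = 9)
  ps1 <- runMultichain(lp, dev, list(c(0, 0)), s1)
  expect_true(all(is.na(ps1@rhat)))
})

test_that("Gelman-Rubin diagnostics separate mixed from unmixed chains", {
  n <- 1000
  x <- matrix(rep(sin(seq_len(n)), 2), n, 2)  # identical chains, B = 0
  expect_equal(gelmanRubin(x), sqrt((n - 1) / n))
  expect_lte(gelmanRubin(x), 1)
  set.seed(13)
  mixed <- matrix(rnorm(4 * 2000), 2000, 4)   # same target per chain
  expect_lt(abs(gelmanRubin(mixed) - 1), 0.01)
  # constant-offset chains: direct formula oracle
  off <- cbind(rnorm(1000, 0), rnorm(1000, 10))
  W <- mean(apply(off, 2, var))
  Bn <- var(colMeans(off))
  expect_equal(gelmanRubin(off), sqrt(((1000 - 1) / 1000 * W + Bn) / W))
  expect_gt(gelmanRubin(off), 2)
  expect_error(gelmanRubin(matrix(1, 100, 2)), "degenerate")
})

test_that("DIC reduces to its closed forms on constructed posteriors", {
  # constant deviance: pD = 0, DIC = the constant
  draws <- array(rnorm(600), c(100, 3, 2))
  psC <- fixtureSample(draws, devFun = function(b) 42)
  dC <- dic(psC)
  expect_equal(dC$pD, 0)
  expect_equal(dC$dic, 42)
  # conjugate normal mean, known variance, flat-ish prior: pD ~ 1
  set.seed(21)
  sigma <- 1; n <- 50
  y <- rnorm(n, 2, sigma)
  postMean <- mean(y); postSd <- sigma / sqrt(n)
  th <- array(rnorm(4000 * 2, postMean, postSd), c(4000, 2, 1))
  devN <- function(b) -2 * sum(dnorm(y, b, sigma, log = TRUE))
  psN <- fixtureSample(th, devFun = devN)
  expect_equal(dic(psN)$pD, 1, tolerance = 0.15)
  # invariance to parameter ordering
  lp <- function(b) -0.5 * sum(b^2)
  dev2 <- function(b) sum(c(1, 3) * b^2)
  s <- mcmcSettings(nChains = 2, nSteps = 4000, seed = 31)
  psA <- runMultichain(lp, dev2, list(c(0, 0), c(1, -1)), s)
  devRev <- function(b) dev2(rev(b))
  psB <- new("PosteriorSample", draws = psA@draws[, , 2:1],
             logPost = psA@logPost, deviance = psA@deviance,
             rhat = psA@rhat[2:1], devFun = devRev, settings = psA@settings)
  expect_equal(dic(psB)$dic, dic(psA)$dic)
  expect_equal(sort(gelmanRubin(psB)), sort(gelmanRubin(psA)),
               ignore_attr = TRUE)
})

test_that("posterior summaries report medians and central intervals", {
  d <- array(1:101, c(101, 1, 1))
  ps <- fixtureSample(d)
  sm <- posteriorSummary(ps)
  expect_equal(sm$median, 51)
  cst <- fixtureSample(array(7, c(50, 2, 1)))
  smC <- posteriorSummary(cst)
  expect_equal(c(smC$median, smC$q2.5, smC$q97.5), c(7, 7, 7))
  set.seed(5)
  sym <- rnorm(20000)
  sym <- c(sym, -sym)
  ps3 <- fixtureSample(array(sym, c(20000, 2, 1)))
  sm3 <- posteriorSummary(ps3)
  expect_equal(sm3$median, 0, tolerance = 1e-10)
  expect_equal(sm3$q2.5, -sm3$q97.5, tolerance = 1e-10)
  expect_equal(sm3$q2.5, quantile(sym, 0.025, names = FALSE))
})

test_that("posterior draws and summaries serialize with headers", {
  lp <- function(b) -0.5 * sum(b^2)
  s <- mcmcSettings(nChains = 2, nSteps = 1000, thin = 5, seed = 3)
  ps <- runMultichain(lp, function(b) sum(b^2), list(0, 1), s,
                      parNames = "theta")
  dp <- withr::local_tempfile(fileext = ".tsv")
  sp <- withr::local_tempfile(fileext = ".tsv")
  writePosterior(ps, dp, sp, header = c("seed: 3"))
  expect_match(readLines(dp, n = 1), "^# seed")
  tab <- read.table(dp, header = TRUE, sep = "\t", comment.char = "#")
  expect_equal(nrow(tab), nDraws(ps) * 2)
  expect_named(tab, c("chain", "iteration", "theta", "log_posterior",
                      "deviance"))
})
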