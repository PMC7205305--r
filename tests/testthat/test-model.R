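test_that("predicted proportions are the inverse-logit of the linear term", {
  u <- fixtureUnits(4)
  des <- buildPairDesign(u, dist = pairwiseDistances(u))
  v0 <- predictVij(c(0, 0, 0, 0), des)
  off <- which(row(v0) != col(v0))
  expect_equal(v0[off], rep(0.5, length(off)))
  expect_true(all(is.na(diag(v0))))
  # at the study's fitted intercept with covariates at zero:
  # logit^{-1}(-7.51) = 1 / (1 + e^{7.51})
  vInt <- 1 / (1 + exp(7.51))
  expect_equal(vInt, 5.464e-4, tolerance = 1e-3)
  u0 <- as.data.frame(u)
  # monotonicity: raising a positive-coefficient covariate raises v
  des2 <- buildPairDesign(u, dist = pairwiseDistances(u),
                          spec = c("DIST_ij", "POP_i", "POP_j"))
  beta <- c(-7.51, -1, 0.5, 0.5)
  v1 <- predictVij(beta, des2)
  X <- designMatrix(des2)
  o <- order(X[, "POP_i"])
  rows <- cbind(des2@origin, des2@dest)
  same <- X[o, "DIST_ij"]
  # pick two rows differing only through POP_i via direct eta comparison
  eta <- beta[1] + X %*% beta[-1]
  expect_equal(v1[rows], as.numeric(plogis(eta)))
  expect_true(all(diff(plogis(sort(eta))) >= 0))
  expect_error(predictVij(c(0, 0), des2), "length")
})

test_that("coarse aggregation is the population-weighted origin average", {
  # two origins (100, 300 persons), one destination unit in J
  u <- UnitTable(data.frame(
    id = c("i1", "i2", "j1"), coarse_id = c("I", "I", "J"),
    population = c(100, 300, 50), urban_prop = 0.5, gcp_pc = 1,
    cx = c(0, 1, 5), cy = 0))
  v <- matrix(0, 3, 3, dimnames = list(c("i1", "i2", "j1"),
                                       c("i1", "i2", "j1")))
  v["i1", "j1"] <- 0.01; v["i2", "j1"] <- 0.02
  v["i1", "i2"] <- 0.001; v["i2", "i1"] <- 0.001
  v["j1", "i1"] <- 0.005; v["j1", "i2"] <- 0.005
  P <- aggregateProportions(v, u)
  expect_equal(P["I", "J"], (100 * 0.01 + 300 * 0.02) / 400)
  # literal printed denominator divides by the destination count
  P2 <- aggregateProportions(v, u, literalDenominator = TRUE)
  expect_equal(P2["I", "J"], P["I", "J"] / 1)
  expect_equal(P2["J", "I"], P["J", "I"] / 2)
})

test_that("aggregation equals a brute-force double loop on random landscapes", {
  for (seed in 1:4) {
    land <- fixtureLandscape(nCoarse = 3, finePerCoarse = 4, seed = seed)
    v <- fixtureV(land$units, seed = seed)
    P <- aggregateProportions(v, land$units)
    expect_equal(P, oracleAggregate(v, land$units), tolerance = 1e-12)
  }
  # identity case: one fine unit per coarse unit
  land1 <- fixtureLandscape(nCoarse = 4, finePerCoarse = 1, seed = 2)
  v1 <- fixtureV(land1$units, seed = 5)
  P1 <- aggregateProportions(v1, land1$units)
  ids <- unitIds(land1$units)
  cids <- as.character(coarseIds(land1$units))
  off <- which(row(P1) != col(P1))
  expect_equal(P1[cids, cids][off], v1[ids, ids][off])
  # constant v, single destination per coarse unit: P equals the constant
  vC <- v1; vC[] <- 0.004; diag(vC) <- NA
  PC <- aggregateProportions(vC, land1$units)
  expect_equal(PC[row(PC) != col(PC)],
               rep(0.004, sum(row(PC) != col(PC))))
})

test_that("aggregation is invariant to unit order and monotone in v", {
  land <- fixtureLandscape(nCoarse = 3, finePerCoarse = 3, seed = 6)
  v <- fixtureV(land$units, seed = 6)
  P <- aggregateProportions(v, land$units)
  perm <- sample(nUnits(land$units))
  uPerm <- UnitTable(as.data.frame(land$units)[perm, ])
  expect_equal(aggregateProportions(v, uPerm), P)
  # shrinking every v shrinks every coarse proportion
  Phalf <- aggregateProportions(v * 0.5, land$units)
  off <- which(row(P) != col(P))
  expect_true(all(Phalf[off] < P[off]))
  # weighted-mean bound: P_IJ between min and max origin row sums
  grp <- as.character(coarseIds(land$units))
  ids <- unitIds(land$units)
  for (I in unique(grp)) for (J in setdiff(unique(grp), I)) {
    rs <- sapply(ids[grp == I], function(i)
      sum(v[i, ids[grp == J]], na.rm = TRUE))
    expect_gte(P[I, J], min(rs) - 1e-12)
    expect_lte(P[I, J], max(rs) + 1e-12)
  }
})

test_that("binomial log-likelihood matches closed forms and is additive", {
  mkFlows <- function(M, n) CoarseFlows(M, n)
  M <- matrix(c(0, 3, 0, 0), 2, 2, byrow = TRUE,
              dimnames = list(c("A", "B"), c("A", "B")))
  fl <- mkFlows(M, c(10, 10))
  P <- matrix(c(NA, 0.3, 0.3, NA), 2, 2, byrow = TRUE,
              dimnames = list(c("A", "B"), c("A", "B")))
  P[is.na(P)] <- 0.5
  ll <- binomialLogLik(P, fl, includeConstant = TRUE)
  expect_equal(ll, lchoose(10, 3) + 3 * log(0.3) + 7 * log(0.7) +
                 dbinom(0, 10, 0.3, log = TRUE))
  # M = 0 pair contributes N log(1 - P)
  M0 <- matrix(0, 2, 2, dimnames = dimnames(M))
  ll0 <- binomialLogLik(P, mkFlows(M0, c(10, 10)))
  expect_equal(ll0, 2 * 10 * log(0.7))
  # additivity over pairs
  expect_equal(binomialLogLik(P, fl),
               3 * log(0.3) + 7 * log(0.7) + 10 * log(0.7))
  expect_error(binomialLogLik(P * 10, fl), "outside")
  expect_equal(binomialLogLik(P * 10, fl, onInvalid = "-Inf"), -Inf)
})

test_that("Cauchy log prior matches its closed form and is symmetric", {
  expect_equal(cauchyLogPrior(0, scales = 2.5), -log(2.5 * pi))
  expect_equal(cauchyLogPrior(0, scales = 10), -log(10 * pi))
  expect_equal(-log(2.5 * pi), -2.0610, tolerance = 1e-4)
  expect_equal(-log(10 * pi), -3.4473, tolerance = 1e-4)
  b <- c(1.3, -0.2, 4)
  expect_equal(cauchyLogPrior(b), cauchyLogPrior(-b))
  expect_equal(priorScales(3), c(10, 2.5, 2.5, 2.5))
  expect_error(cauchyLogPrior(c(0, 0), scales = 2.5), "align")
})

test_that("log posterior composes likelihood and prior; prior tails dominate", {
  land <- fixtureLandscape(nCoarse = 3, finePerCoarse = 3, seed = 8)
  sim <- simulateFlows(land$units, land$adj, land$dist,
                       defaultTrueBeta(), fraction = 0.1, seed = 8)
  beta <- defaultTrueBeta() * 0.9
  lp <- logPosterior(beta, sim$truth$design, land$units, sim$flows)
  v <- predictVij(beta, sim$truth$design)
  P <- aggregateProportions(v, land$units)
  expect_equal(lp, binomialLogLik(P, sim$flows, onInvalid = "-Inf") +
                 cauchyLogPrior(beta))
  # decreasing as any coefficient grows without bound
  bBig <- beta; bBig[2] <- -60
  bBigger <- beta; bBigger[2] <- -600
  expect_gt(logPosterior(beta, sim$truth$design, land$units, sim$flows),
            logPosterior(bBig, sim$truth$design, land$units, sim$flows))
  expect_gt(logPosterior(bBig, sim$truth$design, land$units, sim$flows),
            logPosterior(bBigger, sim$truth$design, land$units, sim$flows))
})

test_that("compiled posterior closures agree with the reference composition", {
  land <- fixtureLandscape(nCoarse = 3, finePerCoarse = 4, seed = 10)
  sim <- simulateFlows(land$units, land$adj, land$dist, defaultTrueBeta(),
                       fraction = 0.1, seed = 10)
  m <- makeModelPosterior(sim$truth$design, sim$flows)
  set.seed(11)
  for (k in 1:10) {
    beta <- defaultTrueBeta() + rnorm(4, 0, 0.3)
    expect_equal(m$logPost(beta),
                 logPosterior(beta, sim$truth$design, land$units, sim$flows),
                 tolerance = 1e-10)
    expect_equal(m$deviance(beta), -2 * m$logLik(beta))
  }
})

test_that("coarse flow tables round-trip through delimited text", {
  land <- fixtureLandscape(nCoarse = 3, finePerCoarse = 2, seed = 12)
  sim <- simulateFlows(land$units, land$adj, land$dist, defaultTrueBeta(),
                       fraction = 0.1, seed = 12)
  cp <- withr::local_tempfile(fileext = ".tsv")
  sp <- withr::local_tempfile(fileext = ".tsv")
  writeCoarseFlows(sim$flows, cp, sp)
  back <- readCoarseFlows(cp, sp)
  expect_equal(flowCounts(back), flowCounts(sim$flows))
  expect_equal(originSizes(back), originSizes(sim$flows))
})
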