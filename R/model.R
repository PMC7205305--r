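# The cross-scale spatial interaction model: logistic-linear fine-pair
# migration proportions, population-weighted aggregation to coarse pairs,
# the binomial likelihood of coarse observed counts, and Cauchy priors.

# numerically stable inverse logit, clamped so v never rounds to exactly
# 0 or 1 (linear predictors beyond +-500 are astronomically unlikely after
# covariate standardization but must not produce log(0))
.invlogit <- function(eta) plogis(pmin(pmax(eta, -500), 500))

#' Predict fine-pair migration proportions
#'
#' Applies the logistic-linear model: `logit(v_ij)` is the intercept plus
#' the standardized covariates times their coefficients; `v_ij` is the
#' modelled proportion of origin i's people migrating to destination j over
#' the study window. Self-pairs are undefined (`NA` diagonal).
#'
#' @param beta numeric coefficient vector: intercept first, then one slope
#'   per design covariate, in design column order.
#' @param design a [PairDesign-class].
#' @return square matrix of proportions in (0, 1) with unit ids as dimnames
#'   and an `NA` diagonal.
#' @examples
#' # with all coefficients zero every proportion is logit^{-1}(0) = 0.5
#' @export
predictVij <- function(beta, design) {
  stopifnot(is(design, "PairDesign"))
  if (length(beta) != ncol(design@X) + 1)
    stop("beta length must be ncol(design) + 1 (intercept first)")
  eta <- beta[1] + as.vector(design@X %*% beta[-1])
  v <- .invlogit(eta)
  ids <- unique(c(design@origin, design@dest))
  out <- matrix(NA_real_, length(ids), length(ids), dimnames = list(ids, ids))
  out[cbind(design@origin, design@dest)] <- v
  out
}

#' Aggregate fine-pair proportions to coarse-pair proportions
#'
#' The coarse-pair proportion is the population-weighted average over origin
#' units i in I of the total proportion of i's people migrating to any fine
#' unit of J:
#' `P_IJ = sum_{i in I} N_i * sum_{j in J} v_ij / sum_{i in I} N_i`.
#' Entries for I = J are produced (from the off-diagonal fine pairs within
#' the coarse unit) but are excluded from the likelihood by its fitting
#' domain I != J.
#'
#' @param v square fine-pair proportion matrix (diagonal ignored).
#' @param units a [UnitTable-class]; populations are the weights.
#' @param partition optional named vector mapping fine id to group id;
#'   defaults to the coarse membership of `units`.
#' @param literalDenominator if `TRUE`, use the literally-printed
#'   denominator `sum_i sum_j N_i` (which divides the above by the number of
#'   destination units in J); kept for auditability, not for analysis.
#' @return square matrix of coarse-pair proportions, group ids as dimnames.
#' @export
aggregateProportions <- function(v, units, partition = NULL,
                                 literalDenominator = FALSE) {
  stopifnot(is(units, "UnitTable"))
  if (is.null(partition)) partition <- coarseIds(units)
  ids <- unitIds(units)
  if (length(bad <- setdiff(ids, names(partition))))
    stop("empty coarse unit / unmapped units: ", paste(bad, collapse = ", "))
  v <- v[ids, ids, drop = FALSE]
  diag(v) <- 0
  grp <- as.character(partition[ids])
  N <- populations(units)[ids]
  # destination aggregation: S[i, J] = sum_{j in J} v_ij
  S <- t(rowsum(t(v), grp))
  # origin aggregation: population-weighted mean over i in I
  num <- rowsum(N * S, grp)
  den <- as.vector(rowsum(N, grp))
  P <- num / den
  if (literalDenominator) {
    sizeJ <- table(grp)[colnames(P)]
    P <- sweep(P, 2, as.numeric(sizeJ), "/")
  }
  P[order(rownames(P)), order(colnames(P)), drop = FALSE]
}

#' Binomial log-likelihood of coarse observed counts
#'
#' Sum over ordered coarse pairs I != J of the binomial log-probability of
#' the observed migrant count `M_IJ` out of `n_I` trials with success
#' probability `P_IJ`. The combinatorial constant
#' `ln n_I! - ln M_IJ! - ln (n_I - M_IJ)!` does not involve the
#' coefficients and is omitted unless requested.
#'
#' @param P square matrix of coarse-pair proportions covering the flow pairs.
#' @param flows a [CoarseFlows-class].
#' @param includeConstant add the log binomial coefficient (via log-gamma)?
#' @param onInvalid `"error"` (default) or `"-Inf"`: behaviour when some
#'   `P_IJ` lies outside (0, 1) on a pair with data. `-Inf` is what a
#'   posterior sampler wants for an impossible parameter value.
#' @return scalar log-likelihood.
#' @export
binomialLogLik <- function(P, flows, includeConstant = FALSE,
                           onInvalid = c("error", "-Inf")) {
  stopifnot(is(flows, "CoarseFlows"))
  onInvalid <- match.arg(onInvalid)
  M <- flows@counts
  nI <- flows@originSizes
  g <- rownames(M)
  if (length(bad <- setdiff(g, rownames(P))))
    stop("proportions missing for: ", paste(bad, collapse = ", "))
  P <- P[g, g, drop = FALSE]
  off <- which(row(M) != col(M))
  m <- M[off]; p <- P[off]; n <- nI[row(M)[off]]
  if (any(m > n)) stop("count exceeds origin size")
  if (any(p <= 0 | p >= 1)) {
    if (onInvalid == "error") stop("P_IJ outside (0,1)")
    return(-Inf)
  }
  ll <- sum(m * log(p) + (n - m) * log1p(-p))
  if (includeConstant)
    ll <- ll + sum(lgamma(n + 1) - lgamma(m + 1) - lgamma(n - m + 1))
  ll
}

#' Default prior scales for the migration model
#'
#' Independent Cauchy priors centred at 0: scale 10 for the intercept and
#' 2.5 for every slope — weakly informative on the logit scale for
#' covariates standardized to sd 0.5 / range 1.
#'
#' @param nCovariates number of slope parameters.
#' @return numeric vector of prior scales, intercept first.
#' @export
priorScales <- function(nCovariates) c(10, rep(2.5, nCovariates))

#' Log prior density of the coefficients
#'
#' Sum of independent Cauchy(0, scale) log-densities.
#'
#' @param beta coefficient vector, intercept first.
#' @param scales prior scales aligned to `beta`; defaults to
#'   [priorScales()].
#' @return scalar log prior density.
#' @export
cauchyLogPrior <- function(beta, scales = priorScales(length(beta) - 1)) {
  if (length(scales) != length(beta)) stop("scales must align with beta")
  if (any(scales <= 0)) stop("prior scales must be positive")
  sum(dcauchy(beta, location = 0, scale = scales, log = TRUE))
}

#' Log posterior of the cross-scale model
#'
#' Composition of the model pipeline at a single coefficient vector:
#' predict fine-pair proportions, aggregate them to the coarse level, score
#' the observed coarse counts under the binomial likelihood
#' (constant omitted — it cancels in MCMC), and add the Cauchy log prior.
#'
#' @inheritParams predictVij
#' @param units a [UnitTable-class].
#' @param flows a [CoarseFlows-class] at the aggregation level.
#' @param partition optional fine-to-group mapping (defaults to coarse
#'   membership).
#' @param scales prior scales, intercept first.
#' @return scalar log posterior (`-Inf` for parameter values driving some
#'   aggregated proportion out of (0,1)).
#' @export
logPosterior <- function(beta, design, units, flows, partition = NULL,
                         scales = priorScales(length(beta) - 1)) {
  v <- predictVij(beta, design)
  P <- aggregateProportions(v, units, partition)
  binomialLogLik(P, flows, includeConstant = FALSE, onInvalid = "-Inf") +
    cauchyLogPrior(beta, scales)
}

#' Compile fast likelihood/posterior closures for sampling
#'
#' Precomputes the pair-to-coarse aggregation weights so that each
#' evaluation is one dense matrix-vector product plus a grouped sum; the
#' returned closures are what the sampler and DIC computation call many
#' thousands of times. Results agree with the reference composition
#' [logPosterior()] to floating-point rounding.
#'
#' @param design a [PairDesign-class].
#' @param flows a [CoarseFlows-class]; its units must match the design's
#'   coarse (or partition) groups.
#' @param partition optional named fine-to-group mapping; defaults to the
#'   design's coarse membership.
#' @param scales prior scales, intercept first.
#' @return list with elements `logPost(beta)`, `logLik(beta)`,
#'   `deviance(beta)`, `predictP(beta)` and `nPar`.
#' @export
makeModelPosterior <- function(design, flows, partition = NULL,
                               scales = priorScales(ncol(design@X))) {
  stopifnot(is(design, "PairDesign"), is(flows, "CoarseFlows"))
  if (is.null(partition)) {
    gO <- design@coarseOrigin; gD <- design@coarseDest
  } else {
    gO <- as.character(partition[design@origin])
    gD <- as.character(partition[design@dest])
    if (anyNA(gO) || anyNA(gD)) stop("partition does not cover the design")
  }
  grpLevels <- sort(unique(c(gO, gD)))
  flowIds <- rownames(flows@counts)
  if (length(setdiff(flowIds, grpLevels)))
    stop("flows refer to groups absent from the design")
  # cross-group pairs only; each keyed to its ordered group pair
  cross <- which(gO != gD)
  pairKey <- factor(paste(gO[cross], gD[cross], sep = "\r"))
  # weight of each design row: origin unit population over the summed unit
  # populations of its group (each unit counted once, not once per pair)
  unitPop <- tapply(design@originPop, design@origin, max)
  grpOfUnit <- tapply(gO, design@origin, function(x) x[1])
  popByGroup <- tapply(unitPop, grpOfUnit, sum)
  w <- design@originPop[cross] / as.numeric(popByGroup[gO[cross]])
  Xf <- cbind(1, design@X)
  keyLevels <- levels(pairKey)
  keyIdx <- as.integer(pairKey)
  # observed data aligned to keys
  Mfull <- flows@counts
  off <- which(row(Mfull) != col(Mfull))
  obsO <- rownames(Mfull)[row(Mfull)[off]]
  obsD <- colnames(Mfull)[col(Mfull)[off]]
  obsKey <- match(paste(obsO, obsD, sep = "\r"), keyLevels)
  if (anyNA(obsKey)) stop("observed flow pair not covered by the design")
  mObs <- Mfull[off]
  nObs <- flows@originSizes[obsO]
  Xc <- Xf[cross, , drop = FALSE]
  p <- ncol(Xf)
  predictP <- function(beta) {
    eta <- as.vector(Xc %*% beta)
    v <- .invlogit(eta)
    agg <- rowsum(w * v, keyIdx, reorder = TRUE)
    P <- as.vector(agg)[obsKey]
    P
  }
  logLik <- function(beta) {
    P <- predictP(beta)
    if (any(P <= 0 | P >= 1)) return(-Inf)
    sum(mObs * log(P) + (nObs - mObs) * log1p(-P))
  }
  list(
    logPost = function(beta) {
      ll <- logLik(beta)
      if (!is.finite(ll)) return(-Inf)
      ll + sum(dcauchy(beta, 0, scales, log = TRUE))
    },
    logLik = logLik,
    deviance = function(beta) -2 * logLik(beta),
    predictP = predictP,
    nPar = p)
}

#' Read / write coarse flow tables
#'
#' Counts as tab-separated `origin_id`, `dest_id`, `count` (self pairs
#' omitted) and origin sizes as `origin_id`, `n`.
#'
#' @param countsPath path of the pair-count table.
#' @param sizesPath path of the origin-size table.
#' @return `readCoarseFlows`: a [CoarseFlows-class].
#' @export
readCoarseFlows <- function(countsPath, sizesPath) {
  cts <- read.table(countsPath, header = TRUE, sep = "\t", comment.char = "#",
                    colClasses = c("character", "character", "numeric"))
  sz <- read.table(sizesPath, header = TRUE, sep = "\t", comment.char = "#",
                   colClasses = c("character", "numeric"))
  ids <- sort(unique(c(cts[[1]], cts[[2]], sz[[1]])))
  M <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  M[cbind(cts[[1]], cts[[2]])] <- cts[[3]]
  n <- setNames(rep(NA_real_, length(ids)), ids)
  n[sz[[1]]] <- sz[[2]]
  if (anyNA(n)) stop("origin sizes missing for some units")
  CoarseFlows(M, n)
}

#' @rdname readCoarseFlows
#' @param flows a [CoarseFlows-class] to write.
#' @export
writeCoarseFlows <- function(flows, countsPath, sizesPath) {
  stopifnot(is(flows, "CoarseFlows"))
  M <- flows@counts
  off <- which(row(M) != col(M))
  cts <- data.frame(origin_id = rownames(M)[row(M)[off]],
                    dest_id = colnames(M)[col(M)[off]],
                    count = M[off])
  write.table(cts, countsPath, sep = "\t", quote = FALSE, row.names = FALSE)
  sz <- data.frame(origin_id = names(flows@originSizes),
                   n = as.numeric(flows@originSizes))
  write.table(sz, sizesPath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(countsPath)
}
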