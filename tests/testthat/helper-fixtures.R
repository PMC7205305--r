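# Shared fixtures and independent oracles, all built in code at test time.

# deterministic hand-rolled unit table: n fine units across nCoarse coarse
# units, attributes seeded but reproducible
fixtureUnits <- function(n = 6, nCoarse = 2, seed = 1) {
  set.seed(seed)
  coarse <- sprintf("C%d", rep_len(seq_len(nCoarse), n))
  coarse <- sort(coarse)
  UnitTable(data.frame(
    id = sprintf("u%02d", seq_len(n)),
    coarse_id = coarse,
    population = round(rlnorm(n, log(5000), 0.8)) + 10,
    urban_prop = runif(n),
    gcp_pc = rlnorm(n, log(4000), 0.4),
    cx = runif(n, 0, 100), cy = runif(n, 0, 100),
    stringsAsFactors = FALSE))
}

fixtureLandscape <- function(nCoarse = 4, finePerCoarse = 4, seed = 1,
                             samplingFraction = 0.1) {
  generateLandscape(landscapeConfig(nCoarse = nCoarse,
                                    finePerCoarse = finePerCoarse,
                                    samplingFraction = samplingFraction,
                                    seed = seed))
}

# random fine-pair proportion matrix for a unit table
fixtureV <- function(units, seed = 1, scale = 0.01) {
  set.seed(seed)
  ids <- unitIds(units)
  v <- matrix(runif(length(ids)^2, 0, scale), length(ids),
              dimnames = list(ids, ids))
  diag(v) <- NA
  v
}

# assemble a PosteriorSample from a [iter, chain, param] array, for testing
# the diagnostics in isolation
fixtureSample <- function(draws, devFun = function(b) 0, deviance = NULL) {
  d <- dim(draws)
  if (is.null(dimnames(draws)[[3]]))
    dimnames(draws)[[3]] <- paste0("p", seq_len(d[3]))
  if (is.null(deviance)) {
    deviance <- matrix(NA_real_, d[1], d[2])
    for (ch in seq_len(d[2]))
      deviance[, ch] <- apply(draws[, ch, , drop = FALSE], 1,
                              function(b) devFun(as.numeric(b)))
  }
  rh <- if (d[2] >= 2)
    setNames(vapply(seq_len(d[3]), function(k)
      tryCatch(gelmanRubin(matrix(draws[, , k], d[1], d[2])),
               error = function(e) NA_real_), numeric(1)),
      dimnames(draws)[[3]])
  else setNames(rep(NA_real_, d[3]), dimnames(draws)[[3]])
  new("PosteriorSample", draws = draws,
      logPost = matrix(0, d[1], d[2]), deviance = deviance, rhat = rh,
      devFun = devFun, settings = list())
}

# ---- independent oracles ----

# one full imputation by naive loops, sweep-by-sweep snapshot semantics
oracleImpute <- function(v) {
  nr <- nrow(v); nc <- ncol(v)
  while (anyNA(v)) {
    snap <- v
    progressed <- FALSE
    for (r in seq_len(nr)) for (c in seq_len(nc)) {
      if (!is.na(snap[r, c])) next
      nb <- c()
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0 && dc == 0) next
        rr <- r + dr; cc <- c + dc
        if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc && !is.na(snap[rr, cc]))
          nb <- c(nb, snap[rr, cc])
      }
      if (length(nb)) { v[r, c] <- mean(nb); progressed <- TRUE }
    }
    if (!progressed) stop("oracle stuck")
  }
  v
}

# zonal stats by explicit loops
oracleZonal <- function(v, z, stat) {
  labs <- sort(unique(z[z > 0]))
  vapply(labs, function(l) {
    cells <- v[z == l]
    if (stat == "mean") mean(cells) else sum(cells)
  }, numeric(1))
}

# brute-force coarse aggregation by double loop over coarse pairs
oracleAggregate <- function(v, units, partition = NULL) {
  if (is.null(partition)) partition <- coarseIds(units)
  ids <- unitIds(units)
  N <- populations(units)
  grp <- as.character(partition[ids])
  G <- sort(unique(grp))
  P <- matrix(NA_real_, length(G), length(G), dimnames = list(G, G))
  for (I in G) for (J in G) {
    num <- 0; den <- 0
    for (i in ids[grp == I]) {
      si <- 0
      for (j in ids[grp == J]) if (i != j) si <- si + v[i, j]
      num <- num + N[i] * si
      den <- den + N[i]
    }
    P[I, J] <- num / den
  }
  P
}

# Pearson correlation by the explicit covariance formula
oracleCor <- function(x, y) {
  n <- length(x)
  sxy <- sum((x - mean(x)) * (y - mean(y))) / (n - 1)
  sxy / (sd(x) * sd(y))
}

# population-weighted centroid by loops
oracleCentroid <- function(popGrid, z) {
  v <- gridValues(popGrid)
  nr <- nrow(v)
  cs <- popGrid@cellSize
  labs <- sort(unique(z[z > 0]))
  t(vapply(labs, function(l) {
    sx <- 0; sy <- 0; sw <- 0
    for (r in seq_len(nr)) for (c in seq_len(ncol(v))) {
      if (z[r, c] != l) next
      w <- v[r, c]
      sx <- sx + w * (popGrid@xll + (c - 0.5) * cs)
      sy <- sy + w * (popGrid@yll + (nr - r + 0.5) * cs)
      sw <- sw + w
    }
    c(sx / sw, sy / sw)
  }, numeric(2)))
}
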