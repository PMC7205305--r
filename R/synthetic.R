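# Synthetic multi-level administrative landscapes and migration
# observations with known ground truth. The generator emulates the
# statistical structure of the real inputs: fine units nested in coarse
# units, heavy-tailed populations, urban fractions in [0, 1], per-capita
# economic values, planar contiguity, and binomially sampled 5-year flows
# observed at a census-sampling fraction.

#' Configuration of a synthetic landscape
#'
#' Defaults emulate a realistic national administrative geography at desk
#' scale: log-normal municipal populations (median ~15k persons,
#' sdlog 1 — heavy-tailed), Beta(2, 2) urban fractions, log-normal
#' per-capita gross cell product (median ~6000, sdlog 0.5), coarse units
#' of 100 km extent, and a 10% census-sampling fraction.
#'
#' @param nCoarse number of coarse (department-like) units.
#' @param finePerCoarse fine units per coarse unit: a single integer or a
#'   `c(min, max)` range sampled per coarse unit.
#' @param popMeanlog,popSdlog log-normal population parameters.
#' @param urbanShape1,urbanShape2 Beta parameters of the urban fraction.
#' @param gcpMeanlog,gcpSdlog log-normal per-capita economic product
#'   parameters.
#' @param coarseExtent planar edge length of one coarse unit (km).
#' @param samplingFraction fraction of the population enumerated, (0, 1].
#' @param seed integer seed.
#' @return validated list of class `landscapeConfig`.
#' @export
landscapeConfig <- function(nCoarse = 8, finePerCoarse = 6,
                            popMeanlog = log(15000), popSdlog = 1,
                            urbanShape1 = 2, urbanShape2 = 2,
                            gcpMeanlog = log(6000), gcpSdlog = 0.5,
                            coarseExtent = 100, samplingFraction = 0.1,
                            seed = 1L) {
  stopifnot(nCoarse >= 1, all(finePerCoarse >= 1),
            length(finePerCoarse) %in% 1:2,
            popSdlog > 0, urbanShape1 > 0, urbanShape2 > 0, gcpSdlog > 0,
            coarseExtent > 0,
            samplingFraction > 0, samplingFraction <= 1)
  structure(as.list(environment()), class = "landscapeConfig")
}

# Brute-force Delaunay adjacency of planar seed points: i and j are
# contiguous iff they share a Delaunay edge (equivalently, their Voronoi
# cells share a boundary). Empty-circumcircle test over all triples;
# assumes general position, which holds a.s. for continuous coordinates.
.delaunayAdjacency <- function(x, y) {
  n <- length(x)
  A <- matrix(0, n, n)
  if (n > 400) stop("tessellation limited to 400 seed points")
  if (n == 2) { A[1, 2] <- A[2, 1] <- 1; return(A) }
  scale2 <- max(diff(range(x)), diff(range(y)))^2
  trip <- combn(n, 3)
  for (t in seq_len(ncol(trip))) {
    i <- trip[1, t]; j <- trip[2, t]; k <- trip[3, t]
    ax <- x[i]; ay <- y[i]; bx <- x[j]; by <- y[j]; cx <- x[k]; cy <- y[k]
    d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
    if (abs(d) < 1e-12 * scale2) next  # collinear triple
    a2 <- ax^2 + ay^2; b2 <- bx^2 + by^2; c2 <- cx^2 + cy^2
    ux <- (a2 * (by - cy) + b2 * (cy - ay) + c2 * (ay - by)) / d
    uy <- (a2 * (cx - bx) + b2 * (ax - cx) + c2 * (bx - ax)) / d
    r2 <- (ax - ux)^2 + (ay - uy)^2
    dd <- (x - ux)^2 + (y - uy)^2
    dd[c(i, j, k)] <- Inf
    if (all(dd >= r2 * (1 - 1e-12))) {
      A[i, j] <- A[j, i] <- 1
      A[j, k] <- A[k, j] <- 1
      A[i, k] <- A[k, i] <- 1
    }
  }
  A
}

#' Generate a synthetic nested administrative landscape
#'
#' Coarse units are laid out as square cells on a planar grid; each coarse
#' unit receives its fine units at uniform random seed points inside its
#' cell. Unit attributes are drawn from the configured distributions;
#' contiguity is the Delaunay tessellation of the seed points (two units
#' are contiguous iff their Voronoi cells share a boundary) and distances
#' are Euclidean between seed points, which play the role of
#' population-weighted centroids.
#'
#' @param cfg a [landscapeConfig()].
#' @return list with `units` (a [UnitTable-class]), `adj` (0/1 contiguity
#'   matrix), `dist` (km distance matrix) and `cfg`.
#' @export
generateLandscape <- function(cfg = landscapeConfig()) {
  stopifnot(inherits(cfg, "landscapeConfig"))
  set.seed(cfg$seed)
  ncolC <- ceiling(sqrt(cfg$nCoarse))
  L <- cfg$coarseExtent
  nFine <- if (length(cfg$finePerCoarse) == 1)
    rep(cfg$finePerCoarse, cfg$nCoarse)
  else
    sample(cfg$finePerCoarse[1]:cfg$finePerCoarse[2], cfg$nCoarse,
           replace = TRUE)
  coarseId <- sprintf("D%02d", seq_len(cfg$nCoarse))
  rows <- lapply(seq_len(cfg$nCoarse), function(k) {
    cellX <- ((k - 1) %% ncolC) * L
    cellY <- ((k - 1) %/% ncolC) * L
    m <- nFine[k]
    data.frame(
      id = sprintf("%s.M%02d", coarseId[k], seq_len(m)),
      coarse_id = coarseId[k],
      population = rlnorm(m, cfg$popMeanlog, cfg$popSdlog),
      urban_prop = rbeta(m, cfg$urbanShape1, cfg$urbanShape2),
      gcp_pc = rlnorm(m, cfg$gcpMeanlog, cfg$gcpSdlog),
      cx = cellX + runif(m, 0, L),
      cy = cellY + runif(m, 0, L),
      stringsAsFactors = FALSE)
  })
  units <- UnitTable(do.call(rbind, rows))
  u <- units@units
  adj <- .delaunayAdjacency(u$cx, u$cy)
  dimnames(adj) <- list(u$id, u$id)
  list(units = units, adj = adj, dist = pairwiseDistances(units), cfg = cfg)
}

#' Simulate coarse-level migration observations at known coefficients
#'
#' Runs the model generatively: builds the standardized pair design for
#' `spec`, computes fine-pair proportions at `betaTrue` and their
#' population-weighted coarse aggregation, sets the origin sample size
#' `n_I = round(fraction * N_I)`, and draws each ordered coarse count
#' independently as `Binomial(n_I, P_IJ)` — matching the likelihood the
#' fitting side uses, so the model is correctly specified by construction.
#'
#' @param units,adj,dist a landscape as from [generateLandscape()].
#' @param betaTrue true coefficients, intercept first.
#' @param spec covariate names (see [covariateCatalogue()]).
#' @param fraction sampling fraction in (0, 1].
#' @param seed integer seed for the binomial draws.
#' @return list with `flows` (a [CoarseFlows-class]), `truth` (list:
#'   `beta`, `spec`, `v`, `P`, `design`, `nI`) .
#' @export
simulateFlows <- function(units, adj, dist, betaTrue,
                          spec = baseGravitySpec(), fraction = 0.1,
                          seed = 1L) {
  stopifnot(is(units, "UnitTable"), all(is.finite(betaTrue)))
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  design <- buildPairDesign(units, adj, dist, spec)
  v <- predictVij(betaTrue, design)
  P <- aggregateProportions(v, units)
  off <- which(row(P) != col(P))
  if (any(P[off] >= 1)) stop("implausible truth: some P_IJ >= 1")
  NI <- tapply(populations(units), coarseIds(units), sum)
  NI <- NI[rownames(P)]
  nI <- round(fraction * NI)
  if (any(nI < 1)) stop("sampling fraction leaves an origin unobserved")
  set.seed(seed)
  M <- matrix(0, nrow(P), ncol(P), dimnames = dimnames(P))
  M[off] <- rbinom(length(off), size = nI[row(P)[off]], prob = P[off])
  flows <- CoarseFlows(M, nI)
  list(flows = flows,
       truth = list(beta = betaTrue, spec = spec, v = v, P = P,
                    design = design, nI = nI))
}

#' Merge contiguous fine units into an intermediate-level partition
#'
#' Emulates intermediate census units: groups of contiguous fine units that
#' never straddle a coarse boundary, mixed with singletons. Starting from
#' all-singleton groups, randomly chosen pairs of adjacent groups within
#' the same coarse unit are merged until `targetGroups` groups remain.
#' Every produced group is connected under the adjacency.
#'
#' @param units a [UnitTable-class].
#' @param adj 0/1 contiguity matrix over the fine units.
#' @param targetGroups desired number of groups; must be between the number
#'   of coarse units and the number of fine units.
#' @param seed integer seed.
#' @return named character vector mapping fine id to group id, with
#'   attribute `"coarse"` mapping group id to its coarse unit.
#' @export
coarsenPartition <- function(units, adj, targetGroups, seed = 1L) {
  stopifnot(is(units, "UnitTable"))
  ids <- unitIds(units)
  cid <- coarseIds(units)
  n <- length(ids)
  if (targetGroups > n) stop("targetGroups exceeds the number of fine units")
  if (targetGroups < length(unique(cid)))
    stop("targetGroups below the number of coarse units")
  set.seed(seed)
  grp <- seq_len(n)  # group index per unit
  adj <- adj[ids, ids, drop = FALSE]
  while (length(unique(grp)) > targetGroups) {
    cand <- which(adj == 1 & outer(cid, cid, "==") &
                    outer(grp, grp, "!=") & upper.tri(adj), arr.ind = TRUE)
    if (nrow(cand) == 0)
      stop("cannot reach targetGroups: no mergeable contiguous pair left")
    pick <- cand[sample.int(nrow(cand), 1), ]
    grp[grp == grp[pick[2]]] <- grp[pick[1]]
  }
  # stable group labels: <coarse>.<k> in order of first appearance
  lab <- character(n)
  for (cc in unique(cid)) {
    sel <- which(cid == cc)
    sub <- match(grp[sel], unique(grp[sel]))
    lab[sel] <- sprintf("%s.G%02d", cc, sub)
  }
  part <- setNames(lab, ids)
  coarseOfGroup <- tapply(cid, lab, function(x) x[1])
  attr(part, "coarse") <- setNames(as.character(coarseOfGroup),
                                   names(coarseOfGroup))
  part
}

#' Default generative coefficients
#'
#' Signs follow a typical fitted fine-scale migration model: strongly
#' negative distance, positive origin population, mildly negative
#' destination population, and a low intercept so 5-year pairwise migration
#' proportions are small.
#'
#' @param spec covariate names the coefficients align to.
#' @return named numeric vector, intercept first.
#' @export
defaultTrueBeta <- function(spec = baseGravitySpec()) {
  ref <- c(DIST_ij = -2.4, POP_i = 0.16, POP_j = -0.12, CONT_ij = 2.2,
           URBANPROP_i = -0.7, URBANPROP_j = 0.8, TINY_j = -0.7,
           MAJCEN_j = 1.5, GECON_i = -0.3, GECON_j = 0.1, TINY_i = 0.1,
           MAJCEN_i = 0.1, URBANPROP_j = 0.8, PERC_i = 0.1, PERC_j = 0.1)
  beta <- c(Intercept = -7, ref[spec])
  beta[is.na(beta)] <- 0.1
  names(beta) <- c("Intercept", spec)
  beta
}

#' Write ground truth as delimited text
#'
#' @param truth the `truth` element returned by [simulateFlows()].
#' @param path file path.
#' @export
writeGroundTruth <- function(truth, path) {
  df <- data.frame(parameter = names(truth$beta),
                   true_value = as.numeric(truth$beta))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
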