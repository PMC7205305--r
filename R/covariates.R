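# Covariate construction and standardization for the pairwise design.
#
# Continuous covariates are scaled to mean 0 and standard deviation 0.5,
# binary covariates centred to mean 0 with range 1 (Gelman-style scaling),
# so slope magnitudes are comparable across terms and weakly-informative
# Cauchy priors have a common meaning.

#' Canonical covariate catalogue
#'
#' The covariates the migration model can draw on: pair distance, origin and
#' destination population, per-capita economic product, urban proportion,
#' population percentile, tiny-population and major-centre indicators, and
#' boundary contiguity.
#'
#' @return character vector of all recognised covariate names.
#' @export
covariateCatalogue <- function() {
  c("DIST_ij", "POP_i", "POP_j", "GECON_i", "GECON_j", "TINY_i", "TINY_j",
    "URBANPROP_i", "URBANPROP_j", "PERC_i", "PERC_j", "MAJCEN_i", "MAJCEN_j",
    "CONT_ij")
}

.binaryCovariates <- c("TINY_i", "TINY_j", "MAJCEN_i", "MAJCEN_j", "CONT_ij")

#' The base gravity model specification
#'
#' Distance plus origin and destination population: the covariate set every
#' forward-selection run starts from.
#'
#' @return character vector `c("DIST_ij", "POP_j", "POP_i")`.
#' @export
baseGravitySpec <- function() c("DIST_ij", "POP_j", "POP_i")

#' Scale a continuous covariate to mean 0, sd 0.5
#'
#' @param values numeric vector, length >= 2, non-constant.
#' @param name covariate name recorded in the scaler.
#' @return list with `scaled` (the transformed vector) and `scaler` (a
#'   one-row data.frame with columns covariate, kind, center, scale).
#' @examples
#' standardizeContinuous(c(1, 2, 3))$scaled  # -0.5 0 0.5
#' @export
standardizeContinuous <- function(values, name = "x") {
  if (length(values) < 2) stop("need at least 2 values")
  s <- sd(values)
  if (!is.finite(s) || s == 0) stop("zero variance")
  ctr <- mean(values); scl <- 2 * s
  list(scaled = (values - ctr) / scl,
       scaler = data.frame(covariate = name, kind = "continuous",
                           center = ctr, scale = scl,
                           stringsAsFactors = FALSE))
}

#' Centre a binary covariate to mean 0, range 1
#'
#' @param values 0/1 vector with both levels present.
#' @param name covariate name recorded in the scaler.
#' @return list with `scaled` and `scaler` as in [standardizeContinuous()].
#' @export
centerBinary <- function(values, name = "x") {
  if (!all(values %in% c(0, 1))) stop("values must be 0/1")
  if (length(unique(values)) < 2) stop("binary covariate has a single level")
  ctr <- mean(values)
  list(scaled = values - ctr,
       scaler = data.frame(covariate = name, kind = "binary",
                           center = ctr, scale = 1,
                           stringsAsFactors = FALSE))
}

#' Population percentile features
#'
#' Per-unit population percentile (`PERC`, in \[0, 1\], average rank over n)
#' and the strict-threshold indicators `TINY` (population below the 10th
#' percentile value) and `MAJCEN` (population above the 90th percentile
#' value). Percentile thresholds use linear interpolation between order
#' statistics (default quantile type).
#'
#' @param populations positive numeric vector, length >= 2.
#' @return data.frame with columns `PERC`, `TINY`, `MAJCEN`.
#' @export
percentileFeatures <- function(populations) {
  if (length(populations) < 2) stop("need at least 2 populations")
  if (any(populations <= 0)) stop("populations must be positive")
  q10 <- quantile(populations, 0.10, names = FALSE)
  q90 <- quantile(populations, 0.90, names = FALSE)
  data.frame(
    PERC = rank(populations, ties.method = "average") / length(populations),
    TINY = as.numeric(populations < q10),
    MAJCEN = as.numeric(populations > q90))
}

# raw (unscaled) covariate columns for a given ordered-pair index pair (oi, di)
.rawPairCovariates <- function(spec, u, feats, adj, dmat, oi, di) {
  get <- function(nm) switch(nm,
    DIST_ij     = dmat[cbind(oi, di)],
    POP_i       = u$population[oi],
    POP_j       = u$population[di],
    GECON_i     = u$gcp_pc[oi],
    GECON_j     = u$gcp_pc[di],
    URBANPROP_i = u$urban_prop[oi],
    URBANPROP_j = u$urban_prop[di],
    PERC_i      = feats$PERC[oi],
    PERC_j      = feats$PERC[di],
    TINY_i      = feats$TINY[oi],
    TINY_j      = feats$TINY[di],
    MAJCEN_i    = feats$MAJCEN[oi],
    MAJCEN_j    = feats$MAJCEN[di],
    CONT_ij     = adj[cbind(oi, di)],
    stop("unknown covariate: ", nm))
  X <- vapply(spec, get, numeric(length(oi)))
  if (!is.matrix(X)) X <- matrix(X, nrow = length(oi), dimnames = list(NULL, spec))
  X
}

#' Build the ordered-pair design for a model specification
#'
#' Enumerates all ordered pairs of distinct fine units (origin-major order),
#' computes each requested covariate from the unit table, distance matrix and
#' contiguity relation, and standardizes: continuous covariates to mean 0 /
#' sd 0.5 and binary covariates to mean 0 / range 1, fitted over the design
#' rows (where the regression sees the data). The fitted transforms are
#' retained for reuse on new data.
#'
#' @param units a [UnitTable-class].
#' @param adj symmetric 0/1 contiguity matrix over the unit ids
#'   (needed only when `CONT_ij` is in `spec`).
#' @param dist symmetric distance matrix over the unit ids.
#' @param spec character vector of covariate names (see
#'   [covariateCatalogue()]); the intercept is implicit.
#' @return A [PairDesign-class].
#' @export
buildPairDesign <- function(units, adj = NULL, dist, spec = baseGravitySpec()) {
  stopifnot(is(units, "UnitTable"))
  if (anyDuplicated(spec)) stop("duplicate covariates in spec")
  if (length(bad <- setdiff(spec, covariateCatalogue())))
    stop("unknown covariate: ", paste(bad, collapse = ", "))
  u <- units@units
  ids <- u$id
  n <- length(ids)
  if (!all(ids %in% rownames(dist)) || !all(ids %in% colnames(dist)))
    stop("distance matrix does not cover all units")
  dmat <- dist[ids, ids, drop = FALSE]
  if (any(grepl("CONT", spec))) {
    if (is.null(adj)) stop("covariate CONT_ij requested but no adjacency given")
    adj <- adj[ids, ids, drop = FALSE]
  }
  feats <- percentileFeatures(u$population)
  oi <- rep(seq_len(n), each = n - 1)
  di <- unlist(lapply(seq_len(n), function(i) setdiff(seq_len(n), i)),
               use.names = FALSE)
  X <- .rawPairCovariates(spec, u, feats, adj, dmat, oi, di)
  scalers <- vector("list", length(spec))
  for (k in seq_along(spec)) {
    nm <- spec[k]
    res <- if (nm %in% .binaryCovariates) centerBinary(X[, k], nm)
           else standardizeContinuous(X[, k], nm)
    X[, k] <- res$scaled
    scalers[[k]] <- res$scaler
  }
  new("PairDesign",
      origin = ids[oi], dest = ids[di],
      coarseOrigin = u$coarse_id[oi], coarseDest = u$coarse_id[di],
      X = X, originPop = u$population[oi],
      scalers = do.call(rbind, c(scalers,
        list(data.frame(covariate = character(), kind = character(),
                        center = numeric(), scale = numeric())))))
}

#' Apply stored scaling transforms to raw covariate values
#'
#' Reproduces the standardized columns of a fitted design bit-identically
#' from raw values, for use at prediction time.
#'
#' @param scalers data.frame of transforms as stored in a
#'   [PairDesign-class] (`@scalers`) or read by [readScaler()].
#' @param raw numeric matrix of raw covariate columns, named like the
#'   scalers' `covariate` entries.
#' @return matrix of standardized columns, in scaler order.
#' @export
applyScaler <- function(scalers, raw) {
  raw <- as.matrix(raw)
  out <- vapply(seq_len(nrow(scalers)), function(k) {
    nm <- scalers$covariate[k]
    if (!nm %in% colnames(raw)) stop("missing raw column: ", nm)
    (raw[, nm] - scalers$center[k]) / scalers$scale[k]
  }, numeric(nrow(raw)))
  if (!is.matrix(out)) out <- matrix(out, nrow = nrow(raw))
  colnames(out) <- scalers$covariate
  out
}

#' Serialize / restore scaling transforms
#'
#' Written as tab-separated text with 17 significant digits so the
#' centre/scale doubles round-trip exactly.
#'
#' @param scalers data.frame of transforms.
#' @param path file path.
#' @return `readScaler`: the scalers data.frame.
#' @export
writeScaler <- function(scalers, path) {
  out <- scalers
  out$center <- formatC(out$center, format = "g", digits = 17)
  out$scale <- formatC(out$scale, format = "g", digits = 17)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeScaler
#' @export
readScaler <- function(path) {
  s <- read.table(path, header = TRUE, sep = "\t",
                  colClasses = c("character", "character", "numeric", "numeric"))
  names(s) <- c("covariate", "kind", "center", "scale")
  s
}

#' Export a pair design as delimited text
#'
#' Tab-separated with a header row preserving covariate order; bookkeeping
#' columns first, then the standardized covariates.
#'
#' @param design a [PairDesign-class].
#' @param path file path.
#' @export
writePairDesign <- function(design, path) {
  stopifnot(is(design, "PairDesign"))
  df <- data.frame(origin = design@origin, dest = design@dest,
                   coarse_origin = design@coarseOrigin,
                   coarse_dest = design@coarseDest,
                   origin_pop = design@originPop,
                   design@X, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
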