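# Raster preprocessing primitives and geographic bookkeeping: neighbour-mean
# imputation, integer block resampling, zonal statistics, urban proportions,
# population-weighted centroids, centroid distances, and boundary contiguity.

#' Fill missing raster cells with the mean of their Moore neighbours
#'
#' Each missing cell is replaced by the mean of its non-missing 8-neighbours
#' (Moore neighbourhood, truncated at the grid border). Sweeps repeat until
#' no missing cell remains, so values propagate into missing regions; cells
#' that were observed are never altered.
#'
#' @param g a [RasterGrid-class] with at least one non-missing cell.
#' @return A [RasterGrid-class] with no missing cells.
#' @examples
#' v <- matrix(1:9, 3, 3, byrow = TRUE); v[2, 2] <- NA
#' gridValues(imputeMissingCells(RasterGrid(v)))[2, 2]  # mean of neighbours
#' @export
imputeMissingCells <- function(g) {
  stopifnot(is(g, "RasterGrid"))
  v <- g@values
  if (all(is.na(v))) stop("empty grid")
  nr <- nrow(v); nc <- ncol(v)
  while (anyNA(v)) {
    # neighbour sums/counts via shifted copies of the current pass snapshot
    vv <- matrix(0, nr + 2, nc + 2)
    kk <- matrix(0, nr + 2, nc + 2)
    known <- !is.na(v)
    vz <- v; vz[!known] <- 0
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      ri <- (2 + dr):(nr + 1 + dr); ci <- (2 + dc):(nc + 1 + dc)
      vv[ri, ci] <- vv[ri, ci] + vz
      kk[ri, ci] <- kk[ri, ci] + known
    }
    nbSum <- vv[2:(nr + 1), 2:(nc + 1)]
    nbCnt <- kk[2:(nr + 1), 2:(nc + 1)]
    fill <- is.na(v) & nbCnt > 0
    if (!any(fill)) stop("imputation failed to progress")  # unreachable
    v[fill] <- nbSum[fill] / nbCnt[fill]
  }
  RasterGrid(v, g@cellSize, g@xll, g@yll)
}

#' Resample a raster to a finer resolution without smoothing
#'
#' Nearest-neighbour block replication: every input cell becomes a
#' `factor` x `factor` block of identical output cells and the cell size is
#' divided by `factor`. No interpolation is performed.
#'
#' @param g a [RasterGrid-class].
#' @param factor integer upsampling factor, >= 1.
#' @return A [RasterGrid-class] with `factor`-times the rows and columns.
#' @export
resampleNearest <- function(g, factor) {
  stopifnot(is(g, "RasterGrid"))
  if (length(factor) != 1 || !is.finite(factor) || factor < 1 ||
      factor != round(factor))
    stop("factor must be a positive integer")
  f <- as.integer(factor)
  v <- kronecker(g@values, matrix(1, f, f))
  RasterGrid(v, g@cellSize / f, g@xll, g@yll)
}

.zoneLabels <- function(z) {
  lab <- sort(unique(as.vector(z)))
  lab <- lab[!is.na(lab) & lab > 0]
  lab
}

#' Zonal statistics over a raster
#'
#' Mean or sum of grid values within each zone of a zone map (an integer
#' matrix of positive zone labels, same shape as the grid; cells labelled
#' `NA` or 0 belong to no zone).
#'
#' @param g a complete (no missing cells) [RasterGrid-class].
#' @param z integer matrix of zone labels, same shape as `g`.
#' @param stat `"mean"` or `"sum"`.
#' @param zones optional vector of zone labels that must be present; a
#'   requested zone with no cells is an error.
#' @return data.frame with columns `zone` and `value`.
#' @export
zonalStat <- function(g, z, stat = c("mean", "sum"), zones = NULL) {
  stopifnot(is(g, "RasterGrid"))
  stat <- match.arg(stat)
  v <- g@values
  if (!identical(dim(v), dim(z))) stop("grid and zone map shapes differ")
  if (anyNA(v)) stop("grid has missing cells; impute first")
  present <- .zoneLabels(z)
  if (is.null(zones)) zones <- present
  if (length(miss <- setdiff(zones, present)))
    stop("zone with zero cells: ", paste(miss, collapse = ", "))
  fn <- if (stat == "mean") mean else sum
  val <- vapply(zones, function(lab) fn(v[which(z == lab)]), numeric(1))
  data.frame(zone = zones, value = val)
}

#' Urban population proportion per zone
#'
#' For each zone, the population-weighted share of urban cells:
#' `sum(pop * mask) / sum(pop)` over the zone's cells.
#'
#' @param pop population [RasterGrid-class] (no missing cells).
#' @param urbanMask binary 0/1 [RasterGrid-class], same shape.
#' @param z integer matrix of zone labels, same shape.
#' @return data.frame with columns `zone` and `proportion` (in \[0, 1\]).
#' @export
urbanProportion <- function(pop, urbanMask, z) {
  stopifnot(is(pop, "RasterGrid"), is(urbanMask, "RasterGrid"))
  p <- pop@values; m <- urbanMask@values
  if (!identical(dim(p), dim(m)) || !identical(dim(p), dim(z)))
    stop("shapes of population, mask and zone map must match")
  if (!all(m %in% c(0, 1))) stop("urban mask must be binary 0/1")
  zones <- .zoneLabels(z)
  prop <- vapply(zones, function(lab) {
    idx <- which(z == lab)
    tot <- sum(p[idx])
    if (tot <= 0) stop("zone ", lab, " has zero total population")
    sum(p[idx] * m[idx]) / tot
  }, numeric(1))
  data.frame(zone = zones, proportion = prop)
}

# centre coordinates of every cell; rows top-down as stored
.cellCentres <- function(g) {
  nr <- nrow(g@values); nc <- ncol(g@values)
  cx <- g@xll + (col(g@values) - 0.5) * g@cellSize
  cy <- g@yll + (nr - row(g@values) + 0.5) * g@cellSize
  list(x = cx, y = cy)
}

#' Population-weighted centroid of each zone
#'
#' The centroid of a zone is the population-weighted mean of its cell-centre
#' coordinates. These centroids are the points between which migration
#' distances are measured.
#'
#' @param pop population [RasterGrid-class] (no missing cells).
#' @param z integer matrix of zone labels, same shape.
#' @return data.frame with columns `zone`, `cx`, `cy`.
#' @export
popWeightedCentroid <- function(pop, z) {
  stopifnot(is(pop, "RasterGrid"))
  p <- pop@values
  if (!identical(dim(p), dim(z))) stop("shapes differ")
  cc <- .cellCentres(pop)
  zones <- .zoneLabels(z)
  out <- t(vapply(zones, function(lab) {
    idx <- which(z == lab)
    w <- p[idx]
    if (sum(w) <= 0) stop("zone ", lab, " has zero total population")
    c(sum(w * cc$x[idx]) / sum(w), sum(w * cc$y[idx]) / sum(w))
  }, numeric(2)))
  data.frame(zone = zones, cx = out[, 1], cy = out[, 2])
}

#' Pairwise Euclidean centroid distances
#'
#' Distances (in the units of the centroid coordinates, km here) between the
#' population-weighted centroids of all units, as a symmetric matrix with a
#' zero diagonal.
#'
#' @param units a [UnitTable-class] with centroid columns `cx`, `cy`.
#' @return symmetric numeric matrix with unit ids as dimnames.
#' @export
pairwiseDistances <- function(units) {
  stopifnot(is(units, "UnitTable"))
  u <- units@units
  if (anyNA(u$cx) || anyNA(u$cy)) stop("missing centroid coordinates")
  d <- as.matrix(dist(cbind(u$cx, u$cy)))
  dimnames(d) <- list(u$id, u$id)
  d
}

#' Build a boundary-contiguity relation from an edge list
#'
#' Contiguity is the binary indicator that two units share a boundary; it is
#' stored as a symmetric 0/1 matrix over all units with a zero diagonal.
#'
#' @param edges data.frame (or 2-column matrix) of unit-id pairs, one row
#'   per shared boundary; order within a row is irrelevant.
#' @param units a [UnitTable-class]; every edge id must appear in it.
#' @return symmetric 0/1 matrix with unit ids as dimnames.
#' @export
buildContiguity <- function(edges, units) {
  stopifnot(is(units, "UnitTable"))
  ids <- unitIds(units)
  A <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  if (NROW(edges) > 0) {
    a <- as.character(edges[[1]]); b <- as.character(edges[[2]])
    if (length(bad <- setdiff(c(a, b), ids)))
      stop("unknown unit id in edge list: ", paste(unique(bad), collapse = ", "))
    if (any(a == b)) stop("self-pair in edge list")
    A[cbind(a, b)] <- 1
    A[cbind(b, a)] <- 1
  }
  A
}

#' Aggregate a unit table over a partition
#'
#' Builds the group-level unit table used when a model is fitted directly
#' at a coarser level: populations are summed; urban proportion, per-capita
#' economic product and centroids are population-weighted means. Each
#' group's parent coarse id is inherited (groups never straddle coarse
#' boundaries); at the coarsest level the group becomes its own parent.
#'
#' @param units a [UnitTable-class].
#' @param partition named vector mapping fine id to group id; defaults to
#'   the coarse membership (yielding the broad-scale table).
#' @return A [UnitTable-class] with one row per group.
#' @export
aggregateUnits <- function(units, partition = NULL) {
  stopifnot(is(units, "UnitTable"))
  u <- units@units
  if (is.null(partition)) partition <- coarseIds(units)
  if (length(bad <- setdiff(u$id, names(partition))))
    stop("unmapped unit: ", paste(bad, collapse = ", "))
  g <- as.character(partition[u$id])
  coarseOf <- attr(partition, "coarse")
  pop <- tapply(u$population, g, sum)
  wmean <- function(x) tapply(x * u$population, g, sum) / pop
  gl <- names(pop)
  parent <- if (!is.null(coarseOf)) as.character(coarseOf[gl]) else {
    byg <- tapply(u$coarse_id, g, function(x) unique(x))
    vapply(byg, function(x) if (length(x) == 1) x else NA_character_, "")
  }
  parent[is.na(parent)] <- gl[is.na(parent)]
  UnitTable(data.frame(
    id = gl, coarse_id = parent, population = as.numeric(pop),
    urban_prop = as.numeric(wmean(u$urban_prop)),
    gcp_pc = as.numeric(wmean(u$gcp_pc)),
    cx = as.numeric(wmean(u$cx)), cy = as.numeric(wmean(u$cy)),
    stringsAsFactors = FALSE))
}

#' Aggregate a contiguity relation over a partition
#'
#' Two groups are contiguous iff any of their member units are contiguous.
#'
#' @param adj 0/1 contiguity matrix over fine units.
#' @param partition named vector mapping fine id to group id.
#' @return symmetric 0/1 matrix over groups, zero diagonal.
#' @export
aggregateAdjacency <- function(adj, partition) {
  ids <- rownames(adj)
  if (length(bad <- setdiff(ids, names(partition))))
    stop("unmapped unit: ", paste(bad, collapse = ", "))
  g <- as.character(partition[ids])
  A <- rowsum(t(rowsum(adj[ids, ids, drop = FALSE], g)), g)
  A <- t(A)
  A <- (A > 0) * 1
  diag(A) <- 0
  A[order(rownames(A)), order(colnames(A)), drop = FALSE]
}

# ---- ESRI ASCII grid and delimited-table I/O ----

#' Read an ESRI ASCII grid
#'
#' Parses the standard six-line header (`ncols`, `nrows`, `xllcorner`,
#' `yllcorner`, `cellsize`, `NODATA_value`; the last is optional) followed by
#' rows of values, northern row first. NODATA cells become `NA`.
#'
#' @param path file path.
#' @return A [RasterGrid-class].
#' @export
readAsciiGrid <- function(path) {
  lines <- readLines(path)
  hdr <- list(); i <- 1
  repeat {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(parts) != 2 || is.na(suppressWarnings(as.numeric(parts[2])))
        || tolower(parts[1]) %in% c("na", "nan")) break
    key <- tolower(parts[1])
    if (!key %in% c("ncols", "nrows", "xllcorner", "yllcorner",
                    "cellsize", "nodata_value")) break
    hdr[[key]] <- as.numeric(parts[2]); i <- i + 1
  }
  for (k in c("ncols", "nrows", "cellsize"))
    if (is.null(hdr[[k]])) stop("ASCII grid header missing ", k)
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE, na.strings = c("NA", "na"))
  if (length(vals) != hdr$ncols * hdr$nrows)
    stop("value count does not match ncols*nrows")
  if (!is.null(hdr$nodata_value)) vals[vals == hdr$nodata_value] <- NA
  v <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  RasterGrid(v, hdr$cellsize,
             if (is.null(hdr$xllcorner)) 0 else hdr$xllcorner,
             if (is.null(hdr$yllcorner)) 0 else hdr$yllcorner)
}

#' Write an ESRI ASCII grid
#'
#' @param g a [RasterGrid-class].
#' @param path file path.
#' @param nodata value written for missing cells (default -9999).
#' @return `path`, invisibly.
#' @export
writeAsciiGrid <- function(g, path, nodata = -9999) {
  stopifnot(is(g, "RasterGrid"))
  v <- g@values
  v[is.na(v)] <- nodata
  hdr <- c(sprintf("ncols %d", ncol(v)), sprintf("nrows %d", nrow(v)),
           sprintf("xllcorner %.10g", g@xll), sprintf("yllcorner %.10g", g@yll),
           sprintf("cellsize %.10g", g@cellSize),
           sprintf("NODATA_value %.10g", nodata))
  body <- apply(v, 1, function(r) paste(formatC(r, format = "g", digits = 15),
                                        collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read / write a unit table as delimited text
#'
#' Tab-separated with a header row; columns `id`, `coarse_id`, `population`,
#' `urban_prop`, `gcp_pc`, `cx`, `cy`. Lines starting with `#` are ignored.
#'
#' @param path file path.
#' @return `readUnitTable`: a [UnitTable-class].
#' @export
readUnitTable <- function(path) {
  u <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                  colClasses = c(id = "character", coarse_id = "character"))
  UnitTable(u)
}

#' @rdname readUnitTable
#' @param units a [UnitTable-class] to write.
#' @param header optional character vector of `#`-prefixed comment lines.
#' @export
writeUnitTable <- function(units, path, header = NULL) {
  stopifnot(is(units, "UnitTable"))
  con <- file(path, "w"); on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  write.table(format(units@units, digits = 17, trim = TRUE), con,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an edge list of contiguous unit pairs
#'
#' Tab-separated, two columns `id_a`, `id_b`, header row required.
#'
#' @param path file path.
#' @return data.frame with columns `id_a`, `id_b`.
#' @export
readEdgeList <- function(path) {
  read.table(path, header = TRUE, sep = "\t", comment.char = "#",
             colClasses = "character")
}

#' @rdname readEdgeList
#' @param edges data.frame of id pairs to write.
#' @export
writeEdgeList <- function(edges, path) {
  colnames(edges)[1:2] <- c("id_a", "id_b")
  write.table(edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
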