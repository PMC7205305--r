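# Flow conversion, cross-scale aggregation/disaggregation, and validation
# metrics.

#' Convert migration proportions to expected flows
#'
#' `flow_ij = samplingFraction * N_i * v_ij`: the expected number of
#' observed migrants from i to j when a fraction of the origin population is
#' enumerated (1 for a full census, 0.1 for a 10% sample).
#'
#' @param v square fine-pair proportion matrix (NA diagonal allowed).
#' @param units a [UnitTable-class] supplying origin populations.
#' @param samplingFraction fraction of the population observed, in (0, 1].
#' @return square flow matrix (persons), zero diagonal.
#' @export
flowsFromProportions <- function(v, units, samplingFraction = 1) {
  stopifnot(is(units, "UnitTable"))
  if (length(samplingFraction) != 1 || samplingFraction <= 0 ||
      samplingFraction > 1)
    stop("samplingFraction must lie in (0, 1]")
  ids <- unitIds(units)
  v <- v[ids, ids, drop = FALSE]
  diag(v) <- 0
  f <- samplingFraction * populations(units)[ids] * v
  dimnames(f) <- list(ids, ids)
  f
}

#' Aggregate a flow matrix over a partition
#'
#' Group-pair flow is the sum of member-pair flows. Flows between distinct
#' members of the same group accumulate on the group diagonal, where they
#' are reported but excluded from between-group comparisons.
#'
#' @param f square flow matrix over fine units.
#' @param partition named vector mapping every unit in `f` to a group id.
#' @return square flow matrix over groups.
#' @export
aggregateFlows <- function(f, partition) {
  ids <- rownames(f)
  if (is.null(ids)) stop("flow matrix needs dimnames")
  if (length(bad <- setdiff(ids, names(partition))))
    stop("unmapped unit: ", paste(bad, collapse = ", "))
  g <- as.character(partition[ids])
  out <- rowsum(t(rowsum(f[ids, ids, drop = FALSE], g)), g)
  out <- t(out)
  out[order(rownames(out)), order(colnames(out)), drop = FALSE]
}

#' Uniformly disaggregate coarse proportions to sub-unit pairs
#'
#' Every ordered pair of sub-units (u in I, w in J), I != J, receives the
#' coarse proportion `P_IJ` unchanged — the benchmark downscaling that
#' assumes no within-coarse-unit heterogeneity. Pairs within the same
#' coarse unit are undefined (`NA`).
#'
#' @param Pcoarse square coarse-pair proportion matrix.
#' @param partition named vector mapping sub-unit id to coarse id; every
#'   coarse id must have a row/column in `Pcoarse`.
#' @return square proportion matrix over the sub-units.
#' @export
disaggregateUniform <- function(Pcoarse, partition) {
  ids <- names(partition)
  grp <- as.character(partition)
  if (length(bad <- setdiff(grp, rownames(Pcoarse))))
    stop("missing coarse proportion for: ", paste(unique(bad), collapse = ", "))
  out <- Pcoarse[grp, grp, drop = FALSE]
  dimnames(out) <- list(ids, ids)
  same <- outer(grp, grp, "==")
  out[same] <- NA_real_
  out
}

#' Compare estimated and observed flows
#'
#' Pearson correlation and residuals over the ordered off-diagonal pairs
#' both matrices share, on the raw scale or (default) on `log10(x + 1)`,
#' which tolerates zero flows and matches how flow scatter is usually
#' reported.
#'
#' @param estimated,observed square flow matrices with matching dimnames.
#' @param scale `"log10p1"` or `"raw"`.
#' @return list with `r` (Pearson correlation), `residuals`
#'   (named estimated - observed on the chosen scale), `n` (pair count) and
#'   `scale`.
#' @export
compareFlows <- function(estimated, observed, scale = c("log10p1", "raw")) {
  scale <- match.arg(scale)
  ids <- intersect(rownames(estimated), rownames(observed))
  e <- estimated[ids, ids, drop = FALSE]
  o <- observed[ids, ids, drop = FALSE]
  off <- which(row(e) != col(e) & !is.na(e) & !is.na(o))
  if (length(off) < 3) stop("need at least 3 comparable pairs")
  ev <- e[off]; ov <- o[off]
  if (scale == "log10p1") { ev <- log10(ev + 1); ov <- log10(ov + 1) }
  if (sd(ev) == 0 || sd(ov) == 0) stop("zero variance in a flow vector")
  res <- ev - ov
  names(res) <- paste(rownames(e)[row(e)[off]], colnames(e)[col(e)[off]],
                      sep = "->")
  list(r = cor(ev, ov), residuals = res, n = length(off), scale = scale)
}

#' Read / write flow matrices and partitions as delimited text
#'
#' Flows: `origin_id`, `dest_id`, `flow` (self pairs omitted). Partition:
#' `unit_id`, `group_id`.
#'
#' @param path file path.
#' @return `readFlowMatrix`: a square flow matrix; `readPartition`: a named
#'   character vector.
#' @export
readFlowMatrix <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                   colClasses = c("character", "character", "numeric"))
  ids <- sort(unique(c(df[[1]], df[[2]])))
  f <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  f[cbind(df[[1]], df[[2]])] <- df[[3]]
  f
}

#' @rdname readFlowMatrix
#' @param f square flow matrix to write.
#' @param header optional `#`-prefixed comment lines.
#' @export
writeFlowMatrix <- function(f, path, header = NULL) {
  off <- which(row(f) != col(f) & !is.na(f))
  df <- data.frame(origin_id = rownames(f)[row(f)[off]],
                   dest_id = colnames(f)[col(f)[off]],
                   flow = f[off])
  con <- file(path, "w"); on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname readFlowMatrix
#' @export
readPartition <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                   colClasses = "character")
  setNames(df[[2]], df[[1]])
}

#' @rdname readFlowMatrix
#' @param partition named vector to write.
#' @export
writePartition <- function(partition, path) {
  df <- data.frame(unit_id = names(partition),
                   group_id = as.character(partition))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
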