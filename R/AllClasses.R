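#' @import methods
#' @importFrom stats dcauchy rnorm runif rbinom rlnorm rbeta quantile median var sd cor dist plogis qlogis setNames rcauchy
#' @importFrom utils read.table write.table combn head
NULL

#' RasterGrid: a rectangular gridded surface
#'
#' A minimal planar raster: a numeric matrix of cell values (row 1 is the
#' northern-most row, as in ESRI ASCII grids), a cell size, and the
#' coordinates of the lower-left corner. Missing cells are `NA`.
#'
#' @slot values numeric matrix; `NA` marks missing cells.
#' @slot cellSize positive cell edge length (km or degrees).
#' @slot xll,yll coordinates of the lower-left corner of the grid.
#' @export
setClass("RasterGrid",
  representation(values = "matrix", cellSize = "numeric",
                 xll = "numeric", yll = "numeric"),
  prototype(cellSize = 1, xll = 0, yll = 0))

setValidity("RasterGrid", function(object) {
  msg <- NULL
  if (!is.numeric(object@values)) msg <- c(msg, "values must be numeric")
  if (length(object@cellSize) != 1 || !is.finite(object@cellSize) ||
      object@cellSize <= 0)
    msg <- c(msg, "cellSize must be a single positive number")
  if (length(object@xll) != 1 || length(object@yll) != 1)
    msg <- c(msg, "xll and yll must be single numbers")
  if (is.null(msg)) TRUE else msg
})

#' Construct a RasterGrid
#'
#' @param values numeric matrix of cell values (`NA` = missing); row 1 is the
#'   top (northern) row.
#' @param cellSize cell edge length.
#' @param xll,yll lower-left corner coordinates.
#' @return A [RasterGrid-class] object.
#' @examples
#' g <- RasterGrid(matrix(1:4, 2, 2), cellSize = 0.5)
#' @export
RasterGrid <- function(values, cellSize = 1, xll = 0, yll = 0) {
  storage.mode(values) <- "double"
  new("RasterGrid", values = values, cellSize = as.numeric(cellSize),
      xll = as.numeric(xll), yll = as.numeric(yll))
}

#' UnitTable: administrative units with model covariates
#'
#' One row per fine-scale unit (e.g. municipality): identifier, parent
#' coarse-unit identifier (e.g. department), population, urban population
#' fraction, per-capita economic product, and planar centroid coordinates
#' in kilometres.
#'
#' @slot units data.frame with columns `id`, `coarse_id`, `population`,
#'   `urban_prop`, `gcp_pc`, `cx`, `cy`.
#' @export
setClass("UnitTable", representation(units = "data.frame"))

setValidity("UnitTable", function(object) {
  u <- object@units
  req <- c("id", "coarse_id", "population", "urban_prop", "gcp_pc", "cx", "cy")
  if (!all(req %in% names(u)))
    return(paste("missing columns:", paste(setdiff(req, names(u)), collapse = ", ")))
  msg <- NULL
  if (anyDuplicated(u$id)) msg <- c(msg, "unit ids must be unique")
  if (any(!nzchar(as.character(u$coarse_id))))
    msg <- c(msg, "every coarse_id must be non-empty")
  if (any(u$population < 0)) msg <- c(msg, "population must be non-negative")
  if (any(u$urban_prop < 0 | u$urban_prop > 1))
    msg <- c(msg, "urban_prop must lie in [0, 1]")
  if (any(u$gcp_pc <= 0)) msg <- c(msg, "gcp_pc must be positive")
  popByCoarse <- tapply(u$population, u$coarse_id, sum)
  if (any(popByCoarse <= 0))
    msg <- c(msg, "population sum per coarse unit must be positive")
  if (is.null(msg)) TRUE else msg
})

#' Construct a UnitTable
#'
#' @param units data.frame with columns `id`, `coarse_id`, `population`,
#'   `urban_prop`, `gcp_pc`, `cx`, `cy`.
#' @return A [UnitTable-class] object.
#' @export
UnitTable <- function(units) {
  units$id <- as.character(units$id)
  units$coarse_id <- as.character(units$coarse_id)
  rownames(units) <- NULL
  new("UnitTable", units = units)
}

#' PairDesign: the ordered origin-destination design matrix
#'
#' One row per ordered pair of distinct fine units, holding the standardized
#' covariate matrix the logistic-linear migration model operates on, together
#' with pair bookkeeping (origin/destination ids and their coarse parents)
#' and the raw origin populations used as aggregation weights.
#'
#' @slot origin,dest fine unit ids per row.
#' @slot coarseOrigin,coarseDest parent coarse ids per row.
#' @slot X numeric matrix of standardized covariates, one column per model
#'   term, in model-specification order.
#' @slot originPop raw origin population per row.
#' @slot scalers data.frame of fitted scaling transforms
#'   (columns covariate, kind, center, scale).
#' @export
setClass("PairDesign",
  representation(origin = "character", dest = "character",
                 coarseOrigin = "character", coarseDest = "character",
                 X = "matrix", originPop = "numeric", scalers = "data.frame"))

setValidity("PairDesign", function(object) {
  m <- length(object@origin)
  msg <- NULL
  if (any(object@origin == object@dest)) msg <- c(msg, "self-pairs not allowed")
  n <- length(unique(c(object@origin, object@dest)))
  if (m != n * (n - 1))
    msg <- c(msg, sprintf("expected %d rows for %d units, got %d", n * (n - 1), n, m))
  if (nrow(object@X) != m || length(object@dest) != m ||
      length(object@originPop) != m)
    msg <- c(msg, "row counts of slots disagree")
  if (is.null(msg)) TRUE else msg
})

#' CoarseFlows: observed coarse-level migrant counts
#'
#' Observed ordered-pair migrant counts `M_IJ` between coarse units over the
#' study window, together with the origin sample sizes `n_I` (the number of
#' persons observed at origin I, e.g. the census-sample count). The diagonal
#' is structurally zero: within-unit movement is outside the model.
#'
#' @slot counts integer-valued matrix of ordered-pair counts, rows = origins.
#' @slot originSizes named vector of origin sample sizes, aligned to rows.
#' @export
setClass("CoarseFlows",
  representation(counts = "matrix", originSizes = "numeric"))

setValidity("CoarseFlows", function(object) {
  msg <- NULL
  M <- object@counts
  n <- object@originSizes
  if (nrow(M) != ncol(M)) msg <- c(msg, "counts must be square")
  if (length(n) != nrow(M)) msg <- c(msg, "originSizes must match rows")
  if (!identical(rownames(M), colnames(M)))
    msg <- c(msg, "rownames and colnames must agree")
  if (!is.null(names(n)) && !identical(names(n), rownames(M)))
    msg <- c(msg, "originSizes names must match counts rownames")
  if (any(M < 0, na.rm = TRUE)) msg <- c(msg, "counts must be non-negative")
  if (any(diag(M) != 0, na.rm = TRUE)) msg <- c(msg, "diagonal must be zero")
  if (any(n <= 0)) msg <- c(msg, "origin sizes must be positive")
  out <- rowSums(M, na.rm = TRUE)
  if (any(out > n)) msg <- c(msg, "row sums of counts exceed origin sizes")
  if (is.null(msg)) TRUE else msg
})

#' Construct a CoarseFlows object
#'
#' @param counts square matrix of ordered-pair migrant counts with matching
#'   row/column names; diagonal zero.
#' @param originSizes origin sample sizes, one per row of `counts`.
#' @return A [CoarseFlows-class] object.
#' @export
CoarseFlows <- function(counts, originSizes) {
  counts <- as.matrix(counts)
  diag(counts)[is.na(diag(counts))] <- 0
  originSizes <- setNames(as.numeric(originSizes), rownames(counts))
  new("CoarseFlows", counts = counts, originSizes = originSizes)
}

#' PosteriorSample: multi-chain MCMC draws with diagnostics
#'
#' Post burn-in, thinned coefficient draws from one or more Markov chains,
#' with the per-draw log-posterior and deviance (-2 log-likelihood), the
#' per-parameter Gelman-Rubin statistic, and the deviance function retained
#' for DIC computation.
#'
#' @slot draws array `[iteration, chain, parameter]` of retained draws.
#' @slot logPost matrix `[iteration, chain]` of log-posterior values.
#' @slot deviance matrix `[iteration, chain]` of deviance values.
#' @slot rhat named per-parameter potential scale reduction factors
#'   (`NA` when only one chain was run).
#' @slot devFun function mapping a coefficient vector to its deviance.
#' @slot settings the sampler settings used (list).
#' @export
setClass("PosteriorSample",
  representation(draws = "array", logPost = "matrix", deviance = "matrix",
                 rhat = "numeric", devFun = "function", settings = "list"))

setValidity("PosteriorSample", function(object) {
  d <- dim(object@draws)
  msg <- NULL
  if (length(d) != 3) msg <- c(msg, "draws must be a 3-d array")
  if (!all(is.finite(object@draws))) msg <- c(msg, "all draws must be finite")
  if (!is.null(dim(object@logPost)) &&
      !identical(dim(object@logPost), d[1:2]))
    msg <- c(msg, "logPost dimensions must match draws")
  if (!identical(dim(object@deviance), d[1:2]))
    msg <- c(msg, "deviance dimensions must match draws")
  if (is.null(msg)) TRUE else msg
})
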