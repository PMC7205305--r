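#' Number of fine units
#' @param x a UnitTable or PairDesign.
#' @return integer count of distinct fine units.
#' @export
setGeneric("nUnits", function(x) standardGeneric("nUnits"))

#' Unit identifiers
#' @param x a UnitTable.
#' @return character vector of fine-unit ids, in table order.
#' @export
setGeneric("unitIds", function(x) standardGeneric("unitIds"))

#' Coarse-unit membership
#' @param x a UnitTable.
#' @return named character vector mapping fine id to parent coarse id.
#' @export
setGeneric("coarseIds", function(x) standardGeneric("coarseIds"))

#' Unit populations
#' @param x a UnitTable.
#' @return named numeric vector of populations.
#' @export
setGeneric("populations", function(x) standardGeneric("populations"))

#' Raster cell values
#' @param x a RasterGrid.
#' @return the numeric value matrix (row 1 = northern row).
#' @export
setGeneric("gridValues", function(x) standardGeneric("gridValues"))

#' Covariate names of a design
#' @param x a PairDesign.
#' @return character vector of covariate (model term) names, in order.
#' @export
setGeneric("covariateNames", function(x) standardGeneric("covariateNames"))

#' Design matrix of standardized covariates
#' @param x a PairDesign.
#' @return numeric matrix, one row per ordered pair.
#' @export
setGeneric("designMatrix", function(x) standardGeneric("designMatrix"))

#' Number of retained draws per chain
#' @param x a PosteriorSample.
#' @return integer.
#' @export
setGeneric("nDraws", function(x) standardGeneric("nDraws"))

#' Number of chains
#' @param x a PosteriorSample.
#' @return integer.
#' @export
setGeneric("nChains", function(x) standardGeneric("nChains"))

#' Parameter names
#' @param x a PosteriorSample.
#' @return character vector.
#' @export
setGeneric("parameterNames", function(x) standardGeneric("parameterNames"))

#' Stacked posterior draws
#'
#' All chains stacked into one matrix, one column per parameter.
#' @param x a PosteriorSample.
#' @return numeric matrix `[iterations * chains, parameters]`.
#' @export
setGeneric("posteriorDraws", function(x) standardGeneric("posteriorDraws"))

#' Observed coarse counts
#' @param x a CoarseFlows.
#' @return square numeric matrix of ordered-pair counts.
#' @export
setGeneric("flowCounts", function(x) standardGeneric("flowCounts"))

#' Origin sample sizes
#' @param x a CoarseFlows.
#' @return named numeric vector.
#' @export
setGeneric("originSizes", function(x) standardGeneric("originSizes"))
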