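# Accessors and show() methods for the S4 containers.

#' @rdname nUnits
#' @export
setMethod("nUnits", "UnitTable", function(x) nrow(x@units))

#' @rdname unitIds
#' @export
setMethod("unitIds", "UnitTable", function(x) x@units$id)

#' @rdname coarseIds
#' @export
setMethod("coarseIds", "UnitTable",
          function(x) setNames(x@units$coarse_id, x@units$id))

#' @rdname populations
#' @export
setMethod("populations", "UnitTable",
          function(x) setNames(x@units$population, x@units$id))

#' @export
#' @describeIn UnitTable coerce to the underlying data.frame
setMethod("as.data.frame", "UnitTable", function(x, ...) x@units)

setMethod("show", "UnitTable", function(object) {
  u <- object@units
  cat(sprintf("UnitTable: %d fine units in %d coarse units\n",
              nrow(u), length(unique(u$coarse_id))))
  cat(sprintf("  population: median %.0f [%.0f, %.0f]\n",
              median(u$population), min(u$population), max(u$population)))
  cat(sprintf("  urban_prop: mean %.3f; gcp_pc: median %.1f\n",
              mean(u$urban_prop), median(u$gcp_pc)))
})

#' @rdname gridValues
#' @export
setMethod("gridValues", "RasterGrid", function(x) x@values)

setMethod("show", "RasterGrid", function(object) {
  v <- object@values
  cat(sprintf("RasterGrid: %d x %d cells of size %g, origin (%g, %g)\n",
              nrow(v), ncol(v), object@cellSize, object@xll, object@yll))
  cat(sprintf("  %d missing cells; range of known values [%g, %g]\n",
              sum(is.na(v)),
              suppressWarnings(min(v, na.rm = TRUE)),
              suppressWarnings(max(v, na.rm = TRUE))))
})

#' @rdname nUnits
#' @export
setMethod("nUnits", "PairDesign",
          function(x) length(unique(c(x@origin, x@dest))))

#' @rdname covariateNames
#' @export
setMethod("covariateNames", "PairDesign", function(x) colnames(x@X))

#' @rdname designMatrix
#' @export
setMethod("designMatrix", "PairDesign", function(x) x@X)

setMethod("show", "PairDesign", function(object) {
  cat(sprintf("PairDesign: %d ordered pairs over %d units\n",
              length(object@origin), nUnits(object)))
  cat("  covariates:", paste(colnames(object@X), collapse = ", "), "\n")
})

#' @rdname flowCounts
#' @export
setMethod("flowCounts", "CoarseFlows", function(x) x@counts)

#' @rdname originSizes
#' @export
setMethod("originSizes", "CoarseFlows", function(x) x@originSizes)

setMethod("show", "CoarseFlows", function(object) {
  M <- object@counts
  cat(sprintf("CoarseFlows: %d coarse units, %d ordered pairs\n",
              nrow(M), nrow(M) * (nrow(M) - 1)))
  cat(sprintf("  total migrants %d; origin sizes %d..%d\n",
              as.integer(sum(M)), as.integer(min(object@originSizes)),
              as.integer(max(object@originSizes))))
})

#' @rdname nDraws
#' @export
setMethod("nDraws", "PosteriorSample", function(x) dim(x@draws)[1])

#' @rdname nChains
#' @export
setMethod("nChains", "PosteriorSample", function(x) dim(x@draws)[2])

#' @rdname parameterNames
#' @export
setMethod("parameterNames", "PosteriorSample", function(x) dimnames(x@draws)[[3]])

#' @rdname posteriorDraws
#' @export
setMethod("posteriorDraws", "PosteriorSample", function(x) {
  d <- dim(x@draws)
  out <- matrix(aperm(x@draws, c(1, 2, 3)), nrow = d[1] * d[2], ncol = d[3])
  colnames(out) <- dimnames(x@draws)[[3]]
  out
})

setMethod("show", "PosteriorSample", function(object) {
  d <- dim(object@draws)
  cat(sprintf("PosteriorSample: %d draws x %d chains x %d parameters\n",
              d[1], d[2], d[3]))
  if (all(is.finite(object@rhat)))
    cat(sprintf("  max R-hat %.4f\n", max(object@rhat)))
  cat(sprintf("  mean deviance %.2f\n", mean(object@deviance)))
})
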