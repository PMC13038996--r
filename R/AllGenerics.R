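#' @name accessors
#' @title Accessors for sentinet containers
#' @description Small accessor generics so user code never touches slots.
#' @param x a sentinet S4 object.
#' @return The requested component.
NULL

#' @rdname accessors
#' @export
setGeneric("nRegions", function(x) standardGeneric("nRegions"))
#' @rdname accessors
#' @export
setGeneric("regionIds", function(x) standardGeneric("regionIds"))
#' @rdname accessors
#' @export
setGeneric("regionCoords", function(x) standardGeneric("regionCoords"))
#' @rdname accessors
#' @export
setGeneric("regionEdges", function(x) standardGeneric("regionEdges"))
#' @rdname accessors
#' @export
setGeneric("demographics", function(x) standardGeneric("demographics"))
#' @rdname accessors
#' @export
setGeneric("kernelBandwidth", function(x) standardGeneric("kernelBandwidth"))
#' @rdname accessors
#' @export
setGeneric("seriesValues", function(x) standardGeneric("seriesValues"))
#' @rdname accessors
#' @export
setGeneric("anomalyLabels", function(x) standardGeneric("anomalyLabels"))
#' @rdname accessors
#' @export
setGeneric("featureNames", function(x) standardGeneric("featureNames"))
#' @rdname accessors
#' @export
setGeneric("timeIndex", function(x) standardGeneric("timeIndex"))
#' @rdname accessors
#' @export
setGeneric("missingMask", function(x) standardGeneric("missingMask"))
#' @rdname accessors
#' @export
setGeneric("policyScheme", function(x) standardGeneric("policyScheme"))
#' @rdname accessors
#' @export
setGeneric("forecastMean", function(x) standardGeneric("forecastMean"))
#' @rdname accessors
#' @export
setGeneric("forecastVariance", function(x) standardGeneric("forecastVariance"))

#' @rdname accessors
#' @export
setMethod("nRegions", "RegionGraph", function(x) length(x@regionIds))
#' @rdname accessors
#' @export
setMethod("regionIds", "RegionGraph", function(x) x@regionIds)
#' @rdname accessors
#' @export
setMethod("regionCoords", "RegionGraph", function(x) x@coords)
#' @rdname accessors
#' @export
setMethod("regionEdges", "RegionGraph", function(x) x@edges)
#' @rdname accessors
#' @export
setMethod("demographics", "RegionGraph", function(x) x@demographics)
#' @rdname accessors
#' @export
setMethod("kernelBandwidth", "RegionGraph", function(x) x@kernelBandwidth)

#' @rdname accessors
#' @export
setMethod("seriesValues", "SummarySeries", function(x) x@values)
#' @rdname accessors
#' @export
setMethod("anomalyLabels", "SummarySeries", function(x) x@anomalyLabels)
#' @rdname accessors
#' @export
setMethod("featureNames", "SummarySeries", function(x) x@featureNames)
#' @rdname accessors
#' @export
setMethod("timeIndex", "SummarySeries", function(x) x@timeIndex)
#' @rdname accessors
#' @export
setMethod("nRegions", "SummarySeries", function(x) dim(x@values)[2L])

#' @rdname accessors
#' @export
setMethod("seriesValues", "PolicySeries", function(x) x@values)
#' @rdname accessors
#' @export
setMethod("missingMask", "PolicySeries", function(x) x@missingMask)
#' @rdname accessors
#' @export
setMethod("policyScheme", "PolicySeries", function(x) x@scheme)
#' @rdname accessors
#' @export
setMethod("nRegions", "PolicySeries", function(x) dim(x@values)[2L])

#' @rdname accessors
#' @export
setMethod("forecastMean", "GaussianForecast", function(x) x@mean)
#' @rdname accessors
#' @export
setMethod("forecastVariance", "GaussianForecast", function(x) x@variance)

setMethod("show", "RegionGraph", function(object) {
  cat(sprintf("RegionGraph: %d regions, %d edges, kernel bandwidth %.3g\n",
              nRegions(object), nrow(object@edges), object@kernelBandwidth))
  cat("  demographics:",
      paste(vapply(object@demographics, function(col) length(unique(col)), 1L),
            names(object@demographics), collapse = ", "), "levels\n")
})

setMethod("show", "SummarySeries", function(object) {
  d <- dim(object@values)
  cat(sprintf("SummarySeries: T=%d, M=%d, k=%d [%s]\n",
              d[1L], d[2L], d[3L], paste(object@featureNames, collapse = ", ")))
  if (nrow(object@anomalyLabels) > 0L)
    cat(sprintf("  anomaly labels: %.2f%% of cells\n",
                100 * mean(object@anomalyLabels)))
})

setMethod("show", "PolicySeries", function(object) {
  d <- dim(object@values)
  cat(sprintf("PolicySeries: T=%d, M=%d, r=%d; %.1f%% cells masked\n",
              d[1L], d[2L], d[3L], 100 * mean(object@missingMask)))
})

setMethod("show", "GaussianForecast", function(object) {
  d <- dim(object@mean)
  cat(sprintf("GaussianForecast: T=%d, M=%d, k=%d (variance floor %g)\n",
              d[1L], d[2L], d[3L], object@varianceFloor))
})

setMethod("show", "HetConfig", function(object) {
  cat(sprintf(
    "HetConfig: depth %d, dModel %d, heads %d (dk %d), ff %d, latent %d, dropout %.2f\n",
    object@depth, object@dModel, object@nHeads,
    object@dModel %/% object@nHeads, object@dFf, object@latentDim,
    object@dropout))
})

setMethod("show", "HetModel", function(object) {
  np <- sum(vapply(object@params, length, 1L))
  cat(sprintf("HetModel: %s, %d parameters\n",
              if (object@fitted) "fitted" else "initialized", np))
})

setMethod("show", "CalibrationState", function(object) {
  cat(sprintf("CalibrationState: m=%d, rho=%.2f, %d divergences observed\n",
              length(object@baseline), object@rho, length(object@history)))
})

setMethod("show", "ThresholdState", function(object) {
  cat(sprintf("ThresholdState: tau=%.4g, target FA %.3f, window %d\n",
              object@tau, object@targetFaRate, object@window))
})
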