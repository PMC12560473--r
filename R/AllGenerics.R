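#' Accessors for gliomaSDC classes
#'
#' @param object a gliomaSDC S4 object.
#' @param b a b-value (s/mm^2) present in the series.
#' @name accessors
NULL

#' @describeIn accessors b-values of a [DWISeries-class] (s/mm^2).
#' @export
setGeneric("bValues", function(object) standardGeneric("bValues"))

#' @describeIn accessors the 3-D signal volume acquired at b; fails loudly
#'   if b is not in the series.
#' @export
setGeneric("volumeAt", function(object, b) standardGeneric("volumeAt"))

#' @describeIn accessors grid dimensions.
#' @export
setGeneric("gridDim", function(object) standardGeneric("gridDim"))

#' @describeIn accessors logical in-ROI array of a [ROIMask-class].
#' @export
setGeneric("maskArray", function(object) standardGeneric("maskArray"))

#' @describeIn accessors number of in-ROI voxels.
#' @export
setGeneric("pixelCount", function(object) standardGeneric("pixelCount"))

#' @describeIn accessors area under the ROC curve of a [ROCResult-class].
#' @export
setGeneric("auc", function(object) standardGeneric("auc"))

setMethod("bValues", "DWISeries", function(object) object@bValues)

setMethod("volumeAt", "DWISeries", function(object, b) {
  i <- match(b, object@bValues)
  if (is.na(i))
    stop(sprintf("no volume at b = %s; series has b = %s", b,
                 paste(object@bValues, collapse = ", ")), call. = FALSE)
  object@volumes[[i]]
})

setMethod("gridDim", "DWISeries", function(object) dim(object@volumes[[1L]]))
setMethod("gridDim", "ROIMask", function(object) dim(object@mask))
setMethod("gridDim", "MetricMaps", function(object) dim(object@sdc))

setMethod("maskArray", "ROIMask", function(object) object@mask)
setMethod("pixelCount", "ROIMask", function(object) sum(object@mask))

setMethod("auc", "ROCResult", function(object) object@auc)

#' @describeIn accessors coefficients of a [LogisticCoefficients-class]
#'   model as a named numeric vector.
#' @param ... ignored.
#' @export
setMethod("coef", "LogisticCoefficients", function(object, ...) {
  c(sdc = object@betaSDC, ddvd = object@betaDDVD,
    adc = object@betaADC, intercept = object@intercept)
})

setMethod("show", "DWISeries", function(object) {
  d <- gridDim(object)
  cat("DWISeries:", length(object@bValues), "b-values (",
      paste(object@bValues, collapse = ", "), "s/mm^2 )\n")
  cat("  grid", paste(d, collapse = " x "), "voxels,",
      paste(signif(object@voxelDims, 3), collapse = " x "), "mm\n")
})

setMethod("show", "ROIMask", function(object) {
  cat("ROIMask:", pixelCount(object), "voxels on grid",
      paste(gridDim(object), collapse = " x "))
  if (object@nExcluded > 0)
    cat(" (", object@nExcluded, "excluded )")
  cat("\n")
})

setMethod("show", "MetricMaps", function(object) {
  cat("MetricMaps on grid", paste(gridDim(object), collapse = " x "), "\n")
  cat("  SDC  (au/s)      b =", paste(object@bPairs$sdc, collapse = "/"), "\n")
  cat("  DDVD (au/pixel)  b =", paste(object@bPairs$ddvd, collapse = "/"), "\n")
  cat("  ADC  (mm^2/s)    b =", paste(object@bPairs$adc, collapse = "/"),
      "|", sum(!object@adcValid), "invalid voxels\n")
})

setMethod("show", "MetricTriplet", function(object) {
  cat(sprintf("MetricTriplet: SDC %.4g au/s, DDVD %.4g au/pixel, ADC %.4g %s\n",
              object@sdc, object@ddvd, object@adc, object@adcUnit))
})

setMethod("show", "LogisticCoefficients", function(object) {
  cat("LogisticCoefficients [", object@label, "]\n", sep = "")
  cat(sprintf("  eta = %.4g*SDC %+.4g*DDVD %+.4g*ADC %+.4g\n",
              object@betaSDC, object@betaDDVD, object@betaADC,
              object@intercept))
  cat("  units:", object@units, "\n")
})

setMethod("show", "ROCResult", function(object) {
  cat(sprintf("ROCResult: AUC = %.4f (%d positives vs %d negatives, rule value %s threshold)\n",
              object@auc, object@nPositive, object@nNegative,
              object@direction))
})
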