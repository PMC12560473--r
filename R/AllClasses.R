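#' @import methods
NULL

#' Multi-b-value diffusion-weighted series
#'
#' A stack of co-registered 3-D signal volumes indexed by b-value, the raw
#' material of the SDC, DDVD and ADC maps. All volumes must share one voxel
#' grid and affine; b-values are stored unique and sorted ascending.
#'
#' @slot bValues numeric vector of diffusion weightings (s/mm^2), sorted
#'   ascending, no duplicates.
#' @slot volumes list of 3-D numeric arrays (arbitrary units), one per
#'   b-value, all with identical dimensions.
#' @slot voxelDims numeric length-3 voxel edge lengths (mm).
#' @slot affine 4x4 voxel-to-world matrix (NIfTI convention).
#'
#' @seealso [loadDWISeries()], [simulatePhantom()], [volumeAt()]
#' @export
setClass("DWISeries",
  representation(
    bValues   = "numeric",
    volumes   = "list",
    voxelDims = "numeric",
    affine    = "matrix"
  )
)

setValidity("DWISeries", function(object) {
  b <- object@bValues
  v <- object@volumes
  if (length(b) != length(v))
    return(sprintf("%d b-values but %d volumes", length(b), length(v)))
  if (anyDuplicated(b))
    return(sprintf("duplicate b-values: %s",
                   paste(unique(b[duplicated(b)]), collapse = ", ")))
  if (is.unsorted(b, strictly = TRUE))
    return("b-values must be strictly increasing")
  if (any(b < 0)) return("b-values must be non-negative")
  dims <- lapply(v, dim)
  if (any(vapply(dims, length, 1L) != 3L))
    return("all volumes must be 3-D arrays")
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) > 1L)
    return("volumes have mismatched grid shapes")
  nbad <- sum(vapply(v, function(x) sum(!is.finite(x)), 0))
  if (nbad > 0)
    return(sprintf("series contains %d non-finite voxel values", nbad))
  if (length(object@voxelDims) != 3L || any(object@voxelDims <= 0))
    return("voxelDims must be 3 positive lengths (mm)")
  if (!all(dim(object@affine) == c(4L, 4L)))
    return("affine must be a 4x4 matrix")
  TRUE
})

#' Region-of-interest mask
#'
#' Binary inclusion mask on the grid of a [DWISeries-class], optionally with
#' an exclusion mask already subtracted (necrosis, cysts, edema,
#' calcifications are excluded from glioma ROI analysis). The effective ROI
#' must be non-empty.
#'
#' @slot mask logical 3-D array; \code{TRUE} marks in-ROI voxels.
#' @slot nExcluded integer count of voxels removed by the exclusion mask.
#'
#' @seealso [loadROIMask()], [roiAggregate()]
#' @export
setClass("ROIMask",
  representation(mask = "array", nExcluded = "integer")
)

setValidity("ROIMask", function(object) {
  if (!is.logical(object@mask)) return("mask array must be logical")
  if (length(dim(object@mask)) != 3L) return("mask must be 3-D")
  if (!any(object@mask)) return("effective ROI is empty")
  TRUE
})

#' Pixelwise diffusion metric maps
#'
#' Whole-volume SDC, DDVD and ADC maps computed from one [DWISeries-class],
#' with a per-metric validity mask. ADC is invalid (NaN) exactly where the
#' signal ratio is non-positive; SDC and DDVD are defined everywhere and
#' negative values are retained (clipping would bias ROI means).
#'
#' @slot sdc 3-D array, au/s.
#' @slot ddvd 3-D array, au/pixel (per-pixel signal drop b_low -> b_high).
#' @slot adc 3-D array, mm^2/s, NaN where invalid.
#' @slot adcValid logical 3-D array, \code{TRUE} where ADC was computable.
#' @slot bPairs named list with the b-value pair used per metric.
#'
#' @seealso [computeMetricMaps()], [roiAggregate()]
#' @export
setClass("MetricMaps",
  representation(
    sdc      = "array",
    ddvd     = "array",
    adc      = "array",
    adcValid = "array",
    bPairs   = "list"
  )
)

setValidity("MetricMaps", function(object) {
  d <- dim(object@sdc)
  if (!identical(d, dim(object@ddvd)) || !identical(d, dim(object@adc)) ||
      !identical(d, dim(object@adcValid)))
    return("metric maps have mismatched grids")
  if (any(!is.finite(object@adc[object@adcValid])))
    return("ADC validity mask marks non-finite voxels as valid")
  TRUE
})

#' Per-lesion diffusion metric triplet
#'
#' ROI-level scalar summary of the three metric maps. The ADC slot carries a
#' mandatory unit tag because the combined logistic model is defined for ADC
#' in 1e-4 mm^2/s: feeding raw mm^2/s into those coefficients is the single
#' most likely user error, so units travel with the value.
#'
#' @slot sdc numeric, au/s.
#' @slot ddvd numeric, au/pixel.
#' @slot adc numeric, in the unit named by \code{adcUnit}.
#' @slot adcUnit either \code{"mm2/s"} or \code{"1e-4 mm2/s"}.
#' @slot nInvalid named integer vector: voxels excluded from each metric's
#'   ROI mean because the formula was not computable there.
#'
#' @seealso [roiAggregate()], [metricTriplet()], [predictProbability()]
#' @export
setClass("MetricTriplet",
  representation(
    sdc      = "numeric",
    ddvd     = "numeric",
    adc      = "numeric",
    adcUnit  = "character",
    nInvalid = "integer"
  )
)

setValidity("MetricTriplet", function(object) {
  if (!all(is.finite(c(object@sdc, object@ddvd, object@adc))))
    return("metric values must be finite")
  if (!object@adcUnit %in% c("mm2/s", "1e-4 mm2/s"))
    return("adcUnit must be 'mm2/s' or '1e-4 mm2/s'")
  TRUE
})

#' Coefficients of the combined three-metric logistic genotype model
#'
#' The linear predictor is
#' \deqn{\eta = \beta_{SDC}\,SDC + \beta_{DDVD}\,DDVD + \beta_{ADC}\,ADC + \beta_0}
#' with SDC in au/s, DDVD in au/pixel and ADC in 1e-4 mm^2/s, and the
#' probability of a tumor being IDH-mutant is \eqn{1/(1+e^{-\eta})}. The unit
#' contract is part of the object: coefficients are meaningless on other
#' scales.
#'
#' @slot betaSDC numeric, per au/s.
#' @slot betaDDVD numeric, per au/pixel.
#' @slot betaADC numeric, per 1e-4 mm^2/s.
#' @slot intercept numeric.
#' @slot units character unit contract string.
#' @slot label character model name (e.g. \code{"paper-2025-reference"}).
#'
#' @seealso [referenceModel()], [fitLogistic()], [predictProbability()]
#' @export
setClass("LogisticCoefficients",
  representation(
    betaSDC   = "numeric",
    betaDDVD  = "numeric",
    betaADC   = "numeric",
    intercept = "numeric",
    units     = "character",
    label     = "character"
  )
)

setValidity("LogisticCoefficients", function(object) {
  val <- c(object@betaSDC, object@betaDDVD, object@betaADC, object@intercept)
  if (length(val) != 4L || !all(is.finite(val)))
    return("all four coefficients must be single finite numbers")
  if (length(object@units) != 1L || !nzchar(object@units))
    return("unit contract string is mandatory")
  TRUE
})

#' Empirical ROC analysis result
#'
#' @slot auc numeric in \[0,1\]; trapezoidal area, equal to the Mann-Whitney
#'   U statistic divided by n1*n2 (ties count one half).
#' @slot curve data.frame with columns \code{threshold}, \code{fpr},
#'   \code{tpr}; starts at (0,0) and ends at (1,1).
#' @slot direction character; \code{">"} means higher values predict the
#'   positive class.
#' @slot nPositive,nNegative integer class sizes.
#'
#' @seealso [rocCurve()], [cutoffTable()]
#' @export
setClass("ROCResult",
  representation(
    auc       = "numeric",
    curve     = "data.frame",
    direction = "character",
    nPositive = "integer",
    nNegative = "integer"
  )
)

setValidity("ROCResult", function(object) {
  if (object@auc < 0 || object@auc > 1) return("auc must lie in [0,1]")
  cv <- object@curve
  if (!all(c("threshold", "fpr", "tpr") %in% names(cv)))
    return("curve must have threshold, fpr, tpr columns")
  if (is.unsorted(cv$fpr) || is.unsorted(cv$tpr))
    return("fpr and tpr must be non-decreasing along the curve")
  TRUE
})
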