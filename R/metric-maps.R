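checkBPair <- function(series, b1, b2, what) {
  if (b1 >= b2)
    stop(sprintf("%s needs b1 < b2, got b1 = %s, b2 = %s", what, b1, b2),
         call. = FALSE)
  for (b in c(b1, b2)) volumeAt(series, b)   # loud failure on missing b
  invisible(NULL)
}

#' Slow diffusion coefficient (SDC) map
#'
#' The SDC is the linear signal difference between a high and a higher
#' b-value image, per unit b:
#' \deqn{SDC = [S(b_1) - S(b_2)] / (b_2 - b_1) \quad (au/s),}
#' by default b1 = 500 and b2 = 750 s/mm^2. Unlike the log-ratio ADC it
#' keeps the arbitrary-unit signal scale, so it is only comparable across
#' scans with consistent intensity normalization. Negative voxels (noise)
#' are preserved, not clipped.
#'
#' @param series a [DWISeries-class].
#' @param b1,b2 the b-value pair, b1 < b2, both present in the series.
#' @return 3-D array, au/s. (The field labels this unit au/s although
#'   Delta-signal over Delta-b is dimensionally au mm^2/s.)
#' @export
computeSDC <- function(series, b1 = 500, b2 = 750) {
  checkBPair(series, b1, b2, "SDC")
  (volumeAt(series, b1) - volumeAt(series, b2)) / (b2 - b1)
}

#' Diffusion-derived vessel density (DDVD)
#'
#' DDVD is the per-pixel signal drop between b = 0 and a very low b-value
#' (default 10 s/mm^2), a surrogate for microvascular perfusion: over the
#' ROI,
#' \deqn{DDVD = S_{b0}/ROI_{area,b0} - S_{b10}/ROI_{area,b10}
#'   \quad (au/pixel),}
#' i.e. the ROI mean of the pixelwise difference map \eqn{S_{b0} - S_{b10}}
#' when the same mask is applied to both volumes (as here).
#'
#' @param series a [DWISeries-class].
#' @param mask a [ROIMask-class] on the series grid (used for the scalar;
#'   the map is whole-volume).
#' @param bLow,bHigh the b-value pair, default 0 and 10 s/mm^2.
#' @return list: `scalar` (au/pixel) and `map` (whole-volume pixelwise
#'   difference array).
#' @export
computeDDVD <- function(series, mask = NULL, bLow = 0, bHigh = 10) {
  checkBPair(series, bLow, bHigh, "DDVD")
  map <- volumeAt(series, bLow) - volumeAt(series, bHigh)
  scalar <- NULL
  if (!is.null(mask)) {
    if (!identical(dim(map), gridDim(mask)))
      stop("geometry error: mask grid does not match series grid",
           call. = FALSE)
    m <- maskArray(mask)
    scalar <- sum(map[m]) / sum(m)
  }
  list(scalar = scalar, map = map)
}

#' Apparent diffusion coefficient (ADC) map
#'
#' Conventional mono-exponential estimate
#' \deqn{ADC = \ln[S(b_1)/S(b_2)] / (b_2 - b_1) \quad (mm^2/s),}
#' by default from b = 0 and 1000 s/mm^2. Voxels where either signal is
#' non-positive (the log-ratio is undefined) are set to NaN and flagged in
#' the validity mask; other voxels are unaffected.
#'
#' @param series a [DWISeries-class].
#' @param b1,b2 the b-value pair, b1 < b2.
#' @return list: `map` (3-D array, mm^2/s, NaN where invalid) and `valid`
#'   (logical array).
#' @export
computeADC <- function(series, b1 = 0, b2 = 1000) {
  checkBPair(series, b1, b2, "ADC")
  s1 <- volumeAt(series, b1)
  s2 <- volumeAt(series, b2)
  valid <- s1 > 0 & s2 > 0
  map <- array(NaN, dim(s1))
  map[valid] <- log(s1[valid] / s2[valid]) / (b2 - b1)
  list(map = map, valid = valid)
}

#' Compute all three metric maps
#'
#' Whole-volume, mask-independent pixelwise maps; the ROI enters only at
#' aggregation ([roiAggregate()]).
#'
#' @param series a [DWISeries-class].
#' @param sdcPair,ddvdPair,adcPair length-2 b-value pairs per metric;
#'   defaults are the acquisition the metrics were proposed for
#'   (SDC 500/750, DDVD 0/10, ADC 0/1000 s/mm^2).
#' @return a [MetricMaps-class].
#' @export
computeMetricMaps <- function(series, sdcPair = c(500, 750),
                              ddvdPair = c(0, 10),
                              adcPair = c(0, 1000)) {
  sdc <- computeSDC(series, sdcPair[1], sdcPair[2])
  ddvd <- computeDDVD(series, mask = NULL, ddvdPair[1], ddvdPair[2])$map
  adc <- computeADC(series, adcPair[1], adcPair[2])
  new("MetricMaps", sdc = sdc, ddvd = ddvd, adc = adc$map,
      adcValid = adc$valid,
      bPairs = list(sdc = sdcPair, ddvd = ddvdPair, adc = adcPair))
}

#' Construct a metric triplet directly
#'
#' @param sdc,ddvd,adc the three scalar metrics.
#' @param adcUnit unit tag for `adc`: `"mm2/s"` or `"1e-4 mm2/s"`.
#' @param nInvalid named integer vector of excluded-voxel counts.
#' @return a [MetricTriplet-class].
#' @export
metricTriplet <- function(sdc, ddvd, adc, adcUnit = c("1e-4 mm2/s", "mm2/s"),
                          nInvalid = c(sdc = 0L, ddvd = 0L, adc = 0L)) {
  adcUnit <- match.arg(adcUnit)
  new("MetricTriplet", sdc = as.numeric(sdc), ddvd = as.numeric(ddvd),
      adc = as.numeric(adc), adcUnit = adcUnit,
      nInvalid = vapply(nInvalid, as.integer, 1L))
}

#' Convert a triplet's ADC to 1e-4 mm^2/s
#'
#' The combined logistic model expects ADC in 1e-4 mm^2/s; this conversion
#' is driven by the unit tag and is a no-op if already converted — it can
#' never be applied twice.
#'
#' @param triplet a [MetricTriplet-class].
#' @return the triplet with `adcUnit == "1e-4 mm2/s"`.
#' @export
adcToModelUnits <- function(triplet) {
  stopifnot(is(triplet, "MetricTriplet"))
  if (triplet@adcUnit == "1e-4 mm2/s") return(triplet)
  triplet@adc <- triplet@adc * 1e4
  triplet@adcUnit <- "1e-4 mm2/s"
  triplet
}

#' Aggregate metric maps over an ROI
#'
#' Per-lesion scalar = mean over valid in-mask voxels per metric (DDVD's
#' defining equation is itself a ROI mean, so the mean is the one statistic
#' consistent across all three metrics). ADC voxels flagged invalid are
#' excluded and counted; if every in-mask voxel is invalid for a metric the
#' aggregation fails naming that metric. The returned ADC is converted to
#' 1e-4 mm^2/s, the unit the genotype model expects.
#'
#' @param maps a [MetricMaps-class].
#' @param mask a [ROIMask-class] on the same grid.
#' @return a [MetricTriplet-class].
#' @export
roiAggregate <- function(maps, mask) {
  if (!identical(gridDim(maps), gridDim(mask)))
    stop("geometry error: mask grid does not match map grid", call. = FALSE)
  m <- maskArray(mask)
  one <- function(map, valid, nm) {
    ok <- m & valid
    if (!any(ok))
      stop("all in-ROI voxels invalid for metric ", nm, call. = FALSE)
    list(mean = mean(map[ok]), nInvalid = sum(m) - sum(ok))
  }
  all3 <- array(TRUE, gridDim(maps))
  s <- one(maps@sdc, all3, "sdc")
  d <- one(maps@ddvd, all3, "ddvd")
  a <- one(maps@adc, maps@adcValid, "adc")
  metricTriplet(s$mean, d$mean, a$mean * 1e4, adcUnit = "1e-4 mm2/s",
                nInvalid = c(sdc = s$nInvalid, ddvd = d$nInvalid,
                             adc = a$nInvalid))
}

#' Write metric maps as NIfTI volumes
#'
#' @param maps a [MetricMaps-class].
#' @param dir output directory.
#' @return named character vector of paths, invisibly.
#' @export
writeMetricMaps <- function(maps, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  out <- c(sdc = file.path(dir, "sdc.nii.gz"),
           ddvd = file.path(dir, "ddvd.nii.gz"),
           adc = file.path(dir, "adc.nii.gz"))
  units <- c(sdc = "au/s", ddvd = "au/pixel", adc = "mm2/s")
  for (nm in names(out)) {
    img <- RNifti::asNifti(slot(maps, nm))
    img <- RNifti::asNifti(img, list(descrip = paste0(nm, " [", units[nm], "]")))
    RNifti::writeNifti(img, out[nm])
  }
  invisible(out)
}
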