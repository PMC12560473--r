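#' Tissue parameters for the bi-exponential phantom
#'
#' The phantom's generative model is the standard intravoxel-incoherent-
#' motion (IVIM) decay: a perfusion (pseudo-diffusion) compartment with
#' fraction `f` and coefficient `Dstar` on top of tissue diffusion `Dt`,
#' \deqn{S(b) = S_0 [f e^{-b D^*} + (1-f) e^{-b D_t}].}
#'
#' @param S0 baseline signal at b = 0 (au), > 0.
#' @param f perfusion fraction in \[0, 1\].
#' @param Dstar pseudo-diffusion coefficient (mm^2/s); must exceed `Dt`.
#' @param Dt tissue (slow) diffusion coefficient (mm^2/s), >= 0.
#' @param snr ratio of `S0` to the Rician noise scale; `Inf` = noiseless.
#' @return a `tissueParams` list.
#' @export
tissueParams <- function(S0 = 1000, f = 0.1, Dstar = 20e-3, Dt = 1e-3,
                         snr = Inf) {
  stopifnot(S0 > 0, f >= 0, f <= 1, Dt >= 0, Dstar > Dt, snr > 0)
  structure(list(S0 = S0, f = f, Dstar = Dstar, Dt = Dt, snr = snr),
            class = "tissueParams")
}

#' Noiseless IVIM signal
#'
#' @param b b-value(s), s/mm^2.
#' @param params a [tissueParams()] list.
#' @return signal (au), same length as `b`.
#' @export
ivimSignal <- function(b, params) {
  params$S0 * (params$f * exp(-b * params$Dstar) +
               (1 - params$f) * exp(-b * params$Dt))
}

#' Default three-region phantom layout
#'
#' A 32 x 32 x 8 grid split into normal-appearing background, a
#' "wildtype-like" lesion (high perfusion fraction, low tissue diffusion:
#' the dense, microvascular-proliferation phenotype, giving low SDC and
#' high DDVD) and a "mutant-like" lesion (low perfusion fraction, high
#' tissue diffusion: the less cellular, more watery phenotype, giving high
#' SDC and low DDVD). Values are illustrative tissue parameters, not
#' measurements.
#'
#' @param snr signal-to-noise ratio applied to all regions.
#' @return list with `regions` (named list of [tissueParams()]) and
#'   `regionMap` (integer array: 1 background, 2 wildtype-like,
#'   3 mutant-like).
#' @export
defaultPhantomRegions <- function(snr = Inf) {
  dim3 <- c(32L, 32L, 8L)
  map <- array(1L, dim3)
  map[5:14, 5:14, 3:6] <- 2L
  map[19:28, 19:28, 3:6] <- 3L
  list(
    regions = list(
      background   = tissueParams(S0 = 800, f = 0.03, Dstar = 10e-3,
                                  Dt = 0.8e-3, snr = snr),
      wildtypeLike = tissueParams(S0 = 1000, f = 0.12, Dstar = 20e-3,
                                  Dt = 0.7e-3, snr = snr),
      mutantLike   = tissueParams(S0 = 1000, f = 0.04, Dstar = 20e-3,
                                  Dt = 1.3e-3, snr = snr)
    ),
    regionMap = map
  )
}

#' Phantom specification
#'
#' @param bValues b-values to simulate (s/mm^2); strictly increasing. The
#'   full pipeline needs at least \{0, 10, 500, 750, 1000\}.
#' @param regions named list of [tissueParams()].
#' @param regionMap integer array assigning every voxel to one entry of
#'   `regions` (by position).
#' @param seed integer RNG seed.
#' @param noise `"rician"` (magnitude MRI) or `"gaussian"` (analytic
#'   checks).
#' @return a `phantomSpec` list.
#' @export
phantomSpec <- function(bValues = c(0, 10, 500, 750, 1000),
                        regions = NULL, regionMap = NULL,
                        seed = 1L, noise = c("rician", "gaussian")) {
  noise <- match.arg(noise)
  if (is.null(regions) || is.null(regionMap)) {
    def <- defaultPhantomRegions()
    if (is.null(regions))   regions   <- def$regions
    if (is.null(regionMap)) regionMap <- def$regionMap
  }
  bad <- which(diff(bValues) <= 0)
  if (length(bad))
    stop(sprintf("b-values must be strictly increasing; offending pair %s, %s",
                 bValues[bad[1L]], bValues[bad[1L] + 1L]), call. = FALSE)
  if (any(bValues < 0)) stop("b-values must be non-negative", call. = FALSE)
  rm <- as.integer(regionMap)
  if (any(is.na(rm)) || any(rm < 1L) || any(rm > length(regions)))
    stop("every voxel must be assigned to exactly one region", call. = FALSE)
  structure(list(bValues = bValues, regions = regions,
                 regionMap = array(rm, dim(regionMap)),
                 seed = as.integer(seed), noise = noise),
            class = "phantomSpec")
}

ricianCorrupt <- function(signal, sigma) {
  n <- length(signal)
  sqrt((signal + stats::rnorm(n, 0, sigma))^2 + stats::rnorm(n, 0, sigma)^2)
}

#' Simulate a multi-b-value DWI phantom
#'
#' Evaluates the noiseless bi-exponential decay per region, then corrupts
#' each b-volume with Rician noise of scale `S0/snr` (magnitude MRI) or
#' additive Gaussian noise of the same scale. Deterministic for a fixed
#' `spec$seed`.
#'
#' @param spec a [phantomSpec()].
#' @return list: `series` ([DWISeries-class]) and `regionMap` (integer
#'   label array).
#' @export
simulatePhantom <- function(spec) {
  stopifnot(inherits(spec, "phantomSpec"))
  map <- spec$regionMap
  set.seed(spec$seed)
  vols <- lapply(spec$bValues, function(b) {
    v <- array(0, dim(map))
    for (i in seq_along(spec$regions)) {
      p <- spec$regions[[i]]
      idx <- map == i
      if (!any(idx)) next
      s <- ivimSignal(b, p)
      if (is.finite(p$snr)) {
        sigma <- p$S0 / p$snr
        v[idx] <- if (spec$noise == "rician")
          ricianCorrupt(rep(s, sum(idx)), sigma)
        else rep(s, sum(idx)) + stats::rnorm(sum(idx), 0, sigma)
      } else v[idx] <- s
    }
    v
  })
  list(series = dwiSeries(spec$bValues, vols), regionMap = map)
}

#' Write a simulated phantom to disk
#'
#' 4-D NIfTI + `.bval` + integer region-label NIfTI.
#'
#' @param phantom result of [simulatePhantom()].
#' @param dir output directory (created if absent).
#' @param stem file stem, default `"phantom"`.
#' @return named character vector of written paths, invisibly.
#' @export
writePhantom <- function(phantom, dir, stem = "phantom") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  nii <- file.path(dir, paste0(stem, ".nii.gz"))
  paths <- writeDWISeries(phantom$series, nii)
  lab <- file.path(dir, paste0(stem, "_regions.nii.gz"))
  RNifti::writeNifti(RNifti::asNifti(phantom$regionMap), lab)
  invisible(c(paths, regions = lab))
}
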