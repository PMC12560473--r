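#' Read an FSL-style .bval file
#'
#' Single line of space-separated b-values (s/mm^2).
#'
#' @param path path to the .bval text file.
#' @return numeric vector of b-values, in file order.
#' @export
readBval <- function(path) {
  if (!file.exists(path)) stop("bval file not found: ", path, call. = FALSE)
  b <- scan(path, what = numeric(), quiet = TRUE)
  if (length(b) == 0L) stop("bval file is empty: ", path, call. = FALSE)
  if (any(b < 0)) stop("negative b-value in ", path, call. = FALSE)
  b
}

#' Write an FSL-style .bval file
#'
#' @param b numeric b-values.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeBval <- function(b, path) {
  writeLines(paste(format(b, scientific = FALSE, trim = TRUE),
                   collapse = " "), path)
  invisible(path)
}

newDWISeries <- function(bValues, volumes, voxelDims = c(1, 1, 1),
                         affine = diag(4)) {
  o <- order(bValues)
  new("DWISeries", bValues = as.numeric(bValues[o]), volumes = volumes[o],
      voxelDims = as.numeric(voxelDims), affine = affine)
}

#' Assemble a DWISeries from in-memory volumes
#'
#' Volumes are sorted by b-value; validity (one grid, unique b, finite
#' signal) is enforced by the class.
#'
#' @param bValues numeric b-values (s/mm^2), one per volume.
#' @param volumes list of 3-D numeric arrays (au).
#' @param voxelDims voxel edge lengths in mm (default 1 mm isotropic).
#' @param affine 4x4 voxel-to-world matrix.
#' @return a [DWISeries-class].
#' @export
dwiSeries <- function(bValues, volumes, voxelDims = c(1, 1, 1),
                      affine = diag(4)) {
  if (length(bValues) != length(volumes))
    stop(sprintf("bval/volume count mismatch: %d b-values vs %d volumes",
                 length(bValues), length(volumes)), call. = FALSE)
  newDWISeries(bValues, volumes, voxelDims, affine)
}

#' Load a multi-b-value diffusion series from NIfTI
#'
#' Accepts either one 4-D NIfTI file or one 3-D file per b-value, plus an
#' FSL-style `.bval` file which is the single source of b truth. Grids and
#' affines must agree exactly; nothing is resampled.
#'
#' @param paths character vector: one 4-D NIfTI path, or one 3-D path per
#'   b-value (any order; volumes are matched to b-values by position and
#'   then sorted).
#' @param bvalPath path to the `.bval` file.
#' @return a [DWISeries-class].
#' @export
loadDWISeries <- function(paths, bvalPath) {
  b <- readBval(bvalPath)
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("volume file(s) not found: ", paste(missing, collapse = ", "),
         call. = FALSE)
  imgs <- lapply(paths, RNifti::readNifti)
  if (length(imgs) == 1L && length(dim(imgs[[1L]])) == 4L) {
    img4 <- imgs[[1L]]
    nvol <- dim(img4)[4L]
    vols <- lapply(seq_len(nvol), function(i) {
      v <- img4[, , , i, drop = FALSE]
      array(as.numeric(v), dim(v)[1:3])
    })
    hdr <- img4
  } else {
    if (any(vapply(imgs, function(x) length(dim(x)), 1L) != 3L))
      stop("per-b inputs must be 3-D NIfTI volumes", call. = FALSE)
    shapes <- vapply(imgs, function(x) paste(dim(x), collapse = "x"), "")
    if (length(unique(shapes)) > 1L)
      stop("geometry error: input volumes have different grid shapes (",
           paste(unique(shapes), collapse = " vs "), ")", call. = FALSE)
    affs <- lapply(imgs, function(x) unclass(RNifti::xform(x)))
    if (any(vapply(affs[-1L], function(a)
          max(abs(a - affs[[1L]])) > 1e-4, TRUE)))
      stop("geometry error: input volumes have different affines; ",
           "register upstream, this loader never resamples", call. = FALSE)
    vols <- lapply(imgs, function(x) array(as.numeric(x), dim(x)))
    hdr <- imgs[[1L]]
  }
  if (length(vols) != length(b))
    stop(sprintf("bval/volume count mismatch: %d b-values vs %d volumes",
                 length(b), length(vols)), call. = FALSE)
  for (i in seq_along(vols)) {
    nbad <- sum(!is.finite(vols[[i]]))
    if (nbad > 0)
      stop(sprintf("volume %d (b = %s) has %d non-finite voxels",
                   i, b[i], nbad), call. = FALSE)
  }
  pd <- RNifti::pixdim(hdr)[1:3]
  newDWISeries(b, vols, voxelDims = pd, affine = unclass(RNifti::xform(hdr)))
}

#' Write a DWISeries as a 4-D NIfTI plus a .bval file
#'
#' @param series a [DWISeries-class].
#' @param niiPath output `.nii`/`.nii.gz` path.
#' @param bvalPath output `.bval` path; defaults to `niiPath` with the
#'   extension replaced.
#' @return named character vector of the two paths, invisibly.
#' @export
writeDWISeries <- function(series, niiPath,
                           bvalPath = sub("\\.nii(\\.gz)?$", ".bval",
                                          niiPath)) {
  d <- gridDim(series)
  arr <- array(0, c(d, length(series@bValues)))
  for (i in seq_along(series@volumes)) arr[, , , i] <- series@volumes[[i]]
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(series@voxelDims, 1)
  RNifti::writeNifti(img, niiPath)
  writeBval(series@bValues, bvalPath)
  invisible(c(nii = niiPath, bval = bvalPath))
}

newROIMask <- function(include, exclude = NULL) {
  inc <- include != 0 & !is.na(include)
  nexc <- 0L
  if (!is.null(exclude)) {
    if (!identical(dim(exclude), dim(inc)))
      stop("geometry error: exclusion mask grid differs from inclusion mask",
           call. = FALSE)
    exc <- exclude != 0 & !is.na(exclude)
    nexc <- sum(inc & exc)
    inc <- inc & !exc
  }
  if (!any(inc))
    stop("empty ROI: no voxels remain after exclusion", call. = FALSE)
  new("ROIMask", mask = array(inc, dim(inc)), nExcluded = as.integer(nexc))
}

#' Build an ROI mask from arrays
#'
#' @param include numeric/logical 3-D array; nonzero marks in-ROI voxels.
#' @param exclude optional array on the same grid; its nonzero voxels
#'   (necrosis, cysts, edema, calcifications) are removed from the ROI.
#' @param series optional [DWISeries-class] to validate the grid against.
#' @return a [ROIMask-class].
#' @export
roiMask <- function(include, exclude = NULL, series = NULL) {
  if (!is.null(series) && !identical(dim(include), gridDim(series)))
    stop("geometry error: mask grid ", paste(dim(include), collapse = "x"),
         " does not match series grid ",
         paste(gridDim(series), collapse = "x"), call. = FALSE)
  newROIMask(include, exclude)
}

#' Load a binary ROI mask from NIfTI
#'
#' @param path NIfTI mask path; nonzero voxels are included.
#' @param series [DWISeries-class] whose grid the mask must match.
#' @param excludePath optional NIfTI exclusion mask subtracted from the ROI.
#' @return a [ROIMask-class].
#' @export
loadROIMask <- function(path, series, excludePath = NULL) {
  img <- RNifti::readNifti(path)
  exc <- if (!is.null(excludePath)) {
    e <- RNifti::readNifti(excludePath)
    array(as.numeric(e), dim(e))
  }
  roiMask(array(as.numeric(img), dim(img)), exclude = exc, series = series)
}

#' Read or write a cohort table
#'
#' Cohort CSVs carry one row per glioma case with the ROI-level metric
#' triplet and the pathology labels. Canonical columns: `subject_id`,
#' `group`, `sdc_au_per_s`, `ddvd_au_per_pixel`, `adc_e4_mm2_per_s`
#' (ADC in 1e-4 mm^2/s — the unit the combined model expects), `idh_gene`
#' (0/1), `idh_ihc` (0 / 0.5 / 1, 0.5 = partially positive), `grade`
#' (2/3/4 or NA for NEC cases excluded from grade analyses), `ki67_pct`.
#'
#' @param path CSV path.
#' @param cohort data.frame to write.
#' @return `readCohort`: the cohort data.frame; `writeCohort`: `path`,
#'   invisibly.
#' @export
readCohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "sdc_au_per_s", "ddvd_au_per_pixel",
            "adc_e4_mm2_per_s")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("cohort table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  df
}

#' @rdname readCohort
#' @export
writeCohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
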