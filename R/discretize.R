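## Gray-level discretization of ROI intensities, prerequisite to the GLCM and
## GLRLM texture matrices.

#' Discretization configuration
#'
#' Fixed-bin-count discretization: ROI intensities are mapped to integer
#' levels `1..n_levels` by equal-width bins spanning the ROI minimum to
#' maximum. This makes all histogram and texture features invariant to any
#' global affine rescaling of the ROI intensities. Default 64 levels.
#'
#' @param n_levels Number of gray levels (>= 2).
#' @return An object of class `discretization_config`.
#' @export
discretization_config <- function(n_levels = 64L) {
  if (!is_count(n_levels) || n_levels < 2) stopf("n_levels must be an integer >= 2")
  structure(list(n_levels = as.integer(n_levels), mode = "fixed-bin-count"),
            class = "discretization_config")
}

#' Discretize ROI intensities to gray levels
#'
#' Maps in-mask voxels to levels `1..n_levels` by equal-width bins over
#' `[roi_min, roi_max]`; `roi_max` maps to `n_levels`. A constant ROI maps
#' every voxel to level 1. Out-of-mask voxels are `NA`.
#'
#' @param scan A [scan_volume()].
#' @param mask A [roi_mask()] aligned with `scan`.
#' @param cfg A [discretization_config()].
#' @return Integer 3D array of levels with `NA` outside the mask, with
#'   attribute `n_levels`.
#' @export
discretize <- function(scan, mask, cfg = discretization_config()) {
  stopifnot(inherits(scan, "scan_volume"), inherits(mask, "roi_mask"))
  check_alignment(scan, mask)
  if (!any(mask$voxels)) stopf("empty ROI mask")
  v <- scan$voxels[mask$voxels]
  rng <- range(v)
  lev <- if (rng[1] == rng[2]) {
    rep.int(1L, length(v))
  } else {
    pmin(floor((v - rng[1]) / (rng[2] - rng[1]) * cfg$n_levels) + 1L, cfg$n_levels)
  }
  out <- array(NA_integer_, dim(scan$voxels))
  out[mask$voxels] <- as.integer(lev)
  attr(out, "n_levels") <- cfg$n_levels
  out
}
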