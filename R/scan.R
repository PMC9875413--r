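## Volumetric scan containers and SUV conversion.

#' Volumetric scan container
#'
#' Wraps a 3D intensity array with its voxel spacing, modality, intensity
#' units and acquisition metadata. PET volumes hold activity concentration in
#' kBq/mL (or dimensionless SUV after [to_suv()]); CT volumes hold an
#' HU-like density.
#'
#' @param voxels Numeric 3D array.
#' @param spacing_mm Length-3 positive voxel spacing in mm.
#' @param modality `"PET"` or `"CT"`.
#' @param units Intensity units: `"kBq/mL"`, `"SUV"` or `"HU"`.
#' @param meta Named list of metadata; for PET conversion,
#'   `injected_dose_MBq` and `body_weight_g` are required (positive).
#'   Typically also carries `subject_id` and `day`.
#' @return An object of class `scan_volume`.
#' @export
scan_volume <- function(voxels, spacing_mm, modality = c("PET", "CT"),
                        units = c("kBq/mL", "SUV", "HU"), meta = list()) {
  modality <- match.arg(modality)
  units <- match.arg(units)
  if (!is.array(voxels) || length(dim(voxels)) != 3L) {
    stopf("voxels must be a 3D array")
  }
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3L || any(!is.finite(spacing_mm)) || any(spacing_mm <= 0)) {
    stopf("spacing_mm must be 3 strictly positive values")
  }
  if (modality == "PET" && any(voxels < 0)) {
    stopf("PET activity must be non-negative")
  }
  structure(list(voxels = voxels, spacing_mm = spacing_mm, modality = modality,
                 units = units, meta = meta),
            class = "scan_volume")
}

#' @export
print.scan_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<scan_volume> %s [%s], %dx%dx%d voxels @ %.3gx%.3gx%.3g mm\n",
              x$modality, x$units, d[1], d[2], d[3],
              x$spacing_mm[1], x$spacing_mm[2], x$spacing_mm[3]))
  if (length(x$meta)) {
    cat("  meta:", paste(names(x$meta), unlist(lapply(x$meta, format)),
                         sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Binary region-of-interest mask
#'
#' A binary tumor mask on the same grid as its parent scan. Texture analysis
#' needs a minimally 3D region, so fewer than 27 foreground voxels is an
#' error unless `minimal = FALSE`.
#'
#' @param voxels Logical/0-1 3D array.
#' @param spacing_mm Voxel spacing, as the parent scan.
#' @param minimal Enforce the 27-voxel minimum (default TRUE).
#' @return An object of class `roi_mask`.
#' @export
roi_mask <- function(voxels, spacing_mm, minimal = TRUE) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L) stopf("mask must be a 3D array")
  if (!all(voxels %in% c(0, 1, TRUE, FALSE))) stopf("mask must be binary")
  voxels <- array(as.logical(voxels), dim(voxels))
  n_fg <- sum(voxels)
  if (minimal && n_fg < 27L) {
    stopf("ROI has %d foreground voxels; at least 27 required for texture analysis", n_fg)
  }
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3L || any(spacing_mm <= 0)) {
    stopf("spacing_mm must be 3 strictly positive values")
  }
  structure(list(voxels = voxels, spacing_mm = spacing_mm),
            class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<roi_mask> %dx%dx%d grid, %d foreground voxels (%.1f mm^3)\n",
              d[1], d[2], d[3], sum(x$voxels),
              sum(x$voxels) * prod(x$spacing_mm)))
  invisible(x)
}

check_alignment <- function(scan, mask) {
  if (!identical(dim(scan$voxels), dim(mask$voxels))) {
    stopf("mask grid %s does not match scan grid %s",
          paste(dim(mask$voxels), collapse = "x"),
          paste(dim(scan$voxels), collapse = "x"))
  }
  if (!isTRUE(all.equal(scan$spacing_mm, mask$spacing_mm))) {
    stopf("mask spacing does not match scan spacing")
  }
  invisible(TRUE)
}

#' Convert a PET activity volume to SUV
#'
#' Standardized uptake value normalizes the activity concentration to the
#' injected FDG dose per unit body weight:
#' `SUV = activity[kBq/mL] * body_weight[g] / injected_dose[kBq]`.
#' No decay correction between injection and acquisition is applied. Voxel
#' values scale linearly with activity and inversely with dose; metadata are
#' preserved and the unit flag is set to `"SUV"`.
#'
#' @param scan A PET `scan_volume` in kBq/mL with positive
#'   `meta$injected_dose_MBq` and `meta$body_weight_g`.
#' @return The scan in SUV units.
#' @export
to_suv <- function(scan) {
  stopifnot(inherits(scan, "scan_volume"))
  if (scan$modality != "PET") stopf("SUV conversion requires a PET scan")
  if (scan$units == "SUV") return(scan)
  for (field in c("injected_dose_MBq", "body_weight_g")) {
    v <- scan$meta[[field]]
    if (is.null(v) || !is.numeric(v) || !is.finite(v) || v <= 0) {
      stopf("metadata field '%s' is missing or non-positive; cannot compute SUV", field)
    }
  }
  dose_kBq <- scan$meta$injected_dose_MBq * 1000
  scan$voxels <- scan$voxels * scan$meta$body_weight_g / dose_kBq
  scan$units <- "SUV"
  scan
}
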