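## NIfTI I/O with JSON metadata sidecars. Phantoms and masks share one grid,
## so world coordinates are never needed; voxel data are stored float32.

#' Write / read a scan volume
#'
#' `write_volume()` stores the voxel grid as compressed NIfTI (float32) with
#' spacing in the header, plus a `.json` sidecar holding modality, units and
#' acquisition metadata. `read_volume()` restores the `scan_volume`;
#' round-trips preserve voxel values to float32 precision, spacing and
#' metadata. Missing sidecar fields (for example `injected_dose_MBq`) do not
#' block loading; [to_suv()] validates them when it needs them.
#'
#' @param scan A [scan_volume()].
#' @param path Output path ending in `.nii` or `.nii.gz`; the sidecar is
#'   written next to it.
#' @return `write_volume()` returns `path` invisibly; `read_volume()` a
#'   `scan_volume`.
#' @export
write_volume <- function(scan, path) {
  stopifnot(inherits(scan, "scan_volume"))
  img <- RNifti::asNifti(scan$voxels)
  RNifti::pixdim(img) <- scan$spacing_mm
  RNifti::writeNifti(img, path, datatype = "float")
  side <- list(modality = scan$modality, units = scan$units, meta = scan$meta)
  jsonlite::write_json(side, sidecar_path(path), auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  side <- if (file.exists(sidecar_path(path))) {
    jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  } else list(modality = "PET", units = "kBq/mL", meta = list())
  meta <- as.list(side$meta)
  scan_volume(array(as.numeric(img), dim(img)), RNifti::pixdim(img)[1:3],
              modality = side$modality, units = side$units, meta = meta)
}

sidecar_path <- function(path) {
  sub("\\.nii(\\.gz)?$", ".json", path)
}

#' Write / read an ROI mask
#'
#' Masks are stored as uint8 NIfTI. `read_mask()` optionally checks alignment
#' against a scan and raises an alignment error on a grid or spacing
#' mismatch.
#'
#' @param mask A [roi_mask()].
#' @param path NIfTI path.
#' @param scan Optional `scan_volume` the mask must align with.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "roi_mask"))
  img <- RNifti::asNifti(array(as.integer(mask$voxels), dim(mask$voxels)))
  RNifti::pixdim(img) <- mask$spacing_mm
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path, scan = NULL) {
  img <- RNifti::readNifti(path)
  mask <- roi_mask(array(as.numeric(img) > 0.5, dim(img)),
                   RNifti::pixdim(img)[1:3], minimal = FALSE)
  if (!is.null(scan)) check_alignment(scan, mask)
  mask
}

#' Write a phantom cohort to disk
#'
#' Writes, per subject, the PET activity volume, CT volume and ROI mask as
#' NIfTI with JSON sidecars, plus a cohort-level `ground_truth.csv`
#' (subject_id, model, day, early/terminal Tex fractions, E/T ratio, PD-1
#' MFI, high-exhaustion label).
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "phantom_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(cohort$subjects)) {
    ph <- cohort$subjects[[i]]
    id <- ph$pet$meta$subject_id
    write_volume(ph$pet, file.path(dir, sprintf("%s_pet.nii.gz", id)))
    write_volume(ph$ct, file.path(dir, sprintf("%s_ct.nii.gz", id)))
    write_mask(ph$mask, file.path(dir, sprintf("%s_mask.nii.gz", id)))
  }
  utils::write.csv(cohort$ground_truth, file.path(dir, "ground_truth.csv"),
                   row.names = FALSE)
  invisible(dir)
}
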