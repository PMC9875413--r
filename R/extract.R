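## Catalog-driven feature extraction: assembles the per-modality feature
## vector from the family computations, in the fixed order of the shipped
## catalog manifest (61 PET features, 57 CT features).

.catalog_cache <- new.env(parent = emptyenv())

#' Feature catalog manifest
#'
#' Returns the ordered feature catalog for a modality, read from the
#' versioned manifest shipped under `extdata`. The PET catalog (61 features)
#' covers the IntensityDirect, IntensityHistogram, GLCM and GLRLM families
#' computed on SUV; the CT catalog (57) adds the shape family and omits the
#' PET-only entries.
#'
#' @param catalog `"pet"` or `"ct"`.
#' @return A data.frame with columns `family`, `name` and `feature`
#'   (prefixed full name).
#' @export
feature_catalog <- function(catalog = c("pet", "ct")) {
  catalog <- match.arg(tolower(catalog), c("pet", "ct"))
  if (is.null(.catalog_cache[[catalog]])) {
    path <- system.file("extdata", sprintf("catalog_%s.tsv", catalog),
                        package = "exhaustscope", mustWork = TRUE)
    man <- utils::read.delim(path, stringsAsFactors = FALSE)
    man$feature <- paste(man$family, man$name, sep = "_")
    if (anyDuplicated(man$feature)) stopf("catalog manifest has duplicate features")
    .catalog_cache[[catalog]] <- man
  }
  .catalog_cache[[catalog]]
}

#' Extract a radiomic feature vector
#'
#' Computes exactly the catalog's features, in fixed order. PET features are
#' computed on SUV (pass the scan through [to_suv()] first); CT features on
#' the raw density volume. Feature names carry their family prefix
#' (`ID_`, `IH_`, `GLCM_`, `GLRLM_`, `Shape_`).
#'
#' @param scan A [scan_volume()] whose modality matches `catalog`.
#' @param mask A [roi_mask()] aligned with the scan.
#' @param catalog `"pet"` or `"ct"`.
#' @param disc_cfg A [discretization_config()].
#' @param tex_cfg A [texture_config()].
#' @return Named numeric vector of length 61 (PET) or 57 (CT), with
#'   attributes `catalog_id` and `config_hash`.
#' @export
extract_features <- function(scan, mask, catalog = c("pet", "ct"),
                             disc_cfg = discretization_config(),
                             tex_cfg = texture_config()) {
  catalog <- match.arg(tolower(catalog), c("pet", "ct"))
  stopifnot(inherits(scan, "scan_volume"), inherits(mask, "roi_mask"))
  check_alignment(scan, mask)
  if (catalog == "pet") {
    if (scan$modality != "PET") stopf("PET catalog requires a PET scan (got %s)", scan$modality)
    if (scan$units != "SUV") {
      stopf("PET features are defined on SUV; convert the scan with to_suv() first")
    }
  } else if (scan$modality != "CT") {
    stopf("CT catalog requires a CT scan (got %s)", scan$modality)
  }
  lv <- discretize(scan, mask, disc_cfg)
  fam <- list(
    ID = intensity_direct_features(scan, mask),
    IH = intensity_histogram_features(lv),
    GLCM = glcm_features(glcm(lv, tex_cfg)),
    GLRLM = glrlm_features(glrlm(lv, tex_cfg))
  )
  if (catalog == "ct") fam$Shape <- shape_features(mask)
  man <- feature_catalog(catalog)
  out <- numeric(nrow(man))
  for (r in seq_len(nrow(man))) {
    v <- fam[[man$family[r]]]
    idx <- match(man$name[r], names(v))
    if (is.na(idx)) stopf("catalog feature %s not produced by family %s",
                          man$name[r], man$family[r])
    out[r] <- v[idx]
  }
  if (any(!is.finite(out))) {
    stopf("non-finite feature values: %s",
          paste(man$feature[!is.finite(out)], collapse = ", "))
  }
  names(out) <- man$feature
  attr(out, "catalog_id") <- catalog
  attr(out, "config_hash") <- config_hash(list(disc = unclass(disc_cfg),
                                               tex = unclass(tex_cfg)))
  out
}

#' Extract features for every subject of a cohort
#'
#' Runs [extract_features()] per subject (PET scans are converted to SUV
#' first) and stacks the results into a feature table.
#'
#' @param cohort A [generate_cohort()] result, or a plain list of phantoms.
#' @param catalog `"pet"` or `"ct"`.
#' @inheritParams extract_features
#' @return A data.frame: `subject_id` column plus one column per catalog
#'   feature, with attributes `catalog_id` and `config_hash`.
#' @export
extract_cohort_features <- function(cohort, catalog = c("pet", "ct"),
                                    disc_cfg = discretization_config(),
                                    tex_cfg = texture_config()) {
  catalog <- match.arg(tolower(catalog), c("pet", "ct"))
  subjects <- if (inherits(cohort, "phantom_cohort")) cohort$subjects else cohort
  rows <- lapply(subjects, function(ph) {
    scan <- if (catalog == "pet") to_suv(ph$pet) else ph$ct
    extract_features(scan, ph$mask, catalog, disc_cfg, tex_cfg)
  })
  tab <- as.data.frame(do.call(rbind, rows))
  tab <- cbind(subject_id = vapply(subjects, function(ph) ph$pet$meta$subject_id,
                                   character(1)),
               tab, stringsAsFactors = FALSE)
  attr(tab, "catalog_id") <- catalog
  attr(tab, "config_hash") <- attr(rows[[1]], "config_hash")
  tab
}
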