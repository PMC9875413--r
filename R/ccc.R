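## Test-retest reproducibility: Lin's concordance correlation coefficient and
## the per-modality robustness filter.

#' Lin's concordance correlation coefficient
#'
#' `CCC = 2 s_xy / (s_x^2 + s_y^2 + (mean(x) - mean(y))^2)` with population
#' (1/n) moments. CCC penalizes both loss of correlation and location/scale
#' shift, so `|CCC| <= |Pearson r|` always. Degenerate policy: if both
#' variances and the mean gap are zero, identical constant series return 1
#' (perfect agreement by convention); otherwise 0 with attribute
#' `degenerate = TRUE`.
#'
#' @param test,retest Equal-length numeric series (n >= 3, finite).
#' @return The coefficient in `[-1, 1]`.
#' @export
lin_ccc <- function(test, retest) {
  if (length(test) != length(retest)) stopf("test and retest series differ in length")
  n <- length(test)
  if (n < 3) stopf("CCC needs at least 3 paired observations (got %d)", n)
  if (any(!is.finite(test)) || any(!is.finite(retest))) stopf("CCC requires finite values")
  mx <- mean(test); my <- mean(retest)
  sx <- mean((test - mx)^2)
  sy <- mean((retest - my)^2)
  sxy <- mean((test - mx) * (retest - my))
  denom <- sx + sy + (mx - my)^2
  if (denom == 0) {
    out <- if (all(test == retest)) 1 else 0
    if (out == 0) attr(out, "degenerate") <- TRUE
    return(out)
  }
  2 * sxy / denom
}

#' Robustness filter by test-retest CCC
#'
#' Computes each feature's CCC between the test and retest feature tables
#' across subjects and retains a feature iff its CCC strictly exceeds the
#' modality threshold (defaults: CT 0.75, PET 0.65). The retained set keeps
#' catalog order.
#'
#' @param test_tab,retest_tab Feature tables from
#'   [extract_cohort_features()] on paired scans, same subjects in the same
#'   order.
#' @param modality `"pet"` or `"ct"` (selects the default threshold).
#' @param threshold Override the CCC cutoff.
#' @return An object of class `robustness_report`: data.frame with columns
#'   `feature`, `ccc`, `pass`, plus attributes `threshold`, `modality`,
#'   `n_retained`.
#' @export
filter_features <- function(test_tab, retest_tab, modality = c("pet", "ct"),
                            threshold = NULL) {
  modality <- match.arg(tolower(modality), c("pet", "ct"))
  if (is.null(threshold)) threshold <- c(pet = 0.65, ct = 0.75)[[modality]]
  if (!identical(test_tab$subject_id, retest_tab$subject_id)) {
    stopf("test and retest tables cover different subjects")
  }
  feats <- setdiff(names(test_tab), "subject_id")
  if (!identical(feats, setdiff(names(retest_tab), "subject_id"))) {
    stopf("test and retest tables have different feature columns")
  }
  ccc <- vapply(feats, function(f) as.numeric(lin_ccc(test_tab[[f]], retest_tab[[f]])),
                numeric(1))
  rep <- data.frame(feature = feats, ccc = ccc, pass = ccc > threshold,
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(rep, class = c("robustness_report", "data.frame"),
            threshold = threshold, modality = modality,
            n_retained = sum(rep$pass))
}

#' @export
print.robustness_report <- function(x, ...) {
  cat(sprintf("<robustness_report> %s: %d / %d features retained (CCC > %.2f)\n",
              toupper(attr(x, "modality")), attr(x, "n_retained"), nrow(x),
              attr(x, "threshold")))
  invisible(x)
}

#' Features retained by a robustness report
#'
#' @param report A [filter_features()] result.
#' @return Character vector of retained feature names, in catalog order.
#' @export
retained_features <- function(report) {
  stopifnot(inherits(report, "robustness_report"))
  report$feature[report$pass]
}
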