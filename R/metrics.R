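## Discrimination and calibration metrics for the binary exhaustion model.

#' Concordance index
#'
#' Over all (high, low) label pairs, the fraction of pairs in which the high
#' subject receives the higher probability, counting ties as 1/2. For binary
#' outcomes this equals the area under the ROC curve; any rank-preserving
#' transform of the predictions (for example logistic score vs probability)
#' leaves it unchanged.
#'
#' @param probabilities Numeric predictions (any monotone score works).
#' @param labels Binary labels (logical or 0/1); both classes must occur.
#' @return Value in `[0, 1]`.
#' @export
c_index <- function(probabilities, labels) {
  labels <- as.logical(labels)
  if (length(probabilities) != length(labels)) stopf("length mismatch")
  if (anyNA(probabilities) || anyNA(labels)) stopf("missing values")
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) stopf("C-index undefined: only one class present")
  p1 <- probabilities[labels]
  p0 <- probabilities[!labels]
  cmp <- outer(p1, p0, `-`)
  (sum(cmp > 0) + 0.5 * sum(cmp == 0)) / (n1 * n0)
}

#' Brier score
#'
#' Mean squared difference between predicted probability and the 0/1 label;
#' 0 for perfect hard predictions, 0.25 for constant 0.5.
#'
#' @inheritParams c_index
#' @return Value in `[0, 1]`.
#' @export
brier_score <- function(probabilities, labels) {
  labels <- as.numeric(as.logical(labels))
  if (length(probabilities) != length(labels)) stopf("length mismatch")
  if (any(probabilities < 0 | probabilities > 1)) stopf("probabilities must lie in [0, 1]")
  mean((probabilities - labels)^2)
}

#' Calibration curve
#'
#' Bins predictions into `n_bins` equal-width probability bins over
#' `[0, 1]`; per non-empty bin, reports the mean predicted probability, the
#' observed event frequency and the count. Empty bins are omitted, so the
#' counts sum to `length(probabilities)`.
#'
#' @inheritParams c_index
#' @param n_bins Number of equal-width bins (default 5).
#' @return data.frame with columns `bin`, `mean_predicted`, `observed`,
#'   `count`.
#' @export
calibration_curve <- function(probabilities, labels, n_bins = 5L) {
  labels <- as.numeric(as.logical(labels))
  if (!is_count(n_bins) || n_bins < 1) stopf("n_bins must be a positive integer")
  if (any(probabilities < 0 | probabilities > 1)) stopf("probabilities must lie in [0, 1]")
  bin <- cut(probabilities, breaks = seq(0, 1, length.out = n_bins + 1),
             include.lowest = TRUE, labels = FALSE)
  keep <- sort(unique(bin))
  data.frame(
    bin = keep,
    mean_predicted = vapply(keep, function(b) mean(probabilities[bin == b]), numeric(1)),
    observed = vapply(keep, function(b) mean(labels[bin == b]), numeric(1)),
    count = vapply(keep, function(b) sum(bin == b), numeric(1))
  )
}
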