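## First-order (intensity) features, in two flavors: statistics of the raw
## ROI intensities (IntensityDirect) and of the discretized gray levels
## (IntensityHistogram).

# Population moments; Pearson (non-excess) kurtosis m4/m2^2. A constant
# sample has undefined skewness/kurtosis: the degenerate policy returns 0
# and flags the vector.
moments_stats <- function(x) {
  n <- length(x)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) {
    sk <- 0; ku <- 0
    attr_flag <- TRUE
  } else {
    sk <- mean((x - m)^3) / m2^1.5
    ku <- mean((x - m)^4) / m2^2
    attr_flag <- FALSE
  }
  list(mean = m, var = m2, sd = sqrt(m2), skew = sk, kurt = ku,
       degenerate = attr_flag)
}

#' First-order intensity features
#'
#' `intensity_direct_features()` computes order and moment statistics of the
#' raw in-mask intensities: mean, median, extrema, range, population
#' variance/SD, skewness, Pearson kurtosis (`m4 / m2^2`, non-excess), energy
#' (sum of squares), total energy (energy times voxel volume), root mean
#' square, mean absolute deviation, percentiles 10/25/75/90, interquartile
#' range and robust mean absolute deviation (MAD over the 10th-90th
#' percentile range). These are deliberately not invariant to intensity
#' rescaling.
#'
#' `intensity_histogram_features()` computes the analogous statistics on the
#' discretized gray levels (mean, variance, skewness, kurtosis, entropy in
#' bits, uniformity, median, mode with smallest-level tie-break, 10th and
#' 90th percentile levels), which are invariant to any global affine intensity
#' rescaling by construction of the fixed-bin-count discretization.
#'
#' Degenerate policy: a constant ROI has skewness and kurtosis set to 0 and
#' the result carries attribute `degenerate = TRUE`.
#'
#' @param scan A [scan_volume()].
#' @param mask A [roi_mask()].
#' @param levels A level array from [discretize()].
#' @return Named numeric vector (with attribute `degenerate` when the
#'   constant-ROI policy fired).
#' @export
intensity_direct_features <- function(scan, mask) {
  stopifnot(inherits(scan, "scan_volume"), inherits(mask, "roi_mask"))
  check_alignment(scan, mask)
  if (!any(mask$voxels)) stopf("empty ROI mask")
  x <- scan$voxels[mask$voxels]
  st <- moments_stats(x)
  q <- stats::quantile(x, c(0.10, 0.25, 0.75, 0.90), names = FALSE, type = 7)
  out <- c(
    Mean = st$mean, Median = stats::median(x), Minimum = min(x), Maximum = max(x),
    Range = max(x) - min(x), Variance = st$var, StdDev = st$sd,
    Skewness = st$skew, Kurtosis = st$kurt,
    Energy = sum(x^2), TotalEnergy = sum(x^2) * prod(scan$spacing_mm),
    RootMeanSquare = sqrt(mean(x^2)),
    MeanAbsoluteDeviation = mean(abs(x - st$mean)),
    Percentile10 = q[1], Percentile25 = q[2], Percentile75 = q[3],
    Percentile90 = q[4], InterquartileRange = q[3] - q[2],
    RobustMeanAbsoluteDeviation = {
      xr <- x[x >= q[1] & x <= q[4]]
      mean(abs(xr - mean(xr)))
    }
  )
  attr(out, "degenerate") <- st$degenerate
  out
}

#' @rdname intensity_direct_features
#' @export
intensity_histogram_features <- function(levels) {
  N <- attr(levels, "n_levels")
  if (is.null(N)) stopf("levels must come from discretize()")
  x <- as.numeric(levels[!is.na(levels)])
  if (!length(x)) stopf("empty ROI mask")
  st <- moments_stats(x)
  p <- tabulate(x, nbins = N) / length(x)
  nz <- p > 0
  out <- c(
    Mean = st$mean, Variance = st$var, Skewness = st$skew, Kurtosis = st$kurt,
    Entropy = -sum(p[nz] * log2(p[nz])), Uniformity = sum(p^2),
    Median = stats::median(x), Mode = which.max(p),
    Percentile10 = stats::quantile(x, 0.10, names = FALSE, type = 7),
    Percentile90 = stats::quantile(x, 0.90, names = FALSE, type = 7)
  )
  attr(out, "degenerate") <- st$degenerate
  out
}
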