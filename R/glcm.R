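## Gray-level co-occurrence matrix and its statistics.

#' Texture configuration
#'
#' GLCM/GLRLM settings: neighbor distance, the 13 unique 3D directions
#' (non-redundant under negation), symmetric pair counting, and aggregation
#' by summing the per-direction matrices before normalization.
#'
#' @param glcm_distance Offset length in voxels (>= 1).
#' @param directions Integer matrix (rows = directions); defaults to the 13
#'   unique 3D neighbor directions.
#' @param symmetric Count both orderings of each pair (default TRUE).
#' @return An object of class `texture_config`.
#' @export
texture_config <- function(glcm_distance = 1L, directions = NULL, symmetric = TRUE) {
  if (!is_count(glcm_distance) || glcm_distance < 1) stopf("glcm_distance must be >= 1")
  if (is.null(directions)) directions <- directions_3d()
  directions <- as.matrix(directions)
  if (ncol(directions) != 3L) stopf("directions must have 3 columns")
  key <- apply(directions, 1, paste, collapse = ",")
  negkey <- apply(-directions, 1, paste, collapse = ",")
  # a direction and its negation count the same pairs: reject redundancy
  if (anyDuplicated(key) || any(key %in% negkey)) {
    stopf("directions must be non-redundant under negation")
  }
  structure(list(glcm_distance = as.integer(glcm_distance),
                 directions = directions, symmetric = isTRUE(symmetric),
                 aggregation = "sum"),
            class = "texture_config")
}

#' The 13 unique 3D neighbor directions
#'
#' All 26-connected neighbor offsets modulo negation: the canonical
#' representative has its first nonzero component positive.
#'
#' @return A 13 x 3 integer matrix.
#' @export
directions_3d <- function() {
  g <- as.matrix(expand.grid(d1 = -1:1, d2 = -1:1, d3 = -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  keep <- apply(g, 1, function(d) {
    nz <- d[d != 0]
    nz[1] > 0
  })
  m <- g[keep, , drop = FALSE]
  dimnames(m) <- NULL
  storage.mode(m) <- "integer"
  m
}

# Pair counts for one offset; levels is the NA-outside-mask level array.
glcm_pairs_one <- function(levels, off) {
  d <- dim(levels)
  N <- attr(levels, "n_levels")
  rng <- function(ax) {
    lo <- max(1L, 1L - off[ax]); hi <- min(d[ax], d[ax] - off[ax])
    if (hi < lo) integer(0) else lo:hi
  }
  i1 <- rng(1); i2 <- rng(2); i3 <- rng(3)
  if (!length(i1) || !length(i2) || !length(i3)) return(numeric(N * N))
  a <- levels[i1, i2, i3, drop = FALSE]
  b <- levels[i1 + off[1], i2 + off[2], i3 + off[3], drop = FALSE]
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok)) return(numeric(N * N))
  tabulate((a[ok] - 1L) * N + b[ok], nbins = N * N)
}

#' Gray-level co-occurrence matrix
#'
#' Counts pairs of discretized levels at the configured offset distance
#' within the mask, in each direction; symmetrized (both orderings counted),
#' summed over directions and normalized to total mass 1.
#'
#' @param levels Level array from [discretize()].
#' @param cfg A [texture_config()].
#' @return An `n_levels` x `n_levels` matrix summing to 1.
#' @export
glcm <- function(levels, cfg = texture_config()) {
  N <- attr(levels, "n_levels")
  if (is.null(N)) stopf("levels must come from discretize()")
  counts <- numeric(N * N)
  for (r in seq_len(nrow(cfg$directions))) {
    counts <- counts + glcm_pairs_one(levels, cfg$directions[r, ] * cfg$glcm_distance)
  }
  P <- matrix(counts, N, N, byrow = TRUE)  # row = first level, col = second
  if (cfg$symmetric) P <- P + t(P)
  tot <- sum(P)
  if (tot < 2) stopf("degenerate texture: fewer than 2 in-mask neighbor pairs")
  P / tot
}

#' GLCM statistics
#'
#' Computes the co-occurrence feature family from a normalized GLCM `P`
#' (indices `i`, `j` are gray levels):
#' `Contrast = sum P(i,j) (i-j)^2`,
#' `Homogeneity2 = sum P(i,j) / (1 + (i-j)^2)`,
#' `InverseVariance = sum_{i != j} P(i,j) / (i-j)^2` (0 for a purely diagonal
#' matrix, the continuous limit of vanishing off-diagonal mass), plus the
#' remaining catalog statistics (autocorrelation, cluster moments,
#' correlation, difference/sum statistics, energy, entropy, homogeneity,
#' maximum probability, variance, normalized inverse difference moment).
#' Entropies use log base 2 with `0 log 0 = 0`.
#'
#' @param P Normalized co-occurrence matrix (must sum to 1).
#' @return Named numeric vector of GLCM features.
#' @export
glcm_features <- function(P) {
  if (!is.matrix(P) || nrow(P) != ncol(P)) stopf("P must be a square matrix")
  if (abs(sum(P) - 1) > 1e-8) stopf("P is not normalized: sum is %.6f", sum(P))
  N <- nrow(P)
  i <- row(P); j <- col(P)
  px <- rowSums(P)
  mu_x <- sum(seq_len(N) * px)
  mu_y <- sum(seq_len(N) * colSums(P))   # equal to mu_x for symmetric P
  sd_x <- sqrt(sum((seq_len(N) - mu_x)^2 * px))
  sd_y <- sqrt(sum((seq_len(N) - mu_y)^2 * colSums(P)))
  dif <- abs(i - j)
  # diagonal-band distribution p_{|x-y|}(k), k = 0..N-1
  pxmy <- vapply(0:(N - 1), function(k) sum(P[dif == k]), numeric(1))
  # anti-diagonal distribution p_{x+y}(k), k = 2..2N
  sm <- i + j
  pxpy <- vapply(2:(2 * N), function(k) sum(P[sm == k]), numeric(1))
  log2z <- function(p) ifelse(p > 0, log2(p), 0)
  da <- sum((0:(N - 1)) * pxmy)
  sa <- sum((2:(2 * N)) * pxpy)
  off <- dif > 0
  corr <- if (sd_x > 0 && sd_y > 0) {
    (sum(i * j * P) - mu_x * mu_y) / (sd_x * sd_y)
  } else 0
  c(
    Autocorrelation = sum(i * j * P),
    ClusterProminence = sum((i + j - mu_x - mu_y)^4 * P),
    ClusterShade = sum((i + j - mu_x - mu_y)^3 * P),
    ClusterTendency = sum((i + j - mu_x - mu_y)^2 * P),
    Contrast = sum(P * (i - j)^2),
    Correlation = corr,
    DifferenceAverage = da,
    DifferenceEntropy = -sum(pxmy * log2z(pxmy)),
    DifferenceVariance = sum(((0:(N - 1)) - da)^2 * pxmy),
    Dissimilarity = sum(P * dif),
    Energy = sum(P^2),
    Entropy = -sum(P * log2z(P)),
    Homogeneity = sum(P / (1 + dif)),
    Homogeneity2 = sum(P / (1 + (i - j)^2)),
    InverseVariance = if (any(off)) sum(P[off] / (i[off] - j[off])^2) else 0,
    MaximumProbability = max(P),
    SumAverage = sa,
    SumEntropy = -sum(pxpy * log2z(pxpy)),
    SumVariance = sum(((2:(2 * N)) - sa)^2 * pxpy),
    Variance = sum((i - mu_x)^2 * P),
    InverseDifferenceMomentNorm = sum(P / (1 + (dif / N)^2))
  )
}
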