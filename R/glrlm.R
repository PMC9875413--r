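## Gray-level run-length matrix and its statistics.

# Run-length matrix for one direction: R[level, run_length] counts maximal
# runs of equal level along `off` within the mask.
glrlm_one <- function(levels, off) {
  d <- dim(levels)
  N <- attr(levels, "n_levels")
  coords <- which(!is.na(levels), arr.ind = TRUE)
  maxlen <- max(d)
  R <- matrix(0, N, maxlen)
  if (nrow(coords) == 0) return(R)
  lin <- function(i, j, k) (k - 1L) * d[1] * d[2] + (j - 1L) * d[1] + i
  inb <- function(i, j, k) i >= 1L & i <= d[1] & j >= 1L & j <= d[2] & k >= 1L & k <= d[3]
  cur <- lin(coords[, 1], coords[, 2], coords[, 3])
  lv <- levels[cur]
  pi <- coords[, 1] - off[1]; pj <- coords[, 2] - off[2]; pk <- coords[, 3] - off[3]
  prev_ok <- inb(pi, pj, pk)
  prev_same <- prev_ok
  prev_same[prev_ok] <- {
    pl <- levels[lin(pi[prev_ok], pj[prev_ok], pk[prev_ok])]
    !is.na(pl) & pl == lv[prev_ok]
  }
  starts <- which(!prev_same)
  for (s in starts) {
    g <- lv[s]
    len <- 1L
    i <- coords[s, 1] + off[1]; j <- coords[s, 2] + off[2]; k <- coords[s, 3] + off[3]
    while (inb(i, j, k)) {
      v <- levels[lin(i, j, k)]
      if (is.na(v) || v != g) break
      len <- len + 1L
      i <- i + off[1]; j <- j + off[2]; k <- k + off[3]
    }
    R[g, len] <- R[g, len] + 1
  }
  R
}

#' Gray-level run-length matrix
#'
#' Counts maximal runs of consecutive equal gray levels along each of the
#' configured directions within the mask, summed over directions.
#'
#' @param levels Level array from [discretize()].
#' @param cfg A [texture_config()] (`glcm_distance` is ignored; runs use unit
#'   steps).
#' @return An `n_levels` x `max_run_length` count matrix with attributes
#'   `n_voxels` and `n_directions`.
#' @export
glrlm <- function(levels, cfg = texture_config()) {
  N <- attr(levels, "n_levels")
  if (is.null(N)) stopf("levels must come from discretize()")
  R <- NULL
  for (r in seq_len(nrow(cfg$directions))) {
    Rr <- glrlm_one(levels, cfg$directions[r, ])
    R <- if (is.null(R)) Rr else R + Rr
  }
  if (sum(R) < 1) stopf("degenerate texture: no runs in the mask")
  attr(R, "n_voxels") <- sum(!is.na(levels))
  attr(R, "n_directions") <- nrow(cfg$directions)
  R
}

#' Run-length statistics
#'
#' Standard GLRLM features from the direction-summed run-length matrix
#' `R(g, l)` with `Nr = sum(R)` runs over `Np` voxels and `n_dir`
#' directions: short/long-run emphasis, gray-level and run-length
#' non-uniformity, run percentage (`Nr / (Np * n_dir)`), low/high gray-level
#' run emphasis and the four joint emphasis statistics.
#'
#' @param R Run-length matrix from [glrlm()].
#' @return Named numeric vector of GLRLM features.
#' @export
glrlm_features <- function(R) {
  Np <- attr(R, "n_voxels")
  nd <- attr(R, "n_directions")
  if (is.null(Np) || is.null(nd)) stopf("R must come from glrlm()")
  Nr <- sum(R)
  g <- row(R); l <- col(R)
  c(
    ShortRunEmphasis = sum(R / l^2) / Nr,
    LongRunEmphasis = sum(R * l^2) / Nr,
    GrayLevelNonuniformity = sum(rowSums(R)^2) / Nr,
    RunLengthNonuniformity = sum(colSums(R)^2) / Nr,
    RunPercentage = Nr / (Np * nd),
    LowGrayLevelRunEmphasis = sum(R / g^2) / Nr,
    HighGrayLevelRunEmphasis = sum(R * g^2) / Nr,
    ShortRunLowGrayLevelEmphasis = sum(R / (g^2 * l^2)) / Nr,
    ShortRunHighGrayLevelEmphasis = sum(R * g^2 / l^2) / Nr,
    LongRunLowGrayLevelEmphasis = sum(R * l^2 / g^2) / Nr,
    LongRunHighGrayLevelEmphasis = sum(R * g^2 * l^2) / Nr
  )
}
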