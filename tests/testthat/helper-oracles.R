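# Independent brute-force oracles for the texture matrices: plain pair and
# run enumeration over voxel coordinates, no shared code with the package
# implementation.

brute_glcm <- function(levels, directions, symmetric = TRUE) {
  N <- attr(levels, "n_levels")
  co <- which(!is.na(levels), arr.ind = TRUE)
  P <- matrix(0, N, N)
  d3 <- dim(levels)
  for (r in seq_len(nrow(directions))) {
    dir <- directions[r, ]
    for (v in seq_len(nrow(co))) {
      q <- co[v, ] + dir
      if (any(q < 1) || any(q > d3)) next
      lb <- levels[q[1], q[2], q[3]]
      if (is.na(lb)) next
      la <- levels[co[v, 1], co[v, 2], co[v, 3]]
      P[la, lb] <- P[la, lb] + 1
      if (symmetric) P[lb, la] <- P[lb, la] + 1
    }
  }
  P / sum(P)
}

brute_glrlm <- function(levels, directions) {
  N <- attr(levels, "n_levels")
  d3 <- dim(levels)
  R <- matrix(0, N, max(d3))
  co <- which(!is.na(levels), arr.ind = TRUE)
  inb <- function(p) all(p >= 1) && all(p <= d3)
  at <- function(p) levels[p[1], p[2], p[3]]
  for (r in seq_len(nrow(directions))) {
    dir <- directions[r, ]
    for (v in seq_len(nrow(co))) {
      p <- co[v, ]
      g <- at(p)
      prev <- p - dir
      if (inb(prev) && !is.na(at(prev)) && at(prev) == g) next  # not a run start
      len <- 1
      nxt <- p + dir
      while (inb(nxt) && !is.na(at(nxt)) && at(nxt) == g) {
        len <- len + 1
        nxt <- nxt + dir
      }
      R[g, len] <- R[g, len] + 1
    }
  }
  R
}

# random small ROI with NA holes, as a discretized level array
random_small_roi <- function(max_dim = 4L, n_levels = 3L) {
  d3 <- c(sample(2:max_dim, 1), sample(2:max_dim, 1), sample(2:max_dim, 1))
  lv <- array(sample.int(n_levels, prod(d3), replace = TRUE), d3)
  holes <- stats::runif(prod(d3)) < 0.25
  lv[holes] <- NA_integer_
  if (sum(!is.na(lv)) < 4) lv[holes] <- 1L  # keep enough voxels for pairs
  attr(lv, "n_levels") <- n_levels
  lv
}
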