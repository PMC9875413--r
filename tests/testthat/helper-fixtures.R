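# Shared fixtures, built in code and memoized so expensive phantoms are
# generated once per test run.

.fix <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fix[[key]])) .fix[[key]] <- force(expr)
  .fix[[key]]
}

# wrap a numeric array as a scan volume on a unit grid
tiny_scan <- function(values, dim3 = NULL, spacing = c(1, 1, 1),
                      modality = "PET", units = "SUV", meta = list()) {
  if (is.null(dim3)) dim3 <- dim(values)
  scan_volume(array(values, dim3), spacing, modality, units, meta)
}

full_mask <- function(dim3, spacing = c(1, 1, 1)) {
  roi_mask(array(TRUE, dim3), spacing, minimal = FALSE)
}

# discretized level array built directly (for texture unit tests)
levels_array <- function(values, dim3, n_levels) {
  out <- array(as.integer(values), dim3)
  attr(out, "n_levels") <- as.integer(n_levels)
  out
}

cube_mask <- function(side, margin = 2L, spacing = c(1, 1, 1)) {
  n <- side + 2L * margin
  v <- array(FALSE, c(n, n, n))
  v[(margin + 1):(margin + side), (margin + 1):(margin + side),
    (margin + 1):(margin + side)] <- TRUE
  roi_mask(v, spacing)
}

ball_mask <- function(radius, margin = 3L, spacing = c(1, 1, 1)) {
  n <- 2L * radius + 2L * margin
  ctr <- (n + 1) / 2
  co <- which(array(TRUE, c(n, n, n)), arr.ind = TRUE)
  v <- array((co[, 1] - ctr)^2 + (co[, 2] - ctr)^2 + (co[, 3] - ctr)^2 <= radius^2,
             c(n, n, n))
  roi_mask(v, spacing)
}

default_state <- function(tex = 0.6, day = 7L) {
  st <- sample_exhaustion_state(llc_rt_timecourse(), day, seed = 99L)
  st$terminal_tex_frac <- tex
  st$early_tex_frac <- 0.9 * (1 - tex)
  st$e_t_ratio <- st$early_tex_frac / tex
  st
}

default_phantom <- function() {
  memo("phantom", generate_phantom(phantom_spec(seed = 5L), default_state()))
}

default_pet_features <- function() {
  memo("pet_features", {
    ph <- default_phantom()
    extract_features(to_suv(ph$pet), ph$mask, "pet")
  })
}

default_ct_features <- function() {
  memo("ct_features", {
    ph <- default_phantom()
    extract_features(ph$ct, ph$mask, "ct")
  })
}

# the full default-condition training/validation experiment (seed 42),
# shared between acceptance-level checks
default_experiment <- function() {
  memo("experiment", {
    cfg <- run_config(seed = 42L)
    training <- run_training_arm(cfg)
    validation <- run_validation_arm(cfg, training$model)
    list(config = cfg, training = training, validation = validation)
  })
}

# frozen golden value: PET features retained by the CCC filter on the
# 12-subject shift-only retest protocol at seed 31 (see test-ccc.R)
.golden_small_pert_retained <- 45L
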