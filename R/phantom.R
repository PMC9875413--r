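## Digital FDG-uptake phantoms: ellipsoidal tumors whose local uptake
## heterogeneity is coupled to the latent terminal-Tex fraction through
## seeded cold-spot suppression blobs.

#' Phantom specification
#'
#' Geometry, uptake and acquisition parameters for one simulated
#' tumor-bearing PET/CT scan. Defaults emulate a mouse tumor at treatment
#' start: a ~200 mm^3 ellipsoid (semi-axes 3.8 x 3.6 x 3.4 mm) in a 48^3 grid
#' at 0.5 mm isotropic spacing, 5.55 MBq injected dose, 20 g body weight,
#' lesion SUV around 2.
#'
#' Heterogeneity model: a pool of 80 cold-spot kernels (Gaussian suppression
#' blobs) is drawn once from `seed`; a phantom activates the first
#' `round(heterogeneity_gain * 80 * terminal_tex_frac)` of them, so the
#' suppressed volume fraction grows with the terminal-Tex fraction while the
#' blob geometry stays nested across exhaustion levels at fixed seed. Blob
#' depth is fixed (cold spots descend to ~35% of the local base uptake);
#' scaling the count rather than the depth keeps the ROI intensity range --
#' and with it the fixed-bin-count discretization window -- stable across
#' exhaustion levels (see the methods vignette).
#'
#' Noise is additive Gaussian on activity, smoothed with a 1.5 mm FWHM
#' Gaussian point-spread kernel (reconstruction-resolution mimic) and floored
#' at 1% of the lesion base activity.
#'
#' @param grid_shape Integer length-3 grid dimensions.
#' @param voxel_spacing_mm Positive length-3 voxel spacing.
#' @param tumor_semi_axes_mm Positive length-3 ellipsoid semi-axes.
#' @param base_suv Mean lesion SUV before suppression.
#' @param heterogeneity_gain Coupling between `terminal_tex_frac` and the
#'   activated cold-spot fraction (default 1).
#' @param noise_sigma Noise standard deviation as a fraction of the lesion
#'   base activity (default 0.05).
#' @param injected_dose_MBq Injected FDG activity.
#' @param body_weight_g Subject body weight.
#' @param seed Integer seed; fully determines the phantom.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(48L, 48L, 48L),
                         voxel_spacing_mm = c(0.5, 0.5, 0.5),
                         tumor_semi_axes_mm = c(3.8, 3.6, 3.4),
                         base_suv = 2,
                         heterogeneity_gain = 1,
                         noise_sigma = 0.05,
                         injected_dose_MBq = 5.55,
                         body_weight_g = 20,
                         seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 8L))
  voxel_spacing_mm <- as.numeric(voxel_spacing_mm)
  tumor_semi_axes_mm <- as.numeric(tumor_semi_axes_mm)
  if (any(voxel_spacing_mm <= 0) || any(tumor_semi_axes_mm <= 0) ||
      base_suv <= 0 || injected_dose_MBq <= 0 || body_weight_g <= 0) {
    stopf("all geometric and acquisition quantities must be strictly positive")
  }
  if (heterogeneity_gain < 0 || noise_sigma < 0) {
    stopf("heterogeneity_gain and noise_sigma must be >= 0")
  }
  structure(list(grid_shape = grid_shape, voxel_spacing_mm = voxel_spacing_mm,
                 tumor_semi_axes_mm = tumor_semi_axes_mm, base_suv = base_suv,
                 heterogeneity_gain = heterogeneity_gain,
                 noise_sigma = noise_sigma,
                 injected_dose_MBq = injected_dose_MBq,
                 body_weight_g = body_weight_g, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf(paste0(
    "<phantom_spec> grid %s @ %s mm, semi-axes %s mm (%.0f mm^3), SUV %.2g,\n",
    "  gain %.2g, noise %.2g, dose %.3g MBq, weight %.3g g, seed %d\n"),
    paste(x$grid_shape, collapse = "x"),
    paste(format(x$voxel_spacing_mm), collapse = "x"),
    paste(format(x$tumor_semi_axes_mm), collapse = "x"),
    4 / 3 * pi * prod(x$tumor_semi_axes_mm), x$base_suv,
    x$heterogeneity_gain, x$noise_sigma, x$injected_dose_MBq,
    x$body_weight_g, x$seed))
  invisible(x)
}

# Separable 3D Gaussian smoothing. With `preserve_noise_var` the kernel is
# rescaled so white-noise input keeps unit marginal variance (the PSF must
# not silently shrink the noise level); without it, plain sum-1 smoothing.
gauss_smooth3 <- function(arr, sigma_vox, preserve_noise_var = TRUE) {
  d <- dim(arr)
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    if (s <= 0) next
    half <- max(1L, ceiling(3 * s))
    w <- stats::dnorm(seq(-half, half), sd = s)
    w <- w / sum(w)
    if (preserve_noise_var) w <- w / sqrt(sum(w^2))
    arr <- apply(arr, setdiff(1:3, ax), function(v) {
      n <- length(v)
      vp <- c(rep(v[1], half), v, rep(v[n], half))
      as.numeric(stats::filter(vp, w, sides = 2))[(half + 1):(half + n)]
    })
    arr <- aperm(arr, order(c(ax, setdiff(1:3, ax))))
  }
  arr
}

# Seeded pool of cold-spot kernels, in lesion-local mm coordinates.
blob_pool <- function(spec, n_pool = 80L) {
  with_seed(spec$seed, {
    centers <- matrix(NA_real_, 0, 3)
    while (nrow(centers) < n_pool) {
      u <- matrix(stats::runif(3 * n_pool, -1, 1), ncol = 3)
      u <- u[rowSums(u^2) <= 0.85^2, , drop = FALSE]
      centers <- rbind(centers, u)
    }
    centers <- centers[seq_len(n_pool), , drop = FALSE]
    centers <- sweep(centers, 2, spec$tumor_semi_axes_mm, `*`)
    sigma_mm <- stats::runif(n_pool, 0.25, 0.5)
    # smooth macroscopic uptake gradient: a few low-frequency cosine modes
    # with a per-subject amplitude, evaluable at any world coordinate so the
    # field moves rigidly with the lesion under retest repositioning
    n_modes <- 4L
    dirs <- matrix(stats::rnorm(3 * n_modes), n_modes, 3)
    dirs <- dirs / sqrt(rowSums(dirs^2))
    wavelen <- stats::runif(n_modes, 3.5, 6)  # mm
    phases <- stats::runif(n_modes, 0, 2 * pi)
    grad_amp <- stats::runif(1, 0.05, 0.3)
    list(centers = centers, sigma_mm = sigma_mm,
         grad = list(k = dirs * (2 * pi / wavelen), phase = phases,
                     amp = grad_amp))
  })
}

# evaluate the unit-scale gradient field at lesion-local mm coordinates
grad_field <- function(grad, xyz) {
  g <- numeric(nrow(xyz))
  for (j in seq_along(grad$phase)) {
    g <- g + cos(xyz %*% grad$k[j, ] + grad$phase[j])
  }
  drop(g) / length(grad$phase)
}

# Core rasterizer; `shift_mm`, `intensity_scale`, `noise_seed_offset` support
# test-retest re-realization of the same latent lesion.
realize_phantom <- function(spec, state, shift_mm = c(0, 0, 0),
                            intensity_scale = 1, noise_seed_offset = 0L,
                            psf_fwhm_mm = 1.5) {
  stopifnot(inherits(spec, "phantom_spec"), inherits(state, "exhaustion_state"))
  d <- spec$grid_shape
  sp <- spec$voxel_spacing_mm
  semi <- spec$tumor_semi_axes_mm
  extent <- d * sp / 2
  if (any(semi + abs(shift_mm) >= extent)) {
    stopf("tumor (semi-axes %s mm, shift %s mm) does not fit inside the grid (half-extent %s mm)",
          paste(format(semi), collapse = "x"), paste(format(shift_mm), collapse = "/"),
          paste(format(extent), collapse = "x"))
  }
  # world coordinates of voxel centers, lesion centered at shift_mm
  ax <- lapply(1:3, function(i) ((seq_len(d[i]) - (d[i] + 1) / 2) * sp[i]) - shift_mm[i])
  e1 <- (ax[[1]] / semi[1])^2
  e2 <- (ax[[2]] / semi[2])^2
  e3 <- (ax[[3]] / semi[3])^2
  r2 <- outer(outer(e1, e2, `+`), e3, `+`)
  inside <- r2 <= 1
  mask <- roi_mask(inside, sp)

  # lesion activity (kBq/mL) giving base_suv after SUV normalization
  act_base <- spec$base_suv * spec$injected_dose_MBq * 1000 / spec$body_weight_g

  pool <- blob_pool(spec)
  k <- max(0L, min(nrow(pool$centers),
                   as.integer(round(spec$heterogeneity_gain * nrow(pool$centers) *
                                      state$terminal_tex_frac))))
  idx <- which(inside)
  coords <- which(inside, arr.ind = TRUE)
  xyz <- sweep(coords, 2, (d + 1) / 2, `-`)
  xyz <- sweep(xyz, 2, sp, `*`)
  xyz <- sweep(xyz, 2, shift_mm, `-`)  # lesion-local mm coordinates
  supp <- numeric(length(idx))
  if (k > 0L) {
    for (b in seq_len(k)) {
      d2 <- (xyz[, 1] - pool$centers[b, 1])^2 +
            (xyz[, 2] - pool$centers[b, 2])^2 +
            (xyz[, 3] - pool$centers[b, 3])^2
      supp <- supp + exp(-d2 / (2 * pool$sigma_mm[b]^2))
    }
    supp <- pmin(supp, 1)
  }

  pet <- array(0.1 * act_base, d)
  # lesion = base uptake, modulated by the tex-independent macroscopic
  # gradient (confounder: spread unrelated to exhaustion), minus cold spots;
  # both heterogeneity sources are gated by heterogeneity_gain
  modulation <- 1 + spec$heterogeneity_gain * pool$grad$amp * grad_field(pool$grad, xyz)
  pet[idx] <- act_base * modulation * (1 - 0.65 * supp)

  # noise is smoothed with the reconstruction point-spread kernel
  psf_sigma_vox <- (psf_fwhm_mm / 2.3548) / sp
  if (spec$noise_sigma > 0) {
    noise <- with_seed(derive_seed(spec$seed, 777L + noise_seed_offset), {
      gauss_smooth3(array(stats::rnorm(prod(d)), d), sigma_vox = psf_sigma_vox)
    })
    pet <- pet + spec$noise_sigma * act_base * noise
  }
  pet <- pmax(pet, 0.01 * act_base)
  pet <- pet * intensity_scale

  ct <- array(0, d)
  ct[idx] <- 40 + 60 * (1 - r2[idx])
  ct <- ct * intensity_scale

  meta <- list(injected_dose_MBq = spec$injected_dose_MBq,
               body_weight_g = spec$body_weight_g,
               subject_id = NA_character_, day = state$day)
  list(pet = scan_volume(pet, sp, "PET", "kBq/mL", meta),
       ct = scan_volume(ct, sp, "CT", "HU", meta),
       mask = mask, state = state, spec = spec)
}

#' Generate one tumor phantom
#'
#' Rasterizes an ellipsoidal lesion into co-aligned PET-activity and CT
#' volumes with its exact ROI mask. ROI voxels carry the base activity minus
#' seeded cold-spot suppression whose total volume fraction scales with
#' `heterogeneity_gain * terminal_tex_frac`, plus smoothed Gaussian noise,
#' floored at 1% of base; background carries low uptake. The CT volume is a
#' smooth density ellipsoid acting as the texture carrier for CT features.
#'
#' @param spec A [phantom_spec()].
#' @param state An exhaustion state from [sample_exhaustion_state()].
#' @return A list with elements `pet` (activity [scan_volume()]), `ct`,
#'   `mask` ([roi_mask()]), `state` and `spec`.
#' @export
generate_phantom <- function(spec, state) {
  realize_phantom(spec, state)
}

#' Generate a test-retest phantom pair
#'
#' Re-realizes the same latent lesion twice: the retest scan applies a
#' sub-voxel repositioning shift, an independent noise realization and a
#' seeded random global intensity rescale (lognormal with log-sd
#' `intensity_scale_sd`, emulating uptake-time/glycemia variability between
#' sessions -- this is what makes raw-intensity features less reproducible
#' than rescale-invariant texture features), and its mask is re-rasterized
#' at the shifted position. With `shift_mm = c(0,0,0)`,
#' `intensity_scale_sd = 0` and `noise_seed_offset = 0` the two scans are
#' voxelwise identical.
#'
#' @inheritParams generate_phantom
#' @param perturbation List with `shift_mm` (length-3 mm shift),
#'   `intensity_scale_sd` (log-sd of the global rescale) and
#'   `noise_seed_offset` (integer; 0 reuses the test noise realization).
#' @return List with elements `test` and `retest`, each as
#'   [generate_phantom()] returns.
#' @export
generate_test_retest_pair <- function(spec, state,
                                      perturbation = list(shift_mm = c(1.2, -0.9, 0.7),
                                                          intensity_scale_sd = 0.15,
                                                          noise_seed_offset = 1L)) {
  shift <- perturbation$shift_mm %||% c(0, 0, 0)
  sd <- perturbation$intensity_scale_sd %||% 0
  off <- as.integer(perturbation$noise_seed_offset %||% 0L)
  scale <- if (sd > 0) {
    with_seed(derive_seed(spec$seed, 555L + off), exp(stats::rnorm(1, 0, sd)))
  } else 1
  list(test = realize_phantom(spec, state),
       retest = realize_phantom(spec, state, shift_mm = shift,
                                intensity_scale = scale,
                                noise_seed_offset = off))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a phantom cohort
#'
#' Draws `n` subjects at the given day(s) of a timecourse, each with an
#' independent seed derived from `seed`, mild per-subject jitter of the tumor
#' semi-axes, and a binary high-exhaustion label assigned by the cohort
#' median split of `terminal_tex_frac` (ties at the median go to the low
#' class).
#'
#' @param n Number of subjects (>= 4; the median split and downstream model
#'   fits are undefined below that).
#' @param timecourse A [cohort_timecourse()].
#' @param day Day index (scalar, or vector recycled across subjects to build
#'   mixed-day cohorts).
#' @param spec_template A [phantom_spec()] used for every subject (per-subject
#'   seeds and jitter are derived internally).
#' @param seed Master integer seed.
#' @param jitter_frac Relative semi-axis jitter (default 0.08).
#' @return An object of class `phantom_cohort`: a list with `subjects` (list
#'   of phantoms) and `ground_truth` (one row per subject).
#' @export
generate_cohort <- function(n, timecourse, day, spec_template = phantom_spec(),
                            seed = 1L, jitter_frac = 0.08) {
  if (!is_count(n) || n < 4) stopf("cohort size n must be an integer >= 4")
  days <- rep_len(as.integer(day), n)
  subjects <- vector("list", n)
  for (i in seq_len(n)) {
    st <- sample_exhaustion_state(timecourse, days[i], derive_seed(seed, i))
    jit <- with_seed(derive_seed(seed, 2000L + i),
                     stats::runif(3, 1 - jitter_frac, 1 + jitter_frac))
    sp <- spec_template
    sp$tumor_semi_axes_mm <- sp$tumor_semi_axes_mm * jit
    sp$seed <- derive_seed(seed, 1000L + i)
    ph <- generate_phantom(sp, st)
    ph$pet$meta$subject_id <- ph$ct$meta$subject_id <- sprintf("S%03d", i)
    subjects[[i]] <- ph
  }
  as_phantom_cohort(subjects, seed = seed)
}

# Assemble subjects into a cohort, (re)computing the median-split label.
as_phantom_cohort <- function(subjects, seed = NA_integer_) {
  tex <- vapply(subjects, function(s) s$state$terminal_tex_frac, numeric(1))
  med <- stats::median(tex)
  for (i in seq_along(subjects)) {
    subjects[[i]]$state$label_high <- tex[i] > med  # ties -> low class
    subjects[[i]]$pet$meta$subject_id <- subjects[[i]]$ct$meta$subject_id <-
      sprintf("S%03d", i)
  }
  gt <- data.frame(
    subject_id = sprintf("S%03d", seq_along(subjects)),
    model = vapply(subjects, function(s) s$state$model, character(1)),
    day = vapply(subjects, function(s) s$state$day, integer(1)),
    early_tex_frac = vapply(subjects, function(s) s$state$early_tex_frac, numeric(1)),
    terminal_tex_frac = tex,
    e_t_ratio = vapply(subjects, function(s) s$state$e_t_ratio, numeric(1)),
    pd1_mfi = vapply(subjects, function(s) s$state$pd1_mfi, numeric(1)),
    label_high = tex > med,
    stringsAsFactors = FALSE
  )
  structure(list(subjects = subjects, ground_truth = gt,
                 median_terminal_tex = med, seed = seed),
            class = "phantom_cohort")
}

#' Combine cohorts into one
#'
#' Concatenates the subjects of several cohorts and recomputes the
#' high-exhaustion label by the median split of the combined cohort (the
#' label is a cohort-level quantity and must never be carried over).
#'
#' @param ... `phantom_cohort` objects.
#' @return A `phantom_cohort`.
#' @export
combine_cohorts <- function(...) {
  cohorts <- list(...)
  stopifnot(length(cohorts) >= 1, all(vapply(cohorts, inherits, logical(1), "phantom_cohort")))
  as_phantom_cohort(do.call(c, lapply(cohorts, `[[`, "subjects")))
}

#' @export
print.phantom_cohort <- function(x, ...) {
  cat(sprintf("<phantom_cohort> %d subjects, median terminal-Tex %.3f\n",
              length(x$subjects), x$median_terminal_tex))
  print(utils::head(x$ground_truth, 6), row.names = FALSE)
  if (length(x$subjects) > 6) cat("  ...\n")
  invisible(x)
}
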