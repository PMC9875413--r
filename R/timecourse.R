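## Exhaustion-state simulation: cohort timecourses of the terminally-exhausted
## (PD-1 high) fraction of tumor-infiltrating CD8+ T cells, and per-subject
## latent immunology sampled from them.

#' Cohort timecourse of terminal T cell exhaustion
#'
#' A `cohort_timecourse` describes, for one tumor model and treatment arm, the
#' mean and spread of the terminally-exhausted (terminal Tex, PD-1^hi)
#' fraction of CD8+ T cells at each sampled day. Phantom cohorts draw their
#' latent exhaustion states from these per-day distributions.
#'
#' @param model Tumor model label, `"LLC"` or `"B16"`.
#' @param timepoints Integer vector of day indices.
#' @param terminal_tex_mean Per-day mean terminal-Tex fraction, in `[0, 1]`.
#' @param terminal_tex_sd Per-day standard deviation (>= 0).
#' @return An object of class `cohort_timecourse`.
#' @seealso [llc_rt_timecourse()], [llc_ici_timecourse()],
#'   [b16_ici_timecourse()], [sample_exhaustion_state()]
#' @export
cohort_timecourse <- function(model, timepoints, terminal_tex_mean, terminal_tex_sd) {
  model <- match.arg(toupper(model), c("LLC", "B16"))
  if (length(timepoints) != length(terminal_tex_mean) ||
      length(timepoints) != length(terminal_tex_sd)) {
    stopf("timepoints, means and sds must have equal length")
  }
  if (any(terminal_tex_mean < 0 | terminal_tex_mean > 1)) {
    stopf("terminal_tex_mean must lie in [0, 1]")
  }
  if (any(terminal_tex_sd < 0)) stopf("terminal_tex_sd must be >= 0")
  structure(
    list(model = model, timepoints = as.integer(timepoints),
         terminal_tex_mean = as.numeric(terminal_tex_mean),
         terminal_tex_sd = as.numeric(terminal_tex_sd)),
    class = "cohort_timecourse"
  )
}

#' @export
print.cohort_timecourse <- function(x, ...) {
  cat(sprintf("<cohort_timecourse> %s model, %d timepoints\n", x$model,
              length(x$timepoints)))
  print(data.frame(day = x$timepoints, mean = x$terminal_tex_mean,
                   sd = x$terminal_tex_sd), row.names = FALSE)
  invisible(x)
}

#' Built-in exhaustion timecourses
#'
#' Default per-day terminal-Tex distributions for the three simulated arms:
#'
#' * `llc_rt_timecourse()`: LLC tumors after a single ablative irradiation
#'   fraction. Terminal Tex starts near 40%, is flat over the first 3 days,
#'   peaks at roughly 70-73% over days 7-14, and drops below baseline by
#'   day 21.
#' * `llc_ici_timecourse()`: LLC tumors under anti-PD-L1 therapy. LLC is
#'   ICI-resistant, so the high (~40%) baseline barely moves.
#' * `b16_ici_timecourse()`: B16 tumors under anti-PD-L1. B16 starts less
#'   exhausted (~20%) and is reinvigorated, so terminal Tex falls.
#'
#' Only the LLC baseline (~0.40), B16 baseline (~0.20), the post-irradiation
#' peak window (0.6944-0.7635 at days 7-14) and the below-baseline day-21
#' value are calibrated quantities; intermediate-day means are package
#' defaults chosen to interpolate those anchors smoothly (see the methods
#' vignette).
#'
#' @return A [cohort_timecourse()].
#' @export
llc_rt_timecourse <- function() {
  cohort_timecourse("LLC",
                    timepoints = c(0L, 3L, 7L, 14L, 21L),
                    terminal_tex_mean = c(0.40, 0.41, 0.72, 0.73, 0.30),
                    terminal_tex_sd   = c(0.06, 0.06, 0.06, 0.06, 0.06))
}

#' @rdname llc_rt_timecourse
#' @export
llc_ici_timecourse <- function() {
  cohort_timecourse("LLC",
                    timepoints = c(0L, 7L, 22L),
                    terminal_tex_mean = c(0.40, 0.41, 0.43),
                    terminal_tex_sd   = c(0.06, 0.06, 0.06))
}

#' @rdname llc_rt_timecourse
#' @export
b16_ici_timecourse <- function() {
  cohort_timecourse("B16",
                    timepoints = c(0L, 7L, 22L),
                    terminal_tex_mean = c(0.20, 0.17, 0.12),
                    terminal_tex_sd   = c(0.05, 0.05, 0.04))
}

#' Sample a latent exhaustion state
#'
#' Draws one subject's latent immunology at a given day of a timecourse. The
#' terminal-Tex fraction is drawn from a normal distribution truncated to
#' `[0, 1]` with the day's mean and sd (an `sd` of 0 returns the mean
#' exactly); the early-Tex (PD-1^int) fraction is a fixed fraction
#' `early_frac_of_rest` of the remaining CD8+ compartment, so
#' `early + terminal <= 1` always holds. PD-1 MFI increases with the terminal
#' fraction with mild lognormal subject noise.
#'
#' @param timecourse A [cohort_timecourse()].
#' @param day A day index present in `timecourse$timepoints`.
#' @param seed Integer seed; the result is a pure function of
#'   `(timecourse, day, seed)`.
#' @param early_frac_of_rest Fraction of the non-terminal CD8+ compartment
#'   that is early Tex (default 0.9).
#' @return An object of class `exhaustion_state` with fields
#'   `early_tex_frac`, `terminal_tex_frac`, `e_t_ratio`, `pd1_mfi`,
#'   `label_high` (NA until assigned by a cohort median split), `model`,
#'   `day`.
#' @export
sample_exhaustion_state <- function(timecourse, day, seed, early_frac_of_rest = 0.9) {
  stopifnot(inherits(timecourse, "cohort_timecourse"))
  idx <- match(day, timecourse$timepoints)
  if (is.na(idx)) {
    stopf("day %s is not a timepoint of this timecourse (available: %s)",
          format(day), paste(timecourse$timepoints, collapse = ", "))
  }
  m <- timecourse$terminal_tex_mean[idx]
  s <- timecourse$terminal_tex_sd[idx]
  with_seed(seed, {
    if (s == 0) {
      terminal <- m
    } else {
      # inverse-CDF draw from Normal(m, s) truncated to [0, 1]
      lo <- stats::pnorm(0, m, s)
      hi <- stats::pnorm(1, m, s)
      terminal <- stats::qnorm(stats::runif(1, lo, hi), m, s)
    }
    terminal <- min(max(terminal, 0), 1)
    early <- early_frac_of_rest * (1 - terminal)
    mfi <- 500 * (1 + 2 * terminal) * exp(stats::rnorm(1, 0, 0.1))
    structure(
      list(early_tex_frac = early,
           terminal_tex_frac = terminal,
           e_t_ratio = if (terminal > 0) early / terminal else NA_real_,
           pd1_mfi = mfi,
           label_high = NA,
           model = timecourse$model,
           day = as.integer(day)),
      class = "exhaustion_state"
    )
  })
}

#' @export
print.exhaustion_state <- function(x, ...) {
  cat(sprintf(
    "<exhaustion_state> %s day %d: terminal %.3f, early %.3f, E/T %.2f, PD-1 MFI %.0f%s\n",
    x$model, x$day, x$terminal_tex_frac, x$early_tex_frac,
    ifelse(is.na(x$e_t_ratio), NA, x$e_t_ratio), x$pd1_mfi,
    if (is.na(x$label_high)) "" else sprintf(", label %s",
                                             ifelse(x$label_high, "high", "low"))))
  invisible(x)
}
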