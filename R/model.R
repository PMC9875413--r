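## The exhaustion model: LASSO selection of exhaustion-correlated features
## and the three-feature binary logistic T-exhaustion score.

#' LASSO selection of exhaustion-correlated features
#'
#' L1-penalized regression of one exhaustion characteristic on the
#' robustness-passing features: linear link for continuous characteristics
#' (Tex proportions, E/T ratio, PD-1 MFI), logistic for a binarized one.
#' Features are standardized to zero mean / unit variance internally; the
#' penalty is chosen by leave-one-out cross-validation with fixed fold order
#' (smallest mean deviance, no one-standard-error rule), so the fit is fully
#' deterministic. Coefficients are reported on the original feature scale.
#' All-constant feature columns are dropped with a warning; an empty
#' selection is a valid result, not an error.
#'
#' @param features data.frame or matrix of candidate features (rows =
#'   subjects; a `subject_id` column is ignored). At least 8 subjects.
#' @param target Numeric response (continuous) or binary labels.
#' @param kind `"continuous"` or `"binary"`.
#' @return data.frame with columns `feature`, `coefficient` for the
#'   nonzero-coefficient features at the selected penalty, with attribute
#'   `lambda`.
#' @export
lasso_select <- function(features, target, kind = c("continuous", "binary")) {
  kind <- match.arg(kind)
  X <- as.matrix(features[, setdiff(colnames(features), "subject_id"), drop = FALSE])
  storage.mode(X) <- "double"
  n <- nrow(X)
  if (n < 8) stopf("LASSO selection needs at least 8 subjects (got %d)", n)
  if (length(target) != n) stopf("target length does not match feature rows")
  const <- apply(X, 2, function(col) length(unique(col)) < 2)
  if (any(const)) {
    warning(sprintf("dropping %d all-constant feature column(s): %s",
                    sum(const), paste(colnames(X)[const], collapse = ", ")),
            call. = FALSE)
    X <- X[, !const, drop = FALSE]
  }
  if (ncol(X) < 2) stopf("need at least 2 non-constant candidate features")
  fam <- if (kind == "binary") "binomial" else "gaussian"
  y <- if (kind == "binary") as.numeric(as.logical(target)) else as.numeric(target)
  cv <- withCallingHandlers(
    glmnet::cv.glmnet(X, y, family = fam, standardize = TRUE,
                      foldid = seq_len(n), grouped = FALSE),
    warning = function(w) {
      # expected at mouse-cohort scale; not actionable for the caller
      if (grepl("fewer than 8", conditionMessage(w))) invokeRestart("muffleWarning")
    })
  beta <- as.matrix(stats::coef(cv, s = "lambda.min"))
  nz <- which(beta[-1, 1] != 0)
  out <- data.frame(feature = rownames(beta)[-1][nz],
                    coefficient = beta[-1, 1][nz],
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "lambda") <- cv$lambda.min
  out
}

#' Per-characteristic LASSO selection table
#'
#' Runs [lasso_select()] of each exhaustion characteristic (early and
#' terminal Tex fractions, E/T ratio, PD-1 MFI as continuous targets; the
#' high-exhaustion label as a binary target) on the robust feature set,
#' mirroring the structure of a per-characteristic selection table.
#'
#' @param features Feature table (e.g. [extract_cohort_features()]) already
#'   restricted to robustness-passing features.
#' @param truth Ground-truth data.frame with columns `early_tex_frac`,
#'   `terminal_tex_frac`, `e_t_ratio`, `pd1_mfi`, `label_high`.
#' @return Named list of [lasso_select()] results, class `selection_result`.
#' @export
select_exhaustion_features <- function(features, truth) {
  targets <- list(
    early_tex_frac = list(y = truth$early_tex_frac, kind = "continuous"),
    terminal_tex_frac = list(y = truth$terminal_tex_frac, kind = "continuous"),
    e_t_ratio = list(y = truth$e_t_ratio, kind = "continuous"),
    pd1_mfi = list(y = truth$pd1_mfi, kind = "continuous"),
    label_high = list(y = truth$label_high, kind = "binary")
  )
  out <- lapply(targets, function(t) lasso_select(features, t$y, t$kind))
  structure(out, class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat("<selection_result>\n")
  for (nm in names(x)) {
    cat(sprintf("  %s: %s\n", nm,
                if (nrow(x[[nm]]) == 0) "(none)"
                else paste(sprintf("%s (%.4g)", x[[nm]]$feature,
                                   x[[nm]]$coefficient), collapse = ", ")))
  }
  invisible(x)
}

.canonical_triple <- c("GLCM_InverseVariance", "GLCM_Homogeneity2", "IH_Kurtosis")

#' Fit the three-feature logistic T-exhaustion score
#'
#' Fits the binary logistic exhaustion model: the outcome is
#' `terminal_tex_frac > median(terminal_tex_frac)` (ties at the median go to
#' the low class) and the linear predictor uses the three named features
#' without penalization (the score is reported as plain logistic
#' coefficients). The T-exhaustion score of a subject is the linear
#' predictor; the high-exhaustion probability is its logistic transform.
#'
#' @param features Feature table (data.frame/matrix; a `subject_id` column is
#'   ignored) containing the three features.
#' @param terminal_tex_frac Per-subject terminal-Tex fraction.
#' @param feature_names The three model features; defaults to GLCM inverse
#'   variance, GLCM homogeneity2 and intensity-histogram kurtosis.
#' @return An object of class `texscore` with `print()`, `summary()`,
#'   `coef()`, `predict()`, `fitted()` and `residuals()` methods.
#' @seealso [texscore_reference()] for the packaged fixed-coefficient score.
#' @export
texscore <- function(features, terminal_tex_frac,
                     feature_names = .canonical_triple) {
  if (length(feature_names) != 3) stopf("the exhaustion score uses exactly 3 features")
  X <- as.data.frame(features)
  miss <- setdiff(feature_names, colnames(X))
  if (length(miss)) stopf("feature table lacks model feature(s): %s",
                          paste(miss, collapse = ", "))
  if (length(terminal_tex_frac) != nrow(X)) stopf("terminal_tex_frac length mismatch")
  med <- stats::median(terminal_tex_frac)
  y <- terminal_tex_frac > med
  if (sum(y) < 2 || sum(!y) < 2) {
    stopf("median split leaves a class with fewer than 2 subjects")
  }
  dat <- X[, feature_names, drop = FALSE]
  dat$.y <- as.numeric(y)
  fml <- stats::as.formula(paste(".y ~", paste(sprintf("`%s`", feature_names),
                                               collapse = " + ")))
  fit <- suppressWarnings(stats::glm(fml, family = stats::binomial(),
                                     data = dat,
                                     control = stats::glm.control(maxit = 100)))
  cf <- stats::coef(fit)
  if (any(!is.finite(cf))) {
    stopf("logistic fit failed to produce finite coefficients (deviance %.3g); %s",
          stats::deviance(fit), paste(names(cf)[!is.finite(cf)], collapse = ", "))
  }
  coefs <- cf[-1]
  names(coefs) <- feature_names
  structure(
    list(feature_names = feature_names,
         coefficients = coefs,
         intercept = unname(cf[1]),
         training_median = med,
         provenance = "refit",
         converged = fit$converged,
         fit = fit,
         n = nrow(X),
         labels = y),
    class = "texscore")
}

#' The packaged reference T-exhaustion score
#'
#' The fixed-coefficient three-feature logistic score shipped with the
#' package:
#' `score = -297.597 * InverseVariance(GLCM) + 178.689 * Homogeneity2(GLCM)
#'  + 1.088 * Kurtosis(IntensityHistogram) + 1.485`.
#' The negative texture coefficients encode that local FDG-uptake
#' homogeneity falls as the terminal-Tex fraction rises. The returned object
#' has provenance `"packaged"` and carries exactly these constants.
#'
#' @return A `texscore` object.
#' @export
texscore_reference <- function() {
  structure(
    list(feature_names = .canonical_triple,
         coefficients = c(GLCM_InverseVariance = -297.597,
                          GLCM_Homogeneity2 = 178.689,
                          IH_Kurtosis = 1.088),
         intercept = 1.485,
         training_median = NA_real_,
         provenance = "packaged",
         converged = TRUE,
         fit = NULL,
         n = NA_integer_,
         labels = NULL),
    class = "texscore")
}

#' @export
coef.texscore <- function(object, ...) {
  c("(Intercept)" = object$intercept, object$coefficients)
}

#' @export
print.texscore <- function(x, ...) {
  cat(sprintf("<texscore> three-feature logistic T-exhaustion score [%s]\n",
              x$provenance))
  eq <- paste(sprintf("%+.4g * %s", x$coefficients, x$feature_names),
              collapse = " ")
  cat(sprintf("  score = %s %+.4g\n", eq, x$intercept))
  if (!is.na(x$training_median)) {
    cat(sprintf("  trained on %d subjects, terminal-Tex median cutoff %.4f\n",
                x$n, x$training_median))
  }
  invisible(x)
}

#' Predict from a T-exhaustion score model
#'
#' @param object A `texscore` model.
#' @param newdata Feature table (data.frame/matrix) or single named feature
#'   vector containing the model's three features.
#' @param type `"link"` (the T-exhaustion score, default), `"prob"`
#'   (logistic probability of high exhaustion) or `"class"` (high-exhaustion
#'   call, probability > 0.5).
#' @param ... Unused.
#' @export
predict.texscore <- function(object, newdata, type = c("link", "prob", "class"), ...) {
  type <- match.arg(type)
  if (is.null(dim(newdata))) newdata <- as.data.frame(as.list(newdata))
  newdata <- as.data.frame(newdata)
  miss <- setdiff(object$feature_names, colnames(newdata))
  if (length(miss)) stopf("missing model feature(s): %s", paste(miss, collapse = ", "))
  M <- as.matrix(newdata[, object$feature_names, drop = FALSE])
  storage.mode(M) <- "double"
  score <- drop(M %*% object$coefficients) + object$intercept
  switch(type,
         link = score,
         prob = stats::plogis(score),
         class = stats::plogis(score) > 0.5)
}

#' @export
fitted.texscore <- function(object, ...) {
  if (is.null(object$fit)) stopf("the packaged reference model stores no training data")
  stats::fitted(object$fit)
}

#' @export
residuals.texscore <- function(object, type = "response", ...) {
  if (is.null(object$fit)) stopf("the packaged reference model stores no training data")
  stats::residuals(object$fit, type = type)
}

#' @export
summary.texscore <- function(object, ...) {
  print(object)
  if (!is.null(object$fit)) {
    cat("\nLogistic fit:\n")
    print(stats::coef(summary(object$fit)))
    p <- stats::fitted(object$fit)
    cat(sprintf("\nTraining C-index %.3f, Brier score %.3f\n",
                c_index(p, object$labels), brier_score(p, object$labels)))
  }
  invisible(object)
}

#' Evaluate the T-exhaustion score
#'
#' Computes the score and high-exhaustion probability per subject and the
#' discrimination/calibration summary: C-index, Brier score and the
#' calibration curve against the given labels. The C-index is computed on
#' the linear score: it is rank-equivalent to the probability, but immune to
#' the artificial ties the logistic transform produces in floating point
#' when scores are large.
#'
#' @param model A `texscore` model.
#' @param features Feature table containing the model features.
#' @param labels Binary high-exhaustion labels.
#' @param n_bins Calibration bins (default 5).
#' @return List with `score`, `probability`, `c_index`, `brier`,
#'   `calibration`.
#' @export
evaluate_texscore <- function(model, features, labels, n_bins = 5L) {
  score <- predict(model, features, type = "link")
  prob <- stats::plogis(score)
  list(score = score, probability = prob,
       c_index = c_index(score, labels),
       brier = brier_score(prob, labels),
       calibration = calibration_curve(prob, labels, n_bins))
}

#' Evaluate the score equation on one feature vector
#'
#' Convenience wrapper returning both the linear T-exhaustion score and the
#' logistic high-exhaustion probability for a single feature vector; a
#' score of 0 maps to probability exactly 0.5.
#'
#' @param model A `texscore` model.
#' @param fv Named feature vector (e.g. from [extract_features()])
#'   containing the model's three features.
#' @return List with `score` and `probability`.
#' @export
t_exhaustion_score <- function(model, fv) {
  score <- unname(predict(model, fv, type = "link"))
  list(score = score, probability = stats::plogis(score))
}

#' Serialize / restore a texscore model as JSON
#'
#' @param model A `texscore` model.
#' @param path JSON file path.
#' @return `read_texscore()` returns the restored model (without the
#'   internal glm object).
#' @export
write_texscore <- function(model, path) {
  stopifnot(inherits(model, "texscore"))
  jsonlite::write_json(
    list(feature_names = model$feature_names,
         coefficients = as.list(model$coefficients),
         intercept = model$intercept,
         training_median = model$training_median,
         provenance = model$provenance),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_texscore
#' @export
read_texscore <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(feature_names = j$feature_names,
         coefficients = unlist(j$coefficients),
         intercept = j$intercept,
         training_median = if (is.null(j$training_median)) NA_real_ else j$training_median,
         provenance = j$provenance,
         converged = TRUE, fit = NULL, n = NA_integer_, labels = NULL),
    class = "texscore")
}
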