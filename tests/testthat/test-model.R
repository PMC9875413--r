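# LASSO selection and the texscore logistic model.

make_design <- function(n = 24, p = 10, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, sprintf("f%02d", 1:p)))
  as.data.frame(X)
}

test_that("a noiseless single-feature signal is recovered with the top coefficient", {
  X <- make_design()
  y <- 3 * X$f03
  sel <- lasso_select(X, y, "continuous")
  expect_true("f03" %in% sel$feature)
  expect_identical(sel$feature[which.max(abs(sel$coefficient))], "f03")
})

test_that("permuted targets yield mostly empty selections", {
  # null behaviour of the leave-one-out lambda.min path: the selection is
  # exactly empty in a clear majority of permutation replicates and small
  # in the vast majority (the minimum-deviance rule keeps a heavier tail
  # than a one-standard-error rule would)
  X <- make_design(n = 20)
  y <- 2 * X$f01 + rnorm(20, sd = 0.1)
  sizes <- integer(100)
  for (r in 1:100) {
    set.seed(9000 + r)
    sizes[r] <- nrow(lasso_select(X, sample(y), "continuous"))
  }
  expect_gte(sum(sizes == 0), 50L)
  expect_gte(sum(sizes <= 3), 80L)
})

test_that("duplicated columns leave the fitted linear predictor unchanged", {
  X <- make_design()
  y <- X$f01 - 0.5 * X$f05 + rnorm(24, sd = 0.2)
  sel1 <- lasso_select(X, y, "continuous")
  X2 <- X; X2$f01_dup <- X$f01
  sel2 <- lasso_select(X2, y, "continuous")
  pred <- function(sel, D) {
    b <- setNames(sel$coefficient, sel$feature)
    as.matrix(D[names(b)]) %*% b
  }
  expect_equal(pred(sel1, X), pred(sel2, X2), tolerance = 1e-3)
})

test_that("constant columns are dropped with a warning, small cohorts rejected", {
  X <- make_design()
  X$f10 <- 1
  expect_warning(lasso_select(X, rnorm(24), "continuous"), "constant")
  expect_error(lasso_select(make_design(n = 6), rnorm(6), "continuous"),
               "at least 8")
})

test_that("a separable cohort is fit with confident probabilities", {
  set.seed(801)
  n <- 20
  tex <- c(runif(n / 2, 0.1, 0.3), runif(n / 2, 0.6, 0.9))
  X <- data.frame(GLCM_InverseVariance = 0.3 - 0.2 * tex + rnorm(n, sd = 0.002),
                  GLCM_Homogeneity2 = 0.3 - 0.2 * tex + rnorm(n, sd = 0.002),
                  IH_Kurtosis = 3 - tex + rnorm(n, sd = 0.01))
  m <- texscore(X, tex)
  p <- predict(m, X, type = "prob")
  expect_true(all(p[tex > median(tex)] >= 0.99))
  expect_true(all(p[tex <= median(tex)] <= 0.01))
  # deterministic refit
  expect_identical(coef(m), coef(texscore(X, tex)))
})

test_that("permutation null centers the out-of-sample C-index at one half", {
  # fit on permuted outcomes, evaluate on an independent permuted cohort:
  # with no real signal, discrimination must vanish out of sample (the
  # apparent in-sample C-index of a 3-predictor fit at n = 20 is
  # optimistically biased and is not the quantity of interest)
  set.seed(802)
  n <- 20
  cs <- replicate(100, {
    X <- data.frame(GLCM_InverseVariance = rnorm(2 * n),
                    GLCM_Homogeneity2 = rnorm(2 * n),
                    IH_Kurtosis = rnorm(2 * n))
    tex <- sample(rep(seq(0.1, 0.9, length.out = n), 2))
    m <- texscore(X[1:n, ], tex[1:n])
    ev <- evaluate_texscore(m, X[(n + 1):(2 * n), ],
                            tex[(n + 1):(2 * n)] > median(tex[(n + 1):(2 * n)]))
    ev$c_index
  })
  expect_equal(mean(cs), 0.5, tolerance = 0.1)
})

test_that("the packaged reference model carries the exact printed constants", {
  m <- texscore_reference()
  expect_identical(m$provenance, "packaged")
  expect_identical(unname(m$coefficients), c(-297.597, 178.689, 1.088))
  expect_identical(m$intercept, 1.485)
  sc <- t_exhaustion_score(m, c(GLCM_InverseVariance = 0, GLCM_Homogeneity2 = 0,
                                IH_Kurtosis = 0))
  expect_identical(sc$score, 1.485)
  sc2 <- t_exhaustion_score(m, c(GLCM_InverseVariance = 0.01,
                                 GLCM_Homogeneity2 = 0.5, IH_Kurtosis = 3))
  expect_equal(sc2$score, 91.11753, tolerance = 1e-9)
  expect_equal(t_exhaustion_score(m, c(GLCM_InverseVariance = 178.689 / 297.597,
                                       GLCM_Homogeneity2 = 1,
                                       IH_Kurtosis = -1.485 / 1.088))$probability,
               0.5, tolerance = 1e-9)
})

test_that("prediction validates its inputs and supports all types", {
  m <- texscore_reference()
  expect_error(predict(m, c(GLCM_InverseVariance = 0.1)), "GLCM_Homogeneity2")
  fv <- c(GLCM_InverseVariance = 0.2, GLCM_Homogeneity2 = 0.2, IH_Kurtosis = 2)
  sc <- predict(m, fv, type = "link")
  expect_equal(predict(m, fv, type = "prob"), plogis(sc))
  expect_identical(predict(m, fv, type = "class"), plogis(sc) > 0.5)
})

test_that("degenerate outcomes are rejected", {
  X <- data.frame(GLCM_InverseVariance = rnorm(6), GLCM_Homogeneity2 = rnorm(6),
                  IH_Kurtosis = rnorm(6))
  expect_error(texscore(X, c(0.1, 0.2, 0.2, 0.2, 0.2, 0.9)), "fewer than 2")
})

test_that("model JSON round trips preserve the score function", {
  X <- make_design(n = 12, p = 3)
  names(X) <- c("GLCM_InverseVariance", "GLCM_Homogeneity2", "IH_Kurtosis")
  tex <- seq(0.1, 0.9, length.out = 12)
  m <- texscore(X, 0.5 * X$GLCM_InverseVariance + tex)
  path <- file.path(withr::local_tempdir(), "model.json")
  write_texscore(m, path)
  back <- read_texscore(path)
  expect_equal(predict(back, X), unname(predict(m, X)))
  expect_equal(back$training_median, m$training_median)
})

test_that("per-characteristic selection runs on all five targets", {
  set.seed(803)
  n <- 12
  X <- data.frame(subject_id = sprintf("S%03d", 1:n),
                  a = rnorm(n), b = rnorm(n), c = rnorm(n), d = rnorm(n))
  tex <- runif(n, 0.1, 0.9)
  truth <- data.frame(early_tex_frac = 0.9 * (1 - tex), terminal_tex_frac = tex,
                      e_t_ratio = 0.9 * (1 - tex) / tex, pd1_mfi = 500 + 100 * tex,
                      label_high = tex > median(tex))
  sel <- select_exhaustion_features(X, truth)
  expect_named(sel, c("early_tex_frac", "terminal_tex_frac", "e_t_ratio",
                      "pd1_mfi", "label_high"))
  expect_s3_class(sel, "selection_result")
})
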