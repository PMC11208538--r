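# Confound removal, scenario designs, ridge/SVM nested CV, subsampling and
# the sweep machinery.

make_cov <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(subject_id = 1:n, age = runif(n, 47, 79),
             gender = rep_len(c(0L, 1L), n), tiv = rnorm(n, 1300, 100))
}

test_that("residualize fits on train rows and applies out of sample", {
  cov <- make_cov(100)
  set.seed(2)
  y <- 0.5 * cov$age + rnorm(100)
  idx <- 1:100
  res <- residualize(y, cov[, c("age", "gender", "tiv")], idx)
  # in-sample residuals are exactly orthogonal to every confound column
  for (cl in c("age", "gender", "tiv"))
    expect_lt(abs(cor(res, cov[[cl]])), 1e-10)
  # values already orthogonal to confounds come back unchanged (centered)
  z <- residualize(res, cov[, c("age", "gender", "tiv")], idx)
  expect_equal(z, res - mean(res), tolerance = 1e-8)
  # a pure confound function residualizes to ~0 on train rows
  expect_lt(max(abs(residualize(2 * cov$age,
                                cov[, c("age", "gender", "tiv")], idx))),
            1e-9)
  # rank-deficient design errors
  cov2 <- cbind(cov[, c("age", "tiv")], age2 = cov$age)
  expect_error(residualize(y, cov2, idx), "rank deficient")
})

test_that("residualize is leakage-free across disjoint train/test rows", {
  cov <- make_cov(200, seed = 3)
  set.seed(4)
  y <- cov$age + rnorm(200, sd = 5)
  tr <- 1:120
  te <- 121:200
  res_tr <- residualize(y, cov[, c("age", "gender", "tiv")], tr, tr)
  res_te <- residualize(y, cov[, c("age", "gender", "tiv")], tr, te)
  # exact orthogonality holds on the fitting rows only
  expect_lt(abs(cor(res_tr, cov$age[tr])), 1e-10)
  expect_gt(abs(cor(res_te, cov$age[te])), 1e-6)
  # and the test residuals differ from what a test-side fit would give
  res_te_refit <- residualize(y, cov[, c("age", "gender", "tiv")], te, te)
  expect_false(isTRUE(all.equal(res_te, res_te_refit)))
})

test_that("scenario designs have the published shapes", {
  n <- 60
  cov <- make_cov(n)
  feat400 <- matrix(rnorm(n * 400), n, 400)
  expect_equal(ncol(assemble_design(feat400, cov,
                                    "S3_features_plus_covariates")$X), 403)
  expect_equal(ncol(assemble_design(feat400, cov,
                                    "S4_covariates_only")$X), 3)
  d1 <- assemble_design(feat400, cov, "S1_features_raw", roi_subset = 1:13)
  expect_equal(ncol(d1$X), 13)
  expect_false(d1$deconfound)
  d2 <- assemble_design(feat400, cov, "S2_features_deconfounded")
  expect_true(d2$deconfound)
  expect_equal(dim(d2$confounds), c(n, 3L))
  expect_error(assemble_design(feat400, cov, "S1_features_raw",
                               roi_subset = integer(0)), "nonempty")
})

test_that("heuristic C is the reciprocal mean row norm", {
  X <- matrix(c(0, 4, 4, 0), 2, 2) # both rows have norm 4
  expect_equal(heuristic_c(X), 0.25)
  expect_equal(heuristic_c(matrix(c(3, 4), 1, 2)), 0.2)
  expect_error(heuristic_c(matrix(0, 3, 2)), "all-zero")
  # z-scored independent columns: E||x|| ~ sqrt(F), so C ~ 1/sqrt(400)
  set.seed(5)
  Xz <- scale(matrix(rnorm(3000 * 400), 3000, 400))
  expect_lt(abs(heuristic_c(Xz) - 0.05), 0.005)
})

test_that("ridge path agrees with the normal-equations solution", {
  set.seed(6)
  X <- matrix(rnorm(80 * 6), 80, 6)
  y <- rnorm(80)
  Xc <- scale(X, scale = FALSE)
  yc <- y - mean(y)
  for (l in c(0, 0.5, 10, 1e4)) {
    rp <- complexconn:::ridge_path(X, y, l)
    ref <- solve(crossprod(Xc) + diag(l, 6), crossprod(Xc, yc))
    expect_equal(as.vector(rp$coef), as.vector(ref), tolerance = 1e-8)
  }
})

test_that("nested CV recovers a noiseless linear target", {
  n <- 120
  cov <- make_cov(n, seed = 7)
  set.seed(8)
  X <- matrix(rnorm(n * 8), n, 8)
  y <- as.vector(X %*% rnorm(8))
  d <- list(X = X, confounds = NULL, deconfound = FALSE, scenario = "S1")
  r <- nested_cv_predict(d, y, model_spec("ridge", "regression"),
                         cv_config(seed = 1))
  expect_gte(r$score, 0.99)
  expect_equal(dim(r$fold_scores), c(5L, 5L))
})

test_that("nested CV stays at chance on null targets", {
  n <- 500
  cov <- make_cov(n, seed = 9)
  set.seed(10)
  X <- matrix(rnorm(n * 10), n, 10)
  ynull <- rnorm(n)
  d <- list(X = X, confounds = as.matrix(cov[, c("age", "gender", "tiv")]),
            deconfound = TRUE, scenario = "S2")
  r <- nested_cv_predict(d, ynull, model_spec("ridge", "regression"),
                         cv_config(seed = 2))
  expect_lt(abs(r$score), 2 / sqrt(100))
  ybin <- rep_len(c(0, 1), n)[sample.int(n)]
  rb <- nested_cv_predict(d, ybin, model_spec("ridge", "classification"),
                          cv_config(seed = 3))
  expect_gte(rb$score, 0.45)
  expect_lte(rb$score, 0.55)
})

test_that("confound placement separates S2 from S4 on an age-driven target", {
  n <- 300
  cov <- make_cov(n, seed = 11)
  set.seed(12)
  X <- matrix(rnorm(n * 6), n, 6) # features carry no signal
  y <- 2 * cov$age               # target is pure confound
  d2 <- assemble_design(X, cov, "S2_features_deconfounded")
  r2 <- nested_cv_predict(d2, y, model_spec("ridge", "regression"),
                          cv_config(seed = 4))
  expect_lt(abs(r2$score), 0.15) # age removed from target: nothing left
  d4 <- assemble_design(X, cov, "S4_covariates_only")
  r4 <- nested_cv_predict(d4, y, model_spec("ridge", "regression"),
                          cv_config(seed = 5))
  expect_gte(r4$score, 0.9)
})

test_that("constant predictions score 0 and are flagged", {
  # zero-variance feature columns are neutralized by the train-side
  # z-scoring, so the ridge predicts the constant train mean everywhere
  n <- 100
  set.seed(13)
  X <- matrix(rep(c(1, 2, 3, 4), each = n), n, 4)
  y <- rnorm(n)
  d <- list(X = X, confounds = NULL, deconfound = FALSE, scenario = "S1")
  r <- nested_cv_predict(d, y, model_spec("ridge", "regression"),
                         cv_config(seed = 6))
  expect_identical(r$score, 0)
  expect_identical(r$constant_prediction_folds, 25L)
})

test_that("linear SVM with heuristic C predicts and classifies", {
  n <- 150
  cov <- make_cov(n, seed = 14)
  set.seed(15)
  X <- matrix(rnorm(n * 5), n, 5)
  y <- as.vector(X %*% rnorm(5)) + rnorm(n, sd = 0.2)
  d <- list(X = X, confounds = NULL, deconfound = FALSE, scenario = "S1")
  r <- nested_cv_predict(d, y, model_spec("linear_svm", "regression"),
                         cv_config(seed = 7))
  expect_gte(r$score, 0.8)
  ybin <- as.integer(X[, 1] + rnorm(n, sd = 0.3) > 0)
  rb <- nested_cv_predict(d, ybin,
                          model_spec("linear_svm", "classification"),
                          cv_config(seed = 8))
  expect_gte(rb$score, 0.8)
})

test_that("balanced subsampling is even, deterministic and validated", {
  gender <- rep_len(c(0L, 1L), 250)
  idx <- balanced_subsample(gender, 100, seed = 1)
  expect_length(idx, 100)
  expect_equal(sum(gender[idx] == 0), 50)
  expect_identical(idx, balanced_subsample(gender, 100, seed = 1))
  expect_false(identical(idx, balanced_subsample(gender, 100, seed = 2)))
  expect_error(balanced_subsample(gender, 99), "even")
  expect_error(balanced_subsample(gender, 400), "not enough")
})

test_that("grid enumeration reproduces the factorial model counts", {
  expect_equal(count_models(9, 4, 78, 13), 36504L)
  expect_equal(count_models(9, 1, 78, 13), 9126L)
  g <- enumerate_grid(paste0("f", 1:3), c("a", "b"), c(100, 150), c(0, 30))
  expect_equal(nrow(g), 3 * 2 * 2 * 2)
  expect_equal(nrow(unique(g)), nrow(g))
  # the default grids: 39 regularization strengths, 75 unique sweep sizes
  expect_length(ridge_lambda_grid(), 39)
  sizes <- ukb_size_grid()
  expect_length(sizes, 75)
  expect_true(!is.unsorted(sizes))
  expect_equal(range(sizes), c(100L, 20000L))
})

test_that("the sweep emits one row per cell and isolates failures", {
  co <- generate_cohort(cohort_spec(260, 5, n_timepoints = 48, seed = 16))
  maps <- list(HE = co$truth$hurst)
  targets <- list(y = co$targets$target_cont)
  res <- sample_size_sweep(maps, targets, co$covariates,
                           scenarios = c("S1_features_raw",
                                         "S4_covariates_only"),
                           spec = model_spec("ridge", "regression"),
                           sizes = c(100L, 150L),
                           cv = cv_config(2, 5, 5), master_seed = 1)
  expect_equal(nrow(res), 1 * 1 * 2 * 2)
  expect_true(all(is.na(res$error)))
  # a size exceeding the cohort is recorded as a failed cell, not an abort
  res2 <- sample_size_sweep(maps, targets, co$covariates,
                            scenarios = "S1_features_raw",
                            spec = model_spec("ridge", "regression"),
                            sizes = c(100L, 5000L),
                            cv = cv_config(2, 5, 5), master_seed = 1)
  expect_equal(sum(!is.na(res2$error)), 1L)
  expect_true(is.na(res2$score[res2$n_subjects == 5000]))
})

test_that("prediction accuracy grows with sample size and plateaus", {
  co <- generate_cohort(cohort_spec(1000, 6, n_timepoints = 48,
                                    beta_feat = 3, beta_age = 0.3,
                                    beta_gender = 0.1, beta_tiv = 0.1,
                                    target_noise_sd = 1.2, seed = 17))
  maps <- list(HE = co$truth$hurst)
  targets <- list(y = co$targets$target_cont)
  res <- sample_size_sweep(maps, targets, co$covariates,
                           scenarios = "S1_features_raw",
                           spec = model_spec("ridge", "regression"),
                           sizes = c(100L, 300L, 900L),
                           cv = cv_config(3, 5, 5), master_seed = 2)
  sc <- res$score[order(res$n_subjects)]
  expect_gt(sc[3], sc[1])                      # rises overall
  expect_lt(sc[3] - sc[2], sc[2] - sc[1] + 0.05) # and flattens
})
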