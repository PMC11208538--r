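# Confound-aware predictive modeling: four scenarios for the role of
# individual characteristics (age, gender, TIV), ridge regression /
# classification with a fixed hyperparameter grid, heuristic-C linear SVM,
# five repeats of 5-fold nested cross-validation, balanced male/female
# subsampling and full sample-size sweeps.

SCENARIOS <- c("S1_features_raw", "S2_features_deconfounded",
               "S3_features_plus_covariates", "S4_covariates_only")

#' The ridge hyperparameter grid used throughout
#'
#' The 39 regularization strengths searched by the inner cross-validation
#' loop, from 0 (unregularized least squares, solved by pseudo-inverse) to
#' 1e6.
#'
#' @return Numeric vector of length 39.
#' @export
ridge_lambda_grid <- function() {
  c(0, 0.00001, 0.0001, 0.001, 0.004, 0.007, 0.01, 0.04, 0.07, 0.1,
    0.4, 0.7, 1, 1.5, 2, 2.5, 3, 3.5, 4, 5, 10, 15, 20, 30, 40, 50,
    60, 70, 80, 100, 150, 200, 300, 500, 700, 1000, 1e4, 1e5, 1e6)
}

#' The sample-size sweep grid
#'
#' Sizes from 100 to 2000 in steps of 50, then 2000 to 20,000 in steps of
#' 500 (duplicate 2000 removed): 75 unique sizes. Note that published
#' model-count bookkeeping sometimes quotes 78 sizes for this sweep; the
#' grid here is what the stated increments produce, and [count_models()]
#' takes the size count as an explicit argument.
#'
#' @return Integer vector of sample sizes.
#' @export
ukb_size_grid <- function() {
  unique(c(seq(100L, 2000L, by = 50L), seq(2000L, 20000L, by = 500L)))
}

#' Model specification
#'
#' @param model `"ridge"` (grid-searched lambda) or `"linear_svm"`
#'   (heuristic C, no search).
#' @param task `"regression"` (scored by Spearman correlation) or
#'   `"classification"` (scored by balanced accuracy).
#' @param lambda_grid Ridge grid (default [ridge_lambda_grid()]).
#' @return Object of class `model_spec`.
#' @export
model_spec <- function(model = c("ridge", "linear_svm"),
                       task = c("regression", "classification"),
                       lambda_grid = ridge_lambda_grid()) {
  model <- match.arg(model)
  task <- match.arg(task)
  stopifnot(length(lambda_grid) >= 1L, all(lambda_grid >= 0))
  structure(list(model = model, task = task, lambda_grid = lambda_grid),
            class = "model_spec")
}

#' Cross-validation configuration
#'
#' @param n_repeats Number of repeats of the outer split (default 5).
#' @param n_outer_folds,n_inner_folds Outer / inner fold counts (default 5).
#' @param seed Seed controlling all fold shuffles.
#' @return Object of class `cv_config`.
#' @export
cv_config <- function(n_repeats = 5L, n_outer_folds = 5L,
                      n_inner_folds = 5L, seed = 1L) {
  stopifnot(n_repeats >= 1L, n_outer_folds >= 2L, n_inner_folds >= 2L)
  structure(list(n_repeats = as.integer(n_repeats),
                 n_outer_folds = as.integer(n_outer_folds),
                 n_inner_folds = as.integer(n_inner_folds),
                 seed = as.integer(seed)),
            class = "cv_config")
}

#' Cross-validation-consistent confound removal
#'
#' Fits ordinary-least-squares confound coefficients (with intercept) on
#' the training rows only and returns residuals for the apply rows using
#' those coefficients, so no information flows from test to train.
#'
#' @param values Numeric vector or matrix (rows = subjects).
#' @param confounds Data frame or matrix of confounds (rows = subjects).
#' @param train_idx Rows used to fit the confound model.
#' @param apply_idx Rows for which residuals are returned (default
#'   `train_idx`).
#' @return Residualized values for `apply_idx` (same type as `values`).
#' @export
residualize <- function(values, confounds, train_idx,
                        apply_idx = train_idx) {
  v <- as.matrix(values)
  X <- cbind(1, as.matrix(confounds))
  storage.mode(X) <- "double"
  Xtr <- X[train_idx, , drop = FALSE]
  qx <- qr(Xtr)
  if (qx$rank < ncol(Xtr))
    stop("confound design is rank deficient", call. = FALSE)
  beta <- qr.coef(qx, v[train_idx, , drop = FALSE])
  res <- v[apply_idx, , drop = FALSE] - X[apply_idx, , drop = FALSE] %*% beta
  if (is.matrix(values)) res else as.vector(res)
}

#' Assemble the design matrix for one prediction scenario
#'
#' The four scenarios differ in the role of the individual characteristics:
#' S1 uses the ROI features as-is; S2 uses ROI features with the
#' characteristics marked as confounds for fold-wise removal (at the target
#' level in regression, at the feature level in classification); S3
#' concatenates ROI features and the three characteristics (`n_roi + 3`
#' columns); S4 uses the three characteristics only.
#'
#' @param features `n_subjects x n_roi` matrix of one ROI feature.
#' @param covariates Data frame with columns `age`, `gender`, `tiv`.
#' @param scenario One of `"S1_features_raw"`, `"S2_features_deconfounded"`,
#'   `"S3_features_plus_covariates"`, `"S4_covariates_only"`.
#' @param roi_subset Integer ROI indices kept (e.g. suprathreshold ROIs);
#'   must be nonempty for S1-S3.
#' @return List with `X` (design matrix), `confounds` (the covariate matrix
#'   or `NULL`), `deconfound` (`TRUE` for S2) and `scenario`.
#' @export
assemble_design <- function(features, covariates, scenario,
                            roi_subset = seq_len(ncol(features))) {
  scenario <- match.arg(scenario, SCENARIOS)
  cov_mat <- as.matrix(covariates[, c("age", "gender", "tiv")])
  if (scenario != "S4_covariates_only") {
    stopifnot(is.matrix(features))
    if (length(roi_subset) == 0L)
      stop("roi_subset must be nonempty for feature scenarios",
           call. = FALSE)
    feat <- features[, roi_subset, drop = FALSE]
  }
  switch(scenario,
    S1_features_raw = list(X = feat, confounds = NULL, deconfound = FALSE,
                           scenario = scenario),
    S2_features_deconfounded = list(X = feat, confounds = cov_mat,
                                    deconfound = TRUE, scenario = scenario),
    S3_features_plus_covariates = list(X = cbind(feat, cov_mat),
                                       confounds = NULL, deconfound = FALSE,
                                       scenario = scenario),
    S4_covariates_only = list(X = cov_mat, confounds = NULL,
                              deconfound = FALSE, scenario = scenario))
}

#' Heuristic SVM cost parameter
#'
#' `C = 1 / mean_n ||x_n||`, the reciprocal of the mean Euclidean row norm
#' of the (z-scored) design matrix.
#'
#' @param X Numeric design matrix, z-scored per column on the training rows.
#' @return Positive scalar cost.
#' @export
heuristic_c <- function(X) {
  X <- as.matrix(X)
  mn <- mean(sqrt(rowSums(X^2)))
  if (mn == 0) stop("all-zero design matrix", call. = FALSE)
  1 / mn
}

# Ridge path via SVD of the centered design: returns coefficients (p x L)
# and intercepts for every lambda at once.  lambda = 0 falls back to the
# minimum-norm least-squares solution (pseudo-inverse): singular values
# below tol are dropped.
ridge_path <- function(X, y, lambdas) {
  xm <- colMeans(X)
  ym <- mean(y)
  Xc <- sweep(X, 2L, xm)
  sv <- svd(Xc)
  uty <- crossprod(sv$u, y - ym)
  d <- sv$d
  tol <- max(dim(X)) * max(d, 0) * .Machine$double.eps
  B <- vapply(lambdas, function(l) {
    f <- if (l == 0) ifelse(d > tol, 1 / d, 0) else d / (d^2 + l)
    as.vector(sv$v %*% (f * uty))
  }, numeric(ncol(X)))
  B <- matrix(B, ncol = length(lambdas))
  list(coef = B, intercept = ym - as.vector(xm %*% B))
}

# z-scoring fit on training rows; columns with zero train SD map to 0.
fit_zscore <- function(X, train_idx) {
  mu <- colMeans(X[train_idx, , drop = FALSE])
  sdv <- apply(X[train_idx, , drop = FALSE], 2L, stats::sd)
  sdv[sdv == 0] <- Inf
  list(mu = mu, sd = sdv)
}
apply_zscore <- function(X, z) sweep(sweep(X, 2L, z$mu), 2L, z$sd, `/`)

spearman <- function(a, b) {
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(0)
  stats::cor(a, b, method = "spearman")
}

balanced_accuracy <- function(truth, pred) {
  classes <- sort(unique(truth))
  mean(vapply(classes, function(cl) mean(pred[truth == cl] == cl),
              numeric(1)))
}

make_folds <- function(y, k, stratify = FALSE) {
  n <- length(y)
  fold <- integer(n)
  if (stratify) {
    for (cl in unique(y)) {
      idx <- sample(which(y == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  } else {
    fold[sample.int(n)] <- rep_len(seq_len(k), n)
  }
  fold
}

# Fit on train, predict on test, for one model; X already z-scored.
fit_predict <- function(Xtr, ytr, Xte, spec, inner_folds) {
  if (spec$model == "ridge") {
    lam <- spec$lambda_grid
    best <- if (length(lam) == 1L) lam else {
      sc <- matrix(NA_real_, inner_folds$k, length(lam))
      for (f in seq_len(inner_folds$k)) {
        itr <- inner_folds$fold != f
        rp <- ridge_path(Xtr[itr, , drop = FALSE], ytr[itr], lam)
        pred <- Xtr[!itr, , drop = FALSE] %*% rp$coef
        pred <- sweep(pred, 2L, rp$intercept, `+`)
        sc[f, ] <- if (spec$task == "regression")
          apply(pred, 2L, spearman, b = ytr[!itr])
        else
          apply(pred > 0, 2L, function(p)
            balanced_accuracy(ytr[!itr] > 0, p))
      }
      lam[which.max(colMeans(sc))]
    }
    rp <- ridge_path(Xtr, ytr, best)
    pred <- as.vector(Xte %*% rp$coef) + rp$intercept
    list(pred = pred, hyper = best)
  } else { # linear SVM with heuristic C, no search
    C <- heuristic_c(Xtr)
    if (spec$task == "classification") {
      fit <- e1071::svm(Xtr, factor(ytr), kernel = "linear", cost = C,
                        scale = FALSE, type = "C-classification")
      pred <- as.numeric(as.character(stats::predict(fit, Xte)))
    } else {
      fit <- e1071::svm(Xtr, ytr, kernel = "linear", cost = C,
                        scale = FALSE, type = "eps-regression")
      pred <- as.vector(stats::predict(fit, Xte))
    }
    list(pred = pred, hyper = C)
  }
}

#' Nested cross-validated prediction
#'
#' Five repeats (by default) of a shuffled k-fold outer split; within each
#' outer-train set, confound residualization (scenario S2: target-level for
#' regression, feature-level for classification), per-column z-scoring and
#' ridge hyperparameter selection by inner k-fold grid search are all fit
#' on the outer-train rows only and applied to the outer-test rows, so no
#' statistic leaks across the fold boundary. The linear SVM uses the
#' heuristic cost of [heuristic_c()] with no search. Each outer fold is
#' scored by the Spearman correlation (regression) or balanced accuracy
#' (classification) between its test-set predictions and truths; the
#' headline score is the mean over all `n_repeats x n_outer_folds` fold
#' scores. Constant predictions score a Spearman of 0 and are flagged.
#'
#' @param design Output of [assemble_design()] (or a list with elements
#'   `X`, `confounds`, `deconfound`, `scenario`).
#' @param target Numeric target vector (binary 0/1 for classification).
#' @param spec A [model_spec()].
#' @param cv A [cv_config()].
#' @return Object of class `prediction_result`: list with `score`,
#'   `fold_scores` (`n_repeats x n_outer_folds`), `hyper` (chosen
#'   hyperparameter per fold), `task`, `model`, `scenario`,
#'   `n_subjects`, and `constant_prediction_folds`.
#' @export
nested_cv_predict <- function(design, target, spec = model_spec(),
                              cv = cv_config()) {
  stopifnot(inherits(spec, "model_spec"), inherits(cv, "cv_config"))
  X <- as.matrix(design$X)
  y <- as.numeric(target)
  n <- nrow(X)
  stopifnot(length(y) == n)
  if (n < 50L) stop("need at least 50 subjects", call. = FALSE)
  classify <- spec$task == "classification"
  if (classify && length(unique(y)) != 2L)
    stop("classification target must have exactly 2 classes", call. = FALSE)
  ycv <- if (classify) ifelse(y == max(y), 1, -1) else y
  fold_scores <- matrix(NA_real_, cv$n_repeats, cv$n_outer_folds)
  hyper <- matrix(NA_real_, cv$n_repeats, cv$n_outer_folds)
  n_const <- 0L
  with_seed(cv$seed, {
    for (rep_i in seq_len(cv$n_repeats)) {
      outer <- make_folds(ycv, cv$n_outer_folds, stratify = classify)
      for (f in seq_len(cv$n_outer_folds)) {
        tr <- which(outer != f)
        te <- which(outer == f)
        if (classify && length(unique(ycv[tr])) < 2L)
          stop("single-class outer training fold; stratification failed",
               call. = FALSE)
        Xf <- X
        yf <- ycv
        if (isTRUE(design$deconfound)) {
          if (classify) {
            Xf <- X
            Xf[c(tr, te), ] <- rbind(
              residualize(X, design$confounds, tr, tr),
              residualize(X, design$confounds, tr, te))
          } else {
            yf[tr] <- residualize(y, design$confounds, tr, tr)
            yf[te] <- residualize(y, design$confounds, tr, te)
          }
        }
        z <- fit_zscore(Xf, tr)
        Xtr <- apply_zscore(Xf[tr, , drop = FALSE], z)
        Xte <- apply_zscore(Xf[te, , drop = FALSE], z)
        inner <- list(fold = make_folds(yf[tr], cv$n_inner_folds,
                                        stratify = classify),
                      k = cv$n_inner_folds)
        fp <- fit_predict(Xtr, yf[tr], Xte, spec, inner)
        hyper[rep_i, f] <- fp$hyper
        if (classify) {
          pred_cl <- if (spec$model == "ridge") fp$pred > 0 else fp$pred > 0
          fold_scores[rep_i, f] <- balanced_accuracy(ycv[te] > 0, pred_cl)
        } else {
          if (stats::sd(fp$pred) == 0) n_const <- n_const + 1L
          fold_scores[rep_i, f] <- spearman(fp$pred, yf[te])
        }
      }
    }
  })
  structure(list(score = mean(fold_scores), fold_scores = fold_scores,
                 hyper = hyper, task = spec$task, model = spec$model,
                 scenario = design$scenario %||% NA_character_,
                 n_subjects = n,
                 constant_prediction_folds = n_const),
            class = "prediction_result")
}

#' @export
print.prediction_result <- function(x, ...) {
  cat(sprintf("nested-CV %s (%s), n = %d, scenario %s\n", x$task, x$model,
              x$n_subjects, x$scenario))
  metric <- if (x$task == "regression") "Spearman rho" else
    "balanced accuracy"
  cat(sprintf("  mean %s over %d folds: %.4f (SD %.4f)\n", metric,
              length(x$fold_scores), x$score, stats::sd(x$fold_scores)))
  invisible(x)
}

#' Balanced male/female subsample
#'
#' Draws `n/2` subjects uniformly at random from each gender,
#' seed-deterministically.
#'
#' @param gender Integer 0/1 vector over subjects.
#' @param n Even total subsample size; each gender must have at least `n/2`
#'   subjects.
#' @param seed RNG seed.
#' @return Sorted integer vector of subject indices.
#' @export
balanced_subsample <- function(gender, n, seed = 1L) {
  if (n %% 2 != 0) stop("n must be even", call. = FALSE)
  half <- n / 2
  i0 <- which(gender == 0)
  i1 <- which(gender == 1)
  if (length(i0) < half || length(i1) < half)
    stop("not enough subjects of each gender for n = ", n, call. = FALSE)
  with_seed(seed, sort(c(sample(i0, half), sample(i1, half))))
}

#' Enumerate an experiment grid and count its models
#'
#' `enumerate_grid()` expands the full factorial of features, targets,
#' sample sizes and tSNR levels (one row per model to fit, per model type);
#' `count_models()` returns the product count without materializing it.
#'
#' @param features,targets Character vectors of names.
#' @param sizes,tsnr_levels Numeric grids.
#' @return `enumerate_grid()`: data frame with one row per cell;
#'   `count_models()`: integer.
#' @export
enumerate_grid <- function(features, targets, sizes, tsnr_levels) {
  expand.grid(feature = features, target = targets, n_subjects = sizes,
              tsnr_level = tsnr_levels, KEEP.OUT.ATTRS = FALSE,
              stringsAsFactors = FALSE)
}

#' @rdname enumerate_grid
#' @param n_features,n_targets,n_sizes,n_levels Grid cardinalities.
#' @export
count_models <- function(n_features, n_targets, n_sizes, n_levels) {
  as.integer(n_features) * as.integer(n_targets) * as.integer(n_sizes) *
    as.integer(n_levels)
}

#' Sample-size sweep of nested-CV predictions
#'
#' Runs [nested_cv_predict()] over the full factorial of features x targets
#' x scenarios x sample sizes x tSNR levels for one model type. Each cell
#' subsamples the cohort with balanced genders using a seed derived
#' deterministically from the master seed and the cell labels; failures are
#' recorded per cell and the sweep continues.
#'
#' @param feature_maps Named list of `n_subjects x n_roi` feature matrices.
#' @param targets Named list of target vectors (aligned to subjects).
#' @param covariates Data frame with `age`, `gender`, `tiv`.
#' @param scenarios Character subset of the four scenario ids.
#' @param spec A [model_spec()]; its `task` must match each target's type
#'   (binary targets are classified when `spec$task == "classification"`).
#' @param sizes Ascending sample sizes (each at most `n_subjects`).
#' @param tsnr_profile Normalized group tSNR profile, or `NULL` to skip
#'   ROI selection.
#' @param tsnr_levels Threshold levels in percent (default 0).
#' @param cv A [cv_config()] template (its seed is overridden per cell).
#' @param master_seed Master seed for per-cell seed derivation.
#' @return Data frame: one row per cell with the mean score, its SD over
#'   folds, the suprathreshold ROI count used, and an `error` column
#'   (`NA` on success).
#' @export
sample_size_sweep <- function(feature_maps, targets, covariates,
                              scenarios = SCENARIOS, spec = model_spec(),
                              sizes, tsnr_profile = NULL, tsnr_levels = 0,
                              cv = cv_config(), master_seed = 1L) {
  stopifnot(!is.unsorted(sizes))
  grid <- expand.grid(feature = names(feature_maps),
                      target = names(targets), scenario = scenarios,
                      n_subjects = sizes, tsnr_level = tsnr_levels,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    rows[[i]] <- tryCatch({
      roi_subset <- if (is.null(tsnr_profile))
        seq_len(ncol(feature_maps[[g$feature]]))
      else suprathreshold_rois(tsnr_profile, g$tsnr_level)
      cell_seed <- derive_seed(master_seed, g$feature, g$target, g$scenario,
                               g$n_subjects, g$tsnr_level)
      idx <- balanced_subsample(covariates$gender, g$n_subjects,
                                seed = cell_seed)
      design <- assemble_design(feature_maps[[g$feature]][idx, ,
                                                          drop = FALSE],
                                covariates[idx, ], g$scenario, roi_subset)
      res <- nested_cv_predict(design, targets[[g$target]][idx], spec,
                               cv_config(cv$n_repeats, cv$n_outer_folds,
                                         cv$n_inner_folds,
                                         seed = cell_seed))
      data.frame(g, n_rois = length(roi_subset), score = res$score,
                 score_sd = stats::sd(res$fold_scores),
                 model = spec$model, task = spec$task,
                 error = NA_character_)
    }, error = function(e) {
      data.frame(g, n_rois = NA_integer_, score = NA_real_,
                 score_sd = NA_real_, model = spec$model, task = spec$task,
                 error = conditionMessage(e))
    })
  }
  do.call(rbind, rows)
}
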