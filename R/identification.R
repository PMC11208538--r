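# Feature-pair identification (fingerprinting): match each subject's map of
# feature X to the most spatially correlated map of feature Y across the
# population and score the proportion of self-matches.

#' Identification accuracy between two feature-map families
#'
#' For each subject `i`, the predicted identity is the subject `j` whose
#' map of type Y has the highest Pearson correlation (across ROIs) with
#' subject `i`'s map of type X; the accuracy is the fraction of subjects
#' whose argmax is themselves. Both match directions are computed, plus
#' their mean (the headline value). Optional confound removal regresses
#' age, gender and TIV out of each ROI column over the whole sample — this
#' analysis is descriptive, not predictive, so no cross-validation is
#' involved. Exact correlation ties in the argmax are counted as misses
#' (conservative; measure-zero under continuous noise). Subjects with a
#' constant map in either family are excluded with a warning.
#'
#' @param maps_x,maps_y `n_subjects x n_roi` matrices (same subjects, same
#'   ROI set).
#' @param confounds Optional data frame / matrix of confounds.
#' @return Object of class `identification_result`: list with
#'   `accuracy` (mean of the two directions), `accuracy_x_to_y`,
#'   `accuracy_y_to_x`, `n_subjects` and `n_excluded`.
#' @export
identify_subjects <- function(maps_x, maps_y, confounds = NULL) {
  stopifnot(is.matrix(maps_x), is.matrix(maps_y),
            all(dim(maps_x) == dim(maps_y)), nrow(maps_x) >= 2L)
  if (!is.null(confounds)) {
    idx <- seq_len(nrow(maps_x))
    maps_x <- residualize(maps_x, confounds, idx)
    maps_y <- residualize(maps_y, confounds, idx)
  }
  sd_x <- apply(maps_x, 1L, stats::sd)
  sd_y <- apply(maps_y, 1L, stats::sd)
  keep <- sd_x > 0 & sd_y > 0
  if (!all(keep))
    warning(sum(!keep), " subject(s) with constant maps excluded from ",
            "identification")
  maps_x <- maps_x[keep, , drop = FALSE]
  maps_y <- maps_y[keep, , drop = FALSE]
  n <- nrow(maps_x)
  if (n < 2L) stop("fewer than 2 usable subjects", call. = FALSE)
  C <- stats::cor(t(maps_x), t(maps_y)) # C[i, j] = cor(x_i, y_j)
  hit_dir <- function(M) { # rows are queries
    vapply(seq_len(nrow(M)), function(i) {
      mx <- max(M[i, ])
      sum(M[i, ] == mx) == 1L && which.max(M[i, ]) == i
    }, logical(1))
  }
  acc_xy <- mean(hit_dir(C))
  acc_yx <- mean(hit_dir(t(C)))
  structure(list(accuracy = (acc_xy + acc_yx) / 2,
                 accuracy_x_to_y = acc_xy, accuracy_y_to_x = acc_yx,
                 n_subjects = n, n_excluded = sum(!keep)),
            class = "identification_result")
}

#' @export
print.identification_result <- function(x, ...) {
  cat(sprintf(
    "identification over %d subjects: accuracy %.3f (x->y %.3f, y->x %.3f)\n",
    x$n_subjects, x$accuracy, x$accuracy_x_to_y, x$accuracy_y_to_x))
  invisible(x)
}

#' Pairwise identification-accuracy matrix over feature types
#'
#' Mean-direction identification accuracy for every unordered pair of
#' feature-map families; the diagonal (a feature against itself) is 1 by
#' construction and the table is symmetric.
#'
#' @param feature_maps Named list of `n_subjects x n_roi` matrices.
#' @param confounds Optional confounds passed to [identify_subjects()].
#' @return Symmetric numeric matrix of accuracies with feature names as
#'   dimnames.
#' @export
identification_matrix <- function(feature_maps, confounds = NULL) {
  stopifnot(is.list(feature_maps), length(feature_maps) >= 2L)
  nm <- names(feature_maps)
  k <- length(nm)
  M <- matrix(NA_real_, k, k, dimnames = list(nm, nm))
  for (i in seq_len(k)) {
    for (j in i:k) {
      acc <- identify_subjects(feature_maps[[i]], feature_maps[[j]],
                               confounds)$accuracy
      M[i, j] <- M[j, i] <- acc
    }
  }
  M
}
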