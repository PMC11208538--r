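# Feature extraction over a cohort: per-subject, per-ROI maps of the four
# temporal-complexity measures and the ROI-level connectivity measures.
# Maps are returned on their physical scale; any z-scoring across subjects
# happens inside the prediction module only.

ROI_FEATURES <- c("HE", "wPE", "RangeEnB_AUC", "MSE_AUC", "fALFF",
                  "EC", "wCC")

#' Extract ROI feature maps for every subject of a cohort
#'
#' Computes, for each subject's `n_roi x n_timepoints` series matrix, a per-
#' ROI value of each requested feature: Hurst exponent (`HE`), weighted
#' permutation entropy (`wPE`, m = 4, tau = 1), the tolerance-domain AUC of
#' range entropy B (`RangeEnB_AUC`, m = 2), the scale-domain AUC of
#' multiscale entropy (`MSE_AUC`, m = 2, r = 0.5, tau_max = 10), fALFF of
#' the ROI-mean series (band 0.008-0.09 Hz), and the two connectome graph
#' measures eigenvector centrality (`EC`) and weighted clustering
#' coefficient (`wCC`) from the Pearson FC matrix. The voxel-level measures
#' GCOR and LCOR are computed from 4D volumes via [voxel_feature_roi()],
#' not from ROI series, and are therefore not available here.
#'
#' @param series List of `n_roi x n_timepoints` matrices (one per subject),
#'   e.g. `generate_cohort(spec)$series`.
#' @param tr_seconds Repetition time, seconds.
#' @param features Character subset of
#'   `c("HE", "wPE", "RangeEnB_AUC", "MSE_AUC", "fALFF", "EC", "wCC")`.
#' @return Named list of `n_subjects x n_roi` matrices, one per feature.
#' @export
extract_feature_maps <- function(series, tr_seconds,
                                 features = ROI_FEATURES) {
  features <- match.arg(features, ROI_FEATURES, several.ok = TRUE)
  ns <- length(series)
  nr <- nrow(series[[1L]])
  maps <- lapply(features, function(f) matrix(NA_real_, ns, nr))
  names(maps) <- features
  for (s in seq_len(ns)) {
    m <- series[[s]]
    per_roi <- intersect(features,
                         c("HE", "wPE", "RangeEnB_AUC", "MSE_AUC", "fALFF"))
    for (f in per_roi) {
      maps[[f]][s, ] <- apply(m, 1L, switch(f,
        HE = hurst_rs,
        wPE = weighted_permutation_entropy,
        RangeEnB_AUC = range_entropy_B_auc,
        MSE_AUC = multiscale_entropy_auc,
        fALFF = function(x) falff(x, tr_seconds)))
    }
    if (any(c("EC", "wCC") %in% features)) {
      fc <- fc_matrix(m)
      if ("EC" %in% features)
        maps[["EC"]][s, ] <- eigenvector_centrality(fc)
      if ("wCC" %in% features)
        maps[["wCC"]][s, ] <- weighted_clustering_coefficient(fc)
    }
  }
  maps
}
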