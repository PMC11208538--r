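# Temporal signal-to-noise ratio (tSNR) per ROI, normalization, group
# averaging and percent-of-maximum thresholding for ROI selection.

#' Per-ROI temporal SNR
#'
#' tSNR of each ROI time series: mean divided by standard deviation over
#' time. Invariant to positive rescaling of the series.
#'
#' @param series Numeric matrix, `n_roi x n_timepoints`; no ROI may have
#'   zero temporal SD.
#' @return Named numeric vector of tSNR values per ROI.
#' @export
roi_tsnr <- function(series) {
  stopifnot(is.matrix(series), ncol(series) >= 2L)
  sds <- apply(series, 1L, stats::sd)
  if (any(sds == 0)) {
    bad <- rownames(series)[sds == 0] %||% which(sds == 0)
    stop("degenerate input: zero temporal SD in ROI(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  stats::setNames(rowMeans(series) / sds,
                  rownames(series) %||% seq_len(nrow(series)))
}

#' Normalize per-subject tSNR profiles and average across subjects
#'
#' Each subject's profile is divided by its own maximum, the normalized
#' profiles are averaged element-wise across subjects, and the group mean is
#' re-divided by its maximum so the result has maximum exactly 1.
#'
#' @param profiles List of numeric per-ROI tSNR vectors (same ROI set,
#'   same order).
#' @return Normalized group-mean tSNR profile (max = 1).
#' @export
normalize_and_group_mean <- function(profiles) {
  if (!is.list(profiles) || length(profiles) == 0L)
    stop("profiles must be a non-empty list", call. = FALSE)
  n_roi <- length(profiles[[1L]])
  if (any(vapply(profiles, length, integer(1)) != n_roi))
    stop("all profiles must cover the same ROI set", call. = FALSE)
  normed <- vapply(profiles, function(p) p / max(p), numeric(n_roi))
  g <- rowMeans(matrix(normed, nrow = n_roi))
  stats::setNames(g / max(g), names(profiles[[1L]]))
}

#' Suprathreshold ROIs at a percent-of-maximum tSNR level
#'
#' Indices of ROIs whose normalized tSNR is *strictly* greater than
#' `level_percent / 100`. The strict inequality makes the sweep endpoints
#' exact: level 0 keeps every ROI (all values are positive) and level 100
#' keeps none (no value exceeds the maximum of 1).
#'
#' @param profile Normalized tSNR profile (maximum 1, e.g. from
#'   [normalize_and_group_mean()]).
#' @param level_percent Threshold level in `[0, 100]`.
#' @return Integer vector of suprathreshold ROI indices.
#' @export
suprathreshold_rois <- function(profile, level_percent) {
  stopifnot(is.numeric(profile), length(profile) >= 1L)
  if (!isTRUE(all.equal(max(profile), 1, tolerance = 1e-8)))
    stop("profile must be normalized (max = 1); see ",
         "normalize_and_group_mean()", call. = FALSE)
  if (length(level_percent) != 1L || level_percent < 0 || level_percent > 100)
    stop("level_percent must lie in [0, 100]", call. = FALSE)
  which(profile > level_percent / 100)
}

#' Suprathreshold ROI counts over a sweep of threshold levels
#'
#' @inheritParams suprathreshold_rois
#' @param levels_percent Vector of levels in `[0, 100]` (default 0 to 60 in
#'   5% steps, the range over which any ROI survives on typical group maps).
#' @return Integer vector of counts, named by level.
#' @export
suprathreshold_counts <- function(profile,
                                  levels_percent = seq(0, 60, by = 5)) {
  counts <- vapply(levels_percent,
                   function(l) length(suprathreshold_rois(profile, l)),
                   integer(1))
  stats::setNames(counts, levels_percent)
}

#' Read a per-ROI tSNR profile
#'
#' `read_tsnr_profile_tsv()` reads a two-column TSV (`roi_id`, `tsnr`).
#' `tsnr_profile_from_nifti()` reads a voxel-wise tSNR map plus an integer
#' label volume (NIfTI-1) and averages the map within each ROI.
#'
#' @param path Path to the TSV file.
#' @return Named numeric tSNR vector (ROI ids as names).
#' @export
read_tsnr_profile_tsv <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE)
  if (ncol(tab) < 2L)
    stop("expected columns roi_id and tsnr", call. = FALSE)
  stats::setNames(as.numeric(tab[[2L]]), tab[[1L]])
}

#' @rdname read_tsnr_profile_tsv
#' @param map_path,label_path Paths to the tSNR map and ROI label NIfTI
#'   volumes (same grid).
#' @export
tsnr_profile_from_nifti <- function(map_path, label_path) {
  map <- as.array(RNifti::readNifti(map_path))
  lab <- as.array(RNifti::readNifti(label_path))
  if (!all(dim(map) == dim(lab)))
    stop("tSNR map and label volume must share a grid", call. = FALSE)
  parcellate(map, array(as.integer(round(lab)), dim(lab)))
}
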