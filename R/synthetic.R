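# Synthetic cohorts with the statistical structure the analysis assumes:
# per-ROI fractional Gaussian noise with controllable Hurst exponents,
# shared latent factors controlling inter-ROI correlation, per-ROI tSNR via
# a constant offset, covariates (age, gender, TIV) and targets that are
# noisy linear functions of a ground-truth feature and/or covariates, plus
# null targets.

#' Specify a synthetic cohort
#'
#' Defaults emulate the acquisition geometry of a large population rsfMRI
#' study: 490 time points at TR 0.735 s. Gender is balanced by
#' construction; age is uniform on `age_range` years; TIV is Gaussian with
#' a gender-dependent mean (ml). Per-ROI tSNR is controlled by a constant
#' offset `roi_offset` added to the standardized fluctuation: the total
#' fluctuation SD is scaled so that mean/SD equals `tsnr_target`.
#'
#' The continuous target is a standardized linear combination of the
#' per-subject ground-truth feature (the per-ROI Hurst exponents, weighted
#' by `beta_feat`) and the z-scored covariates, plus Gaussian noise of SD
#' `target_noise_sd`; the binary target thresholds an independent draw of
#' the same latent score at its median. Null targets are independent of
#' everything.
#'
#' @param n_subjects,n_rois,n_timepoints Cohort dimensions (`n_subjects >=
#'   2`, `n_rois >= 2`, `n_timepoints >= 32`).
#' @param tr_seconds Repetition time, seconds.
#' @param hurst_range Interval inside (0, 1); each subject x ROI Hurst
#'   exponent is drawn uniformly from it.
#' @param n_latent_factors Number of shared latent time courses.
#' @param factor_loading_scale SD of the Gaussian factor loadings; 0 gives
#'   independent ROIs.
#' @param roi_noise_sd Per-ROI additive white-noise SD (recycled), applied
#'   before standardization (degrades the latent/fGn structure).
#' @param roi_offset Constant signal offset per ROI (recycled).
#' @param tsnr_target Requested per-ROI tSNR (recycled); the fluctuation is
#'   scaled so mean/SD of each ROI series equals it. `NULL` leaves the
#'   fluctuation at unit SD around the offset.
#' @param age_range,tiv_mean,tiv_sd Covariate distributions: age uniform in
#'   years; TIV Gaussian, `tiv_mean` is `c(female, male)` in ml.
#' @param beta_feat Per-ROI weight vector of the ground-truth feature effect
#'   (recycled to `n_rois`).
#' @param beta_age,beta_gender,beta_tiv Covariate effects on the target.
#' @param target_noise_sd SD of the target noise (target is standardized
#'   before noise is added).
#' @param seed RNG seed; identical spec + seed give bit-identical cohorts.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects, n_rois, n_timepoints = 490L,
                        tr_seconds = 0.735,
                        hurst_range = c(0.55, 0.85),
                        n_latent_factors = 3L,
                        factor_loading_scale = 0.7,
                        roi_noise_sd = 0.3,
                        roi_offset = 100,
                        tsnr_target = 50,
                        age_range = c(47, 79),
                        tiv_mean = c(1250, 1400),
                        tiv_sd = 110,
                        beta_feat = 1,
                        beta_age = 1,
                        beta_gender = 0.5,
                        beta_tiv = 0.5,
                        target_noise_sd = 0.5,
                        seed = 1L) {
  spec <- list(n_subjects = as.integer(n_subjects),
               n_rois = as.integer(n_rois),
               n_timepoints = as.integer(n_timepoints),
               tr_seconds = tr_seconds, hurst_range = hurst_range,
               n_latent_factors = as.integer(n_latent_factors),
               factor_loading_scale = factor_loading_scale,
               roi_noise_sd = rep_len(roi_noise_sd, n_rois),
               roi_offset = rep_len(roi_offset, n_rois),
               tsnr_target = if (is.null(tsnr_target)) NULL
                             else rep_len(tsnr_target, n_rois),
               age_range = age_range, tiv_mean = tiv_mean, tiv_sd = tiv_sd,
               beta_feat = rep_len(beta_feat, n_rois),
               beta_age = beta_age, beta_gender = beta_gender,
               beta_tiv = beta_tiv, target_noise_sd = target_noise_sd,
               seed = as.integer(seed))
  validate_cohort_spec(spec)
  structure(spec, class = "cohort_spec")
}

validate_cohort_spec <- function(s) {
  if (s$n_subjects < 2L) stop("n_subjects must be >= 2", call. = FALSE)
  if (s$n_rois < 2L) stop("n_rois must be >= 2", call. = FALSE)
  if (s$n_timepoints < 32L) stop("n_timepoints must be >= 32", call. = FALSE)
  if (s$hurst_range[1] <= 0 || s$hurst_range[2] >= 1 ||
      s$hurst_range[1] > s$hurst_range[2])
    stop("hurst_range must be an interval inside (0, 1)", call. = FALSE)
  if (any(s$roi_noise_sd < 0)) stop("roi_noise_sd must be >= 0", call. = FALSE)
  if (s$target_noise_sd < 0) stop("target_noise_sd must be >= 0",
                                  call. = FALSE)
  if (s$n_latent_factors < 0) stop("n_latent_factors must be >= 0",
                                   call. = FALSE)
  if (!is.null(s$tsnr_target) && any(s$tsnr_target <= 0))
    stop("tsnr_target must be positive", call. = FALSE)
  invisible(s)
}

#' Generate a synthetic cohort
#'
#' Draws ROI time series (latent-factor mixture + per-ROI fGn + white
#' noise, offset and scaled to the requested tSNR), covariates and targets
#' per [cohort_spec()]. The returned `truth` element records the generating
#' parameters (per-subject-per-ROI Hurst exponents, factor loadings, effect
#' sizes) for ground-truth evaluation.
#'
#' @param spec A [cohort_spec()].
#' @return List of class `synthetic_cohort` with elements `series` (list of
#'   `n_roi x n_timepoints` matrices, one per subject), `tr_seconds`,
#'   `covariates` (data frame: `subject_id`, `age`, `gender`, `tiv`),
#'   `targets` (data frame: `subject_id`, `target_cont`, `target_bin`,
#'   `null_cont`, `null_bin`) and `truth`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  validate_cohort_spec(spec)
  ns <- spec$n_subjects; nr <- spec$n_rois; nt <- spec$n_timepoints
  with_seed(spec$seed, {
    loadings <- matrix(stats::rnorm(nr * spec$n_latent_factors,
                                    sd = spec$factor_loading_scale),
                       nr, spec$n_latent_factors)
    H <- matrix(stats::runif(ns * nr, spec$hurst_range[1],
                             spec$hurst_range[2]), ns, nr)
    series <- vector("list", ns)
    for (s in seq_len(ns)) {
      fac <- matrix(stats::rnorm(spec$n_latent_factors * nt),
                    spec$n_latent_factors, nt)
      y <- matrix(0, nr, nt)
      for (r in seq_len(nr)) {
        z <- generate_fgn(nt, H[s, r])
        if (spec$n_latent_factors > 0L)
          z <- z + as.vector(loadings[r, , drop = FALSE] %*% fac)
        if (spec$roi_noise_sd[r] > 0)
          z <- z + stats::rnorm(nt, sd = spec$roi_noise_sd[r])
        z <- (z - mean(z)) / stats::sd(z) # exact zero mean, unit SD
        amp <- if (is.null(spec$tsnr_target)) 1
               else spec$roi_offset[r] / spec$tsnr_target[r]
        y[r, ] <- spec$roi_offset[r] + amp * z
      }
      rownames(y) <- seq_len(nr)
      series[[s]] <- y
    }
    # covariates: balanced gender, uniform age, gender-dependent TIV
    gender <- sample(rep_len(c(0L, 1L), ns))
    age <- stats::runif(ns, spec$age_range[1], spec$age_range[2])
    tiv <- stats::rnorm(ns, mean = spec$tiv_mean[gender + 1L],
                        sd = spec$tiv_sd)
    covariates <- data.frame(subject_id = seq_len(ns), age = age,
                             gender = gender, tiv = tiv)
    # targets: standardized linear score + noise
    zscore <- function(v) if (stats::sd(v) == 0) v * 0 else
      (v - mean(v)) / stats::sd(v)
    # H columns are z-scored so beta_feat is on the same scale as the
    # covariate betas (which act on z-scored covariates)
    Hz <- apply(H, 2L, zscore)
    latent <- as.vector(Hz %*% spec$beta_feat) / sqrt(nr) +
      spec$beta_age * zscore(age) + spec$beta_gender * zscore(gender) +
      spec$beta_tiv * zscore(tiv)
    latent <- zscore(latent)
    target_cont <- latent + stats::rnorm(ns, sd = spec$target_noise_sd)
    latent_bin <- latent + stats::rnorm(ns, sd = spec$target_noise_sd)
    target_bin <- as.integer(latent_bin > stats::median(latent_bin))
    null_cont <- stats::rnorm(ns)
    null_bin <- sample(rep_len(c(0L, 1L), ns))
    targets <- data.frame(subject_id = seq_len(ns),
                          target_cont = target_cont,
                          target_bin = target_bin,
                          null_cont = null_cont, null_bin = null_bin)
    structure(list(series = series, tr_seconds = spec$tr_seconds,
                   covariates = covariates, targets = targets,
                   truth = list(hurst = H, loadings = loadings,
                                beta_feat = spec$beta_feat,
                                beta_age = spec$beta_age,
                                beta_gender = spec$beta_gender,
                                beta_tiv = spec$beta_tiv,
                                tsnr_target = spec$tsnr_target),
                   spec = spec),
              class = "synthetic_cohort")
  })
}

#' Specify and generate a synthetic 4D voxel volume
#'
#' Each voxel's time series is its ROI's source signal plus iid Gaussian
#' noise; background voxels (label 0) carry pure noise and are excluded from
#' all downstream ROI statistics by the mask contract of [voxel_image()].
#'
#' @param grid_dims Three positive integers (x, y, z).
#' @param voxel_size_mm Three positive voxel edge lengths, mm.
#' @param labels 3D integer ROI label array (`0` = background); ids must be
#'   contiguous `1..K` with at least one voxel each.
#' @param n_timepoints,tr_seconds Temporal geometry.
#' @param source_signals Optional `K x n_timepoints` matrix of ROI source
#'   signals; default: independent unit-variance white noise per ROI.
#' @param voxel_noise_sd SD of the iid voxel noise (default 1).
#' @param seed RNG seed.
#' @return A [voxel_image()].
#' @export
generate_voxel_volume <- function(grid_dims, voxel_size_mm, labels,
                                  n_timepoints = 490L, tr_seconds = 0.735,
                                  source_signals = NULL, voxel_noise_sd = 1,
                                  seed = 1L) {
  stopifnot(length(grid_dims) == 3L, all(grid_dims >= 1),
            voxel_noise_sd >= 0)
  labels <- array(as.integer(labels), dim = grid_dims)
  if (!all(dim(labels) == grid_dims))
    stop("label volume shape must match grid_dims", call. = FALSE)
  ids <- sort(unique(labels[labels > 0]))
  if (length(ids) == 0L || !identical(ids, seq_along(ids)))
    stop("ROI label ids must be contiguous positive integers 1..K",
         call. = FALSE)
  nt <- as.integer(n_timepoints)
  with_seed(seed, {
    if (is.null(source_signals))
      source_signals <- matrix(stats::rnorm(length(ids) * nt),
                               length(ids), nt)
    if (!all(dim(source_signals) == c(length(ids), nt)))
      stop("source_signals must be K x n_timepoints", call. = FALSE)
    nvox <- prod(grid_dims)
    dat <- matrix(if (voxel_noise_sd > 0)
                    stats::rnorm(nvox * nt, sd = voxel_noise_sd)
                  else 0, nvox, nt)
    lab_flat <- as.vector(labels)
    for (id in ids) {
      vox <- which(lab_flat == id)
      dat[vox, ] <- dat[vox, , drop = FALSE] +
        matrix(source_signals[id, ], length(vox), nt, byrow = TRUE)
    }
    voxel_image(array(dat, c(grid_dims, nt)), voxel_size_mm, labels,
                tr_seconds)
  })
}
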