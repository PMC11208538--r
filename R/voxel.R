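# Voxel-level connectivity measures (GCOR, LCOR) and ROI parcellation.
# A voxel image is a light container: 4D data (x, y, z, t), voxel sizes in
# mm, an integer ROI label volume (0 = background) and the TR.

#' Construct a voxel image
#'
#' @param data 4D numeric array `(x, y, z, t)`.
#' @param voxel_size_mm Three positive voxel edge lengths, mm.
#' @param labels 3D integer ROI label array matching the spatial dimensions
#'   of `data`; 0 marks background voxels excluded from all statistics.
#' @param tr_seconds Repetition time, seconds.
#' @return Object of class `voxel_image`.
#' @export
voxel_image <- function(data, voxel_size_mm, labels, tr_seconds) {
  stopifnot(is.array(data), length(dim(data)) == 4L,
            length(voxel_size_mm) == 3L, all(voxel_size_mm > 0),
            is.array(labels), length(dim(labels)) == 3L,
            tr_seconds > 0)
  if (!all(dim(data)[1:3] == dim(labels)))
    stop("spatial dimensions of data and labels must match", call. = FALSE)
  if (any(labels < 0) || any(labels != round(labels)))
    stop("labels must be nonnegative integers", call. = FALSE)
  structure(list(data = data, voxel_size_mm = as.double(voxel_size_mm),
                 labels = array(as.integer(labels), dim(labels)),
                 tr_seconds = tr_seconds),
            class = "voxel_image")
}

# In-mask voxel series as rows of a matrix plus their grid coordinates.
mask_series <- function(img) {
  d <- dim(img$data)
  mask <- which(img$labels > 0)
  if (length(mask) < 2L)
    stop("need at least 2 in-mask voxels", call. = FALSE)
  flat <- matrix(img$data, prod(d[1:3]), d[4])
  v <- flat[mask, , drop = FALSE]
  idx <- arrayInd(mask, d[1:3])
  list(series = v, mask = mask, coords_mm = sweep(idx - 1, 2,
                                                  img$voxel_size_mm, `*`))
}

# Row-normalize to zero mean, unit Euclidean norm; rows with zero variance
# become NA rows (excluded downstream with a warning).
normalize_rows <- function(v) {
  v <- v - rowMeans(v)
  nrm <- sqrt(rowSums(v^2))
  bad <- nrm == 0
  nrm[bad] <- NA_real_
  list(v = v / nrm, bad = bad)
}

#' Global correlation (GCOR)
#'
#' For every in-mask voxel, the mean Pearson correlation with all other
#' in-mask voxels (self excluded by default). Computed from normalized
#' series so the cost is linear in voxel count per time point. Constant
#' voxels are excluded with a warning and returned as `NA`.
#'
#' @param img A [voxel_image()].
#' @param include_self If `TRUE`, the self-correlation (1) is included in
#'   the average, shifting every value by about `1/n_voxels`.
#' @return 3D array of GCOR values (`NA` outside the mask).
#' @export
gcor <- function(img, include_self = FALSE) {
  ms <- mask_series(img)
  nz <- normalize_rows(ms$series)
  if (any(nz$bad))
    warning(sum(nz$bad), " constant voxel(s) excluded from GCOR")
  v <- nz$v[!nz$bad, , drop = FALSE]
  keep <- ms$mask[!nz$bad]
  nv <- nrow(v)
  if (nv < 2L) stop("fewer than 2 usable voxels", call. = FALSE)
  s <- colSums(v)
  rowsum_corr <- as.vector(v %*% s) # sum_j corr(i, j), including self (=1)
  val <- if (include_self) rowsum_corr / nv else (rowsum_corr - 1) / (nv - 1)
  out <- array(NA_real_, dim(img$labels))
  out[keep] <- pmin(1, pmax(-1, val))
  out
}

#' Local correlation (LCOR)
#'
#' For every in-mask voxel, the Gaussian-kernel-weighted mean of its Pearson
#' correlations with neighboring in-mask voxels. The kernel has
#' `sigma = fwhm_mm / (2 sqrt(2 log 2))`, is truncated at `3 sigma`, excludes
#' the voxel itself, and the weights are renormalized over the neighbors
#' actually available (mask edges). Voxels with no in-mask neighbor within
#' `3 sigma` are returned as `NA` with a warning.
#'
#' @param img A [voxel_image()].
#' @param fwhm_mm Kernel full width at half maximum, mm (default 25).
#' @return 3D array of LCOR values (`NA` outside the mask or where
#'   undefined).
#' @export
lcor <- function(img, fwhm_mm = 25) {
  stopifnot(fwhm_mm > 0)
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2)))
  ms <- mask_series(img)
  nz <- normalize_rows(ms$series)
  if (any(nz$bad))
    warning(sum(nz$bad), " constant voxel(s) excluded from LCOR")
  keep_rows <- which(!nz$bad)
  v <- nz$v[keep_rows, , drop = FALSE]
  xyz <- ms$coords_mm[keep_rows, , drop = FALSE]
  nv <- nrow(v)
  cutoff2 <- (3 * sigma)^2
  cmat <- v %*% t(v) # pairwise correlations (small synthetic volumes)
  vals <- rep(NA_real_, nv)
  n_orphans <- 0L
  for (i in seq_len(nv)) {
    d2 <- colSums((t(xyz) - xyz[i, ])^2)
    nb <- which(d2 <= cutoff2)
    nb <- nb[nb != i]
    if (length(nb) == 0L) { n_orphans <- n_orphans + 1L; next }
    w <- exp(-d2[nb] / (2 * sigma^2))
    vals[i] <- sum(w * cmat[i, nb]) / sum(w)
  }
  if (n_orphans > 0L)
    warning(n_orphans, " voxel(s) have no in-mask neighbor within 3 sigma; ",
            "LCOR undefined there")
  out <- array(NA_real_, dim(img$labels))
  out[ms$mask[keep_rows]] <- pmin(1, pmax(-1, vals))
  out
}

#' Average a voxel map within ROIs
#'
#' Arithmetic mean of a voxel-wise map over the voxels of each ROI of the
#' label volume, ignoring undefined (`NA`) voxels. An ROI with no defined
#' voxel raises an error naming the ROI.
#'
#' @param voxel_map 3D numeric array (e.g. from [gcor()] or [lcor()]).
#' @param labels 3D integer ROI label array of the same shape.
#' @return Named numeric vector, one mean per ROI id (ascending).
#' @export
parcellate <- function(voxel_map, labels) {
  stopifnot(is.array(voxel_map), is.array(labels))
  if (!all(dim(voxel_map) == dim(labels)))
    stop("voxel map and labels must have the same shape", call. = FALSE)
  ids <- sort(unique(labels[labels > 0]))
  vals <- vapply(ids, function(id) {
    v <- voxel_map[labels == id]
    v <- v[is.finite(v)]
    if (length(v) == 0L)
      stop("ROI ", id, " has no defined voxels", call. = FALSE)
    mean(v)
  }, numeric(1))
  stats::setNames(vals, ids)
}

#' Apply a voxel-wise measure and parcellate in one step
#'
#' Convenience wrapper: computes fALFF, GCOR or LCOR voxel-wise on a
#' [voxel_image()] and averages within ROIs.
#'
#' @param img A [voxel_image()].
#' @param measure One of `"falff"`, `"gcor"`, `"lcor"`.
#' @param ... Passed to the underlying measure.
#' @return Named per-ROI vector (see [parcellate()]).
#' @export
voxel_feature_roi <- function(img, measure = c("falff", "gcor", "lcor"),
                              ...) {
  measure <- match.arg(measure)
  map <- switch(measure,
    gcor = gcor(img, ...),
    lcor = lcor(img, ...),
    falff = {
      d <- dim(img$data)
      flat <- matrix(img$data, prod(d[1:3]), d[4])
      out <- array(NA_real_, d[1:3])
      for (i in which(img$labels > 0))
        out[i] <- falff(flat[i, ], img$tr_seconds, ...)
      out
    })
  parcellate(map, img$labels)
}
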