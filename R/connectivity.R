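# Functional-connectivity features: Pearson connectome plus eigenvector
# centrality and weighted clustering coefficient at the ROI level; fALFF,
# local correlation (LCOR) and global correlation (GCOR) at the voxel level
# (see voxel.R) with ROI averaging.

#' Pearson functional-connectivity matrix
#'
#' Pairwise Pearson correlations between ROI-mean time series. Rows of
#' `series` are ROIs, columns time points.
#'
#' @param series Numeric matrix, `n_roi x n_timepoints` (at least 2 ROIs and
#'   3 time points; no constant ROI series).
#' @return Symmetric correlation matrix with unit diagonal; ROI row names
#'   are preserved.
#' @export
fc_matrix <- function(series) {
  stopifnot(is.matrix(series), nrow(series) >= 2L, ncol(series) >= 3L)
  sds <- apply(series, 1L, stats::sd)
  if (any(sds == 0)) {
    bad <- rownames(series)[sds == 0] %||% which(sds == 0)
    stop("degenerate input: constant ROI series: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  fc <- stats::cor(t(series))
  fc <- (fc + t(fc)) / 2
  diag(fc) <- 1
  fc
}

# Shared preprocessing for graph measures: negative correlations and the
# diagonal are zeroed so the matrix is nonnegative (Perron-Frobenius).
fc_graph_weights <- function(fc) {
  stopifnot(is.matrix(fc), nrow(fc) == ncol(fc))
  if (max(abs(fc - t(fc))) > 1e-10)
    stop("connectivity matrix must be symmetric", call. = FALSE)
  w <- fc
  w[w < 0] <- 0
  diag(w) <- 0
  w
}

#' Eigenvector centrality of the functional connectome
#'
#' Leading eigenvector of the preprocessed connectome (negative weights and
#' diagonal zeroed), sign-fixed to be nonnegative and scaled to unit
#' Euclidean norm. ROI `i`'s centrality is the `i`-th element.
#'
#' @param fc Symmetric connectivity matrix (e.g. from [fc_matrix()]).
#' @return Named numeric vector of centralities (unit Euclidean norm).
#' @export
eigenvector_centrality <- function(fc) {
  w <- fc_graph_weights(fc)
  if (all(w == 0))
    stop("degenerate input: connectome has no positive weights", call. = FALSE)
  e <- eigen(w, symmetric = TRUE)
  v <- e$vectors[, 1L]
  if (sum(v) < 0) v <- -v
  v[v < 0 & v > -1e-12] <- 0
  v <- v / sqrt(sum(v^2))
  stats::setNames(v, rownames(fc))
}

#' Weighted clustering coefficient (Onnela)
#'
#' Per-ROI triangle intensity of the preprocessed connectome: with weights
#' rescaled to `[0, 1]` by the global maximum, node `i`'s coefficient is the
#' sum of geometric-mean triangle intensities `(w_ij w_ih w_jh)^(1/3)` over
#' neighbor pairs, divided by the `k_i (k_i - 1)` ordered pairs possible at
#' its degree `k_i`. Nodes of degree below 2 get coefficient 0.
#'
#' @param fc Symmetric connectivity matrix.
#' @return Named numeric vector of clustering coefficients in `[0, 1]`.
#' @export
weighted_clustering_coefficient <- function(fc) {
  w <- fc_graph_weights(fc)
  mx <- max(w)
  if (mx == 0)
    stop("degenerate input: connectome has no positive weights", call. = FALSE)
  wh <- (w / mx)^(1 / 3)
  num <- diag(wh %*% wh %*% wh)
  k <- rowSums(w > 0)
  cc <- ifelse(k >= 2, num / (k * (k - 1)), 0)
  stats::setNames(cc, rownames(fc))
}

#' Fractional amplitude of low-frequency fluctuations (fALFF)
#'
#' Ratio of the amplitude-spectrum mass (square root of periodogram power,
#' single taper, DC excluded) inside `band_hz` to the mass over the full
#' range `(0, Nyquist]`. Invariant to amplitude scaling of the input and
#' bounded in `[0, 1]`.
#'
#' @param x Numeric time series (demeaned internally).
#' @param tr_seconds Sampling interval (repetition time), seconds.
#' @param band_hz Two-element band `(low, high)` in Hz, default
#'   `c(0.008, 0.09)`; must lie inside `(0, Nyquist]`.
#' @return fALFF in `[0, 1]`.
#' @export
falff <- function(x, tr_seconds, band_hz = c(0.008, 0.09)) {
  check_series(x, 8L)
  check_not_constant(x)
  stopifnot(tr_seconds > 0, length(band_hz) == 2L)
  nyq <- 1 / (2 * tr_seconds)
  if (band_hz[1] <= 0 || band_hz[2] <= band_hz[1] || band_hz[2] > nyq)
    stop("band must satisfy 0 < low < high <= Nyquist (", signif(nyq, 4),
         " Hz)", call. = FALSE)
  n <- length(x)
  amp <- Mod(stats::fft(x - mean(x)))[2:(floor(n / 2) + 1L)]
  freq <- seq_len(floor(n / 2)) / (n * tr_seconds)
  inband <- freq >= band_hz[1] & freq <= band_hz[2]
  sum(amp[inband]) / sum(amp)
}
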