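# Temporal-complexity features of a single (ROI-mean) BOLD time series:
# Hurst exponent by rescaled-range analysis, weighted permutation entropy,
# range entropy (type B) with its tolerance-domain AUC, and multiscale
# entropy with its scale-domain AUC.

#' Hurst exponent by rescaled-range (R/S) analysis
#'
#' Estimates the Hurst exponent as the slope of a least-squares fit of
#' `log(R/S)` against `log(window length)` over log-spaced window sizes from
#' `min_window` up to `n/2`. Each window is demeaned before taking the range
#' of its cumulative deviations; R/S is averaged over the non-overlapping
#' windows of each size. Values above 0.5 indicate long-range dependence,
#' below 0.5 anti-persistence, and about 0.5 a memoryless series. The plain
#' R/S estimator carries a small upward bias for white noise at moderate
#' lengths; it is reported as-is, matching common practice.
#'
#' @param x Numeric time series, length at least 64, not constant.
#' @param min_window Smallest window size (default 16).
#' @param n_window_sizes Number of log-spaced window sizes (at least 8).
#' @return Hurst exponent estimate (scalar).
#' @export
hurst_rs <- function(x, min_window = 16L, n_window_sizes = 10L) {
  check_series(x, 64L)
  check_not_constant(x)
  n <- length(x)
  n_window_sizes <- max(8L, as.integer(n_window_sizes))
  sizes <- unique(round(exp(seq(log(min_window), log(n / 2),
                                length.out = n_window_sizes))))
  rs <- vapply(sizes, function(w) {
    nb <- floor(n / w)
    vals <- vapply(seq_len(nb), function(b) {
      seg <- x[((b - 1) * w + 1):(b * w)]
      s <- stats::sd(seg)
      if (s == 0) return(NA_real_)
      z <- cumsum(seg - mean(seg))
      (max(z) - min(z)) / s
    }, numeric(1))
    mean(vals, na.rm = TRUE)
  }, numeric(1))
  ok <- is.finite(rs) & rs > 0
  if (sum(ok) < 3L)
    stop("degenerate input: too few usable windows for R/S fit", call. = FALSE)
  unname(coef(stats::lm(log(rs[ok]) ~ log(sizes[ok])))[2])
}

#' Weighted permutation entropy
#'
#' Ordinal patterns of length `m` at delay `tau` are extracted from the
#' series; each occurrence is weighted by the variance of its embedded
#' vector, and the Shannon entropy of the weight-normalized pattern
#' distribution is divided by `log2(m!)` so the result lies in `[0, 1]`.
#' Ordinal ties are broken by order of occurrence (stable ranking), and
#' zero-variance embedded vectors carry zero weight.
#'
#' @param x Numeric time series.
#' @param m Embedding dimension (default 4).
#' @param tau Time delay (default 1).
#' @param min_length Minimum accepted series length (default 32).
#' @return Normalized weighted permutation entropy in `[0, 1]`.
#' @export
weighted_permutation_entropy <- function(x, m = 4L, tau = 1L,
                                         min_length = 32L) {
  check_series(x, max(min_length, m * tau + 1L))
  stopifnot(m >= 2L, tau >= 1L)
  n <- length(x)
  nvec <- n - (m - 1L) * tau
  E <- vapply(seq_len(m), function(j) x[(j - 1L) * tau + seq_len(nvec)],
              numeric(nvec))
  # rank of column j within each row, ties broken by column order
  pat <- integer(nvec)
  ranks <- matrix(0L, nvec, m)
  for (j in seq_len(m)) {
    r <- rep.int(0L, nvec)
    for (k in seq_len(m)) {
      if (k == j) next
      if (k < j) r <- r + (E[, k] <= E[, j]) else r <- r + (E[, k] < E[, j])
    }
    ranks[, j] <- r
  }
  for (j in seq_len(m)) pat <- pat * m + ranks[, j]
  w <- apply(E, 1L, stats::var)
  tot <- sum(w)
  if (tot == 0)
    stop("degenerate input: all embedded vectors have zero variance",
         call. = FALSE)
  p <- vapply(split(w, pat), sum, numeric(1)) / tot
  p <- p[p > 0]
  -sum(p * log2(p)) / log2(factorial(m))
}

#' Sample entropy
#'
#' Computes `-ln(A/B)` where `B` counts template pairs (self-matches
#' excluded) within Chebyshev distance `r * sd(x)` at embedding length `m`
#' and `A` the same at length `m + 1`. The tolerance is expressed in units
#' of the series standard deviation; `sample_entropy_abs()` accepts an
#' absolute tolerance (used by multiscale entropy, which holds the
#' scale-1 tolerance fixed across scales). When no template pair matches at
#' either length the entropy is undefined and `NA` is returned rather than
#' an error, so callers can handle undefined points explicitly.
#'
#' @param x Numeric time series, not constant.
#' @param m Embedding dimension (default 2).
#' @param r Tolerance in SD units (default 0.5).
#' @param min_length Minimum accepted series length (default 32).
#' @return Sample entropy (nats), or `NA` if undefined.
#' @export
sample_entropy <- function(x, m = 2L, r = 0.5, min_length = 32L) {
  check_series(x, max(min_length, m + 2L))
  check_not_constant(x)
  stopifnot(r >= 0)
  sample_entropy_abs(x, m, r * stats::sd(x), min_length = min_length)
}

#' @rdname sample_entropy
#' @param r_abs Absolute tolerance (same units as `x`).
#' @export
sample_entropy_abs <- function(x, m = 2L, r_abs, min_length = 32L) {
  check_series(x, max(min_length, m + 2L))
  stopifnot(m >= 1L, r_abs >= 0)
  cnt <- .sampen_counts(as.double(x), as.integer(m), as.double(r_abs))
  if (cnt[1] == 0 || cnt[2] == 0) return(NA_real_)
  -log(cnt[2] / cnt[1])
}

#' Range entropy (type B)
#'
#' Sample-entropy counting with the Chebyshev distance replaced by the
#' normalized range distance
#' \deqn{d(x_i, x_j) = \frac{\max_k |x_{ik}-x_{jk}| - \min_k |x_{ik}-x_{jk}|}
#'                          {\max_k |x_{ik}-x_{jk}| + \min_k |x_{ik}-x_{jk}|},}
#' which lies in `[0, 1]` (identical templates, a 0/0 case, are assigned
#' distance 0). Because every pair matches at tolerance `r = 1`, the value
#' there is exactly 0 for any finite non-constant series, so the whole
#' `r`-trajectory is a bounded signature of the signal dynamics.
#'
#' @param x Numeric time series, not constant.
#' @param m Embedding dimension (default 2).
#' @param r Tolerance(s) in (0, 1]; `range_entropy_B()` takes a scalar,
#'   `range_entropy_B_trajectory()` a strictly increasing grid.
#' @param min_length Minimum accepted series length (default 32).
#' @return Entropy in nats (`NA` where undefined); the trajectory version
#'   returns a data frame with columns `r` and `entropy`.
#' @export
range_entropy_B <- function(x, m = 2L, r, min_length = 32L) {
  traj <- range_entropy_B_trajectory(x, m = m, r_grid = r,
                                     min_length = min_length)
  traj$entropy
}

#' @rdname range_entropy_B
#' @param r_grid Strictly increasing tolerance grid inside (0, 1].
#' @export
range_entropy_B_trajectory <- function(x, m = 2L,
                                       r_grid = seq(0.05, 1, by = 0.05),
                                       min_length = 32L) {
  check_series(x, max(min_length, m + 2L))
  check_not_constant(x)
  stopifnot(m >= 1L)
  if (any(r_grid <= 0) || any(r_grid > 1))
    stop("tolerance r must lie in (0, 1]", call. = FALSE)
  if (length(r_grid) > 1L && any(diff(r_grid) <= 0))
    stop("r_grid must be strictly increasing", call. = FALSE)
  cnt <- .rangeen_counts(as.double(x), as.integer(m), as.double(r_grid))
  ent <- ifelse(cnt[1, ] == 0 | cnt[2, ] == 0, NA_real_,
                -log(cnt[2, ] / cnt[1, ]) + 0) # + 0 normalizes IEEE -0
  data.frame(r = r_grid, entropy = ent)
}

#' Area under the range-entropy trajectory
#'
#' Trapezoidal area of the `RangeEn_B` trajectory along the tolerance axis.
#' Undefined points (zero match counts at small `r`) are dropped and the
#' area is renormalized to the full grid span, with a warning, so series of
#' different noisiness stay comparable.
#'
#' @inheritParams range_entropy_B_trajectory
#' @return Scalar AUC (`NA` if the whole trajectory is undefined).
#' @export
range_entropy_B_auc <- function(x, m = 2L, r_grid = seq(0.05, 1, by = 0.05),
                                min_length = 32L) {
  if (length(r_grid) < 10L)
    stop("r_grid must contain at least 10 points", call. = FALSE)
  traj <- range_entropy_B_trajectory(x, m = m, r_grid = r_grid,
                                     min_length = min_length)
  auc_with_gaps(traj$r, traj$entropy, span = diff(range(traj$r)))
}

# Trapezoidal AUC dropping undefined points with abscissa renormalization:
# the integral over the defined sub-span is rescaled to the nominal span.
auc_with_gaps <- function(a, y, span) {
  ok <- is.finite(y)
  if (sum(ok) < 2L) {
    warning("entropy trajectory undefined almost everywhere; AUC is NA")
    return(NA_real_)
  }
  if (!all(ok))
    warning(sum(!ok), " undefined point(s) dropped from entropy trajectory; ",
            "area renormalized to the full abscissa span")
  defined_span <- diff(range(a[ok]))
  if (defined_span == 0) return(NA_real_)
  trapz(a[ok], y[ok]) * span / defined_span
}

#' Coarse-grain a time series
#'
#' Averages non-overlapping consecutive windows of length `scale`; the
#' output has length `floor(n / scale)` and any remainder is dropped.
#'
#' @param x Numeric time series.
#' @param scale Positive integer window length, at most `length(x)/2`.
#' @return Coarse-grained numeric vector.
#' @export
coarse_grain <- function(x, scale) {
  check_series(x)
  stopifnot(scale >= 1L)
  scale <- as.integer(scale)
  if (scale == 1L) return(x)
  n <- length(x)
  if (scale > n / 2) stop("scale must not exceed length(x)/2", call. = FALSE)
  nb <- floor(n / scale)
  colMeans(matrix(x[seq_len(nb * scale)], nrow = scale))
}

#' Multiscale entropy and its scale-domain AUC
#'
#' Sample entropy of the coarse-grained series at scales `1..tau_max`, with
#' the tolerance held fixed at `r` times the standard deviation of the
#' original (scale-1) series — the standard multiscale convention.
#' `multiscale_entropy_auc()` returns the trapezoidal area of the scale
#' trajectory divided by `tau_max`; undefined scales are dropped with
#' abscissa renormalization and a warning.
#'
#' @param x Numeric time series, length at least `2 * tau_max * (m + 2)`.
#' @param m Embedding dimension (default 2).
#' @param r Tolerance in units of the scale-1 SD (default 0.5).
#' @param tau_max Largest scale (default 10).
#' @return `multiscale_entropy()`: data frame with columns `scale` and
#'   `entropy`; `multiscale_entropy_auc()`: scalar.
#' @export
multiscale_entropy <- function(x, m = 2L, r = 0.5, tau_max = 10L) {
  check_series(x, 2L * tau_max * (m + 2L))
  check_not_constant(x)
  stopifnot(tau_max >= 1L, r >= 0)
  r_abs <- r * stats::sd(x)
  ent <- vapply(seq_len(tau_max), function(s) {
    cg <- coarse_grain(x, s)
    if (stats::sd(cg) == 0) return(NA_real_)
    sample_entropy_abs(cg, m = m, r_abs = r_abs, min_length = m + 2L)
  }, numeric(1))
  data.frame(scale = seq_len(tau_max), entropy = ent)
}

#' @rdname multiscale_entropy
#' @export
multiscale_entropy_auc <- function(x, m = 2L, r = 0.5, tau_max = 10L) {
  traj <- multiscale_entropy(x, m = m, r = r, tau_max = tau_max)
  auc_with_gaps(traj$scale, traj$entropy, span = tau_max - 1) / tau_max
}
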