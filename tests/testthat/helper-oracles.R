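# Independent brute-force oracles used to validate the fast implementations.

# Sample entropy by direct O(n^2) template enumeration.
sampen_brute <- function(x, m, r_abs) {
  n <- length(x)
  nt <- n - m
  B <- 0; A <- 0
  for (i in seq_len(nt - 1)) {
    for (j in (i + 1):nt) {
      dm <- max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)]))
      if (dm <= r_abs) {
        B <- B + 1
        if (max(dm, abs(x[i + m] - x[j + m])) <= r_abs) A <- A + 1
      }
    }
  }
  if (B == 0 || A == 0) return(NA_real_)
  -log(A / B)
}

# Range entropy B by direct pair enumeration at a single tolerance.
rangeen_brute <- function(x, m, r) {
  n <- length(x)
  nt <- n - m
  rdist <- function(a, b) {
    d <- abs(a - b)
    if (max(d) + min(d) == 0) return(0)
    (max(d) - min(d)) / (max(d) + min(d))
  }
  B <- 0; A <- 0
  for (i in seq_len(nt - 1)) {
    for (j in (i + 1):nt) {
      if (rdist(x[i:(i + m - 1)], x[j:(j + m - 1)]) <= r) B <- B + 1
      if (rdist(x[i:(i + m)], x[j:(j + m)]) <= r) A <- A + 1
    }
  }
  if (B == 0 || A == 0) return(NA_real_)
  -log(A / B)
}

# Weighted permutation entropy by explicit pattern tabulation (stable ties).
wpe_brute <- function(x, m, tau) {
  nvec <- length(x) - (m - 1) * tau
  pats <- character(nvec)
  w <- numeric(nvec)
  for (i in seq_len(nvec)) {
    v <- x[i + (0:(m - 1)) * tau]
    pats[i] <- paste(order(v), collapse = "-") # order() is stable
    w[i] <- var(v)
  }
  p <- tapply(w, pats, sum) / sum(w)
  p <- p[p > 0]
  -sum(p * log2(p)) / log2(factorial(m))
}

# Onnela weighted clustering coefficient by O(n^3) triangle enumeration.
wcc_brute <- function(w) {
  w[w < 0] <- 0
  diag(w) <- 0
  wh <- w / max(w)
  n <- nrow(w)
  cc <- numeric(n)
  for (i in seq_len(n)) {
    k <- sum(w[i, ] > 0)
    if (k < 2) next
    s <- 0
    for (j in seq_len(n)) for (h in seq_len(n))
      if (j != i && h != i && j != h)
        s <- s + (wh[i, j] * wh[i, h] * wh[j, h])^(1 / 3)
    cc[i] <- s / (k * (k - 1))
  }
  cc
}

# Leading eigenvector by power iteration (independent of eigen()).
ec_power_oracle <- function(w, iters = 5000) {
  w[w < 0] <- 0
  diag(w) <- 0
  v <- rep(1, nrow(w))
  for (i in seq_len(iters)) {
    v2 <- as.vector(w %*% v)
    v <- v2 / sqrt(sum(v2^2))
  }
  v
}

# ROI series matrix with prescribed structure for small fixtures.
toy_series <- function(n_roi, n_t, seed = 1) {
  set.seed(seed)
  matrix(rnorm(n_roi * n_t), n_roi, n_t)
}
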