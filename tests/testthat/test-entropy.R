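# Weighted permutation entropy, sample entropy, range entropy and
# multiscale entropy, each checked against brute-force oracles and
# analytic limits.

test_that("weighted permutation entropy handles canonical signals", {
  # a monotone ramp realizes a single ordinal pattern: zero entropy
  expect_equal(weighted_permutation_entropy(1:200), 0)
  # iid noise approaches the equiprobable-pattern maximum of 1
  set.seed(1)
  expect_gte(weighted_permutation_entropy(runif(1e5)), 0.97)
  # bounded in [0, 1]
  for (s in 1:5) {
    set.seed(s)
    v <- weighted_permutation_entropy(rnorm(200))
    expect_gte(v, 0)
    expect_lte(v, 1)
  }
})

test_that("weighted permutation entropy equals brute-force enumeration", {
  # period-2 alternation visits exactly 2 ordinal patterns
  x <- as.numeric(rbind(seq(2, 64, 2), seq(1, 63, 2)))[1:64]
  expect_equal(weighted_permutation_entropy(x, m = 4, tau = 1),
               wpe_brute(x, 4, 1))
  set.seed(7)
  for (y in list(rnorm(120), cumsum(rnorm(90)), sin(1:150 / 5) + rnorm(150,
                                                                  sd = .1)))
    expect_equal(weighted_permutation_entropy(y, m = 4, tau = 1,
                                              min_length = 16),
                 wpe_brute(y, 4, 1), tolerance = 1e-12)
})

test_that("wPE is invariant to increasing affine transforms", {
  set.seed(2)
  x <- rnorm(300)
  expect_equal(weighted_permutation_entropy(3.7 * x + 11),
               weighted_permutation_entropy(x), tolerance = 1e-9)
})

test_that("sample entropy equals brute-force pair counting", {
  set.seed(3)
  for (m in c(2L, 3L)) {
    for (n in c(120, 300)) {
      x <- rnorm(n)
      r_abs <- 0.5 * sd(x)
      expect_equal(sample_entropy(x, m = m, r = 0.5),
                   sampen_brute(x, m, r_abs), tolerance = 1e-12)
    }
  }
})

test_that("sample entropy of iid Gaussian matches the analytic value", {
  # for m where template matches decorrelate, SampEn -> -ln P(|X-Y|<=r sd),
  # X - Y ~ N(0, 2 sd^2): -ln(0.2763) = 1.286 at r = 0.5
  set.seed(4)
  est <- mean(vapply(1:3, function(s) {
    set.seed(s)
    sample_entropy(rnorm(30000), m = 2, r = 0.5)
  }, numeric(1)))
  analytic <- -log(2 * pnorm(0.5 / sqrt(2)) - 1)
  expect_lt(abs(est - analytic), 0.05)
  expect_equal(analytic, 1.286, tolerance = 1e-3)
})

test_that("sample entropy orders regular vs irregular signals", {
  set.seed(5)
  sine <- sin(2 * pi * (1:2000) / 50)
  noise <- rnorm(2000)
  expect_lt(sample_entropy(sine, 2, 0.5), sample_entropy(noise, 2, 0.5))
  # sinusoid value agrees with the brute-force oracle too
  expect_equal(sample_entropy(sine, 2, 0.5),
               sampen_brute(sine, 2, 0.5 * sd(sine)), tolerance = 1e-12)
})

test_that("sample entropy degenerate and undefined cases", {
  expect_error(sample_entropy(rep(2, 100)), "degenerate")
  # tolerance so small that no templates match: undefined marker, not error
  set.seed(6)
  expect_true(is.na(sample_entropy_abs(rnorm(40), m = 2, r_abs = 1e-12,
                                       min_length = 8)))
})

test_that("sample entropy is invariant to positive affine transforms", {
  set.seed(7)
  x <- rnorm(400)
  expect_equal(sample_entropy(2.5 * x - 3, 2, 0.5),
               sample_entropy(x, 2, 0.5), tolerance = 1e-12)
})

test_that("range entropy B is exactly 0 at tolerance r = 1", {
  set.seed(8)
  for (x in list(rnorm(490), runif(100), sin(1:200 / 7) + rnorm(200, sd = 2)))
    expect_identical(range_entropy_B(x, m = 2, r = 1), 0)
})

test_that("range entropy B equals brute-force enumeration", {
  set.seed(9)
  x <- rnorm(200)
  for (r in c(0.2, 0.5, 0.8, 1.0))
    expect_equal(range_entropy_B(x, m = 2, r = r), rangeen_brute(x, 2, r),
                 tolerance = 1e-12)
})

test_that("range entropy B decreases with tolerance and validates r", {
  set.seed(10)
  x <- rnorm(2000)
  expect_gt(range_entropy_B(x, 2, 0.2), range_entropy_B(x, 2, 0.8))
  traj <- range_entropy_B_trajectory(x)
  d <- diff(traj$entropy[is.finite(traj$entropy)])
  expect_true(all(d <= 1e-9)) # non-increasing trajectory
  expect_error(range_entropy_B(x, 2, 0), "\\(0, 1\\]")
  expect_error(range_entropy_B(x, 2, 1.2), "\\(0, 1\\]")
  expect_error(range_entropy_B(rep(1, 100), 2, 0.5), "degenerate")
})

test_that("range entropy AUC is stable under grid refinement", {
  set.seed(11)
  x <- rnorm(2000)
  a51 <- range_entropy_B_auc(x, r_grid = seq(0.02, 1, length.out = 51))
  a501 <- range_entropy_B_auc(x, r_grid = seq(0.02, 1, length.out = 501))
  expect_lt(abs(a51 - a501) / a501, 0.02)
  expect_error(range_entropy_B_auc(x, r_grid = c(0.5, 1)), "10 points")
})

test_that("coarse graining averages non-overlapping windows", {
  expect_identical(coarse_grain(c(1, 2, 3, 4, 5, 6), 2), c(1.5, 3.5, 5.5))
  expect_identical(coarse_grain(c(1, 2, 3, 4, 5), 2), c(1.5, 3.5))
  x <- rnorm(100)
  expect_identical(coarse_grain(x, 1), x)
  expect_error(coarse_grain(rnorm(10), 6), "scale")
})

test_that("multiscale entropy declines with scale for white noise", {
  # coarse-graining shrinks white-noise variance while r stays fixed at the
  # scale-1 SD, so matches get easier and entropy falls
  slopes <- vapply(1:20, function(s) {
    set.seed(s)
    traj <- multiscale_entropy(rnorm(2048))$entropy
    mean(diff(traj))
  }, numeric(1))
  expect_lt(mean(slopes), 0)
  expect_gt(mean(slopes < 0), 0.9)
})

test_that("persistent fGn keeps more entropy than white noise at deep scales", {
  deep <- function(h, s) {
    x <- if (h == 0.5) with_seed_rnorm(s, 4096) else
      generate_fgn(4096, h, seed = s)
    mean(multiscale_entropy(x)$entropy[5:10])
  }
  with_seed_rnorm <- function(s, n) { set.seed(s); rnorm(n) }
  wn <- mean(vapply(1:8, function(s) deep(0.5, s), numeric(1)))
  fg <- mean(vapply(1:8, function(s) deep(0.9, s), numeric(1)))
  expect_gt(fg, wn)
})

test_that("MSE AUC reduces to the trapezoid arithmetic", {
  # constant trajectory at c integrates to c*(tau_max-1)/tau_max
  expect_equal(complexconn:::auc_with_gaps(1:10, rep(2, 10), span = 9) / 10,
               2 * 9 / 10)
  # dropped undefined points renormalize the abscissa
  expect_warning(
    a <- complexconn:::auc_with_gaps(1:10, c(NA, rep(2, 9)), span = 9) / 10,
    "renormalized")
  expect_equal(a, 2 * 9 / 10)
})

test_that("MSE AUC is computable at the design length of 490 points", {
  x <- generate_fgn(490, 0.7, seed = 12)
  a <- multiscale_entropy_auc(x)
  expect_true(is.finite(a))
  expect_gt(a, 0)
})
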