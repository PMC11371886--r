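test_that("PRSA capacities match direct anchor evaluation and hand cases", {
  # strictly alternating series: symmetric cancellation, dc = 0
  alt <- rep(c(800, 810), 50)
  expect_equal(prsa_capacity(nn_of(alt), "deceleration")$capacity, 0,
               tolerance = 1e-12)

  # linear ramp +2 ms/beat: dc exactly 2, no acceleration anchors
  ramp <- 800 + 2 * (0:199)
  pr <- prsa_capacity(nn_of(ramp), "deceleration")
  expect_equal(pr$capacity, 2)
  expect_gt(pr$profile$anchor_count, 100)
  ac <- prsa_capacity(nn_of(ramp), "acceleration")
  expect_true(is.na(ac$capacity))
  expect_match(attr(ac$capacity, "reason"), "anchor")

  # descending ramp: mirror case
  down <- 1000 - 2 * (0:199)
  expect_equal(prsa_capacity(nn_of(down), "acceleration")$capacity, -2)

  # oracle agreement on noisy series
  set.seed(21)
  x <- 800 + cumsum(rnorm(400, 0, 6))
  for (dir in c("deceleration", "acceleration"))
    expect_equal(prsa_capacity(nn_of(x), dir)$capacity,
                 oracle_prsa(x, dir), tolerance = 1e-10)
})

test_that("PRSA is offset invariant and scale equivariant", {
  set.seed(22)
  x <- 900 + cumsum(rnorm(300, 0, 5))
  dc0 <- prsa_capacity(nn_of(x), "deceleration")$capacity
  # adding a constant: anchor set may only change via the relative-change
  # filter; use a generous offset-compatible filter to isolate the effect
  p <- nonlinear_params(prsa_max_rel_change = 0.5)
  dc1 <- prsa_capacity(nn_of(x), "deceleration", p)$capacity
  dc2 <- prsa_capacity(nn_of(x + 400), "deceleration", p)$capacity
  expect_equal(dc1, dc2, tolerance = 1e-9)
  dc3 <- prsa_capacity(nn_of(1.5 * x), "deceleration", p)$capacity
  expect_equal(dc3, 1.5 * dc1, tolerance = 1e-9)
})

test_that("time lag follows the autocorrelation decay", {
  set.seed(31)
  expect_equal(time_lag(rnorm(1e4)), 1L)
  set.seed(32)
  ar <- as.numeric(arima.sim(list(ar = 0.9), 1e5))
  expect_true(abs(time_lag(ar) - 10L) <= 1)  # first k with 0.9^k < 1/e
  expect_error(time_lag(rep(5, 1000)), "zero-variance")
})

test_that("time lag grows with serial correlation (monotone property)", {
  lags <- vapply(c(0.5, 0.8, 0.95), function(a) {
    set.seed(33)
    time_lag(as.numeric(arima.sim(list(ar = a), 1e5)))
  }, numeric(1))
  expect_true(all(diff(lags) >= 0))
})

test_that("Cao's method finds low dimensions for deterministic systems", {
  h <- gen_chaotic_series("henon", n = 5000)
  d <- embedding_dimension(h, lag = 1)
  expect_true(d %in% 2:3)
  expect_gte(attr(d, "E1")[d], 0.95)

  set.seed(41)
  d_noise <- embedding_dimension(rnorm(3000), lag = 1,
                                 p = nonlinear_params(max_dim = 8))
  expect_true(isTRUE(attr(d_noise, "saturated")) || d_noise >= 6)

  # non-commensurate sampling avoids exactly duplicated points, which make
  # nearest-neighbour distance ratios degenerate
  tt <- seq(0, 400, by = 0.5001)
  s <- sin(2 * pi * 0.05 * tt)
  d_sine <- embedding_dimension(s, lag = 10)
  expect_lte(as.integer(d_sine), 2)
})

test_that("correlation dimension recovers analytic dimensions", {
  xs <- gen_chaotic_series("logistic", list(r = 4), 1e4, 0.2)
  d2 <- correlation_dimension(xs, m = 2, lag = 1)
  expect_gte(d2, 0.85)
  expect_lte(d2, 1.15)

  # points uniform on a line segment embedded in 3 dims
  set.seed(51)
  seg <- sort(runif(2000))
  d_line <- correlation_dimension(seg, m = 3, lag = 1)
  expect_equal(as.numeric(d_line), 1, tolerance = 0.1)

  # identical repeated point: C(r) = 1 for all r, slope 0
  d0 <- correlation_dimension(rep(1, 500), m = 2, lag = 1,
                              radii = c(0.1, 1, 10))
  expect_true(is.na(d0) || d0 == 0)
})

test_that("correlation sums equal the naive O(n^2) oracle", {
  set.seed(52)
  x <- rnorm(400)
  radii <- sort(exp(seq(log(0.05), log(2), length.out = 8)))
  C <- hrvcohort:::cpp_corr_sums(x, 3L, 2L, radii, 5L)
  Co <- oracle_corr_sums(x, 3, 2, radii, 5)
  expect_lt(max(abs(C - Co)), 1e-12)
})

test_that("sample entropy matches brute force and behaves with r and m", {
  expect_equal(sample_entropy(rep(c(1, 2), 500)), 0, tolerance = 1e-12)

  set.seed(61)
  x <- runif(200)
  p <- nonlinear_params()
  se <- sample_entropy(x, p)
  cnt <- oracle_sampen_counts(x, p$sampen_m, p$sampen_r_frac * sd(x))
  expect_equal(se, -log(cnt["A"] / cnt["B"]), ignore_attr = TRUE,
               tolerance = 1e-12)

  # monotone ramp with a tiny tolerance exercises the A = 0 missing path
  ramp <- seq(0, 100, length.out = 60)
  se_na <- sample_entropy(ramp, nonlinear_params(sampen_r_frac = 0.001))
  expect_true(is.na(se_na))
  expect_match(attr(se_na, "reason"), "template")

  # entropy decreases as the tolerance r grows
  set.seed(62)
  y <- rnorm(500)
  se_small <- sample_entropy(y, nonlinear_params(sampen_r_frac = 0.1))
  se_large <- sample_entropy(y, nonlinear_params(sampen_r_frac = 0.3))
  expect_gt(se_small, se_large)

  expect_error(sample_entropy(rep(3, 100)), "zero-variance")
})

test_that("Lyapunov estimator recovers analytic exponents", {
  xs <- gen_chaotic_series("logistic", list(r = 4), 1e4, 0.2)
  ly <- max_lyapunov(xs, m = 1, lag = 1)
  expect_equal(as.numeric(ly), log(2), tolerance = 0.07 / log(2))

  tt <- seq(0, 2500, by = 0.5)
  s <- 10 * sin(2 * pi * 0.05 * tt)
  ly_per <- max_lyapunov(s, m = 2, lag = 5)
  expect_lte(as.numeric(ly_per), 0.02)

  set.seed(71)
  noise <- 1000 * rnorm(1500)
  ly_na <- max_lyapunov(noise, m = 3, lag = 1,
                        p = nonlinear_params(lyap_radius = 1e-6))
  expect_true(is.na(ly_na))
  expect_match(attr(ly_na, "reason"), "neighbour")
})
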