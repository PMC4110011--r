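test_that("incremental updates reproduce two-pass sample moments", {
  s <- stats_update(sufficient_stats(), 1)
  expect_equal(unclass(s)[c("n", "sum_r", "sum_r2")],
               list(n = 1, sum_r = 1, sum_r2 = 1))

  expect_equal(q_value(stats_from(c(0, 1, 1, 0))), 0.5)
  expect_equal(q_value(sufficient_stats(4, 2, 0)), 0.5)
  expect_equal(q_value(sufficient_stats(1, 0.3, 0.09)), 0.3)

  set.seed(11)
  x <- runif(1000)
  s <- stats_from(x)
  expect_equal(q_value(s), mean(x), tolerance = 1e-12)

  set.seed(12)
  y <- pmax(pmin(rnorm(1e4), 5), -5)
  sy <- stats_from(y)
  expect_equal(q_value(sy), mean(y), tolerance = 1e-9)
  expect_equal(sample_std(sy), sd(y), tolerance = 1e-9)
})

test_that("sample_std matches the closed form and degenerate cases", {
  expect_equal(sample_std(sufficient_stats(4, 2, 1.2)), sqrt(0.2 / 3),
               tolerance = 1e-12)
  expect_equal(sample_std(stats_from(rep(0.7, 50))), 0)
  # cancellation guard: radicand a hair below zero clamps to zero
  expect_equal(sample_std(sufficient_stats(3, 0.3, 0.03 - 1e-17)), 0)
  expect_error(sample_std(sufficient_stats(1, 1, 1)), "n < 2")
  expect_error(q_value(sufficient_stats()), "empty")
})

test_that("rewards outside the declared support are rejected", {
  expect_error(stats_update(sufficient_stats(), 1.2), "outside")
  expect_error(stats_update(sufficient_stats(), -0.1), "outside")
  expect_silent(stats_update(sufficient_stats(), 1.2, reward_range(0, 2)))
  expect_error(reward_range(1, 1), "strictly below")
})

test_that("Student-t interval matches the closed form and cold-start rule", {
  ci <- ci_student(sufficient_stats(4, 2, 1.2), 0.05)
  hw <- qt(0.975, 3) * sqrt(0.2 / 3) / 2
  expect_equal(ci$lower, 0.5 - hw, tolerance = 1e-12)
  expect_equal(ci$upper, 0.5 + hw, tolerance = 1e-12)
  expect_equal(round(c(ci$lower, ci$upper), 3), c(0.089, 0.911))

  degen <- ci_student(stats_from(rep(0.25, 10)), 0.05)
  expect_equal(c(degen$lower, degen$upper), c(0.25, 0.25))
  # non-dyadic constant rewards collapse to the mean up to float dust
  d4 <- ci_student(stats_from(rep(0.4, 10)), 0.05)
  expect_equal(c(d4$lower, d4$upper), c(0.4, 0.4), tolerance = 1e-6)

  cold <- ci_student(sufficient_stats(1, 0.5, 0.25), 0.05)
  expect_equal(c(cold$lower, cold$upper), c(-Inf, Inf))
  expect_error(ci_student(sufficient_stats(4, 2, 1.2), 1.5), "alpha")
})

test_that("Chebyshev interval uses the worst-case variance on the support", {
  ci <- ci_chebyshev(sufficient_stats(25, 12.5, 6.25), 0.04, reward_range(0, 1))
  expect_equal(c(ci$lower, ci$upper), c(0, 1))
  # half-width shrinks like 1/sqrt(n)
  big <- ci_chebyshev(sufficient_stats(1e8, 5e7, 2.5e7), 0.04)
  expect_lt(ci_length(big), 1e-3)
  expect_equal(ci_length(ci_chebyshev(sufficient_stats())), Inf)
})

test_that("Bernstein interval is variance-aware", {
  s0 <- binary_cell(100, 0)        # constant rewards, s = 0
  ci <- ci_bernstein(sufficient_stats(100, 50, 25), 0.05)  # s = 0 too
  expect_equal(ci_length(ci) / 2, 3 * log(60) / 100, tolerance = 1e-12)
  # wider when the estimated SD is larger, everything else equal
  half <- sufficient_stats(100, 50, 50)                    # s = 0.5ish
  expect_lt(ci_length(ci), ci_length(ci_bernstein(half, 0.05)))
  expect_equal(ci_length(ci_bernstein(sufficient_stats(1, 1, 1), 0.05)), Inf)
  expect_equal(ci_length(ci_bernstein(s0, 0.05)),
               2 * 3 * log(60) / 100, tolerance = 1e-12)
})

test_that("interval length is non-increasing in n at fixed spread", {
  for (bound in c("student_t", "chebyshev", "bernstein")) {
    prev <- Inf
    for (n in c(2, 3, 5, 10, 30, 100, 1000, 10000)) {
      # mean 0.5, sample SD held at ~0.2 via matched sufficient stats
      s2 <- 0.2^2 * (n - 1) + n * 0.25
      len <- ci_length(ci_bound(sufficient_stats(n, 0.5 * n, s2), bound, 0.05))
      expect_lte(len, prev + 1e-12)
      prev <- len
    }
  }
})

test_that("finite intervals always bracket the cell mean", {
  set.seed(21)
  for (i in 1:50) {
    x <- runif(sample(2:40, 1))
    s <- stats_from(x)
    for (bound in c("student_t", "chebyshev", "bernstein")) {
      ci <- ci_bound(s, bound, runif(1, 0.01, 0.5))
      expect_lte(ci$lower, q_value(s))
      expect_gte(ci$upper, q_value(s))
    }
  }
})

test_that("empirical coverage: t-interval nominal, distribution-free bounds conservative", {
  set.seed(31)
  alpha <- 0.05
  reps <- 1e4
  n <- 30
  x <- matrix(rnorm(n * reps, mean = 0.5, sd = 0.15), nrow = n)
  m <- colMeans(x)
  sdv <- sqrt(colSums((x - rep(m, each = n))^2) / (n - 1))
  hw_t <- qt(1 - alpha / 2, n - 1) * sdv / sqrt(n)
  cover_t <- mean(abs(m - 0.5) <= hw_t)
  expect_lt(abs(cover_t - (1 - alpha)), 0.02)

  # same replicates pushed through the package constructors on a support
  # wide enough for the truncation to be irrelevant
  rng <- reward_range(-1, 2)
  hw_c <- (rng$hi - rng$lo) / (2 * sqrt(n * alpha))
  expect_gte(mean(abs(m - 0.5) <= hw_c), 1 - alpha)
  lg <- log(3 / alpha)
  hw_b <- sdv * sqrt(2 * lg / n) + 3 * (rng$hi - rng$lo) * lg / n
  expect_gte(mean(abs(m - 0.5) <= hw_b), 1 - alpha)

  # spot-check that the vectorized oracle above matches the constructors
  s7 <- stats_from(x[, 7], rng)
  ci7 <- ci_student(s7, alpha)
  expect_equal(ci7$upper - ci7$lower, 2 * hw_t[7], tolerance = 1e-9)
  cb7 <- ci_bernstein(s7, alpha, rng)
  expect_equal(cb7$upper - cb7$lower, 2 * hw_b[7], tolerance = 1e-9)
})
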