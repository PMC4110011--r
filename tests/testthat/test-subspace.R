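test_that("source enumeration yields singletons or all proper subsets", {
  expect_identical(enumerate_sources(3), list(1L, 2L, 3L))
  expect_identical(enumerate_sources(2, powerset = TRUE), list(1L, 2L))
  ps3 <- enumerate_sources(3, powerset = TRUE)
  expect_length(ps3, 6)  # 2^3 - 2 non-empty proper subsets
  expect_identical(ps3, list(1L, 2L, 3L, c(1L, 2L), c(1L, 3L), c(2L, 3L)))
  expect_length(enumerate_sources(4, powerset = TRUE), 14)
  # a lone sensor's space is the joint space itself, never a source
  expect_identical(enumerate_sources(1), list())
  expect_error(enumerate_sources(0), "positive")
})

test_that("projection picks the source's readings in ascending index order", {
  st <- c(7L, 12L, 3L)
  expect_identical(project(st, 2), 12L)
  expect_identical(project(st, c(1, 3)), c(7L, 3L))
  expect_identical(project(st, c(3, 1)), c(7L, 3L))
  expect_identical(project(st, 1:3), st)
})

test_that("recording an experience touches the joint cell and every marginal once", {
  tab <- stat_tables(3, 4, 2, powerset = TRUE)
  record_experience(tab, c(1L, 2L, 3L), 2L, 0.5)
  expect_equal(cell_stats(tab, c(1, 2, 3), 2)$n, 1)
  for (src in tab$sources) {
    m <- cell_stats(tab, project(c(1L, 2L, 3L), src), 2, source = src)
    expect_equal(m$n, 1)
    expect_equal(m$sum_r, 0.5)
  }
  # an untouched projection stays empty
  expect_equal(cell_stats(tab, c(2L, 2L), 2, source = c(1, 2))$n, 0)
  expect_error(record_experience(tab, c(1L, 2L, 3L), 2L, 1.5), "outside")
})

test_that("two aliased states pool their counts in the shared marginal", {
  tab <- stat_tables(2, 5, 3)
  for (i in 1:2) record_experience(tab, c(1L, 2L), 1L, 1)
  for (i in 1:3) record_experience(tab, c(1L, 4L), 1L, 0)
  m <- cell_stats(tab, 1L, 1, source = 1)
  expect_equal(m$n, 5)
  expect_equal(m$sum_r, 2)
})

test_that("incremental marginals equal brute-force marginalization of the joint table", {
  log <- random_log(1000, k = 3, n_pos = 4, n_actions = 3, seed = 5)
  tab <- tables_from_log(3, 4, 3, log, powerset = TRUE)
  for (src in tab$sources) {
    key <- log[, src, drop = FALSE]
    for (a in 1:3) {
      sub <- log[log$action == a, , drop = FALSE]
      agg <- aggregate(cbind(n = 1, s = sub$r, s2 = sub$r^2),
                       by = sub[, src, drop = FALSE], FUN = sum)
      for (i in seq_len(nrow(agg))) {
        obs <- as.integer(agg[i, seq_along(src)])
        m <- cell_stats(tab, obs, a, source = src)
        expect_identical(m$n, as.numeric(agg$n[i]))
        expect_equal(m$sum_r, agg$s[i], tolerance = 1e-9)
        expect_equal(m$sum_r2, agg$s2[i], tolerance = 1e-9)
      }
    }
  }
})

test_that("residual extraction is the exact complement of the joint cell", {
  r <- residual_stats(sufficient_stats(5, 3.0, 2.2), sufficient_stats(3, 2.0, 1.5))
  expect_equal(unclass(r)[c("n", "sum_r", "sum_r2")],
               list(n = 2, sum_r = 1.0, sum_r2 = 0.7))
  expect_equal(q_value(r), 0.5)

  same <- residual_stats(sufficient_stats(3, 2, 1.5), sufficient_stats(3, 2, 1.5))
  expect_equal(same$n, 0)
  expect_equal(same$sum_r, 0)

  expect_error(residual_stats(sufficient_stats(2, 1, 1), sufficient_stats(3, 2, 1.5)),
               "inconsistent")

  # additivity over a random run: residual + joint = marginal, every cell
  log <- random_log(400, k = 2, n_pos = 3, n_actions = 2, seed = 9)
  tab <- tables_from_log(2, 3, 2, log)
  for (i in seq_len(50)) {
    st <- as.integer(log[i, 1:2]); a <- log$action[i]
    for (src in tab$sources) {
      joint <- cell_stats(tab, st, a)
      marg <- cell_stats(tab, project(st, src), a, source = src)
      res <- residual_stats(marg, joint)
      expect_equal(res$n + joint$n, marg$n)
      expect_equal(res$sum_r + joint$sum_r, marg$sum_r, tolerance = 1e-9)
      expect_equal(res$sum_r2 + joint$sum_r2, marg$sum_r2, tolerance = 1e-9)
    }
  }
})

test_that("interval intersection is closed and sentinel-aware", {
  ci <- function(l, u) conf_int(l, u)
  expect_true(intervals_intersect(ci(0.1, 0.4), ci(0.3, 0.8)))
  expect_false(intervals_intersect(ci(0.0, 0.2), ci(0.5, 0.9)))
  expect_true(intervals_intersect(ci(0, 0.5), ci(0.5, 1)))   # touching ends
  expect_true(intervals_intersect(ci(-Inf, Inf), ci(0.99, 0.99)))
  expect_true(intervals_intersect(ci(-Inf, 0.1), ci(0.1, Inf)))
})

test_that("generalization test accepts under-sampled sources unconditionally", {
  tab <- stat_tables(2, 5, 2)
  record_experience(tab, c(2L, 3L), 1L, 1)
  gt <- g_test(tab, c(2L, 3L), 1, 1)
  expect_true(gt$accept)
  expect_equal(ci_length(gt$residual_ci), Inf)
})

test_that("generalization test rejects garbage aliasing in the two-state toy", {
  # two joint states share the first sensor's observation but have opposite
  # deterministic rewards for the same action: the classic harmful aliasing
  reject_at <- function(n_per_cell) {
    tab <- stat_tables(2, 3, 2)
    for (i in seq_len(n_per_cell)) {
      record_experience(tab, c(1L, 1L), 1L, 1)   # rewarding state
      record_experience(tab, c(1L, 2L), 1L, 0)   # punished state
    }
    !g_test(tab, c(1L, 1L), 1, 1, "student_t", 0.05)$accept
  }
  expect_false(reject_at(1))    # cold start must pass
  expect_true(reject_at(150))   # rejection certain once intervals separate
  expect_true(reject_at(500))
})

test_that("generalizing aliasing keeps passing the test at matched means", {
  # residual and joint cells drawn from the same Bernoulli(0.5) reward law;
  # acceptance should hold in the vast majority of replicates
  set.seed(77)
  n <- 1000
  acc <- vapply(1:200, function(i) {
    joint <- binary_cell(n, rbinom(1, n, 0.5))
    marg_extra <- rbinom(1, n, 0.5)
    marg <- binary_cell(2 * n, joint$sum_r + marg_extra)
    intervals_intersect(ci_student(residual_stats(marg, joint), 0.05),
                        ci_student(joint, 0.05))
  }, logical(1))
  expect_gte(mean(acc), 0.9)
})

test_that("tables serialize to a flat cell dump", {
  log <- random_log(50, k = 2, n_pos = 3, n_actions = 2, seed = 3)
  tab <- tables_from_log(2, 3, 2, log)
  df <- tables_to_df(tab)
  expect_true(all(c("source", "obs", "action", "n", "sum_r", "sum_r2") %in% names(df)))
  expect_equal(sum(df$n[df$source == "joint"]), 50)
  for (j in seq_along(tab$sources)) {
    expect_equal(sum(df$n[df$source == as.character(j)]), 50)
  }
  # joint rows reconstruct their cells exactly
  jr <- df[df$source == "joint", ][1, ]
  obs <- as.integer(strsplit(jr$obs, ":")[[1]])
  cs <- cell_stats(tab, obs, jr$action)
  expect_equal(cs$n, jr$n)
  expect_equal(cs$sum_r, jr$sum_r)
})
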