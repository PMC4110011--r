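test_that("a fresh agent is maximally optimistic: every source passes, any action can win", {
  tab <- stat_tables(2, 6, 6)
  cfg <- agent_config("mos")
  dec <- select_action(tab, c(2L, 5L), cfg, u = 0.37)
  expect_true(all(dec$accept))
  expect_true(all(dec$values == Inf))
  expect_equal(dec$action, floor(0.37 * 6) + 1)   # uniform tie-break
})

test_that("a single-sensor interval agent reduces to the joint-interval policy", {
  env <- env_config(sensors = list(sensor_gaussian(1, "visual")))
  st <- make_streams(env, 400, 5)
  mos <- run_lifetime(env, agent_config("mos"), streams = st)
  lus <- run_lifetime(env, agent_config("lus"), streams = st)
  expect_length(mos$sources, 0)
  expect_identical(mos$records$action, lus$records$action)   # same joint rule
  expect_true(all(mos$records$dominant == "joint"))
})

test_that("the interval policy solves a deterministic two-action bandit", {
  # one state, action 1 always pays 1, action 2 always pays 0
  final_greedy <- vapply(1:20, function(seed) {
    set.seed(seed)
    tab <- stat_tables(1, 1, 2)
    for (t in 1:1000) {
      dec <- select_action(tab, 1L, agent_config("mos"), u = runif(1))
      learn(tab, 1L, dec$action, as.numeric(dec$action == 1L))
    }
    which.max(c(q_value(cell_stats(tab, 1L, 1)), q_value(cell_stats(tab, 1L, 2))))
  }, integer(1))
  expect_true(all(final_greedy == 1L))
})

test_that("learning delegates to the shared experience recorder", {
  tab <- stat_tables(2, 4, 3)
  learn(tab, c(1L, 2L), 3L, 0.8)
  expect_equal(cell_stats(tab, c(1, 2), 3)$n, 1)
  expect_equal(cell_stats(tab, 1L, 3, source = 1)$sum_r, 0.8)
  # replaying a log reproduces identical tables
  log <- random_log(200, 2, 4, 3, seed = 2)
  t1 <- tables_from_log(2, 4, 3, log)
  t2 <- tables_from_log(2, 4, 3, log)
  expect_identical(tables_to_df(t1), tables_to_df(t2))
})

test_that("lifetimes are reproducible and the right length", {
  env <- env_config()
  f1 <- run_lifetime(env, agent_config("mos"), horizon = 100, seed = 3)
  f2 <- run_lifetime(env, agent_config("mos"), horizon = 100, seed = 3)
  expect_equal(nrow(f1$records), 100)
  expect_identical(f1$records, f2$records)
})

test_that("compiled engine and R reference stepper agree bitwise", {
  env <- env_config(n_positions = 12)
  st <- make_streams(env, 250, 42)
  for (pol in c("mos", "lus")) {
    for (b in c("student_t", "chebyshev", "bernstein")) {
      cfg <- agent_config(pol, b, 0.1)
      a <- run_lifetime(env, cfg, streams = st, engine = "cpp")
      b_ <- run_lifetime(env, cfg, streams = st, engine = "r")
      expect_identical(a$records, b_$records)
      expect_equal(a$tables$joint, b_$tables$joint)
    }
  }
  u <- run_lifetime(env, agent_config("ucb1"), streams = st)
  ur <- run_lifetime(env, agent_config("ucb1"), streams = st, engine = "r")
  expect_identical(u$records, ur$records)

  env3 <- env_experiment2(n_positions = 6)
  st3 <- make_streams(env3, 250, 7)
  cfg <- agent_config("lus", alpha = 0.25, powerset = TRUE)
  expect_identical(run_lifetime(env3, cfg, streams = st3)$records,
                   run_lifetime(env3, cfg, streams = st3, engine = "r")$records)
})

test_that("average reward improves over a lifetime", {
  env <- env_config()
  fit <- run_lifetime(env, agent_config("mos"), horizon = 5e4, seed = 17,
                      return_tables = FALSE)
  r <- fit$records$reward
  expect_gt(mean(tail(r, 5e3)), mean(head(r, 5e3)))
  expect_gt(mean(tail(r, 5e3)), 0.9)
})

test_that("the selection-to-integration transition emerges in almost every lifetime", {
  env <- env_config()
  res <- vapply(1:20, function(seed) {
    fit <- run_lifetime(env, agent_config("mos"), horizon = 1e5, seed = seed,
                        return_tables = FALSE)
    rec <- fit$records
    q1 <- rec[rec$step <= 25000, ]
    q4 <- rec[rec$step > 75000, ]
    d1 <- dominance_shares(q1); d4 <- dominance_shares(q4)
    a1v <- mean(q1$accept_visual); a4v <- mean(q4$accept_visual)
    a1a <- mean(q1$accept_auditory); a4a <- mean(q4$accept_auditory)
    c(joint_up = d4[["joint"]] > d1[["joint"]],
      sensors_down = (d4[["visual"]] + d4[["auditory"]]) <
        (d1[["visual"]] + d1[["auditory"]]),
      accept_decay = a4v <= a1v && a4a <= a1a,
      auditory_faster = (a1a - a4a) > (a1v - a4v))
  }, logical(4))
  expect_gte(sum(res["joint_up", ]), 18)
  expect_gte(sum(res["sensors_down", ]), 18)
  expect_gte(sum(res["accept_decay", ]), 18)
  expect_gte(sum(res["auditory_faster", ]), 18)
})

test_that("the mature MOS agent tracks the Bayesian observer's reward", {
  env <- env_config()
  st <- make_streams(env, 1e5, 23)
  fit <- run_lifetime(env, agent_config("mos"), streams = st,
                      return_tables = FALSE)
  bay <- bayes_observer_run(st)
  last <- 75001:1e5
  agent_rate <- mean(fit$records$reward[last])
  bayes_rate <- mean(bay$reward[last])
  expect_gt(agent_rate, 0.95 * bayes_rate)
})

test_that("fitted-agent methods expose the learned policy", {
  env <- env_config(n_positions = 8)
  fit <- run_lifetime(env, agent_config("mos"), horizon = 4000, seed = 2)
  s <- summary(fit)
  expect_s3_class(s, "summary.ms_agent")
  expect_equal(sum(s$dominance), 1, tolerance = 1e-12)
  # a well-visited state should be predicted near its stimulus
  p <- predict(fit, cbind(4L, 4L))
  expect_true(abs(p - 4) <= 3)
  expect_true(is.na(predict(fit, cbind(1L, 8L))[1]) ||
              predict(fit, cbind(1L, 8L)) %in% 1:8)
  q <- coef(fit)
  expect_equal(dim(q), c(64, 8))
  expect_output(print(fit), "MOS agent")
})
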