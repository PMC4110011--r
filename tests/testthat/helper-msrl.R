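## shared fixtures built in code

# fold a reward vector into sufficient statistics via the incremental update
stats_from <- function(rewards, range = reward_range(-1e6, 1e6)) {
  s <- sufficient_stats()
  for (r in rewards) s <- stats_update(s, r, range)
  s
}

# construct a cell directly from a 0/1 reward count (sum_r2 == sum_r)
binary_cell <- function(n, n_ones) sufficient_stats(n, n_ones, n_ones)

# a tiny table set pre-filled from an explicit experience log, plus the log
# itself for brute-force oracles
tables_from_log <- function(k, n_pos, n_actions, log, powerset = FALSE) {
  tab <- stat_tables(k, n_pos, n_actions, powerset = powerset)
  for (i in seq_len(nrow(log))) {
    record_experience(tab, as.integer(log[i, 1:k]), log$action[i], log$r[i])
  }
  tab
}

random_log <- function(n, k, n_pos, n_actions, seed = 1) {
  set.seed(seed)
  log <- as.data.frame(matrix(sample.int(n_pos, n * k, TRUE), ncol = k))
  names(log) <- paste0("o", seq_len(k))
  log$action <- sample.int(n_actions, n, TRUE)
  log$r <- round(runif(n), 3)
  log
}
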