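## The full per-step learning/decision loop: build the joint interval for
## every action, screen every source with the generalization test, select a
## representative value per action with MOS or LUS, act greedily on the
## upper bounds, observe the reward and update all tables at once.

#' Agent configuration
#'
#' @param policy `"mos"` or `"lus"` for the interval-selection learner, or
#'   `"ucb1"` for a baseline that runs UCB1 directly on its sensor space
#'   (no sources, no generalization test).
#' @param bound confidence bound used for every interval: `"student_t"`,
#'   `"chebyshev"` or `"bernstein"`.
#' @param alpha significance level of all intervals; the framework's single
#'   free parameter.  Smaller alpha means wider intervals, more exploration
#'   and a later switch from selection to integration.
#' @param powerset use every proper sensor subset as a source instead of
#'   the singleton sensors.
#' @param ucb_c UCB1 exploration coefficient (baseline agents only).
#' @param sensors integer indices of the environment sensors this agent
#'   reads; `NULL` means all of them.  A UCB1 baseline on a single modality
#'   is `agent_config("ucb1", sensors = 1)`.
#' @param range the declared [reward_range()].
#' @return a list of class `ms_agent_config`.
#' @export
agent_config <- function(policy = c("mos", "lus", "ucb1"),
                         bound = c("student_t", "chebyshev", "bernstein"),
                         alpha = 0.05, powerset = FALSE, ucb_c = 0.2,
                         sensors = NULL, range = reward_range()) {
  policy <- match.arg(policy)
  bound <- match.arg(bound)
  .check_alpha(alpha)
  structure(list(policy = policy, bound = bound, alpha = alpha,
                 powerset = isTRUE(powerset), ucb_c = ucb_c,
                 sensors = if (is.null(sensors)) NULL else as.integer(sensors),
                 range = range),
            class = "ms_agent_config")
}

#' One decision of the interval-selection agent
#'
#' For the current state: builds the joint-space interval `M` for every
#' action, runs the generalization test for every source, feeds the accepted
#' intervals to [mos_select()]/[lus_select()], and picks the action with the
#' maximal representative value via [choose_action()].  This is the
#' per-step decision phase of the full algorithm; [learn()] is its update
#' phase.
#'
#' @param tables an [stat_tables()] environment.
#' @param state the current joint state (readings of the agent's sensors).
#' @param cfg an [agent_config()] (policy `"mos"` or `"lus"`).
#' @param u uniform deviate for tie-breaking.
#' @return list with `action`, `dominant` (source index, 0 = joint),
#'   `accept` (logical vector over the tables' sources, for the chosen
#'   action) and `values` (per-action representative values).
#' @export
select_action <- function(tables, state, cfg, u = stats::runif(1)) {
  stopifnot(inherits(tables, "ms_tables"), inherits(cfg, "ms_agent_config"))
  if (cfg$policy == "ucb1") stop("select_action: use select_action_ucb1 for UCB1 agents")
  n_act <- tables$n_actions
  n_src <- length(tables$sources)
  values <- numeric(n_act)
  dominant <- integer(n_act)
  acc <- matrix(FALSE, n_act, max(n_src, 1))
  for (a in seq_len(n_act)) {
    joint_ci <- ci_bound(cell_stats(tables, state, a), cfg$bound, cfg$alpha,
                         tables$range)
    accepted <- list()
    for (j in seq_len(n_src)) {
      gt <- g_test(tables, state, tables$sources[[j]], a, cfg$bound, cfg$alpha)
      acc[a, j] <- gt$accept
      if (gt$accept) {
        accepted[[length(accepted) + 1]] <-
          sourced_interval(tables$sources[[j]], gt$residual_ci)
      }
    }
    sel <- if (cfg$policy == "mos") mos_select(joint_ci, accepted)
           else lus_select(joint_ci, accepted)
    values[a] <- sel$value
    dominant[a] <- if (is.null(sel$source)) 0L else .source_slot(tables, sel$source)
  }
  action <- choose_action(values, u)
  list(action = action, dominant = dominant[action],
       accept = acc[action, seq_len(n_src)], values = values)
}

#' One decision of a UCB1 baseline agent
#'
#' @inheritParams select_action
#' @param cfg an [agent_config()] with `policy = "ucb1"`.
#' @return list with `action` and `values`.
#' @export
select_action_ucb1 <- function(tables, state, cfg, u = stats::runif(1)) {
  stopifnot(inherits(tables, "ms_tables"))
  idx <- .obs_index(state, tables$n_pos)
  total <- sum(tables$joint$n[idx, ])
  values <- vapply(seq_len(tables$n_actions), function(a) {
    ucb1_value(cell_stats(tables, state, a), total, cfg$ucb_c)
  }, numeric(1))
  list(action = choose_action(values, u), values = values)
}

#' Update phase of one step
#'
#' Records the observed reward into the joint cell and every marginal cell;
#' thin wrapper over [record_experience()] so that the decision and update
#' phases of the algorithm have matching entry points.
#'
#' @inheritParams record_experience
#' @return the tables, invisibly.
#' @export
learn <- function(tables, state, action, r) {
  record_experience(tables, state, action, r)
}

.policy_code <- function(p) match(p, c("ucb1", "mos", "lus")) - 1L
.bound_code <- function(b) match(b, c("student_t", "chebyshev", "bernstein")) - 1L

.source_labels <- function(env, sensors, sources) {
  nm <- vapply(env$sensors, `[[`, character(1), "name")[sensors]
  vapply(sources, function(src) paste(nm[src], collapse = "+"), character(1))
}

#' Run one lifetime of an agent in the localization environment
#'
#' The fitting entry point of the package: simulates `horizon` interactive
#' steps of the configured agent and returns the fitted agent — its learned
#' statistics tables plus the per-step diagnostic records (action, reward,
#' dominant source, generalization-test outcomes for the chosen action).
#'
#' Identical `(env, config, horizon, seed)` always reproduce the identical
#' trajectory.  The default engine is the compiled core; `engine = "r"`
#' runs the pure-R reference stepper built from the exported module
#' operations, which produces the same trajectory bit for bit and exists
#' for verification and didactics (it is orders of magnitude slower).
#'
#' @param env an [env_config()].
#' @param config an [agent_config()].
#' @param horizon number of steps (`>= 1`).
#' @param seed integer seed for the run's streams.
#' @param engine `"cpp"` (default) or `"r"`.
#' @param streams optional pregenerated [make_streams()] object; when
#'   supplied, `seed`/`horizon` are taken from it (this is how paired
#'   comparisons share one stimulus stream across agents).
#' @param return_tables keep the learned tables in the fit (needed by
#'   `predict`/`coef`; switch off to save memory in large sweeps).
#' @return an object of class `ms_agent`; see [summary.ms_agent()],
#'   [plot.ms_agent()], [predict.ms_agent()].
#' @examples
#' env <- env_config()
#' fit <- run_lifetime(env, agent_config("mos"), horizon = 500, seed = 1)
#' summary(fit)
#' @export
run_lifetime <- function(env, config, horizon, seed = 1,
                         engine = c("cpp", "r"), streams = NULL,
                         return_tables = TRUE) {
  engine <- match.arg(engine)
  stopifnot(inherits(env, "ms_env"), inherits(config, "ms_agent_config"))
  if (is.null(streams)) {
    stopifnot(horizon >= 1)
    streams <- make_streams(env, horizon, seed)
  }
  horizon <- streams$horizon
  sensors <- if (is.null(config$sensors)) seq_along(env$sensors) else config$sensors
  stopifnot(all(sensors >= 1), all(sensors <= length(env$sensors)))
  shape <- match(env$reward_shape, c("binary", "linear")) - 1L

  if (engine == "cpp") {
    res <- .run_engine_cpp(streams$stimulus, streams$obs, streams$u,
                           env$n_positions, env$n_positions,
                           env$reward_radius, shape,
                           .policy_code(config$policy),
                           .bound_code(config$bound),
                           config$alpha, config$ucb_c,
                           as.integer(sensors), config$powerset,
                           config$range$lo, config$range$hi, return_tables)
    tables <- if (return_tables) {
      .tables_from_engine(res$tables, length(sensors), env$n_positions,
                          config, streams)
    } else NULL
  } else {
    res <- .run_lifetime_r(streams, env, config, sensors)
    tables <- if (return_tables) res$tables else NULL
  }

  sources <- if (config$policy == "ucb1") list()
             else enumerate_sources(length(sensors), config$powerset)
  own <- if (length(sensors) == length(env$sensors)) "joint"
         else .source_labels(env, sensors, list(seq_along(sensors)))
  labels <- c(own, .source_labels(env, sensors, sources))
  records <- data.frame(step = seq_len(horizon),
                        stimulus = streams$stimulus,
                        action = res$action,
                        reward = res$reward,
                        dominant = factor(labels[res$dominant + 1L],
                                          levels = labels))
  if (length(sources)) {
    acc <- as.matrix(res$accept)
    colnames(acc) <- paste0("accept_", labels[-1])
    records <- cbind(records, acc)
  }
  structure(list(config = config, env = env, sensors = sensors,
                 sources = sources, source_labels = labels,
                 horizon = horizon, seed = streams$seed,
                 records = records, tables = tables, engine = engine),
            class = "ms_agent")
}

## Rebuild an ms_tables environment from the engine's returned arrays.
.tables_from_engine <- function(et, k, n_pos, config, streams) {
  tab <- stat_tables(k, n_pos, n_pos,
                     powerset = config$policy != "ucb1" && config$powerset,
                     range = config$range)
  if (config$policy == "ucb1") tab$sources <- list()
  tab$joint <- list(n = et$joint$n, s = et$joint$s, s2 = et$joint$s2)
  if (config$policy != "ucb1") {
    tab$marg <- lapply(et$marg, function(m) list(n = m$n, s = m$s, s2 = m$s2))
  } else {
    tab$marg <- list()
  }
  tab
}

## Pure-R reference stepper; exact mirror of the compiled engine, built from
## the exported per-step operations.
.run_lifetime_r <- function(streams, env, config, sensors) {
  k <- length(sensors)
  tables <- stat_tables(k, env$n_positions, env$n_positions,
                        powerset = config$policy != "ucb1" && config$powerset,
                        range = config$range)
  if (config$policy == "ucb1") {
    tables$sources <- list()
    tables$marg <- list()
  }
  n_src <- length(tables$sources)
  horizon <- streams$horizon
  action <- integer(horizon)
  reward <- numeric(horizon)
  dominant <- integer(horizon)
  accept <- matrix(NA, horizon, n_src)
  for (t in seq_len(horizon)) {
    state <- streams$obs[t, sensors]
    if (config$policy == "ucb1") {
      dec <- select_action_ucb1(tables, state, config, streams$u[t])
      dominant[t] <- 0L
    } else {
      dec <- select_action(tables, state, config, streams$u[t])
      dominant[t] <- dec$dominant
      accept[t, ] <- dec$accept
    }
    action[t] <- dec$action
    reward[t] <- reward_value(dec$action, streams$stimulus[t], env)
    learn(tables, state, dec$action, reward[t])
  }
  list(action = action, reward = reward, dominant = dominant,
       accept = accept, tables = tables)
}

#' @export
print.ms_agent <- function(x, ...) {
  cat(sprintf("Multisensory %s agent (%s bound, alpha = %g%s)\n",
              toupper(x$config$policy), x$config$bound, x$config$alpha,
              if (x$config$powerset) ", powerset sources" else ""))
  cat(sprintf("  %d sensors, %d-step lifetime, seed %d\n",
              length(x$sensors), x$horizon, x$seed))
  cat(sprintf("  mean reward: %.3f (final 10%%: %.3f)\n",
              mean(x$records$reward),
              mean(utils::tail(x$records$reward, ceiling(x$horizon / 10)))))
  invisible(x)
}

#' Summarize a fitted agent's lifetime
#'
#' Reports mean reward and the dominance share of every source over the
#' whole run and by quarters, plus (for interval-selection agents) the mean
#' generalization-test acceptance of each source in the first and last
#' quarter — the quantities whose time courses constitute the
#' selection-to-integration transition.
#'
#' @param object an `ms_agent` fit.
#' @param ... unused.
#' @return a list of class `summary.ms_agent`.
#' @export
summary.ms_agent <- function(object, ...) {
  rec <- object$records
  qtr <- cut(rec$step, 4, labels = paste0("Q", 1:4))
  dom_all <- dominance_shares(rec)
  dom_q <- vapply(levels(qtr), function(l) dominance_shares(rec[qtr == l, ]),
                  numeric(length(object$source_labels)))
  acc <- NULL
  acols <- grep("^accept_", names(rec), value = TRUE)
  if (length(acols)) {
    acc <- vapply(acols, function(cl) {
      c(first_quarter = mean(rec[[cl]][qtr == "Q1"]),
        last_quarter = mean(rec[[cl]][qtr == "Q4"]))
    }, numeric(2))
    colnames(acc) <- sub("^accept_", "", acols)
  }
  structure(list(config = object$config, horizon = object$horizon,
                 mean_reward = mean(rec$reward),
                 reward_by_quarter = tapply(rec$reward, qtr, mean),
                 dominance = dom_all, dominance_by_quarter = dom_q,
                 acceptance = acc),
            class = "summary.ms_agent")
}

#' @export
print.summary.ms_agent <- function(x, ...) {
  cat(sprintf("Lifetime of %d steps, %s policy\n", x$horizon,
              toupper(x$config$policy)))
  cat(sprintf("Mean reward: %.3f  (by quarter: %s)\n", x$mean_reward,
              paste(sprintf("%.3f", x$reward_by_quarter), collapse = " ")))
  cat("Dominance shares (%):\n")
  print(round(100 * x$dominance, 1))
  cat("Dominance by quarter (%):\n")
  print(round(100 * x$dominance_by_quarter, 1))
  if (!is.null(x$acceptance)) {
    cat("Generalization-test acceptance (first vs last quarter):\n")
    print(round(x$acceptance, 3))
  }
  invisible(x)
}

#' Greedy action predictions from a fitted agent
#'
#' Returns, for each queried joint state, the action with the highest
#' learned joint-space Q-value (ties to the lowest action id; `NA` for a
#' never-visited state).
#'
#' @param object an `ms_agent` fit with tables retained.
#' @param newdata matrix or data frame of sensor readings, one state per
#'   row (columns in the agent's sensor order).
#' @param ... unused.
#' @return integer vector of actions.
#' @export
predict.ms_agent <- function(object, newdata, ...) {
  if (is.null(object$tables)) stop("predict: fit was run with return_tables = FALSE")
  newdata <- as.matrix(newdata)
  stopifnot(ncol(newdata) == length(object$sensors))
  vapply(seq_len(nrow(newdata)), function(i) {
    idx <- .obs_index(newdata[i, ], object$tables$n_pos)
    n <- object$tables$joint$n[idx, ]
    if (all(n == 0)) return(NA_integer_)
    q <- ifelse(n > 0, object$tables$joint$s[idx, ] / pmax(n, 1), -Inf)
    which.max(q)
  }, integer(1))
}

#' Learned joint-space Q-values
#'
#' @param object an `ms_agent` fit with tables retained.
#' @param ... unused.
#' @return matrix of sample-mean rewards, states (linearized joint
#'   observations) by actions; `NaN` where a cell was never visited.
#' @export
coef.ms_agent <- function(object, ...) {
  if (is.null(object$tables)) stop("coef: fit was run with return_tables = FALSE")
  with(object$tables$joint, s / n)
}

#' Developmental diagnostics plot of a fitted agent
#'
#' Three stacked panels over the lifetime: smoothed average reward, the
#' smoothed generalization-test acceptance rate of each source (for the
#' chosen action), and the smoothed dominance share of each source — the
#' standard picture of the selection-to-integration transition.
#'
#' @param x an `ms_agent` fit.
#' @param window trailing moving-average window in steps.
#' @param ... passed to `matplot`.
#' @return `x`, invisibly.
#' @export
plot.ms_agent <- function(x, window = 500, ...) {
  rec <- x$records
  labels <- x$source_labels
  op <- graphics::par(mfrow = c(if (length(x$sources)) 3 else 1, 1),
                      mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(moving_average(rec$reward, window), type = "l",
                 xlab = "time step", ylab = "avg reward",
                 main = "Smoothed average reward", ...)
  if (length(x$sources)) {
    acols <- grep("^accept_", names(rec), value = TRUE)
    am <- vapply(acols, function(cl) moving_average(rec[[cl]], window),
                 numeric(nrow(rec)))
    graphics::matplot(am, type = "l", lty = 1, xlab = "time step",
                      ylab = "acceptance rate",
                      main = "Generalization-test acceptance")
    graphics::legend("bottomleft", legend = sub("^accept_", "", acols),
                     lty = 1, col = seq_along(acols), bty = "n")
    dm <- vapply(labels, function(l) {
      moving_average(as.numeric(rec$dominant == l), window)
    }, numeric(nrow(rec)))
    graphics::matplot(dm, type = "l", lty = 1, xlab = "time step",
                      ylab = "dominance share", main = "Source dominance")
    graphics::legend("topleft", legend = labels, lty = 1,
                     col = seq_along(labels), bty = "n")
  }
  invisible(x)
}
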