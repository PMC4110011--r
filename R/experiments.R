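## Experiment drivers and figure/table metrics: paired multi-run
## comparisons against the Bayesian observer, learning-speed criteria,
## dominance and acceptance time courses, and the alpha sensitivity sweep.

#' Trailing moving average
#'
#' At step `t` the mean of the last `min(window, t)` elements, so the
#' output has the same length as the input and is defined from the first
#' step (no leading NAs).
#'
#' @param series numeric vector.
#' @param window window size in steps (`>= 1`).
#' @return smoothed vector of the same length.
#' @export
moving_average <- function(series, window) {
  stopifnot(window >= 1)
  n <- length(series)
  if (n == 0) return(numeric(0))
  window <- min(as.integer(window), n)
  cs <- cumsum(series)
  out <- numeric(n)
  head_part <- seq_len(window)
  out[head_part] <- cs[head_part] / head_part
  if (window < n) {
    idx <- (window + 1):n
    out[idx] <- (cs[idx] - cs[idx - window]) / window
  }
  out
}

#' Dominance share of each source
#'
#' Fraction of decisions attributed to each source of information, overall
#' or per consecutive window.
#'
#' @param records a fit's `records` data frame (needs the `dominant`
#'   factor).
#' @param by_window optional window length; when given, shares are computed
#'   per consecutive block of that many steps.
#' @return named shares summing to 1 (a matrix with one row per window when
#'   `by_window` is set).
#' @export
dominance_shares <- function(records, by_window = NULL) {
  stopifnot(is.factor(records$dominant))
  if (is.null(by_window)) {
    return(prop.table(table(records$dominant)))
  }
  blk <- (seq_len(nrow(records)) - 1) %/% by_window
  t(vapply(split(records$dominant, blk),
           function(d) as.numeric(prop.table(table(d))),
           numeric(nlevels(records$dominant))))
}

#' Windowed generalization-test acceptance rate of one source
#'
#' The chosen action's accept flag for the source, smoothed with a trailing
#' moving average — the quantity whose decline over a lifetime shows the
#' test progressively rejecting aliased subspaces.
#'
#' @param records a fit's `records` data frame.
#' @param sensor source label (e.g. `"visual"`) or index into the fit's
#'   source list.
#' @param window moving-average window.
#' @return smoothed acceptance sequence in `[0, 1]`.
#' @export
acceptance_rate <- function(records, sensor, window = 500) {
  acols <- grep("^accept_", names(records), value = TRUE)
  if (!length(acols)) stop("acceptance_rate: records carry no test outcomes")
  col <- if (is.numeric(sensor)) acols[sensor] else paste0("accept_", sensor)
  if (is.na(col) || !col %in% acols) {
    stop("acceptance_rate: unknown source '", sensor, "'")
  }
  moving_average(as.numeric(records[[col]]), window)
}

#' Steps to reach a fraction of the Bayesian observer's reward
#'
#' The learning-speed criterion: the first step from which the agent's
#' accumulated reward *sustainedly* holds at least `frac` times the paired
#' Bayesian observer's accumulated reward on the same stimulus stream —
#' i.e. one past the last step at which the criterion is violated.  In the
#' first few steps the cumulative ratio is dominated by luck (a single
#' chance reward makes it cross any fraction), so the momentary first
#' crossing is uninformative; the sustained crossing is the step at which
#' learning has genuinely caught up.
#'
#' @param agent_cum agent's cumulative reward sequence.
#' @param bayes_cum observer's cumulative reward sequence (same stream,
#'   same length).
#' @param frac fraction in `(0, 1]`.
#' @return the 1-based crossing step (1 when the criterion always held), or
#'   `NA_integer_` if it is still violated at the end of the horizon.
#' @export
steps_to_fraction <- function(agent_cum, bayes_cum, frac) {
  if (!is.numeric(frac) || length(frac) != 1L || frac <= 0 || frac > 1) {
    stop("steps_to_fraction: 'frac' must lie in (0, 1]")
  }
  stopifnot(length(agent_cum) == length(bayes_cum))
  bad <- which(agent_cum < frac * bayes_cum)
  if (!length(bad)) return(1L)
  if (bad[length(bad)] == length(agent_cum)) return(NA_integer_)
  bad[length(bad)] + 1L
}

#' Standard two-sensor environment (visual SD 1, auditory SD 2)
#' @param ... overrides passed to [env_config()].
#' @return an [env_config()].
#' @export
env_experiment1 <- function(...) {
  env_config(sensors = list(sensor_gaussian(1, "visual"),
                            sensor_gaussian(2, "auditory")), ...)
}

#' Three-sensor environment with an added uniform-noise sensor
#' @param ... overrides passed to [env_config()].
#' @return an [env_config()].
#' @export
env_experiment2 <- function(...) {
  env_config(sensors = list(sensor_gaussian(1, "visual"),
                            sensor_gaussian(2, "auditory"),
                            sensor_uniform("noise")), ...)
}

#' Two-sensor environment whose visual sensor fails mid-run
#' @param failure_step step at which the visual sensor's reliability drops
#'   to the lowest possible value (uniform noise).
#' @param ... overrides passed to [env_config()].
#' @return an [env_config()].
#' @export
env_failure <- function(failure_step, ...) {
  env_config(sensors = list(sensor_gaussian(1, "visual"),
                            sensor_gaussian(2, "auditory")),
             failure_schedule = list(sensor = 1, step = failure_step), ...)
}

#' Default agent roster for a paired comparison
#'
#' Single-sensor UCB1 baselines, the joint-space UCB1 baseline, and the
#' MOS and LUS interval-selection learners.
#'
#' @param env the [env_config()] (one UCB1 baseline per sensor).
#' @param bound,alpha,ucb_c,powerset passed to [agent_config()].
#' @return named list of agent configurations.
#' @export
standard_roster <- function(env, bound = "student_t", alpha = 0.05,
                            ucb_c = 0.2, powerset = FALSE) {
  k <- length(env$sensors)
  roster <- lapply(seq_len(k), function(i) {
    agent_config("ucb1", ucb_c = ucb_c, sensors = i)
  })
  names(roster) <- vapply(env$sensors, `[[`, character(1), "name")
  roster$joint <- agent_config("ucb1", ucb_c = ucb_c)
  roster$mos <- agent_config("mos", bound, alpha, powerset = powerset)
  roster$lus <- agent_config("lus", bound, alpha, powerset = powerset)
  roster
}

#' Run a paired multi-run experiment
#'
#' Drives every agent of the roster over `runs` independent lifetimes.
#' Within a run all agents (and the Bayesian observer) consume the same
#' pregenerated stimulus/observation streams, so learning-speed comparisons
#' are exactly paired; run `i` uses seed `seed + i`.  For each agent and
#' each threshold fraction, the crossing step of the accumulated-reward
#' criterion and the dominance shares over the steps up to the crossing are
#' averaged over runs.
#'
#' @param agents named list of [agent_config()]s (see [standard_roster()]).
#' @param env an [env_config()].
#' @param horizon steps per run; crossings beyond it are `NA`.
#' @param runs number of independent runs.
#' @param seed base seed.
#' @param window moving-average window for the aggregated series.
#' @param fracs threshold fractions of the observer's accumulated reward.
#' @param keep_series keep run-averaged reward/acceptance/dominance series
#'   (switch off to save memory).
#' @return an object of class `ms_experiment`: `summary` (one row per
#'   agent x fraction), `series` (per agent), `bayes_mean_reward`, and the
#'   call parameters.
#' @export
run_experiment <- function(agents, env, horizon, runs = 20, seed = 1,
                           window = 500, fracs = c(0.6, 0.75, 0.9),
                           keep_series = TRUE) {
  stopifnot(length(agents) >= 1, !is.null(names(agents)), horizon >= 1,
            runs >= 1, window >= 1)
  nm <- names(agents)
  cross <- array(NA_real_, c(runs, length(agents), length(fracs)),
                 dimnames = list(NULL, nm, paste0("f", fracs)))
  dom_sum <- NULL
  series <- NULL
  bayes_reward_total <- 0

  for (i in seq_len(runs)) {
    streams <- make_streams(env, horizon, seed + i)
    bay <- bayes_observer_run(streams)
    bayes_cum <- cumsum(bay$reward)
    bayes_reward_total <- bayes_reward_total + mean(bay$reward)
    for (ai in seq_along(agents)) {
      fit <- run_lifetime(env, agents[[ai]], streams = streams,
                          return_tables = FALSE)
      cum <- cumsum(fit$records$reward)
      labs <- fit$source_labels
      if (is.null(dom_sum)) {
        all_labs <- unique(c("joint", unlist(lapply(env$sensors, `[[`, "name"))))
        dom_sum <- array(0, c(length(agents), length(fracs),
                              length(all_labs) + 1),
                         dimnames = list(nm, paste0("f", fracs),
                                         c(all_labs, "other")))
      }
      for (fi in seq_along(fracs)) {
        ct <- steps_to_fraction(cum, bayes_cum, fracs[fi])
        cross[i, ai, fi] <- ct
        upto <- if (is.na(ct)) horizon else ct
        sh <- dominance_shares(fit$records[seq_len(upto), , drop = FALSE])
        for (l in names(sh)) {
          slot <- if (l %in% dimnames(dom_sum)[[3]]) l else "other"
          dom_sum[ai, fi, slot] <- dom_sum[ai, fi, slot] + sh[[l]]
        }
      }
      if (keep_series) {
        if (is.null(series)) {
          series <- lapply(seq_along(agents), function(j) {
            list(reward = numeric(horizon), dominance = NULL,
                 acceptance = NULL)
          })
          names(series) <- nm
        }
        series[[ai]]$reward <- series[[ai]]$reward + fit$records$reward
        if (length(fit$sources)) {
          dm <- vapply(labs, function(l) {
            as.numeric(fit$records$dominant == l)
          }, numeric(horizon))
          am <- as.matrix(fit$records[, grep("^accept_", names(fit$records)),
                                      drop = FALSE])
          if (is.null(series[[ai]]$dominance)) {
            series[[ai]]$dominance <- dm
            series[[ai]]$acceptance <- am
          } else {
            series[[ai]]$dominance <- series[[ai]]$dominance + dm
            series[[ai]]$acceptance <- series[[ai]]$acceptance + am
          }
        }
      }
    }
  }

  if (keep_series) {
    series <- lapply(series, function(sr) {
      out <- list(reward = moving_average(sr$reward / runs, window))
      if (!is.null(sr$dominance)) {
        out$dominance <- apply(sr$dominance / runs, 2, moving_average,
                               window = window)
        out$acceptance <- apply(sr$acceptance / runs, 2, moving_average,
                                window = window)
      }
      out
    })
  }

  summ <- do.call(rbind, lapply(seq_along(agents), function(ai) {
    do.call(rbind, lapply(seq_along(fracs), function(fi) {
      steps <- cross[, ai, fi]
      row <- data.frame(agent = nm[ai], frac = fracs[fi],
                        mean_steps = mean(steps, na.rm = TRUE),
                        runs_crossed = sum(!is.na(steps)))
      dom <- 100 * dom_sum[ai, fi, ] / runs
      names(dom) <- paste0("pct_", names(dom))
      cbind(row, as.data.frame(as.list(dom)))
    }))
  }))
  rownames(summ) <- NULL

  structure(list(summary = summ, series = series,
                 crossings = cross,
                 bayes_mean_reward = bayes_reward_total / runs,
                 env = env, agents = agents, horizon = horizon,
                 runs = runs, seed = seed, window = window, fracs = fracs),
            class = "ms_experiment")
}

#' @export
print.ms_experiment <- function(x, ...) {
  cat(sprintf("Paired experiment: %d agents x %d runs x %d steps (seed %d)\n",
              length(x$agents), x$runs, x$horizon, x$seed))
  cat(sprintf("Bayesian observer mean reward: %.3f\n", x$bayes_mean_reward))
  cat("Steps to reach a fraction of the observer's accumulated reward,\n")
  cat("with dominance percentages over the steps up to the crossing:\n")
  print(cbind(x$summary[, 1:4],
              round(x$summary[, -(1:4), drop = FALSE], 1)))
  invisible(x)
}

#' Sensitivity sweep over the confidence coefficient alpha
#'
#' Runs the MOS learner at several significance levels and aggregates the
#' per-sensor acceptance-rate and dominance time courses; smaller alpha
#' (wider intervals) makes the test easier to pass and postpones the switch
#' from selection to integration.
#'
#' @param alphas significance levels to sweep.
#' @param env an [env_config()].
#' @param horizon,runs,seed,window as in [run_experiment()].
#' @param bound confidence bound.
#' @return named list (one entry per alpha) of run-averaged series:
#'   `reward`, `acceptance`, `dominance`.
#' @export
alpha_sweep <- function(alphas = c(0.05, 0.25, 0.45, 0.80),
                        env = env_experiment1(), horizon = 20000,
                        runs = 10, seed = 1, window = 500,
                        bound = "student_t") {
  out <- lapply(alphas, function(al) {
    ex <- run_experiment(list(mos = agent_config("mos", bound, al)),
                         env, horizon, runs, seed, window,
                         fracs = 0.6)
    ex$series$mos
  })
  names(out) <- paste0("alpha_", alphas)
  out
}

#' Write a fit's per-step records to CSV
#'
#' The trajectory stream format consumed by the summarize tooling: step,
#' stimulus, action, reward, dominant source and the chosen action's
#' per-source test outcomes.
#'
#' @param fit an `ms_agent` fit.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_records_csv <- function(fit, path) {
  utils::write.csv(fit$records, path, row.names = FALSE)
  invisible(path)
}
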