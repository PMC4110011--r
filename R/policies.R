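## Interval-selection decision policies and the two reference policies:
## UCB1 on a single source space and the reliability-weighted Bayesian
## observer that knows the sensor noise models.

#' Pair a source with its confidence interval
#'
#' @param source integer vector of sensor indices (the source's identity).
#' @param ci an [conf_int()] object.
#' @return a list of class `ms_sourced_ci`.
#' @export
sourced_interval <- function(source, ci) {
  stopifnot(inherits(ci, "ms_ci"))
  structure(list(source = sort(as.integer(source)), interval = ci),
            class = "ms_sourced_ci")
}

#' Most-Optimistic-Source interval selection
#'
#' Given the joint-space interval `M` for an action and the intervals of the
#' sources that passed the generalization test, picks the accepted interval
#' with the greatest upper bound and uses that upper bound as the action's
#' representative value.  The value is capped at `M`'s upper bound: the
#' joint space is the least-aliased description of the environment, so any
#' optimism beyond its upper bound is unrealistic.  When the cap fires (or
#' no source was accepted) the decision is attributed to the joint space.
#'
#' Ties on the upper bound go to the lowest sensor-index source, for
#' reproducibility.
#'
#' @param joint the joint-space [conf_int()].
#' @param accepted list of [sourced_interval()]s that passed the test.
#' @return list with `value` (the representative upper bound) and `source`
#'   (`NULL` for the joint space, else the winning source's indices).
#' @export
mos_select <- function(joint, accepted = list()) {
  stopifnot(inherits(joint, "ms_ci"))
  if (length(accepted) == 0) {
    return(list(value = joint$upper, source = NULL))
  }
  uppers <- vapply(accepted, function(x) x$interval$upper, numeric(1))
  best <- which.max(uppers)   # first maximum: lowest source index wins ties
  if (uppers[best] > joint$upper) {
    list(value = joint$upper, source = NULL)
  } else {
    list(value = uppers[best], source = accepted[[best]]$source)
  }
}

#' Least-Uncertain-Source interval selection
#'
#' Candidates are the accepted source intervals plus the joint interval
#' itself; the shortest interval wins (shorter means less uncertainty).
#' Length ties prefer the joint space, then the lowest sensor index.  The
#' chosen interval's upper bound is the representative value, again capped
#' at the joint upper bound, with the cap re-attributing the decision to
#' the joint space.
#'
#' @inheritParams mos_select
#' @return same shape as [mos_select()].
#' @export
lus_select <- function(joint, accepted = list()) {
  stopifnot(inherits(joint, "ms_ci"))
  if (length(accepted) == 0) {
    return(list(value = joint$upper, source = NULL))
  }
  lens <- vapply(accepted, function(x) ci_length(x$interval), numeric(1))
  jlen <- ci_length(joint)
  if (jlen <= min(lens)) {          # joint preferred on ties
    return(list(value = joint$upper, source = NULL))
  }
  best <- which.min(lens)           # first minimum: lowest index on ties
  up <- accepted[[best]]$interval$upper
  if (up > joint$upper) {
    list(value = joint$upper, source = NULL)
  } else {
    list(value = up, source = accepted[[best]]$source)
  }
}

#' Choose the action with the maximal representative value
#'
#' Unbounded (`Inf`) values beat every finite value, which is what forces a
#' fresh agent to try every action of a state.  Exact ties are broken
#' uniformly at random using a single uniform deviate, supplied explicitly
#' so that trajectories are reproducible from pregenerated streams.
#'
#' @param values numeric vector, one representative value per action.
#' @param u a uniform(0,1) deviate used only for tie-breaking.
#' @return the chosen action id.
#' @export
choose_action <- function(values, u = stats::runif(1)) {
  if (length(values) == 0) stop("choose_action: empty value list")
  m <- max(values)
  tied <- which(values == m)
  if (length(tied) == 1L) return(tied)
  tied[floor(min(u, 1 - 1e-12) * length(tied)) + 1]
}

#' UCB1 upper-confidence value of one action
#'
#' `q + sqrt(c * log(N) / n)` where `N` is the total number of visits to the
#' state and `n` the visits of this action there.  An unvisited action gets
#' an unbounded value (forced first trial).  The classical coefficient is
#' `c = 2`; the experiments use a much smaller default (0.2) because the
#' full coefficient wastes steps on re-exploration in large stationary
#' state-action spaces.
#'
#' @param stats the action's [sufficient_stats()] in this state.
#' @param total_state_visits total visits of the state, `>= stats$n`.
#' @param c exploration coefficient.
#' @return the UCB1 value (possibly `Inf`).
#' @export
ucb1_value <- function(stats, total_state_visits, c = 0.2) {
  stopifnot(inherits(stats, "ms_stats"), total_state_visits >= stats$n)
  if (stats$n == 0) return(Inf)
  stats$sum_r / stats$n + sqrt(c * log(total_state_visits) / stats$n)
}

#' Reliability-weighted Bayesian position estimate
#'
#' The optimal observer that knows the Gaussian sensor noise models fuses
#' the auditory and visual readings by inverse-variance weighting:
#' `(x_a / sigma_a^2 + x_v / sigma_v^2) / (1 / sigma_a^2 + 1 / sigma_v^2)`,
#' rounded half-up to the nearest grid position and clamped to the grid.
#' The estimate always lies between the two readings, and collapses onto
#' the more reliable one as the other sensor's noise grows.
#'
#' @param x_a,x_v auditory and visual readings (vectorized).
#' @param sigma_a,sigma_v their Gaussian noise SDs (positive).
#' @param n_pos grid size for the clamp (default 30).
#' @return integer grid position(s).
#' @export
bayes_optimal_estimate <- function(x_a, x_v, sigma_a, sigma_v, n_pos = 30) {
  if (!is.numeric(sigma_a) || !is.numeric(sigma_v) ||
      any(sigma_a <= 0) || any(sigma_v <= 0)) {
    stop("bayes_optimal_estimate: noise SDs must be positive")
  }
  wa <- 1 / sigma_a^2
  wv <- 1 / sigma_v^2
  est <- (x_a * wa + x_v * wv) / (wa + wv)
  pmin(pmax(floor(est + 0.5), 1), n_pos)
}
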