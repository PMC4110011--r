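## Joint-space statistics plus incrementally maintained marginals for every
## information source (sensor subset), residual-experience extraction and the
## generalization test that separates helpful from harmful perceptual aliasing.

#' Enumerate the information sources of a k-sensor agent
#'
#' A source is a non-empty subset of the sensors, excluding the full set:
#' the joint space is always present implicitly and is never listed.  With
#' `powerset = FALSE` only the k singleton sensors are sources (the primary
#' algorithm); with `powerset = TRUE` every non-empty proper subset is a
#' source (`2^k - 2` of them), which lets the agent discover reliable sensor
#' *combinations* such as the visual+auditory pair in the presence of a
#' noise sensor.
#'
#' @param k number of sensors (`k >= 1`).
#' @param powerset enumerate all proper subsets instead of singletons.
#' @return a list of integer vectors (ascending sensor indices), ordered by
#'   subset size then lexicographically.
#' @examples
#' enumerate_sources(3)                  # {1} {2} {3}
#' length(enumerate_sources(3, TRUE))    # 6
#' @export
enumerate_sources <- function(k, powerset = FALSE) {
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k != floor(k)) {
    stop("enumerate_sources: 'k' must be a positive integer")
  }
  k <- as.integer(k)
  if (k == 1L) return(list())   # the lone singleton IS the joint space
  if (!powerset) {
    return(lapply(seq_len(k), identity))
  }
  out <- list()
  for (sz in seq_len(k - 1L)) {
    combos <- utils::combn(k, sz, simplify = FALSE)
    out <- c(out, combos)
  }
  lapply(out, as.integer)
}

#' Project a joint state onto a source
#'
#' The aliasing map: returns the readings of the source's sensors, in
#' ascending sensor-index order.  Many joint states project onto the same
#' observation tuple, which is exactly the perceptual aliasing the
#' generalization test reasons about.
#'
#' @param state integer vector of k sensor readings.
#' @param source integer vector of sensor indices (a [enumerate_sources()]
#'   element, or `seq_along(state)` for the identity).
#' @return the projected observation tuple.
#' @export
project <- function(state, source) {
  stopifnot(all(source >= 1), all(source <= length(state)))
  state[sort(as.integer(source))]
}

## Linear index of an observation tuple in a dense table with n_pos positions
## per sensor: 1-based mixed-radix encoding, first sensor fastest.
.obs_index <- function(obs, n_pos) {
  idx <- 0
  for (i in rev(seq_along(obs))) idx <- idx * n_pos + (obs[i] - 1)
  idx + 1
}

#' Create an empty statistics table set
#'
#' Holds the joint-space table and one marginal table per source, all as
#' dense (observations x actions) count/sum/sum-of-squares arrays.
#' Marginals are maintained incrementally on every recorded experience, so
#' a marginal cell always equals the sum of the joint cells that project
#' onto it — no extra learning trials are needed for the subspaces.
#'
#' The object is an environment (reference semantics): [record_experience()]
#' updates it in place, mirroring how the agent accumulates a lifetime of
#' experience into one table set.
#'
#' @param k number of sensors.
#' @param n_pos number of grid positions each sensor can read.
#' @param n_actions size of the action set.
#' @param powerset use all proper sensor subsets as sources.
#' @param range the declared [reward_range()].
#' @return an environment of class `ms_tables`.
#' @export
stat_tables <- function(k, n_pos, n_actions, powerset = FALSE,
                        range = reward_range()) {
  stopifnot(k >= 1, n_pos >= 1, n_actions >= 1)
  if (n_pos^k * n_actions > 5e7) {
    stop("stat_tables: joint space too large for a dense table")
  }
  tab <- new.env(parent = emptyenv())
  tab$k <- as.integer(k)
  tab$n_pos <- as.integer(n_pos)
  tab$n_actions <- as.integer(n_actions)
  tab$powerset <- isTRUE(powerset)
  tab$range <- range
  tab$sources <- enumerate_sources(k, powerset)
  n_joint <- n_pos^k
  zero <- function(nr) matrix(0, nrow = nr, ncol = n_actions)
  tab$joint <- list(n = zero(n_joint), s = zero(n_joint), s2 = zero(n_joint))
  tab$marg <- lapply(tab$sources, function(src) {
    nr <- n_pos^length(src)
    list(n = zero(nr), s = zero(nr), s2 = zero(nr))
  })
  class(tab) <- "ms_tables"
  tab
}

#' @export
print.ms_tables <- function(x, ...) {
  cat(sprintf(
    "<ms_tables: %d sensors, %d positions, %d actions, %d sources%s; %d experiences>\n",
    x$k, x$n_pos, x$n_actions, length(x$sources),
    if (x$powerset) " (powerset)" else "", sum(x$joint$n)))
  invisible(x)
}

#' Extract one cell's sufficient statistics
#'
#' @param tables an [stat_tables()] environment.
#' @param obs observation tuple: the full joint state for `source = NULL`, or
#'   the projected tuple for a source.
#' @param action action id.
#' @param source `NULL` for the joint table, otherwise an integer vector
#'   matching one of the table's sources.
#' @return an [sufficient_stats()] object.
#' @export
cell_stats <- function(tables, obs, action, source = NULL) {
  stopifnot(inherits(tables, "ms_tables"))
  if (is.null(source)) {
    t <- tables$joint
    idx <- .obs_index(obs, tables$n_pos)
  } else {
    j <- .source_slot(tables, source)
    t <- tables$marg[[j]]
    idx <- .obs_index(obs, tables$n_pos)
  }
  sufficient_stats(t$n[idx, action], t$s[idx, action], t$s2[idx, action])
}

.source_slot <- function(tables, source) {
  src <- sort(as.integer(source))
  for (j in seq_along(tables$sources)) {
    if (identical(tables$sources[[j]], src)) return(j)
  }
  stop("unknown source: {", paste(source, collapse = ","), "}")
}

#' Record one experience into the joint table and every marginal
#'
#' Updates the joint cell `(state, action)` and, for each source, the cell
#' of the state's projection, all with the same reward.  Because marginal
#' statistics are plain sums over joint cells, this incremental maintenance
#' is mathematically identical to recomputing every marginal from the joint
#' table after the fact (and is tested to be).
#'
#' @param tables an [stat_tables()] environment (modified in place).
#' @param state integer vector of k sensor readings.
#' @param action action id in `1..n_actions`.
#' @param r observed reward; must lie in the declared range.
#' @return the tables, invisibly.
#' @export
record_experience <- function(tables, state, action, r) {
  stopifnot(inherits(tables, "ms_tables"), length(state) == tables$k,
            action >= 1, action <= tables$n_actions)
  rng <- tables$range
  if (is.na(r) || r < rng$lo || r > rng$hi) {
    stop(sprintf("record_experience: reward %g outside support [%g, %g]",
                 r, rng$lo, rng$hi))
  }
  ji <- .obs_index(state, tables$n_pos)
  tables$joint$n[ji, action] <- tables$joint$n[ji, action] + 1
  tables$joint$s[ji, action] <- tables$joint$s[ji, action] + r
  tables$joint$s2[ji, action] <- tables$joint$s2[ji, action] + r * r
  for (j in seq_along(tables$sources)) {
    mi <- .obs_index(state[tables$sources[[j]]], tables$n_pos)
    tables$marg[[j]]$n[mi, action] <- tables$marg[[j]]$n[mi, action] + 1
    tables$marg[[j]]$s[mi, action] <- tables$marg[[j]]$s[mi, action] + r
    tables$marg[[j]]$s2[mi, action] <- tables$marg[[j]]$s2[mi, action] + r * r
  }
  invisible(tables)
}

#' Residual experiences of a marginal cell
#'
#' Subtracts the current joint cell's statistics from its marginal cell's,
#' leaving the experiences the source accumulated in *other* joint states
#' that alias to the same observation.  Comparing this residual against the
#' joint cell is what makes the generalization test informative: the
#' marginal contains the joint cell's own rewards, so testing the raw
#' marginal against the joint cell would be circular.
#'
#' @param marginal [sufficient_stats()] of the source cell.
#' @param joint_entry [sufficient_stats()] of the current joint cell.
#' @return the componentwise difference as an [sufficient_stats()].
#' @export
residual_stats <- function(marginal, joint_entry) {
  stopifnot(inherits(marginal, "ms_stats"), inherits(joint_entry, "ms_stats"))
  n <- marginal$n - joint_entry$n
  s <- marginal$sum_r - joint_entry$sum_r
  s2 <- marginal$sum_r2 - joint_entry$sum_r2
  if (n < 0 || s < -1e-9 || s2 < -1e-9) {
    stop("residual_stats: joint cell exceeds its marginal; tables inconsistent")
  }
  if (n == 0) {
    s <- 0   # mathematically exact; kills float dust from the subtraction
    s2 <- 0
  }
  sufficient_stats(n, max(s, 0), max(s2, 0))
}

#' Do two confidence intervals intersect?
#'
#' Closed-interval test: touching endpoints count as an intersection.
#' Unbounded sentinels behave as minus/plus infinity, so an interval from an
#' under-sampled cell intersects everything.
#'
#' @param a,b [conf_int()] objects.
#' @return logical flag.
#' @export
intervals_intersect <- function(a, b) {
  stopifnot(inherits(a, "ms_ci"), inherits(b, "ms_ci"))
  max(a$lower, b$lower) <= min(a$upper, b$upper)
}

#' Generalization test for one source, state and action
#'
#' Decides whether the perceptual aliasing of `source` at the current state
#' is a beneficial generalization for `action` or garbage.  It builds the
#' confidence interval `M` on the joint cell's mean and the interval on the
#' *residual* experiences of the source's cell (marginal minus joint cell),
#' and accepts the source iff the two intervals intersect — i.e. iff the
#' rewards the source gathered in the other states aliased to this
#' observation are statistically compatible with this state's own rewards.
#'
#' Early in learning both intervals are wide (or unbounded, when a cell has
#' fewer than two samples) and every source passes; with experience the
#' intervals shrink and only genuinely generalizing sources keep passing.
#'
#' @param tables an [stat_tables()] environment.
#' @param state the current joint state.
#' @param source one of the table's sources.
#' @param action action id.
#' @param bound interval construction: `"student_t"`, `"chebyshev"` or
#'   `"bernstein"`.
#' @param alpha significance level of both intervals.
#' @return a list with `accept` (flag), `residual_ci` and `joint_ci`.
#' @export
g_test <- function(tables, state, source, action,
                   bound = c("student_t", "chebyshev", "bernstein"),
                   alpha = 0.05) {
  bound <- match.arg(bound)
  joint <- cell_stats(tables, state, action)
  marg <- cell_stats(tables, project(state, source), action, source = source)
  resid <- residual_stats(marg, joint)
  joint_ci <- ci_bound(joint, bound, alpha, tables$range)
  resid_ci <- ci_bound(resid, bound, alpha, tables$range)
  list(accept = intervals_intersect(resid_ci, joint_ci),
       residual_ci = resid_ci, joint_ci = joint_ci)
}

#' Dump non-empty cells as a data frame
#'
#' Flat inspection/checkpoint format: one row per visited cell of the joint
#' table and of every marginal, with the observation tuple, action and the
#' three sufficient statistics.  `utils::write.csv()` on the result is the
#' documented on-disk checkpoint.
#'
#' @param tables an [stat_tables()] environment.
#' @return a data frame with columns `source`, `obs`, `action`, `n`,
#'   `sum_r`, `sum_r2`.
#' @export
tables_to_df <- function(tables) {
  stopifnot(inherits(tables, "ms_tables"))
  one <- function(tag, tl, arity) {
    hit <- which(tl$n > 0, arr.ind = TRUE)
    if (nrow(hit) == 0) return(NULL)
    obs <- vapply(hit[, 1], function(idx) {
      idx <- idx - 1
      paste((idx %/% tables$n_pos^(seq_len(arity) - 1)) %% tables$n_pos + 1,
            collapse = ":")
    }, character(1))
    data.frame(source = tag, obs = obs, action = hit[, 2],
               n = tl$n[hit], sum_r = tl$s[hit], sum_r2 = tl$s2[hit])
  }
  out <- list(one("joint", tables$joint, tables$k))
  for (j in seq_along(tables$sources)) {
    tag <- paste(tables$sources[[j]], collapse = "+")
    out <- c(out, list(one(tag, tables$marg[[j]], length(tables$sources[[j]]))))
  }
  do.call(rbind, Filter(Negate(is.null), out))
}
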