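#' Reward support range
#'
#' Declares the closed interval `[lo, hi]` that contains every reward the
#' environment can emit.  The distribution-free confidence bounds (Chebyshev
#' and empirical Bernstein) need this support; the reward update refuses
#' samples outside it (fail-fast, so a mis-configured environment is caught
#' at the first bad sample rather than corrupting the tables).
#'
#' @param lo,hi numeric scalars, `lo < hi`.  Defaults match the binary
#'   localization reward, which pays in `[0, 1]`.
#' @return an object of class `ms_range` with fields `lo` and `hi`.
#' @examples
#' reward_range()        # the default unit interval
#' reward_range(-1, 1)
#' @export
reward_range <- function(lo = 0, hi = 1) {
  stopifnot(is.numeric(lo), is.numeric(hi), length(lo) == 1L, length(hi) == 1L)
  if (!(lo < hi)) stop("reward_range: 'lo' must be strictly below 'hi'")
  structure(list(lo = as.numeric(lo), hi = as.numeric(hi)), class = "ms_range")
}

#' Sufficient statistics of one reward cell
#'
#' A reward cell (one observation–action pair in some source space) is fully
#' summarised by the visit count, the running reward sum and the running sum
#' of squared rewards.  Every Q-value, sample standard deviation and
#' confidence interval in the framework is a function of these three numbers,
#' which is what makes exact marginalization and residual extraction possible
#' without storing individual samples.
#'
#' @param n visit count (non-negative integer).
#' @param sum_r running sum of rewards.
#' @param sum_r2 running sum of squared rewards.
#' @return an object of class `ms_stats`.
#' @seealso [stats_update()], [q_value()], [sample_std()]
#' @export
sufficient_stats <- function(n = 0, sum_r = 0, sum_r2 = 0) {
  n <- as.numeric(n)
  if (length(n) != 1L || n < 0 || n != floor(n)) {
    stop("sufficient_stats: 'n' must be a single non-negative integer")
  }
  if (n == 0 && (sum_r != 0 || sum_r2 != 0)) {
    stop("sufficient_stats: empty cell must have zero sums")
  }
  structure(list(n = n, sum_r = as.numeric(sum_r), sum_r2 = as.numeric(sum_r2)),
            class = "ms_stats")
}

#' @export
print.ms_stats <- function(x, ...) {
  if (x$n == 0) {
    cat("<reward cell: empty>\n")
  } else {
    cat(sprintf("<reward cell: n = %d, mean = %.4g%s>\n", as.integer(x$n),
                x$sum_r / x$n,
                if (x$n >= 2) sprintf(", sd = %.4g", sample_std(x)) else ""))
  }
  invisible(x)
}

#' Record one reward in a cell
#'
#' Incremental update with learning rate `1/n`: after `n` updates the cell's
#' Q-value is exactly the sample mean of the rewards seen, which is the
#' stationary-environment estimator the whole framework builds on.
#'
#' @param stats an [sufficient_stats()] object.
#' @param r the observed reward.
#' @param range an [reward_range()]; rewards outside it are rejected.
#' @return the updated `ms_stats` object.
#' @examples
#' s <- sufficient_stats()
#' for (r in c(0, 1, 1, 0)) s <- stats_update(s, r)
#' q_value(s)  # 0.5
#' @export
stats_update <- function(stats, r, range = reward_range()) {
  stopifnot(inherits(stats, "ms_stats"), is.numeric(r), length(r) == 1L)
  if (is.na(r) || r < range$lo || r > range$hi) {
    stop(sprintf("stats_update: reward %g outside declared support [%g, %g]",
                 r, range$lo, range$hi))
  }
  stats$n <- stats$n + 1
  stats$sum_r <- stats$sum_r + r
  stats$sum_r2 <- stats$sum_r2 + r * r
  stats
}

#' Q-value (sample mean reward) of a cell
#'
#' @param stats an [sufficient_stats()] object with `n >= 1`.
#' @return the sample mean `sum_r / n`.
#' @export
q_value <- function(stats) {
  stopifnot(inherits(stats, "ms_stats"))
  if (stats$n < 1) stop("q_value: undefined for an empty cell (n = 0)")
  stats$sum_r / stats$n
}

#' Sample standard deviation of a cell
#'
#' Computed from the sufficient statistics as
#' `sqrt((sum_r2 - n * q^2) / (n - 1))`.  Floating-point cancellation can
#' drive the radicand a hair below zero for near-constant rewards; it is
#' clamped to zero.
#'
#' @inheritParams q_value
#' @return the n-1 denominator sample SD; requires `n >= 2`.
#' @export
sample_std <- function(stats) {
  stopifnot(inherits(stats, "ms_stats"))
  if (stats$n < 2) stop("sample_std: undefined for n < 2")
  .sample_std_raw(stats$n, stats$sum_r, stats$sum_r2)
}

## shared with the vectorized interval code; identical arithmetic to the C++ engine
.sample_std_raw <- function(n, s, s2) {
  q <- s / n
  sqrt(pmax(0, (s2 - n * q * q) / (n - 1)))
}

#' Confidence interval on the mean of a reward distribution
#'
#' Container for the interval estimates the policies and the generalization
#' test consume.  `-Inf`/`Inf` act as the unbounded sentinels produced when a
#' cell has too few samples for its bound; an unbounded interval implements
#' optimism in the face of uncertainty (untried cells look maximally good and
#' always pass the generalization test).
#'
#' @param lower,upper interval endpoints (may be infinite).
#' @param method one of `"student_t"`, `"chebyshev"`, `"bernstein"`.
#' @param alpha the significance level; the interval is two-sided at
#'   confidence `1 - alpha`.
#' @return an object of class `ms_ci`.
#' @export
conf_int <- function(lower, upper, method = "student_t", alpha = 0.05) {
  method <- match.arg(method, c("student_t", "chebyshev", "bernstein"))
  if (is.na(lower) || is.na(upper) || lower > upper) {
    stop("conf_int: need lower <= upper")
  }
  structure(list(lower = as.numeric(lower), upper = as.numeric(upper),
                 method = method, alpha = alpha),
            class = "ms_ci")
}

#' @export
print.ms_ci <- function(x, ...) {
  cat(sprintf("<%s %g%% CI: [%g, %g]>\n", x$method, 100 * (1 - x$alpha),
              x$lower, x$upper))
  invisible(x)
}

#' Length of a confidence interval
#'
#' @param ci an [conf_int()] object.
#' @return `upper - lower`; `Inf` if either end is a sentinel.
#' @export
ci_length <- function(ci) {
  stopifnot(inherits(ci, "ms_ci"))
  ci$upper - ci$lower
}

.check_alpha <- function(alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
      alpha <= 0 || alpha >= 1) {
    stop("alpha must be a single probability in (0, 1)")
  }
  invisible(alpha)
}

#' Student-t confidence interval on a cell mean
#'
#' Two-sided interval `q +/- t_{alpha/2, n-1} * s / sqrt(n)`.  Exact for
#' Gaussian rewards and a good approximation once `n` is moderately large;
#' it is the tightest of the three bounds and the default throughout.
#' With fewer than two samples the sample SD does not exist and the
#' unbounded interval is returned.
#'
#' @inheritParams q_value
#' @param alpha significance level in (0, 1).
#' @return an [conf_int()] with `method = "student_t"`.
#' @examples
#' s <- sufficient_stats(4, 2, 1.2)
#' ci_student(s, 0.05)  # [0.089, 0.911]
#' @export
ci_student <- function(stats, alpha = 0.05) {
  stopifnot(inherits(stats, "ms_stats"))
  .check_alpha(alpha)
  if (stats$n < 2) return(conf_int(-Inf, Inf, "student_t", alpha))
  q <- stats$sum_r / stats$n
  hw <- stats::qt(1 - alpha / 2, stats$n - 1) *
    .sample_std_raw(stats$n, stats$sum_r, stats$sum_r2) / sqrt(stats$n)
  conf_int(q - hw, q + hw, "student_t", alpha)
}

#' Worst-case Chebyshev confidence interval on a cell mean
#'
#' Distribution-free interval using the maximal variance `(hi - lo)^2 / 4`
#' of any distribution supported on the reward range:
#' `q +/- (hi - lo) / (2 * sqrt(n * alpha))`.  Valid for every reward
#' distribution on the support but very conservative, especially when the
#' true variance is small.  Defined from the first sample on.
#'
#' @inheritParams ci_student
#' @param range the declared [reward_range()].
#' @return an [conf_int()] with `method = "chebyshev"`.
#' @export
ci_chebyshev <- function(stats, alpha = 0.05, range = reward_range()) {
  stopifnot(inherits(stats, "ms_stats"))
  .check_alpha(alpha)
  if (stats$n < 1) return(conf_int(-Inf, Inf, "chebyshev", alpha))
  q <- stats$sum_r / stats$n
  hw <- (range$hi - range$lo) / (2 * sqrt(stats$n * alpha))
  conf_int(q - hw, q + hw, "chebyshev", alpha)
}

#' Empirical-Bernstein confidence interval on a cell mean
#'
#' Variance-aware distribution-free interval
#' `q +/- (s * sqrt(2 * log(3/alpha) / n) + 3 * (hi - lo) * log(3/alpha) / n)`.
#' Like Chebyshev it is valid for any distribution on the support, but the
#' half-width scales with the *estimated* SD, so it is much tighter when the
#' rewards are nearly constant.  Needs `n >= 2` for the SD estimate.
#'
#' @inheritParams ci_chebyshev
#' @return an [conf_int()] with `method = "bernstein"`.
#' @export
ci_bernstein <- function(stats, alpha = 0.05, range = reward_range()) {
  stopifnot(inherits(stats, "ms_stats"))
  .check_alpha(alpha)
  if (stats$n < 2) return(conf_int(-Inf, Inf, "bernstein", alpha))
  q <- stats$sum_r / stats$n
  s <- .sample_std_raw(stats$n, stats$sum_r, stats$sum_r2)
  lg <- log(3 / alpha)
  hw <- s * sqrt(2 * lg / stats$n) + 3 * (range$hi - range$lo) * lg / stats$n
  conf_int(q - hw, q + hw, "bernstein", alpha)
}

#' Dispatch on the bound name
#'
#' @param stats an [sufficient_stats()] object.
#' @param bound `"student_t"`, `"chebyshev"` or `"bernstein"`.
#' @param alpha significance level.
#' @param range the declared [reward_range()].
#' @return the corresponding [conf_int()].
#' @export
ci_bound <- function(stats, bound = c("student_t", "chebyshev", "bernstein"),
                     alpha = 0.05, range = reward_range()) {
  switch(match.arg(bound),
         student_t = ci_student(stats, alpha),
         chebyshev = ci_chebyshev(stats, alpha, range),
         bernstein = ci_bernstein(stats, alpha, range))
}

## Vectorized interval bounds over parallel vectors of sufficient statistics.
## Used by the R reference stepper so that one call covers all actions of the
## current state; arithmetic mirrors ci_student/ci_chebyshev/ci_bernstein and
## the C++ engine exactly.  Returns list(lower, upper).
.ci_bounds_vec <- function(n, s, s2, bound, alpha, rlo, rhi) {
  q <- ifelse(n > 0, s / pmax(n, 1), 0)
  if (bound == "student_t") {
    ok <- n >= 2
    hw <- rep(Inf, length(n))
    if (any(ok)) {
      sd <- .sample_std_raw(n[ok], s[ok], s2[ok])
      hw[ok] <- stats::qt(1 - alpha / 2, n[ok] - 1) * sd / sqrt(n[ok])
    }
  } else if (bound == "chebyshev") {
    ok <- n >= 1
    hw <- ifelse(ok, (rhi - rlo) / (2 * sqrt(pmax(n, 1) * alpha)), Inf)
  } else {
    ok <- n >= 2
    hw <- rep(Inf, length(n))
    if (any(ok)) {
      sd <- .sample_std_raw(n[ok], s[ok], s2[ok])
      lg <- log(3 / alpha)
      hw[ok] <- sd * sqrt(2 * lg / n[ok]) + 3 * (rhi - rlo) * lg / n[ok]
    }
  }
  lower <- ifelse(is.finite(hw), q - hw, -Inf)
  upper <- ifelse(is.finite(hw), q + hw, Inf)
  list(lower = lower, upper = upper)
}
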