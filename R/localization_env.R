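## The audiovisual localization simulator: a stimulus appears uniformly on a
## discrete grid, each sensor returns a noisy reading, and an action (a
## position guess) is rewarded when it falls within a fixed radius of the
## stimulus.

#' Gaussian sensor model
#'
#' Reading = round-half-up(stimulus + Normal(0, sigma)), clamped to the
#' grid.  The SD (in grid units) controls the sensor's reliability.
#'
#' @param sigma noise SD in grid units, `> 0`.
#' @param name optional label (e.g. `"visual"`).
#' @return a list of class `ms_sensor`.
#' @export
sensor_gaussian <- function(sigma, name = NULL) {
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0) {
    stop("sensor_gaussian: sigma must be a positive scalar")
  }
  structure(list(kind = "gaussian", sigma = sigma, name = name),
            class = "ms_sensor")
}

#' Uniform-noise sensor model
#'
#' Reading is uniform over the grid, independent of the stimulus — a sensor
#' carrying no information (equivalently, a Gaussian sensor in the limit of
#' infinite noise on a bounded grid).  Used for the unreliable sensor of
#' Experiment 2 and as the post-failure model of a broken sensor.
#'
#' @param name optional label (e.g. `"noise"`).
#' @return a list of class `ms_sensor`.
#' @export
sensor_uniform <- function(name = NULL) {
  structure(list(kind = "uniform_noise", sigma = NA_real_, name = name),
            class = "ms_sensor")
}

#' Localization environment configuration
#'
#' @param n_positions number of grid positions (and of actions); default 30.
#' @param reward_radius actions within this distance of the stimulus are
#'   rewarded; default 3 grid units.
#' @param reward_shape `"binary"` (1 inside the radius, 0 outside — the
#'   default) or `"linear"` (graded `(radius + 1 - d) / (radius + 1)` inside
#'   the radius).  Both pay strictly positive reward iff `d <= radius`.
#' @param sensors list of [sensor_gaussian()] / [sensor_uniform()] models;
#'   default a visual sensor (SD 1) and an auditory sensor (SD 2), so vision
#'   is the more reliable modality.
#' @param failure_schedule optional `list(sensor = i, step = t)`: from step
#'   `t` on, sensor `i`'s model is replaced by uniform noise (reliability
#'   drops to the lowest value a bounded grid admits).
#' @return a list of class `ms_env`.
#' @export
env_config <- function(n_positions = 30, reward_radius = 3,
                       reward_shape = c("binary", "linear"),
                       sensors = list(sensor_gaussian(1, "visual"),
                                      sensor_gaussian(2, "auditory")),
                       failure_schedule = NULL) {
  reward_shape <- match.arg(reward_shape)
  stopifnot(n_positions >= 2, reward_radius >= 0)
  if (!length(sensors) || !all(vapply(sensors, inherits, TRUE, "ms_sensor"))) {
    stop("env_config: 'sensors' must be a non-empty list of sensor models")
  }
  if (!is.null(failure_schedule)) {
    if (!is.list(failure_schedule) ||
        is.null(failure_schedule$sensor) || is.null(failure_schedule$step) ||
        failure_schedule$sensor < 1 || failure_schedule$sensor > length(sensors)) {
      stop("env_config: failure_schedule must be list(sensor = i, step = t) with a valid sensor index")
    }
  }
  nm <- vapply(seq_along(sensors), function(i) {
    if (is.null(sensors[[i]]$name)) paste0("s", i) else sensors[[i]]$name
  }, character(1))
  for (i in seq_along(sensors)) sensors[[i]]$name <- nm[i]
  structure(list(n_positions = as.integer(n_positions),
                 reward_radius = reward_radius,
                 reward_shape = reward_shape,
                 sensors = sensors,
                 failure_schedule = failure_schedule),
            class = "ms_env")
}

#' @export
print.ms_env <- function(x, ...) {
  sens <- vapply(x$sensors, function(s) {
    if (s$kind == "gaussian") sprintf("%s~N(0,%g)", s$name, s$sigma)
    else sprintf("%s~U", s$name)
  }, character(1))
  cat(sprintf("<localization env: %d positions, radius %g (%s reward), sensors: %s%s>\n",
              x$n_positions, x$reward_radius, x$reward_shape,
              paste(sens, collapse = ", "),
              if (is.null(x$failure_schedule)) "" else
                sprintf("; sensor %d fails at step %d",
                        x$failure_schedule$sensor, x$failure_schedule$step)))
  invisible(x)
}

#' Draw stimulus positions
#'
#' @param cfg an [env_config()].
#' @param n number of draws.
#' @return integer positions, uniform on `1..n_positions`.
#' @export
sample_stimulus <- function(cfg, n = 1) {
  stopifnot(inherits(cfg, "ms_env"))
  sample.int(cfg$n_positions, n, replace = TRUE)
}

#' Observe a stimulus through a sensor
#'
#' @param stimulus integer position(s).
#' @param model an `ms_sensor`.
#' @param cfg the [env_config()] (for grid bounds).
#' @return integer reading(s): Gaussian sensors add noise then round half-up
#'   and clamp; uniform-noise sensors ignore the stimulus entirely.
#' @export
observe <- function(stimulus, model, cfg) {
  stopifnot(inherits(model, "ms_sensor"), inherits(cfg, "ms_env"))
  n <- length(stimulus)
  if (model$kind == "gaussian") {
    raw <- stimulus + stats::rnorm(n, 0, model$sigma)
    as.integer(pmin(pmax(floor(raw + 0.5), 1), cfg$n_positions))
  } else {
    sample.int(cfg$n_positions, n, replace = TRUE)
  }
}

#' Reward of a localization guess
#'
#' Strictly positive iff the guess is within `reward_radius` of the
#' stimulus.  Binary shape pays 1 inside the radius; linear shape decays
#' from 1 at the stimulus to `1/(radius+1)` at the radius edge.
#'
#' @param action guessed position(s).
#' @param stimulus true position(s).
#' @param cfg the [env_config()].
#' @return reward(s) in `[0, 1]`.
#' @export
reward_value <- function(action, stimulus, cfg) {
  stopifnot(inherits(cfg, "ms_env"))
  if (any(action < 1 | action > cfg$n_positions) ||
      any(stimulus < 1 | stimulus > cfg$n_positions)) {
    stop("reward_value: positions must lie on the grid")
  }
  d <- abs(action - stimulus)
  if (cfg$reward_shape == "binary") {
    as.numeric(d <= cfg$reward_radius)
  } else {
    ifelse(d <= cfg$reward_radius,
           (cfg$reward_radius + 1 - d) / (cfg$reward_radius + 1), 0)
  }
}

#' Apply the scheduled sensor failure
#'
#' @param cfg the [env_config()].
#' @param step current time step.
#' @return the configuration in force at `step`: identical to `cfg` before
#'   the scheduled step (or when no schedule exists); at and after it, the
#'   scheduled sensor's model is replaced by uniform noise.
#' @export
apply_failure <- function(cfg, step) {
  stopifnot(inherits(cfg, "ms_env"))
  fs <- cfg$failure_schedule
  if (is.null(fs) || step < fs$step) return(cfg)
  nm <- cfg$sensors[[fs$sensor]]$name
  cfg$sensors[[fs$sensor]] <- sensor_uniform(nm)
  cfg
}

#' Pregenerate the stochastic streams of one run
#'
#' Draws, from one seed, everything random a lifetime needs: the stimulus
#' stream, every sensor's reading stream (with any scheduled failure already
#' applied), and a uniform tie-breaking stream.  All agents of a paired
#' comparison run on the same streams object, so they see identical stimuli
#' and observations; the engines themselves are then fully deterministic.
#'
#' @param cfg an [env_config()].
#' @param horizon number of steps.
#' @param seed integer seed.
#' @return a list of class `ms_streams` with `stimulus` (length-`horizon`
#'   integer vector), `obs` (`horizon x k` integer matrix) and `u`
#'   (length-`horizon` uniforms).
#' @export
make_streams <- function(cfg, horizon, seed) {
  stopifnot(inherits(cfg, "ms_env"), horizon >= 1)
  set.seed(as.integer(seed))
  stim <- sample_stimulus(cfg, horizon)
  k <- length(cfg$sensors)
  obs <- matrix(0L, nrow = horizon, ncol = k)
  fs <- cfg$failure_schedule
  for (i in seq_len(k)) {
    obs[, i] <- observe(stim, cfg$sensors[[i]], cfg)
    if (!is.null(fs) && fs$sensor == i && fs$step <= horizon) {
      post <- fs$step:horizon
      failed <- apply_failure(cfg, fs$step)$sensors[[i]]
      obs[post, i] <- observe(stim[post], failed, cfg)
    }
  }
  u <- stats::runif(horizon)
  structure(list(stimulus = stim, obs = obs, u = u,
                 cfg = cfg, horizon = as.integer(horizon),
                 seed = as.integer(seed)),
            class = "ms_streams")
}

#' Bayesian observer rewards on a stream
#'
#' Runs the reliability-weighted optimal observer over a pregenerated
#' stream: it fuses the Gaussian sensors' readings by inverse-variance
#' weighting (uniform-noise sensors carry no information and are ignored)
#' and collects the same reward the learning agents would get for those
#' guesses.  Used as the paired performance yardstick.  After a scheduled
#' sensor failure the observer is assumed to know the new (uninformative)
#' model and drops the failed sensor from the fusion.
#'
#' @param streams an [make_streams()] object.
#' @return list with `action` and `reward` vectors.
#' @export
bayes_observer_run <- function(streams) {
  stopifnot(inherits(streams, "ms_streams"))
  cfg <- streams$cfg
  horizon <- streams$horizon
  fs <- cfg$failure_schedule
  est_for <- function(cfg_now, rows) {
    gau <- which(vapply(cfg_now$sensors, function(s) s$kind == "gaussian",
                        TRUE))
    if (length(gau) == 0) {
      stop("bayes_observer_run: no informative sensor available")
    }
    w <- vapply(gau, function(i) 1 / cfg_now$sensors[[i]]$sigma^2, numeric(1))
    num <- rep(0, length(rows))
    for (j in seq_along(gau)) num <- num + streams$obs[rows, gau[j]] * w[j]
    pmin(pmax(floor(num / sum(w) + 0.5), 1), cfg_now$n_positions)
  }
  act <- integer(horizon)
  if (is.null(fs) || fs$step > horizon) {
    act <- est_for(cfg, seq_len(horizon))
  } else {
    pre <- seq_len(fs$step - 1)
    post <- fs$step:horizon
    if (length(pre)) act[pre] <- est_for(cfg, pre)
    act[post] <- est_for(apply_failure(cfg, fs$step), post)
  }
  list(action = as.integer(act),
       reward = reward_value(act, streams$stimulus, cfg))
}
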