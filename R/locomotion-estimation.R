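#' Onset-detection configuration
#'
#' Rest-to-motion onsets are detected where the speed crosses the threshold
#' `eps = th_acc * dt` from below: `I = { t : |v|_t < eps, |v|_{t+1} >= eps }`.
#'
#' @param th_acc acceleration threshold, normalized units/s^2; > 0.
#' @param dt sampling interval, seconds.
#' @return list of class `onset_config` with `th_acc`, `dt` and the derived
#'   speed threshold `eps`.
#' @export
onset_config <- function(th_acc, dt = 0.1) {
  if (th_acc <= 0) stopf("th_acc must be positive")
  structure(list(th_acc = th_acc, dt = dt, eps = th_acc * dt),
            class = "onset_config")
}

#' Pick the default acceleration threshold for a dataset
#'
#' The threshold is chosen so that the speed threshold `eps` equals 5% of the
#' 95th percentile of the pooled nonzero speeds of the requested agent. Tying
#' `eps` to the top of the speed distribution keeps it strictly below the
#' one-step post-rest speed across damping regimes: for agents that are
#' almost always in motion, low speed quantiles sit at or above the post-rest
#' speed itself, and an `eps` at or above that speed would shift every
#' detected onset one step late and inflate the estimated thrust amplitude.
#' A small `eps` also rejects restarts from incomplete rest, whose
#' first-step speed retains a damped remnant of the previous motion.
#'
#' @param episodes list of [episode()] objects.
#' @param agent_index 1-based agent index.
#' @param dt sampling interval.
#' @return an [onset_config()].
#' @export
default_onset_config <- function(episodes, agent_index, dt = NULL) {
  if (is.null(dt)) dt <- diff(episodes[[1]]$times[1:2])
  speeds <- unlist(lapply(episodes, function(ep) {
    vnorm(matrix(ep$velocities[agent_index, , ], ncol = 2))
  }))
  nz <- speeds[speeds > 0]
  if (length(nz) == 0) stopf("agent %d never moves", agent_index)
  eps <- 0.05 * stats::quantile(nz, 0.95, names = FALSE)
  onset_config(th_acc = eps / dt, dt = dt)
}

#' Detect rest-to-motion onsets in a speed series
#'
#' @param speed_series nonnegative numeric vector of speeds.
#' @param config an [onset_config()].
#' @return integer vector of 1-based indices `t` with
#'   `speed[t] < eps` and `speed[t + 1] >= eps`.
#' @export
detect_onsets <- function(speed_series, config) {
  if (length(speed_series) < 2) stopf("speed series must have length >= 2")
  eps <- config$eps
  n <- length(speed_series)
  which(speed_series[-n] < eps & speed_series[-1] >= eps)
}

#' Estimate locomotion parameters from demonstration episodes
#'
#' Pools the speed series of one agent across episodes, detects rest-to-motion
#' onsets, and sets
#' `u = |v|_on / dt` and `d = |v|_on / |v|_max`, where `|v|_on` is the median
#' speed immediately after an onset and `|v|_max` the median of speeds above
#' the 99th percentile. With fewer than 100 pooled speed samples the top-1%
#' statistic falls back to the single maximum speed (with a warning).
#'
#' @param episodes list of [episode()] objects (training split).
#' @param agent_index 1-based agent index.
#' @param config an [onset_config()], or `NULL` for
#'   [default_onset_config()].
#' @param holdout_episodes optional episodes on which to evaluate the
#'   one-step velocity RMSE of the fitted model.
#' @param noop_threshold_frac forwarded to [velocity_rmse()].
#' @return list of class `estimation_report` with fields `params`
#'   ([locomotion_params()]), `v_on`, `v_max`, `n_onsets` and
#'   `velocity_rmse` (`NA` unless `holdout_episodes` given).
#' @export
estimate_locomotion_params <- function(episodes, agent_index, config = NULL,
                                       holdout_episodes = NULL,
                                       noop_threshold_frac = 0.5) {
  if (length(episodes) == 0) stopf("no episodes supplied")
  dt <- diff(episodes[[1]]$times[1:2])
  if (is.null(config)) {
    config <- default_onset_config(episodes, agent_index, dt = dt)
  }
  speeds_all <- numeric(0)
  onset_speeds <- numeric(0)
  n_onsets <- 0L
  for (ep in episodes) {
    s <- vnorm(matrix(ep$velocities[agent_index, , ], ncol = 2))
    idx <- detect_onsets(s, config)
    n_onsets <- n_onsets + length(idx)
    onset_speeds <- c(onset_speeds, s[idx + 1L])
    speeds_all <- c(speeds_all, s)
  }
  if (n_onsets == 0) {
    stopf("estimation error: no rest-to-motion onsets found for agent %d",
          agent_index)
  }
  v_on <- stats::median(onset_speeds)
  if (length(speeds_all) < 100) {
    warnf("fewer than 100 speed samples; using the maximum speed instead of the top-1%% median")
    v_max <- max(speeds_all)
  } else {
    p99 <- stats::quantile(speeds_all, 0.99, names = FALSE)
    top <- speeds_all[speeds_all > p99]
    v_max <- if (length(top) > 0) stats::median(top) else max(speeds_all)
  }
  if (v_max <= 0) {
    stopf("degenerate data: maximal speed is zero for agent %d", agent_index)
  }
  d_hat <- v_on / v_max
  if (d_hat > 1) {
    warnf("onset speed exceeds top speed (d = %.3g); clamping d to 1", d_hat)
    d_hat <- 1
  }
  params <- locomotion_params(d = d_hat, u = v_on / dt, dt = dt)
  rmse <- NA_real_
  if (!is.null(holdout_episodes)) {
    rmse <- velocity_rmse(holdout_episodes, agent_index, params,
                          noop_threshold_frac = noop_threshold_frac)
  }
  structure(list(params = params, v_on = v_on, v_max = v_max,
                 n_onsets = n_onsets, velocity_rmse = rmse,
                 agent_index = agent_index),
            class = "estimation_report")
}

#' @export
print.estimation_report <- function(x, ...) {
  cat(sprintf(
    "<estimation_report> agent %d: d = %.4g, u = %.4g (|v|_on = %.4g, |v|_max = %.4g, %d onsets)\n",
    x$agent_index, x$params$d, x$params$u, x$v_on, x$v_max, x$n_onsets))
  if (!is.na(x$velocity_rmse)) {
    cat(sprintf("  hold-out velocity RMSE: %.4g\n", x$velocity_rmse))
  }
  invisible(x)
}

#' One-step velocity prediction RMSE of a locomotion model
#'
#' For every step of every episode, the action is labeled by inverse dynamics
#' ([infer_actions()]), the next velocity predicted by the locomotion model,
#' and the squared error against the observed next velocity accumulated over
#' both components (2(T-1) terms per episode). Invariant to episode order and
#' concatenation.
#'
#' @param episodes list of [episode()] objects.
#' @param agent_index 1-based agent index.
#' @param params a [locomotion_params()].
#' @param noop_threshold_frac forwarded to [infer_actions()].
#' @return scalar root-mean-square error, normalized units/s.
#' @export
velocity_rmse <- function(episodes, agent_index, params,
                          noop_threshold_frac = 0.5) {
  if (length(episodes) == 0) stopf("no episodes supplied")
  units <- action_unit_vectors()
  sse <- 0
  n <- 0L
  for (ep in episodes) {
    lab <- infer_actions(ep, params, noop_threshold_frac = noop_threshold_frac)
    v <- matrix(ep$velocities[agent_index, , ], ncol = 2)
    Tn <- nrow(v)
    a <- units[lab$actions[agent_index, ] + 1L, , drop = FALSE]
    pred <- (1 - params$d) * v[-Tn, , drop = FALSE] + params$u * a * params$dt
    err <- pred - v[-1, , drop = FALSE]
    sse <- sse + sum(err^2)
    n <- n + length(err)
  }
  sqrt(sse / n)
}
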