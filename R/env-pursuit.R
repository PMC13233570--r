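#' Reset the pursuit-evasion environment
#'
#' @param config an [env_config()].
#' @param init_mode `"uniform"` (positions sampled uniformly from the square
#'   \[-0.5, 0.5\]^2, velocities zero) or `"from_episode"` (positions and
#'   velocities copied from frame 1 of a demonstration episode, which is also
#'   recorded as the DTW reference).
#' @param rng_or_episode for `"uniform"`, an integer seed or `NULL` to use the
#'   current RNG state; for `"from_episode"`, an [episode()].
#' @return An object of class `pursuit_state` with fields `positions` (K x 2),
#'   `velocities` (K x 2), `t` (step index, starting at 0), `done`,
#'   `done_reason`, `roles`, and `reference_id`.
#' @export
reset_pursuit <- function(config, init_mode = c("uniform", "from_episode"),
                          rng_or_episode = NULL) {
  init_mode <- match.arg(init_mode)
  K <- config$n_agents
  roles <- if (K == 1) "solo" else c(rep("chaser", K - 1), "target")
  if (init_mode == "uniform") {
    sample_pos <- function() matrix(stats::runif(K * 2, -0.5, 0.5), K, 2)
    pos <- if (is.null(rng_or_episode)) sample_pos() else {
      with_seed(rng_or_episode, sample_pos())
    }
    vel <- matrix(0, K, 2)
    ref <- NULL
  } else {
    ep <- rng_or_episode
    if (!inherits(ep, "episode")) {
      stopf("from_episode init requires an episode object")
    }
    if (episode_agents(ep) != K) {
      stopf("episode has %d agents but the environment expects %d",
            episode_agents(ep), K)
    }
    pos <- ep$positions[, 1, , drop = TRUE]
    vel <- ep$velocities[, 1, , drop = TRUE]
    if (K == 1) { pos <- matrix(pos, 1, 2); vel <- matrix(vel, 1, 2) }
    roles <- ep$roles
    ref <- ep$meta$id %||% NA_character_
  }
  structure(list(positions = pos, velocities = vel, t = 0L, done = FALSE,
                 done_reason = "ongoing", roles = roles, reference_id = ref),
            class = "pursuit_state")
}

#' @export
print.pursuit_state <- function(x, ...) {
  cat(sprintf("<pursuit_state> t = %d, done = %s (%s)\n", x$t, x$done,
              x$done_reason))
  invisible(x)
}

#' @noRd
out_of_bounds <- function(positions, config) {
  lim <- 1 + config$boundary_margin
  if (config$arena == "square") {
    apply(abs(positions), 1, max) > lim
  } else if (config$arena == "circle") {
    sqrt(rowSums(positions^2)) > lim
  } else {
    rep(FALSE, nrow(positions))
  }
}

#' Advance the pursuit environment by one joint step
#'
#' Kinematics are semi-implicit under the locomotion model: the velocity is
#' updated first (`v' = (1 - d) v + u a dt`) and the position then moves by
#' `v' dt`. Chaser-target contact (center distance <= `contact_radius`) ends
#' the episode with +1 to the touching chaser (to both chasers under the
#' shared scheme) and pays the target its elapsed-time reward; crossing the
#' virtual boundary ends the episode with `boundary_penalty` to the
#' transgressor; exceeding the time limit ends it with the target's
#' elapsed-time reward. Chaser-chaser contacts are ignored.
#'
#' @param state a [reset_pursuit()] state, not terminated.
#' @param joint_action integer vector of K actions in `0..12` (0 = no-op).
#' @param params a single [locomotion_params()] shared by all agents, or a
#'   list of one per agent.
#' @param config an [env_config()].
#' @return `list(state, rewards, done, info)`; `rewards` is a length-K numeric
#'   vector and `info$reason` one of `contact/boundary/time_limit/ongoing`.
#' @export
step_pursuit <- function(state, joint_action, params, config) {
  if (state$done) stopf("episode already terminated (%s)", state$done_reason)
  K <- config$n_agents
  if (length(joint_action) != K) stopf("joint_action must have %d entries", K)
  if (any(joint_action < 0 | joint_action > 12)) {
    stopf("actions must lie in 0..12")
  }
  if (inherits(params, "locomotion_params")) {
    params <- rep(list(params), K)
  }
  units <- action_unit_vectors()
  pos <- state$positions
  vel <- state$velocities
  for (k in seq_len(K)) {
    a <- units[joint_action[k] + 1L, ]
    vel[k, ] <- predict_next_velocity(vel[k, ], a, params[[k]])
    pos[k, ] <- pos[k, ] + vel[k, ] * params[[k]]$dt
  }
  t_next <- state$t + 1L
  elapsed <- t_next * config$dt
  rewards <- numeric(K)
  reason <- "ongoing"
  chasers <- which(state$roles == "chaser")
  target <- which(state$roles == "target")

  oob <- out_of_bounds(pos, config)
  touching <- integer(0)
  if (length(target) == 1 && length(chasers) > 0) {
    dist_to_target <- sqrt(rowSums((pos[chasers, , drop = FALSE] -
      matrix(pos[target, ], length(chasers), 2, byrow = TRUE))^2))
    touching <- chasers[dist_to_target <= config$contact_radius]
  }
  if (length(touching) > 0) {
    reason <- "contact"
    if (config$reward_scheme == "shared") {
      rewards[chasers] <- rewards[chasers] + 1
    } else {
      rewards[touching] <- rewards[touching] + 1
    }
    if (config$target_time_reward && length(target) == 1) {
      rewards[target] <- rewards[target] + elapsed
    }
  } else if (any(oob)) {
    reason <- "boundary"
    rewards[oob] <- rewards[oob] + config$boundary_penalty
  } else if (elapsed > config$time_limit) {
    reason <- "time_limit"
    if (config$target_time_reward && length(target) == 1) {
      rewards[target] <- rewards[target] + elapsed
    }
  }
  if (!config$target_time_reward && reason == "ongoing" &&
      length(target) == 1) {
    rewards[target] <- rewards[target] + config$dt
  }
  state$positions <- pos
  state$velocities <- vel
  state$t <- t_next
  state$done <- reason != "ongoing"
  state$done_reason <- reason
  list(state = state, rewards = rewards, done = state$done,
       info = list(reason = reason, touching = touching))
}

#' Build an agent's observation vector
#'
#' The observation concatenates the ego absolute position (2), optionally the
#' ego velocity (2, off by default), and for every other agent in ascending
#' index order the relative position (2) and relative velocity (2). When
#' `include_condition_cue` is `TRUE` the binary condition flag is appended as
#' the last entry.
#'
#' @param state a `pursuit_state`.
#' @param agent_index 1-based agent index.
#' @param config an [env_config()].
#' @param include_condition_cue append the condition flag.
#' @param condition the binary flag value to append.
#' @return numeric observation vector.
#' @export
build_observation <- function(state, agent_index, config,
                              include_condition_cue = FALSE, condition = 0) {
  K <- config$n_agents
  if (agent_index < 1 || agent_index > K) stopf("agent_index out of range")
  pos <- state$positions
  vel <- state$velocities
  obs <- pos[agent_index, ]
  if (config$include_ego_velocity) obs <- c(obs, vel[agent_index, ])
  for (j in setdiff(seq_len(K), agent_index)) {
    obs <- c(obs, pos[j, ] - pos[agent_index, ], vel[j, ] - vel[agent_index, ])
  }
  if (include_condition_cue) obs <- c(obs, as.numeric(condition))
  obs
}

#' Observation dimension implied by a configuration
#' @param config an [env_config()].
#' @param include_condition_cue whether the cue is appended.
#' @return integer length of [build_observation()] output.
#' @export
observation_dim <- function(config, include_condition_cue = FALSE) {
  2L + (if (config$include_ego_velocity) 2L else 0L) +
    4L * (config$n_agents - 1L) + (if (include_condition_cue) 1L else 0L)
}

#' Classify the termination status of a state
#'
#' @param state a `pursuit_state`.
#' @param config an [env_config()].
#' @return list with `reason` in `contact/boundary/time_limit/ongoing`.
#' @export
check_termination <- function(state, config) {
  if (state$done) return(list(reason = state$done_reason))
  chasers <- which(state$roles == "chaser")
  target <- which(state$roles == "target")
  if (length(target) == 1 && length(chasers) > 0) {
    d <- sqrt(rowSums((state$positions[chasers, , drop = FALSE] -
      matrix(state$positions[target, ], length(chasers), 2, byrow = TRUE))^2))
    if (any(d <= config$contact_radius)) return(list(reason = "contact"))
  }
  if (any(out_of_bounds(state$positions, config))) {
    return(list(reason = "boundary"))
  }
  if (state$t * config$dt > config$time_limit) {
    return(list(reason = "time_limit"))
  }
  list(reason = "ongoing")
}
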