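#' Generate synthetic demonstration datasets
#'
#' Emulates the deposited demonstration recordings: episodes start from rest
#' (zero velocity) at positions sampled uniformly from \[-0.5, 0.5\]^2,
#' every agent moves under the exact first-order locomotion dynamics
#' (`v' = (1 - d) v + u a dt`), and episodes end on chaser-target contact,
#' boundary crossing or the time limit. Four scripted policies are available:
#'
#' * `straight_pursuit`: chasers accelerate straight at the target; the
#'   target flees the nearest chaser while avoiding the boundary.
#' * `stop_and_go_pursuit`: as above, but agents insert geometric-length
#'   pauses (no-op actions), producing the low-velocity-dominant speed
#'   histograms characteristic of the animal recordings; the target wanders
#'   with a persistent random heading instead of fleeing.
#' * `random_walk`: every agent picks uniformly random actions.
#' * `moth_cast`: a single agent zigzags (casting) toward an odor source at
#'   the origin.
#'
#' When `condition_effect` is supplied, episodes alternate between conditions
#' 0 and 1 and the chaser policy changes under condition 1: its pause
#' probability is multiplied by `pause_scale` and its aim direction is rotated
#' by `aim_rotation` radians. Both mechanisms lengthen chaser paths, so the
#' condition flip has a known signed effect on mean path length.
#'
#' @param config an [env_config()]; use
#'   `species_env_config("agents", demo = TRUE)` for the 30 s
#'   demonstration-generation limit.
#' @param params a [locomotion_params()] or a list of one per agent. When a
#'   single object is given to a pursuit task, chasers use it as-is and the
#'   target's thrust amplitude is divided by
#'   `config$predator_mobility_factor` (predator mobility is 120% of the
#'   prey's by default, so pursuits terminate in contact); pass an explicit
#'   list to override.
#' @param policy_kind one of `"straight_pursuit"`, `"stop_and_go_pursuit"`,
#'   `"random_walk"`, `"moth_cast"`.
#' @param n_episodes number of episodes (>= 0).
#' @param condition_effect `NULL` for a single condition, or a list with
#'   `pause_scale` (default 1) and `aim_rotation` (radians, default 0).
#' @param paired_conditions when `TRUE` (two-condition datasets only),
#'   consecutive episodes 2i-1 and 2i share the same initial positions under
#'   conditions 0 and 1. Pairing makes the condition cue informative beyond
#'   the initial state — with unique initial states a policy can infer the
#'   whole reference episode from frame 0 and learn to ignore the cue.
#' @param seed integer seed; the same seed reproduces the dataset exactly.
#' @param policy_opts scripted-policy tuning knobs: `p_pause` (chaser pause
#'   start probability per step, default 0.12), `pause_continue` (geometric
#'   continuation probability, default 0.7), `target_p_pause` (default 0.25),
#'   `heading_switch` (target heading re-draw probability, default 0.15),
#'   `cast_angle` (radians, default 1.2) and `cast_switch` (default 0.25)
#'   for the moth; `flee_margin` (default 0.7) is how close to the arena
#'   half-width the target's boundary-averse policy will go (real prey keep
#'   away from walls rather than hugging them).
#' @param species_tag species label stored in the dataset.
#' @return A [demo_dataset()] with the true action labels in
#'   `meta$actions` of every episode.
#' @export
generate_synthetic_demos <- function(config, params,
                                     policy_kind = c("straight_pursuit",
                                                     "stop_and_go_pursuit",
                                                     "random_walk",
                                                     "moth_cast"),
                                     n_episodes,
                                     condition_effect = NULL,
                                     paired_conditions = FALSE,
                                     seed = 1L,
                                     policy_opts = list(),
                                     species_tag = "agents") {
  policy_kind <- match.arg(policy_kind)
  if (n_episodes < 0) stopf("n_episodes must be >= 0")
  K <- config$n_agents
  if (inherits(params, "locomotion_params")) {
    prey <- locomotion_params(params$d,
                              params$u / config$predator_mobility_factor,
                              params$dt)
    params <- c(rep(list(params), max(K - 1L, 1L)),
                if (K > 1) list(prey))
  }
  if (length(params) != K) stopf("need one locomotion_params per agent")
  opts <- utils::modifyList(
    list(p_pause = 0.12, pause_continue = 0.7, target_p_pause = 0.25,
         heading_switch = 0.15, cast_angle = 1.2, cast_switch = 0.25,
         flee_margin = 0.7),
    policy_opts)
  eff <- if (is.null(condition_effect)) NULL else {
    utils::modifyList(list(pause_scale = 1, aim_rotation = 0),
                      condition_effect)
  }
  conditions <- if (is.null(eff)) rep(0L, n_episodes) else {
    rep(c(0L, 1L), length.out = n_episodes)
  }
  if (paired_conditions && is.null(eff)) {
    stopf("paired_conditions requires a condition_effect")
  }
  eps <- with_seed(seed, {
    inits <- if (paired_conditions) {
      lapply(seq_len(ceiling(n_episodes / 2)), function(i) {
        matrix(stats::runif(K * 2, -0.5, 0.5), K, 2)
      })
    } else NULL
    lapply(seq_len(n_episodes), function(i) {
      generate_one_episode(config, params, policy_kind, conditions[i], eff,
                           opts, id = sprintf("ep_%04d", i),
                           init_pos = if (paired_conditions) {
                             inits[[ceiling(i / 2)]]
                           } else NULL)
    })
  })
  demo_dataset(eps, hz = 1 / config$dt, species_tag = species_tag)
}

# choose the directional action (1..12, 0-based labels) closest to `aim`
#' @noRd
quantize_direction <- function(aim) {
  units <- action_unit_vectors()[-1, , drop = FALSE]
  which.max(units %*% aim)  # 0-based action label = this index (1..12)
}

#' @noRd
rotate2 <- function(v, theta) {
  c(cos(theta) * v[1] - sin(theta) * v[2],
    sin(theta) * v[1] + cos(theta) * v[2])
}

# boundary-aware flee/wander direction: score candidate directions by
# alignment with `want`, heavily penalizing headings whose projected position
# leaves the safe interior of the arena
#' @noRd
safe_direction <- function(pos, want, config, vel = c(0, 0),
                           lookahead = 0.15, margin = 0.9) {
  units <- action_unit_vectors()[-1, , drop = FALSE]
  proj <- sweep(units * lookahead, 2, pos + vel * 0.3, "+")
  viol <- if (config$arena == "circle") {
    pmax(sqrt(rowSums(proj^2)) - margin, 0)
  } else if (config$arena == "square") {
    pmax(apply(abs(proj), 1, max) - margin, 0)
  } else {
    rep(0, 12)
  }
  nw <- sqrt(sum(want^2))
  align <- if (nw > 0) units %*% (want / nw) else rep(0, 12)
  which.max(align - 20 * viol)
}

#' @noRd
generate_one_episode <- function(config, params, policy_kind, condition, eff,
                                 opts, id, init_pos = NULL) {
  K <- config$n_agents
  dt <- config$dt
  roles <- if (K == 1) "solo" else c(rep("chaser", K - 1), "target")
  max_steps <- ceiling(config$time_limit / dt) + 1L

  pos <- init_pos %||% matrix(stats::runif(K * 2, -0.5, 0.5), K, 2)
  if (policy_kind == "moth_cast") {
    while (sqrt(sum(pos[1, ]^2)) < 0.3) {
      pos <- matrix(stats::runif(2, -0.5, 0.5), 1, 2)
    }
  }
  state <- structure(list(positions = pos, velocities = matrix(0, K, 2),
                          t = 0L, done = FALSE, done_reason = "ongoing",
                          roles = roles, reference_id = NULL),
                     class = "pursuit_state")

  # chaser condition-dependent knobs
  p_pause <- opts$p_pause
  aim_rot <- 0
  if (!is.null(eff) && condition == 1L) {
    p_pause <- min(1, p_pause * eff$pause_scale)
    aim_rot <- eff$aim_rotation
  }

  paused <- rep(FALSE, K)
  heading <- sample.int(12, K, replace = TRUE)    # persistent wander heading
  cast_sign <- sample(c(-1, 1), 1)

  positions <- array(NA_real_, c(K, max_steps + 1L, 2))
  velocities <- array(0, c(K, max_steps + 1L, 2))
  actions <- matrix(NA_integer_, K, max_steps)
  positions[, 1, ] <- state$positions
  events <- list()

  target <- if (K > 1) K else NA_integer_
  chasers <- if (K > 1) seq_len(K - 1) else integer(0)

  step_i <- 0L
  while (!state$done && step_i < max_steps) {
    step_i <- step_i + 1L
    act <- integer(K)
    for (k in seq_len(K)) {
      if (policy_kind == "random_walk") {
        act[k] <- sample.int(13, 1) - 1L
        next
      }
      if (policy_kind == "moth_cast") {
        if (stats::runif(1) < opts$cast_switch) cast_sign <- -cast_sign
        if (stats::runif(1) < p_pause) { act[k] <- 0L; next }
        to_src <- -state$positions[1, ]
        aim <- rotate2(to_src, cast_sign * opts$cast_angle)
        act[k] <- quantize_direction(aim)
        next
      }
      is_chaser <- k %in% chasers
      pp <- if (is_chaser) p_pause else opts$target_p_pause
      if (policy_kind == "stop_and_go_pursuit") {
        if (paused[k]) {
          paused[k] <- stats::runif(1) < opts$pause_continue
        } else {
          paused[k] <- stats::runif(1) < pp
        }
        if (paused[k]) { act[k] <- 0L; next }
      }
      if (is_chaser) {
        aim <- state$positions[target, ] - state$positions[k, ]
        if (aim_rot != 0) aim <- rotate2(aim, aim_rot)
        act[k] <- safe_direction(state$positions[k, ], aim, config,
                                 vel = state$velocities[k, ])
      } else if (policy_kind == "straight_pursuit") {
        d2 <- rowSums((state$positions[chasers, , drop = FALSE] -
          matrix(state$positions[k, ], length(chasers), 2, byrow = TRUE))^2)
        flee <- state$positions[k, ] - state$positions[chasers[which.min(d2)], ]
        act[k] <- safe_direction(state$positions[k, ], flee, config,
                                 vel = state$velocities[k, ],
                                 margin = opts$flee_margin)
      } else {
        if (stats::runif(1) < opts$heading_switch) {
          heading[k] <- sample.int(12, 1)
        }
        units <- action_unit_vectors()[-1, , drop = FALSE]
        act[k] <- safe_direction(state$positions[k, ], units[heading[k], ],
                                 config, vel = state$velocities[k, ],
                                 margin = opts$flee_margin)
        heading[k] <- act[k]
      }
    }

    if (policy_kind == "moth_cast") {
      a <- action_unit_vectors()[act[1] + 1L, ]
      state$velocities[1, ] <- predict_next_velocity(state$velocities[1, ], a,
                                                     params[[1]])
      state$positions[1, ] <- state$positions[1, ] +
        state$velocities[1, ] * dt
      state$t <- state$t + 1L
      rewards <- 0
      if (sqrt(sum(state$positions[1, ]^2)) <= config$contact_radius) {
        state$done <- TRUE; state$done_reason <- "contact"; rewards <- 1
      } else if (state$t * dt > config$time_limit) {
        state$done <- TRUE; state$done_reason <- "time_limit"
      }
      res <- list(state = state, rewards = rewards)
    } else {
      res <- step_pursuit(state, act, params, config)
      state <- res$state
    }
    frame <- step_i + 1L
    positions[, frame, ] <- state$positions
    velocities[, frame, ] <- state$velocities
    actions[, step_i] <- act
    nz <- which(res$rewards != 0)
    for (k in nz) {
      events[[length(events) + 1L]] <-
        data.frame(t = frame, agent = k, value = res$rewards[k])
    }
  }

  Tn <- step_i + 1L
  reward_events <- if (length(events) > 0) do.call(rbind, events) else NULL
  # terminal boundary-crossing frames may overshoot the virtual boundary by
  # up to one step at the speed cap
  overshoot <- max(vapply(params, function(p) {
    (p$u * p$dt / max(p$d, 1e-6) + p$u * p$dt) * dt
  }, numeric(1)))
  episode(boundary_limit = 1 + config$boundary_margin + overshoot,
          times = (seq_len(Tn) - 1) * dt,
          positions = positions[, seq_len(Tn), , drop = FALSE],
          velocities = velocities[, seq_len(Tn), , drop = FALSE],
          roles = roles, condition = condition,
          reward_events = reward_events,
          meta = list(id = id, source = "synthetic",
                      policy_kind = policy_kind,
                      actions = actions[, seq_len(Tn - 1L), drop = FALSE],
                      end_reason = state$done_reason))
}
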