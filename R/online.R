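# Online fine-tuning in the simulated environment, and greedy/epsilon rollouts
# used for evaluation. Rollouts are seeded from a demonstration episode: the
# learning agents act from their own networks while the remaining agents
# replay the demonstrated trajectories (and hold their final position once
# the demonstration ends).

#' @noRd
frozen_frame <- function(ep, t) {
  Tn <- episode_length(ep)
  K <- episode_agents(ep)
  if (t <= Tn) {
    list(pos = matrix(ep$positions[, t, ], K, 2),
         vel = matrix(ep$velocities[, t, ], K, 2))
  } else {
    list(pos = matrix(ep$positions[, Tn, ], K, 2),
         vel = matrix(0, K, 2))
  }
}

# advance the mixed world (learning agents act, others replay `ref`) by one
# step; returns the new state, per-agent touch/boundary rewards and the
# termination reason
#' @noRd
mixed_step <- function(state, actions0, bundle, ref, t_next) {
  config <- bundle$config
  K <- config$n_agents
  units <- action_unit_vectors()
  pos <- state$positions
  vel <- state$velocities
  learn <- bundle$learn_agents
  fr <- frozen_frame(ref, t_next + 1L)  # frame index of the new step
  for (k in seq_len(K)) {
    if (k %in% learn) {
      a <- units[actions0[[match(k, learn)]] + 1L, ]
      vel[k, ] <- predict_next_velocity(vel[k, ], a, bundle$params[[k]])
      pos[k, ] <- pos[k, ] + vel[k, ] * bundle$params[[k]]$dt
    } else {
      pos[k, ] <- fr$pos[k, ]
      vel[k, ] <- fr$vel[k, ]
    }
  }
  elapsed <- (t_next) * config$dt
  rewards <- numeric(K)
  reason <- "ongoing"
  chasers <- which(state$roles == "chaser")
  target <- which(state$roles == "target")
  touching <- integer(0)
  if (length(target) == 1 && length(chasers) > 0) {
    d <- sqrt(rowSums((pos[chasers, , drop = FALSE] -
      matrix(pos[target, ], length(chasers), 2, byrow = TRUE))^2))
    touching <- chasers[d <= config$contact_radius]
  }
  oob <- out_of_bounds(pos, config)
  if (length(touching) > 0) {
    reason <- "contact"
    if (config$reward_scheme == "shared") rewards[chasers] <- 1 else {
      rewards[touching] <- 1
    }
    if (config$target_time_reward && length(target) == 1) {
      rewards[target] <- rewards[target] + elapsed
    }
  } else if (any(oob)) {
    reason <- "boundary"
    rewards[oob] <- config$boundary_penalty
  } else if (elapsed > config$time_limit) {
    reason <- "time_limit"
    if (config$target_time_reward && length(target) == 1) {
      rewards[target] <- rewards[target] + elapsed
    }
  }
  state$positions <- pos
  state$velocities <- vel
  state$t <- t_next
  state$done <- reason != "ongoing"
  state$done_reason <- reason
  list(state = state, rewards = rewards, reason = reason,
       touching = touching)
}

# Thread hidden states of several stored observation sequences jointly with
# the current network (rows = sequences, stepped through time together);
# returns a list of (T_i + 1) x hidden matrices (hidden after each frame).
#' @noRd
thread_hidden <- function(net, obs_list) {
  n <- length(obs_list)
  lens <- vapply(obs_list, nrow, integer(1))
  H <- matrix(0, n, net$hidden)
  out <- lapply(lens, function(Tn) matrix(0, Tn, net$hidden))
  for (t in seq_len(max(lens))) {
    act <- which(lens >= t)
    X <- do.call(rbind, lapply(act, function(i) obs_list[[i]][t, ]))
    st <- qnet_step(net, X, H[act, , drop = FALSE], keep_cache = FALSE)
    H[act, ] <- st$H
    for (j in seq_along(act)) out[[act[j]]][t, ] <- st$H[j, ]
  }
  out
}

# One sequence-replay update: sample n_seq stored episodes (probability
# proportional to priority^per_alpha), recompute their hidden states with the
# current online network, and take a single one-step double-Q gradient step
# over all their transitions. Returns new priorities (mean |TD| per episode).
#' @noRd
sequence_update <- function(net, target, ebuf, lcfg, opt, lr, n_seq,
                            per_alpha, beta) {
  n <- length(ebuf$eps)
  p <- ebuf$prio[seq_len(n)]^per_alpha
  p <- p / sum(p)
  idx <- sample.int(n, min(n_seq, n), replace = TRUE, prob = p)
  eps <- ebuf$eps[idx]
  hs <- thread_hidden(net, lapply(eps, `[[`, "obs"))
  rows <- lapply(seq_along(eps), function(j) {
    e <- eps[[j]]
    Tn <- length(e$act)
    h <- hs[[j]]
    list(obs = e$obs[seq_len(Tn), , drop = FALSE],
         next_obs = e$obs[2:(Tn + 1L), , drop = FALSE],
         h_prev = rbind(matrix(0, 1, ncol(h)),
                        h[seq_len(Tn - 1L), , drop = FALSE]),
         h_next = h[seq_len(Tn), , drop = FALSE])
  })
  w <- (n * p[idx])^(-beta)
  w <- w / max(w)
  lens <- vapply(eps, function(e) length(e$act), integer(1))
  batch <- list(obs = do.call(rbind, lapply(rows, `[[`, "obs")),
                next_obs = do.call(rbind, lapply(rows, `[[`, "next_obs")),
                h_prev = do.call(rbind, lapply(rows, `[[`, "h_prev")),
                h_next = do.call(rbind, lapply(rows, `[[`, "h_next")),
                action = unlist(lapply(eps, `[[`, "act")),
                reward = unlist(lapply(eps, `[[`, "rew")),
                done = unlist(lapply(eps, `[[`, "done")),
                condition = unlist(lapply(eps, function(e) {
                  rep(e$cond, length(e$act))
                })),
                expert_action = unlist(lapply(eps, `[[`, "expert")),
                weights = rep(w, lens))
  up <- update_step(net, target, batch, lcfg, opt, lr)
  if (!is.null(up$new_prio)) {
    td_by_ep <- split(up$new_prio, rep(seq_along(eps), lens))
    ebuf$prio[idx] <- vapply(td_by_ep, mean, numeric(1))
  }
  up
}

#' Online fine-tuning (or training from scratch) in the pursuit environment
#'
#' Loops episodes: the world is reset from the initial state of a training
#' demonstration episode, learning agents act epsilon-greedily from their own
#' networks with the recurrent hidden state threaded across the episode
#' (non-learning agents replay the demonstration), and per-step rewards are
#' shaped incrementally against the reference trajectory. Completed episodes
#' enter a sequence replay buffer; every `update_every` environment steps a
#' prioritized sample of stored episodes is re-threaded with the current
#' network (so hidden states are never stale) and a one-step double-Q
#' gradient update runs over all their transitions, with periodic target
#' synchronization. The exploration rate follows a linear schedule over the
#' first `schedule$decay_steps` environment steps.
#'
#' @param bundle a [policy_bundle()] (pre-trained or fresh).
#' @param demos reference demonstrations (a [demo_dataset()] restricted to
#'   the training split, or a list of episodes).
#' @param lcfg a [loss_config()]; `alpha` weighs the DTW penalty (ignored for
#'   `dqn`, which sees the unshaped reward).
#' @param budget total environment steps (> 0).
#' @param schedule an [exploration_schedule()].
#' @param lr learning rate; decays linearly to `lr_final_frac * lr` over the
#'   budget.
#' @param n_seq episodes re-threaded per update.
#' @param buffer_capacity episode capacity of the sequence replay buffer.
#' @param target_sync target-network synchronization period, in updates.
#' @param update_every environment steps between updates.
#' @param warmup episodes collected before updates start.
#' @param per_alpha episode-priority exponent (priority = mean |TD error|);
#'   the importance-sampling exponent anneals from `per_beta0` to 1.
#' @param per_beta0 initial importance-sampling exponent.
#' @param lr_final_frac final learning-rate fraction (1 = constant).
#' @param reward_clip length-2 clipping range applied to rewards inside the
#'   TD loss (standard value-learning conditioning: the -10 boundary penalty
#'   would otherwise dominate the small per-step action-value differences);
#'   `NULL` disables clipping. Logged returns are unclipped.
#' @param eval_refs optional validation episodes for checkpoint selection:
#'   every `eval_every` steps the current policy is rolled out greedily from
#'   each and scored by the method's own shaped objective (touch return minus
#'   `alpha` times the final DTW cost; `alpha = 0` effect for `dqn`), and the
#'   best-scoring parameters are returned. Deep value learning at desk scale
#'   is not monotone, so model selection on held-out references replaces the
#'   final iterate.
#' @param eval_every steps between validation evaluations (default
#'   `budget / 10`).
#' @param retain_demos seed the sequence replay buffer with the reference
#'   demonstrations themselves (their DTW penalty against themselves is
#'   zero, so they carry the plain touch reward). Keeping expert episodes in
#'   replay propagates the value of the demonstrated paths without requiring
#'   epsilon-greedy exploration to rediscover them.
#' @param seed integer seed (environment sampling, exploration, replay).
#' @return the trained bundle with attribute `train_log` (one row per
#'   episode: steps, touch return, shaped return, epsilon, end reason) and,
#'   when `eval_refs` is given, `eval_log`.
#' @export
finetune_online <- function(bundle, demos, lcfg = loss_config(bundle$method),
                            budget = 2e4, schedule = exploration_schedule(),
                            lr = 1e-3, n_seq = 4L,
                            buffer_capacity = 400L, target_sync = 100L,
                            update_every = 8L, warmup = 10L,
                            per_alpha = 0.6, per_beta0 = 0.4,
                            lr_final_frac = 0.1,
                            reward_clip = c(-1, 1), eval_refs = NULL,
                            eval_every = NULL, retain_demos = TRUE,
                            seed = 1L) {
  episodes <- if (inherits(demos, "demo_dataset")) demos$episodes else demos
  if (length(episodes) == 0) stopf("no reference episodes")
  if (budget <= 0) stopf("budget must be positive")
  config <- bundle$config
  nA <- length(bundle$learn_agents)
  ebufs <- lapply(seq_len(nA), function(i) {
    e <- new.env(parent = baseenv())
    e$eps <- list()
    e$prio <- numeric(buffer_capacity)
    e$pos <- 0L
    e$base <- 0L
    e
  })
  opts <- lapply(seq_len(nA), function(i) adam_init(bundle$nets[[i]]))
  if (retain_demos) {
    for (i in seq_len(nA)) {
      k <- bundle$learn_agents[i]
      for (ep in episodes) {
        acts <- ep$meta$actions
        if (is.null(acts)) {
          acts <- infer_actions(ep, bundle$params[[k]])$actions
        }
        touch <- episode_touch_rewards(ep, k)
        if (!is.null(reward_clip)) {
          touch <- pmin(pmax(touch, reward_clip[1]), reward_clip[2])
        }
        Tn <- episode_length(ep)
        slot <- ebufs[[i]]$pos %% buffer_capacity + 1L
        ebufs[[i]]$eps[[slot]] <- list(
          obs = episode_observations(ep, k, config, bundle$include_cue),
          act = acts[k, ], rew = touch,
          done = c(rep(FALSE, Tn - 2L), TRUE), cond = ep$condition,
          expert = acts[k, ])
        ebufs[[i]]$prio[slot] <- 1
        ebufs[[i]]$pos <- ebufs[[i]]$pos + 1L
      }
      # demonstration slots are permanent (DQfD-style); collected episodes
      # cycle through the remaining capacity
      ebufs[[i]]$base <- ebufs[[i]]$pos
      ebufs[[i]]$pos <- 0L
    }
  }
  updates <- 0L
  step_count <- 0L
  log_rows <- list()
  max_steps_ep <- ceiling(config$time_limit / config$dt)
  D <- bundle$obs_dim
  if (is.null(eval_every)) eval_every <- max(1L, floor(budget / 10))
  next_eval <- eval_every
  best_score <- -Inf
  best_nets <- NULL
  eval_log <- list()
  score_bundle <- function() {
    mean(vapply(eval_refs, function(ref) {
      ro <- rollout_policy(bundle, ref, epsilon = 0)
      sum(ro$touch[bundle$learn_agents]) -
        lcfg$alpha * (if (lcfg$method == "dqn") 0 else {
          mean(ro$dtw_final, na.rm = TRUE)
        })
    }, numeric(1)))
  }

  with_seed(seed, {
    while (step_count < budget) {
      ref <- episodes[[sample.int(length(episodes), 1)]]
      state <- reset_pursuit(config, "from_episode", ref)
      cond <- ref$condition
      h <- lapply(seq_len(nA), function(i) matrix(0, 1, bundle$hidden))
      run <- lapply(seq_len(nA), function(i) NULL)   # incremental DTW
      ref_pos <- lapply(bundle$learn_agents, function(k) {
        matrix(ref$positions[k, , ], ncol = 2)
      })
      ref_act <- ref$meta$actions
      if (is.null(ref_act) && lcfg$method == "dqaas") {
        ref_act <- do.call(rbind, lapply(seq_len(config$n_agents), function(k) {
          infer_actions(ref, bundle$params[[k]])$actions[k, ]
        }))
      }
      obs <- lapply(seq_len(nA), function(i) {
        build_observation(state, bundle$learn_agents[i], config,
                          bundle$include_cue, cond)
      })
      # per-episode transition storage, one block per learning agent
      OB <- lapply(seq_len(nA), function(i) {
        m <- matrix(NA_real_, max_steps_ep + 1L, D)
        m[1, ] <- obs[[i]]
        m
      })
      AC <- matrix(NA_integer_, nA, max_steps_ep)
      RW <- matrix(NA_real_, nA, max_steps_ep)
      EA <- matrix(NA_integer_, nA, max_steps_ep)
      ep_touch <- 0
      ep_shaped <- 0
      eps_now <- epsilon_at(schedule, step_count)
      t_ep <- 0L
      while (!state$done && t_ep < max_steps_ep && step_count < budget) {
        eps_now <- epsilon_at(schedule, step_count)
        acts <- integer(nA)
        for (i in seq_len(nA)) {
          st <- qnet_step(bundle$nets[[i]], matrix(obs[[i]], 1), h[[i]],
                          keep_cache = FALSE)
          h[[i]] <- st$H
          acts[i] <- greedy_action(as.numeric(st$Q), eps_now)
        }
        t_ep <- t_ep + 1L
        res <- mixed_step(state, as.list(acts), bundle, ref, t_ep)
        state <- res$state
        step_count <- step_count + 1L
        for (i in seq_len(nA)) {
          k <- bundle$learn_agents[i]
          run[[i]] <- incremental_dtw(state$positions[k, ], run[[i]],
                                      ref_pos[[i]])
          touch <- res$rewards[k]
          r <- if (lcfg$method == "dqn") touch else {
            shaped_reward(touch, run[[i]]$penalty, lcfg$alpha)
          }
          if (!is.null(reward_clip)) {
            r <- min(max(r, reward_clip[1]), reward_clip[2])
          }
          obs[[i]] <- build_observation(state, k, config, bundle$include_cue,
                                        cond)
          OB[[i]][t_ep + 1L, ] <- obs[[i]]
          AC[i, t_ep] <- acts[i]
          RW[i, t_ep] <- r
          if (lcfg$method %in% c("dqaas", "bc") && !is.null(ref_act)) {
            jstar <- which.min(run[[i]]$rows[[run[[i]]$n]])
            EA[i, t_ep] <- ref_act[k, min(jstar, ncol(ref_act))]
          }
          ep_touch <- ep_touch + touch
          ep_shaped <- ep_shaped + r
        }
        if (step_count %% update_every == 0L &&
            length(ebufs[[1]]$eps) >= warmup) {
          beta <- per_beta0 + (1 - per_beta0) * min(1, step_count / budget)
          lr_now <- lr * (1 - (1 - lr_final_frac) *
                            min(1, step_count / budget))
          for (i in seq_len(nA)) {
            up <- sequence_update(bundle$nets[[i]], bundle$target_nets[[i]],
                                  ebufs[[i]], lcfg, opts[[i]], lr_now,
                                  n_seq, per_alpha, beta)
            bundle$nets[[i]] <- up$net
            opts[[i]] <- up$opt
          }
          updates <- updates + 1L
          if (updates %% target_sync == 0L) {
            bundle$target_nets <- bundle$nets
          }
        }
      }
      if (t_ep > 0L) {
        done_vec <- c(rep(FALSE, t_ep - 1L), state$done)
        for (i in seq_len(nA)) {
          room <- buffer_capacity - ebufs[[i]]$base
          slot <- ebufs[[i]]$base + ebufs[[i]]$pos %% room + 1L
          ebufs[[i]]$eps[[slot]] <- list(
            obs = OB[[i]][seq_len(t_ep + 1L), , drop = FALSE],
            act = AC[i, seq_len(t_ep)], rew = RW[i, seq_len(t_ep)],
            done = done_vec, cond = cond, expert = EA[i, seq_len(t_ep)])
          ebufs[[i]]$prio[slot] <- max(ebufs[[i]]$prio[
            seq_along(ebufs[[i]]$eps)], 1e-3)
          ebufs[[i]]$pos <- ebufs[[i]]$pos + 1L
        }
      }
      log_rows[[length(log_rows) + 1L]] <- data.frame(
        steps = t_ep, touch_return = ep_touch, shaped_return = ep_shaped,
        epsilon = eps_now, reason = state$done_reason,
        total_steps = step_count)
      if (!is.null(eval_refs) && step_count >= next_eval) {
        sc <- score_bundle()
        eval_log[[length(eval_log) + 1L]] <- data.frame(
          total_steps = step_count, score = sc)
        if (sc >= best_score) {
          best_score <- sc
          best_nets <- bundle$nets
        }
        next_eval <- next_eval + eval_every
      }
    }
    if (!is.null(eval_refs)) {
      sc <- score_bundle()
      eval_log[[length(eval_log) + 1L]] <- data.frame(
        total_steps = step_count, score = sc)
      if (sc >= best_score) {
        best_score <- sc
        best_nets <- bundle$nets
      }
    }
  })
  if (!is.null(best_nets)) {
    bundle$nets <- best_nets
    bundle$target_nets <- best_nets
  }
  attr(bundle, "train_log") <- do.call(rbind, log_rows)
  if (length(eval_log) > 0) {
    attr(bundle, "eval_log") <- do.call(rbind, eval_log)
  }
  bundle
}

#' Roll out a trained policy from a demonstration's initial state
#'
#' Learning agents act from their networks (epsilon-greedy, or greedy at
#' `epsilon = 0`); the remaining agents replay the reference episode. The
#' rollout terminates on contact, boundary crossing or the configured time
#' limit.
#'
#' @param bundle a [policy_bundle()].
#' @param ref a reference [episode()] supplying the initial state, the
#'   replayed agents and the condition cue.
#' @param epsilon exploration rate during the rollout.
#' @param flip_cue present the opposite condition cue to the networks
#'   (counterfactual query); the replayed agents are unchanged.
#' @param seed optional integer seed (exploration noise reproducibility).
#' @return list of class `rollout` with the simulated `episode`, per-agent
#'   `touch` rewards, `reason`, `steps` and the DTW penalties accumulated
#'   against the reference.
#' @export
rollout_policy <- function(bundle, ref, epsilon = 0, flip_cue = FALSE,
                           seed = NULL) {
  config <- bundle$config
  K <- config$n_agents
  nA <- length(bundle$learn_agents)
  cond_true <- ref$condition
  cond_cue <- if (flip_cue) 1L - cond_true else cond_true
  max_steps <- ceiling(config$time_limit / config$dt)
  run_rollout <- function() {
    state <- reset_pursuit(config, "from_episode", ref)
    h <- lapply(seq_len(nA), function(i) matrix(0, 1, bundle$hidden))
    run <- lapply(seq_len(nA), function(i) NULL)
    ref_pos <- lapply(bundle$learn_agents, function(k) {
      matrix(ref$positions[k, , ], ncol = 2)
    })
    obs <- lapply(seq_len(nA), function(i) {
      build_observation(state, bundle$learn_agents[i], config,
                        bundle$include_cue, cond_cue)
    })
    positions <- array(NA_real_, c(K, max_steps + 1L, 2))
    velocities <- array(0, c(K, max_steps + 1L, 2))
    positions[, 1, ] <- state$positions
    velocities[, 1, ] <- state$velocities
    touch <- numeric(K)
    t_ep <- 0L
    while (!state$done && t_ep < max_steps) {
      acts <- integer(nA)
      for (i in seq_len(nA)) {
        st <- qnet_step(bundle$nets[[i]], matrix(obs[[i]], 1), h[[i]],
                        keep_cache = FALSE)
        h[[i]] <- st$H
        acts[i] <- greedy_action(as.numeric(st$Q), epsilon)
      }
      t_ep <- t_ep + 1L
      res <- mixed_step(state, as.list(acts), bundle, ref, t_ep)
      state <- res$state
      positions[, t_ep + 1L, ] <- state$positions
      velocities[, t_ep + 1L, ] <- state$velocities
      touch <- touch + res$rewards
      for (i in seq_len(nA)) {
        k <- bundle$learn_agents[i]
        run[[i]] <- incremental_dtw(state$positions[k, ], run[[i]],
                                    ref_pos[[i]])
        obs[[i]] <- build_observation(state, k, config, bundle$include_cue,
                                      cond_cue)
      }
    }
    Tn <- t_ep + 1L
    sim_ep <- episode(times = (seq_len(Tn) - 1) * config$dt,
                      positions = positions[, seq_len(Tn), , drop = FALSE],
                      velocities = velocities[, seq_len(Tn), , drop = FALSE],
                      roles = state$roles, condition = cond_true,
                      meta = list(id = paste0("rollout_", ref$meta$id %||% "x"),
                                  source = "rollout", cue = cond_cue),
                      validate = FALSE)
    structure(list(episode = sim_ep, touch = touch, reason = state$done_reason,
                   steps = t_ep,
                   dtw_final = vapply(run, function(r) {
                     if (is.null(r)) NA_real_ else r$rows[[r$n]][nrow(r$expert)]
                   }, numeric(1))),
              class = "rollout")
  }
  if (is.null(seed)) run_rollout() else with_seed(seed, run_rollout())
}
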