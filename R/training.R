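#' Loss and method configuration
#'
#' Bundles the discount and loss weights shared by the method variants:
#' `dqn` (double-Q TD loss on the unshaped reward), `bc` (behavioral cloning,
#' action cross-entropy only), `dqaas` (TD + DTW-aligned action supervision),
#' `dqdil` (TD on the DTW-shaped reward) and `dqcil` (`dqdil` plus the
#' adversarial treatment head).
#'
#' @param method one of `"dqn"`, `"bc"`, `"dqaas"`, `"dqdil"`, `"dqcil"`.
#' @param gamma discount factor in (0, 1\].
#' @param lambda1 l2 regularization weight (default 1e-5).
#' @param lambda2 treatment-loss weight (counterfactual variant).
#' @param lambda3 action-supervision weight (`dqaas`).
#' @param alpha DTW pseudo-reward weight.
#' @return list of class `loss_config`.
#' @export
loss_config <- function(method = c("dqdil", "dqcil", "dqaas", "bc", "dqn"),
                        gamma = 0.99, lambda1 = 1e-5, lambda2 = 10,
                        lambda3 = 50, alpha = 10) {
  method <- match.arg(method)
  if (gamma <= 0 || gamma > 1) stopf("gamma must lie in (0, 1]")
  if (any(c(lambda1, lambda2, lambda3, alpha) < 0)) {
    stopf("loss weights must be nonnegative")
  }
  structure(list(method = method, gamma = gamma, lambda1 = lambda1,
                 lambda2 = lambda2, lambda3 = lambda3, alpha = alpha),
            class = "loss_config")
}

#' Linear exploration schedule
#'
#' @param eps_start initial exploration rate.
#' @param eps_finish rate after the decay horizon (constant thereafter).
#' @param eps_test evaluation-time rate.
#' @param decay_steps environment steps over which the rate decays linearly.
#' @return list of class `exploration_schedule`.
#' @export
exploration_schedule <- function(eps_start = 0.1, eps_finish = 0.1,
                                 eps_test = 0.1, decay_steps = 5e4) {
  stopifnot(all(c(eps_start, eps_finish, eps_test) >= 0),
            all(c(eps_start, eps_finish, eps_test) <= 1))
  structure(list(eps_start = eps_start, eps_finish = eps_finish,
                 eps_test = eps_test, decay_steps = decay_steps),
            class = "exploration_schedule")
}

#' @rdname exploration_schedule
#' @param schedule an `exploration_schedule`.
#' @param step 0-based environment step count.
#' @export
epsilon_at <- function(schedule, step) {
  f <- min(1, step / schedule$decay_steps)
  schedule$eps_start + f * (schedule$eps_finish - schedule$eps_start)
}

# ---------------------------------------------------------------------------
# losses

#' Double Q-learning temporal-difference loss
#'
#' Per transition, the online network picks the best next action
#' `a_max = argmax_a Q_online(s', a)` and the target network evaluates it:
#' `y = R + gamma * Q_target(s', a_max)` (no bootstrap at terminal
#' transitions). The loss is the importance-weighted mean squared TD error.
#'
#' @param batch list with `obs` (`B x D`), `action` (0-based), `reward`,
#'   `next_obs`, `done`, optionally `h_prev`, `h_next` (`B x hidden`, zeros
#'   when missing) and `weights` (importance weights, 1 when missing).
#' @param online,target [qnet_init()] networks (synchronized copies).
#' @param gamma discount factor.
#' @return list with `loss` (scalar), `td_error` (length B) and internals
#'   used by the training loop (`dQ`, `cache`).
#' @export
double_q_loss <- function(batch, online, target, gamma) {
  B <- nrow(batch$obs)
  H <- online$hidden
  h_prev <- batch$h_prev %||% matrix(0, B, H)
  h_next <- batch$h_next %||% matrix(0, B, H)
  w <- batch$weights %||% rep(1, B)
  fwd_next_on <- qnet_step(online, batch$next_obs, h_next, keep_cache = FALSE)
  a_max <- max.col(fwd_next_on$Q, ties.method = "first")
  fwd_next_tg <- qnet_step(target, batch$next_obs, h_next, keep_cache = FALSE)
  boot <- fwd_next_tg$Q[cbind(seq_len(B), a_max)]
  y <- batch$reward + gamma * ifelse(batch$done, 0, boot)
  fwd <- qnet_step(online, batch$obs, h_prev, keep_cache = TRUE)
  qsa <- fwd$Q[cbind(seq_len(B), batch$action + 1L)]
  td <- qsa - y
  loss <- mean(w * td^2)
  dQ <- matrix(0, B, online$n_actions)
  dQ[cbind(seq_len(B), batch$action + 1L)] <- 2 * w * td / B
  list(loss = loss, td_error = td, dQ = dQ, cache = fwd$cache, Q = fwd$Q,
       H = fwd$H)
}

#' Treatment-prediction cross-entropy loss
#'
#' `-[c log c_hat + (1 - c) log(1 - c_hat)]`, averaged over the batch;
#' finite because predictions are clipped away from 0 and 1.
#'
#' @param chat predicted condition probabilities in (0, 1).
#' @param c binary condition labels.
#' @return scalar mean cross-entropy.
#' @export
treatment_loss <- function(chat, c) {
  stopifnot(all(chat > 0 & chat < 1), all(c %in% c(0, 1)))
  mean(-(c * log(chat) + (1 - c) * log(1 - chat)))
}

#' Softmax cross-entropy between Q-logits and expert actions
#' @noRd
softmax_ce <- function(Q, actions0, w = NULL) {
  B <- nrow(Q)
  if (is.null(w)) w <- rep(1, B)
  m <- apply(Q, 1, max)
  ex <- exp(Q - m)
  p <- ex / rowSums(ex)
  idx <- cbind(seq_len(B), actions0 + 1L)
  loss <- mean(w * -log(pmax(p[idx], 1e-12)))
  dQ <- p
  dQ[idx] <- dQ[idx] - 1
  dQ <- dQ * (w / B)
  list(loss = loss, dQ = dQ, probs = p)
}

#' DTW-aligned action-supervision loss
#'
#' Aligns the rollout state history to the expert state history by DTW; each
#' rollout step `t` is paired with the expert index
#' `j*(t) = argmin_j W[t, j]`, and the loss is the mean cross-entropy between
#' the policy's softmaxed Q-values and the expert action at `j*(t)` (the last
#' expert action when `j*` is the final expert state).
#'
#' @param rollout_states `n x d` matrix of rollout features (positions).
#' @param q_logits `n x n_actions` Q-values along the rollout.
#' @param expert_states `m x d` expert features.
#' @param expert_actions length `m - 1` vector of 0-based expert actions.
#' @return list with `loss`, `aligned_idx` (the `j*(t)`), and `dQ`.
#' @export
action_supervision_loss <- function(rollout_states, q_logits, expert_states,
                                    expert_actions) {
  if (is.null(expert_states) || NROW(expert_states) == 0) {
    stopf("empty expert sequence")
  }
  res <- dtw_matrix(rollout_states, expert_states)
  jstar <- apply(res$W, 1, which.min)
  j_act <- pmin(jstar, length(expert_actions))
  ce <- softmax_ce(q_logits, expert_actions[j_act])
  list(loss = ce$loss, aligned_idx = jstar, dQ = ce$dQ)
}

#' Composite training loss of a method variant
#'
#' Evaluates the scalar objective on a batch: `dqdil`/`dqn`:
#' `J_DQ + lambda1 J_l2`; `dqcil`: adds `lambda2 J_tr` (whose gradient is
#' reversed into the shared trunk); `dqaas`: adds
#' `lambda3 J_AS` (cross-entropy to the DTW-aligned expert action, supplied
#' in `batch$expert_action`); `bc`: action cross-entropy plus the l2 term.
#'
#' @param batch as for [double_q_loss()], plus `condition` (for `dqcil`) and
#'   `expert_action` (for `dqaas`/`bc`).
#' @param nets list with `online` and `target` networks.
#' @param config a [loss_config()].
#' @return list with `loss` and the component values.
#' @export
total_loss <- function(batch, nets, config) {
  l2 <- sum(vapply(nets$online$params, function(p) sum(p^2), numeric(1)))
  comp <- list(l2 = l2)
  if (config$method == "bc") {
    B <- nrow(batch$obs)
    h_prev <- batch$h_prev %||% matrix(0, B, nets$online$hidden)
    fwd <- qnet_step(nets$online, batch$obs, h_prev, keep_cache = FALSE)
    ce <- softmax_ce(fwd$Q, batch$expert_action %||% batch$action,
                     batch$weights)
    comp$ce <- ce$loss
    loss <- ce$loss + config$lambda1 * l2
  } else {
    dq <- double_q_loss(batch, nets$online, nets$target, config$gamma)
    comp$dq <- dq$loss
    loss <- dq$loss + config$lambda1 * l2
    if (config$method == "dqcil") {
      chat <- treatment_forward(nets$online, dq$H)
      comp$tr <- treatment_loss(chat, batch$condition)
      loss <- loss + config$lambda2 * comp$tr
    }
    if (config$method == "dqaas") {
      ce <- softmax_ce(dq$Q, batch$expert_action, batch$weights)
      comp$as <- ce$loss
      loss <- loss + config$lambda3 * ce$loss
    }
  }
  c(list(loss = loss), comp)
}

# ---------------------------------------------------------------------------
# replay buffer (proportional prioritized experience replay)

#' @noRd
replay_init <- function(capacity, obs_dim, hidden) {
  e <- new.env(parent = baseenv())
  e$capacity <- as.integer(capacity)
  e$obs <- matrix(NA_real_, capacity, obs_dim)
  e$next_obs <- matrix(NA_real_, capacity, obs_dim)
  e$h_prev <- matrix(NA_real_, capacity, hidden)
  e$h_next <- matrix(NA_real_, capacity, hidden)
  e$action <- integer(capacity)
  e$reward <- numeric(capacity)
  e$done <- logical(capacity)
  e$condition <- numeric(capacity)
  e$expert_action <- integer(capacity)
  e$prio <- numeric(capacity)
  e$max_prio <- 1
  e$size <- 0L
  e$pos <- 0L
  e
}

# Mutation happens via evalq inside the buffer environment: assigning through
# `buf$obs[i, ] <- v` would force R's complex-assignment copy of the full
# preallocated matrix on every push.
#' @noRd
replay_push <- function(buf, obs, action, reward, next_obs, done, condition,
                        h_prev, h_next, expert_action = NA_integer_,
                        prio = NULL) {
  buf$.i <- buf$pos %% buf$capacity + 1L
  buf$.obs <- obs
  buf$.nobs <- next_obs
  buf$.hp <- h_prev
  buf$.hn <- h_next
  buf$.a <- action
  buf$.r <- reward
  buf$.d <- done
  buf$.c <- condition
  buf$.ea <- expert_action
  buf$.p <- prio %||% buf$max_prio
  evalq({
    obs[.i, ] <- .obs
    next_obs[.i, ] <- .nobs
    h_prev[.i, ] <- .hp
    h_next[.i, ] <- .hn
    action[.i] <- .a
    reward[.i] <- .r
    done[.i] <- .d
    condition[.i] <- .c
    expert_action[.i] <- .ea
    prio[.i] <- .p
    max_prio <- max(max_prio, .p)
    pos <- pos + 1L
    size <- min(size + 1L, capacity)
  }, buf)
  invisible(buf$.i)
}

#' @noRd
replay_set_prio <- function(buf, idx, prio) {
  buf$.idx <- idx
  buf$.p <- prio
  evalq({
    prio[.idx] <- .p
    max_prio <- max(max_prio, max(.p))
  }, buf)
  invisible(NULL)
}

#' @noRd
replay_sample <- function(buf, batch_size, per_alpha = 0.6, beta = 0.4) {
  n <- buf$size
  p <- buf$prio[seq_len(n)]^per_alpha
  p <- p / sum(p)
  idx <- sample.int(n, batch_size, replace = TRUE, prob = p)
  w <- (n * p[idx])^(-beta)
  w <- w / max(w)
  list(idx = idx,
       batch = list(obs = buf$obs[idx, , drop = FALSE],
                    action = buf$action[idx],
                    reward = buf$reward[idx],
                    next_obs = buf$next_obs[idx, , drop = FALSE],
                    done = buf$done[idx],
                    condition = buf$condition[idx],
                    expert_action = buf$expert_action[idx],
                    h_prev = buf$h_prev[idx, , drop = FALSE],
                    h_next = buf$h_next[idx, , drop = FALSE],
                    weights = w))
}

# ---------------------------------------------------------------------------
# observations and demonstration transitions

#' Observation sequence of one agent along a recorded episode
#'
#' @param ep an [episode()].
#' @param agent_index 1-based agent index.
#' @param config an [env_config()].
#' @param include_condition_cue append the episode's condition flag.
#' @param condition_override replace the recorded flag (counterfactual cue).
#' @return `T x obs_dim` matrix.
#' @export
episode_observations <- function(ep, agent_index, config,
                                 include_condition_cue = FALSE,
                                 condition_override = NULL) {
  K <- episode_agents(ep)
  Tn <- episode_length(ep)
  cond <- condition_override %||% ep$condition
  D <- observation_dim(config, include_condition_cue)
  out <- matrix(NA_real_, Tn, D)
  for (t in seq_len(Tn)) {
    st <- list(positions = matrix(ep$positions[, t, ], K, 2),
               velocities = matrix(ep$velocities[, t, ], K, 2))
    out[t, ] <- build_observation(structure(st, class = "pursuit_state"),
                                  agent_index, config,
                                  include_condition_cue, cond)
  }
  out
}

# Touch rewards of one agent along an episode (value at transition t means
# the reward received on entering frame t + 1)
#' @noRd
episode_touch_rewards <- function(ep, agent_index) {
  r <- numeric(episode_length(ep) - 1L)
  ev <- ep$reward_events
  if (nrow(ev) > 0) {
    sel <- ev$agent == agent_index
    for (i in which(sel)) {
      t <- ev$t[i] - 1L
      if (t >= 1 && t <= length(r)) r[t] <- r[t] + ev$value[i]
    }
  }
  r
}

# ---------------------------------------------------------------------------
# policy bundle

#' Create an untrained policy bundle
#'
#' One independent recurrent dueling Q-network (and target copy) per learning
#' agent; no parameters are shared across agents.
#'
#' @param config an [env_config()].
#' @param params [locomotion_params()] (shared) or list per agent.
#' @param learn_agents integer indices of the learning agents.
#' @param method method variant name (see [loss_config()]).
#' @param include_cue append the binary condition cue to observations.
#' @param hidden hidden width.
#' @param seed integer seed for weight initialization.
#' @return list of class `policy_bundle`.
#' @export
policy_bundle <- function(config, params, learn_agents = 1L,
                          method = "dqdil", include_cue = FALSE,
                          hidden = 32L, seed = 1L) {
  if (inherits(params, "locomotion_params")) {
    params <- rep(list(params), config$n_agents)
  }
  D <- observation_dim(config, include_cue)
  treatment <- method == "dqcil"
  nets <- list()
  for (i in seq_along(learn_agents)) {
    nets[[i]] <- qnet_init(D, hidden = hidden, treatment = treatment,
                           seed = seed + i - 1L)
  }
  structure(list(nets = nets, target_nets = nets,
                 learn_agents = as.integer(learn_agents), method = method,
                 include_cue = include_cue, config = config, params = params,
                 obs_dim = D, hidden = as.integer(hidden)),
            class = "policy_bundle")
}

#' @export
print.policy_bundle <- function(x, ...) {
  cat(sprintf("<policy_bundle> method %s, %d learning agent(s) [%s], obs dim %d%s\n",
              x$method, length(x$nets),
              paste(x$learn_agents, collapse = ","), x$obs_dim,
              if (x$include_cue) ", condition cue input" else ""))
  invisible(x)
}

#' Zero the condition-cue input weights of a bundle
#'
#' Returns a copy of the bundle whose first-layer weights for the appended
#' cue entry are zero, so the policy provably ignores the condition flag
#' (the cue-ablated control for counterfactual analyses).
#'
#' @param bundle a [policy_bundle()] with `include_cue = TRUE`.
#' @return the ablated bundle.
#' @export
ablate_cue <- function(bundle) {
  if (!bundle$include_cue) stopf("bundle has no condition cue input")
  for (i in seq_along(bundle$nets)) {
    bundle$nets[[i]]$params$W1[bundle$obs_dim, ] <- 0
    bundle$target_nets[[i]]$params$W1[bundle$obs_dim, ] <- 0
  }
  bundle
}

# ---------------------------------------------------------------------------
# offline pre-training

# Flatten demo episodes into per-agent transition tables with DTW-shaped
# rewards (an episode aligned against itself has zero DTW penalty, so
# demonstration transitions carry the touch reward only).
#' @noRd
build_demo_transitions <- function(episodes, agent_index, bundle, lcfg) {
  obs_list <- list()
  rows <- list()
  for (i in seq_along(episodes)) {
    ep <- episodes[[i]]
    obs <- episode_observations(ep, agent_index, bundle$config,
                                bundle$include_cue)
    acts <- ep$meta$actions
    if (is.null(acts)) {
      acts <- infer_actions(ep, bundle$params[[agent_index]])$actions
    }
    touch <- episode_touch_rewards(ep, agent_index)
    pos <- matrix(ep$positions[agent_index, , ], ncol = 2)
    pen <- dtw_matrix(pos, pos)$penalties
    Tn <- episode_length(ep)
    shaped <- shaped_reward(touch, pen[-1], lcfg$alpha)
    if (bundle$method == "dqn") shaped <- touch
    rows[[i]] <- data.frame(ep = i, t = seq_len(Tn - 1L),
                            action = acts[agent_index, ],
                            reward = shaped,
                            done = c(rep(FALSE, Tn - 2L), TRUE),
                            condition = ep$condition)
    obs_list[[i]] <- obs
  }
  list(obs = obs_list, table = do.call(rbind, rows))
}

# Batched sweep recomputing the hidden states of every episode under the
# current online network; returns a list of T x hidden matrices.
#' @noRd
refresh_hidden <- function(net, obs_list) {
  n <- length(obs_list)
  lens <- vapply(obs_list, nrow, integer(1))
  maxT <- max(lens)
  H <- matrix(0, n, net$hidden)
  out <- lapply(lens, function(Tn) matrix(0, Tn, net$hidden))
  for (t in seq_len(maxT)) {
    act <- which(lens >= t)
    X <- do.call(rbind, lapply(act, function(i) obs_list[[i]][t, ]))
    st <- qnet_step(net, X, H[act, , drop = FALSE], keep_cache = FALSE)
    H[act, ] <- st$H
    for (j in seq_along(act)) out[[act[j]]][t, ] <- st$H[j, ]
  }
  out
}

#' Offline policy pre-training from demonstrations
#'
#' Fills a replay table with every demonstration transition (shaped rewards
#' computed against each episode's own trajectory, so the DTW penalty is
#' zero and the touch reward is retained) and runs prioritized minibatch
#' updates for the configured number of epochs. Hidden states for the
#' recurrent core are recomputed for the whole dataset at the start of every
#' epoch with the current weights.
#'
#' @param demos a [demo_dataset()] or list of [episode()]s (training split).
#' @param bundle a [policy_bundle()] (method must not be `"dqn"`, which
#'   learns online from scratch).
#' @param lcfg a [loss_config()].
#' @param epochs training epochs (default 30).
#' @param lr learning rate.
#' @param batch_size minibatch size.
#' @param target_sync target-network synchronization period, in updates.
#' @param per_alpha,per_beta prioritized-replay exponents.
#' @param seed integer seed.
#' @return the trained bundle, with an attached `loss_curve` (mean loss per
#'   epoch).
#' @export
pretrain_offline <- function(demos, bundle, lcfg = loss_config(bundle$method),
                             epochs = 30L, lr = 1e-3, batch_size = 32L,
                             target_sync = 200L, per_alpha = 0.6,
                             per_beta = 0.4, seed = 1L) {
  episodes <- if (inherits(demos, "demo_dataset")) demos$episodes else demos
  if (length(episodes) == 0) stopf("empty demonstration set")
  if (bundle$method == "dqn") {
    stopf("the dqn variant trains online from scratch; nothing to pre-train")
  }
  loss_curve <- matrix(NA_real_, epochs, length(bundle$nets))
  with_seed(seed, {
    for (ai in seq_along(bundle$learn_agents)) {
      agent <- bundle$learn_agents[ai]
      net <- bundle$nets[[ai]]
      target <- net
      tr <- build_demo_transitions(episodes, agent, bundle, lcfg)
      tab <- tr$table
      n <- nrow(tab)
      prio <- rep(1, n)
      opt <- adam_init(net)
      updates <- 0L
      for (epoch in seq_len(epochs)) {
        hid <- refresh_hidden(net, tr$obs)
        n_batches <- ceiling(n / batch_size)
        losses <- numeric(n_batches)
        for (b in seq_len(n_batches)) {
          p <- prio^per_alpha
          p <- p / sum(p)
          idx <- sample.int(n, batch_size, replace = TRUE, prob = p)
          w <- (n * p[idx])^(-per_beta)
          w <- w / max(w)
          batch <- list(
            obs = t(vapply(idx, function(i) {
              tr$obs[[tab$ep[i]]][tab$t[i], ]
            }, numeric(bundle$obs_dim))),
            next_obs = t(vapply(idx, function(i) {
              tr$obs[[tab$ep[i]]][tab$t[i] + 1L, ]
            }, numeric(bundle$obs_dim))),
            h_prev = t(vapply(idx, function(i) {
              if (tab$t[i] == 1L) numeric(net$hidden) else {
                hid[[tab$ep[i]]][tab$t[i] - 1L, ]
              }
            }, numeric(net$hidden))),
            h_next = t(vapply(idx, function(i) {
              hid[[tab$ep[i]]][tab$t[i], ]
            }, numeric(net$hidden))),
            action = tab$action[idx], reward = tab$reward[idx],
            done = tab$done[idx], condition = tab$condition[idx],
            expert_action = tab$action[idx], weights = w)
          res <- update_step(net, target, batch, lcfg, opt, lr)
          net <- res$net
          opt <- res$opt
          losses[b] <- res$loss
          if (!is.null(res$new_prio)) prio[idx] <- res$new_prio
          updates <- updates + 1L
          if (lcfg$method != "bc" && updates %% target_sync == 0L) {
            target <- net
          }
        }
        loss_curve[epoch, ai] <- mean(losses)
      }
      bundle$nets[[ai]] <- net
      bundle$target_nets[[ai]] <- target
    }
  })
  attr(bundle, "loss_curve") <- loss_curve
  bundle
}

# One gradient update on a batch for any method; returns updated net/opt,
# the scalar loss and new priorities (|TD| + eps) when TD-based.
#' @noRd
update_step <- function(net, target, batch, lcfg, opt, lr) {
  if (lcfg$method == "bc") {
    B <- nrow(batch$obs)
    fwd <- qnet_step(net, batch$obs, batch$h_prev, keep_cache = TRUE)
    ce <- softmax_ce(fwd$Q, batch$expert_action, batch$weights)
    grads <- qnet_backward(net, fwd$cache, ce$dQ)
    res <- adam_update(net, grads, opt, lr, lambda1 = lcfg$lambda1)
    return(list(net = res$net, opt = res$state, loss = ce$loss,
                new_prio = NULL))
  }
  dq <- double_q_loss(batch, net, target, lcfg$gamma)
  dQ <- dq$dQ
  loss <- dq$loss
  dH_extra <- NULL
  if (lcfg$method == "dqaas") {
    ce <- softmax_ce(dq$Q, batch$expert_action, batch$weights)
    dQ <- dQ + lcfg$lambda3 * ce$dQ
    loss <- loss + lcfg$lambda3 * ce$loss
  }
  tr_grads <- NULL
  if (lcfg$method == "dqcil") {
    B <- nrow(batch$obs)
    chat <- treatment_forward(net, dq$H)
    loss_tr <- treatment_loss(chat, batch$condition)
    loss <- loss + lcfg$lambda2 * loss_tr
    dlogit <- matrix((chat - batch$condition) / B, B, 1)
    tb <- treatment_backward(net, dq$H, lcfg$lambda2 * dlogit, gate = -1)
    tr_grads <- tb$grads
    dH_extra <- tb$dH
  }
  grads <- qnet_backward(net, dq$cache, dQ, dH_extra = dH_extra)
  if (!is.null(tr_grads)) grads <- accumulate_grads(grads, tr_grads)
  res <- adam_update(net, grads, opt, lr, lambda1 = lcfg$lambda1)
  list(net = res$net, opt = res$state, loss = loss,
       new_prio = abs(dq$td_error) + 1e-3)
}
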