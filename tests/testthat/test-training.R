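make_batch <- function(net, B = 4, seed = 1, done = rep(FALSE, B),
                       reward = rep(0, B)) {
  set.seed(seed)
  list(obs = matrix(rnorm(B * net$obs_dim), B),
       next_obs = matrix(rnorm(B * net$obs_dim), B),
       action = sample(0:(net$n_actions - 1), B, replace = TRUE),
       reward = reward, done = done,
       condition = sample(0:1, B, replace = TRUE),
       expert_action = sample(0:(net$n_actions - 1), B, replace = TRUE),
       h_prev = matrix(0, B, net$hidden), h_next = matrix(0, B, net$hidden),
       weights = rep(1, B))
}

test_that("double-Q loss matches a hand computation of the TD targets", {
  net <- qnet_init(4, n_actions = 5, hidden = 8, seed = 2)
  tgt <- qnet_init(4, n_actions = 5, hidden = 8, seed = 3)
  batch <- make_batch(net, B = 6, seed = 4,
                      done = c(TRUE, FALSE, FALSE, TRUE, FALSE, FALSE),
                      reward = c(1, 0, 0.5, -1, 0, 0))
  gamma <- 0.9
  res <- double_q_loss(batch, net, tgt, gamma)
  # independent route: q_forward on each row
  y <- qsa <- numeric(6)
  for (i in 1:6) {
    qn <- q_forward(net, batch$next_obs[i, ])$Q
    amax <- which.max(qn)
    qt <- q_forward(tgt, batch$next_obs[i, ])$Q[amax]
    y[i] <- batch$reward[i] + gamma * ifelse(batch$done[i], 0, qt)
    qsa[i] <- q_forward(net, batch$obs[i, ])$Q[batch$action[i] + 1]
  }
  expect_equal(res$loss, mean((qsa - y)^2))
  expect_equal(res$td_error, qsa - y)

  # gamma = 0: target is the reward exactly
  res0 <- double_q_loss(batch, net, tgt, gamma = 1e-12)
  expect_equal(res0$td_error, qsa - batch$reward, tolerance = 1e-9)

  # terminal transitions never bootstrap, even at gamma = 1
  batch_t <- make_batch(net, B = 3, seed = 5, done = rep(TRUE, 3),
                        reward = c(1, 0, -1))
  res_t <- double_q_loss(batch_t, net, tgt, gamma = 1)
  qsa_t <- vapply(1:3, function(i) {
    q_forward(net, batch_t$obs[i, ])$Q[batch_t$action[i] + 1]
  }, numeric(1))
  expect_equal(res_t$td_error, qsa_t - batch_t$reward)
})

test_that("treatment loss matches the cross-entropy formula and clip contract", {
  expect_equal(treatment_loss(0.5, 1), log(2))
  expect_equal(treatment_loss(0.5, 0), log(2))
  expect_lt(treatment_loss(c(1 - 1e-6, 1e-6), c(1, 0)), 1e-5)
  expect_equal(treatment_loss(1e-6, 1), -log(1e-6))
  expect_error(treatment_loss(0, 1), "chat")
})

test_that("composite losses reduce to their components", {
  net <- qnet_init(4, n_actions = 5, hidden = 8, treatment = TRUE, seed = 2)
  tgt <- qnet_init(4, n_actions = 5, hidden = 8, treatment = TRUE, seed = 3)
  nets <- list(online = net, target = tgt)
  batch <- make_batch(net, B = 5, seed = 6)
  l2 <- sum(vapply(net$params, function(p) sum(p^2), numeric(1)))

  dqdil0 <- total_loss(batch, nets, loss_config("dqdil", lambda1 = 0))
  expect_equal(dqdil0$loss, double_q_loss(batch, net, tgt, 0.99)$loss)

  dqcil0 <- total_loss(batch, nets, loss_config("dqcil", lambda2 = 0))
  dqdil <- total_loss(batch, nets, loss_config("dqdil"))
  expect_equal(dqcil0$loss, dqdil$loss)
  expect_equal(dqdil$l2, l2)

  aas <- total_loss(batch, nets, loss_config("dqaas", lambda3 = 2))
  expect_equal(aas$loss, aas$dq + 2 * aas$as + 1e-5 * aas$l2)
})

test_that("action supervision aligns by DTW and hits ln(13) for a uniform policy", {
  # uniform policy: all-equal logits
  q <- matrix(0, 3, 13)
  res <- action_supervision_loss(c(0, 1, 2), q, c(0, 2), c(5L))
  expect_equal(res$loss, log(13))
  # alignment on the worked example: row 3 maps to expert index 2
  expect_equal(res$aligned_idx, c(1, 1, 2))
  expect_error(action_supervision_loss(c(0, 1), q[1:2, ], numeric(0), 1L),
               "empty expert")

  # a policy already matching the expert action has near-zero loss
  q2 <- matrix(0, 2, 13)
  q2[, 6] <- 50
  res2 <- action_supervision_loss(c(0, 1), q2, c(0, 1), c(5L))
  expect_lt(res2$loss, 1e-5)
})

test_that("replay sampling frequencies follow priority^alpha and pushes wrap", {
  ns <- asNamespace("pursuitRL")
  buf <- ns$replay_init(4, 2, 3)
  prios <- c(1, 2, 4, 8)
  for (i in 1:4) {
    ns$replay_push(buf, c(i, i), i, 0, c(i, i), FALSE, 0, numeric(3),
                   numeric(3), prio = prios[i])
  }
  alpha <- 0.6
  set.seed(2)
  draws <- integer(4)
  for (r in 1:2000) {
    sm <- ns$replay_sample(buf, 8, per_alpha = alpha, beta = 1)
    draws <- draws + tabulate(sm$idx, 4)
  }
  n <- sum(draws)
  p <- prios^alpha / sum(prios^alpha)
  expect_true(all(abs(draws - n * p) < 3.5 * sqrt(n * p * (1 - p))))
  # importance weights undo the skew at beta = 1
  sm <- ns$replay_sample(buf, 4, per_alpha = alpha, beta = 1)
  w_expected <- (4 * p[sm$idx])^(-1)
  expect_equal(sm$batch$weights, w_expected / max(w_expected))

  # ring buffer overwrites the oldest slot
  ns$replay_push(buf, c(9, 9), 9, 0, c(9, 9), FALSE, 0, numeric(3),
                 numeric(3), prio = 1)
  expect_equal(buf$obs[1, ], c(9, 9))
  expect_equal(buf$size, 4L)
})

test_that("demonstration transitions self-align to zero DTW penalty", {
  ns <- asNamespace("pursuitRL")
  ds <- stop_and_go_demos(n = 6, seed = 3)
  cfg <- species_env_config("agents")
  b <- policy_bundle(cfg, agents_params(), learn_agents = 1L,
                     method = "dqdil", seed = 1)
  lcfg <- loss_config("dqdil", alpha = 10)
  tr <- ns$build_demo_transitions(ds$episodes, 1L, b, lcfg)
  touch <- unlist(lapply(ds$episodes, function(ep) {
    ns$episode_touch_rewards(ep, 1L)
  }))
  # shaped reward = touch - alpha * 0 on an episode aligned against itself
  expect_equal(tr$table$reward, touch)
})

test_that("the exploration schedule interpolates linearly then plateaus", {
  sc <- exploration_schedule(0.5, 0.3, 0.5, 5e4)
  expect_equal(epsilon_at(sc, 0), 0.5)
  expect_equal(epsilon_at(sc, 2.5e4), 0.4)
  expect_equal(epsilon_at(sc, 5e4), 0.3)
  expect_equal(epsilon_at(sc, 2e5), 0.3)
})

test_that("offline pre-training: zero epochs is the identity; BC imitates a toy expert", {
  ds <- straight_demos(n = 20, seed = 21)
  cfg <- species_env_config("agents")
  b <- policy_bundle(cfg, agents_params(), learn_agents = 1L, method = "bc",
                     seed = 4)
  b0 <- pretrain_offline(ds$episodes[1:10], b, loss_config("bc"), epochs = 0,
                         seed = 1)
  expect_identical(b0$nets[[1]]$params, b$nets[[1]]$params)
  expect_error(pretrain_offline(list(), b, loss_config("bc")), "empty")

  dqn_b <- policy_bundle(cfg, agents_params(), learn_agents = 1L,
                         method = "dqn")
  expect_error(pretrain_offline(ds$episodes, dqn_b), "online from scratch")

  # 30 epochs of behavioral cloning on a deterministic toy expert (thrust +x
  # left of the origin, -x right of it) matches it on >= 95% of demo states
  cfg1 <- env_config(n_agents = 1L, arena = "open", dt = 0.1, time_limit = 5)
  p <- agents_params()
  units <- action_unit_vectors()
  set.seed(31)
  toy_eps <- lapply(1:20, function(i) {
    Tn <- 40L
    pos <- matrix(NA_real_, Tn, 2); vel <- matrix(NA_real_, Tn, 2)
    pos[1, ] <- stats::runif(2, -0.5, 0.5); vel[1, ] <- 0
    acts <- integer(Tn - 1L)
    for (t in 2:Tn) {
      a <- if (pos[t - 1, 1] < 0) 1L else 7L
      acts[t - 1L] <- a
      vel[t, ] <- predict_next_velocity(vel[t - 1, ], units[a + 1L, ], p)
      pos[t, ] <- pos[t - 1, ] + vel[t, ] * p$dt
    }
    parr <- array(0, c(1, Tn, 2)); varr <- array(0, c(1, Tn, 2))
    parr[1, , ] <- pos; varr[1, , ] <- vel
    episode((seq_len(Tn) - 1) * 0.1, parr, varr, roles = "solo",
            meta = list(id = sprintf("toy%d", i),
                        actions = matrix(acts, 1)))
  })
  b1 <- policy_bundle(cfg1, p, learn_agents = 1L, method = "bc", seed = 4)
  bt <- pretrain_offline(toy_eps, b1, loss_config("bc"), epochs = 30,
                         lr = 1e-3, seed = 2)
  agree <- vapply(toy_eps, function(ep) {
    obs <- episode_observations(ep, 1, cfg1)
    f <- q_forward(bt$nets[[1]], obs[-nrow(obs), , drop = FALSE])
    mean(max.col(f$Q, ties.method = "first") - 1L == ep$meta$actions[1, ])
  }, numeric(1))
  expect_gte(mean(agree), 0.95)
})

test_that("online fine-tuning is reproducible from the seed", {
  ds <- straight_demos(n = 8, seed = 33)
  cfg <- species_env_config("agents", target_time_reward = FALSE)
  lcfg <- loss_config("dqn", gamma = 0.95)
  run <- function() {
    b <- policy_bundle(cfg, agents_params(), learn_agents = 1L,
                       method = "dqn", seed = 3)
    b <- finetune_online(b, ds$episodes, lcfg, budget = 400,
                         schedule = exploration_schedule(0.5, 0.5, 0.5, 100),
                         warmup = 2L, update_every = 16L, seed = 11)
    list(log = attr(b, "train_log"), p = b$nets[[1]]$params$W1)
  }
  r1 <- run()
  r2 <- run()
  expect_identical(r1, r2)
  expect_error(
    finetune_online(policy_bundle(cfg, agents_params(), method = "dqn"),
                    ds$episodes, lcfg, budget = 0), "budget")
})
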