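test_that("dueling combine satisfies Q = V + A - mean(A) and the identity", {
  net <- qnet_init(5, seed = 1)
  set.seed(2)
  obs <- matrix(rnorm(15), 3, 5)
  f <- q_forward(net, obs)
  expect_equal(f$Q,
               sweep(f$Adv, 1, rowMeans(f$Adv), "-") + matrix(f$V, 3, 13))
  expect_equal(rowMeans(f$Q - f$V), rep(0, 3), tolerance = 1e-12)

  # zeroed advantage output layer -> all Q equal V
  net0 <- net
  net0$params$Wa2[] <- 0
  net0$params$ba2[] <- 0
  f0 <- q_forward(net0, obs)
  expect_equal(f0$Q, matrix(f0$V, 3, 13))

  # determinism
  expect_identical(q_forward(net, obs), q_forward(net, obs))
  expect_error(q_forward(net, matrix(0, 2, 4)), "parameter error")
})

test_that("hidden state is carried across the sequence", {
  net <- qnet_init(4, seed = 3)
  set.seed(4)
  obs <- matrix(rnorm(12), 3, 4)
  f <- q_forward(net, obs)
  # feeding the final hidden back reproduces a continued sequence
  f12 <- q_forward(net, obs[1:2, , drop = FALSE])
  f3 <- q_forward(net, obs[3, , drop = FALSE], h0 = f12$final_hidden)
  expect_equal(f3$Q[1, ], f$Q[3, ])
  # shuffling history changes the hidden state (memory is real)
  fswap <- q_forward(net, obs[c(2, 1, 3), ])
  expect_false(isTRUE(all.equal(fswap$final_hidden, f$final_hidden)))
})

test_that("epsilon-greedy selection: tie-breaks, argmax, uniformity", {
  expect_equal(greedy_action(c(0, 5, 5), 0), 1L)
  expect_equal(greedy_action(c(3, 1, 2), 0), 0L)
  set.seed(6)
  draws <- replicate(1e4, greedy_action(rep(0, 13), 1))
  tab <- tabulate(draws + 1L, 13)
  p0 <- 1 / 13
  sigma <- sqrt(1e4 * p0 * (1 - p0))
  expect_true(all(abs(tab - 1e4 * p0) < 3.5 * sigma))
  expect_error(greedy_action(c(1, 2), 1.5), "epsilon")
})

test_that("treatment head stays in the clip band and reverses gradients", {
  net <- qnet_init(4, hidden = 6, treatment = TRUE, seed = 5)
  # extreme inputs cannot escape (eta, 1 - eta)
  net$params$Wt2[] <- 100
  chat <- treatment_forward(net, matrix(10, 1, 6))
  expect_lte(chat, 1 - net$eta_clip)
  expect_gte(chat, net$eta_clip)
  expect_error(treatment_forward(qnet_init(4), matrix(0, 1, 32)), "head")

  # gradient contract: encoder gradients from the treatment loss are exactly
  # the negative of the no-gate gradients; head gradients are untouched
  ns <- asNamespace("pursuitRL")
  net <- qnet_init(3, n_actions = 4, hidden = 5, treatment = TRUE, seed = 9)
  set.seed(10)
  X <- matrix(rnorm(6), 2, 3)
  H0 <- matrix(rnorm(10) * 0.2, 2, 5)
  cc <- c(1, 0)
  st <- ns$qnet_step(net, X, H0, keep_cache = TRUE)
  chat <- treatment_forward(net, st$H)
  dlogit <- matrix((chat - cc) / 2, 2, 1)
  tb_rev <- ns$treatment_backward(net, st$H, dlogit, gate = -1)
  tb_fwd <- ns$treatment_backward(net, st$H, dlogit, gate = +1)
  g_rev <- ns$qnet_backward(net, st$cache, matrix(0, 2, 4),
                            dH_extra = tb_rev$dH)
  g_fwd <- ns$qnet_backward(net, st$cache, matrix(0, 2, 4),
                            dH_extra = tb_fwd$dH)
  expect_equal(g_rev$W1, -g_fwd$W1)
  expect_equal(g_rev$Wz, -g_fwd$Wz)
  expect_identical(tb_rev$grads, tb_fwd$grads)

  # no-gate gradient agrees with finite differences (tolerance 1e-4)
  lossT <- function(net) {
    stl <- ns$qnet_step(net, X, H0, keep_cache = FALSE)
    ch <- treatment_forward(net, stl$H)
    mean(-(cc * log(ch) + (1 - cc) * log(1 - ch)))
  }
  e <- 1e-5
  for (i in c(1, 7)) {
    n2 <- net
    n2$params$W1[i] <- net$params$W1[i] + e
    f1 <- lossT(n2)
    n2$params$W1[i] <- net$params$W1[i] - e
    f0 <- lossT(n2)
    expect_equal(g_fwd$W1[i], (f1 - f0) / (2 * e), tolerance = 1e-4)
  }
})

test_that("Q-path backpropagation matches finite differences", {
  ns <- asNamespace("pursuitRL")
  net <- qnet_init(5, n_actions = 4, hidden = 6, seed = 9)
  set.seed(3)
  B <- 3
  X <- matrix(rnorm(B * 5), B, 5)
  H0 <- matrix(rnorm(B * 6) * 0.3, B, 6)
  a <- c(1, 3, 2)
  yv <- c(0.2, -0.5, 1.0)
  lossQ <- function(net) {
    st <- ns$qnet_step(net, X, H0, keep_cache = FALSE)
    mean((st$Q[cbind(1:B, a)] - yv)^2)
  }
  st <- ns$qnet_step(net, X, H0, keep_cache = TRUE)
  dQ <- matrix(0, B, 4)
  dQ[cbind(1:B, a)] <- 2 * (st$Q[cbind(1:B, a)] - yv) / B
  g <- ns$qnet_backward(net, st$cache, dQ)
  e <- 1e-5
  for (nm in c("W1", "Wz", "Un", "Wv2", "Wa1", "bhn")) {
    for (i in seq_len(min(length(net$params[[nm]]), 3))) {
      n2 <- net
      n2$params[[nm]][i] <- net$params[[nm]][i] + e
      f1 <- lossQ(n2)
      n2$params[[nm]][i] <- net$params[[nm]][i] - e
      f0 <- lossQ(n2)
      expect_equal(g[[nm]][i], (f1 - f0) / (2 * e), tolerance = 1e-6)
    }
  }
})

test_that("target synchronization makes both networks agree bitwise", {
  cfg <- species_env_config("agents", n_agents = 2L)
  b <- policy_bundle(cfg, agents_params(), learn_agents = 1L, seed = 2)
  b$target_nets <- b$nets
  set.seed(8)
  obs <- matrix(rnorm(12), 2, 6)
  expect_identical(q_forward(b$nets[[1]], obs),
                   q_forward(b$target_nets[[1]], obs))
})
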