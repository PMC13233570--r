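test_that("episode metrics: path length, duration, return", {
  # stationary episode: zero path length, correct duration
  ep <- parked_episode("still", Tn = 11)
  m <- episode_metrics(ep)
  expect_equal(m$path_length, 0)
  expect_equal(m$duration, 1.0)
  expect_equal(m$return, 0L)

  # constant speed v for n steps: path length n * v * dt
  v <- 0.4
  ep2 <- toy_episode(matrix(c(rep(0, 1), rep(v, 10), rep(0, 11)), 11, 2))
  m2 <- episode_metrics(ep2)
  expect_equal(m2$path_length, 10 * v * 0.1)

  # a generated contact episode counts as a capture
  ds <- straight_demos(n = 5, seed = 51)
  contact_ep <- Filter(function(e) e$meta$end_reason == "contact",
                       ds$episodes)[[1]]
  expect_equal(episode_metrics(contact_ep)$return, 1L)

  # DTW-to-GT of an episode against itself is zero
  expect_equal(episode_metrics(contact_ep, gt_episode = contact_ep)$dtw_to_gt,
               0)
})

test_that("KDE distance is a pseudometric and matches the closed-form oracle", {
  set.seed(2)
  x <- rnorm(300)
  expect_lt(kde_distance(x, x), 1e-12)
  y <- rnorm(300, 1)
  expect_identical(kde_distance(x, y), kde_distance(y, x))
  expect_error(kde_distance(rep(1, 10), x), "degenerate")
  expect_error(kde_distance(1, x), "length")

  # oracle: numerically integrated L1 distance between N(0,1) and N(3,1)
  # densities, inflated by the KDE bandwidth: the Gaussian KDE of N(mu, 1)
  # estimates N(mu, 1 + h^2) for large n
  set.seed(7)
  a <- rnorm(2000, 0)
  b <- rnorm(2000, 3)
  h <- 2000^(-1/5)
  grid <- seq(-6, 9, length.out = 4001)
  f1 <- stats::dnorm(grid, 0, sqrt(1 + h^2))
  f2 <- stats::dnorm(grid, 3, sqrt(1 + h^2))
  oracle <- sum(abs(f1 - f2)) * diff(grid[1:2])
  expect_lt(abs(kde_distance(a, b) - oracle), 0.05)

  # triangle inequality on random sample triples
  set.seed(9)
  for (i in 1:5) {
    s1 <- rnorm(100); s2 <- rnorm(100, 1); s3 <- rt(100, 5)
    expect_lte(kde_distance(s1, s3),
               kde_distance(s1, s2) + kde_distance(s2, s3) + 1e-9)
  }
})

test_that("paired bootstrap CI: degenerate exactness and coverage calibration", {
  a <- c(1, 2, 3, 4)
  ci <- paired_bootstrap_ci(a + 0.7, a, B = 500, seed = 1)
  expect_equal(ci$median, 0.7)
  expect_equal(ci$low, 0.7)
  expect_equal(ci$high, 0.7)

  ci0 <- paired_bootstrap_ci(a, a, B = 200, seed = 1)
  expect_equal(c(ci0$low, ci0$median, ci0$high), c(0, 0, 0))
  expect_error(paired_bootstrap_ci(1:3, 1:4), "equal length")

  # known unit effect: 95% CI covers it between 90% and 99% of the time
  set.seed(5)
  covered <- vapply(1:200, function(i) {
    d <- rnorm(40, 1)
    ci <- paired_bootstrap_ci(d, numeric(40), B = 400, seed = i)
    ci$low <= 1 && 1 <= ci$high
  }, logical(1))
  expect_gte(mean(covered), 0.90)
  expect_lte(mean(covered), 0.99)

  # the CI excludes zero for a clearly positive effect (power check)
  set.seed(6)
  excl <- vapply(1:100, function(i) {
    d <- rnorm(100, 1)
    paired_bootstrap_ci(d, numeric(100), B = 400, seed = i)$low > 0
  }, logical(1))
  expect_gte(mean(excl), 0.99)
})

test_that("bootstrap ANOVA: identical groups give F = 0; separated groups large F", {
  g <- rnorm(30)
  res <- bootstrap_anova(list(g, g, g), B = 200, seed = 3)
  expect_equal(res$median_F, 0)
  expect_true(all(res$F_values == 0))

  set.seed(4)
  sep <- lapply(c(0, 3, 6), function(mu) rnorm(30, mu))
  res2 <- bootstrap_anova(sep, B = 500, seed = 5)
  expect_gt(res2$median_F, 4)
  expect_equal(res2$frac_positive, 1)

  expect_error(bootstrap_anova(list(rnorm(5))), "2 groups")
  # replicate F agrees with aov on the original (unresampled) grouping
  ns <- asNamespace("pursuitRL")
  dat <- data.frame(y = unlist(sep), grp = factor(rep(1:3, each = 30)))
  f_aov <- summary(stats::aov(y ~ grp, dat))[[1]]$`F value`[1]
  expect_equal(ns$oneway_F(sep), f_aov)
})

test_that("matched-rng counterfactuals: a cue-blind policy shifts by exactly zero", {
  cfg <- species_env_config("agents", n_agents = 2L)
  prey <- locomotion_params(0.25, 2.5, 0.1)
  b <- policy_bundle(cfg, list(agents_params(), prey), learn_agents = 1L,
                     method = "dqcil", include_cue = TRUE, seed = 6)
  b <- ablate_cue(b)
  ds <- stop_and_go_demos(n = 6, seed = 3)
  two <- lapply(ds$episodes[1:4], function(e) {
    # reduce to 2 agents for the small bundle
    episode(e$times, e$positions[c(1, 3), , , drop = FALSE],
            e$velocities[c(1, 3), , , drop = FALSE],
            roles = c("chaser", "target"), condition = e$condition,
            meta = e$meta, validate = FALSE)
  })
  cf <- counterfactual_shift(b, two, B = 200, seed = 9)
  expect_equal(cf$shift, rep(0, 4))
  expect_equal(c(cf$shift_ci$low, cf$shift_ci$high), c(0, 0))

  b_nocue <- policy_bundle(cfg, agents_params(), learn_agents = 1L,
                           method = "dqdil", include_cue = FALSE)
  expect_error(counterfactual_shift(b_nocue, two), "configuration error")
})

test_that("rollout metrics are invariant to padding after termination", {
  ds <- straight_demos(n = 5, seed = 51)
  ep <- Filter(function(e) e$meta$end_reason == "contact", ds$episodes)[[1]]
  m <- episode_metrics(ep)
  # pad the trajectory with stationary frames past termination
  Tn <- episode_length(ep)
  K <- episode_agents(ep)
  pad <- 5L
  pos <- array(NA_real_, c(K, Tn + pad, 2))
  vel <- array(0, c(K, Tn + pad, 2))
  pos[, seq_len(Tn), ] <- ep$positions
  vel[, seq_len(Tn), ] <- ep$velocities
  for (t in Tn + seq_len(pad)) pos[, t, ] <- ep$positions[, Tn, ]
  padded <- episode(times = (seq_len(Tn + pad) - 1) * 0.1, positions = pos,
                    velocities = vel, roles = ep$roles,
                    condition = ep$condition,
                    reward_events = ep$reward_events, meta = ep$meta,
                    validate = FALSE)
  m_pad <- episode_metrics(padded)
  expect_equal(m_pad$path_length, m$path_length)
  expect_equal(m_pad$return, m$return)
})
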