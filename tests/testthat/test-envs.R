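test_that("uniform resets sample the inner square; episode resets copy frame 0", {
  cfg <- species_env_config("agents")
  st <- reset_pursuit(cfg, "uniform", rng_or_episode = 4)
  expect_true(all(abs(st$positions) <= 0.5))
  expect_true(all(st$velocities == 0))

  ep <- straight_demos()$episodes[[1]]
  st2 <- reset_pursuit(cfg, "from_episode", ep)
  expect_equal(st2$positions, matrix(ep$positions[, 1, ], 3, 2))
  expect_equal(st2$velocities, matrix(ep$velocities[, 1, ], 3, 2))
  expect_equal(st2$reference_id, ep$meta$id)

  cfg2 <- species_env_config("agents", n_agents = 2L)
  expect_error(reset_pursuit(cfg2, "from_episode", ep), "2")
})

test_that("step kinematics follow the velocity transition and position update", {
  cfg <- species_env_config("agents", n_agents = 2L)
  p <- agents_params()
  st <- reset_pursuit(cfg, "uniform", 1)
  st$positions <- rbind(c(-0.5, 0), c(0.5, 0))

  r0 <- step_pursuit(st, c(0L, 0L), p, cfg)
  expect_equal(r0$state$positions, st$positions)
  expect_equal(r0$state$velocities, st$velocities)

  r1 <- step_pursuit(st, c(1L, 0L), p, cfg)   # +x thrust from rest
  expect_equal(r1$state$velocities[1, ], c(0.3, 0))
  expect_equal(r1$state$positions[1, ], c(-0.5 + 0.03, 0))

  expect_error(step_pursuit(st, c(13L, 0L), p, cfg), "0..12")
})

test_that("constant thrust converges to the closed-form terminal speed", {
  cfg <- species_env_config("agents", n_agents = 2L, arena = "open",
                            time_limit = 1e6)
  p <- agents_params()
  st <- reset_pursuit(cfg, "uniform", 1)
  st$positions <- rbind(c(0, 0), c(500, 500))  # target far away
  for (i in 1:200) st <- step_pursuit(st, c(1L, 0L), p, cfg)$state
  expect_lt(abs(st$velocities[1, 1] - 1.2), 1e-3)

  # predator mobility scales u only, hence the terminal speed linearly
  f <- cfg$predator_mobility_factor
  pf <- mobility_scaled_params(p, f)
  st2 <- reset_pursuit(cfg, "uniform", 1)
  st2$positions <- rbind(c(0, 0), c(500, 500))
  for (i in 1:200) st2 <- step_pursuit(st2, c(1L, 0L), pf, cfg)$state
  expect_lt(abs(st2$velocities[1, 1] - 1.2 * f), 1e-3)
})

test_that("contact, boundary and time-limit termination and rewards", {
  p <- agents_params()
  cfg <- species_env_config("agents")
  st <- reset_pursuit(cfg, "uniform", 1)
  st$positions <- rbind(c(0, 0.05), c(0.4, 0), c(0, 0))  # chaser 1 near target
  r <- step_pursuit(st, c(0L, 0L, 0L), p, cfg)
  expect_true(r$done)
  expect_equal(r$info$reason, "contact")
  expect_equal(r$rewards[1], 1)
  expect_equal(r$rewards[2], 0)  # individual scheme: only the toucher
  expect_equal(r$rewards[3], r$state$t * cfg$dt)  # prey's elapsed-time reward

  cfg_sh <- species_env_config("agents", reward_scheme = "shared")
  r_sh <- step_pursuit(st, c(0L, 0L, 0L), p, cfg_sh)
  expect_equal(r_sh$rewards[1:2], c(1, 1))

  # boundary crossing: transgressor only, episode over
  st_b <- reset_pursuit(cfg, "uniform", 1)
  st_b$positions <- rbind(c(1.09, 0), c(-0.4, 0), c(0.4, 0.4))
  st_b$velocities <- rbind(c(1.2, 0), c(0, 0), c(0, 0))
  r_b <- step_pursuit(st_b, c(1L, 0L, 0L), p, cfg)
  expect_equal(r_b$info$reason, "boundary")
  expect_equal(r_b$rewards, c(-10, 0, 0))
  expect_error(step_pursuit(r_b$state, c(0L, 0L, 0L), p, cfg), "terminated")

  # time limit classification
  st_t <- reset_pursuit(cfg, "uniform", 1)
  st_t$t <- 149L
  expect_equal(check_termination(st_t, cfg)$reason, "time_limit")
  st_o <- reset_pursuit(cfg, "uniform", 1)
  st_o$positions <- rbind(c(0, 0), c(0.5, 0.5), c(-0.5, -0.5))
  expect_equal(check_termination(st_o, cfg)$reason, "ongoing")
})

test_that("observations have the documented layout and ordering", {
  cfg <- species_env_config("agents")
  st <- reset_pursuit(cfg, "uniform", 1)
  obs <- build_observation(st, 2, cfg)
  expect_length(obs, 10)                      # 2 + 2 * (2 + 2)
  expect_equal(observation_dim(cfg), 10L)
  expect_equal(obs[1:2], st$positions[2, ])
  expect_equal(obs[3:4], st$positions[1, ] - st$positions[2, ])
  expect_equal(obs[7:8], st$positions[3, ] - st$positions[2, ])

  st$positions <- matrix(0.1, 3, 2)
  st$velocities <- matrix(0, 3, 2)
  obs0 <- build_observation(st, 1, cfg)
  expect_equal(obs0[3:10], rep(0, 8))

  obs_cue <- build_observation(st, 1, cfg, include_condition_cue = TRUE,
                               condition = 1)
  expect_length(obs_cue, 11)
  expect_equal(obs_cue[11], 1)
})

test_that("stepping is deterministic and the speed bound holds on rollouts", {
  cfg <- species_env_config("agents", n_agents = 2L)
  p <- agents_params()
  st <- reset_pursuit(cfg, "uniform", 3)
  a <- c(4L, 9L)
  r1 <- step_pursuit(st, a, p, cfg)
  r2 <- step_pursuit(st, a, p, cfg)
  expect_identical(r1, r2)

  cap <- p$u * p$dt / p$d + p$u * p$dt
  set.seed(5)
  st <- reset_pursuit(cfg, "uniform", 5)
  for (i in 1:100) {
    if (st$done) break
    st <- step_pursuit(st, sample(0:12, 2, replace = TRUE), p, cfg)$state
    expect_lte(max(sqrt(rowSums(st$velocities^2))), cap + 1e-12)
  }
})

test_that("synthetic plume: constant when not intermittent, maximal at source, seeded", {
  pl0 <- make_synthetic_plume(c(21, 21), n_frames = 5, intermittency = 0,
                              seed = 2)
  expect_true(all(pl0$odor[1, , ] == pl0$odor[5, , ]))
  for (t in 1:5) {
    expect_equal(max(pl0$odor[t, , ]), 1)
  }
  pl1 <- make_synthetic_plume(c(21, 21), n_frames = 5, intermittency = 0.5,
                              seed = 7)
  pl2 <- make_synthetic_plume(c(21, 21), n_frames = 5, intermittency = 0.5,
                              seed = 7)
  expect_identical(pl1, pl2)
  si <- c(11, 11)  # source cell of a symmetric grid centered at the origin
  for (t in 1:5) expect_equal(pl1$odor[t, si[1], si[2]], 1)
})

test_that("moth environment: source reward, antennae, observation layout", {
  cfg <- species_env_config("moth")
  p <- locomotion_params(0.2, 0.02, 0.5)
  pl <- make_synthetic_plume(seed = 1)

  st <- reset_moth(position = c(0.03, 0))
  r <- step_moth(st, 0L, pl, p, cfg)     # already within contact radius
  expect_equal(r$reward, 1)
  expect_true(r$done)

  # a spatially constant field reads identically at both antennae
  flat <- pl
  flat$odor[] <- 0.37
  obs <- moth_observation(reset_moth(c(0.5, 0.2)), flat)
  expect_equal(obs[1], 0.37)
  expect_equal(obs[2], 0.37)

  # observation excludes absolute position: odor(2) + wind(4) + vision(2) +
  # velocity(2) + body angle as cos/sin(2)
  expect_length(obs, 12)
  expect_equal(sum(obs[3:6]), 1)   # one-hot wind sector

  # body angle follows the velocity direction once moving
  st2 <- reset_moth(c(0.5, 0))
  r2 <- step_moth(st2, 4L, pl, p, cfg)   # 90-degree thrust
  expect_equal(r2$state$body_angle, pi / 2)
})
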