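test_that("write/read round trip reproduces the dataset exactly", {
  ds <- stop_and_go_demos(n = 10, seed = 3)
  ds <- split_dataset(ds, counts = c(6, 2, 2), seed = 1)
  dir <- withr::local_tempdir()
  info <- write_demos(ds, dir)
  expect_equal(info$n_episodes, 10)
  back <- read_demos(dir)
  expect_equal(back, ds)

  empty <- demo_dataset(list(), hz = 10)
  dir2 <- withr::local_tempdir()
  write_demos(empty, dir2)
  expect_length(read_demos(dir2)$episodes, 0)
})

test_that("read_demos rejects malformed archives and warns on extra columns", {
  expect_error(read_demos(withr::local_tempdir()), "manifest")

  ds <- stop_and_go_demos(n = 10, seed = 3)
  dir <- withr::local_tempdir()
  write_demos(demo_dataset(ds$episodes[1:2], hz = ds$hz), dir)
  # corrupt the time grid of episode 1
  f <- file.path(dir, "episodes", paste0(ds$episodes[[1]]$meta$id, ".csv"))
  df <- utils::read.csv(f)
  df$t[2] <- df$t[2] + 0.05
  utils::write.csv(df, f, row.names = FALSE, quote = FALSE)
  expect_error(read_demos(dir), "time grid|increasing")

  dir2 <- withr::local_tempdir()
  write_demos(demo_dataset(ds$episodes[1:2], hz = ds$hz), dir2)
  f2 <- file.path(dir2, "episodes", paste0(ds$episodes[[1]]$meta$id, ".csv"))
  df2 <- utils::read.csv(f2)
  df2$mystery <- 1
  utils::write.csv(df2, f2, row.names = FALSE, quote = FALSE)
  expect_warning(read_demos(dir2), "mystery")
})

test_that("inverse dynamics recovers hand-computed thrusts and labels", {
  p <- agents_params()
  # rest -> v' = (0.3, 0): thrust (1, 0), the 0-degree direction (label 1)
  ep <- toy_episode(rbind(c(0, 0), c(0.3, 0)))
  lab <- infer_actions(ep, p)
  expect_equal(lab$actions[1, 1], 1L)
  expect_equal(lab$residuals[1, 1], 0)

  # pure damping (v' = (1 - d) v): zero thrust, no-op
  ep2 <- toy_episode(rbind(c(0.4, 0.2), 0.75 * c(0.4, 0.2)))
  lab2 <- infer_actions(ep2, p)
  expect_equal(lab2$actions[1, 1], 0L)
  expect_equal(lab2$residuals[1, 1], 0)

  # thrust at 45 degrees: equidistant between 30 and 60; snaps to the lower
  # index (label 2 = 30 degrees)
  dir45 <- c(cos(pi / 4), sin(pi / 4))
  ep3 <- toy_episode(rbind(c(0, 0), p$u * p$dt * dir45))
  lab3 <- infer_actions(ep3, p)
  expect_equal(lab3$actions[1, 1], 2L)
  expect_equal(lab3$residuals[1, 1],
               sqrt(sum((dir45 - c(cos(pi / 6), sin(pi / 6)))^2)))

  expect_error(infer_actions(ep, locomotion_params(0.25, 1, 0.1)), NA)
})

test_that("inverse dynamics recovers generated action sequences exactly", {
  ds <- stop_and_go_demos(n = 10, seed = 3)
  for (frac in c(0.1, 0.3, 0.49)) {
    acc <- vapply(ds$episodes, function(ep) {
      # generator gave the target reduced thrust; label with matching params
      prey <- locomotion_params(0.25, 3.0 / 1.2, 0.1)
      a1 <- infer_actions(ep, agents_params(), frac)$actions[1:2, ,
                                                             drop = FALSE]
      a3 <- infer_actions(ep, prey, frac)$actions[3, ]
      mean(rbind(a1, a3) == ep$meta$actions)
    }, numeric(1))
    expect_equal(mean(acc), 1)
  }
})

test_that("straight-pursuit top speed approaches the closed-form terminal speed", {
  # equal chaser/prey thrust and a wall-hugging prey give long chases with
  # sustained straight runs
  p <- agents_params()
  ds <- generate_synthetic_demos(species_env_config("agents", demo = TRUE),
                                 rep(list(p), 3), "straight_pursuit", 100,
                                 seed = 42,
                                 policy_opts = list(flee_margin = 0.9))
  sp <- vapply(ds$episodes, function(ep) {
    max(sqrt(ep$velocities[1, , 1]^2 + ep$velocities[1, , 2]^2))
  }, numeric(1))
  vterm <- 3.0 * 0.1 / 0.25
  expect_lt(abs(max(sp) - vterm) / vterm, 0.02)
  # speed never exceeds the cap (fixed point plus one step)
  expect_lt(max(sp), vterm + 3.0 * 0.1)
})

test_that("generation is deterministic and n = 0 yields an empty dataset", {
  cfg <- species_env_config("agents", demo = TRUE)
  a <- generate_synthetic_demos(cfg, agents_params(), "random_walk", 3,
                                seed = 9)
  b <- generate_synthetic_demos(cfg, agents_params(), "random_walk", 3,
                                seed = 9)
  expect_identical(a, b)
  expect_length(generate_synthetic_demos(cfg, agents_params(), "random_walk",
                                         0, seed = 1)$episodes, 0)
  expect_error(generate_synthetic_demos(cfg, agents_params(), "random_walk",
                                        -1, seed = 1), "n_episodes")
})

test_that("a positive pause-scaling condition effect lengthens chaser paths", {
  ds <- stop_and_go_demos(n = 200, seed = 13, pause_scale = 3)
  pl <- vapply(ds$episodes, function(ep) {
    mean(vapply(1:2, function(k) {
      sum(sqrt(rowSums(diff(matrix(ep$positions[k, , ], ncol = 2))^2)))
    }, numeric(1)))
  }, numeric(1))
  cond <- vapply(ds$episodes, function(ep) ep$condition, integer(1))
  expect_gt(mean(pl[cond == 1]), mean(pl[cond == 0]))
  # sign test on bootstrap resamples of the mean difference: the fraction of
  # positive resamples must exceed chance decisively (binomial p < 0.01)
  B <- 2000
  a <- pl[cond == 1]; b <- pl[cond == 0]
  set.seed(1)
  reps <- vapply(seq_len(B), function(i) {
    mean(sample(a, length(a), replace = TRUE)) -
      mean(sample(b, length(b), replace = TRUE))
  }, numeric(1))
  pv <- stats::binom.test(sum(reps > 0), B, 0.5,
                          alternative = "greater")$p.value
  expect_lt(pv, 0.01)
})

test_that("splits are stratified by condition and reproducible", {
  set.seed(1)
  eps <- lapply(seq_len(500), function(i) {
    parked_episode(sprintf("e%03d", i), condition = (i - 1L) %% 2L)
  })
  ds <- demo_dataset(eps, hz = 10)
  sp <- split_dataset(ds, counts = c(400, 50, 50), seed = 2)
  cond <- vapply(sp$episodes, function(e) e$condition, integer(1))
  tab <- table(sp$split, cond)
  expect_equal(unname(tab["train", ]), c(200, 200))
  expect_equal(unname(tab["val", ]), c(25, 25))
  expect_equal(unname(tab["test", ]), c(25, 25))

  sp2 <- split_dataset(ds, counts = c(400, 50, 50), seed = 2)
  expect_identical(sp$split, sp2$split)

  all_train <- split_dataset(ds, fractions = c(1, 0, 0), seed = 1)
  expect_true(all(all_train$split == "train"))

  expect_error(split_dataset(ds, counts = c(400, 80, 80)), "parameter error")
})
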