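# Shared fixtures and independent oracles for the test suite.

agents_params <- function() locomotion_params(d = 0.25, u = 3.0, dt = 0.1)

# lazily-built shared datasets (generation is deterministic but not free)
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- force(expr)
  .fixture_cache[[name]]
}

straight_demos <- function(n = 200, seed = 42) {
  cached(sprintf("straight_%d_%d", n, seed), {
    generate_synthetic_demos(species_env_config("agents", demo = TRUE),
                             agents_params(), "straight_pursuit", n,
                             seed = seed)
  })
}

stop_and_go_demos <- function(n = 60, seed = 7, pause_scale = 3) {
  cached(sprintf("sg_%d_%d_%g", n, seed, pause_scale), {
    generate_synthetic_demos(species_env_config("agents", demo = TRUE),
                             agents_params(), "stop_and_go_pursuit", n,
                             condition_effect = list(pause_scale = pause_scale),
                             seed = seed)
  })
}

# minimal hand-built episode: one agent, given velocity rows (T x 2);
# positions integrated to stay consistent with the stored velocities
toy_episode <- function(vel, dt = 0.1, roles = "solo", condition = 0L,
                        id = "toy") {
  Tn <- nrow(vel)
  disp <- vel * dt
  disp[1, ] <- 0                      # p[t] = p[t-1] + v[t] dt, p[1] = 0
  pos <- apply(disp, 2, cumsum)
  K <- 1L
  p <- array(0, c(K, Tn, 2)); v <- array(0, c(K, Tn, 2))
  p[1, , ] <- pos; v[1, , ] <- vel
  episode(times = (seq_len(Tn) - 1) * dt, positions = p, velocities = v,
          roles = roles, condition = condition, meta = list(id = id))
}

# small multi-agent episode with constant positions (for split tests etc.)
parked_episode <- function(id, condition = 0L, K = 3L, Tn = 3L, dt = 0.1,
                           pos0 = NULL) {
  pos <- array(0, c(K, Tn, 2)); vel <- array(0, c(K, Tn, 2))
  if (is.null(pos0)) pos0 <- matrix(stats::runif(K * 2, -0.4, 0.4), K, 2)
  for (t in seq_len(Tn)) pos[, t, ] <- pos0
  roles <- if (K == 1) "solo" else c(rep("chaser", K - 1), "target")
  episode(times = (seq_len(Tn) - 1) * dt, positions = pos, velocities = vel,
          roles = roles, condition = condition, meta = list(id = id))
}

# brute-force DTW: minimum summed local cost over all admissible warping
# paths from (1,1) to (t,j) with steps (1,0), (0,1), (1,1)
brute_dtw <- function(a, b) {
  n <- length(a); m <- length(b)
  best <- matrix(Inf, n, m)
  rec <- function(t, j, acc) {
    acc <- acc + abs(a[t] - b[j])
    if (acc >= best[t, j]) return(invisible())
    best[t, j] <<- acc
    if (t < n) rec(t + 1, j, acc)
    if (j < m) rec(t, j + 1, acc)
    if (t < n && j < m) rec(t + 1, j + 1, acc)
    invisible()
  }
  rec(1, 1, 0)
  best
}

# all sequences of length 1..maxlen over the given alphabet
all_sequences <- function(alphabet, maxlen) {
  out <- list()
  for (len in seq_len(maxlen)) {
    grid <- do.call(expand.grid, rep(list(alphabet), len))
    for (i in seq_len(nrow(grid))) out[[length(out) + 1L]] <-
        as.numeric(grid[i, ])
  }
  out
}
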