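# Simplified odor-source navigation environment: a single agent (silkmoth)
# moves in an open field under the same first-order locomotion model and
# senses a synthetic, intermittently gated Gaussian plume.

#' Generate a synthetic odor/wind plume
#'
#' A time-varying Gaussian-plume-like odor field: concentration decays with
#' downwind distance from the source and crosswind offset (the plume widens
#' downwind), gated multiplicatively by an intermittent on/off factor per
#' frame (the source cell itself always reads the maximal value 1). The wind
#' field is constant in direction with small per-frame noise. Grids live on
#' \[-1, 1\]^2 arena coordinates.
#'
#' @param grid_shape `c(ny, nx)` grid size.
#' @param n_frames number of time frames.
#' @param source source position, arena coordinates (default origin).
#' @param advection_dir downwind direction, radians (odor drifts this way).
#' @param diffusion_scale crosswind widening rate (arena units per unit
#'   downwind distance).
#' @param intermittency probability per frame that the plume is "off"
#'   (gated to 20% concentration); 0 gives a time-constant field.
#' @param seed integer seed.
#' @return list of class `plume_field` with `odor` (`t x ny x nx`), `wind`
#'   (`t x ny x nx x 2`), `source`, `xs`, `ys`.
#' @export
make_synthetic_plume <- function(grid_shape = c(41L, 41L), n_frames = 50L,
                                 source = c(0, 0), advection_dir = pi,
                                 diffusion_scale = 0.15, intermittency = 0.3,
                                 seed = 1L) {
  if (any(grid_shape <= 0) || n_frames <= 0) {
    stopf("grid shape and frame count must be positive")
  }
  if (intermittency < 0 || intermittency > 1) {
    stopf("intermittency must lie in [0, 1]")
  }
  ny <- grid_shape[1]; nx <- grid_shape[2]
  xs <- seq(-1, 1, length.out = nx)
  ys <- seq(-1, 1, length.out = ny)
  down <- c(cos(advection_dir), sin(advection_dir))
  base <- outer(ys, xs, function(y, x) {
    rx <- x - source[1]; ry <- y - source[2]
    s <- rx * down[1] + ry * down[2]          # downwind distance
    cw <- -rx * down[2] + ry * down[1]        # crosswind offset
    sigma <- diffusion_scale * (0.05 + pmax(s, 0))
    ifelse(s >= 0, exp(-cw^2 / (2 * sigma^2)) * exp(-s), 0)
  })
  si <- c(which.min(abs(ys - source[2])), which.min(abs(xs - source[1])))
  with_seed(seed, {
    gate <- ifelse(stats::runif(n_frames) < intermittency, 0.2, 1)
    if (intermittency == 0) gate <- rep(1, n_frames)
    odor <- array(NA_real_, c(n_frames, ny, nx))
    wind <- array(NA_real_, c(n_frames, ny, nx, 2))
    for (t in seq_len(n_frames)) {
      fr <- base * gate[t]
      fr[si[1], si[2]] <- 1       # source cell always maximal
      odor[t, , ] <- fr
      w <- -down + stats::rnorm(2, sd = 0.05)   # wind blows from the source
      wind[t, , , 1] <- w[1]
      wind[t, , , 2] <- w[2]
    }
    structure(list(odor = odor, wind = wind, source = source, xs = xs,
                   ys = ys),
              class = "plume_field")
  })
}

#' Bilinear interpolation of one plume frame at an arena position
#' @noRd
plume_sample <- function(field2d, xs, ys, pos) {
  x <- min(max(pos[1], xs[1]), xs[length(xs)])
  y <- min(max(pos[2], ys[1]), ys[length(ys)])
  ix <- findInterval(x, xs, all.inside = TRUE)
  iy <- findInterval(y, ys, all.inside = TRUE)
  fx <- (x - xs[ix]) / (xs[ix + 1] - xs[ix])
  fy <- (y - ys[iy]) / (ys[iy + 1] - ys[iy])
  (1 - fy) * ((1 - fx) * field2d[iy, ix] + fx * field2d[iy, ix + 1]) +
    fy * ((1 - fx) * field2d[iy + 1, ix] + fx * field2d[iy + 1, ix + 1])
}

#' Initial state of the moth environment
#'
#' @param position starting position, arena coordinates.
#' @return list of class `moth_state` (`position`, `velocity`, `body_angle`,
#'   `t`, `done`).
#' @export
reset_moth <- function(position = c(0.8, 0)) {
  structure(list(position = as.numeric(position), velocity = c(0, 0),
                 body_angle = pi, t = 0L, done = FALSE),
            class = "moth_state")
}

#' Moth sensory observation (absolute position excluded)
#'
#' Odor at the left/right antennae (bilinear plume samples at lateral offsets
#' from the body axis), a 4-way one-hot wind direction relative to the body
#' angle (front/back/left/right, 45-degree sectors), a left/right optic-flow
#' proxy (positive parts of the lateral self-velocity component), the
#' velocity and the body angle as (cos, sin). 12 entries in total.
#'
#' @param state a `moth_state`.
#' @param plume a [make_synthetic_plume()] field.
#' @param antenna_offset lateral antenna offset, arena units.
#' @return numeric observation vector of length 12.
#' @export
moth_observation <- function(state, plume, antenna_offset = 0.05) {
  fr <- state$t %% dim(plume$odor)[1] + 1L
  odor2d <- plume$odor[fr, , ]
  ba <- state$body_angle
  lat <- c(-sin(ba), cos(ba))
  oL <- plume_sample(odor2d, plume$xs, plume$ys,
                     state$position + antenna_offset * lat)
  oR <- plume_sample(odor2d, plume$xs, plume$ys,
                     state$position - antenna_offset * lat)
  w <- c(plume$wind[fr, 1, 1, 1], plume$wind[fr, 1, 1, 2])
  rel <- atan2(w[2], w[1]) - ba
  rel <- atan2(sin(rel), cos(rel))
  wind4 <- numeric(4)                     # front/back/left/right
  sector <- if (abs(rel) <= pi / 4) 1 else if (abs(rel) >= 3 * pi / 4) 2 else {
    if (rel > 0) 3 else 4
  }
  wind4[sector] <- 1
  vlat <- sum(state$velocity * lat)
  vision <- c(max(vlat, 0), max(-vlat, 0))
  c(oL, oR, wind4, vision, state$velocity, cos(ba), sin(ba))
}

#' Advance the moth environment by one step
#'
#' Kinematics follow the locomotion model; the body angle equals the
#' direction of the velocity vector whenever the moth is moving (held at its
#' previous value at rest). Reaching within `config$contact_radius` of the
#' odor source yields +1 and terminates; there is no boundary (open field).
#'
#' @param state a `moth_state`.
#' @param action 0-based action label in `0..12`.
#' @param plume a [make_synthetic_plume()] field.
#' @param params a [locomotion_params()].
#' @param config an [env_config()] (moth preset: open arena).
#' @return `list(state, reward, done, observation)`.
#' @export
step_moth <- function(state, action, plume, params, config) {
  if (state$done) stopf("episode already terminated")
  if (action < 0 || action > 12) stopf("action must lie in 0..12")
  a <- action_unit_vectors()[action + 1L, ]
  v <- predict_next_velocity(state$velocity, a, params)
  state$position <- state$position + v * params$dt
  state$velocity <- v
  if (sqrt(sum(v^2)) > 0) state$body_angle <- atan2(v[2], v[1])
  state$t <- state$t + 1L
  reward <- 0
  if (sqrt(sum((state$position - plume$source)^2)) <= config$contact_radius) {
    reward <- 1
    state$done <- TRUE
  } else if (state$t * config$dt > config$time_limit) {
    state$done <- TRUE
  }
  list(state = state, reward = reward, done = state$done,
       observation = moth_observation(state, plume))
}
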