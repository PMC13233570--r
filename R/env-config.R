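#' Environment configuration for the pursuit and odor-navigation tasks
#'
#' @param n_agents number of agents `K`.
#' @param arena one of `"square"` (half-width 1), `"circle"` (radius 1) or
#'   `"open"` (no boundary).
#' @param boundary_margin the virtual boundary sits at `1 + boundary_margin`
#'   (default 0.1, i.e. at 1.1).
#' @param agent_diameter disc diameter of every agent, arena units.
#' @param dt simulation time step, seconds.
#' @param time_limit episode time limit, seconds.
#' @param contact_radius chaser-target center distance that counts as contact
#'   and terminates the episode.
#' @param boundary_penalty reward paid to an agent that crosses the virtual
#'   boundary (default -10); the episode then ends for all agents.
#' @param reward_scheme `"individual"` (+1 only to the touching chaser) or
#'   `"shared"` (+1 to every chaser on any capture).
#' @param predator_mobility_factor thrust multiplier applied to chasers when
#'   mobility scaling is requested (see [mobility_scaled_params()]).
#' @param target_time_reward if `TRUE` (default) the target collects a reward
#'   equal to the elapsed time in seconds, paid once at termination; if
#'   `FALSE`, paid as `dt` per surviving step.
#' @param include_ego_velocity include the ego velocity in observations
#'   (default `FALSE`: observations are the ego absolute position plus
#'   relative positions/velocities of the others).
#' @param action_count fixed at 13 (no-op + 12 directions).
#' @return An object of class `env_config`.
#' @export
env_config <- function(n_agents = 3L,
                       arena = c("square", "circle", "open"),
                       boundary_margin = 0.1,
                       agent_diameter = 0.1,
                       dt = 0.1,
                       time_limit = 14.8,
                       contact_radius = 0.1,
                       boundary_penalty = -10,
                       reward_scheme = c("individual", "shared"),
                       predator_mobility_factor = 1.2,
                       target_time_reward = TRUE,
                       include_ego_velocity = FALSE,
                       action_count = 13L) {
  arena <- match.arg(arena)
  reward_scheme <- match.arg(reward_scheme)
  if (dt <= 0) stopf("dt must be positive")
  if (time_limit <= 0) stopf("time_limit must be positive")
  if (contact_radius <= 0) stopf("contact_radius must be positive")
  if (action_count != 13L) stopf("action_count is fixed at 13")
  structure(list(n_agents = as.integer(n_agents), arena = arena,
                 boundary_margin = boundary_margin,
                 agent_diameter = agent_diameter, dt = dt,
                 time_limit = time_limit, contact_radius = contact_radius,
                 boundary_penalty = boundary_penalty,
                 reward_scheme = reward_scheme,
                 predator_mobility_factor = predator_mobility_factor,
                 target_time_reward = target_time_reward,
                 include_ego_velocity = include_ego_velocity,
                 action_count = 13L),
            class = "env_config")
}

#' @export
print.env_config <- function(x, ...) {
  cat(sprintf("<env_config> K = %d, %s arena, dt = %g s, limit = %g s, contact = %g, reward = %s\n",
              x$n_agents, x$arena, x$dt, x$time_limit, x$contact_radius,
              x$reward_scheme))
  invisible(x)
}

#' Species presets for the environment configuration
#'
#' Bundles the per-species time step, time limit, arena shape and contact
#' radius: artificial agents (10 Hz, 14.8 s limit, square, contact 0.1),
#' flies (10 Hz, 50 s, circular, 0.2), newts (10 Hz, 50 s, square, 0.15) and
#' silkmoths (2 Hz, 300 s, open field, 0.1). For the artificial agents the
#' demonstration-generation limit (30 s) differs from the RL limit (14.8 s);
#' pass `demo = TRUE` for the former.
#'
#' @param species one of `"agents"`, `"fly"`, `"newt"`, `"moth"`.
#' @param demo use the demonstration-generation time limit where it differs.
#' @param ... overrides forwarded to [env_config()].
#' @return An [env_config()].
#' @export
species_env_config <- function(species = c("agents", "fly", "newt", "moth"),
                               demo = FALSE, ...) {
  species <- match.arg(species)
  base <- switch(species,
    agents = list(n_agents = 3L, arena = "square", dt = 0.1,
                  time_limit = if (demo) 30 else 14.8, contact_radius = 0.1),
    fly = list(n_agents = 3L, arena = "circle", dt = 0.1, time_limit = 50,
               contact_radius = 0.2),
    newt = list(n_agents = 3L, arena = "square", dt = 0.1, time_limit = 50,
                contact_radius = 0.15),
    moth = list(n_agents = 1L, arena = "open", dt = 0.5, time_limit = 300,
                contact_radius = 0.1))
  args <- utils::modifyList(base, list(...))
  do.call(env_config, args)
}
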