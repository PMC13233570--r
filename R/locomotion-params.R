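#' Locomotion parameters of the first-order velocity transition model
#'
#' The velocity of an agent evolves as
#' \deqn{v' = (1 - d)\,v + u\,a\,\Delta t,}
#' where `d` is a dimensionless damping coefficient in \[0, 1\], `u > 0` is the
#' amplitude of the discrete control input `a` (a unit vector or zero for
#' no-op), and `dt` is the sampling interval in seconds. All spatial
#' coordinates are normalized arena units, so `u` is in normalized units per
#' second squared.
#'
#' @param d damping coefficient, in \[0, 1\].
#' @param u control input amplitude, > 0.
#' @param dt time step in seconds, > 0.
#' @return An object of class `locomotion_params`.
#' @examples
#' p <- locomotion_params(d = 0.25, u = 3.0, dt = 0.1)
#' predict_next_velocity(c(1, 0), c(1, 0), p) # c(1.05, 0)
#' @export
locomotion_params <- function(d, u, dt = 0.1) {
  if (!is.numeric(d) || length(d) != 1 || d < 0 || d > 1) {
    stopf("`d` must be a single number in [0, 1], got %s", format(d))
  }
  if (!is.numeric(u) || length(u) != 1 || u <= 0) {
    stopf("`u` must be a single positive number, got %s", format(u))
  }
  if (!is.numeric(dt) || length(dt) != 1 || dt <= 0) {
    stopf("`dt` must be a single positive number, got %s", format(dt))
  }
  structure(list(d = as.numeric(d), u = as.numeric(u), dt = as.numeric(dt)),
            class = "locomotion_params")
}

#' @export
print.locomotion_params <- function(x, ...) {
  cat(sprintf("<locomotion_params> d = %.4g, u = %.4g, dt = %.4g s\n",
              x$d, x$u, x$dt))
  invisible(x)
}

#' One-step velocity prediction under the locomotion model
#'
#' @param v current velocity, numeric length-2 (or an n x 2 matrix).
#' @param action_unit_vector the control direction: a unit vector, or the zero
#'   vector for the no-acceleration action (matching `v` in shape).
#' @param params a [locomotion_params()] object.
#' @return The next velocity `(1 - d) v + u a dt`, same shape as `v`.
#' @export
predict_next_velocity <- function(v, action_unit_vector, params) {
  stopifnot(inherits(params, "locomotion_params"))
  (1 - params$d) * v + params$u * action_unit_vector * params$dt
}

#' Discrete action set: no-op plus 12 directions every 30 degrees
#'
#' Action index 1 (R indexing; index 0 in the on-disk labels) is the
#' no-acceleration action. Indices 2..13 map to unit vectors at angles
#' `(k - 1) * 30` degrees for k = 1..12, with 0 degrees along +x and angles
#' counter-clockwise.
#'
#' @return A 13 x 2 matrix of control vectors; row 1 is `c(0, 0)`.
#' @export
action_unit_vectors <- function() {
  ang <- (0:11) * pi / 6
  rbind(c(0, 0), cbind(cos(ang), sin(ang)))
}

#' Scale chaser thrust by the predator mobility factor
#'
#' The pursuit environment can make predators faster than the prey by scaling
#' the thrust amplitude `u` only (damping and the time step are untouched), so
#' terminal speeds scale by the same factor.
#'
#' @param prey_params [locomotion_params()] of the prey.
#' @param factor mobility factor (e.g. 1.2 for 120%).
#' @return [locomotion_params()] for the predator.
#' @export
mobility_scaled_params <- function(prey_params, factor) {
  locomotion_params(d = prey_params$d, u = prey_params$u * factor,
                    dt = prey_params$dt)
}
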