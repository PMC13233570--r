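#' A single demonstration or rollout episode
#'
#' Stores the time-indexed 2D positions and velocities of `K` agents on a
#' uniform time grid, together with agent roles, the binary experimental
#' condition flag and per-episode reward events. Coordinates are normalized
#' arena units with the arena center at the origin.
#'
#' @param times numeric vector of length `T`, strictly increasing with a
#'   constant step `dt`.
#' @param positions `K x T x 2` array of positions.
#' @param velocities `K x T x 2` array of velocities (normalized units/s).
#' @param roles character vector of length `K`; each one of
#'   `"chaser"`, `"target"`, `"solo"`.
#' @param condition binary condition flag (0 or 1).
#' @param reward_events data.frame with columns `t` (time index), `agent`
#'   (agent index) and `value`, or `NULL` for none.
#' @param meta list of metadata; `meta$id` names the episode. The generator
#'   stores the true action labels in `meta$actions` (`K x (T-1)` integer
#'   matrix, 0 = no-op).
#' @param validate run invariant checks (default `TRUE`).
#' @param tol tolerance for the position/velocity consistency check.
#' @param boundary_limit forwarded to [validate_episode()]; a terminating
#'   boundary-crossing frame may legitimately overshoot 1.1 by up to one step
#'   at the speed cap.
#' @return An object of class `episode`.
#' @export
episode <- function(times, positions, velocities, roles, condition = 0L,
                    reward_events = NULL, meta = list(), validate = TRUE,
                    tol = 1e-6, boundary_limit = 1.1) {
  if (is.null(reward_events)) {
    reward_events <- data.frame(t = integer(), agent = integer(),
                                value = numeric())
  }
  ep <- structure(
    list(times = as.numeric(times), positions = positions,
         velocities = velocities, roles = as.character(roles),
         condition = as.integer(condition), reward_events = reward_events,
         meta = meta),
    class = "episode")
  if (validate) validate_episode(ep, tol = tol,
                                 boundary_limit = boundary_limit)
  ep
}

#' Check the structural invariants of an episode
#'
#' Verifies the uniform time grid, array shapes, role labels, that positions
#' stay within the inflated arena boundary, and that stored velocities are
#' consistent with the finite differences of positions
#' (`v[t] = (p[t] - p[t-1]) / dt` for `t >= 2`).
#'
#' @param ep an [episode()].
#' @param tol numeric tolerance for the velocity consistency check; `Inf`
#'   disables it (real tracking data are smoothed, so stored velocities may
#'   legitimately differ from raw differences).
#' @param boundary_limit positions must satisfy `max(|x|, |y|) <=` this value
#'   (arena half-width plus boundary margin, default 1.1) plus `1e-9`.
#' @return `ep`, invisibly; errors describe the failing episode by id.
#' @export
validate_episode <- function(ep, tol = 1e-6, boundary_limit = 1.1) {
  id <- ep$meta$id %||% "<unnamed>"
  tt <- ep$times
  if (length(tt) < 2) stopf("episode %s: needs at least 2 time points", id)
  dts <- diff(tt)
  if (any(dts <= 0)) stopf("episode %s: times must be strictly increasing", id)
  if (max(dts) - min(dts) > 1e-9 * max(dts)) {
    stopf("episode %s: non-uniform time grid (dt ranges %.3g..%.3g)",
          id, min(dts), max(dts))
  }
  K <- dim(ep$positions)[1]
  Tn <- length(tt)
  if (!identical(dim(ep$positions), c(K, Tn, 2L)) &&
      !identical(dim(ep$positions), as.integer(c(K, Tn, 2)))) {
    stopf("episode %s: positions must be K x T x 2", id)
  }
  if (!identical(dim(ep$velocities), dim(ep$positions))) {
    stopf("episode %s: velocities must match positions in shape", id)
  }
  if (length(ep$roles) != K) stopf("episode %s: one role per agent", id)
  if (!all(ep$roles %in% c("chaser", "target", "solo"))) {
    stopf("episode %s: roles must be chaser/target/solo", id)
  }
  if (!ep$condition %in% c(0L, 1L)) {
    stopf("episode %s: condition must be 0 or 1", id)
  }
  if (max(abs(ep$positions)) > boundary_limit + 1e-9) {
    stopf("episode %s: positions exceed the boundary limit %.3g",
          id, boundary_limit)
  }
  if (is.finite(tol) && Tn >= 2) {
    dt <- dts[1]
    fd <- (ep$positions[, -1, , drop = FALSE] -
             ep$positions[, -Tn, , drop = FALSE]) / dt
    err <- max(abs(fd - ep$velocities[, -1, , drop = FALSE]))
    if (err > tol) {
      stopf("episode %s: stored velocities deviate from position differences by %.3g (tol %.3g)",
            id, err, tol)
    }
  }
  invisible(ep)
}

#' @export
print.episode <- function(x, ...) {
  cat(sprintf("<episode %s> K = %d, T = %d (%.1f s), condition = %d, roles: %s\n",
              x$meta$id %||% "?", dim(x$positions)[1], length(x$times),
              diff(range(x$times)), x$condition,
              paste(x$roles, collapse = "/")))
  invisible(x)
}

#' Number of time points / agents of an episode
#' @param ep an [episode()].
#' @return integer.
#' @export
episode_length <- function(ep) length(ep$times)

#' @rdname episode_length
#' @export
episode_agents <- function(ep) dim(ep$positions)[1]

#' A set of demonstration episodes with a train/validation/test split
#'
#' @param episodes list of [episode()] objects.
#' @param hz sampling rate in 1/s; must satisfy `hz * dt = 1`.
#' @param split character vector (one of `"train"`, `"val"`, `"test"`) per
#'   episode, or `NULL` for unassigned.
#' @param species_tag one of `"agents"`, `"fly"`, `"newt"`, `"moth"`.
#' @return An object of class `demo_dataset`.
#' @export
demo_dataset <- function(episodes, hz, split = NULL,
                         species_tag = c("agents", "fly", "newt", "moth")) {
  species_tag <- match.arg(species_tag)
  if (is.null(split)) split <- rep(NA_character_, length(episodes))
  if (length(split) != length(episodes)) {
    stopf("`split` must have one entry per episode")
  }
  if (length(episodes) > 0) {
    dt <- diff(episodes[[1]]$times[1:2])
    if (abs(hz * dt - 1) > 1e-6) {
      stopf("hz (%g) is inconsistent with the episode time step (%g s)", hz, dt)
    }
  }
  structure(list(episodes = episodes, hz = as.numeric(hz), split = split,
                 species_tag = species_tag),
            class = "demo_dataset")
}

#' @export
print.demo_dataset <- function(x, ...) {
  n <- length(x$episodes)
  cat(sprintf("<demo_dataset> %d episodes, %g Hz, species '%s'\n",
              n, x$hz, x$species_tag))
  if (n > 0) {
    tab <- table(factor(x$split, levels = c("train", "val", "test")),
                 useNA = "ifany")
    cat("  split:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
        "\n")
    cond <- vapply(x$episodes, function(e) e$condition, integer(1))
    cat("  conditions:", paste(sprintf("c%d=%d", as.integer(names(table(cond))),
                                       table(cond)), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Subset a dataset by split label
#' @param dataset a [demo_dataset()].
#' @param which one of `"train"`, `"val"`, `"test"`.
#' @return a [demo_dataset()] containing only the requested episodes.
#' @export
dataset_split <- function(dataset, which) {
  keep <- !is.na(dataset$split) & dataset$split == which
  demo_dataset(dataset$episodes[keep], hz = dataset$hz,
               split = dataset$split[keep], species_tag = dataset$species_tag)
}
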