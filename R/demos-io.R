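#' Write a demonstration dataset to disk
#'
#' The on-disk layout is one JSON manifest (`manifest.json`: time step,
#' sampling rate, species tag, schema version, and per-episode roles, split,
#' condition, reward events and optional recorded action labels) plus one CSV
#' per episode under `episodes/` with columns `t,agent,x,y,vx,vy`. Numeric
#' values are written with 17 significant digits, so
#' `read_demos(write_demos(x))` reproduces `x` exactly.
#'
#' @param dataset a [demo_dataset()].
#' @param path directory to create/write into.
#' @return invisibly, a manifest summary list (`path`, `n_episodes`, `hz`).
#' @export
write_demos <- function(dataset, path) {
  stopifnot(inherits(dataset, "demo_dataset"))
  ok <- dir.exists(path) || dir.create(path, recursive = TRUE,
                                       showWarnings = FALSE)
  if (!ok || !dir.exists(path)) stopf("cannot create directory '%s'", path)
  ep_dir <- file.path(path, "episodes")
  dir.create(ep_dir, showWarnings = FALSE)
  fmt <- function(x) sprintf("%.17g", x)

  entries <- vector("list", length(dataset$episodes))
  for (i in seq_along(dataset$episodes)) {
    ep <- dataset$episodes[[i]]
    id <- ep$meta$id %||% sprintf("ep_%04d", i)
    K <- episode_agents(ep)
    Tn <- episode_length(ep)
    rows <- do.call(rbind, lapply(seq_len(K), function(k) {
      data.frame(t = fmt(ep$times), agent = k,
                 x = fmt(ep$positions[k, , 1]), y = fmt(ep$positions[k, , 2]),
                 vx = fmt(ep$velocities[k, , 1]),
                 vy = fmt(ep$velocities[k, , 2]))
    }))
    file_rel <- file.path("episodes", paste0(id, ".csv"))
    utils::write.csv(rows, file.path(path, file_rel), row.names = FALSE,
                     quote = FALSE)
    entries[[i]] <- list(
      id = id, file = file_rel, n_frames = Tn, roles = ep$roles,
      condition = ep$condition,
      split = if (is.na(dataset$split[i])) NULL else dataset$split[i],
      source = ep$meta$source, policy_kind = ep$meta$policy_kind,
      end_reason = ep$meta$end_reason,
      actions = if (is.null(ep$meta$actions)) NULL else {
        unname(apply(ep$meta$actions, 1, as.list, simplify = FALSE))
      },
      reward_events = if (nrow(ep$reward_events) == 0) NULL else {
        ep$reward_events
      })
  }
  manifest <- list(schema_version = 1L, hz = dataset$hz,
                   dt = if (length(dataset$episodes) > 0) {
                     diff(dataset$episodes[[1]]$times[1:2])
                   } else 1 / dataset$hz,
                   species_tag = dataset$species_tag,
                   n_episodes = length(dataset$episodes),
                   episodes = entries)
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(list(path = path, n_episodes = length(dataset$episodes),
                 hz = dataset$hz))
}

#' Read a demonstration dataset from disk
#'
#' Reads the layout written by [write_demos()]. All episode invariants are
#' checked on load; unknown CSV columns are ignored with a warning.
#'
#' @param path dataset directory containing `manifest.json`.
#' @param schema_version expected manifest schema version.
#' @param tol velocity-consistency tolerance forwarded to
#'   [validate_episode()]; use `Inf` for smoothed real recordings.
#' @return a [demo_dataset()].
#' @export
read_demos <- function(path, schema_version = 1L, tol = 1e-6) {
  mf <- file.path(path, "manifest.json")
  if (!file.exists(mf)) {
    stopf("format error: no manifest.json under '%s'", path)
  }
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE,
                                  simplifyDataFrame = FALSE,
                                  simplifyMatrix = FALSE)
  if (!identical(as.integer(manifest$schema_version),
                 as.integer(schema_version))) {
    stopf("format error: schema version %s, expected %s",
          manifest$schema_version, schema_version)
  }
  known <- c("t", "agent", "x", "y", "vx", "vy")
  episodes <- vector("list", length(manifest$episodes))
  split <- rep(NA_character_, length(manifest$episodes))
  for (i in seq_along(manifest$episodes)) {
    e <- manifest$episodes[[i]]
    df <- utils::read.csv(file.path(path, e$file))
    extra <- setdiff(names(df), known)
    if (length(extra) > 0) {
      warnf("episode %s: ignoring unknown columns: %s", e$id,
            paste(extra, collapse = ", "))
      df <- df[known]
    }
    K <- length(e$roles)
    Tn <- as.integer(e$n_frames)
    if (nrow(df) != K * Tn) {
      stopf("validation error: episode %s has %d rows, expected %d",
            e$id, nrow(df), K * Tn)
    }
    pos <- array(NA_real_, c(K, Tn, 2))
    vel <- array(NA_real_, c(K, Tn, 2))
    tt <- NULL
    for (k in seq_len(K)) {
      sub <- df[df$agent == k, , drop = FALSE]
      if (nrow(sub) != Tn) {
        stopf("validation error: episode %s agent %d has %d frames, expected %d",
              e$id, k, nrow(sub), Tn)
      }
      sub <- sub[order(sub$t), , drop = FALSE]
      if (is.null(tt)) tt <- sub$t
      pos[k, , 1] <- sub$x; pos[k, , 2] <- sub$y
      vel[k, , 1] <- sub$vx; vel[k, , 2] <- sub$vy
    }
    rev_df <- if (is.null(e$reward_events)) NULL else {
      data.frame(
        t = as.integer(vapply(e$reward_events, `[[`, numeric(1), "t")),
        agent = as.integer(vapply(e$reward_events, `[[`, numeric(1), "agent")),
        value = as.numeric(vapply(e$reward_events, `[[`, numeric(1), "value")))
    }
    actions <- if (is.null(e$actions)) NULL else {
      do.call(rbind, lapply(e$actions, function(r) {
        as.integer(unlist(r))
      }))
    }
    meta <- list(id = e$id, source = e$source, policy_kind = e$policy_kind,
                 actions = actions, end_reason = e$end_reason)
    meta <- meta[!vapply(meta, is.null, logical(1))]
    episodes[[i]] <- episode(times = tt, positions = pos, velocities = vel,
                             roles = unlist(e$roles),
                             condition = e$condition,
                             reward_events = rev_df, meta = meta, tol = tol)
    split[i] <- if (is.null(e$split)) NA_character_ else e$split
  }
  demo_dataset(episodes, hz = manifest$hz, split = split,
               species_tag = manifest$species_tag)
}

#' Label discrete actions by inverse dynamics
#'
#' Inverts the locomotion model for each step: the implied control vector is
#' `thrust = (v' - (1 - d) v) / (u dt)`. Steps with `||thrust||` below
#' `noop_threshold_frac` (a fraction of the nominal unit thrust) are labeled
#' no-op (action 0); otherwise the action is the direction among the 12 whose
#' unit vector maximizes the dot product with the thrust, ties broken toward
#' the lowest index. The residual is the distance between the thrust and the
#' chosen control vector.
#'
#' @param ep an [episode()].
#' @param params [locomotion_params()] (single, applied to the given agents).
#' @param noop_threshold_frac no-op threshold as a fraction of unit thrust,
#'   in (0, 1); default 0.5.
#' @return list of class `action_labeling` with `actions`
#'   (`K x (T-1)` integer matrix, labels 0..12) and `residuals`
#'   (same shape).
#' @export
infer_actions <- function(ep, params, noop_threshold_frac = 0.5) {
  stopifnot(inherits(ep, "episode"))
  if (params$u <= 0) stopf("parameter error: u must be positive")
  K <- episode_agents(ep)
  Tn <- episode_length(ep)
  dt <- params$dt
  units <- action_unit_vectors()[-1, , drop = FALSE]
  actions <- matrix(NA_integer_, K, Tn - 1L)
  residuals <- matrix(NA_real_, K, Tn - 1L)
  for (k in seq_len(K)) {
    v <- ep$velocities[k, , , drop = TRUE]
    if (Tn == 2) v <- matrix(v, 2, 2, byrow = FALSE)
    thrust <- (v[-1, , drop = FALSE] - (1 - params$d) * v[-Tn, , drop = FALSE]) /
      (params$u * dt)
    mag <- sqrt(rowSums(thrust^2))
    dots <- thrust %*% t(units)
    for (s in seq_len(Tn - 1L)) {
      if (mag[s] < noop_threshold_frac) {
        actions[k, s] <- 0L
        residuals[k, s] <- mag[s]
      } else {
        row <- dots[s, ]
        best <- which(row >= max(row) - 1e-12)[1]
        actions[k, s] <- as.integer(best)
        residuals[k, s] <- sqrt(sum((thrust[s, ] - units[best, ])^2))
      }
    }
  }
  structure(list(actions = actions, residuals = residuals),
            class = "action_labeling")
}

#' Assign a stratified train/validation/test split
#'
#' When both conditions are present the split is stratified by condition:
#' each condition contributes a share of every split proportional to its
#' prevalence (e.g. 500 episodes, counts `c(400, 50, 50)` and balanced
#' conditions give 200/25/25 per condition).
#'
#' @param dataset a [demo_dataset()].
#' @param counts integer counts `c(train, val, test)`; alternatively
#'   `fractions` of the dataset size.
#' @param fractions numeric fractions summing to <= 1 (used when `counts` is
#'   missing).
#' @param seed integer seed for the shuffle.
#' @return the dataset with its `split` field assigned (episodes beyond the
#'   requested counts stay unassigned).
#' @export
split_dataset <- function(dataset, counts = NULL, fractions = NULL,
                          seed = 1L) {
  n <- length(dataset$episodes)
  if (is.null(counts)) {
    if (is.null(fractions)) stopf("provide counts or fractions")
    counts <- round(fractions * n)
  }
  if (length(counts) != 3) stopf("counts must be c(train, val, test)")
  if (sum(counts) > n) {
    stopf("parameter error: requested %d episodes but only %d available",
          sum(counts), n)
  }
  cond <- vapply(dataset$episodes, function(e) e$condition, integer(1))
  groups <- split(seq_len(n), cond)
  labels <- c("train", "val", "test")
  assignment <- rep(NA_character_, n)
  with_seed(seed, {
    # proportional allocation per condition, largest-remainder rounding
    alloc <- lapply(counts, function(ct) {
      raw <- ct * vapply(groups, length, integer(1)) / n
      base <- floor(raw)
      rem <- ct - sum(base)
      if (rem > 0) {
        extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
        base[extra] <- base[extra] + 1
      }
      base
    })
    for (g in seq_along(groups)) {
      idx <- sample(groups[[g]])
      offset <- 0
      for (s in seq_along(labels)) {
        take <- alloc[[s]][g]
        if (take > 0) {
          assignment[idx[offset + seq_len(take)]] <- labels[s]
          offset <- offset + take
        }
      }
    }
  })
  dataset$split <- assignment
  dataset
}
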