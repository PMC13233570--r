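#' Summary metrics of a rollout episode
#'
#' `return` is the capture indicator (1 if any chaser touched the target, or
#' the solo agent reached the source), `path_length` the mean over chasers
#' (or the solo agent) of the summed stepwise displacement, `duration` the
#' episode length in seconds, and `dtw_to_gt` the mean final DTW cost between
#' each designated agent's rollout positions and its ground-truth positions.
#' Frames after termination contribute nothing (rollouts stop at
#' termination, and a padded stationary tail adds zero displacement and
#' repeats the terminal DTW row minimum only if explicitly included).
#'
#' @param x a `rollout` (from [rollout_policy()]) or an [episode()].
#' @param gt_episode optional ground-truth [episode()] for the DTW metric.
#' @param config an [env_config()] (defines the designated agents via roles).
#' @return list of class `episode_metrics` with fields `return`,
#'   `path_length`, `duration`, `dtw_to_gt`.
#' @export
episode_metrics <- function(x, gt_episode = NULL, config = NULL) {
  if (inherits(x, "rollout")) {
    ep <- x$episode
    chasers <- which(ep$roles %in% c("chaser", "solo"))
    ret <- as.integer(any(x$touch[chasers] > 0))
  } else {
    ep <- x
    chasers <- which(ep$roles %in% c("chaser", "solo"))
    ev <- ep$reward_events
    ret <- as.integer(nrow(ev) > 0 && any(ev$agent %in% chasers &
                                            ev$value > 0))
  }
  dt <- diff(ep$times[1:2])
  pl <- mean(vapply(chasers, function(k) {
    p <- matrix(ep$positions[k, , ], ncol = 2)
    sum(sqrt(rowSums(diff(p)^2)))
  }, numeric(1)))
  dur <- (episode_length(ep) - 1L) * dt
  dtw_gt <- NA_real_
  if (!is.null(gt_episode)) {
    dtw_gt <- mean(vapply(chasers, function(k) {
      dtw_matrix(matrix(ep$positions[k, , ], ncol = 2),
                 matrix(gt_episode$positions[k, , ], ncol = 2))$final_cost
    }, numeric(1)))
  }
  structure(list(return = ret, path_length = pl, duration = dur,
                 dtw_to_gt = dtw_gt),
            class = "episode_metrics")
}

#' L1 distance between Gaussian kernel density estimates
#'
#' Fits a Gaussian KDE to each sample (Scott's bandwidth
#' `sd(x) * n^(-1/5)` by default), evaluates both densities on a shared
#' 512-point grid spanning the pooled range plus three pooled bandwidths,
#' and integrates the absolute difference by the trapezoid rule. The result
#' is symmetric and lies in \[0, 2\].
#'
#' @param a,b numeric samples (length >= 2, nonzero variance).
#' @param bandwidth `"scott"` or a numeric bandwidth.
#' @param grid_size number of grid points (default 512).
#' @return scalar distance.
#' @export
kde_distance <- function(a, b, bandwidth = "scott", grid_size = 512L) {
  for (s in list(a, b)) {
    if (length(s) < 2) stopf("samples must have length >= 2")
    if (stats::sd(s) == 0) {
      stopf("degenerate (constant) sample; consider adding jitter")
    }
  }
  bw <- function(x) {
    if (is.numeric(bandwidth)) bandwidth else stats::sd(x) * length(x)^(-1/5)
  }
  ha <- bw(a); hb <- bw(b)
  h3 <- 3 * max(ha, hb)
  grid <- seq(min(a, b) - h3, max(a, b) + h3, length.out = grid_size)
  dens <- function(x, h) {
    rowMeans(stats::dnorm(outer(grid, x, "-") / h)) / h
  }
  fa <- dens(a, ha)
  fb <- dens(b, hb)
  dx <- diff(grid)
  dif <- abs(fa - fb)
  sum((dif[-1] + dif[-grid_size]) / 2 * dx)
}

#' Paired bootstrap confidence interval
#'
#' Resamples episode indices with replacement `B` times, recomputes
#' `statistic(a*, b*)` per replicate (default: mean difference `a - b`), and
#' reports the percentile interval at the requested level together with the
#' replicate median.
#'
#' @param a,b paired numeric vectors of equal length >= 2.
#' @param statistic function of two resampled vectors returning a scalar.
#' @param B bootstrap replicates (default 10000).
#' @param level confidence level (default 0.95).
#' @param seed integer seed.
#' @return list of class `bootstrap_result` with `median`, `low`, `high`,
#'   `n_replicates`, `level`.
#' @export
paired_bootstrap_ci <- function(a, b,
                                statistic = function(a, b) mean(a - b),
                                B = 10000L, level = 0.95, seed = 1L) {
  if (length(a) != length(b)) stopf("paired samples must have equal length")
  n <- length(a)
  if (n < 2) stopf("need at least 2 pairs")
  reps <- with_seed(seed, {
    vapply(seq_len(B), function(i) {
      idx <- sample.int(n, n, replace = TRUE)
      statistic(a[idx], b[idx])
    }, numeric(1))
  })
  qs <- stats::quantile(reps, c((1 - level) / 2, 0.5, (1 + level) / 2),
                        names = FALSE)
  structure(list(median = qs[2], low = qs[1], high = qs[3],
                 n_replicates = B, level = level),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("%.4g [%.4g, %.4g] (%d replicates, %g%% CI)\n",
              x$median, x$low, x$high, x$n_replicates, 100 * x$level))
  invisible(x)
}

#' One-way F statistic (between/within mean squares)
#' @noRd
oneway_F <- function(groups) {
  ni <- vapply(groups, length, integer(1))
  mi <- vapply(groups, mean, numeric(1))
  gm <- sum(ni * mi) / sum(ni)
  ssb <- sum(ni * (mi - gm)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  if (ssb <= 1e-12 * (ssb + ssw)) return(0)
  dfb <- length(groups) - 1L
  dfw <- sum(ni) - length(groups)
  (ssb / dfb) / (ssw / dfw)
}

#' Bootstrap one-way ANOVA on groups of absolute gaps
#'
#' Per replicate, one episode index set is drawn with replacement and applied
#' to every group (the groups are paired per-episode gaps of different
#' methods, so the same resamples feed every group), and the one-way F
#' statistic is computed. Reports the replicate median F and the fraction of
#' replicates with `F > 0`. Identical groups therefore give F = 0 in every
#' replicate.
#'
#' @param groups list of >= 2 numeric vectors of equal length >= 2.
#' @param B bootstrap replicates.
#' @param seed integer seed.
#' @return list with `median_F`, `frac_positive`, and the replicate values
#'   `F_values`.
#' @export
bootstrap_anova <- function(groups, B = 10000L, seed = 1L) {
  if (length(groups) < 2) stopf("need at least 2 groups")
  ni <- vapply(groups, length, integer(1))
  if (any(ni < 2)) stopf("every group needs at least 2 values")
  if (length(unique(ni)) != 1) {
    stopf("groups are paired per episode and must have equal length")
  }
  n <- ni[1]
  Fs <- with_seed(seed, {
    vapply(seq_len(B), function(i) {
      idx <- sample.int(n, n, replace = TRUE)
      oneway_F(lapply(groups, function(g) g[idx]))
    }, numeric(1))
  })
  list(median_F = stats::median(Fs), frac_positive = mean(Fs > 0),
       F_values = Fs)
}

#' Counterfactual cue-flip analysis
#'
#' Rolls out every evaluation episode twice from the same initial state --
#' once with the recorded condition cue, once with the flipped cue -- under
#' matched RNG (the same seed per pair, so with greedy rollouts the two
#' differ only through the cue). The per-episode shift is the counterfactual
#' minus the factual mean chaser path length; bootstrap CIs are reported for
#' the signed shift and for the absolute error of the factual prediction
#' against the ground-truth path length.
#'
#' @param bundle a [policy_bundle()] with `include_cue = TRUE`.
#' @param episodes evaluation episodes (all recorded under the same
#'   condition for the directional query).
#' @param epsilon rollout exploration rate (0 = greedy).
#' @param B bootstrap replicates.
#' @param seed integer seed (pair-matched rollout RNG and bootstrap).
#' @return list with `factual` and `counterfactual` mean path lengths,
#'   per-episode `shift`, `shift_ci` and `abs_error_ci`
#'   ([paired_bootstrap_ci()] results).
#' @export
counterfactual_shift <- function(bundle, episodes, epsilon = 0, B = 10000L,
                                 seed = 1L) {
  if (!bundle$include_cue) {
    stopf("configuration error: policy has no condition cue input")
  }
  if (inherits(episodes, "demo_dataset")) episodes <- episodes$episodes
  n <- length(episodes)
  pl_f <- pl_c <- pl_gt <- numeric(n)
  for (i in seq_len(n)) {
    ep <- episodes[[i]]
    ro_f <- rollout_policy(bundle, ep, epsilon = epsilon, flip_cue = FALSE,
                           seed = seed + i)
    ro_c <- rollout_policy(bundle, ep, epsilon = epsilon, flip_cue = TRUE,
                           seed = seed + i)
    pl_f[i] <- episode_metrics(ro_f)$path_length
    pl_c[i] <- episode_metrics(ro_c)$path_length
    pl_gt[i] <- episode_metrics(ep)$path_length
  }
  shift_ci <- paired_bootstrap_ci(pl_c, pl_f, B = B, seed = seed)
  abs_err_ci <- paired_bootstrap_ci(abs(pl_f - pl_gt), numeric(n) * 0,
                                    statistic = function(a, b) mean(a),
                                    B = B, seed = seed)
  list(factual = mean(pl_f), counterfactual = mean(pl_c),
       shift = pl_c - pl_f, shift_ci = shift_ci, abs_error_ci = abs_err_ci,
       path_length_factual = pl_f, path_length_counterfactual = pl_c,
       path_length_gt = pl_gt)
}
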