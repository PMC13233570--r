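#' Dynamic time warping between a simulated and an expert state history
#'
#' Computes the full cumulative DTW cost matrix `W` under the standard
#' monotonicity, continuity and boundary constraints:
#' `W[t, j] = d(s_t, sE_j) + min(W[t-1, j], W[t, j-1], W[t-1, j-1])` with
#' `W[1, 1] = d(s_1, sE_1)`. The per-step DTW penalty used for reward shaping
#' is the row minimum `min_j W[t, j]`: the smallest cumulative alignment cost
#' between the simulated prefix ending at `t` and any expert prefix.
#'
#' @param sim_states numeric matrix (rows = time) or vector; the simulated
#'   state history (by default the controlled agent's 2D positions).
#' @param expert_states the demonstrated state history, same feature
#'   dimension.
#' @param metric local distance: `"euclidean"` or `"sqeuclidean"`.
#' @return object of class `dtw_result` with the cumulative matrix `W`,
#'   per-step `penalties` (`min_j W[t, j]`), the `final_cost` `W[n, m]` and
#'   the `metric` name.
#' @export
dtw_matrix <- function(sim_states, expert_states,
                       metric = c("euclidean", "sqeuclidean")) {
  metric <- match.arg(metric)
  A <- as_state_matrix(sim_states)
  B <- as_state_matrix(expert_states)
  if (nrow(A) == 0 || nrow(B) == 0) stopf("sequences must be nonempty")
  if (ncol(A) != ncol(B)) {
    stopf("parameter error: feature dimensions differ (%d vs %d)",
          ncol(A), ncol(B))
  }
  local <- local_cost_matrix(A, B, metric)
  W <- dtw_accumulate_cpp(local)
  structure(list(W = W, metric = metric,
                 penalties = apply(W, 1, min),
                 final_cost = W[nrow(W), ncol(W)]),
            class = "dtw_result")
}

#' @noRd
as_state_matrix <- function(x) {
  if (is.matrix(x)) x else matrix(as.numeric(x), ncol = 1)
}

# exact elementwise differences (not the expanded-square identity, whose
# cancellation error breaks the exact-zero self-alignment of identical states)
#' @noRd
local_cost_matrix <- function(A, B, metric) {
  sq <- matrix(0, nrow(A), nrow(B))
  for (d in seq_len(ncol(A))) {
    sq <- sq + outer(A[, d], B[, d], "-")^2
  }
  if (metric == "euclidean") sqrt(sq) else sq
}

#' @export
print.dtw_result <- function(x, ...) {
  cat(sprintf("<dtw_result> %d x %d (%s), final cost %.4g\n",
              nrow(x$W), ncol(x$W), x$metric, x$final_cost))
  invisible(x)
}

#' Per-step DTW penalty
#'
#' @param result a [dtw_matrix()] result.
#' @param t 1-based simulated time index.
#' @return `min_j W[t, j]`, the DTW penalty at step `t`.
#' @export
dtw_penalty_at <- function(result, t) {
  n <- nrow(result$W)
  if (t < 1 || t > n) stopf("index error: t = %d outside 1..%d", t, n)
  result$penalties[t]
}

#' Mix the task reward with the DTW penalty
#'
#' The shaped reward is `R_t = touch_reward - alpha * dtw_penalty`. Because
#' the penalty is nonnegative, the shaped reward never exceeds the touch
#' reward.
#'
#' @param touch_reward the environment's contact reward at this step.
#' @param dtw_penalty the per-step DTW penalty (raw metric units).
#' @param alpha nonnegative pseudo-reward weight.
#' @return the shaped reward.
#' @export
shaped_reward <- function(touch_reward, dtw_penalty, alpha) {
  if (any(alpha < 0)) stopf("alpha must be nonnegative")
  touch_reward - alpha * dtw_penalty
}

#' Grow a DTW alignment one simulated step at a time
#'
#' Appends one row of the cumulative cost matrix in `O(m)` and returns the
#' penalty for the new step; after `n` calls the accumulated rows equal
#' [dtw_matrix()] on the full sequences elementwise. Pass `running = NULL`
#' on the first call.
#'
#' @param new_state the new simulated state (numeric vector).
#' @param running the running result from the previous call, or `NULL`.
#' @param expert_states the expert state history (fixed across calls).
#' @param metric local distance name.
#' @return list of class `dtw_running` with fields `rows` (list of cumulative
#'   rows), `n`, `penalty` (for the newest step), `expert` and `metric`.
#' @export
incremental_dtw <- function(new_state, running = NULL, expert_states = NULL,
                            metric = c("euclidean", "sqeuclidean")) {
  if (is.null(running)) {
    metric <- match.arg(metric)
    B <- as_state_matrix(expert_states)
    if (is.null(expert_states) || nrow(B) == 0) {
      stopf("expert sequence must be nonempty")
    }
    running <- structure(list(rows = list(), n = 0L, penalty = NA_real_,
                              expert = B, metric = metric),
                         class = "dtw_running")
  }
  B <- running$expert
  d <- vnorm(sweep(B, 2, as.numeric(new_state), "-"))
  if (running$metric == "sqeuclidean") d <- d^2
  prev <- if (running$n == 0L) numeric(0) else running$rows[[running$n]]
  row <- dtw_next_row_cpp(prev, d)
  running$n <- running$n + 1L
  running$rows[[running$n]] <- row
  running$penalty <- min(row)
  running
}
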