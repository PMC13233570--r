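#' Recurrent dueling Q-network
#'
#' The backbone shared by all methods: observations pass through a
#' two-layer fully connected encoder, a single-layer gated recurrent unit
#' (GRU) whose hidden state is carried across time, and a dueling decoder
#' with a state-value branch `V(h)` and an advantage branch `A(h, a)`
#' combined as `Q = V + A - mean_a A`. All hidden widths are 32. The
#' counterfactual variant adds a treatment-prediction head (two FC layers,
#' 8 hidden units, sigmoid output) behind a gradient-reversal gate.
#'
#' Parameters are plain R matrices (stored input-by-output), so networks are
#' fully deterministic, serializable and seedable. Training uses manual
#' backpropagation with one-step gradients through the GRU (the previous
#' hidden state is treated as an input).
#'
#' @param obs_dim observation dimension.
#' @param n_actions number of discrete actions (13).
#' @param hidden hidden width (32 everywhere unless overridden).
#' @param treatment add the treatment-prediction head.
#' @param treatment_hidden width of the treatment head (8).
#' @param seed integer seed for the fan-in uniform initialization.
#' @return list of class `qnet` with a `params` list and the architecture
#'   description.
#' @export
qnet_init <- function(obs_dim, n_actions = 13L, hidden = 32L,
                      treatment = FALSE, treatment_hidden = 8L, seed = 1L) {
  mk <- function(nin, nout) {
    lim <- 1 / sqrt(nin)
    matrix(stats::runif(nin * nout, -lim, lim), nin, nout)
  }
  params <- with_seed(seed, {
    p <- list(
      W1 = mk(obs_dim, hidden), b1 = numeric(hidden),
      W2 = mk(hidden, hidden), b2 = numeric(hidden),
      Wz = mk(hidden, hidden), Uz = mk(hidden, hidden), bz = numeric(hidden),
      Wr = mk(hidden, hidden), Ur = mk(hidden, hidden), br = numeric(hidden),
      Wn = mk(hidden, hidden), Un = mk(hidden, hidden), bn = numeric(hidden),
      bhn = numeric(hidden),
      Wv1 = mk(hidden, hidden), bv1 = numeric(hidden),
      Wv2 = mk(hidden, 1L), bv2 = numeric(1),
      Wa1 = mk(hidden, hidden), ba1 = numeric(hidden),
      Wa2 = mk(hidden, n_actions), ba2 = numeric(n_actions))
    if (treatment) {
      p$Wt1 <- mk(hidden, treatment_hidden); p$bt1 <- numeric(treatment_hidden)
      p$Wt2 <- mk(treatment_hidden, 1L); p$bt2 <- numeric(1)
    }
    p
  })
  structure(list(params = params, obs_dim = as.integer(obs_dim),
                 n_actions = as.integer(n_actions),
                 hidden = as.integer(hidden), treatment = treatment,
                 eta_clip = 1e-6),
            class = "qnet")
}

#' @export
print.qnet <- function(x, ...) {
  cat(sprintf("<qnet> obs %d -> FC(%d) x2 -> GRU(%d) -> dueling V/A over %d actions%s\n",
              x$obs_dim, x$hidden, x$hidden, x$n_actions,
              if (x$treatment) " + treatment head (GRL)" else ""))
  invisible(x)
}

#' @noRd
relu <- function(x) x * (x > 0)

#' @noRd
sigmoid <- function(x) 1 / (1 + exp(-x))

#' @noRd
addb <- function(X, b) sweep(X, 2, b, "+")

#' Batched single-step forward pass (rows = batch items)
#' @noRd
qnet_step <- function(net, X, Hprev, keep_cache = TRUE) {
  p <- net$params
  E1 <- relu(addb(X %*% p$W1, p$b1))
  E2 <- relu(addb(E1 %*% p$W2, p$b2))
  z <- sigmoid(addb(E2 %*% p$Wz + Hprev %*% p$Uz, p$bz))
  r <- sigmoid(addb(E2 %*% p$Wr + Hprev %*% p$Ur, p$br))
  hn_in <- addb(Hprev %*% p$Un, p$bhn)
  n <- tanh(addb(E2 %*% p$Wn, p$bn) + r * hn_in)
  H <- (1 - z) * n + z * Hprev
  Va1 <- relu(addb(H %*% p$Wv1, p$bv1))
  V <- addb(Va1 %*% p$Wv2, p$bv2)
  Aa1 <- relu(addb(H %*% p$Wa1, p$ba1))
  Adv <- addb(Aa1 %*% p$Wa2, p$ba2)
  Q <- sweep(Adv, 1, rowMeans(Adv), "-") + matrix(V, nrow(Adv), ncol(Adv))
  out <- list(Q = Q, V = V, Adv = Adv, H = H)
  if (keep_cache) {
    out$cache <- list(X = X, Hprev = Hprev, E1 = E1, E2 = E2, z = z, r = r,
                      hn_in = hn_in, n = n, H = H, Va1 = Va1, Aa1 = Aa1)
  }
  out
}

#' Forward pass of the recurrent dueling Q-network over a sequence
#'
#' @param net a [qnet_init()] network.
#' @param obs_seq `T x obs_dim` matrix of observations (a single sequence),
#'   or a numeric vector for one step.
#' @param h0 initial hidden state (length `hidden`); zeros at episode start
#'   when `NULL`.
#' @return list with `Q` (`T x n_actions`), `V` (length `T`), `Adv`
#'   (`T x n_actions`), `hidden` (`T x hidden`, the state after each step)
#'   and `final_hidden`.
#' @export
q_forward <- function(net, obs_seq, h0 = NULL) {
  if (!is.matrix(obs_seq)) obs_seq <- matrix(obs_seq, nrow = 1)
  if (ncol(obs_seq) != net$obs_dim) {
    stopf("parameter error: observation dim %d, network expects %d",
          ncol(obs_seq), net$obs_dim)
  }
  Tn <- nrow(obs_seq)
  H <- matrix(if (is.null(h0)) 0 else h0, 1, net$hidden)
  Q <- matrix(NA_real_, Tn, net$n_actions)
  V <- numeric(Tn)
  Adv <- matrix(NA_real_, Tn, net$n_actions)
  hidden <- matrix(NA_real_, Tn, net$hidden)
  for (t in seq_len(Tn)) {
    st <- qnet_step(net, obs_seq[t, , drop = FALSE], H, keep_cache = FALSE)
    Q[t, ] <- st$Q
    V[t] <- st$V
    Adv[t, ] <- st$Adv
    H <- st$H
    hidden[t, ] <- H
  }
  list(Q = Q, V = V, Adv = Adv, hidden = hidden, final_hidden = as.numeric(H))
}

#' Epsilon-greedy action selection
#'
#' With probability `1 - epsilon` the greedy action (argmax of Q, ties broken
#' toward the lowest index); otherwise uniform over all actions. Reproducible
#' from the R RNG state.
#'
#' @param q numeric vector of Q-values.
#' @param epsilon exploration rate in \[0, 1\].
#' @return 0-based action label in `0..length(q) - 1`.
#' @export
greedy_action <- function(q, epsilon = 0) {
  if (epsilon < 0 || epsilon > 1) stopf("epsilon must lie in [0, 1]")
  if (epsilon > 0 && stats::runif(1) < epsilon) {
    sample.int(length(q), 1) - 1L
  } else {
    which.max(q) - 1L
  }
}

#' Treatment-prediction head forward pass
#'
#' The gradient-reversal gate between the shared hidden state and the head is
#' the identity on the forward pass; the sigmoid output is clipped to
#' `(eta_clip, 1 - eta_clip)` so the cross-entropy stays finite.
#'
#' @param net a [qnet_init()] network with `treatment = TRUE`.
#' @param H hidden state(s), vector or `B x hidden` matrix.
#' @return predicted condition probabilities `c_hat` in (0, 1).
#' @export
treatment_forward <- function(net, H) {
  if (!net$treatment) stopf("network has no treatment head")
  if (!is.matrix(H)) H <- matrix(H, nrow = 1)
  p <- net$params
  T1 <- relu(addb(H %*% p$Wt1, p$bt1))
  chat <- sigmoid(addb(T1 %*% p$Wt2, p$bt2))
  pmin(pmax(as.numeric(chat), net$eta_clip), 1 - net$eta_clip)
}

#' @noRd
zero_grads <- function(net) lapply(net$params, function(p) p * 0)

# Backward pass for a batched single step. dQ is B x n_actions; dH_extra
# (optional, B x hidden) adds an external gradient on the new hidden state
# (the treatment path delivers its reversed gradient this way). The previous
# hidden state is treated as a constant input (one-step credit assignment).
#' @noRd
qnet_backward <- function(net, cache, dQ, dH_extra = NULL) {
  p <- net$params
  g <- list()
  B <- nrow(dQ)
  # dueling combine: dAdv = dQ - rowMeans(dQ); dV = rowSums(dQ)
  dAdv <- sweep(dQ, 1, rowMeans(dQ), "-")
  dV <- matrix(rowSums(dQ), B, 1)
  # value branch
  dVa1 <- (dV %*% t(p$Wv2)) * (cache$Va1 > 0)
  g$Wv2 <- t(cache$Va1) %*% dV
  g$bv2 <- colSums(dV)
  g$Wv1 <- t(cache$H) %*% dVa1
  g$bv1 <- colSums(dVa1)
  # advantage branch
  dAa1 <- (dAdv %*% t(p$Wa2)) * (cache$Aa1 > 0)
  g$Wa2 <- t(cache$Aa1) %*% dAdv
  g$ba2 <- colSums(dAdv)
  g$Wa1 <- t(cache$H) %*% dAa1
  g$ba1 <- colSums(dAa1)
  dH <- dVa1 %*% t(p$Wv1) + dAa1 %*% t(p$Wa1)
  if (!is.null(dH_extra)) dH <- dH + dH_extra
  # GRU
  dz <- dH * (cache$Hprev - cache$n)
  dn <- dH * (1 - cache$z)
  dn_pre <- dn * (1 - cache$n^2)
  dr <- dn_pre * cache$hn_in
  dz_pre <- dz * cache$z * (1 - cache$z)
  dr_pre <- dr * cache$r * (1 - cache$r)
  g$Wn <- t(cache$E2) %*% dn_pre
  g$bn <- colSums(dn_pre)
  g$Un <- t(cache$Hprev) %*% (dn_pre * cache$r)
  g$bhn <- colSums(dn_pre * cache$r)
  g$Wz <- t(cache$E2) %*% dz_pre
  g$Uz <- t(cache$Hprev) %*% dz_pre
  g$bz <- colSums(dz_pre)
  g$Wr <- t(cache$E2) %*% dr_pre
  g$Ur <- t(cache$Hprev) %*% dr_pre
  g$br <- colSums(dr_pre)
  dE2 <- dn_pre %*% t(p$Wn) + dz_pre %*% t(p$Wz) + dr_pre %*% t(p$Wr)
  # encoder
  dE2 <- dE2 * (cache$E2 > 0)
  g$W2 <- t(cache$E1) %*% dE2
  g$b2 <- colSums(dE2)
  dE1 <- (dE2 %*% t(p$W2)) * (cache$E1 > 0)
  g$W1 <- t(cache$X) %*% dE1
  g$b1 <- colSums(dE1)
  g
}

# Treatment head backward. dlogit is B x 1 (d loss / d pre-sigmoid logit).
# Head parameter gradients are untouched by the reversal gate; the gradient
# returned for the shared hidden state is multiplied by `gate` (-1 for the
# gradient-reversal layer, +1 for the no-reversal ablation).
#' @noRd
treatment_backward <- function(net, H, dlogit, gate = -1) {
  p <- net$params
  if (!is.matrix(H)) H <- matrix(H, nrow = 1)
  T1 <- relu(addb(H %*% p$Wt1, p$bt1))
  g <- list()
  g$Wt2 <- t(T1) %*% dlogit
  g$bt2 <- colSums(dlogit)
  dT1 <- (dlogit %*% t(p$Wt2)) * (T1 > 0)
  g$Wt1 <- t(H) %*% dT1
  g$bt1 <- colSums(dT1)
  dH <- gate * (dT1 %*% t(p$Wt1))
  list(grads = g, dH = dH)
}

#' @noRd
accumulate_grads <- function(a, b) {
  for (nm in names(b)) {
    a[[nm]] <- if (is.null(a[[nm]])) b[[nm]] else a[[nm]] + b[[nm]]
  }
  a
}

#' Adam optimizer state for a network
#' @noRd
adam_init <- function(net) {
  list(m = lapply(net$params, function(p) p * 0),
       v = lapply(net$params, function(p) p * 0),
       t = 0L)
}

# One Adam update; adds the l2 gradient 2*lambda1*theta, clips the global
# gradient norm at `clip`, and returns list(net, state).
#' @noRd
adam_update <- function(net, grads, state, lr, lambda1 = 1e-5,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8, clip = 10) {
  for (nm in names(net$params)) {
    g <- grads[[nm]]
    if (is.null(g)) g <- net$params[[nm]] * 0
    grads[[nm]] <- g + 2 * lambda1 * net$params[[nm]]
  }
  gn <- sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1))))
  if (is.finite(gn) && gn > clip) {
    grads <- lapply(grads, function(g) g * (clip / gn))
  }
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(net$params)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    net$params[[nm]] <- net$params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(net = net, state = state)
}
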