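---
title: "Data-driven pursuit simulation: locomotion estimation, DTW-shaped Q-learning, and counterfactual queries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Data-driven pursuit simulation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Multi-animal pursuit recordings — two chasers converging on an evader, males
pursuing a female, a silkmoth walking up an odor plume — give us trajectories
but not dynamics. `pursuitRL` builds a closed-loop simulator of such behavior
in three stages: (1) fit an explicit, interpretable locomotion model to the
demonstration trajectories; (2) label the demonstrations with discrete
actions by inverting that model; (3) train per-agent recurrent Q-policies
whose reward mixes the task's contact signal with a dynamic-time-warping
(DTW) trajectory-distance penalty, so the agents both earn reward and move
like the demonstrators. A counterfactual variant conditions the policy on a
binary experimental-condition cue and adds an adversarial cue-prediction
head, enabling "what-if" rollouts in which only the cue is flipped.

# The locomotion model

Each agent's velocity follows a first-order transition
$$v' = (1 - d)\,v + u\,a\,\Delta t,$$
with damping coefficient $d \in [0,1]$ (dimensionless), thrust amplitude
$u > 0$ (normalized units s$^{-2}$), time step $\Delta t$ (s), and a
discrete control $a$: either the zero vector (no-op) or one of 12 unit
vectors every 30 degrees (0 degrees along $+x$, counter-clockwise; the
global frame, not a body-aligned frame). Coordinates are normalized so the
arena center is the origin and the walls sit at $\pm 1$.

## Estimating $d$ and $u$

Starting from rest, the first step after a thrust reaches speed
$u \Delta t$; sustained thrust in one direction converges to the terminal
speed $u \Delta t / d$. The estimator reads both quantities off the data:

* **onsets**: time steps where the speed crosses a threshold
  $\varepsilon = th_{acc}\Delta t$ from below. The median speed immediately
  after an onset estimates $|v|_{on} = u\Delta t$, so
  $\hat u = |v|_{on}/\Delta t$.
* **top speed**: the median of speeds above the 99th percentile estimates
  the terminal speed, so $\hat d = |v|_{on}/|v|_{max}$.

The acceleration threshold $th_{acc}$ is the one genuinely free knob. The
default sets $\varepsilon$ to 5% of the 95th percentile of nonzero speeds.
Two failure modes motivated this choice over low-quantile rules: for agents
that are almost always in motion, low speed quantiles sit at or above the
post-rest speed itself, which would shift every detected onset one step late
and inflate $\hat u$ by up to the factor $1 + (1-d)$; and a large
$\varepsilon$ accepts restarts from incomplete rest, whose first-step speed
retains a damped remnant of the previous motion. A small $\varepsilon$
anchored to the top of the speed distribution avoids both; with fewer than
100 pooled speed samples the top-1% statistic falls back to the maximum
(with a warning). Validation is one-step velocity RMSE: actions are labeled
by inverse dynamics on held-out episodes, the next velocity predicted by the
fitted model, and the root mean squared error accumulated over both
components.

## Inverse-dynamics action labels

Q-learning from demonstrations needs $(s, a)$ pairs, but recordings carry
none. Inverting the transition gives the implied control
$\text{thrust} = (v' - (1-d)v)/(u\Delta t)$; steps with
$\lVert\text{thrust}\rVert$ below half the nominal unit magnitude are
labeled no-op (the midpoint separates rest from thrust robustly), the rest
snap to the nearest of the 12 directions (ties to the lower index). On
noiseless synthetic data this recovers the generating action sequence
exactly for any threshold in (0, 1/2).

# The synthetic demonstration generator

The generator stands in for the deposited recordings and defines the study
conditions used throughout the tests: episodes start from rest at positions
uniform in $[-0.5, 0.5]^2$, evolve under the exact transition law, and end
on chaser-target contact (center distance at or below 0.1), a boundary
crossing (virtual wall at 1.1), or a 30 s limit at 10 Hz. Scripted policies
produce four styles: `straight_pursuit` (chasers aim at the target, the
target flees the nearest chaser), `stop_and_go_pursuit` (geometric-length
no-op pauses, emulating the low-speed-dominant histograms of terrestrial
animals; the target wanders with a persistent heading), `random_walk`, and
`moth_cast` (a single agent zigzagging toward an odor source). Default
locomotion parameters are $d = 0.25$, $u = 3.0$, $\Delta t = 0.1$ s; when a
single parameter set is supplied the target's thrust is divided by the
predator-mobility factor 1.2, so chasers are 20% faster than the prey and
pursuits terminate in contact. The prey's boundary-averse policy will not
steer beyond 0.7 of the arena half-width (`flee_margin`) — real prey keep
away from walls, and captures then happen in the arena interior.

Two-condition datasets scale the chaser pause probability
(`pause_scale`) and/or rotate the chaser's aim (`aim_rotation`, a
target-approach gain) under condition 1. Both lengthen chaser paths, giving
the condition flip a known, signed effect on mean path length — the ground
truth against which counterfactual queries are judged. With
`paired_conditions = TRUE` consecutive episodes share initial positions
under the two conditions. Pairing matters for learning cue-conditioned
policies: with unique initial states, frame 0 already identifies the
reference episode (and hence the condition), the cue carries no extra
information, and a trained policy is free to ignore it; paired designs make
the cue the only signal separating the two behaviors.

What the generator does *not* emulate: measurement noise, smoothing and
occlusions of video tracking, inter-individual variability of locomotion
parameters, and the bimodal speed mixtures seen in real flies. Tests passing
on this generator therefore certify the estimators and the learning
machinery under the model's own assumptions, not performance on raw tracking
data.

# Environments

The pursuit environment is a discrete-time predator-prey arena: semi-implicit
integration (velocity first, then position), contact when the chaser-target
center distance is at or below the contact radius (+1 to the touching
chaser, or to both under the shared scheme; the target banks its elapsed
time in seconds), a $-10$ penalty and episode end for crossing the virtual
boundary, and species presets for time step, limit, arena shape and contact
radius (agents 10 Hz/14.8 s/square/0.1; flies 10 Hz/50 s/circle/0.2; newts
10 Hz/50 s/square/0.15; silkmoth 2 Hz/300 s/open/0.1). Observations are the
ego absolute position plus, per other agent in index order, relative
position and velocity; the ego velocity is excluded by default, and the
binary condition cue is appended when requested. The demonstration-generation
limit for agents (30 s) intentionally differs from the RL limit (14.8 s);
both are configurable.

The silkmoth environment replaces the arena with an open field and a
synthetic plume: a Gaussian-shaped concentration ridge widening downwind of
the source, gated intermittently in time, with a constant-direction noisy
wind field. Antennae sample the odor bilinearly at lateral offsets from the
body axis; the body angle is the direction of the velocity vector; the wind
is encoded as a 4-way one-hot relative to the body angle (45-degree
sectors); and the left/right vision channel is an optic-flow proxy, the
positive parts of the lateral self-velocity. The observation excludes the
absolute position, which would make the task trivial.

# DTW reward shaping

For a simulated state history $s_{1..n}$ and expert history $s^E_{1..m}$,
the cumulative DTW cost matrix under the standard monotonicity, continuity
and boundary constraints is
$$W_{t,j} = d(s_t, s^E_j) + \min(W_{t-1,j}, W_{t,j-1}, W_{t-1,j-1}),$$
with Euclidean local costs over the controlled agent's 2D position (the one
state component shared by all four datasets). The per-step penalty is the
row minimum $R^{DTW}_t = \min_j W_{t,j}$ — the cheapest alignment of the
simulated prefix against any expert prefix — and the shaped reward is
$R_t = R^{touch}_t - \alpha R^{DTW}_t$. The penalty is computed online in
$O(m)$ per step by growing one row at a time; the incremental rows equal the
batch matrix exactly, which is asserted property-style in the tests, and the
batch recursion itself is checked against brute-force enumeration over all
admissible warping paths for short sequences. Local costs are computed from
exact elementwise differences rather than the expanded-square identity: the
latter's cancellation error breaks the exact-zero self-alignment that makes
demonstration transitions carry exactly their touch reward. Penalties are
raw metric units, not normalized by $n$ or $m$; when a rollout outlives its
reference the rows keep growing against the fixed expert sequence, and the
mounting penalty is precisely the pressure to terminate. The reference
episode is the one whose initial state seeded the rollout.

# Networks and training

Every agent carries an independent recurrent dueling Q-network: two
fully-connected ReLU encoder layers, a single-layer GRU whose hidden state
is threaded across the episode, and dueling value/advantage heads combined
as $Q = V + A - \frac{1}{|A|}\sum_{a'} A$. All hidden widths are 32; there
are 13 outputs. The counterfactual variant adds a treatment head (two FC
layers, 8 hidden units, sigmoid clipped to $(10^{-6}, 1-10^{-6})$) behind a
gradient-reversal gate: identity on the forward pass, exact negation of the
gradient flowing from the cue-prediction cross-entropy into the shared
trunk. No deep-learning framework is involved: forward passes, the GRU and
dueling backward passes, the reversal gate and the Adam optimizer are
implemented directly in matrix algebra, and the backward pass is verified
against finite differences in the test suite.

Methods differ only in their loss: `dqn` is the one-step double-Q TD loss on
the unshaped reward; `dqdil` the same TD loss on the DTW-shaped reward;
`dqcil` adds $\lambda_2$ times the adversarial treatment cross-entropy;
`dqaas` adds $\lambda_3$ times a cross-entropy aligning the policy's softmax
to the DTW-aligned expert action; `bc` is that supervised cross-entropy
alone. All carry an $\ell_2$ penalty $\lambda_1 = 10^{-5}$.

## Offline pre-training

Demonstration transitions (with actions from the recorded labels or inverse
dynamics, and shaped rewards that reduce to the touch reward because an
episode aligned to itself has zero DTW penalty) fill a prioritized replay
table; 30 epochs of minibatch updates follow, with proportional
prioritization (exponent 0.6, importance-sampling exponent 0.4) and target
synchronization every 200 updates. Hidden states are not stored: they are
recomputed for the whole dataset at the start of every epoch by a batched
sweep with the current weights, so the recurrent inputs never go stale.

## Online fine-tuning

Rollouts reset from a training reference episode's initial state; learning
agents act $\varepsilon$-greedily (linear decay over the first
`decay_steps` environment steps) with hidden state threaded across the
episode; non-learning agents can replay the reference trajectory. Completed
episodes enter a sequence replay buffer (capacity 400 episodes). Every
`update_every` steps, a prioritized sample of stored episodes (priority =
mean |TD error|, exponent 0.6) is *re-threaded*: their hidden states are
recomputed with the current online network before a single one-step
double-Q gradient step over all of their transitions.

Three choices here deserve justification because each was decisive in
desk-scale experiments:

* **Fresh hidden states.** Storing per-transition hidden states at
  collection time (the obvious transition-level buffer) makes the replayed
  $(o, h)$ pairs drift off the current network's hidden distribution as the
  GRU trains; value estimates at act time are then evaluated off-replay, and
  greedy performance collapses even on a stationary-target control task.
  Re-threading sampled episodes with the current network removes the
  staleness at the cost of one forward sweep per update, which the batched
  implementation makes cheap.
* **Reward clipping.** Rewards are clipped to $[-1, 1]$ inside the TD loss
  (configurable; shaped runs typically widen to $[-5, 1]$). The $-10$
  boundary penalty otherwise sets the scale of the value function, and the
  per-step action-value differences that encode "which direction closes the
  distance" — on the order of $1 - \gamma$ — drown in its approximation
  error. Logged returns are never clipped.
* **Checkpoint selection.** Desk-scale deep value learning is not monotone:
  runs reach strong policies and degrade again. When validation references
  are supplied, the policy is scored on greedy rollouts (touch return minus
  $\alpha$ times the final DTW cost) at regular intervals and the best
  checkpoint is returned. This is ordinary model selection on held-out data,
  not a change of objective.
* **Demonstration retention.** By default the sequence buffer is seeded with
  the reference demonstrations themselves, in permanent slots (the
  demonstrations-from-demonstrations convention). Their self-aligned DTW
  penalty is zero, so they carry the plain touch reward, and TD backups
  propagate the value of the demonstrated paths without requiring
  $\varepsilon$-greedy exploration to rediscover long imitative
  trajectories.

Defaults left open by the problem: discount $\gamma = 0.99$ (0.95 in the
scaled-down runs, where horizons are short and value propagation speed
matters more than long-range credit), target sync every 100
sequence-updates online, learning rate $10^{-3}$ decaying linearly to 10%,
4 episodes re-threaded per update.

## Scaled-down study sizes

The full-scale protocol (about $10^6$ environment steps per method) is out
of desk range; the package's own experiments and tests run scaled-down
presets: 200 demonstration episodes for locomotion recovery, $2\times10^4$
environment steps for from-scratch value learning, $3\times10^4$ for
DTW-shaped fine-tuning, 10-50 reference episodes. At these sizes the
from-scratch pursuit learner is trained with all agents learning
simultaneously as independent learners (chasers and prey co-adapt; the
untrained prey makes early captures frequent, an emergent curriculum),
whereas imitation-focused runs train the focal chaser against replayed
demonstrations. Trajectory-reproduction comparisons (DTW to ground truth)
are made on the training references' initial states: a policy can only know
a *specific* reference path from its initial state, so reproduction of the
demonstrated episodes is the capability the DTW reward actually trains at
this scale; style generalization to novel initial states requires far more
data and steps.

# Evaluation statistics

* **Episode metrics**: capture indicator, mean chaser path length
  (summed stepwise displacement), duration, and the final DTW cost to the
  ground-truth trajectory.
* **KDE distance**: Gaussian kernel density estimates (Scott's bandwidth
  $\hat\sigma n^{-1/5}$) of a summary statistic under two sources, compared
  by the L1 distance between the density curves on a shared 512-point grid
  spanning the pooled range plus three bandwidths, trapezoid-integrated.
  This is a genuine pseudometric bounded by 2; Jensen-Shannon would be an
  alternative, but L1 keeps the units of a probability mass difference.
* **Paired bootstrap CIs**: episode indices resampled with replacement
  (default $B = 10^4$), percentile intervals (plain 95% CIs; no BCa
  correction since only central coverage is reported).
* **Bootstrap one-way ANOVA**: the *same* resampled index set is applied to
  every (episode-paired, equal-length) group before computing the F
  statistic, so identical groups give F = 0 in every replicate.
* **Counterfactual shift**: every evaluation episode is rolled out twice
  from the same initial state — recorded cue and flipped cue — under
  matched RNG, isolating the cue effect; the per-episode difference in mean
  chaser path length is bootstrap-summarized, alongside the absolute error
  of the factual prediction against ground truth. A policy whose cue input
  weights are zeroed (`ablate_cue()`) shifts by exactly zero, the natural
  negative control.

# Numerical and degenerate-input conventions

Ties in action selection and DTW argmins resolve to the lowest index.
Constant samples are rejected by the KDE with a jitter suggestion rather
than silently producing a delta spike. The treatment head's output is
clipped away from 0 and 1 so the cross-entropy stays finite. Episodes must
carry a strictly uniform time grid; stored velocities are checked against
position differences at a configurable tolerance (disable for smoothed real
recordings). A terminating boundary-crossing frame may overshoot the
virtual wall by up to one step at the speed cap, and the episode validator
accounts for exactly that allowance.

# Counterfactual training at desk scale

Learning a genuinely cue-conditioned policy is the hardest scaled-down task
in the package, and three study-design elements are required. First, the
counterfactual rollouts use one learning chaser with the prey replayed: a
second replayed chaser would terminate every rollout at the reference's own
capture moment and truncate the counterfactual path. Second, the
two-condition demonstrations are paired on initial states (see the generator
section); otherwise the cue is redundant and ignored. Third, the constructed
condition effect must be strong — a large aim rotation makes the
straight-capture policy clearly suboptimal under condition 1, so the value
function has to split on the cue. The adversarial treatment weight
$\lambda_2$ is kept small (0.1) in the scaled preset: with a 32-unit trunk
and short training, a strong reversal signal can strip the cue from the
representation faster than the TD signal writes it in. Even so, cue use is
a symmetry-breaking outcome: some training seeds converge to cue-blind
policies (their cue-flip shift is exactly zero), which is reported rather
than averaged away — the full-scale protocol trains orders of magnitude
longer.

# Known limitations

The locomotion model is first-order and unimodal: bimodal movers (real
flies) violate it, and the estimator reports — honestly — a larger velocity
RMSE there. Desk-scale budgets train competent but not converged policies;
the package's comparisons are directional properties, not reproductions of
full-scale confidence intervals. The plume is a synthetic stand-in;
measured plume playback is out of scope. Recurrent credit assignment is
one-step (no backpropagation through time): with fully observable pursuit
states this loses little, but tasks that genuinely require long memory
would need BPTT over the threaded sequences.
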