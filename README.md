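# pursuitRL

Data-driven simulation of multi-animal pursuit behavior from demonstration
trajectories, for behavioral ecologists and computational ethologists who
have tracking data (chasers and evaders on a 2D arena, or a single animal
navigating to an odor source) but no dynamical model of how the animals
move.

The package implements a three-stage pipeline:

1. **Locomotion model estimation.** Each agent's velocity is assumed to
   follow the first-order transition
   `v' = (1 - d) v + u a Δt`, with damping coefficient `d ∈ [0, 1]`, thrust
   amplitude `u > 0` and a discrete control `a` (no-op or one of 12 unit
   vectors every 30°). Rest-to-motion onsets give the post-rest speed
   `|v|_on = uΔt`; the median of the top-1% speeds estimates the terminal
   speed `uΔt/d`; hence `u = |v|_on/Δt` and `d = |v|_on/|v|_max`. The model
   is validated by one-step velocity RMSE on held-out episodes, with actions
   labeled by inverse dynamics.
2. **Imitation-shaped reinforcement learning.** Per-agent recurrent dueling
   double-Q networks (FC×2 encoder → GRU(32) → dueling V/A heads, written in
   plain matrix algebra with manual backpropagation and Adam) are trained
   offline on demonstration transitions and online in the simulated arena.
   The reward mixes the task's contact signal with a dynamic-time-warping
   penalty, `R_t = R_touch - α · min_j W[t, j]`, where `W` is the cumulative
   DTW cost between the simulated and demonstrated state histories — the
   policy earns reward *and* moves like the demonstrator. Method variants:
   `dqn` (no demonstrations), `bc` (behavioral cloning), `dqaas` (TD +
   DTW-aligned action supervision), `dqdil` (TD on the shaped reward) and
   `dqcil` (plus an adversarial condition-prediction head behind a
   gradient-reversal layer).
3. **Evaluation and counterfactual queries.** Rollout metrics (capture,
   path length, duration, DTW to ground truth), Gaussian-KDE L1 distances
   between metric distributions, paired bootstrap CIs, bootstrap one-way
   ANOVA, and cue-flip counterfactuals: roll out the same initial state with
   the experimental-condition cue flipped and bootstrap the signed
   path-length shift.

A synthetic demonstration generator (rest-start episodes, stop-and-go speed
profiles, contact-terminated pursuit, two-condition designs with a known
signed path-length effect) stands in for deposited animal recordings and
drives the whole test suite.

## Worked example

```r
library(pursuitRL)

params <- locomotion_params(d = 0.25, u = 3.0, dt = 0.1)
cfg <- species_env_config("agents", demo = TRUE)
demos <- generate_synthetic_demos(cfg, params, "straight_pursuit",
                                  n_episodes = 200, seed = 42)
fit <- estimate_locomotion_params(demos$episodes, agent_index = 1)
fit
#> <estimation_report> agent 1: d = 0.26, u = 3 (|v|_on = 0.3, |v|_max = 1.154, 200 onsets)

holdout <- generate_synthetic_demos(cfg, params, "straight_pursuit",
                                    n_episodes = 50, seed = 43)
velocity_rmse(holdout$episodes, 1, fit$params)
#> [1] 0.006409225
```

The generator used chaser thrust `u = 3.0` and damping `d = 0.25`; the
estimator recovers them from the trajectories alone (`u` exactly, `d` as
0.260 — slightly high because median chases stop a little short of full
terminal speed), and the fitted model predicts held-out next-step
velocities to about 0.006 normalized units/s — well inside the 0.045 bound
used to call the locomotion fit adequate.

DTW reward shaping in one line: with the worked matrix
`dtw_matrix(c(0, 1, 2), c(0, 2))`, the per-step penalties are `0, 1, 1` and
`shaped_reward(1, 0.05, alpha = 10)` returns `0.5`.

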