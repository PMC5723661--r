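# flexlearn

Trial-by-trial inference of a *flexible learning rate* in probabilistic
reward learning, with everything needed to study it end to end: a simulator
for a two-armed red/green reward task, a grid-approximation Bayesian filter
that infers the learning rate and reward belief from choices and outcomes,
fixed-rate reinforcement-learning baselines, cross-validated model
comparison, behavioral analyses of reward-modulated learning, and a
model-based fMRI design/GLM stage exercised on synthetic BOLD.

The package is aimed at computational cognitive neuroscientists who want a
tested, reproducible implementation of this model family — for simulation
studies, parameter/model-recovery checks, or as a starting point for
analyzing their own two-armed bandit data.

## The task

Participants (here: simulated agents) choose between a red and a green
square for 8 runs of 40 trials and receive a high (coded 1) or low (coded 0)
reward. The probability that red pays the high reward, `p_red`, is fixed at
0.2 or 0.8 in *easy* runs and steps every 4 trials through
0.2, 0.4, 0.6, 0.8, 0.6, 0.4, 0.2, 0.4, 0.6, 0.8 (or the reverse) in *hard*
runs; green always pays with probability `1 − p_red`, so chance level of a
high reward is exactly 50%.

## The model

Each observation is reduced to an outcome code *o* = 1 iff the choice/reward
pair supports "red is the more rewarding color" (red & high, or green &
low). The model maintains a discretized joint posterior over

- *k* — the probability that the learning rate keeps its value between
  trials,
- *α* — the trial-varying learning rate,
- *p* — the belief that red is the more rewarding color,

initialized uniform at each run start. Between trials the posterior is
pushed through three kernels:

1. **learning-rate transition** `p(α' | α) = (1 − k)/m + k·δ(α' − α)` — stay
   with probability *k*, otherwise jump uniformly over the α grid;
2. **belief propagation** — each *p* is smeared through a
   `Beta(p·v + 1, v − p·v + 1)` kernel with `v = 1/α − 2`, so high learning
   rates forget the belief faster;
3. **delta-rule drift** `p ← p + α (o − p)` driven by the previous trial's
   outcome, re-binned onto the grid.

The trial's observation then reweights the joint mass by the likelihood
`(1 − |o − p|)(1 − |s − sp|)`, where `sp = logistic(β₁ + β₂ p)` is the
softmax prediction of the choice *s*. Posterior means E[α], E[p] per trial
are the model estimates; `β₁, β₂` are fitted to the observed choices by an
EM alternation. Models are compared by two-fold cross-validated
`BIC = n·ln(σe²)` (no free-parameter penalty), where σe² is the squared
error between held-out choices and their predicted probabilities.

## Worked example

```r
library(flexlearn)

grid     <- make_grid(10, 10, 10)          # default is 30^3; smaller = faster
session  <- make_session("sub01", seed = 7)
behavior <- run_agent(session, agent_spec("flexible", grid = grid), seed = 8)

fit <- em_fit(behavior, grid = grid)
fit
#> <em_fit> beta1 = -3.996, beta2 = 6.177 (5 iterations, converged)

head(fit$trace, 5)
#> # A tibble: 5 x 7
#>     run trial alpha_mean p_mean     ps     o     pe
#>   <int> <int>      <dbl>  <dbl>  <dbl> <int>  <dbl>
#> 1     1     1      0.5    0.5   0.288      0  0.5
#> 2     1     2      0.5    0.214 0.0646     0  0.214
#> 3     1     3      0.519  0.195 0.0579     0  0.195
#> 4     1     4      0.527  0.189 0.0558     1 -0.811
#> 5     1     5      0.481  0.699 0.579      0  0.699

repetition_deltas(behavior)
#>   participant rep_after_high rep_after_low delta_rep
#> 1 sub01                0.967         0.659     0.308

reward_modulated_alpha(behavior, fit$trace)
#>   participant alpha_after_high alpha_after_low delta_alpha
#> 1 sub01                  0.432           0.375      0.0566

compare_models(behavior, grid = grid, seed = 1, max_iter = 15)
#>   model    sigma_e2   bic     n
#> 1 flexible    0.157 -592.   320
#> 2 PE-M        0.174 -560.   320
#> 3 RL_1        0.175 -558.   320
#> 4 RL_2        0.212 -497.   320
```

Reading the output: the agent chose red (s = 1) or green (s = 0) each trial;
`alpha_mean` and `p_mean` are the filter's trial-wise learning-rate and
reward-belief estimates, `ps` the predicted probability of choosing red,
`pe` the signed reward prediction error of the chosen color. This agent
repeated its color choice far more often after a high reward (96.7%) than
after a low one (65.9%), its fitted learning rate was higher after high
rewards (0.432 vs 0.375), and the flexible model predicted its held-out
choices best (lowest cross-validated BIC).

The fMRI stage turns a trace into onset-locked regressor groups, applies
within-group orthogonalization and canonical-HRF convolution, and fits
per-voxel GLMs — see `?build_groups`, `?fit_glm` and the vignette.

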