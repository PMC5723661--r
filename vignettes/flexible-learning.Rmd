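---
title: "The flexible learning model: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The flexible learning model: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flexlearn)
```

This vignette is the package's account of the science it implements: the
task, the model and its assumptions, the estimation machinery, the
synthetic-data generator and what it does and does not emulate, and the
numerical and design choices that were genuinely open.

## The task and its generator

The task is a two-armed probabilistic reward task: on every trial the
subject picks the red or the green square and receives a high (5 points,
coded 1) or low (1 point, coded 0) reward. The red square pays the high
reward with probability `p_red`; the green square always pays with
probability `1 − p_red`, so an indifferent chooser receives the high reward
exactly 50% of the time. A session holds eight 40-trial runs, four *easy*
(`p_red` fixed at 0.2 or 0.8, two runs each) and four *hard* (`p_red`
stepping every 4 trials through 0.2, 0.4, 0.6, 0.8, 0.6, 0.4, 0.2, 0.4,
0.6, 0.8 or its reverse, two runs each). With this multiset of schedules the
session-wide mean of `p_red` is exactly 0.5 regardless of run order.

```{r schedules}
make_schedule("hard", "hard-ascending")$p_red[1:12]
sess <- make_session("sub01", seed = 1)
mean(sess$p_red_true)
```

Design choices in the generator, fixed once:

- **Counterbalancing.** The original design counterbalances run order
  "within and across participants" without giving the scheme. The default
  here is a seeded uniform permutation of the eight-schedule multiset per
  session; any other scheme can be supplied via `variants` /
  `order_policy = "as-given"`.
- **Event timing.** Pre-choice and inter-trial intervals are
  "exponentially jittered" between 4 and 5.5 s in 0.5 s steps; no decay
  constant is given, so the generator uses a truncated discrete geometric
  over {4, 4.5, 5, 5.5} with configurable decay (default 0.5). Feedback is
  shown for 1 s. Response latencies are uniform 0.3–1.3 s within the cue
  interval; they only matter for the fMRI onset columns.
- **No-response trials** occur at a configurable rate (default 0; the
  original task reported under 0.3%). They carry no choice/reward/outcome
  codes and every analysis drops them.
- **Reward points** (1 vs 5) enter every computation only through the
  binary code; the point values are display metadata.

## The flexible learning model

Each trial's observation is reduced to an outcome code
$o = 1$ iff the choice/reward pair supports "red is the more rewarding
color" (red & high reward, or green & low reward); with the 0/1 codings
this is $o = \mathbf{1}[s = r]$. The model maintains a joint probability
mass over three latents on a discrete grid:

- $k \in (0,1)$: probability that the learning rate keeps its value from
  one trial to the next;
- $\alpha_i \in (0,1)$: the trial-varying learning rate;
- $p_i \in (0,1)$: the belief that red is the more rewarding color.

The posterior is re-initialized uniform at every run start (subjects were
told the contingencies reset between runs). At the start of trial $i > 1$
three kernels are applied:

1. **Learning-rate transition.** $p(\alpha_{i+1}\mid\alpha_i) =
   (1-k)/m_\alpha + k\,\delta(\alpha_{i+1}-\alpha_i)$ on the grid: stay with
   probability $k$, otherwise jump to a uniformly drawn grid value. As
   printed, the stay/jump rule ($1 - k + k\delta$) is unnormalized on a
   discrete grid; the implementation uses the mixture the accompanying text
   describes — weight $k$ on staying, weight $1-k$ spread evenly (the jump
   may land on the current value).
2. **Belief propagation.** For each $(k, \alpha)$ slice the conditional
   over $p$ is convolved with a Beta kernel
   $\mathrm{Beta}(p v + 1,\; v - p v + 1)$, $v = 1/\alpha - 2$, evaluated on
   the $p$ grid and row-normalized. Small $\alpha$ gives a concentrated
   kernel (beliefs persist); $\alpha = 0.5$ gives $v = 0$, a uniform kernel
   that forgets the belief; $\alpha > 0.5$ gives $v < 0$, a U-shaped kernel
   pushing mass toward confident beliefs. Grid interiority guarantees both
   shape parameters stay positive.
3. **Delta-rule drift.** Every cell's $p$ is shifted to
   $p + \alpha\,(o_{i-1} - p)$ and re-binned by linear interpolation
   between the two flanking grid bins (mass beyond the boundary bins goes
   to the end bin). The tilde in the printed update is read as a
   deterministic shift-and-rebin, not stochastic sampling: the filter is a
   deterministic map, so estimates are exactly reproducible.

E[$\alpha_i$] and E[$p_i$] are recorded *before* the trial's observation,
then the joint mass is reweighted by the likelihood

$$p(s, o \mid p) = (1 - |o - p|)\,(1 - |s - sp|), \qquad
  sp = \mathrm{logistic}(\beta_1 + \beta_2\, p),$$

and renormalized. Note each outcome is used twice — in this update at trial
$i$ and in the drift at the start of trial $i+1$ — exactly as the equations
sequence it.

### Grid and numerics

The default grid is $30^3$ with bin centers $(j - 0.5)/m$: it keeps the
filter at $O(10^4)$ cells per trial and all Beta shapes positive. The
posterior is renormalized after every kernel; validity checks use a
tolerance of $10^{-10}$. The test suite verifies the whole per-trial loop
against an independent brute-force enumeration on a $3^3$ grid to
$10^{-12}$, and runs its simulation studies on $10^3$–$12^3$ grids (the
model is grid-configurable; coarser grids trade a little smoothness of the
estimates for speed, and none of the qualitative results below depend on
the choice).

### What the learning rate does and does not track

The reward-modulation signature — E[$\alpha$] higher on trials following a
high than a low reward — is robust in fitted traces (see the acceptance
suite). Tonic volatility tracking is *not* a property of this filter on
this task: relative to a matched stable schedule, the average E[$\alpha$]
after a mid-run reversal is not elevated — long confirmation streaks
inflate $\alpha$ (the linear outcome likelihood favors fast-updating cells,
whose beliefs are most extreme), and the first surprising outcome
transiently favors the *lagging* low-$\alpha$ cells. This is consistent
with the original study's null result of no mean-$\alpha$ difference
between easy and hard runs. What is robust at the trial level is
responsiveness: the one-step revision of E[$\alpha$] at a reversal is
roughly twice the typical stable-stretch movement, which is the property
the test suite asserts.

## Choice model and EM estimation

Choices are linked to the belief by a two-parameter softmax
$ps_i = \mathrm{logistic}(\beta_1 + \beta_2\, p_i)$. Estimation alternates:

- **E step** — run the filter with the current $(\beta_1, \beta_2)$ to get
  trial-wise E[$p_i$]. The first E step runs before any estimate exists and
  uses $sp = p$ inside the likelihood.
- **M step** — refit $(\beta_1, \beta_2)$ by logistic regression of the
  observed choices on E[$p_i$] (Bernoulli maximum likelihood; the original
  description says only "fitting ps to the actual choices", and likelihood
  was chosen over least squares for statistical coherence — a least-squares
  objective is available via `objective = "ls"` since the model-comparison
  criterion is squared-error based).

Iteration stops when both coefficients move by less than $10^{-3}$ (cap 50
iterations, then flagged). Degenerate M steps are handled explicitly:
constant beliefs leave $\beta_2$ unidentifiable (returned 0, flagged), and
perfect separation caps coefficients at $|\beta| = 50$ with a warning.
Because the E-step trace changes between iterations, the pooled choice
log-likelihood is not guaranteed to increase monotonically across
iterations (tiny decreases are possible and observed); what is guaranteed,
and tested, is that each M step is optimal for its trace and that the whole
pipeline is deterministic.

## Baselines and model comparison

Three fixed-rate learners share the belief-update form
$p \leftarrow p + \alpha_{\mathrm{eff}}(o - p)$, with $p = 0.5$ at each run
start (the original is silent on the reset; per-run matches the flexible
model):

- **RL_1**: one rate for the whole session;
- **RL_2**: one rate per difficulty condition;
- **PE-M**: $\alpha_{\mathrm{eff}} = \alpha\,|r - p_{\mathrm{chosen}}|$, the
  base rate scaled by the prediction-error magnitude of the chosen color.

Rates are found by exhaustive search over 0.01–0.99 (step 0.01), scoring
the mean squared error of softmax-fitted choice predictions, ties broken to
the smallest rate. Model comparison uses two-fold cross-validation: folds
of 2 easy + 2 hard runs for flexible/RL_1/PE-M, folds within difficulty for
RL_2 (run pairing is seeded-random within these constraints; the original
does not say which runs were paired). Held-out squared errors are pooled
over both swaps — pooling rather than averaging per-fold criteria was an
open choice, documented here — and scored as
$\mathrm{BIC} = n \ln \sigma_e^2$ with $\sigma_e^2$ the maximum-likelihood
(denominator $n$) error variance and *no* free-parameter penalty, as in the
original comparison.

## Behavioral analyses

All analyses use responded trials only and never pair trials across run
boundaries; the first trial of a run has no predecessor and is excluded
from repetition and history analyses (the original is silent; this is the
conservative choice).

- **Repetition**: frequency of repeating the previous color choice, per
  cell of previous reward (high/low) by difficulty (easy/hard).
- **Dynamic choice regression**: choices recoded red = 1 / green = −1;
  separately for trials after a high vs. a low reward, the normalized
  current choice is regressed (OLS, no intercept) on the normalized choices
  one and two trials back. Normalization is z-scoring within each reward
  set (per-set rather than per-run was an open choice). Collinear designs
  fall back to an SVD pseudo-inverse and are flagged.
- **Learning-rate/repetition correlation**: per participant,
  $\Delta\alpha$ = mean E[$\alpha$] after high minus after low reward and
  $\Delta$rep the analogous repetition contrast; Pearson correlation across
  participants.
- **Reward vs. prediction error**: the binary repeat-next-trial vector is
  regressed separately on the trial's reward and on the model's signed
  prediction error; $\Delta R^2 = R^2(r) - R^2(pe)$.
- The 2×2 within-subject ANOVA and paired-*t* helpers are summary plumbing
  at exactly the level the behavioral tables need (subject-cell means,
  `aov` with an `Error(subject/(A*B))` stratification), not a general
  ANOVA engine.

## The fMRI design stage

The GLM machinery is validated on synthetic BOLD; there is no spatial
model, preprocessing, or cluster correction — "voxels" are independent
columns. Ten task regressors form three onset-locked groups: cue (stick,
$\alpha$, predicted reward probability of the later-chosen color), feedback
(stick, $r$, $pe$, $\alpha \times pe$, $\alpha \times r$) and response
(stick, response side). Interactions are products of the raw series;
parametric regressors are then z-scored, by default across the concatenated
session (the original concatenates runs but is ambiguous about the
normalization span; per-run is available). To attribute variance uniquely,
the regressor of interest is orthogonalized against the other members of
its group at the trial level, *before* convolution, replacing the original
column. Columns are convolved with the canonical double-gamma HRF (response
peak parameter 6 s, undershoot 16 s, ratio 6, unit dispersions — the
standard canonical parameterization; only the function's family is named in
the original) at a microtime resolution of 0.1 s and sampled at TR = 2 s.
Six random-walk motion parameters and one grand-mean column per run are
appended, and full column rank is checked. Events are zero-duration sticks
at the generated onsets. Per-voxel OLS returns the encoding strength of the
orthogonalized regressor; group inference is a one-sample *t* across
participants with zero-variance voxels masked.

The end-to-end property the tests assert: with positive $\alpha \times r$
weights planted in one voxel block and negative $\alpha \times pe$ weights
in another at SNR 1 (per-voxel noise sd = planted signal sd), the group
*t*-map signs recover at least 95% of the planted pattern with 20 synthetic
participants, and noiseless recovery is exact to $10^{-8}$.

## Simulated agents: the study conditions

Because no behavioral data were deposited, the generator's agents stand in
for participants, and their defaults define the study conditions:

- `beta2 = 7`, `beta1 = -beta2/2` (the fitted human range for the slope was
  roughly 4.5–25; the intercept centers indifference at $p = 0.5$).
- **Reward-modulated learning rate** (`reward_mod = 2`): after each
  outcome, the agent's $\alpha$ posterior is tilted by
  $\exp\{\gamma\,(2r - 1)\,\alpha\}$ — up after high reward, down after low
  — making high rewards weigh the latest observation more heavily.
- **Choice kernel** (`perseveration = 1.2` logits toward repeating the
  previous choice), with an optional reward-asymmetric component
  (`reward_stick`, default 0) used to build cohorts with individually
  different reward modulation of repetition.

These values were calibrated once against the published group behavior
(repetition 89.3% after high vs 47.6% after low reward; accuracy 84.0%
easy / 60.5% hard); the default agents produce ≈ 96% / 49% repetition and
≈ 81% / 65% accuracy. The heterogeneous 27-agent cohort used for the
correlation analysis expresses a single "reward-modulation strength" trait
in both channels (`reward_mod = 4·t`, `reward_stick = 3·t`, trait *t*
uniform on [0, 1]) — mirroring the interpretation that learning-rate
modulation and repetition modulation are two expressions of one individual
disposition. With it, the fitted $\Delta\alpha$–$\Delta$rep correlation is
reliably positive (r ≈ 0.5 at n = 27; the human study reported r = 0.86).

What the generator does **not** emulate: reaction-time structure, fatigue
or drift across runs, response biases beyond the choice kernel, and true
human between-subject variability in everything else. Passing tests
therefore show that the *pipeline* recovers what it should under the
model's own assumptions — not that those assumptions hold for any
particular human dataset.

## Problem sizes used by the test suite

Simulation studies run at sizes chosen to make the suite comfortably
reproducible on a laptop: filters on $10^3$–$12^3$ grids, EM capped at 15
iterations for cross-validation studies, 20 participants for model
recovery (the flexible model wins the CV-BIC comparison for ~70% of its
own agents; fixed-rate learners with a free rate can mimic part of the
agents' perseveration, which the original four-model family does not
represent), 27 agents for the correlation cohort, 20 participants × 60
voxels for the fMRI recovery, and $10^5$ trials for the chance-level
benchmark.

## Known limitations

- The filter is a grid approximation; very fine beliefs (|p − 0.5| near
  0.5 on coarse grids) are quantized, and the propagation kernel's
  row-normalization on the grid is itself part of the model definition
  here.
- The EM alternation is approximate (see above); it converges in a handful
  of iterations in practice but carries no global optimality guarantee.
- BIC without a complexity penalty compares raw predictive fit only, by
  design.
- The fMRI stage deliberately omits everything spatial: its claims end at
  "the design/GLM machinery recovers planted encodings".
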