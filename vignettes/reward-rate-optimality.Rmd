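---
title: "Hierarchical diffusion modelling of reward-rate optimal decision thresholds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical diffusion modelling of reward-rate optimal decision thresholds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(rrddm)
library(dplyr)
```

## The scientific question

In a two-alternative forced-choice task where every correct answer earns a
point, a decision maker controls one dial: how much evidence to require
before responding. A high decision threshold buys accuracy at the price of
time; a low one buys speed at the price of errors. For a given perceptual
sensitivity and trial timing there is a unique threshold that maximises the
reward rate — points per unit time — and a long-standing question is whether
people find it, and whether the block structure of the task (completing a
fixed number of trials versus responding for a fixed amount of time) changes
how close they get.

`rrddm` implements the full model-based analysis pipeline for this question:
a simple diffusion decision model estimated hierarchically by
differential-evolution MCMC, reward-rate-optimal threshold computation,
Savage–Dickey Bayes factors for the optimality hypotheses, the preregistered
exclusion rules, a synthetic-data generator that emulates the two-group
block design, a parameter-recovery harness, and a preregistration-skeleton
renderer.

## The measurement model

The simple diffusion model describes each decision as a Wiener process with
drift $v$ (evidence quality), diffusion coefficient $s$ (fixed at 1 as the
scaling convention; $s = 0.1$ selectable for fast-dm-scaled values), absorbing
boundaries at $0$ and $a$ (the threshold), start point $z = z_r a$, and a
non-decision time $t_{er}$ added to every first-passage time. Between-trial
variability parameters are deliberately excluded: without them the model has
markedly better parameter recovery, and they play no role in the optimality
question.

Three closed forms do most of the work. The probability of absorbing at the
upper (correct) boundary is

$$P(v, a, z_r) = \frac{1 - e^{-2 v z_r a / s^2}}{1 - e^{-2 v a / s^2}},$$

the mean decision time at an unbiased start is
$\mathrm{DT}(v, a) = \tfrac{a}{2v} \tanh\!\big(\tfrac{v a}{2 s^2}\big)$, and
the first-passage-time *density* is evaluated by the standard small-time /
large-time series representations, choosing per evaluation whichever needs
fewer terms for an absolute truncation error below $10^{-7}$. The tests
verify the density against quadrature (normalisation and moments) and against
large-sample simulation.

### Reward rate and the optimal threshold

With a per-trial overhead $D$ (inter-trial interval plus feedback), the
reward rate of a threshold $a$ is

$$\mathrm{RR}(a) = \frac{P(v, a, 0.5)}{\mathrm{DT}(v, a) + t_{er} + D},$$

and the optimal threshold $a^*(v, t_{er}, D)$ is its argmax, found by a
coarse global scan plus golden-section refinement (tolerance $10^{-6}$; the
scan is a cheap guard against non-unimodality, although RR is unimodal in
$a$ for this model class). Two limiting behaviours are built into the test
suite: $a^* \to 0$ as total dead time vanishes (instant guessing becomes
optimal), and $a^*$ is non-decreasing in overhead.

The overhead $D$ defaults to 1.0 s. This is an explicit placeholder —
experiments of this kind rarely print their trial bookkeeping — so $D$ is
configurable everywhere, and every Bayes-factor report records the timing
under which it was computed.

## The four hierarchical structures

All individual-level parameters follow group-level truncated normal
distributions, and the two groups (`fixed_time`, `fixed_trial`) always get
fully separate hierarchies.

* **`block_threshold`** (qualitative analysis): per participant $v_i$,
  $z_{r,i}$, $t_{er,i}$ and one threshold $a_{ij}$ per block — only the
  threshold varies between blocks. Group level: $(\mu, \sigma)$ for each
  scalar parameter and per-block $(\mu_{a,j}, \sigma_{a,j})$. Whether the
  block-threshold group levels should be shared across blocks was an open
  choice; per-block levels were adopted because the scientific object of
  interest is precisely the block-resolved threshold trajectory.
* **`optimality_offset`** (each group vs optimality): per participant $v_i$,
  $t_{er,i}$ and an *additive* offset $c_i$ with the single threshold over
  the analysis window defined deterministically as
  $a_i = a^*(v_i, t_{er,i}, D) + c_i$, $c_i \sim N(\mu_c, \sigma_c)$. The
  additive convention was chosen over a ratio because "too cautious" then
  maps directly onto $\mu_c > 0$. The start point is fixed at $0.5$ here:
  the optimality closed forms assume an unbiased start. Only the second
  half of the session (blocks 11–20) enters the likelihood, allowing for
  participants adjusting to the task.
* **`group_difference`**: both groups jointly, with
  $\mu_{c,\text{fixed-time}} = \bar\mu_c + \Delta_c/2$ and
  $\mu_{c,\text{fixed-trial}} = \bar\mu_c - \Delta_c/2$. The $\pm\Delta_c/2$
  parameterisation keeps the pair identifiable and gives $\Delta_c$ a direct
  prior centred at 0, which the Savage–Dickey ratio requires.
* **`block_threshold_drift`** (robustness): as `block_threshold` but drift
  is also block-indexed, with per-block group levels.

Default priors (overridable from configuration) are weakly informative on
the $s = 1$ scale: $\mu_v \sim \mathrm{TN}(2, 2, [0, 10])$,
$\mu_{z_r} \sim \mathrm{TN}(0.5, 0.2, [0.2, 0.8])$,
$\mu_{t_{er}} \sim \mathrm{TN}(0.3, 0.3, [0, 1])$,
$\mu_a \sim \mathrm{TN}(1.5, 1.5, [0, 6])$, all group SDs
$\sim \mathrm{TN}(0.5, 0.5, [0, 5])$, and $\mu_c, \Delta_c \sim N(0, 1)$.
The truncation bounds double as the domains of the individual-level
truncated normals. Inside the posterior, $a^*$ is memoised on $(v, t_{er})$
rounded to $10^{-6}$ to bound the cost of the deterministic node.

Numerical guard rails: densities are floored at $10^{-10}$ before logging,
so a stray impossible trial (e.g. an RT below $t_{er}$ under the current
proposal) contributes a large finite penalty instead of $-\infty$ and keeps
DE proposals comparable; parameter vectors outside any truncation bound get
$-\infty$ outright.

## Estimation

Estimation is Markov chain Monte Carlo with differential-evolution
proposals: chain $k$ proposes
$\theta_k' = \theta_k + \gamma(\theta_m - \theta_n) + U(-\varepsilon, \varepsilon)$
with distinct random donors, Metropolis-accepted. Defaults follow the
preregistered settings: 66 chains, 3,000 iterations, the first 1,500
discarded, no thinning. $\gamma = 2.38/\sqrt{2d}$ for a $d$-dimensional
update with 10% of proposals at $\gamma = 1$ (mode jumping), jitter
$\varepsilon = 10^{-4}$. With probability 0.05 per iteration, a *migration*
step replaces DE crossover: a random subset of chains passes states around a
random cycle, each transfer Metropolis-accepted, which frees stuck chains
while preserving the target.

Hierarchical fits update parameters in conditional blocks — the group level,
then each participant's scalar parameters, then each block-indexed parameter
separately — with cached posterior components so a block update recomputes
only what it touches. The fine (per-block-parameter) blocking matters: joint
13-dimensional participant updates mix an order of magnitude more slowly at
the designs used here. Chain starts are drawn from the priors until the log
posterior is finite (at most 1,000 attempts per chain). Convergence is
monitored by split-chain $\widehat R$; the pipeline warns above 1.1 but does
not abort, and recovery reports record per-replicate convergence.

## Inference

The Savage–Dickey ratio for a point null at 0 is the prior density over the
posterior density at 0. The posterior density is estimated by a Gaussian
kernel with Silverman's bandwidth on the pooled post-burn-in draws (a
moment-matched normal approximation is available as an alternative, and the
report records the estimator used). We report `bf10` = prior/posterior at 0
(evidence against the null), its reciprocal `bf01`, and a `direction`
statistic (posterior mass above 0) in place of one-sided priors; under the
additive-offset convention, direction near 1 reads "too cautious". A
vanishing density estimate is floored at $10^{-12}$ and the BF flagged as a
lower bound. The KDE-at-a-point estimator is the method's known weak spot
when the null lies far in the posterior tail — its relative error is checked
against the conjugate normal-mean closed form in the tests.

The qualitative trend analysis compares the block-threshold posteriors with
the posterior predictive distribution of $a^*$ (drawn by pushing group-level
posterior draws through a new participant's truncated normals), summarised
as 0.2/0.4/0.6/0.8 quantile bands plus 95% tails, with a descriptive
Kendall's $\tau$ of |threshold − optimal| against block. No Bayes factor is
attached to this analysis; it is preregistered as qualitative.

## The synthetic-data generator

The generator emulates the behavioural table of the study design: two groups
of 35 participants (defaults), 20 blocks, fixed-trial blocks of 30 trials,
fixed-time blocks of 60 s in which trials accrue while cumulative
RT + overhead remains under the duration. Those block constants are the
package's chosen study conditions: the source design prints neither block
duration nor trial timing, so values typical of random-dot-motion sessions
were fixed once. Individual parameters come from truncated normals typical
of practiced RDM performance ($v \sim \mathrm{TN}(2.2, 0.4)$,
$z_r \sim \mathrm{TN}(0.5, 0.04)$, $t_{er} \sim \mathrm{TN}(0.3, 0.05)$).

Block thresholds follow
$a_{ij} = a^*_i + (a_{i1} - a^*_i) e^{-\lambda (j - 1)}$ with
$a_{i1} \sim \mathrm{TN}(2.5, 0.5)$ and $\lambda = 0.15$: participants start
too cautious and converge most of the way to their optimal threshold over 20
blocks. This trajectory is an emulation device — it gives synthetic data the
qualitative approach-to-optimality structure that the trend analysis needs
to have signal to detect — not a claim about the learning process. A second
mode (`c_offset`) plants $a_{ij} = a^*_i + c_i$ with
$c_i \sim N(\mu_c^{\mathrm{gen}}, \sigma)$ directly, which is how the
simulation studies put a known $\mu_c$ or $\Delta_c$ into the ground truth.

Trials are simulated by Euler–Maruyama with step 0.001 s plus an exact
Brownian-bridge within-step crossing test. The bridge test matters: with
constant drift and diffusion the within-step crossing probability
$\exp(-2 d_0 d_1 / s^2 \Delta t)$ is exact per boundary, and without it the
missed-crossing bias shifts the effective boundary by
$\approx 0.58\, s\sqrt{\Delta t}$ — roughly $+0.3\%$ accuracy and $+12$ ms
mean RT at typical parameters, far outside what large-sample fidelity checks
against the closed forms tolerate. The uncorrected scheme remains available
as `method = "euler"` with that documented bias.

What the generator does *not* emulate: stimulus rendering, learning dynamics
other than the threshold trajectory, within-block non-stationarity,
contaminant RTs, or lapses. Passing tests on synthetic data therefore show
that the pipeline recovers what it assumes, not that real data satisfy those
assumptions.

## Preprocessing

The preregistered exclusions run in a fixed order: drop block 1 (practice),
drop trials with RT below 150 ms or above 10 s, then — on the surviving
trials — drop participants with accuracy below 60% or fewer than 200
eligible trials, tagging each excluded participant with the first failing
rule (accuracy checked first). All thresholds are strict inequalities, so
boundary values (exactly 150 ms, exactly 60%, exactly 200 trials) are kept;
the source text says "below"/"less than" and the boundary convention is
otherwise unstated. The report object carries per-rule counts and satisfies
row conservation exactly; fitting refuses a table that has not been through
the pipeline (use `no_exclusions()` to run the robustness variant that
reinstates everything).

## Recovery, robustness, and problem sizes

`run_recovery()` is the preregistered substitute for a power analysis:
generate, preprocess, refit, and compare generating values with recovered
posterior medians (correlation, signed bias, RMSE per parameter type). No
universal pass/fail bar is imposed; the acceptance suite pins one scaled
design — 8 participants, 10 blocks, ~40 trials per block, 24 chains × 800
iterations — at which drift and block-threshold correlations comfortably
exceed 0.8 (~2–3 minutes on one core). That design and the 6-participant ×
300-trial hypothesis-test simulations are the package's chosen test scales:
large enough for the statistical claims being checked, small enough to run
routinely. The full preregistered sampler (66 × 3,000) is the default for
real analyses.

`run_robustness()` reruns the key analyses under exactly the two
preregistered variants — (a) exclusion-free preprocessing, (b) the
block-threshold-and-drift model — labelled as robustness results and never
overwriting the primary ones.

## A worked example at demonstration scale

```{r example, eval = FALSE}
design <- experiment_design(n_per_group = 6, timing = trial_timing(1))
trials <- generate_dataset(design, seed = 7)

clean <- apply_exclusions(trials)
exclusion_report(clean)

cfg <- de_config(n_chains = 24, n_iter = 500, burn_in = 250)
fits <- lapply(
  setNames(nm = c("fixed_time", "fixed_trial")),
  function(g) fit_ddm(clean, "optimality_offset", group = g,
                      config = cfg, seed = 7)
)
bf_optimality_offset(fits)

fit_blocks <- fit_ddm(clean, "block_threshold", config = cfg, seed = 7)
tab <- threshold_optimality_table(fit_blocks, trial_timing(1))
optimality_trend(tab)
autoplot(tab)
```

## Known limitations

* The KDE Savage–Dickey estimate degrades when the posterior is many SDs
  from the null; the reported BF is then a flagged lower bound rather than a
  calibrated value.
* The reward-rate objective uses a single lumped overhead; tasks with
  error-dependent timeouts or accuracy-weighted payoffs need a different
  objective (out of scope).
* Hierarchical shrinkage biases individual posterior medians toward group
  means; recovery statistics on small groups should be read with that in
  mind.
* The optimality analyses assume an unbiased start point; data with strong
  response bias violate the deterministic-node construction.
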