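---
title: "Reward-driven multisensory learning: from sensory selection to integration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reward-driven multisensory learning: from sensory selection to integration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msrl)
```

## The problem

Adults combine the readings of their senses close to the statistically
optimal, reliability-weighted way; children instead tend to rely on a single
modality. `msrl` implements an interactive, reward-driven account of that
developmental transition: a single-step learner that knows nothing about its
sensors' noise models, maintains reward statistics for the *joint* sensory
space and for all of its subspaces in parallel, statistically screens each
subspace's ability to generalize, and always acts on the most useful source
of information. Sensory "selection" and "integration" then both fall out of
one reward-maximization mechanism: subspaces win early (they are small and
learn fast), the joint space wins late (it is unambiguous but slow to fill),
and the crossover is smooth and autonomous.

## The model

An agent has $k$ sensors; sensor $i$ returns an observation $o^i$ and the
joint state is $s = (o^1, \dots, o^k)$. Each step it picks an action $a$ and
receives a reward drawn from an unknown distribution attached to $(s, a)$,
with known support $[r_{lo}, r_{hi}]$ (default $[0,1]$). With learning rate
$1/n$ the value estimate $Q(s,a)$ is exactly the sample mean, so each cell
is fully summarised by the sufficient statistics
$(n, \sum r, \sum r^2)$ — the representation `sufficient_stats()` stores and
`stats_update()` maintains.

### Confidence intervals on a cell mean

All decisions operate on interval estimates of the mean reward, at a single
significance level $\alpha$:

* **Student-t** (`ci_student`): $Q \pm t_{\alpha/2,\,n-1}\, s/\sqrt{n}$.
  Exact for Gaussian rewards, a good approximation at moderate $n$; the
  tightest of the three and the default.
* **Chebyshev** (`ci_chebyshev`):
  $Q \pm (r_{hi}-r_{lo})/(2\sqrt{n\alpha})$, using the worst-case variance
  $(r_{hi}-r_{lo})^2/4$ of any distribution on the support. Distribution-free
  and very conservative.
* **Empirical Bernstein** (`ci_bernstein`):
  $Q \pm \big(s\sqrt{2\ln(3/\alpha)/n} + 3(r_{hi}-r_{lo})\ln(3/\alpha)/n\big)$.
  Distribution-free but variance-aware: much tighter than Chebyshev when
  rewards are nearly constant. The canonical empirical-Bernstein constants
  are used; the construction is swappable behind the `bound` argument.

A cell with too few samples for its bound ($n<2$ for the variance-based
bounds, $n<1$ for Chebyshev) gets the unbounded interval
$(-\infty, \infty)$. That one convention implements optimism in the face of
uncertainty everywhere at once: an untried action looks maximally good, and
an under-sampled subspace can never be rejected.

### Marginal subspaces without extra trials

Because cells are additive sufficient statistics, the statistics of any
sensor subset are plain sums of joint cells:
$n^i(o^i,a) = \sum_{s \ni o^i} n(s,a)$ and likewise for the reward sums.
`stat_tables()` keeps one table per *source* (every singleton sensor by
default, every non-empty proper subset with `powerset = TRUE`) and
`record_experience()` updates the joint cell and all projections in one
pass, so subspace learning costs no extra trials. Incremental maintenance is
an optimization, not an assumption — the test suite checks it against
brute-force re-marginalization cell by cell.

### The generalization test

Perceptual aliasing makes a subspace cell pool experiences from many joint
states. That pooling is *useful* when the aliased states share a policy and
*garbage* when they do not. Because the marginal cell contains the current
joint cell's own rewards, comparing them directly would be circular;
`residual_stats()` first subtracts the joint cell, leaving only the
experiences gathered in the *other* aliased states. The test
(`g_test()`) then accepts the source for this state and action iff the
residual interval intersects the joint cell's interval (closed intervals;
touching endpoints intersect). Early in learning everything is accepted
(wide or unbounded intervals); asymptotically both intervals shrink to
points and only genuinely generalizing sources keep passing.

### Decision policies

Per action, the accepted sources' residual intervals compete with the joint
interval $M$:

* **MOS** (`mos_select`) takes the greatest accepted upper bound — the most
  optimistic source.
* **LUS** (`lus_select`) takes the shortest candidate interval — the least
  uncertain source — with the joint interval itself among the candidates.

Either way the representative value is capped at $M$'s upper bound: the
joint space has no aliasing, so optimism beyond its upper bound is
unrealistic. The action with the greatest representative value is executed
(`choose_action`), with exact ties broken uniformly. The *dominant source*
of a step is the source whose interval supplied the chosen action's value
(the joint space when the cap fires); its time course is the
selection-to-integration transition made measurable.

### Reference policies

`ucb1_value()` implements the classical UCB1 rule
$Q + \sqrt{c \ln N / n}$ used by the baseline agents (per-sensor and
joint-space learners), and `bayes_optimal_estimate()` the omniscient
reliability-weighted observer
$\hat s = (x_a/\sigma_a^2 + x_v/\sigma_v^2)/(1/\sigma_a^2 + 1/\sigma_v^2)$
that knows the true noise SDs and serves as the performance yardstick.

## The simulated task

`env_config()` builds the localization world: a stimulus uniform on 30
discrete positions, one action per position, and reward strictly positive
iff the guess lands within 3 grid units of the stimulus. Gaussian sensors
read the stimulus plus Normal noise, rounded half-up and clamped (not
wrapped) to the grid; a uniform-noise sensor reads pure noise. A failure
schedule can replace a sensor's model with uniform noise mid-run — the
lowest reliability a bounded grid admits.

Defaults, all configurable:

| parameter | default | why |
|---|---|---|
| grid / action set | 30 | size of the discrete localization task |
| reward | binary 1/0, radius 3 | simplest function positive exactly within the radius; a graded linear shape is available |
| $\sigma_{visual}$ | 1.0 grid units | vision as the more reliable modality |
| $\sigma_{auditory}$ | 2.0 grid units | audition noisier, as in audiovisual localization |
| $\alpha$ | 0.05 | conventional two-sided 95% intervals; the framework's only free parameter |
| UCB1 $c$ | 0.2 | the classical $c=2$ over-explores large stationary spaces; a small coefficient keeps the baselines competitive |
| reward support | $[0, 1]$ | matches the binary reward |

## What the generator emulates — and what it does not

The simulator reproduces the structure that drives the phenomenon: a
fully observable joint space, aliasing in every subspace, sensor
reliabilities that differ, and a reward that depends on the true stimulus
only. It does *not* emulate correlated sensor noise, non-uniform stimulus
priors, continuous space, reward non-stationarity beyond the scheduled
failure, or sensorimotor delays. Results on this task therefore demonstrate
the mechanism — fast subspace learning first, joint-space dominance later,
noise subspaces filtered — not quantitative predictions for any particular
psychophysical dataset.

## Numerical and design choices

* **Exact pairing.** All randomness (stimulus stream, sensor noise,
  tie-break uniforms) is pregenerated per run from one seed
  (`make_streams()`); every agent and the Bayesian observer consume the same
  streams, so learning-speed comparisons are paired and runs are exactly
  reproducible. Run $i$ of a multi-run experiment uses seed $\texttt{seed}+i$.
* **Two engines, one arithmetic.** The per-step loop exists as a pure-R
  reference built from the exported operations and as a compiled core used
  for long horizons; the suite asserts bitwise-identical trajectories for
  every policy and bound.
* **Ties.** MOS upper-bound ties go to the lowest sensor index; LUS length
  ties prefer the joint space, then the lowest index; action-value ties are
  uniform random. Cap-triggered decisions are attributed to the joint space,
  whose bound supplied the value actually used.
* **Degenerate inputs.** A lone sensor has no proper subspaces, so a
  single-sensor agent reduces to the joint-interval policy. Variance
  radicands pushed below zero by cancellation are clamped to zero. Rewards
  outside the declared support abort the run rather than corrupt the tables.
* **Learning-speed criterion.** `steps_to_fraction()` reports the first
  step from which the agent's accumulated reward *sustainedly* holds the
  target fraction of the observer's: in the first steps the cumulative
  ratio is dominated by luck, so a momentary crossing says nothing about
  learning.
* **Problem sizes.** The package's standard analyses use 20 paired runs of
  $2\times10^5$ steps for the two-sensor learning-speed comparison, 10 runs
  of $10^5$ steps for the three-sensor (noise) study, and $10^5$ steps
  before and after the scheduled failure; the test suite uses shorter
  horizons chosen to keep each property sharp at small cost.

## A worked run

```{r, eval = FALSE}
env <- env_experiment1()
fit <- run_lifetime(env, agent_config("mos"), horizon = 1e5, seed = 1)
summary(fit)    # reward by quarter; dominance and acceptance time courses
plot(fit)       # smoothed reward, acceptance and dominance panels

roster <- standard_roster(env)[c("joint", "mos", "lus")]
ex <- run_experiment(roster, env, horizon = 2e5, runs = 20, seed = 1,
                     fracs = 0.6)
ex              # steps to 60% of the observer, dominance percentages
```

The diagnostics to look at: the joint source's dominance share rising from
the first to the last quarter while the single sensors' shares fall; the
per-sensor acceptance rate decaying, faster for the noisier sensor; and the
interval-selection agents reaching any fixed fraction of the Bayesian
observer's accumulated reward in far fewer steps than the joint-space UCB1
baseline.

## Limitations

The state representation is tabular, so memory and learning time grow with
the product of the sensors' observation ranges; the power-set extension
multiplies the per-step cost by $2^k - 2$. The generalization test inherits
the assumptions of its interval construction (the Student-t bound is only
approximate for small $n$ and non-Gaussian rewards; the distribution-free
bounds are conservative and slow learning accordingly — with them, larger
$\alpha$ values are advisable). Statistics are cumulative over the whole
lifetime, so adaptation to abrupt environmental change is driven by the
generalization test rather than by forgetting, and is correspondingly
gradual in the joint space.
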