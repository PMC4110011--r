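# msrl — multisensory reward learning with subspace generalization testing

`msrl` is for computational cognitive scientists and reinforcement-learning
researchers studying how optimal multisensory *integration* can develop out
of early single-modality *selection*. It implements an interactive,
single-step reward-maximization learner that needs no prior knowledge of
its sensors' noise models: it keeps reward statistics for the joint sensory
space and for all of its subspaces in parallel, screens every subspace with
a statistical generalization test, and acts through confidence-interval
policies. On a simulated audiovisual localization task the same mechanism
reproduces the developmental arc — sensory selection early, reliability-
weighted integration late — as emergent behavior rather than a programmed
switch.

## The model in brief

For state $s=(o^1,\dots,o^k)$ and action $a$, the value estimate
$Q(s,a)=\sum r / n$ is the sample mean of the rewards seen, held as
sufficient statistics $(n, \sum r, \sum r^2)$ per cell. Three two-sided
confidence intervals on a cell's mean are available at level $\alpha$:

* Student-t: $Q \pm t_{\alpha/2,n-1}\, s/\sqrt{n}$ (default),
* worst-case Chebyshev: $Q \pm (r_{hi}-r_{lo})/(2\sqrt{n\alpha})$,
* empirical Bernstein:
  $Q \pm \big(s\sqrt{2\ln(3/\alpha)/n}+3(r_{hi}-r_{lo})\ln(3/\alpha)/n\big)$.

Marginal statistics of any sensor subset are exact sums over joint cells
and are maintained incrementally at no extra sampling cost. For each state,
source and action, the **generalization test** subtracts the current joint
cell from its marginal (the *residual* experiences of the aliased sibling
states) and accepts the source iff the residual interval intersects the
joint cell's interval. Accepted sources compete per action: **MOS** takes
the greatest upper bound, **LUS** the shortest interval, both capped at the
joint space's upper bound; the action with the maximal representative value
is executed. UCB1 baselines ($Q+\sqrt{c\ln N/n}$) and the omniscient
reliability-weighted Bayesian observer
$\hat s = (x_a/\sigma_a^2 + x_v/\sigma_v^2)/(1/\sigma_a^2+1/\sigma_v^2)$
provide the comparisons.

## A worked example

```r
library(msrl)
env <- env_experiment1()   # 30 positions; visual sigma = 1, auditory sigma = 2
env
#> <localization env: 30 positions, radius 3 (binary reward), sensors: visual~N(0,1), auditory~N(0,2)>

fit <- run_lifetime(env, agent_config("mos"), horizon = 20000, seed = 1)
summary(fit)
#> Lifetime of 20000 steps, MOS policy
#> Mean reward: 0.779  (by quarter: 0.368 0.852 0.931 0.964)
#> Dominance shares (%):
#>    joint   visual auditory
#>     20.3     60.5     19.2
#> Dominance by quarter (%):
#>            Q1   Q2   Q3   Q4
#> joint     3.9 20.6 26.8 29.8
#> visual   58.7 55.4 63.0 65.0
#> auditory 37.4 24.0 10.2  5.2
#> Generalization-test acceptance (first vs last quarter):
#>               visual auditory
#> first_quarter  0.998    0.995
#> last_quarter   0.825    0.323
```

Reading it: reward per quarter climbs from 0.368 to 0.964 as the policy
matures. The joint (integrated) source's share of decisions grows from
3.9% to 29.8% while the auditory share collapses — the
selection-to-integration transition in progress — and the generalization
test, which accepts nearly everything at first, increasingly rejects the
aliased single-sensor subspaces, fastest for the noisier auditory sensor.
`plot(fit)` draws the smoothed reward, acceptance and dominance time
courses; `predict(fit, cbind(10, 12))` returns the learned greedy position
(here `8`; the fused estimate for readings 10 and 12 once learning is
mature lands near 11–12, and keeps improving with longer lifetimes).

Paired multi-agent comparisons run through `run_experiment()`:

```r
roster <- standard_roster(env)[c("joint", "mos", "lus")]
ex <- run_experiment(roster, env, horizon = 2e5, runs = 20, seed = 1, fracs = 0.6)
ex$summary[, 1:4]
#>   agent frac mean_steps runs_crossed
#> 1 joint  0.6   15679.75           20
#> 2   mos  0.6    9633.80           20
#> 3   lus  0.6    6194.60           20
```

Every agent in a run sees the identical stimulus/observation stream, so
the steps-to-60%-of-the-observer criterion is exactly paired: the
interval-selection learners reach it several times faster than the
joint-space UCB1 baseline.

A thin command-line wrapper for batch runs lives at `inst/cli/msrl.R`
(`Rscript inst/cli/msrl.R run --experiment 2 --policy mos --steps 100000
--runs 10 --seed 1 --out results/`).

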