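---
title: "Methods: models, tests and design decisions in riskshift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, tests and design decisions in riskshift}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`riskshift` analyses blocked on/off stimulation sessions of a time-pressured
two-alternative risk task. This vignette documents the statistical machinery
in full: the psychometric model, the priors and sampler, the fit
classification, the frequentist companions, the simulator that generates
study-condition data, and the numerical and design decisions behind each.

## The task and the data

A session consists of `n_blocks` blocks of `trials_per_block` trials
(default 6 × 160 = 960). Stimulation is on during a fixed subset of blocks
(default blocks 3 and 5). On each trial a cue signals the reward probability
of the risky option — one of 0.1, 0.3, 0.5, 0.7, 0.9 by default — and the
participant chooses, within a 1 s deadline, between the risky option (50 or
0 points with the cued probability) and a safe option (always 10 points).
Trials with no response before the deadline are omissions: unrewarded
non-choices, excluded from every choice and reaction-time analysis. The
analysis consumes a flat trial log (one row per trial:
`block, trial, condition, cue_prob, choice, outcome, rt_ms`), so any session
with this structure — patient, control, or simulated — runs through the same
pipeline. `partition_by_block()` relabels conditions by block so an
unstimulated control session can be pushed through the identical analysis as
a negative control.

## The psychometric model

The probability of choosing the risky option at cued probability $p$ is

$$\psi(p) = \mathrm{floor} + (\mathrm{ceiling} - \mathrm{floor})
\cdot \frac{1}{1 + e^{-(p - m)/w}}$$

* $m$ (threshold, reward-probability units): where the choice probability is
  midway between the asymptotes. Lower $m$ means risk-seeking at lower cued
  probabilities.
* $w$ (scale, reward-probability units): the logistic scale. We use the
  *scale* convention — smaller $w$ is steeper — rather than a
  slope-at-midpoint convention, because it keeps $(m, w)$ a pair of free
  location/scale parameters with simple box supports.
* `floor`, `ceiling` (probabilities): asymptotic biases toward the risky and
  safe option irrespective of the cue; $1 - \mathrm{ceiling}$ is the
  cue-independent tendency to take the safe option.

Responded trials are modelled as independent Bernoulli draws with success
probability $\psi(p_\ell)$, so per-level counts $(k_\ell, n_\ell)$ are
sufficient and the log likelihood is
$\sum_\ell k_\ell \log \psi_\ell + (n_\ell - k_\ell) \log(1 - \psi_\ell)$.
When $\psi$ saturates numerically against discordant counts the likelihood
returns $-\infty$ rather than `NaN`, so the sampler simply rejects such
proposals.

### Priors

Each parameter carries an independent uniform prior:
$m \sim U(-0.25, 1.25)$, $w \sim U(0.01, 1)$,
$\mathrm{floor} \sim U(0, 0.5)$, $\mathrm{ceiling} \sim U(0.5, 1)$. These
are deliberately weakly informative: the $m$ support extends beyond the
tested cue range so strongly shifted thresholds remain representable; the
lower bound on $w$ excludes a degenerate step; the disjoint floor/ceiling
boxes enforce $\mathrm{floor} < \mathrm{ceiling}$ and keep the two
asymptotes identified. All bounds are user-settable through `prior_spec()`
and round-trip through the YAML configuration.

## The sampler

`sample_posterior()` is a self-contained component-wise Gaussian random-walk
Metropolis sampler. Each parameter is mapped to an unconstrained coordinate
by a scaled logit over its prior support (all four parameters have bounded
uniform supports, so one transform family serves all of them, including $w$,
whose upper bound a plain log transform would ignore); the log-Jacobian is
included in the target. Design choices:

* **Initialisation.** The maximum-posterior point of a coarse $11^4$
  midpoint grid over the prior box, jittered independently per chain
  (N(0, 0.2) on the transformed scale). If 100 jittered restarts fail to
  produce a finite log posterior, sampling aborts with an initialisation
  error.
* **Adaptation.** Per-coordinate proposal scales follow a Robbins–Monro
  recursion toward a target acceptance rate (default 0.35, appropriate for
  one-dimensional updates) during warmup *only*; they are frozen afterwards
  so the retained chain is a genuine Markov chain. The frozen scales are
  exposed on the result so this invariant is testable.
* **Defaults.** 4 chains × 1000 warmup × 2000 retained draws, thin 1. For a
  4-dimensional posterior with 5-level binomial data this gives split-Rhat
  ≈ 1.00–1.01 and effective sample sizes of several hundred per parameter in
  well under a second.
* **Determinism.** All randomness flows through R's RNG (also inside the
  compiled inner loop), so identical inputs and seed give byte-identical
  draws; the sampler saves and restores the caller's RNG state.

`diagnostics()` reports split-Rhat (each chain halved), an effective sample
size from pooled autocovariances with Geyer-style positive-pair truncation,
and per-parameter acceptance rates, flagging failure when any Rhat exceeds
1.05 or any ESS falls below 400. The ESS estimator is validated against the
closed-form AR(1) value and against an independent implementation; the
sampler itself is validated against dense-grid numerical integration of the
posterior (marginal means, intervals, and total variation of the threshold
marginal) and, with no data, against the prior it must then reproduce.

## Fit classification and the threshold shift

`fit_condition()` fits one condition and classifies the result. Goodness of
fit uses a posterior-predictive check with the $\chi^2$-style discrepancy
$T = \sum_\ell (k_\ell - n_\ell \psi_\ell)^2 /
(n_\ell \psi_\ell (1 - \psi_\ell))$, comparing the observed counts with
counts replicated from the model at the same posterior draw;
`ppc_p = P(T_{rep} \ge T_{obs})`. Status is `ok` when the chains pass the
Rhat gate and `ppc_p ≥ 0.05`; `poor_fit` below 0.05; `unfittable` below
0.005. The two cut-offs operationalise "behaviour a monotone psychometric
function cannot capture" — grossly non-monotonic choice patterns (e.g.
risky-choice proportions 0.8, 0.2, 0.5, 0.7, 0.9 across increasing cue
levels) land far below the 0.005 line, while well-specified data rarely dip
under 0.05. The denominator is clamped at $10^{-12}$ so saturated cells
cannot produce division by zero.

The stimulation effect is summarised by pairing independent posterior draws
of the threshold from the two fits (seeded random pairing, one pair per
retained draw up to the shorter chain) and reporting the posterior of
$\Delta m = m_{on} - m_{off}$: mean, 90% interval, and
$P(\Delta m < 0)$ (`prob_left_shift`). We chose a difference-of-posteriors
statement over an overlap measure or a joint hierarchical model because the
conditions are fitted independently and the question — did the threshold
move left? — is a direct posterior probability. When either fit is not `ok`
the report is flagged; when both are unfittable the shift is marked
unavailable rather than reported.

## Frequentist companions

**Per-level mid-P Fisher tests.** For each cue probability a 2×2 table
(condition × risky/safe, omissions excluded) is tested by enumerating the
hypergeometric distribution under the observed margins. The two-sided value
follows Fisher's point-probability ordering with the mid-P correction: all
tables strictly less probable than the observed one count fully, the
observed probability class counts half. Probability equality uses a relative
tolerance of $10^{-12}$, so exact ties (e.g. symmetric tables) are grouped
correctly. A zero row or column margin leaves a single admissible table; the
test returns 0.5 with a degeneracy flag. Significance tiers use strict
inequalities at 0.05, 0.01, 0.001. The implementation is tested to equal an
independent enumeration oracle exactly for every table with total ≤ 30 and
never to exceed the conventional two-sided exact p.

**Reaction-time ANOVA.** A fixed-effects full-factorial linear model of RT
on stimulation, choice, and cue probability, all categorical (probability
has five discrete levels by design, so treating it as a factor makes no
functional-form assumption). Sums of squares are Type II, computed by nested
least-squares model comparisons that respect marginality; this matches the
classical Type II table on complete balanced data (verified against an
independent implementation to $10^{-8}$) while tolerating empty cells, whose
aliased columns simply reduce the term's degrees of freedom. Constant RT is
reported as all-zero sums of squares with p = 1; designs without residual
degrees of freedom raise an error. Both the Type II choice and the
categorical treatment of probability can be revisited by fitting the
returned model formula differently; they are the defaults because simulated
designs here are near-balanced and levels are few and fixed.

## The simulator

`simulate_session()` generates study-condition data: 960 trials in six
blocks of 160, stimulation on in blocks 3 and 5, five cue probabilities
appearing exactly 32 times per block in a seeded shuffled order (the real
task's sequencing rule is unknown; balancing within block is the choice that
makes the per-level tests well-posed in every block subset). Per trial, an
independent Bernoulli omission draw (default rate 0.033) precedes the choice
draw from the condition's ψ; risky outcomes win with the cued probability.
Reaction times follow a log-normal law truncated at the deadline via
inverse-CDF sampling — right-skewed, positive, and deadline-respecting, which
is all the ANOVA surface requires — with a condition-specific location.

The default agent is risk-averse at baseline ($m = 0.55$, $w = 0.10$,
floor 0.05, ceiling 0.95) and shifts its threshold left by 0.2 under
stimulation with all other parameters unchanged — a threshold-only effect of
the size and direction the analysis is built to detect — and responds about
20 ms slower when stimulated (locations log 680 → log 700 ms, scale 0.20),
giving the RT ANOVA a small real main effect to find. These defaults are the
package's reference conditions and are not tuned per analysis.

What the simulator deliberately does **not** model: feedback learning or any
within-block adaptation (agents have fixed parameters; the practice block of
the real task is outside the analysed data), sequential dependencies between
trials, affective responses, or stimulation electrophysiology. Passing tests
on simulated sessions therefore demonstrates correctness of the *analysis*
under the stated generative assumptions, not that real behaviour satisfies
those assumptions.

## Numerical and reproducibility choices

* One master seed per run; stage seeds (simulation, per-condition sampling,
  predictive check, draw pairing) are derived deterministically from it, so
  whole-pipeline runs are reproducible file-for-file while stages stay
  decoupled.
* Likelihood saturation yields $-\infty$, never an exception or `NaN`.
* Deviance ($-2 \log L$) is stored per draw and is recomputable from the
  draw's parameters, which doubles as a cross-check between the compiled
  and interpreted likelihood paths.
* Report JSON is schema-versioned
  (`inst/extdata/shift-report-schema.json`, version 1) and a pure function
  of the inputs.
* Validation of trial logs collects all row-level problems (unknown labels,
  reaction times present for omissions or beyond the deadline) and reports
  them together with row numbers.

The test suite sizes its simulations to keep the full run in the
low minutes on a single CPU while leaving comfortable statistical margins:
calibration and power use 200 sessions per arm at reduced sampler settings
(2 chains × 500 draws), parameter recovery uses 50 sessions of 640
off-condition trials, grid–sampler agreement uses a two-stage dense grid
(coarse pass over the full prior box, 81-point refinement per axis), and the
mid-P exactness sweep enumerates all 46,375 tables with total ≤ 30.

## Known limitations

* Single-session, single-participant inference only; no hierarchical
  pooling across participants.
* One sigmoid family (logistic); Weibull or Gumbel alternatives are out of
  scope.
* The component-wise random-walk sampler is adequate for this 4-parameter
  posterior but would mix poorly on strongly correlated, higher-dimensional
  targets; it is not a general-purpose MCMC engine.
* The mid-P tests are reported per level without multiplicity correction,
  matching the conventional presentation of per-level stars.
* With all-degenerate data (every level all-risky or all-safe) the
  posterior is prior-dominated; the sampler warns and proceeds, and the
  predictive check rather than the sampler flags the problem.
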