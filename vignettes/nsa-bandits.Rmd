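---
title: "A two-population rate-network agent for non-stationary bandits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A two-population rate-network agent for non-stationary bandits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nsabandit)
```

## The problem

A K-armed Bernoulli bandit offers `K` options ("arms") with unknown success
probabilities `p = (p_1, ..., p_K)`. Each round the agent pulls one arm and
receives reward `R ~ Bernoulli(p_k)`. Performance is measured by mean
per-round pseudo-regret,

    rho = (1/T) * sum_t (p*_t - p_{chosen, t}),

the average gap between the optimal arm's probability and the chosen arm's
probability. Pseudo-regret is computed on probabilities rather than realized
rewards, so the oracle policy scores exactly 0 and a uniformly random policy
converges to `p* - mean(p)`.

This package targets the *non-stationary* case — concept drift — where `p`
changes over time and the agent must keep recalibrating. Four drift regimes
are provided by `bandit_env()`:

* **mab-p** (piecewise stationary): `p ~ Normal(0.5, 0.2)` per arm, clipped
  to `[0, 1]`, redrawn abruptly at every trial boundary (a *trial* is a
  block of rounds, 2000 in the benchmark protocol; a *round* is one
  action–reward event).
* **mab-d** (gradual drift): `p` relaxes toward a target `q` by
  `tau_p * dp/dt = q - p`, integrated with one explicit Euler step per
  round; when every arm is within `delta` of the target (sup norm), a new
  target is drawn. There are no proper trials, but per-2000-round blocks
  are kept for uniform reporting.
* **mab-sin**: each arm follows `sin(2 pi f_k t + lambda_k)` with unit
  amplitude, clipped to `[0, 1]`.
* **mab-sinp**: as mab-sin, but `floor(K/2)` randomly chosen arms are
  frozen at constants drawn from the clipped Normal(0.5, 0.2). The vector
  is not normalized — arms are independent Bernoulli sources.

### Environment parameter defaults

The drift speed and sinusoid parameters are tunable with these defaults,
chosen so that a 2 x 2000-round run sees several distribution changes of
each kind:

| parameter | meaning | default |
|---|---|---|
| `tau_p` | drift time constant (rounds) | 200 |
| `delta` | target-switch threshold (sup-norm probability distance) | 0.05 |
| `freq_range` | per-arm sinusoid frequency (cycles/round), uniform | `[1/4000, 1/500]` |
| phases | per-arm sinusoid phase (radians), uniform | `[0, 2 pi)` |

With `tau_p = 200` the drifting variant reaches a new target in roughly
600–800 rounds, giving a handful of target switches per 4000-round episode;
the frequency range gives one to several full probability cycles per
episode. Negative sine half-waves are clipped to 0 (rather than, say,
half-wave rectified and rescaled) because clipping is the simplest map that
keeps every emitted value a valid Bernoulli probability; the clipped-sine
time average over a full period is `1/pi`. Clipping uses the closed
interval `[0, 1]`: boundary mass is negligible at these parameters and an
open-interval clip is ill-defined. The sup norm is used for the `delta`
test so that a target switch happens only when *every* arm has essentially
converged. Sinusoid parameters are drawn once per episode, not per trial.

## The agent

The neural selection agreement agent is a minimal rate network with two
populations of `K` units each. Population U holds the option traces and
receives a constant, uniform external input `I_ext`; population V encodes
option values. Connectivity is diagonal in both directions: the V-to-U
weights are fixed at 1, and the U-to-V diagonal weights `W` are the only
plastic parameters, initialized to zero so that a fresh network favors no
arm. The coupled dynamics are

    tau_u du/dt = -u + phi_v(v) + I_ext
    tau_v dv/dt = -v + Phi_v(W) * phi_u(u)

integrated by forward Euler with `dt = 1` ms (`euler_step()`, and a
compiled loop in `integrate_round()` that is tested to agree with the R
step function to 1e-12). Both populations are advanced synchronously from
their pre-step values; a sequential update would introduce an undocumented
asymmetry between the layers.

`phi_u`, `phi_v` are *thresholded sigmoids* (`neural_response()`): a
generalized sigmoid whose output passes through only when it reaches a
threshold, and is 0 otherwise. A hard step applied on top of a sigmoid
could also be read as emitting a binary 0/1; the pass-through convention is
used here because argmax selection needs graded activities — an all-binary
population would tie almost always. `Phi_v` (the *option-value function*)
and `Phi_eta` (the *learning-rate function*) are Gaussian-sigmoid mixtures
(`gaussian_sigmoid()`): a weighted sum of a saturating sigmoid and a tuned
Gaussian bump, letting optimization blend saturation with
range-selectivity.

### A selection round

Each round has two phases (`integrate_round()`):

1. activities are reset to zero and the network integrates `dur_pre` ms
   with `I_ext` on; the input acts as an attention-like prompt, not as
   information about the arms;
2. the input is removed and the network evolves autonomously for
   `dur_post` ms, driven purely by the inter-population coupling.

Activities are reset at the start of every round: the round is defined by
its input-driven and autonomous phases, and carrying activity across rounds
would confound consecutive decisions (the plastic weights, not the
activities, are the agent's memory). After phase 2, each population
nominates its argmax (first index on exact ties). If the nominations agree
the common arm is chosen — exploitation; otherwise a uniformly random arm
is chosen — exploration (`select_option()`). Disagreement arises when the
weights are too weak for the V-side winner to pull its U counterpart above
the input-driven baseline, so uncertainty itself triggers exploration.

### Learning

After observing reward `R` on arm `k`, only that arm's weight moves
(`update_weights()`):

    W_k <- W_k + eta_k * (R * w_plus - W_k),   eta_k = clip(Phi_eta(W_k), 0, 1)

The learning rate is a function of the synapse's *own current weight*
(a synapse-type-specific rule), so the agent can learn fast on uncertain
(weak) synapses and consolidate strong ones. `Phi_eta` is clipped to
`[0, 1]` before use: larger rates overshoot the update target and would
break the invariant that weights stay in `[0, w_plus]` forever. With a
constant rate and i.i.d. Bernoulli(p) rewards the stationary mean weight is
`w_plus * p`, which the tests verify by Monte Carlo.

Weights persist across trial boundaries within an episode and are reset
only at episode start: adaptation to the changed distribution — not a
restart — is the behavior under study. For the same reason the baseline
algorithms also run continuously through distribution changes without
resetting their statistics.

### The genome

The 22 tunable scalars (`nsa_genome()`, canonical order in
`genome_to_vector()`): two time constants, the input amplitude, two phase
durations, the weight ceiling `w_plus` (6), gain/offset/threshold per
population response (6), and alpha/slope/offset/center/width per
Gaussian-sigmoid (10). Durations are constrained to `[400, 3000]` ms — a
plausible decision-time range — and rounded to integer multiples of `dt`.
The remaining boxes in `genome_bounds()` are generous brackets around the
useful shapes of each function (weights live in `[0, w_plus]`, so offsets
and centers range somewhat beyond that interval); they are choices of this
package, configurable, not sharp constraints.

## Evolutionary fitting

The agent is non-differentiable end to end (argmax selection, thresholds),
so the genome is fitted by a covariance-matrix-adaptation evolution
strategy (`cma_es()`, a standard (mu/mu_w, lambda) implementation with
rank-one and rank-mu updates and cumulative step-size adaptation,
implemented in this package and verified by a sphere-function self-test
over the 22-dimensional genome box). Box constraints are handled by
evaluating each candidate at its projection onto the box; the search
coordinates are box-scaled so a single step size fits parameters of very
different magnitudes.

Fitness (`nsa_fitness()`) is the grand mean per-round reward over a suite
of environments — by default the abrupt, gradual and oscillatory variants
(mab-p, mab-d, mab-sin), covering the three qualitatively different drift
regimes — across configurable arm counts and repetitions. Episode seeds are
derived from the configuration seed only and are therefore *shared across
individuals* (common random numbers): fitness differences between genomes
are then differences in policy, not in environment luck, and the fitness is
deterministic in the genome.

The shipped `default_genome()` was produced by this package's own short
two-stage search (populations of 10–12 for 14–16 generations on the
piecewise variant at small K, seeded from a hand-designed starting point)
and is a working stand-in: it exhibits the intended commit/abandon behavior
at moderate arm counts. Fitting at larger scale (populations of hundreds
over ~80 generations across the full suite) is supported by the same code
path via `evolve_genome()` or the `nsa evolve` CLI subcommand.

## Analytics

* `regret()` — mean per-round pseudo-regret of an episode log.
* `selection_entropy()` — Shannon entropy (nats) of the empirical
  distribution of chosen arms over a trailing window of 20 rounds,
  optionally smoothed with a 30-round moving average; 0 means confident
  exploitation, `log(K)` (or `log(window)` if smaller) means full
  exploration. The agent's signature on the piecewise variant is
  near-zero entropy while a distribution is stable, with transient peaks
  just after each redraw.
* `distribution_entropy()` — entropy of a reward profile. Arm
  probabilities are independent Bernoulli parameters and need not sum to
  1, so the vector is normalized before the entropy is taken; entropy is
  only defined for a distribution.
* `make_entropy_ladder()` — reward profiles of strictly increasing entropy
  at fixed mean probability, built by convex mixing between a one-dominant-
  arm profile and the homogeneous profile of equal mean. Fixing the mean
  isolates profile *shape* (how hard the best arm is to spot) from overall
  reward density.
* `compare_algorithms()` — Welch's independent two-sample t-test of every
  algorithm against a reference, Bonferroni-corrected, with `*`, `**`,
  `***` at adjusted p < 0.05, 0.01, 0.001 (conventional cutoffs).
  Zero-variance pairs are treated as exact ties (p = 1 when means
  coincide) rather than errors.

## The experiment runner

`run_experiment()` executes the benchmark protocol: per simulation index, a
fresh environment and one full episode per algorithm, then aggregation and
the comparison table. Seeds are derived from one master seed by a fixed
linear map modulo 2^31 - 1 (`derive_seed()`), giving collision-free,
reproducible streams per (algorithm, simulation). Within a simulation index
all algorithms face the *same* probability trajectory and the same reward
draws (one uniform variate per round, compared against the chosen arm's
probability) — paired environments reduce comparison variance without
biasing means. An `--unpaired` mode draws independent environments per
algorithm for a literal independent reading of the protocol. Re-running any
configuration is bit-identical; that contract is tested.

## What the generator does and does not emulate

The environments are synthetic by design — the benchmark *is* simulation.
They capture abrupt, gradual, oscillatory and mixed drift of independent
Bernoulli arms at controlled speeds. They do not model reward correlations
between arms, state-dependent or adversarial drift, continuous-valued
rewards, or observation noise in the agent's dynamics (the network is
deliberately noise-free; its only stochasticity is the
disagreement-triggered uniform choice and the Bernoulli rewards). Passing
tests therefore certify the algorithms and protocol on these drift classes,
not performance on any particular real foraging or recommendation dataset.

## Numerical choices and degenerate cases

* `dt = 1` ms everywhere; durations rounded to whole steps.
* Ties in every argmax (both populations, all baselines) resolve to the
  first index, uniformly across agents.
* The epsilon-greedy rate uses the arm-count rule
  `0.4 * log2(0.6 K)` clipped into `[0, 1]`; the raw formula exceeds 1
  from K = 6, and its empirically fitted per-K values are not public, so
  quantitative expectations for this baseline are weaker than for the
  others and it is excluded from the quantitative acceptance checks.
* A fresh network is fully symmetric, so its first choices fall on arm 1
  until the first rewarded pull breaks the tie; an arm with exactly zero
  probability can in principle pin a fresh agent (no reward, no weight
  change). Under the clipped-normal generator this occurs with probability
  below 1% per trial and is visible as a heavy-regret tail, not a crash.
* Non-finite activities abort integration with an error; all-zero reward
  profiles are rejected by `distribution_entropy()`.

## Problem sizes in the shipped tests

The test suite runs the full 2-trials x 2000-rounds x 64-simulations
protocol for the Thompson sampling and UCB1 checks at K up to 1000, the
neural agent at K = 10 over 24 simulations, and scaled-down configurations
(tens of rounds, a few arms, populations of 4–16) for the unit and property
tests — sizes chosen to exercise every code path at interactive runtimes.
The evolution self-test optimizes a known quadratic over the genome box
instead of the expensive behavioral fitness.

## Known limitations

* The default genome is tuned at small K on the piecewise variant; it is
  not the publication-scale optimum, and the agent's quantitative cells at
  large K are not claimed by this package's tests.
* First-index tie-breaking gives arm 1 a structural role in fresh networks
  (see above).
* The drifting variant's `tau_p`, `delta` and the sinusoid parameter
  ranges are package defaults, exposed on the CLI, not canonical
  constants.
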