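---
title: "Multi-timescale reinforcement learning for perceptual decisions: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-timescale reinforcement learning for perceptual decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(mtagent)
```

This vignette is the package's account of its science: the task and agent
it simulates, the assumptions behind each component, the parameters that
matter and why their defaults are what they are, and the numerical and
design choices a maintainer should know about.

## The task

A two-alternative forced choice on the sign of the mean of a noisy scalar
signal, abstracting a random-dots motion discrimination. Every
`dt` = 10 ms the stimulus emits s(t) ~ N(μ, σ²/dt). The division by `dt`
is the white-noise convention: `sigma` = 0.18 carries units s^−1/2, so the
statistical information per unit time — and hence the accuracy of any
observer — is invariant to the choice of time step. One consequence used
throughout as a reference: an ideal observer forced to answer at time t
from the sign of the summed signal is correct with probability
1/2 + arctan(σ_μ√t/σ)/π, ≈ 0.850 at t = 2 s under the defaults
(`fixed_t_accuracy()`; the package verifies this against a Monte-Carlo
sign-of-sum simulation rather than trusting the algebra).

μ is redrawn each episode from N(0, σ_μ²) with σ_μ = 0.25, so the agent
faces a broad, unsignalled range of difficulties. Stimulus difficulty maps
to random-dots coherence (percent) via |μ| = 0.216·c/√(100 − c)
(`coherence_to_mu()`): a stimulus model in which a fraction c of dots
moves coherently (contributing mean) and 1 − c at random (contributing
variance) forces the μ/σ ∝ c/√(100 − c) form, and this form also makes the
drift-diffusion CV law below come out as ((100 − c)/c²)^{1/4}. Under it a
50% coherence corresponds to ≈ 6.1 σ_μ — far in the tail of the training
distribution, which is exactly why behaviour at high coherence probes
generalisation.

Rewards are sparse and terminal: 1 for the correct side within
`t_max` = 2 s, 0 otherwise (including timeouts). Throughout the package,
*accuracy* means the fraction of correct **choices** — timeouts are not
choices and are tracked separately as the late-response fraction (for the
trained agent that fraction is a few percent, so the distinction moves
accuracy by under a point; the reward rate, which does charge timeouts, is
also recorded in the training trace).

## The agent

Ten leaky integrators of the signal and ten of a constant input (the
clock), time constants log-spaced on [0.1, 10] s, updated with the exact
zero-order-hold map x ← x e^{−dt/τ} + (1 − e^{−dt/τ}) u. The exact map,
rather than forward Euler, keeps the clock trajectory equal to
1 − e^{−t/τ} to machine precision — a property the tests assert at 1e−12
and which Euler would miss by ~0.5% at dt/τ = 0.1. Each integrator is
observed through fresh i.i.d. Gaussian read-out noise (σ_I = 0.02) per
step, per timescale, per bank. The noise is *non-accumulating*: it models
fluctuation of the instantaneous rate conveying the integrator's value,
not a perturbation of the integration itself (both readings are plausible
biologically; the non-accumulating one is also what makes the α_I noise
rescaling of the single-integrator comparison coherent). Actor and critic
share one noisy read-out per step.

The actor computes six sums — per action a ∈ {left, wait, right}, a
signal part Σ^s_a and a clock part Σ^c_a (the latter carrying the bias
b_a) — and draws an action from softmax(Σ_left, Σ_wait, Σ_right). The
'wait' row reads |x^s_τ|: evidence magnitude, not direction, should defer
a decision. The parameterisation is redundant under a common bias shift
(softmax invariance); no canonicalisation is enforced.

All analyses run on the decision variables ΔΣ_right = Σ_right − Σ_wait =
ΔΣ^s − ΔΣ^c, with ΔΣ^c = Σ^c_wait − Σ^c_right carrying time-only
information. ΔΣ^c uses the 'right' clock sums; the 'left' variant is
numerically near-identical (the task is symmetric) and is available as a
diagnostic (`action_sums(..., dsc_left = TRUE)`).

## Learning

A standard online actor-critic: the critic V(t) is linear in |x^s_τ| and
x^c_τ (the absolute value respects the left/right symmetry of expected
reward — the paper-level description says only "linear summation", and the
symmetric reading is the one under which a signal and its mirror have equal
value), TD errors δ = r + γV' − V drive both critic and actor through
eligibility traces e ← γλe + ∇, parameters += lr·δ·e, applied within the
episode. Gradients are the exact softmax score function, verified against
central finite differences in the tests.

Hyperparameters are design decisions of this package (no authoritative
values were available) and sit in `training_config()`:

* `gamma = 1` — episodic, terminal-only reward; discounting would add an
  artificial urgency the task already supplies via T_max.
* `lr_actor = 1.2e-2`, `lr_critic = 7e-2`, `lambda_actor = 0.8`,
  `lambda_critic = 0` — chosen for fast, stable learning: the one-step
  critic tolerates a large critic rate, which in turn stabilises a fast
  actor. Configurations with slower rates learn the same policies but take
  several-fold more episodes; per-episode batched updates and per-timescale
  diagonal preconditioning were both tried and rejected (the slow-τ
  read-outs are nearly collinear ramps, so equalising their step sizes
  destabilises the updates rather than accelerating them).
* `delta_clip = 1` — rewards lie in [0, 1], so a well-behaved TD error
  never exceeds 1 plus the value error; clipping bounds the gain of the
  value→update→value loop, which can otherwise run away during the long,
  high-variance episodes early in training. Clipping does not move the
  fixed points of the update.
* `b_wait_init = 4` — the untrained agent then waits with probability
  ≈ 0.98 per step, i.e. makes a random choice after a random ~0.5 s.
  Without this head start the agent cannot experience rewards and learning
  does not lift off.
* The comparison models are trained with the same procedure but their own
  scales: the single-timescale agent at τ = 2 s sees features an order of
  magnitude smaller than the fastest multi-τ features and trains at
  correspondingly larger rates (0.03/0.15 in the test suite).

**Halting.** Training evaluates frozen held-out batches every
`checkpoint_every = 2000` episodes: one random-μ batch for accuracy and
one batch per coherence in {0, 3.2, 6.4, 12.8, 25.6, 51.2}% for the
decision-aligned curves and response-time CVs (2000 episodes each; the
same seed sequence at every checkpoint so curves are comparable). The
returned agent is the snapshot at the running maximum of signal
neutrality over checkpoints whose accuracy is ≥ `accuracy_floor = 0.81`;
training stops when that maximum has not improved for
`peak_detection_window = 10` checkpoints, or at
`n_episodes_max = 150000`. The global peak is not knowable online, so the
patience window stands in for it; the recorded `halting_episode` is the
episode index of the returned peak snapshot, which across seeds falls at
roughly 40–100 thousand episodes.

## The operational measures

*Signal neutrality* (`signal_neutrality()`): average ΔΣ_right aligned to
the decision over the 600 ms before it, per coherence, over correct
'right' episodes (at 0% coherence, where no side is correct, episodes
whose *choice* was 'right' — the convention that mirrors conditioning on
choice in experiments); shrink each curve's support where fewer than 100
episodes contribute; jointly min-max rescale all curves to [0, 1]; at
each lag take the maximum pairwise distance among curves defined there
(lags with fewer than two curves are skipped); average and invert.
Degenerate perfect collapse returns a configurable cap (1e6) rather than
infinity so training traces stay plottable. The joint rescaling makes the
measure invariant under common affine transforms of all curves.

*Scalar property* (`scalar_property()`): 1/(max CV − min CV) across the
six coherence batches, CV computed with the n−1 standard deviation; same
cap. Invariant under common rescaling of all response times.

*Collapsing boundary* (`boundary_strip()`): ΔΣ^c(t) computed on the
noise-free clock trajectories, paired with the central-80% band
(10th–90th percentile) of ΔΣ^s at decision time, binned per step; bins
with fewer than 20 decisions are flagged NA rather than interpolated. For
the trained agent ΔΣ^c rises to an interior peak near 0.2 s and then
collapses; a single-timescale clock can only produce a monotone curve,
and a clock-less agent a constant b_wait − b_right.

## Comparison models and references

The OU threshold model integrates the signal at one τ and answers at the
first |noisy x| ≥ Θ. Θ is optimised by grid search (60 candidates on
[0, 3σ_μ], common random numbers across candidates, ties to the smaller
Θ, the full accuracy-vs-Θ curve returned as an attribute). Its read-out
noise is rescaled by α_I = max_τ|θ*|/√(Σ_τ θ*²) computed from the trained
agent's 'right' signal weights — 1 for a single non-zero weight,
1/√n_τ for equal weights — so that the single integrator is not charged
for noise the multi-τ agent averages away. Under the default task this
baseline is strong: its best-τ reward rate sits within about a point of
the trained agent's, rather than clearly below it, and its optimal
thresholds are small enough that its decision variable also collapses
when aligned at decision — a caveat worth keeping in mind when comparing
against it (the single-timescale *agent* separates much more cleanly on
both accuracy and signal neutrality).

The pure drift-diffusion CV law ((100 − c)/c²)^{1/4} is cross-checked by
first-passage simulation (`simulate_ddm_fpt()`) at boundary
Θ = σ²/0.216, where the analytic inverse-Gaussian CV coincides with the
law; the simulation uses dt = 0.5 ms to keep discretisation bias well
below the Monte-Carlo error at n = 10⁴.

## What the synthetic task does and does not emulate

The generator reproduces the statistical structure of a random-dots
session — per-step Gaussian evidence, per-episode difficulty drawn from a
continuous distribution, a response deadline, terminal reward — and the
default constants are the study conditions stated above. It does not
render dot kinematograms, model non-decision (motor) time, sequential
dependencies between trials, lapses, or reward schedules other than
0/1-correct. Passing tests therefore support claims about the model class
under these statistics, not about fits to any particular animal's data.

## Problem sizes and determinism

The test suite trains five full agents (default configuration), five
single-timescale agents (120k episodes) and five clock-less agents (48k),
evaluates model comparisons on 2000-episode batteries per coherence, runs
the Monte-Carlo oracles at n = 10⁵ (fixed-t observer) and n = 10⁴
(first passages), and continues one run to 10⁶ episodes for the long-run
refinement check. Every stochastic step is seeded; a run is a pure
function of (configuration, seed, code version), and `run_experiment()`
writes a manifest (seed, configuration, hash) alongside its outputs so
reruns are bit-identical.

## Known limitations

* The actor-critic reaches held-out accuracy ≈ 0.81 at its halting point
  and does not improve much beyond it under the default rates (the
  long-run refinement from 10⁵ to 10⁶ episodes adds roughly a point or
  less); slower rates can reach ≈ 0.835 but take several hundred thousand
  episodes, incompatible with halting in the tens of thousands.
* The noise-matched OU baseline ties the agent on reward rate under these
  conditions instead of trailing it; the package reports the comparison
  honestly rather than weakening the baseline.
* Measures are estimated from finite checkpoint batches; signal
  neutrality in particular is noisy at 2000 episodes per coherence, which
  is why halting uses a patience window rather than a point estimate of
  the peak.
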