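---
title: "Reward-modulated attractor dynamics: model, assumptions, and numerical choices"
author: "rewardnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reward-modulated attractor dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(fig.width = 6, fig.height = 4)
library(rewardnet)
```

## The model

`rewardnet` simulates a population of `N` rate units `v` coupled through a
recurrent matrix `M` and driven by a one-dimensional stimulus `u(t)` through
feedforward weights `W`:

$$\tau_v \dot v = -v + M\,\tanh(v) + W u$$

Three plasticity processes act on the weights:

* **Memory embedding.** A finite set of binary patterns $\{a^\Omega\}$ with
  sparseness $\alpha$ is embedded once, before the run, by the sparse
  covariance rule
  $$M_{ij} = \frac{1}{(1-\alpha)\,\alpha\,P} \sum_\Omega
  (a_i^\Omega - \alpha)(a_j^\Omega - \alpha) \;-\; \frac{1}{\alpha P},$$
  with $P$ the number of patterns.  Embedded patterns become attractors of
  the rate dynamics and local minima of the energy below.
* **Reward-modulated feedforward plasticity** (Rescorla–Wagner rule): with
  a scalar reward $r(t)$ and the gating matrix $K = I - M$,
  $$\tau_W \dot W = \varepsilon\, (K W u) \odot (r\mathbf{1} - v).$$
  The update is proportional to the reward-prediction error $r - v$ and
  stops when the network predicts the reward ($v = r\mathbf{1}$) or becomes
  autonomous ($M = I$, so $K = 0$).
* **Anti-Hebbian recurrent plasticity** (Goodall rule):
  $$\tau_M \dot M = (I - M) - (W u)\,v^\top,$$
  which relaxes `M` toward the identity while removing input-driven
  pairwise correlations.  This is the route by which sustained stimulation
  erodes the embedded attractor.

Binary spikes are read out from the rates by the logistic
$P[\text{spike}_i] = 1/(1+e^{-v_i})$; sampling does not feed back into the
rate dynamics (spikes are an observation model; letting them feed back
would turn the dynamics into a binary Markov chain, a variant this package
deliberately does not implement).

Every binary state has a Boltzmann energy.  Two sign conventions are
implemented behind `sign_convention`:

* `hopfield` (default): $E(v,u) = -u\,W^\top v - \tfrac12 v^\top M v$.
  High-overlap states have *low* energy, which matches the stability
  narrative (embedded memories sit in energy wells) and is the convention
  under which asynchronous Glauber updates have $e^{-E}/Z$ as their
  stationary law.
* `as_printed`: $E(v,u) = -u\,W^\top v + \tfrac12 v^\top M v$, the same
  energy with the sign of the quadratic term flipped, kept for completeness
  and comparison.  Under it, high-overlap states are energy *maxima*; it is
  not used by the stability analyses.

## The stimulus–reward world

Drug usage is modelled by three binary templates over `T = 200` steps —
`exposure` (one pulse, onset 10, width 10), `chronic` (ON from step 10
onward) and `cessation` (ON for steps 10–119, then OFF) — and individual
susceptibility by the shape of a peak-normalized reward-salience kernel:

* **susceptible**: log-Gaussian (`mu_log = log 10`, `sigma_log = 0.6`) —
  fast rise, heavy tail, integrated salience ≈ 12.6;
* **resilient**: Gaussian (`mu = 20`, `sigma = 4`) — slower and softer,
  integrated salience ≈ 10.

The reward trace of each condition is the causal convolution of template
and kernel, truncated to `T` samples, with no further normalization:
amplitude differences between conditions are part of the model.

```{r grid, fig.height = 3}
grid <- make_condition_grid()
plot(grid$cessation_susceptible)
```

The templates' timings and the kernel shapes are free parameters of the
model; the values above are this package's frozen defaults.  The Gaussian
width was set so the resilient kernel carries roughly 25% less
integrated salience than the susceptible one — with a much wider Gaussian
the "resilient" kernel would paradoxically deliver *more* total reward than
the susceptible one, inverting the axis the two kernels are meant to encode.

## Default dynamical parameters and why

| parameter | default | rationale |
|---|---|---|
| `N` | 64 | population size; large enough for 10 sparse memories |
| `n_patterns` | 10 | sets the attractor field scale $\sim N(1-\alpha)/P \approx 5$, so the logistic spike read-out produces graded firing rather than saturated 0/1 rows |
| `alpha` | 0.25 | sparseness of the memories; also centres the covariance rule |
| `tau_v` | 1 | unit of time |
| `tau_W` | 20 | reward learning integrates over tens of steps |
| `tau_M` | 200 | structural memory persists for the protocol length; a much smaller value dissolves the embedded memory autonomously before cessation begins, so no post-cessation contrast could exist |
| `epsilon` | 0.02 | associability; keeps the total feedforward change over 200 steps order one relative to `w0` (the update is stiff — its linear growth rate is $\varepsilon\|K\|\,|r-v|/\tau_W$, and at $\varepsilon \approx 1$ the coupled system diverges within two steps of stimulus onset) |
| `w0` | 0.01 | initial uniform feedforward weight; must be nonzero ($\dot W$ is linear in $W$) but small enough that unlearned drive is negligible |
| `dt` | 0.1 | forward Euler, $dt \le \min(\tau)/10$; first-order convergence is property-tested |
| `flip_fraction` | 0.05 | "within the basin": the initial state is embedded pattern 1 with 5% of entries flipped |
| `v_max` | $10^3$ | divergence guard; exceeded rates abort with the offending time step |

With these values the six-condition experiment reproduces, as orderings
(never as exact values), the headline phenomenology: the chronic stimulus
destabilizes the preset pattern most; after cessation the resilient network
returns closer to the preset pattern than the susceptible one.  This holds
across the seeds we checked and is asserted by the test suite for the
default seed.

## Similarity analysis

Two rasters are compared by the mean row-wise cosine
$q_{ab} = \frac1N \sum_n \cos\theta(v_{n,a}, v_{n,b})$, each neuron
contributing the cosine between its two spike time-series.  Conventions:

* the denominator uses both rows' norms — the only normalization under
  which $q(a,a) = 1$;
* two silent rows have cosine 1 (identical silence), a one-sided silent row
  contributes 0 — so $q(a,a) = 1$ holds exactly for any raster;
* the mean is the plain arithmetic mean of cosines, not a circular mean:
  cosines are lengths, not angles, and only the arithmetic reading keeps
  $q(a,a) = 1$.

Significance is judged against a row-shuffle null: neuron rows are pooled
across all rasters, the assignment of rows to (raster, neuron) slots is
permuted, and the change in `q` against the reference recorded.  The
threshold is the 85th percentile of the magnitude of those changes.  Any
particular numeric value of that threshold depends on the simulation
parameters and is not a reproducible constant; the machinery itself is
validated exactly against exhaustive permutation enumeration on small
rasters.

## What the generator does and does not emulate

The synthetic world covers: binary stimulus protocols, smooth reward
kernels, their convolution, sparse random well-separated binary memories,
and seeded spike sampling.  It does not model pharmacokinetics, negative
reinforcement or withdrawal, neuromodulator nonlinearity,
multi-dimensional stimuli, or acquisition of new memories during a run —
all explicitly out of scope.  A green experiment therefore establishes that
the *mechanism* (reward-gated feedforward learning plus anti-Hebbian
erosion of an embedded attractor) yields the claimed ordering in this
stated world, not that real populations behave this way.

## Numerical notes and edge cases

* **Integration**: explicit forward Euler with zero-order hold of `u`, `r`
  within each stimulus step; all three derivatives are evaluated at the
  current state and applied simultaneously; `K` is recomputed after the
  `M` update.
* **Embedding offset**: the trailing $-1/(\alpha P)$ is applied to the diagonal
  only by default (`uniform_offset = FALSE`).  Subtracting it uniformly
  makes every within-pattern coupling $-1/P$ at any $\alpha$, so embedded
  patterns are never local energy minima, contradicting the stability
  account; the uniform reading remains available as a flag.
* **Glauber sampling** applies the logistic to the *local field*
  $(Mv + Wu)_i$ (with the half self-coupling correction), the only choice
  with the Boltzmann law as stationary distribution; the rate read-out in
  simulations applies the logistic to $v_i$ itself.  Detailed balance is
  tested as an identity over all one-bit state pairs.
* **Exact enumeration** is bounded at $N \le 20$ ($\sim 10^6$ states) and
  uses a max-shifted softmax for the probabilities.
* **Ties**: a state whose single-flip neighbours all have equal energy
  counts as stable; threshold updates keep the current value on a zero
  field.
* **Degenerate inputs**: empty memory sets, non-binary patterns,
  $\alpha \notin (0,1)$, shape mismatches and out-of-range onsets/offsets
  raise typed errors; `validate_config()` reports all findings without
  running anything.
* **Reproducibility**: one top-level seed derives all stage seeds; the run
  manifest records the resolved configuration, seeds and MD5 checksums of
  every output file.

## Known limitations

The rasters' late-time texture depends on the spike read-out's fixed unit
gain; there is no temperature parameter.  The headline orderings are
properties of the frozen default world — they are not calibrated to any
empirical effect size, and single-seed runs at other configurations can
order differently.  Energies recorded along plastic trajectories use the
instantaneous weights, so they are descriptive (a Lyapunov property holds
only for frozen symmetric `M`).

## A minimal session

```{r session, eval = FALSE}
res <- run_experiment(seed = 1)
print(res)                      # similarity of each condition to baseline
plot(res$traces$chronic_susceptible)
plot(res$similarity)
```
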