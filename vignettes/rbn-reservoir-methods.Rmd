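---
title: "Random Boolean network reservoirs: model, measures, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Random Boolean network reservoirs: model, measures, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rbnreservoir)
library(dplyr)
```

## The model

A random Boolean network (RBN) reservoir is a directed random graph of `n`
binary threshold neurons. Each neuron `i` receives exactly `k` recurrent
synapses from distinct other neurons (no self-loops, no multi-edges), with
weights drawn once from a normal law and then frozen. The state update is
synchronous and memoryless:

$$x_i(t) = \theta\Big(u_i(t) + \sum_j w_{ij}\, x_j(t-1)\Big),$$

with $\theta$ the Heaviside step. Half of the neurons receive the scalar
input stream ($u_i(t) = w^{in} u(t)$); the disjoint other half is exposed to
a single trained sigmoid readout $y(t) = f(W^{out} \vec{x} + c)$, so input
information must propagate through the recurrent graph before the readout can
use it. Only $W^{out}$ and $c$ are trained.

### Control parameters

Three parameters control the ensemble:

* **`n`** — neuron count (full-scale studies use 100, 1,000 and 10,000);
* **`k`** — homogeneous in-degree, between 1 and 16;
* **`sigma_star`** ($\sigma^\star$) — the signed coefficient of variation
  $\sigma/\mu$ of the weight law. We fix $|\mu| = 1$ and set
  $\sigma = |\sigma^\star|$, with the sign of $\sigma^\star$ carried by the
  mean. Free-running trajectories are invariant under positive rescaling of
  all weights (the threshold is zero), so only the ratio matters.

The excitatory-inhibitory balance $b = (S_+ - S_-)/S$ — the normalized
difference between positive and negative synapse counts — follows from
$\sigma^\star$ as the expected sign imbalance of a normal draw:

$$b = \operatorname{sign}(\sigma^\star)\,\big(2\Phi(1/|\sigma^\star|) - 1\big).$$

`balance_from_sigma_star()` implements this sampling-consistent form. An
alternative closed form $b = \mathrm{erf}[1/(2\sigma^\star)]$ circulates in
the literature; it is inconsistent with the sampling process above (whose
error-function form is $\mathrm{erf}[1/(\sqrt{2}\sigma^\star)]$) and with the
anchor pairing $\sigma^\star = -10 \leftrightarrow b \approx -0.08$ that the
sampling form reproduces exactly. The printed form is kept available as
`form = "erf-printed"` for comparison but is never used in analyses.

```{r balance}
balance_from_sigma_star(c(-10, -2, 25, 1000))
```

## Free-running dynamics and the order-disorder axis

The characterization protocol runs each reservoir freely (no input) for
`D = 2000` steps from a random state with 20% of neurons active, recording the
mean activity $A(t) = \frac1n \sum_i x_i(t)$. The second half of the trace
($t > 1000$) is treated as steady.

**BiEntropy.** The steady activity is binarized about its mean (strictly
above the mean maps to 1, everything else to 0) and scored with Croll's
BiEntropy: the weighted mean of the Shannon entropies of the string's
successive binary derivatives. Perfectly periodic strings score 0; irregular
ones approach 1. Two weightings exist: `power` ($w_k = 2^k$), the classical
form for short strings, and `logarithmic` ($w_k = \log_2(k+2)$), appropriate
for long strings. For the 1000-bit steady windows the package defaults to the
logarithmic weighting: the power weights put half of the total weight on the
2-bit deepest derivative, whose entropy on a random string is 0 or 1 with
equal probability, so the power score of a long random string hovers near
0.55 instead of approaching 1 — it cannot resolve the disorder axis at this
length. Both variants are available in `bientropy()` and the sweep
configuration.

**Ensembles.** For each grid point, `R` reservoirs (100 at full scale) are
generated and the per-reservoir scores aggregated as the mean and the
*population* variance (the `1/R` form, deliberately not `1/(R-1)`). Regions
of the balance axis where the ensemble variance exceeds `0.0001` mark the
critical (order-disorder) transition; a second, disjoint above-threshold run
closer to `b = 0` is labeled re-entrant (`find_variance_regions()`).

**Attractor taxonomy.** Each steady trace is classified, in order, as
*extinguished* (identically zero), *fixed* (constant nonzero), *cyclic*
(minimal period `p` between 2 and half the window), or *irregular* (no
period detectable). Because $A(t)$ is an integer multiple of $1/n$ by
construction, equality is tested exactly on the integer counts
`round(A * n)` — never with a floating-point tolerance. The period cap of
half the window means a candidate period must be observed at least twice;
the system is deterministic and finite, so every trajectory is eventually
cyclic, but with state-cycle lengths up to $2^n$ the window can only resolve
short cycles, and "irregular" operationally means "no cycle within reach of
the window". `exact_cycle_oracle()` provides the brute-force ground truth
(first state recurrence) for networks small enough to enumerate, and the test
suite checks the classifier against it across hundreds of small reservoirs.

Two conventions the protocol leaves open are fixed here and flagged as
conventions: $\theta(0) = 0$, which makes the all-zero state absorbing and
gives the *extinguished* class its meaning (ties have probability zero under
continuous weights); and the initial 20% activation is an exact count,
`round(0.2 n)`, rather than independent Bernoulli draws, for reproducibility
at small `n`.

### A note on `k = 1`

At `k = 1` and `b` near +1 every neuron copies one other neuron, so the
network is a functional graph and the activity is exactly periodic with
period equal to the lcm of its cycle lengths. That lcm frequently exceeds
any practical detection window (values in the tens of thousands arise at
`n = 1000`), so a substantial share of these runs is operationally labeled
irregular even though the dynamics is ordered in the damage-spreading sense
in which `k = 1` networks are classically called ordered. The attractor
census at `k = 1` therefore shows irregular labels concentrated at `b`
near +1; they are an artifact of finite-window period detection, not of
chaotic dynamics.

## Tasks and the readout

Two task families probe computation:

* **Delayed memory**: the input is i.i.d. white noise and the target is the
  input $|\delta|$ steps in the past, $\delta \in \{-2, -6, -10, -14, -18\}$;
  larger delays are harder because the memoryless neurons must reverberate
  the information. The noise is uniform on $[0,1]$ (configurable to
  Gaussian): the readout is a sigmoid, so a uniform target is representable.
* **Prediction**: the input is the discrete Mackey-Glass map
  $x_{t+1} = a x_t + b x_{t-\tau}/(c + x_{t-\tau}^d)$ with
  $a=0.9,\ b=0.2,\ c=0.9,\ d=10,\ x_0=0.1$ and constant pre-history; the
  target is the orbit 10 steps ahead. $\tau = 5$ yields a (quasi-)periodic
  orbit, $\tau = 28$ a chaotic one. The orbit is min-max normalized to
  $[0,1]$; the normalization is affine, so the Pearson score is unaffected.
  The $\tau = 5$ orbit converges to an invariant circle rather than an exact
  cycle (best recurrence error about $10^{-3}$), which is why the test suite
  contrasts the regimes with a recurrence-error statistic rather than exact
  period detection.

Series geometry defaults to 2600 generated steps — a 100-step washout, with
the remaining usable indices split 80/20 into train and test — and is fully
configurable; the protocol source does not print its lengths. The
scaled-down presets shorten this to 900 steps.

The readout is a single sigmoid unit trained by full-batch ADAM on the MSE,
with the standard settings $\alpha = 0.001$ and 4000 epochs, weights
initialized from a small centered normal scaled by $1/\sqrt{p}$, seeded.
Performance is the Pearson correlation $\mathrm{Corr}(y, T)$ on the held-out
test range. A reservoir whose readout states are constant on the test range
(a dead reservoir) has an undefined correlation; sweeps record it as 0 with a
`degenerate` flag, which is the score such a reservoir deserves.

## Sweeps, seeds, and scaled-down presets

`run_dynamics_sweep()` and `run_task_sweep()` iterate the protocol over a
(n, k, sigma*) grid, returning raw per-run tibbles that `summarize_dynamics()`
and `summarize_performance()` aggregate (aggregates are recomputable from the
raw rows exactly). Every reservoir, initial state, noise realization and
weight initialization draws its seed from `derive_seed(base_seed, ...)`, a
documented integer hash, so sweeps are bit-reproducible end to end and
resumable from per-grid-point checkpoints.

`select_b_opt()` picks, per (n, k, sign, task), the balance maximizing mean
performance at the hardest setting ($\delta = -18$ or $\tau = 28$), with ties
broken toward smaller $|b|$; `summarize_best_k()` reports every difficulty at
that balance.

Full-scale grids (up to `n = 10000`, 100-reservoir ensembles, dense sigma*
grids, all tasks) are hours of compute; the package ships scaled-down presets
chosen once as realistic desk-scale study conditions:

* `entropy-transition-mini` — `n = 1000`, `k = 16`, 16 negative-sign
  magnitudes, `R = 30`: the ordered phase (BiEntropy near 0 at
  $\sigma^\star = -0.01$), the disordered phase (near 1 at $-1000$), and an
  above-threshold variance region between them.
* `k1-order-mini` — `n = 1000`, `k = 1`, both signs, `R = 30`: the `k = 1`
  attractor census (see the caveat above).
* `memory-mini` — `n = 1000`, `k = 4`, $\sigma^\star = 25$ (b ≈ 0.03, the
  near-balanced optimum for moderate in-degree), 10 reservoirs per setting,
  900-step series: the difficulty ladder and the symmetry dip.
* `best-k-mini` — material for per-k summaries at the hardest memory setting.

The exact-balance dip is probed with a construction rather than sampling:
signs are assigned to the drawn weight magnitudes in exactly equal counts
(`exact_zero_balance = TRUE`), because sampled weights cannot reach
$b = 0$ at any finite $\sigma^\star$. The probe uses magnitude
$|\sigma^\star| = 1000$: the vanishing-balance regime *is* the
large-$\sigma$ regime, where recurrent magnitudes dwarf the unit-scale input
and the network's activity decouples from the signal. At moderate magnitudes
an exactly balanced network still transmits its input and shows no dip.

## What the scaled-down conditions do and do not show

The presets reproduce the qualitative structure — phase transition location
on the grid, attractor taxonomy shifts, difficulty ordering, the symmetry
dip, dead-reservoir nulls — with `n = 1000` and reduced ensembles, chosen to
keep a full verification run in minutes on one CPU. They do not reproduce
figure-level quantities that depend on `n = 10000` and dense grids: the
re-entrant critical region at `k = 4`, `b < 0` (a large-`n` phenomenon), the
precise $b_{opt}$ values (e.g. ~0.2 for `k = 16`, `b > 0`), or the full
best-k curves; those require the full-scale configuration
(`sweep_config()` defaults) and hours of compute. Synthetic inputs emulate
the stated generators exactly; nothing here models real measured signals.

## Numerical choices

* Heaviside ties: $\theta(0) = 0$; probability-zero events under continuous
  weights, decisive only in hand-built toys.
* Binarization ties: values exactly at the window mean map to 0, so constant
  windows give the all-zero string and score 0.
* Attractor equality: exact integer-count comparison; minimal period
  reported; period search capped at half the window.
* Exactly-zero weights (possible only in contrived edge tables) count in `S`
  but in neither `S_+` nor `S_-`.
* Serialization: weights are written with 17 significant digits and parsed
  with `strtod`, so reservoirs round-trip bit-exactly through text.
* ADAM is full-batch (the protocol specifies epochs, not batches); the loss
  trace is recorded per epoch and its 100-epoch moving average is
  non-increasing on the test fixtures.

## Worked example

```{r example, fig.width = 6, fig.height = 3}
res <- build_reservoir(reservoir_spec(n = 1000, k = 4, sigma_star = 25, seed = 1))
glance(res)

run <- free_run(res, steps = 2000, seed = 2)
classify_attractor(run, t0 = 1000)
bientropy(binarize_steady(run$trace))

task <- make_memory_task(-6, length = 900, washout = 50, seed = 3)
run_task_on_reservoir(res, task, train_config(seed = 4)) |>
  select(n, k, b, difficulty, correlation)
```

## Limitations

* Synchronous deterministic updates only; no asynchronous or stochastic
  schedules, no continuous-state (echo-state) units.
* Homogeneous in-degree only; no scale-free or small-world topologies, no
  plastic recurrent weights.
* Period detection is window-limited (see the `k = 1` note); full attractor
  enumeration and basin analysis are out of scope.
* The sigmoid/ADAM readout is the only trainer; ridge or pseudo-inverse
  readouts are deliberately not provided.
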