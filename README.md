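# rbnreservoir

Simulation and analysis toolkit for **reservoir computing with random Boolean
networks (RBNs)** — for researchers studying how a reservoir's topology and
synaptic statistics shape its dynamics and its usefulness for temporal
computation.

An RBN reservoir is a directed random graph of `N` binary threshold neurons,
each receiving exactly `K` recurrent synapses with frozen normal weights:

    x_i(t) = θ( u_i(t) + Σ_j w_ij x_j(t−1) ),   θ(z) = 1 iff z > 0

Half of the neurons receive the scalar input stream; the other half feeds a
single trained sigmoid readout, so information must propagate through the
recurrent graph. The signed coefficient of variation σ\* = σ/μ of the weight
law controls the **excitatory–inhibitory balance**

    b = (S₊ − S₋)/S = sign(σ*) · (2Φ(1/|σ*|) − 1),

the normalized difference between positive and negative synapse counts. The
package provides, as tidy pipe-friendly functions:

* **Reservoir construction** — fixed in-degree graphs parameterized by
  (N, K, σ\*), the σ\* ↔ b conversion, synapse-sign censuses, bit-exact
  text serialization (`build_reservoir()`, `balance_from_sigma_star()`,
  `summarize_balance()`).
* **Dynamics** — synchronous Heaviside evolution (compiled core), free and
  input-driven runs, mean-activity traces (`free_run()`, `driven_run()`).
* **Order/disorder measures** — BiEntropy of the binarized steady activity
  (power and logarithmic weightings), ensemble mean/variance, critical and
  re-entrant variance regions at the 0.0001 threshold (`bientropy()`,
  `ensemble_entropy()`, `find_variance_regions()`).
* **Attractor taxonomy** — extinguished / fixed / cyclic / irregular with
  exact integer-count arithmetic, plus a brute-force cycle oracle for small
  networks (`classify_attractor()`, `exact_cycle_oracle()`).
* **Tasks** — delayed memory of white noise (δ ∈ {−2…−18}) and prediction of
  the discrete Mackey-Glass map (a = 0.9, b = 0.2, c = 0.9, d = 10, τ ∈
  {5, 15, 28}) with washout and train/test splits (`make_memory_task()`,
  `make_prediction_task()`).
* **Readout training** — full-batch ADAM (α = 0.001, 4000 epochs) on a
  sigmoid unit with MSE loss, scored as Pearson Corr(y, T)
  (`train_readout()`, `run_task_on_reservoir()`).
* **Sweep orchestration** — seeded, checkpointed, resumable grids over
  (N, K, σ\*) with raw-record tibbles, aggregation, optimal-balance and
  best-K summaries, and `autoplot()` methods (`run_dynamics_sweep()`,
  `run_task_sweep()`, `select_b_opt()`, `summarize_best_k()`,
  `sweep_preset()`).

## Worked example

```r
library(rbnreservoir)

# a near-balanced reservoir: N = 1000, K = 4, sigma* = 25 (b ≈ 0.032)
res <- build_reservoir(reservoir_spec(n = 1000, k = 4, sigma_star = 25, seed = 1))
glance(res)
#> # A tibble: 1 × 8
#>       n     k sigma_star density     s b_empirical b_analytic  seed
#>   <int> <int>      <dbl>   <dbl> <int>       <dbl>      <dbl> <int>
#> 1  1000     4         25   0.004  4000      0.0255     0.0319     1

# free-running dynamics: classify the steady attractor and score its disorder
run <- free_run(res, steps = 2000, seed = 2)
classify_attractor(run, t0 = 1000)
#> # A tibble: 1 × 2
#>   category period
#>   <fct>     <int>
#> 1 cyclic       54
bientropy(binarize_steady(run$trace))
#> [1] 0.9794

# a delayed-memory task: reproduce the input 6 steps in the past
task <- make_memory_task(-6, length = 900, washout = 50, seed = 3)
run_task_on_reservoir(res, task, train_config(seed = 4))$correlation
#> [1] 0.7634
```

The reservoir sits near the balance optimum for moderate in-degree: its
free-running steady activity is a long cycle (period 54) whose binarized
string still scores a BiEntropy close to 1, and its trained readout
reconstructs the 6-step-delayed white noise with correlation ≈ 0.76 on
held-out data.

Scaled-down sweep presets reproduce the qualitative findings in minutes —
e.g. the order–disorder transition along the negative balance axis:

```r
dyn <- summarize_dynamics(run_dynamics_sweep(sweep_preset("entropy-transition-mini")))
autoplot(dyn)                      # BiEntropy heat map over (K, |sigma*|)
plot_attractor_fractions(dyn)      # attractor census along the balance axis
```

See the methods vignette (`vignettes/rbn-reservoir-methods.Rmd`) for the
model, the measures, all conventions and the known limitations.

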