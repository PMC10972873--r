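test_that("the mutual-excitation toy passes its one-step and cycle checks", {
  toy <- toy_mutual()
  expect_equal(rbn_step(toy, c(1, 0)), c(0, 1))
  expect_equal(rbn_step(toy, c(0, 1)), c(1, 0))
  # zero threshold: the all-zero state is absorbing
  expect_equal(rbn_step(toy, c(0, 0)), c(0, 0))
  orc <- exact_cycle_oracle(toy, c(1, 0))
  expect_equal(orc$transient, 0)
  expect_equal(orc$period, 2)
  orc0 <- exact_cycle_oracle(toy, c(0, 0))
  expect_equal(orc0$transient, 0)
  expect_equal(orc0$period, 1)
})

test_that("initial states have the exact active count and are seed-deterministic", {
  expect_equal(sum(initial_state(10, 0.2, seed = 3)), 2)
  expect_equal(initial_state(5, 0, seed = 1), rep(0, 5))
  expect_identical(initial_state(50, 0.2, seed = 8), initial_state(50, 0.2, seed = 8))
  expect_error(initial_state(10, 1.2), class = "rbn_domain_error")
})

test_that("free-run traces are activity fractions quantized to 1/n", {
  res <- build_reservoir(reservoir_spec(50, 3, -2, seed = 2))
  run <- free_run(res, steps = 300, seed = 5)
  tr <- as.numeric(run$trace)
  expect_length(tr, 300)
  expect_true(all(tr >= 0 & tr <= 1))
  expect_equal(round(tr * 50), tr * 50, tolerance = 1e-12)
})

test_that("free runs are invariant under positive rescaling of recurrent weights", {
  spec <- reservoir_spec(80, 4, -3, seed = 21)
  res <- build_reservoir(spec)
  scaled <- reservoir_from_edges(
    80, transform(res$edges, weight = weight * 7.3),
    input_scale = res$spec$input_scale
  )
  expect_identical(
    as.numeric(free_run(res, 200, seed = 3)$trace),
    as.numeric(free_run(scaled, 200, seed = 3)$trace)
  )
})

test_that("every small free run revisits a state and is periodic thereafter", {
  # exhaustive brute-force: at n = 8 the state space has 256 configurations
  for (seed in 1:5) {
    res <- build_reservoir(reservoir_spec(8, 2, c(-1, 1, -100)[seed %% 3 + 1], seed = seed))
    init <- initial_state(8, 0.25, seed = seed + 50)
    orc <- exact_cycle_oracle(res, init)
    expect_lte(orc$transient + orc$period, 256)
    # replay: state at transient equals state at transient + period
    x <- init
    for (t in seq_len(orc$transient)) x <- rbn_step(res, x, 0)
    x_cycle_start <- x
    for (t in seq_len(orc$period)) x <- rbn_step(res, x, 0)
    expect_identical(x, x_cycle_start)
  }
})

test_that("free and driven trajectories agree bit for bit on zero input", {
  res <- build_reservoir(reservoir_spec(60, 3, 2, seed = 4))
  fr <- free_run(res, 150, seed = 9)
  dr <- driven_run(res, rep(0, 150), seed = 9)
  expect_identical(as.numeric(fr$trace), as.numeric(dr$trace))
  expect_equal(nrow(dr$readout_states), 150)
  expect_equal(ncol(dr$readout_states), length(res$readout_set))
})

test_that("driven runs validate their input and record one row per step", {
  res <- build_reservoir(reservoir_spec(20, 2, 1, seed = 1))
  expect_error(driven_run(res, numeric(0)), class = "rbn_input_error")
  expect_error(driven_run(res, c(1, NA)), class = "rbn_input_error")
  expect_error(rbn_step(res, rep(0, 19)), class = "rbn_state_shape_error")
  dr <- driven_run(res, white_noise(37, seed = 2), seed = 1)
  expect_equal(nrow(dr$readout_states), 37)
})

test_that("a positively driven input neuron with no recurrent drive fires every step", {
  # neuron 1 (input half) receives only the external input; neuron 2 listens to it
  toy <- reservoir_from_edges(2, data.frame(target = 2L, source = 1L, weight = 1))
  dr <- driven_run(toy, rep(1, 10), active_fraction = 0, seed = 1)
  # readout half = neuron 2; it fires from step 2 on, echoing neuron 1
  expect_equal(as.numeric(dr$readout_states[, 1]), c(0, rep(1, 9)))
  expect_equal(as.numeric(dr$trace) * 2, c(1, rep(2, 9)))
})

test_that("trajectories are reproducible bit for bit and states can be windowed", {
  res <- build_reservoir(reservoir_spec(100, 4, -5, seed = 6))
  a <- free_run(res, 400, seed = 2, keep_states_from = 300)
  b <- free_run(res, 400, seed = 2, keep_states_from = 300)
  expect_identical(a$trace, b$trace)
  expect_identical(a$states, b$states)
  expect_equal(dim(a$states), c(100, 100))
  # recorded states reproduce the trace on the recorded window
  expect_equal(unname(rowMeans(a$states)), as.numeric(a$trace)[301:400])
})
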