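test_that("every neuron has exactly k distinct non-self sources and builds reproduce", {
  spec <- reservoir_spec(10, 2, sigma_star = -1.5, seed = 11)
  res <- build_reservoir(spec)
  deg <- table(res$edges$target)
  expect_length(deg, 10)
  expect_true(all(deg == 2))
  expect_true(all(res$edges$target != res$edges$source))
  per_target <- split(res$edges$source, res$edges$target)
  expect_true(all(vapply(per_target, function(s) !anyDuplicated(s), logical(1))))

  again <- build_reservoir(spec)
  expect_identical(res$edges, again$edges)
  other <- build_reservoir(reservoir_spec(10, 2, -1.5, seed = 12))
  expect_false(identical(res$edges, other$edges))
})

test_that("infeasible degree and tiny sizes are rejected", {
  expect_error(reservoir_spec(4, 4, 1), class = "rbn_degree_error")
  expect_error(reservoir_spec(1, 1, 1), class = "rbn_size_error")
  expect_warning(reservoir_spec(10, 2, 1e-3), "supported sweep regime")
})

test_that("input and readout halves partition the neurons", {
  for (n in c(9, 10, 501)) {
    res <- build_reservoir(reservoir_spec(n, 2, 1, seed = 1))
    expect_length(res$input_set, n %/% 2)
    expect_length(res$readout_set, n - n %/% 2)
    expect_length(intersect(res$input_set, res$readout_set), 0)
    expect_setequal(c(res$input_set, res$readout_set), seq_len(n))
  }
})

test_that("density is reported exactly and glance is one row", {
  g <- glance(build_reservoir(reservoir_spec(1000, 16, 2, seed = 3)))
  expect_equal(g$density, 16 / 1000)
  expect_equal(nrow(g), 1)
})

test_that("empirical balance matches the analytic expectation within binomial error", {
  # large single build
  res <- build_reservoir(reservoir_spec(10000, 16, 2, seed = 5))
  bal <- summarize_balance(res)
  s <- bal$s
  expect_equal(s, 160000)
  b <- bal$b_analytic
  expect_lt(abs(bal$b_empirical - b), 4 * sqrt((1 - b^2) / s))

  # negative sign, moderate size
  bal2 <- summarize_balance(build_reservoir(reservoir_spec(1000, 4, -2, seed = 6)))
  b2 <- bal2$b_analytic
  expect_lt(abs(bal2$b_empirical - b2), 4 * sqrt((1 - b2^2) / bal2$s))
})

test_that("mean empirical balance over many seeds is unbiased", {
  b <- balance_from_sigma_star(3)
  emp <- vapply(1:200, function(r) {
    summarize_balance(build_reservoir(reservoir_spec(500, 4, 3, seed = r)))$b_empirical
  }, numeric(1))
  se_mean <- sqrt((1 - b^2) / 2000) / sqrt(200)
  expect_lt(abs(mean(emp) - b), 2 * se_mean)
})

test_that("sign census counts zeros in S but in neither S+ nor S-", {
  toy <- reservoir_from_edges(3, data.frame(
    target = c(1, 1, 2, 2), source = c(2, 3, 1, 3), weight = c(1, -1, 2, -3)
  ))
  bal <- summarize_balance(toy)
  expect_equal(bal$s, 4)
  expect_equal(bal$s_plus, 2)
  expect_equal(bal$s_minus, 2)
  expect_equal(bal$b_empirical, 0)

  with_zero <- reservoir_from_edges(3, data.frame(
    target = c(1, 2), source = c(2, 1), weight = c(0, 1)
  ))
  bz <- summarize_balance(with_zero)
  expect_equal(bz$s, 2)
  expect_equal(bz$s_plus, 1)
  expect_equal(bz$s_minus, 0)
})

test_that("exact-zero-balance construction yields b_empirical of exactly zero", {
  res <- build_reservoir(reservoir_spec(100, 4, 25, seed = 2, exact_zero_balance = TRUE))
  expect_equal(summarize_balance(res)$b_empirical, 0)
})

test_that("reservoirs round-trip bit-exactly through the JSON + CSV serialization", {
  res <- build_reservoir(reservoir_spec(40, 3, -0.7, input_scale = 1.5, seed = 9))
  base <- file.path(withr::local_tempdir(), "res40")
  write_reservoir(res, base)
  back <- read_reservoir(base)
  expect_identical(back$edges$weight, res$edges$weight)
  expect_identical(back$edges$target, res$edges$target)
  expect_equal(back$spec, res$spec)
  expect_identical(
    free_run(back, 100, seed = 4)$trace,
    free_run(res, 100, seed = 4)$trace
  )
})
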