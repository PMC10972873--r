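test_that("grid points carry their balance and infeasible degrees are dropped", {
  cfg <- sweep_config(n = c(4, 100), k = c(3, 4), sigma_star = c(-2, 2),
                      r_dynamics = 1)
  grid <- rbnreservoir:::grid_points(cfg)
  # k = 4 is infeasible at n = 4 (needs 4 distinct non-self sources among 3)
  expect_false(any(grid$n == 4 & grid$k == 4))
  expect_equal(grid$b, balance_from_sigma_star(grid$sigma_star))
})

test_that("dynamics sweeps are deterministic and aggregate exactly", {
  cfg <- tiny_sweep_config()
  runs1 <- run_dynamics_sweep(cfg)
  runs2 <- run_dynamics_sweep(cfg)
  expect_equal(as.data.frame(runs1), as.data.frame(runs2))
  expect_equal(nrow(runs1), 2 * 4)

  s <- summarize_dynamics(runs1)
  for (i in seq_len(nrow(s))) {
    sub <- runs1[runs1$sigma_star == s$sigma_star[i], ]
    expect_equal(s$mean_hb[i], mean(sub$hb), tolerance = 1e-12)
    expect_equal(s$var_hb[i], mean((sub$hb - mean(sub$hb))^2), tolerance = 1e-12)
    expect_equal(s$pct_extinguished[i], 100 * mean(sub$category == "extinguished"))
    expect_equal(s$r[i], nrow(sub))
  }
  expect_equal(
    rowSums(s[, c("pct_extinguished", "pct_fixed", "pct_cyclic", "pct_irregular")]),
    rep(100, nrow(s)), tolerance = 1e-9, ignore_attr = TRUE
  )
})

test_that("interrupted sweeps resume to the identical table via checkpoints", {
  dir <- withr::local_tempdir()
  cfg <- tiny_sweep_config(checkpoint_dir = dir)
  full <- run_dynamics_sweep(cfg)
  files <- list.files(dir, pattern = "^dynamics_")
  expect_length(files, 2)
  # drop one finished grid point: the rerun recomputes only that point
  unlink(file.path(dir, files[1]))
  resumed <- run_dynamics_sweep(cfg)
  expect_equal(as.data.frame(resumed[order(resumed$sigma_star, resumed$replicate), ]),
               as.data.frame(full[order(full$sigma_star, full$replicate), ]),
               tolerance = 1e-12)
})

test_that("task sweeps return raw records that reaggregate exactly", {
  cfg <- tiny_sweep_config()
  recs <- run_task_sweep(cfg)
  expect_equal(nrow(recs), 2 * 2)  # 2 grid points x 1 delta x 2 replicates
  expect_true(all(recs$task == "memory"))
  s <- summarize_performance(recs)
  for (i in seq_len(nrow(s))) {
    sub <- recs[recs$sigma_star == s$sigma_star[i], ]
    expect_equal(s$mean_corr[i], mean(sub$correlation), tolerance = 1e-12)
    expect_equal(s$sd_corr[i], sd(sub$correlation), tolerance = 1e-12)
  }
  # determinism end to end
  recs2 <- run_task_sweep(cfg)
  expect_equal(as.data.frame(recs), as.data.frame(recs2))
})

test_that("an empty task roster yields an empty table without error", {
  cfg <- tiny_sweep_config()
  cfg$deltas <- numeric()
  out <- run_task_sweep(cfg)
  expect_equal(nrow(out), 0)
  expect_s3_class(out, "rbn_performance_runs")
})

test_that("b_opt selection maximizes the hardest setting and breaks ties inward", {
  toy <- tibble::tibble(
    n = 1000, k = 4,
    sigma_star = c(-3, -8, -30),
    b = balance_from_sigma_star(c(-3, -8, -30)),
    task = "memory", difficulty = -18,
    mean_corr = c(0.2, 0.5, 0.3), sd_corr = 0.05, r = 10
  )
  class(toy) <- c("rbn_performance_summary", class(toy))
  opt <- select_b_opt(toy, 1000, 4, -1, "memory")
  expect_equal(opt$mean_corr, 0.5)
  expect_equal(opt$sigma_star_opt, -8)

  tie <- toy
  tie$mean_corr <- c(0.5, 0.5, 0.3)
  tie$b <- c(-0.1, -0.4, -0.6)
  opt2 <- select_b_opt(tie, 1000, 4, -1, "memory")
  expect_equal(opt2$b_opt, -0.1)

  missing_hard <- toy
  missing_hard$difficulty <- -6
  expect_error(select_b_opt(missing_hard, 1000, 4, -1, "memory"),
               class = "rbn_coverage_error")
})

test_that("best-K summaries report every difficulty at the selected balance", {
  tab <- tidyr::expand_grid(
    n = 1000, k = c(2, 4), sigma_star = c(-3, -8), difficulty = c(-2, -18)
  ) |>
    dplyr::mutate(
      b = balance_from_sigma_star(sigma_star),
      task = "memory",
      mean_corr = c(0.6, 0.3, 0.7, 0.4, 0.8, 0.5, 0.9, 0.6),
      sd_corr = 0.1, r = 10
    )
  class(tab) <- c("rbn_performance_summary", class(tab))
  best <- summarize_best_k(tab)
  expect_equal(nrow(best), 4)  # 2 K x 2 difficulties, one sign, one task
  expect_setequal(unique(best$k), c(2, 4))
  # the selected balance per k is the argmax at difficulty -18
  for (kk in c(2, 4)) {
    sub <- tab[tab$k == kk & tab$difficulty == -18, ]
    expect_equal(unique(best$b_opt[best$k == kk]), sub$b[which.max(sub$mean_corr)])
  }
})

test_that("presets build valid configurations", {
  for (p in c("entropy-transition-mini", "k1-order-mini", "memory-mini", "best-k-mini")) {
    cfg <- sweep_preset(p, base_seed = 3)
    expect_s3_class(cfg, "sweep_config")
    expect_equal(cfg$base_seed, 3L)
  }
  expect_equal(sweep_preset("memory-mini")$include_zero_balance, TRUE)
})

test_that("derived seeds are stable, distinct across contexts, and in range", {
  a <- derive_seed(1, "dynamics", 1000, 16, 2.5, 7)
  expect_identical(a, derive_seed(1, "dynamics", 1000, 16, 2.5, 7))
  expect_false(a == derive_seed(1, "dynamics", 1000, 16, 2.5, 8))
  expect_false(a == derive_seed(2, "dynamics", 1000, 16, 2.5, 7))
  seeds <- vapply(1:500, function(r) derive_seed(1, "x", r), integer(1))
  expect_true(all(seeds >= 1 & seeds < 2^31))
  expect_gt(length(unique(seeds)), 495)
})

test_that("plot constructors return ggplot objects", {
  cfg <- tiny_sweep_config()
  s <- summarize_dynamics(run_dynamics_sweep(cfg))
  expect_s3_class(ggplot2::autoplot(s), "ggplot")
  expect_s3_class(ggplot2::autoplot(s, fill = "var_hb"), "ggplot")
  expect_s3_class(plot_attractor_fractions(s), "ggplot")

  perf <- summarize_performance(run_task_sweep(cfg))
  expect_s3_class(ggplot2::autoplot(perf), "ggplot")
})
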