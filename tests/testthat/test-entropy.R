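test_that("binarization clips about the steady-window mean", {
  expect_equal(binarize_steady(rep(0.3, 10), t0 = 0), rep(0L, 10))
  expect_equal(binarize_steady(c(0.2, 0.4, 0.2, 0.4), t0 = 0), c(0L, 1L, 0L, 1L))
  w <- c(0.1, 0.5, 0.2, 0.9, 0.4, 0.4)
  expect_identical(binarize_steady(w, t0 = 0), binarize_steady(w + 0.17, t0 = 0))
  # the default window drops the first t0 steps
  tr <- c(rep(0.9, 6), 0.2, 0.4, 0.2, 0.4)
  expect_equal(binarize_steady(tr, t0 = 6), c(0L, 1L, 0L, 1L))
  expect_error(binarize_steady(c(1, 0, 1), t0 = 0), class = "rbn_length_error")
  expect_error(binarize_steady(rep(1, 10), t0 = 10), class = "rbn_length_error")
})

test_that("bientropy reproduces the hand-derived golden values", {
  expect_equal(bientropy(rep(0, 10), "power"), 0)
  expect_equal(bientropy(rep(0, 10), "logarithmic"), 0)
  expect_equal(bientropy(rep(1, 8), "power"), 0)
  expect_equal(bientropy(c(0, 1, 0, 1), "power"), 1 / 7)
  # (1*H(3/4) + 2*H(2/3) + 4*H(1/2)) / 7
  h <- function(p) -p * log2(p) - (1 - p) * log2(1 - p)
  expect_equal(bientropy(c(1, 0, 1, 1), "power"), (h(3 / 4) + 2 * h(2 / 3) + 4) / 7)
  expect_equal(bientropy(c(1, 0, 1, 1), "power"), 0.94970, tolerance = 1e-5)
  expect_error(bientropy(c(0, 1)), class = "rbn_length_error")
  expect_error(bientropy(c(0, 1, 2, 1)), class = "rbn_content_error")
})

test_that("bientropy stays in [0, 1] on random strings under both variants", {
  set.seed(99)
  for (variant in c("power", "logarithmic")) {
    vals <- vapply(seq_len(5000), function(i) {
      bientropy(rbinom(16, 1, runif(1, 0.1, 0.9)), variant)
    }, numeric(1))
    expect_true(all(vals >= 0 & vals <= 1))
  }
})

test_that("long balanced random strings approach full disorder", {
  set.seed(7)
  strings <- replicate(15, rbinom(1000, 1, 0.5), simplify = FALSE)
  # the logarithmic weighting is the long-string disorder measure: near 1
  m_log <- mean(vapply(strings, bientropy, numeric(1), variant = "logarithmic"))
  expect_gt(m_log, 0.95)
  # the power weighting is dominated by the 2-bit deepest derivative, whose
  # entropy is 0 or 1 with equal probability on random strings, so its
  # long-string mean sits near the middle of the scale rather than near 1
  m_pow <- mean(vapply(strings, bientropy, numeric(1), variant = "power"))
  expect_gt(m_pow, 0.45)
  expect_lt(m_pow, m_log)
})

test_that("ensemble statistics use the population normalization", {
  e <- ensemble_entropy(c(0, 1))
  expect_equal(e$mean, 0.5)
  expect_equal(e$variance, 0.25)
  expect_equal(ensemble_entropy(rep(0.4, 9))$variance, 0)
  expect_error(ensemble_entropy(numeric(0)), class = "rbn_ensemble_error")

  # independent two-pass oracle on arbitrary values
  set.seed(31)
  vals <- runif(100)
  two_pass_mean <- sum(vals) / 100
  two_pass_var <- sum((vals - two_pass_mean)^2) / 100
  e2 <- ensemble_entropy(vals)
  expect_equal(e2$mean, two_pass_mean, tolerance = 1e-12)
  expect_equal(e2$variance, two_pass_var, tolerance = 1e-12)
  # variance times R equals the sum of squared deviations exactly
  expect_equal(e2$variance * 100, sum((vals - mean(vals))^2))
})

test_that("variance regions extract maximal above-threshold runs with labels", {
  one <- find_variance_regions(c(-0.9, -0.5, -0.1), c(0, 2e-4, 5e-5))
  expect_equal(nrow(one), 1)
  expect_equal(one$start, 2)
  expect_equal(one$end, 2)
  expect_equal(one$label, "critical")

  none <- find_variance_regions(c(-0.9, -0.5, -0.1), c(0, 5e-5, 9e-5))
  expect_equal(nrow(none), 0)

  # two separated bumps: outer (largest |b|) is critical, inner re-entrant
  axis <- -c(0.95, 0.85, 0.7, 0.5, 0.3, 0.15, 0.05)
  vars <- c(0, 3e-4, 2e-4, 0, 0, 5e-4, 0)
  two <- find_variance_regions(axis, vars)
  expect_equal(nrow(two), 2)
  expect_equal(two$label[two$start == 2], "critical")
  expect_equal(two$label[two$start == 6], "re-entrant")

  # on a sigma* axis the ordered phase sits at small |sigma*| instead
  two_s <- find_variance_regions(-c(0.01, 0.1, 1, 10, 100, 500, 1000),
                                 c(0, 3e-4, 0, 0, 5e-4, 5e-4, 0),
                                 axis_type = "sigma_star")
  expect_equal(two_s$label, c("critical", "re-entrant"))

  expect_error(find_variance_regions(c(-0.5, -0.9, -0.1), rep(0, 3)),
               class = "rbn_axis_error")
  expect_error(find_variance_regions(c(-0.5, 0.9), c(0, 0)),
               class = "rbn_axis_error")
})
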