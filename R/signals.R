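#' White-noise input series
#'
#' I.i.d. draws, uniform on `[0, 1]` by default (matching the codomain of the
#' sigmoid readout, so delayed copies of the input are representable targets)
#' or standard Gaussian. Deterministic in the seed.
#'
#' @param length Number of steps (>= 1).
#' @param seed Integer seed.
#' @param law `"uniform"` (default) or `"gaussian"`.
#' @return Numeric vector of length `length`.
#' @examples
#' u <- white_noise(100, seed = 1)
#' range(u)
#' @export
white_noise <- function(length, seed = 1L, law = c("uniform", "gaussian")) {
  law <- match.arg(law)
  if (length < 1) abort("`length` must be >= 1.", class = "rbn_domain_error")
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  if (law == "uniform") runif(length) else rnorm(length)
}

#' Discrete Mackey-Glass map
#'
#' Iterates the delayed recurrence
#' `x[t+1] = mg_a * x[t] + mg_b * x[t - tau] / (mg_c + x[t - tau]^mg_d)`
#' with constant pre-history `x[t] = x0` for all `t <= 0`. With the default
#' constants (`mg_a = 0.9`, `mg_b = 0.2`, `mg_c = 0.9`, `mg_d = 10`,
#' `x0 = 0.1`) the delay `tau` controls the dynamics: `tau = 5` settles into a
#' periodic orbit, `tau = 15` is mildly complex, `tau = 28` chaotic. This is
#' the discrete benchmark map, not an integration of the continuous
#' delay-differential system.
#'
#' @param length Number of generated steps (x\[1\]..x\[length\]).
#' @param tau Positive integer delay.
#' @param mg_a,mg_b,mg_c,mg_d Map constants.
#' @param x0 Initial value and constant pre-history.
#' @return Tibble with columns `t`, `x` (raw orbit) and `x_scaled` (the same
#'   orbit min-max normalized to `[0, 1]`; the normalization is affine, so
#'   Pearson correlations computed downstream are unaffected).
#' @examples
#' mg <- mackey_glass(500, tau = 28)
#' mg$x[1]  # 0.1122222...
#' @export
mackey_glass <- function(length, tau, mg_a = 0.9, mg_b = 0.2, mg_c = 0.9,
                         mg_d = 10, x0 = 0.1) {
  if (length < 1) abort("`length` must be >= 1.", class = "rbn_domain_error")
  if (tau < 1) abort("`tau` must be >= 1.", class = "rbn_domain_error")
  tau <- as.integer(tau)
  # x[s] for s in -tau .. length, stored with offset tau + 1
  x <- c(rep(x0, tau + 1L), numeric(length))
  for (t in seq_len(length)) {
    xt <- x[tau + t]  # x[t - 1]
    xd <- x[t]        # x[t - 1 - tau]
    denom <- mg_c + xd^mg_d
    if (denom <= 0) {
      abort("Mackey-Glass denominator became non-positive.", class = "rbn_divergence_error")
    }
    val <- mg_a * xt + mg_b * xd / denom
    if (!is.finite(val)) {
      abort("Mackey-Glass orbit diverged.", class = "rbn_divergence_error")
    }
    x[tau + 1L + t] <- val
  }
  orbit <- x[(tau + 2L):(tau + 1L + length)]
  rng <- range(orbit)
  scaled <- if (rng[1] == rng[2]) rep(0, length) else (orbit - rng[1]) / (rng[2] - rng[1])
  tibble::tibble(t = seq_len(length), x = orbit, x_scaled = scaled)
}

new_task <- function(kind, difficulty, input, target, washout, train_idx, test_idx, seed) {
  structure(
    list(
      kind = kind, difficulty = difficulty,
      input = input, target = target, washout = washout,
      train_idx = train_idx, test_idx = test_idx, seed = seed
    ),
    class = "rbn_task"
  )
}

#' @export
print.rbn_task <- function(x, ...) {
  cat(sprintf(
    "<rbn_task> %s (difficulty %s): %d steps, washout %d, train %d, test %d\n",
    x$kind, x$difficulty, length(x$input), x$washout,
    length(x$train_idx), length(x$test_idx)
  ))
  invisible(x)
}

#' @exportS3Method tibble::as_tibble
as_tibble.rbn_task <- function(x, ...) {
  part <- rep("excluded", length(x$input))
  part[x$train_idx] <- "train"
  part[x$test_idx] <- "test"
  tibble::tibble(t = seq_along(x$input), u = x$input, target = x$target, part = part)
}

split_fit_indices <- function(usable, train_frac) {
  n_train <- floor(train_frac * length(usable))
  if (n_train < 2 || n_train > length(usable) - 2) {
    abort("train/test split leaves fewer than 2 points on one side.",
          class = "rbn_alignment_error")
  }
  list(train = usable[seq_len(n_train)], test = usable[(n_train + 1L):length(usable)])
}

#' Delayed-memory task on white noise
#'
#' The reservoir receives white noise `u(t)` and the readout must reproduce
#' the input `|delta|` steps in the past: `T(t) = u(t - |delta|)`. The
#' standard difficulty ladder is `delta in {-2, -6, -10, -14, -18}`; the
#' larger `|delta|`, the longer input information must reverberate through the
#' memoryless neurons, and the harder the task. Fitting indices exclude the
#' first `washout + |delta|` steps and are split contiguously into train
#' (first `train_frac`) and test (rest).
#'
#' @param delta Negative integer delay.
#' @param length Series length (default 2600, giving roughly 2000 train and
#'   500 test points after a 100-step washout).
#' @param washout Steps excluded at the start (default 100).
#' @param train_frac Fraction of usable indices used for training (default 0.8).
#' @param seed Seed for the white noise.
#' @param law Noise law, see [white_noise()].
#' @return An `rbn_task`.
#' @examples
#' task <- make_memory_task(-6, length = 400, washout = 20, seed = 1)
#' all(task$target[task$train_idx] == task$input[task$train_idx - 6])
#' @export
make_memory_task <- function(delta, length = 2600, washout = 100,
                             train_frac = 0.8, seed = 1L, law = "uniform") {
  if (delta >= 0) abort("`delta` must be a negative integer.", class = "rbn_domain_error")
  lag <- as.integer(abs(delta))
  if (lag >= length - washout) {
    abort("|delta| too large for the series length.", class = "rbn_alignment_error")
  }
  u <- white_noise(length, seed = seed, law = law)
  target <- c(rep(NA_real_, lag), u[seq_len(length - lag)])
  usable <- seq.int(washout + lag + 1L, length)
  idx <- split_fit_indices(usable, train_frac)
  new_task("memory", as.integer(delta), u, target, washout, idx$train, idx$test, seed)
}

#' Mackey-Glass prediction task
#'
#' The reservoir receives the min-max-normalized Mackey-Glass orbit and the
#' readout must predict it 10 steps ahead: `T(t) = u(t + 10)`. The delay
#' `tau` sets the signal complexity (`5` periodic, `15` intermediate, `28`
#' chaotic). The last 10 indices (no defined target) and the washout are
#' excluded from fitting.
#'
#' @param tau Mackey-Glass delay (typically 5, 15 or 28).
#' @param length Series length (default 2600).
#' @param washout Steps excluded at the start (default 100).
#' @param train_frac Train fraction of usable indices (default 0.8).
#' @param horizon Prediction horizon in steps (default 10).
#' @return An `rbn_task`.
#' @examples
#' task <- make_prediction_task(5, length = 600, washout = 50)
#' all(task$target[task$train_idx] == task$input[task$train_idx + 10])
#' @export
make_prediction_task <- function(tau, length = 2600, washout = 100,
                                 train_frac = 0.8, horizon = 10L) {
  horizon <- as.integer(horizon)
  if (horizon < 1) abort("`horizon` must be >= 1.", class = "rbn_domain_error")
  if (washout + horizon + 4 >= length) {
    abort("series too short for the washout and horizon.", class = "rbn_alignment_error")
  }
  u <- mackey_glass(length, tau = tau)$x_scaled
  target <- c(u[(horizon + 1L):length], rep(NA_real_, horizon))
  usable <- seq.int(washout + 1L, length - horizon)
  idx <- split_fit_indices(usable, train_frac)
  new_task("prediction", as.integer(tau), u, target, washout, idx$train, idx$test,
           NA_integer_)
}
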