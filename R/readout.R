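#' Training configuration for the sigmoid readout
#'
#' Full-batch ADAM on a single sigmoid output unit with mean-squared-error
#' loss; the standard settings are a learning rate of 0.001 and 4000 epochs.
#' Readout weights are initialized from a small centered normal scaled by
#' `1 / sqrt(p)` (p readout neurons), seeded for bit-reproducible training.
#'
#' @param learning_rate ADAM step size alpha (default 0.001).
#' @param epochs Full-batch iterations (default 4000).
#' @param beta1,beta2,eps ADAM moment decays and stabilizer
#'   (defaults 0.9, 0.999, 1e-8).
#' @param seed Seed for weight initialization.
#' @return A `train_config` list.
#' @export
train_config <- function(learning_rate = 0.001, epochs = 4000,
                         beta1 = 0.9, beta2 = 0.999, eps = 1e-8, seed = 1L) {
  if (learning_rate <= 0) abort("`learning_rate` must be > 0.", class = "rbn_domain_error")
  if (epochs < 1) abort("`epochs` must be >= 1.", class = "rbn_domain_error")
  structure(
    list(learning_rate = learning_rate, epochs = as.integer(epochs),
         beta1 = beta1, beta2 = beta2, eps = eps, seed = as.integer(seed)),
    class = "train_config"
  )
}

#' Train the sigmoid readout on collected readout-half states
#'
#' Fits `y(t) = sigmoid(w . row_t + c)` to the target by full-batch ADAM
#' minimizing the MSE, for a fixed number of epochs. Rows are the 0/1 readout
#' states collected by [driven_run()] on the training range; the target must
#' take at least two distinct values (a constant target is degenerate). The
#' run is deterministic given the config seed.
#'
#' @param readout_states Numeric matrix, one row per training step.
#' @param target Numeric vector aligned with the rows.
#' @param config A [train_config()].
#' @return A `readout_model`: `weights`, `bias`, `loss` (per-epoch trace),
#'   `config`.
#' @examples
#' x <- matrix(rbinom(400, 1, 0.5), 100, 4)
#' y <- 0.1 + 0.8 * x[, 1]
#' fit <- train_readout(x, y, train_config(epochs = 500))
#' glance(fit)
#' @export
train_readout <- function(readout_states, target, config = train_config()) {
  readout_states <- as.matrix(readout_states)
  if (nrow(readout_states) != length(target)) {
    abort("rows and target are not aligned.", class = "rbn_alignment_error")
  }
  if (length(unique(target)) < 2) {
    abort("target is constant: nothing to fit.", class = "rbn_degenerate_target_error")
  }
  p <- ncol(readout_states)
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(config$seed)
  w0 <- rnorm(p, sd = 1 / sqrt(p))
  fit <- cpp_adam_sigmoid(
    readout_states, as.numeric(target), w0, 0.0,
    config$epochs, config$learning_rate, config$beta1, config$beta2, config$eps
  )
  structure(
    list(weights = as.numeric(fit$weights), bias = as.numeric(fit$bias),
         loss = as.numeric(fit$loss), config = config),
    class = "readout_model"
  )
}

#' @export
print.readout_model <- function(x, ...) {
  cat(sprintf(
    "<readout_model> %d weights, bias %.4f, final MSE %.6f after %d epochs\n",
    length(x$weights), x$bias, x$loss[length(x$loss)], x$config$epochs
  ))
  invisible(x)
}

#' @describeIn train_readout `tidy()` returns one row per readout weight plus
#'   the bias.
#' @param x A `readout_model`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.readout_model <- function(x, ...) {
  tibble::tibble(
    term = c(paste0("w", seq_along(x$weights)), "bias"),
    estimate = c(x$weights, x$bias)
  )
}

#' @describeIn train_readout `glance()` returns a one-row training summary.
#' @exportS3Method generics::glance
glance.readout_model <- function(x, ...) {
  tibble::tibble(
    n_weights = length(x$weights),
    epochs = x$config$epochs,
    learning_rate = x$config$learning_rate,
    initial_loss = x$loss[1],
    final_loss = x$loss[length(x$loss)]
  )
}

readout_predict <- function(model, readout_states) {
  z <- as.numeric(as.matrix(readout_states) %*% model$weights) + model$bias
  1 / (1 + exp(-z))
}

#' Score a trained readout by Pearson correlation with the target
#'
#' Computes `Corr(y, T)` between the sigmoid outputs on the given rows and the
#' target over an index range. An uninformative reservoir yields a correlation
#' near zero; an ideal one, near one. The score is invariant under positive
#' affine transformations of the target. A constant output or target on the
#' range leaves the correlation undefined and raises an error (see
#' [run_task_on_reservoir()] for the convention used in sweeps).
#'
#' @param model A `readout_model`.
#' @param readout_states Matrix of readout-half states (full series).
#' @param target Target series aligned with the rows.
#' @param idx Index range to score (e.g. the task's `test_idx`).
#' @return Pearson correlation (scalar).
#' @export
evaluate_readout <- function(model, readout_states, target, idx) {
  if (length(idx) == 0) abort("`idx` is empty.", class = "rbn_domain_error")
  y <- readout_predict(model, as.matrix(readout_states)[idx, , drop = FALSE])
  tt <- target[idx]
  if (sd(tt) == 0 || sd(y) == 0) {
    abort("correlation undefined: constant output or target on the range.",
          class = "rbn_undefined_correlation_error")
  }
  cor(y, tt)
}

#' Drive, train and score one reservoir on one task
#'
#' Runs the full evaluation protocol for a single reservoir: drive it with the
#' task input ([driven_run()]), train the sigmoid readout on the training
#' range ([train_readout()]), and score the Pearson correlation on the
#' held-out test range. A reservoir whose readout output (or whose target) is
#' constant on the test range carries no information about the signal; its
#' correlation is recorded as 0 with `degenerate = TRUE` rather than left
#' undefined — this is how dead (extinguished) reservoirs score.
#'
#' @param reservoir A `reservoir`.
#' @param task An `rbn_task`.
#' @param config A [train_config()].
#' @param state_seed Seed for the initial reservoir state (default the
#'   reservoir's own seed).
#' @return One-row tibble (a performance record): `n`, `k`, `sigma_star`, `b`,
#'   `task`, `difficulty`, `seed`, `correlation`, `final_loss`, `degenerate`.
#' @examples
#' res <- build_reservoir(reservoir_spec(100, 4, 25, seed = 1))
#' task <- make_memory_task(-2, length = 400, washout = 20, seed = 5)
#' run_task_on_reservoir(res, task, train_config(epochs = 200))
#' @export
run_task_on_reservoir <- function(reservoir, task, config = train_config(),
                                  state_seed = NULL) {
  stopifnot(inherits(reservoir, "reservoir"), inherits(task, "rbn_task"))
  if (is.null(state_seed)) {
    state_seed <- if (is.na(reservoir$spec$seed)) 1L else reservoir$spec$seed
  }
  dr <- driven_run(reservoir, task$input, seed = state_seed)
  x_train <- dr$readout_states[task$train_idx, , drop = FALSE]
  t_train <- task$target[task$train_idx]
  degenerate <- FALSE
  correlation <- 0
  final_loss <- NA_real_
  rows_constant <- all(apply(x_train, 2, function(col) all(col == col[1])))
  if (length(unique(t_train)) < 2 || rows_constant) {
    degenerate <- TRUE
  } else {
    model <- train_readout(x_train, t_train, config)
    final_loss <- model$loss[length(model$loss)]
    y <- readout_predict(model, dr$readout_states[task$test_idx, , drop = FALSE])
    tt <- task$target[task$test_idx]
    if (sd(y) == 0 || sd(tt) == 0) {
      degenerate <- TRUE
    } else {
      correlation <- cor(y, tt)
    }
  }
  b <- if (reservoir$spec$exact_zero_balance) 0 else if (is.na(reservoir$spec$sigma_star))
    NA_real_ else balance_from_sigma_star(reservoir$spec$sigma_star)
  kind <- task$kind
  difficulty <- task$difficulty
  tibble::tibble(
    n = reservoir$spec$n, k = reservoir$spec$k,
    sigma_star = reservoir$spec$sigma_star, b = b,
    task = kind, difficulty = difficulty,
    seed = reservoir$spec$seed,
    correlation = correlation, final_loss = final_loss, degenerate = degenerate
  )
}
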