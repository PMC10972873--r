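new_activity_trace <- function(values, n) {
  structure(values, n = n, class = "activity_trace")
}

#' @export
print.activity_trace <- function(x, ...) {
  cat(sprintf(
    "<activity_trace> %d steps, n = %d, mean activity %.4f\n",
    length(x), attr(x, "n"), mean(x)
  ))
  invisible(x)
}

#' @exportS3Method tibble::as_tibble
as_tibble.activity_trace <- function(x, ...) {
  tibble::tibble(t = seq_along(unclass(x)), activity = as.numeric(x))
}

#' Plot a mean-activity trace
#'
#' @param object An `activity_trace` (from [free_run()] or [driven_run()]).
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.activity_trace <- function(object, ...) {
  df <- tibble::tibble(t = seq_along(unclass(object)), activity = as.numeric(object))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$activity)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time step", y = "mean activity A(t)") +
    ggplot2::ylim(0, 1)
}

#' Random initial state with a fixed active fraction
#'
#' Exactly `round(active_fraction * n)` neurons are set to one, at uniformly
#' random positions (an exact count, not independent Bernoulli draws, so small
#' networks start at the nominal fraction reproducibly). The conventional
#' starting condition is 20% active.
#'
#' @param n Neuron count.
#' @param active_fraction Fraction of neurons initially active, in `[0, 1]`.
#' @param seed Integer seed.
#' @return A 0/1 numeric vector of length `n`.
#' @examples
#' sum(initial_state(10, 0.2, seed = 1))  # exactly 2
#' @export
initial_state <- function(n, active_fraction = 0.2, seed = 1L) {
  if (active_fraction < 0 || active_fraction > 1) {
    abort("`active_fraction` must lie in [0, 1].", class = "rbn_domain_error")
  }
  n_on <- round(active_fraction * n)
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  x <- numeric(n)
  if (n_on > 0) x[sample.int(n, n_on)] <- 1
  x
}

#' One synchronous Heaviside update
#'
#' Applies `x_i(t) = theta(u_i(t) + sum_j w_ij x_j(t-1))` with
#' `theta(z) = 1` iff `z > 0` (so `theta(0) = 0` and the all-zero state is
#' absorbing in a free run). Neurons of the input half receive
#' `u_i = input_scale * input_value`; all others receive zero. Because the
#' threshold is zero, free-run trajectories are invariant under any positive
#' rescaling of the recurrent weights.
#'
#' @param reservoir A `reservoir`.
#' @param state 0/1 numeric vector of length `n`.
#' @param input_value External input value for this step (0 for a free run).
#' @return The next 0/1 state vector.
#' @examples
#' toy <- reservoir_from_edges(2, data.frame(target = c(1, 2), source = c(2, 1), weight = 1))
#' rbn_step(toy, c(1, 0))  # -> c(0, 1)
#' @export
rbn_step <- function(reservoir, state, input_value = 0) {
  stopifnot(inherits(reservoir, "reservoir"))
  if (length(state) != reservoir$spec$n) {
    abort("`state` length does not match the reservoir size.",
          class = "rbn_state_shape_error")
  }
  if (!is.finite(input_value)) {
    abort("`input_value` must be finite.", class = "rbn_domain_error")
  }
  u <- numeric(reservoir$spec$n)
  u[reservoir$input_set] <- reservoir$spec$input_scale * input_value
  field <- u + as.numeric(reservoir$w %*% state)
  as.numeric(field > 0)
}

#' Free-running evolution of a reservoir
#'
#' Runs the reservoir for `steps` synchronous updates with no external input,
#' starting from a random state with the given active fraction, and records
#' the mean-activity trace `A(t) = (1/n) sum_i x_i(t)` for `t = 1..steps`
#' (every value is an integer multiple of `1/n`). The conventional protocol is
#' 2000 steps with 20% initial activity; the second half of the trace is the
#' steady window used by [binarize_steady()] and [classify_attractor()].
#'
#' @param reservoir A `reservoir`.
#' @param steps Duration in steps (>= 1); default 2000.
#' @param active_fraction Initial active fraction; default 0.2.
#' @param seed Seed for the initial state.
#' @param keep_states_from If non-`NULL`, the full bit-state rows for steps
#'   `keep_states_from + 1 .. steps` are retained (memory grows as
#'   `n * (steps - keep_states_from)`; intended for small `n` or short
#'   windows).
#' @return An `rbn_run`: list with `trace` (an `activity_trace`), `states`
#'   (matrix or `NULL`), and `init` (the initial state).
#' @examples
#' res <- build_reservoir(reservoir_spec(100, 4, -2, seed = 1))
#' run <- free_run(res, steps = 500, seed = 2)
#' print(run$trace)
#' @export
free_run <- function(reservoir, steps = 2000, active_fraction = 0.2, seed = 1L,
                     keep_states_from = NULL) {
  stopifnot(inherits(reservoir, "reservoir"))
  if (steps < 1) abort("`steps` must be >= 1.", class = "rbn_domain_error")
  init <- initial_state(reservoir$spec$n, active_fraction, seed)
  record <- !is.null(keep_states_from)
  out <- cpp_run_network(
    reservoir$w, init, numeric(steps), reservoir$input_set - 1L,
    reservoir$spec$input_scale,
    seq_len(reservoir$spec$n) - 1L,
    if (record) as.integer(keep_states_from) else 0L,
    record
  )
  structure(
    list(
      trace = new_activity_trace(out$trace, reservoir$spec$n),
      states = if (record) out$states else NULL,
      init = init
    ),
    class = "rbn_run"
  )
}

#' Drive a reservoir with an input series and collect readout-half states
#'
#' Feeds `input_series` one value per step through the input half and records,
#' for each step `t`, the bit states of the readout half after consuming
#' `input_series[t]` (row `t` of `readout_states`), together with the
#' mean-activity trace. With an all-zero input series the trajectory is
#' identical to [free_run()] with the same seed.
#'
#' @param reservoir A `reservoir`.
#' @param input_series Finite numeric vector (one value per step).
#' @param active_fraction Initial active fraction; default 0.2.
#' @param seed Seed for the initial state.
#' @return A list: `readout_states` (length(input) x |readout half| 0/1
#'   matrix), `trace` (an `activity_trace`).
#' @examples
#' res <- build_reservoir(reservoir_spec(100, 4, 25, seed = 1))
#' dr <- driven_run(res, white_noise(200, seed = 3), seed = 2)
#' dim(dr$readout_states)
#' @export
driven_run <- function(reservoir, input_series, active_fraction = 0.2, seed = 1L) {
  stopifnot(inherits(reservoir, "reservoir"))
  if (length(input_series) == 0) {
    abort("`input_series` is empty.", class = "rbn_input_error")
  }
  if (any(!is.finite(input_series))) {
    abort("`input_series` must be finite-valued.", class = "rbn_input_error")
  }
  init <- initial_state(reservoir$spec$n, active_fraction, seed)
  out <- cpp_run_network(
    reservoir$w, init, as.numeric(input_series), reservoir$input_set - 1L,
    reservoir$spec$input_scale,
    reservoir$readout_set - 1L, 0L, TRUE
  )
  list(
    readout_states = out$states,
    trace = new_activity_trace(out$trace, reservoir$spec$n)
  )
}

#' Exact transient and cycle length of a small reservoir
#'
#' Brute-force first-recurrence detection on the full bit-state trajectory:
#' states are iterated and hashed until one repeats, giving the exact
#' transient length and state-cycle period. Tractable only for small networks
#' (the trajectory must revisit a state within at most `2^n` steps); `n` is
#' capped to keep memory bounded.
#'
#' @param reservoir A `reservoir` with `n <= cap`.
#' @param init 0/1 initial state (e.g. from [initial_state()]).
#' @param cap Maximum supported `n` (default 12).
#' @return A list: `transient` (steps before the cycle is entered) and
#'   `period` (state-cycle length; 1 for fixed points, including the all-zero
#'   state).
#' @examples
#' toy <- reservoir_from_edges(2, data.frame(target = c(1, 2), source = c(2, 1), weight = 1))
#' exact_cycle_oracle(toy, c(1, 0))  # transient 0, period 2
#' @export
exact_cycle_oracle <- function(reservoir, init, cap = 12L) {
  stopifnot(inherits(reservoir, "reservoir"))
  n <- reservoir$spec$n
  if (n > cap) {
    abort(sprintf("exact oracle supports n <= %d, got n = %d.", cap, n),
          class = "rbn_oracle_scope_error")
  }
  seen <- new.env(hash = TRUE, parent = emptyenv())
  x <- init
  t <- 0L
  repeat {
    key <- paste(x, collapse = "")
    prev <- seen[[key]]
    if (!is.null(prev)) {
      return(list(transient = prev, period = t - prev))
    }
    assign(key, t, envir = seen)
    x <- rbn_step(reservoir, x, 0)
    t <- t + 1L
  }
}
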