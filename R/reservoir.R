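#' Specification of a random Boolean network reservoir
#'
#' Collects the control parameters of one reservoir: the neuron count `n`,
#' the homogeneous in-degree `k` (every neuron receives exactly `k` recurrent
#' synapses), and the signed coefficient of variation `sigma_star` of the
#' normal weight law (mean `sign(sigma_star)`, sd `|sigma_star|`). The derived
#' density is `k / n` and the expected excitatory-inhibitory balance is
#' [balance_from_sigma_star()].
#'
#' @param n Neuron count (integer >= 2).
#' @param k In-degree per neuron (integer, `1 <= k <= n - 1`).
#' @param sigma_star Signed nonzero real. Magnitudes in `[1e-2, 1e3]` are the
#'   supported sweep regime; values outside are accepted with a warning.
#' @param input_scale Positive scale applied to the external input for the
#'   neurons of the input half (default 1).
#' @param seed Integer RNG seed; construction is a pure function of the spec.
#' @param exact_zero_balance If `TRUE`, signs are assigned to the drawn weight
#'   magnitudes in exactly equal counts, forcing the empirical balance to zero
#'   (unreachable at any finite `sigma_star` by plain sampling). Used to probe
#'   the performance dip at perfect excitation-inhibition symmetry.
#' @return A `reservoir_spec` object.
#' @examples
#' reservoir_spec(n = 100, k = 4, sigma_star = -2, seed = 1)
#' @export
reservoir_spec <- function(n, k, sigma_star, input_scale = 1, seed = 1L,
                           exact_zero_balance = FALSE) {
  n <- as.integer(n)
  k <- as.integer(k)
  if (is.na(n) || n < 2) {
    abort("`n` must be an integer >= 2.", class = "rbn_size_error")
  }
  if (is.na(k) || k < 1 || k > n - 1) {
    abort(
      sprintf("`k` must satisfy 1 <= k <= n - 1; got k = %s with n = %s.", k, n),
      class = "rbn_degree_error"
    )
  }
  if (!is.finite(sigma_star) || sigma_star == 0) {
    abort("`sigma_star` must be finite and nonzero.", class = "rbn_domain_error")
  }
  if (abs(sigma_star) < 1e-2 || abs(sigma_star) > 1e3) {
    warn(sprintf(
      "|sigma_star| = %g lies outside the supported sweep regime [1e-2, 1e3].",
      abs(sigma_star)
    ))
  }
  if (!is.finite(input_scale) || input_scale <= 0) {
    abort("`input_scale` must be a positive real.", class = "rbn_domain_error")
  }
  structure(
    list(
      n = n, k = k, sigma_star = as.numeric(sigma_star),
      input_scale = as.numeric(input_scale), seed = as.integer(seed),
      exact_zero_balance = isTRUE(exact_zero_balance)
    ),
    class = "reservoir_spec"
  )
}

#' @export
print.reservoir_spec <- function(x, ...) {
  cat(sprintf(
    "<reservoir_spec> n = %d, k = %d, sigma* = %g (b = %.4f), input_scale = %g, seed = %d%s\n",
    x$n, x$k, x$sigma_star, balance_from_sigma_star(x$sigma_star),
    x$input_scale, x$seed,
    if (x$exact_zero_balance) ", exact b = 0" else ""
  ))
  invisible(x)
}

#' Build a random Boolean network reservoir from its specification
#'
#' For each target neuron (in id order) `k` distinct source neurons are drawn
#' uniformly without replacement from the other `n - 1` neurons (no self-loops,
#' no multi-edges), then all `n * k` weights are drawn from the normal law
#' `N(sign(sigma*), |sigma*|)` in target-major order. The first `floor(n / 2)`
#' neuron ids form the input half (they receive the external input) and the
#' remaining `ceiling(n / 2)` ids form the readout half (exposed to the trained
#' readout); a neuron is never in both halves. Construction is a deterministic
#' function of the spec, including its seed.
#'
#' @param spec A [reservoir_spec()].
#' @return A `reservoir` object: the spec, an `edges` tibble
#'   (`target`, `source`, `weight`), the sparse weight matrix `w` with
#'   `w[i, j]` the synapse from `j` to `i`, and the `input_set` / `readout_set`
#'   id vectors.
#' @examples
#' res <- build_reservoir(reservoir_spec(n = 50, k = 4, sigma_star = 2, seed = 7))
#' glance(res)
#' @export
build_reservoir <- function(spec) {
  stopifnot(inherits(spec, "reservoir_spec"))
  n <- spec$n
  k <- spec$k
  withr_seed <- spec$seed
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(withr_seed)

  sources <- integer(n * k)
  for (i in seq_len(n)) {
    pool <- sample.int(n - 1L, k)
    # shift ids >= i by one to exclude the self-loop
    pool <- ifelse(pool >= i, pool + 1L, pool)
    sources[((i - 1L) * k + 1L):(i * k)] <- pool
  }
  targets <- rep(seq_len(n), each = k)
  weights <- rnorm(n * k, mean = sign(spec$sigma_star), sd = abs(spec$sigma_star))
  if (spec$exact_zero_balance) {
    s <- n * k
    n_neg <- s %/% 2L
    if (s %% 2L != 0L) {
      warn("odd synapse count: exact zero balance off by 1/S.")
    }
    signs <- rep(c(-1, 1), c(n_neg, s - n_neg))[sample.int(s)]
    weights <- abs(weights) * signs
  }

  edges <- tibble::tibble(target = targets, source = sources, weight = weights)
  new_reservoir(spec, edges)
}

new_reservoir <- function(spec, edges) {
  n <- spec$n
  w <- Matrix::sparseMatrix(
    i = edges$target, j = edges$source, x = edges$weight, dims = c(n, n)
  )
  n_in <- n %/% 2L
  structure(
    list(
      spec = spec,
      edges = edges,
      w = w,
      input_set = seq_len(n_in),
      readout_set = seq.int(n_in + 1L, n)
    ),
    class = "reservoir"
  )
}

#' Assemble a reservoir directly from an edge table
#'
#' Escape hatch for hand-built toy networks in examples and tests. The usual
#' in-degree, no-self-loop and distinct-source constraints are checked unless
#' `check_degree = FALSE` (useful for toys whose in-degree is not homogeneous).
#'
#' @param n Neuron count.
#' @param edges Data frame with columns `target`, `source`, `weight`.
#' @param input_scale Input scale for the input half (default 1).
#' @param check_degree Verify the homogeneous in-degree constraint (default
#'   `FALSE`: toys are usually irregular).
#' @return A `reservoir` object.
#' @examples
#' # two neurons feeding each other with weight +1
#' toy <- reservoir_from_edges(2, data.frame(target = c(1, 2), source = c(2, 1), weight = 1))
#' @export
reservoir_from_edges <- function(n, edges, input_scale = 1, check_degree = FALSE) {
  n <- as.integer(n)
  edges <- tibble::as_tibble(edges)[, c("target", "source", "weight")]
  if (any(edges$target == edges$source)) {
    abort("self-loops are not allowed.", class = "rbn_structure_error")
  }
  if (anyDuplicated(edges[, c("target", "source")])) {
    abort("duplicate (target, source) pairs are not allowed.", class = "rbn_structure_error")
  }
  if (check_degree) {
    deg <- tabulate(edges$target, nbins = n)
    if (length(unique(deg)) != 1L) {
      abort("in-degree is not homogeneous.", class = "rbn_structure_error")
    }
  }
  k <- max(tabulate(edges$target, nbins = n))
  spec <- structure(
    list(n = n, k = as.integer(k), sigma_star = NA_real_,
         input_scale = as.numeric(input_scale), seed = NA_integer_,
         exact_zero_balance = FALSE),
    class = "reservoir_spec"
  )
  new_reservoir(spec, edges)
}

#' @export
print.reservoir <- function(x, ...) {
  cat(sprintf(
    "<reservoir> n = %d, k = %d, sigma* = %g, %d synapses, input half %d / readout half %d\n",
    x$spec$n, x$spec$k, x$spec$sigma_star, nrow(x$edges),
    length(x$input_set), length(x$readout_set)
  ))
  invisible(x)
}

#' @describeIn build_reservoir `tidy()` returns the edge table as a tibble.
#' @param x A `reservoir`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.reservoir <- function(x, ...) {
  x$edges
}

#' @describeIn build_reservoir `glance()` returns a one-row summary (parameters,
#'   density, empirical and analytic balance).
#' @exportS3Method generics::glance
glance.reservoir <- function(x, ...) {
  bal <- summarize_balance(x)
  tibble::tibble(
    n = x$spec$n, k = x$spec$k, sigma_star = x$spec$sigma_star,
    density = x$spec$k / x$spec$n,
    s = bal$s, b_empirical = bal$b_empirical, b_analytic = bal$b_analytic,
    seed = x$spec$seed
  )
}

#' Synapse-sign census and empirical balance of a reservoir
#'
#' Counts positive and negative synapses over all `n * k` weights and reports
#' the empirical balance `b = (S+ - S-) / S` next to the analytic expectation
#' for the spec's sigma*. Exactly-zero weights (probability zero under the
#' continuous law, possible in hand-built toys) count in `S` but in neither
#' `S+` nor `S-`.
#'
#' @param reservoir A `reservoir`.
#' @return A one-row tibble: `s`, `s_plus`, `s_minus`, `b_empirical`,
#'   `b_analytic` (`NA` when sigma* is unknown, e.g. toys).
#' @examples
#' summarize_balance(build_reservoir(reservoir_spec(1000, 4, -2, seed = 1)))
#' @export
summarize_balance <- function(reservoir) {
  stopifnot(inherits(reservoir, "reservoir"))
  w <- reservoir$edges$weight
  s_plus <- sum(w > 0)
  s_minus <- sum(w < 0)
  s <- length(w)
  tibble::tibble(
    s = s, s_plus = s_plus, s_minus = s_minus,
    b_empirical = (s_plus - s_minus) / s,
    b_analytic = if (is.na(reservoir$spec$sigma_star)) NA_real_ else
      balance_from_sigma_star(reservoir$spec$sigma_star)
  )
}

#' Write / read a reservoir as a JSON header plus an edge CSV
#'
#' `write_reservoir()` stores `<base>.json` (the spec and counts) and
#' `<base>_edges.csv` (target, source, weight). `read_reservoir()` restores the
#' reservoir bit-exactly (weights round-trip through the CSV at full
#' precision).
#'
#' @param reservoir A `reservoir`.
#' @param base Path prefix (without extension).
#' @return `write_reservoir()` returns `base` invisibly; `read_reservoir()`
#'   returns the restored `reservoir`.
#' @examples
#' res <- build_reservoir(reservoir_spec(20, 3, 2, seed = 1))
#' base <- file.path(tempdir(), "res20")
#' write_reservoir(res, base)
#' identical(tidy(read_reservoir(base)), tidy(res))
#' @export
write_reservoir <- function(reservoir, base) {
  stopifnot(inherits(reservoir, "reservoir"))
  header <- c(
    reservoir$spec,
    list(
      n_synapses = nrow(reservoir$edges),
      input_set_size = length(reservoir$input_set),
      format = "rbnreservoir/edge-table-v1"
    )
  )
  jsonlite::write_json(header, paste0(base, ".json"), auto_unbox = TRUE, digits = NA)
  edges_out <- reservoir$edges
  # 17 significant digits round-trip any double bit-exactly through text
  edges_out$weight <- sprintf("%.17g", edges_out$weight)
  readr::write_csv(edges_out, paste0(base, "_edges.csv"))
  invisible(base)
}

#' @rdname write_reservoir
#' @export
read_reservoir <- function(base) {
  header <- jsonlite::read_json(paste0(base, ".json"), simplifyVector = TRUE)
  edges <- readr::read_csv(
    paste0(base, "_edges.csv"),
    col_types = readr::cols(
      target = readr::col_integer(),
      source = readr::col_integer(),
      weight = readr::col_character()
    ),
    progress = FALSE
  )
  # strtod via as.numeric is correctly rounded, giving bit-exact round-trips
  edges$weight <- as.numeric(edges$weight)
  spec <- structure(
    list(
      n = as.integer(header$n), k = as.integer(header$k),
      sigma_star = as.numeric(header$sigma_star),
      input_scale = as.numeric(header$input_scale),
      seed = as.integer(header$seed),
      exact_zero_balance = isTRUE(header$exact_zero_balance)
    ),
    class = "reservoir_spec"
  )
  new_reservoir(spec, edges)
}
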