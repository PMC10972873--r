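#' Classify a steady activity window into an attractor category
#'
#' The four mutually exclusive categories, decided in order:
#' \describe{
#'   \item{extinguished}{the steady activity is zero at every step;}
#'   \item{fixed}{the activity is constant and nonzero (zero derivative);}
#'   \item{cyclic}{the activity repeats with the minimal period
#'     `p` in `2 .. floor(L/2)` such that `A(t) = A(t + p)` throughout the
#'     window (a candidate period must therefore be observed at least twice);}
#'   \item{irregular}{none of the above — no period is detectable within the
#'     window, which for a deterministic finite system means the true cycle
#'     is longer than half the window.}
#' }
#' Activity values are integer multiples of `1/n` by construction, so equality
#' is tested exactly on the underlying integer counts `round(A * n)`, never on
#' floating-point representations.
#'
#' @param steady Steady-window activity values: an `activity_trace`, or a
#'   numeric vector, or an `rbn_run` (in which case the window `t > t0` of its
#'   trace is used).
#' @param n Neuron count (taken from the trace attribute when available).
#' @param t0 Steady-window start when `steady` is a full run/trace longer than
#'   needed; default 0 (use the window as given).
#' @return One-row tibble: `category` (factor with the four levels) and
#'   `period` (integer, `NA` unless cyclic).
#' @examples
#' classify_attractor(rep(0, 10), n = 100)                    # extinguished
#' classify_attractor(rep(0.35, 10), n = 100)                 # fixed
#' classify_attractor(rep(c(0.1, 0.2, 0.3), 8), n = 10)       # cyclic, period 3
#' @export
classify_attractor <- function(steady, n = NULL, t0 = 0) {
  if (inherits(steady, "rbn_run")) steady <- steady$trace
  if (is.null(n)) n <- attr(steady, "n")
  if (is.null(n)) {
    abort("`n` is required when `steady` is a plain numeric vector.",
          class = "rbn_domain_error")
  }
  values <- as.numeric(steady)
  if (t0 > 0) {
    if (t0 >= length(values)) {
      abort("`t0` must be smaller than the trace length.", class = "rbn_length_error")
    }
    values <- values[(t0 + 1):length(values)]
  }
  len <- length(values)
  if (len < 4) {
    abort("steady window must contain at least 4 steps.", class = "rbn_length_error")
  }
  counts <- as.integer(round(values * n))

  category <- NULL
  period <- NA_integer_
  if (all(counts == 0L)) {
    category <- "extinguished"
  } else if (all(counts == counts[1L])) {
    category <- "fixed"
  } else {
    for (p in 2:(len %/% 2L)) {
      if (all(counts[seq_len(len - p)] == counts[(p + 1L):len])) {
        category <- "cyclic"
        period <- as.integer(p)
        break
      }
    }
    if (is.null(category)) category <- "irregular"
  }
  tibble::tibble(
    category = factor(category, levels = attractor_categories()),
    period = period
  )
}

attractor_categories <- function() c("extinguished", "fixed", "cyclic", "irregular")

#' Attractor-category histogram over an ensemble of runs
#'
#' Counts and percentages per category over the labels of an ensemble of
#' reservoirs sharing the same control parameters. Percentages sum to 100 and
#' the order of the labels is irrelevant.
#'
#' @param labels A tibble of rows from [classify_attractor()] (stacked with
#'   e.g. `dplyr::bind_rows()`), or a character/factor vector of categories.
#' @return Tibble with one row per category: `category`, `count`, `pct`, `r`.
#' @examples
#' labs <- dplyr::bind_rows(
#'   classify_attractor(rep(0, 8), n = 10),
#'   classify_attractor(rep(0.5, 8), n = 10)
#' )
#' attractor_statistics(labs)
#' @export
attractor_statistics <- function(labels) {
  cats <- if (is.data.frame(labels)) labels$category else labels
  if (length(cats) == 0) {
    abort("`labels` must be nonempty.", class = "rbn_ensemble_error")
  }
  cats <- factor(as.character(cats), levels = attractor_categories())
  counts <- table(cats)
  r <- length(cats)
  tibble::tibble(
    category = factor(attractor_categories(), levels = attractor_categories()),
    count = as.integer(counts),
    pct = 100 * as.integer(counts) / r,
    r = r
  )
}
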