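#' Binarize the steady part of an activity trace
#'
#' Takes the steady window `t > t0` of the trace, subtracts its mean, and
#' clips: values strictly above the window mean become 1, all others
#' (including values exactly at the mean, hence any constant window) become 0.
#' The result is the bit string whose disorder [bientropy()] measures. Adding
#' a constant to the whole window leaves the bits unchanged.
#'
#' @param trace An `activity_trace` or numeric vector.
#' @param t0 Last step excluded from the steady window (default 1000, matching
#'   a 2000-step free run whose second half is treated as steady).
#' @return Integer 0/1 vector of length `length(trace) - t0`.
#' @examples
#' binarize_steady(c(rep(0.2, 4), 0.2, 0.4, 0.2, 0.4), t0 = 4)
#' @export
binarize_steady <- function(trace, t0 = 1000) {
  values <- as.numeric(trace)
  if (t0 >= length(values)) {
    abort("`t0` must be smaller than the trace length.", class = "rbn_length_error")
  }
  window <- values[(t0 + 1):length(values)]
  if (length(window) < 4) {
    abort("steady window must contain at least 4 steps.", class = "rbn_length_error")
  }
  as.integer(window > mean(window))
}

binary_shannon <- function(p) {
  ifelse(p <= 0 | p >= 1, 0, -p * log2(p) - (1 - p) * log2(1 - p))
}

#' BiEntropy of a bit string
#'
#' Croll's order/disorder measure for binary strings: form the successive
#' binary derivatives `d_0 = bits`, `d_(k+1) = XOR` of adjacent bits of `d_k`
#' (k = 0 .. length - 2 levels), take the Shannon entropy `H(p_k)` of the
#' fraction of ones at each level, and return the weighted mean
#' `sum_k w_k H(p_k) / sum_k w_k`. The `power` variant uses `w_k = 2^k`
#' (dominated by the deepest derivative; the classical form for short
#' strings), the `logarithmic` variant `w_k = log2(k + 2)` (the tres-entropy
#' form, appropriate for long strings where `2^k` overflows all but the last
#' level). The score is 0 for perfectly periodic strings (every derivative
#' level constant, e.g. all-zeros) and approaches 1 for irregular ones.
#'
#' @param bits 0/1 vector of length >= 4.
#' @param variant `"logarithmic"` (default, used for the 1000-bit steady
#'   windows) or `"power"`.
#' @return A value in `[0, 1]`.
#' @examples
#' bientropy(c(0, 1, 0, 1), variant = "power")   # 1/7
#' bientropy(rep(0, 10))                         # exactly 0
#' @export
bientropy <- function(bits, variant = c("logarithmic", "power")) {
  variant <- match.arg(variant)
  bits <- as.numeric(bits)
  if (length(bits) < 4) {
    abort("BiEntropy needs at least 4 bits.", class = "rbn_length_error")
  }
  if (any(!(bits %in% c(0, 1)))) {
    abort("`bits` must contain only 0 and 1.", class = "rbn_content_error")
  }
  n_levels <- length(bits) - 1L  # k = 0 .. length - 2
  p <- numeric(n_levels)
  d <- bits
  for (k in seq_len(n_levels)) {
    p[k] <- mean(d)
    d <- as.numeric(xor(d[-length(d)], d[-1]))
  }
  # power weights computed relative to the deepest level so long strings
  # cannot overflow; the ratio sum(w H)/sum(w) is unchanged
  w <- if (variant == "power") 2^(seq_len(n_levels) - n_levels) else log2(seq_len(n_levels) + 1)
  sum(w * binary_shannon(p)) / sum(w)
}

#' Ensemble mean and variance of per-reservoir BiEntropy values
#'
#' Aggregates the BiEntropy scores of an ensemble of reservoirs sharing the
#' same control parameters: `mean = (1/R) sum_r H_r` and the population-form
#' variance `variance = (1/R) sum_r (H_r - mean)^2` (deliberately `1/R`, not
#' the unbiased `1/(R-1)`).
#'
#' @param values Numeric vector of per-reservoir BiEntropy values (length R >= 1).
#' @return One-row tibble: `mean`, `variance`, `r`.
#' @examples
#' ensemble_entropy(c(0, 1))  # mean 0.5, variance 0.25
#' @export
ensemble_entropy <- function(values) {
  if (length(values) == 0) {
    abort("`values` must be nonempty.", class = "rbn_ensemble_error")
  }
  m <- mean(values)
  tibble::tibble(mean = m, variance = mean((values - m)^2), r = length(values))
}

#' Above-threshold BiEntropy-variance regions along a one-sign balance grid
#'
#' Scans a grid of one balance sign, ordered by `|axis|`, for maximal runs of
#' grid points whose ensemble BiEntropy variance exceeds `threshold`. The run
#' adjacent to the ordered phase — the one containing the largest `|b|`
#' (equivalently the smallest `|sigma*|` when the axis is sigma*) — marks the
#' order-disorder transition and is labeled `critical`; any additional
#' disjoint run closer to perfect balance is labeled `re-entrant`.
#'
#' @param axis Strictly `|.|`-ordered grid of b (or sigma*) values, one sign.
#' @param variances Ensemble BiEntropy variance at each grid point.
#' @param threshold Variance threshold (default 0.0001).
#' @param axis_type `"balance"` (ordered phase at large `|b|`, the default) or
#'   `"sigma_star"` (ordered phase at small `|sigma*|`).
#' @return Tibble with one row per region: `start`, `end` (grid indices),
#'   `axis_from`, `axis_to`, `label`.
#' @examples
#' find_variance_regions(c(-0.9, -0.5, -0.1), c(0, 2e-4, 5e-5))
#' @export
find_variance_regions <- function(axis, variances, threshold = 0.0001,
                                  axis_type = c("balance", "sigma_star")) {
  axis_type <- match.arg(axis_type)
  if (length(axis) != length(variances)) {
    abort("`axis` and `variances` lengths differ.", class = "rbn_axis_error")
  }
  mags <- abs(axis)
  if (any(diff(mags) == 0) || (any(diff(mags) > 0) && any(diff(mags) < 0))) {
    abort("`axis` must be strictly ordered by |value|.", class = "rbn_axis_error")
  }
  if (length(unique(sign(axis))) > 1) {
    abort("`axis` must contain a single sign.", class = "rbn_axis_error")
  }
  above <- variances > threshold
  if (!any(above)) {
    return(tibble::tibble(
      start = integer(), end = integer(),
      axis_from = numeric(), axis_to = numeric(), label = character()
    ))
  }
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  starts <- starts[keep]
  ends <- ends[keep]
  regions <- tibble::tibble(
    start = starts, end = ends,
    axis_from = axis[starts], axis_to = axis[ends]
  )
  # ordered phase sits at large |b| / small |sigma*|; the adjacent run is critical
  peak_mag <- pmax(abs(regions$axis_from), abs(regions$axis_to))
  critical_idx <- if (axis_type == "balance") which.max(peak_mag) else {
    which.min(pmin(abs(regions$axis_from), abs(regions$axis_to)))
  }
  regions$label <- ifelse(seq_len(nrow(regions)) == critical_idx, "critical", "re-entrant")
  regions
}
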