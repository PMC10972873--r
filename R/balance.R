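#' Excitatory-inhibitory balance implied by the weight parameter sigma*
#'
#' Reservoir weights are drawn from a normal law with mean `sign(sigma_star)`
#' and standard deviation `|sigma_star|`, so `sigma_star` is the coefficient
#' of variation sigma/mu of the weight distribution. The expected balance
#' b = (S+ - S-)/S between excitatory and inhibitory synapse counts is the
#' expected sign imbalance of a draw:
#'
#'   b = sign(sigma*) * (2 * Phi(1 / |sigma*|) - 1)
#'
#' with Phi the standard normal CDF. `b` has the sign of `sigma_star`,
#' |b| -> 1 as |sigma*| -> 0 (all weights share the sign of the mean) and
#' b -> 0 as |sigma*| -> Inf (signs become equiprobable).
#'
#' An alternative closed form `b = erf(1 / (2 sigma*))` circulates in the
#' literature; it is not consistent with the sampling process above (the
#' sampling-consistent identity is `erf(1 / (sqrt(2) sigma*))`) and is
#' provided only as `form = "erf-printed"` for comparison. All analyses in
#' this package use the default sampling-consistent form.
#'
#' @param sigma_star Signed, nonzero coefficient of variation (vectorized).
#' @param form `"sampling"` (default, exact for the implemented weight draw)
#'   or `"erf-printed"` (the alternative conversion, for comparison only).
#' @return Balance value(s) in `[-1, 1]`, same length as `sigma_star`.
#' @seealso [sigma_star_from_balance()] for the inverse.
#' @examples
#' balance_from_sigma_star(c(-10, -2, 2, 10))
#' balance_from_sigma_star(0.01)  # essentially fully excitatory
#' @export
balance_from_sigma_star <- function(sigma_star, form = c("sampling", "erf-printed")) {
  form <- match.arg(form)
  if (any(!is.finite(sigma_star)) || any(sigma_star == 0)) {
    abort("`sigma_star` must be finite and nonzero.", class = "rbn_domain_error")
  }
  if (form == "sampling") {
    sign(sigma_star) * (2 * pnorm(1 / abs(sigma_star)) - 1)
  } else {
    # erf(x) = 2 * Phi(x * sqrt(2)) - 1, evaluated at x = 1 / (2 sigma*)
    2 * pnorm(sqrt(2) / (2 * sigma_star)) - 1
  }
}

#' Sigma* producing a given expected balance
#'
#' Inverse of [balance_from_sigma_star()] (sampling form):
#' `sigma* = sign(b) / qnorm((|b| + 1) / 2)`.
#'
#' @param b Balance in `(-1, 1)`, nonzero (vectorized).
#' @return Signed sigma* value(s).
#' @examples
#' sigma_star_from_balance(balance_from_sigma_star(-2))
#' @export
sigma_star_from_balance <- function(b) {
  if (any(!is.finite(b)) || any(b == 0) || any(abs(b) >= 1)) {
    abort("`b` must be in (-1, 0) or (0, 1).", class = "rbn_domain_error")
  }
  sign(b) / qnorm((abs(b) + 1) / 2)
}
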