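## Logistic link: inverse link and its first three derivatives with
## respect to the linear predictor, in saturation-safe form.

#' Inverse logit and derivatives
#'
#' Computes \eqn{\mu = 1/(1+e^{-\eta})} together with its first three
#' derivatives with respect to \eqn{\eta}. These are the building blocks of
#' the estimating function, the Firth-type penalty and the second-order bias
#' tensors: for the canonical logit link
#' \eqn{\mu' = \mu(1-\mu)}, \eqn{\mu'' = \mu'(1-2\mu)} and
#' \eqn{\mu''' = \mu'(1-6\mu+6\mu^2)}.
#'
#' All quantities saturate smoothly for large \eqn{|\eta|}; no overflow
#' occurs.
#'
#' @param eta numeric vector of linear-predictor values.
#' @return a list with components `mu`, `d1`, `d2`, `d3`, each a numeric
#'   vector of the same length as `eta`.
#' @examples
#' logit_derivatives(0) # mu = 0.5, d1 = 0.25, d2 = 0, d3 = -0.125
#' @export
logit_derivatives <- function(eta) {
  mu <- stats::plogis(eta)
  d1 <- mu * (1 - mu)
  d2 <- d1 * (1 - 2 * mu)
  d3 <- d1 * (1 - 6 * mu + 6 * mu^2)
  list(mu = mu, d1 = d1, d2 = d2, d3 = d3)
}
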