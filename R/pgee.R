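## Firth-type penalized estimating equation: the penalty adds
## g_r = tr(Phi^-1 dPhi/dbeta_r)/2 to each score component. With the logit
## link, beta enters Phi = (1/phi) sum_i X_i' A_i^{1/2} R_i^{-1} A_i^{1/2} X_i
## only through A_i = diag(mu(1-mu)); the working correlation and scale are
## held fixed while differentiating.

#' Derivatives of the Fisher information and the Firth-type penalty
#'
#' Computes \eqn{\partial\Phi/\partial\beta_r} analytically for each
#' coefficient and the penalty vector
#' \eqn{g_r = \frac12\,\mathrm{tr}[\Phi^{-1}\partial\Phi/\partial\beta_r]}.
#' With clusters of size one, an independence structure and unit scale this
#' reduces to the classical Firth modified-score adjustment for logistic
#' regression.
#'
#' @param cq per-cluster quantities from [score_and_information()].
#' @param Phi Fisher information matrix at the same beta.
#' @return list with `g` (p-vector) and `dPhi` (list of p symmetric
#'   matrices).
#' @export
information_derivatives <- function(cq, Phi) {
  p <- ncol(Phi)
  dPhi <- vector("list", p)
  for (r in seq_len(p)) dPhi[[r]] <- matrix(0, p, p)
  for (q in cq) {
    s <- sqrt(q$a)
    d2 <- q$a * (1 - 2 * q$mu)            # d a / d eta
    ## RinvS = R^{-1}/phi scaled: Vinv = (1/phi) diag(1/s) Rinv diag(1/s)
    ## so  (1/phi) Rinv = diag(s) %*% Vinv %*% diag(s)
    RinvPhi <- (q$Vinv * s) * rep(s, each = length(s))  # s_t Vinv_ts s_s
    B <- q$X * s                           # A^{1/2} X
    for (r in seq_len(p)) {
      ds_r <- d2 * q$X[, r] / (2 * s)      # d s / d beta_r
      S <- q$X * ds_r
      M <- crossprod(S, RinvPhi %*% B)
      dPhi[[r]] <- dPhi[[r]] + M + t(M)
    }
  }
  Phi_inv <- chol2inv(chol(Phi))
  g <- vapply(dPhi, function(M) 0.5 * sum(Phi_inv * M), 0)
  list(g = g, dPhi = dPhi)
}

## Penalty hook for gee_solve.
pgee_penalty <- function(beta, cq, Phi) {
  information_derivatives(cq, Phi)$g
}
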