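## Second-order bias correction of the GEE estimator. The bias vector is
## assembled from cumulants of the estimating function U and its
## derivatives, evaluated at the converged fit with the working correlation
## and scale held fixed. Expectation-type cumulants are evaluated
## analytically with Y replaced by mu-hat; cumulants involving products of
## U use empirical per-cluster residual cross-products, so the correction
## stays valid when the working correlation structure is misspecified.

## Derivatives of G_i = D_i' V_i^{-1} (p x n) with respect to beta, with
## R and phi fixed. G = (1/phi) X' diag(s) Rinv diag(1/s), s = sqrt(mu(1-mu)).
## Returns first derivatives dG[[r]] and (optionally) second derivatives
## d2G[[r]][[s]] for s >= r.
cluster_G_derivs <- function(q, second = FALSE) {
  n <- length(q$a); p <- ncol(q$X)
  s <- sqrt(q$a)
  qv <- 1 / s
  d2 <- q$a * (1 - 2 * q$mu)                       # da/deta
  d3 <- q$a * (1 - 6 * q$mu + 6 * q$mu^2)          # d2a/deta2
  RinvPhi <- (q$Vinv * s) * rep(s, each = n)       # R^{-1}/phi
  Xt <- t(q$X)

  da <- q$X * d2                                   # da/dbeta_r (cols r)
  ds <- da / (2 * s)
  dq <- -ds * qv^2

  dG <- vector("list", p)
  for (r in seq_len(p))
    dG[[r]] <- Xt %*% (t(t(RinvPhi * ds[, r]) * qv) +
                       t(t(RinvPhi * s) * dq[, r]))
  if (!second) return(list(dG = dG))

  d2G <- vector("list", p)
  for (r in seq_len(p)) {
    d2G[[r]] <- vector("list", p)
    for (u in seq_len(p)) {
      d2a_ru <- d3 * q$X[, r] * q$X[, u]
      d2s_ru <- d2a_ru / (2 * s) - da[, r] * ds[, u] / (2 * q$a)
      d2q_ru <- -d2s_ru * qv^2 + 2 * ds[, r] * ds[, u] * qv^3
      d2G[[r]][[u]] <- Xt %*% (t(t(RinvPhi * d2s_ru) * qv) +
                               t(t(RinvPhi) * dq[, u]) * ds[, r] +
                               t(t(RinvPhi) * dq[, r]) * ds[, u] +
                               t(t(RinvPhi * s) * d2q_ru))
    }
  }
  list(dG = dG, d2G = d2G)
}

#' Cumulants of the estimating function
#'
#' Evaluates, at the converged coefficients with nuisance parameters held
#' fixed, the cumulant arrays entering the second-order bias:
#' \eqn{\kappa_{rs} = E[\partial U_r/\partial\beta_s]} (equal to
#' \eqn{-\Phi} under the canonical link),
#' \eqn{\kappa_{r,s} = E[U_r U_s]} (empirical residual cross-products),
#' \eqn{\kappa_{rsu} = E[\partial^2 U_r/\partial\beta_s\partial\beta_u]},
#' \eqn{\kappa_{rs,u} = E[(\partial U_r/\partial\beta_s)U_u]} (empirical,
#' with the derivative centered at its model-based mean), and
#' \eqn{\kappa_{rs}^{(u)} = \partial\kappa_{rs}/\partial\beta_u}.
#'
#' @param cq per-cluster quantities from [score_and_information()].
#' @param Phi Fisher information at the same beta.
#' @return list with `k_rs` (p x p), `k_inv` (inverse of `k_rs`), `k_r_s`
#'   (p x p), `k_rsu` (p x p x p), `k_rs_u` (p x p x p), `k_rs_du`
#'   (p x p x p).
#' @export
compute_cumulants <- function(cq, Phi) {
  p <- ncol(Phi)
  k_rs <- -Phi
  k_r_s <- matrix(0, p, p)
  k_rsu <- array(0, c(p, p, p))
  k_rs_u <- array(0, c(p, p, p))

  for (q in cq) {
    u_i <- drop(q$B %*% q$eps)
    k_r_s <- k_r_s + tcrossprod(u_i)
    gd <- cluster_G_derivs(q)
    d2 <- q$a * (1 - 2 * q$mu)
    for (s in seq_len(p)) {
      dGD <- gd$dG[[s]] %*% q$D                    # p x p, [r, u]
      k_rsu[, s, ] <- k_rsu[, s, ] - dGD
      k_rsu[, , s] <- k_rsu[, , s] - dGD
      W_s <- drop(gd$dG[[s]] %*% q$eps)            # centered dU/dbeta_s
      k_rs_u[, s, ] <- k_rs_u[, s, ] + tcrossprod(W_s, u_i)
      for (u in seq_len(p))
        k_rsu[, s, u] <- k_rsu[, s, u] -
          drop(q$B %*% (d2 * q$X[, s] * q$X[, u]))
    }
  }

  k_inv <- tryCatch(-chol2inv(chol(Phi)), error = function(e)
    stop("cumulant matrix [kappa_rs] is singular; bias not computable",
         call. = FALSE))
  k_rs_du <- array(0, c(p, p, p))
  dPhi <- information_derivatives(cq, Phi)$dPhi
  for (u in seq_len(p)) k_rs_du[, , u] <- -dPhi[[u]]

  list(k_rs = k_rs, k_inv = k_inv, k_r_s = k_r_s,
       k_rsu = k_rsu, k_rs_u = k_rs_u, k_rs_du = k_rs_du)
}

#' Second-order bias vector of the GEE estimator
#'
#' Contracts the cumulant arrays into the bias
#' \deqn{b_r = \sum_s \kappa^{rs} \sum_{u,v}\Big[\kappa_{su,v}
#'   - \tfrac12\sum_{k,\ell}\kappa^{k\ell}\kappa_{sv\ell}\kappa_{u,k}\Big]
#'   \kappa^{uv},}
#' the quantity subtracted from the GEE estimate to form the
#' bias-corrected estimate. The bias is O(1/K) in the number of clusters.
#'
#' @param cum cumulant list from [compute_cumulants()].
#' @return p-vector of bias values.
#' @export
bias_vector <- function(cum) {
  p <- nrow(cum$k_rs)
  Kinv <- cum$k_inv
  C <- cum$k_r_s
  inner <- numeric(p)
  for (s in seq_len(p)) {
    Ts <- cum$k_rsu[s, , ]                         # [v, l]
    Ms <- cum$k_rs_u[s, , ]                        # [u, v]
    Bmat <- Ms - 0.5 * C %*% Kinv %*% t(Ts)
    inner[s] <- sum(Bmat * Kinv)
  }
  drop(Kinv %*% inner)
}
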