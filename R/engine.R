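## Core estimating-equation machinery shared by GEE, BCGEE and PGEE:
## per-cluster quantities, score U and Fisher information Phi, and the
## Fisher-scoring loop with interleaved moment updates of phi and alpha.

## Per-cluster quantities at a given beta. Returns a list per cluster:
##   mu, a (variance diag mu(1-mu)), eps = y - mu, e = Pearson residuals,
##   D = A X, Vinv = (1/phi) A^-1/2 R^-1 A^-1/2, B = D' Vinv (p x n), occ, X, y.
cluster_quantities <- function(blocks, beta, corstr, alpha, phi, n_max) {
  lapply(blocks, function(b) {
    eta <- drop(b$X %*% beta)
    ld <- logit_derivatives(eta)
    a <- pmax(ld$d1, 1e-10)        # guard against exact saturation
    eps <- b$y - ld$mu
    s <- sqrt(a)
    R <- build_corr_matrix(corstr, alpha, b$occ, n_max)
    Rinv <- chol2inv(chol(R))
    Vinv <- (1 / phi) * (Rinv / tcrossprod(s))     # A^-1/2 R^-1 A^-1/2 / phi
    D <- b$X * a
    list(id = b$id, y = b$y, X = b$X, occ = b$occ,
         mu = ld$mu, a = a, eps = eps, e = eps / s,
         D = D, Vinv = Vinv, B = crossprod(D, Vinv))
  })
}

#' Estimating function and Fisher information
#'
#' Evaluates \eqn{U(\beta) = \sum_i D_i^\top V_i^{-1} \varepsilon_i} and
#' \eqn{\Phi = \sum_i D_i^\top V_i^{-1} D_i} at a given coefficient
#' vector, with the working correlation and scale held fixed.
#'
#' @param blocks a `gee_blocks` object (or its `blocks` element).
#' @param beta coefficient vector.
#' @param corstr working correlation structure name.
#' @param alpha correlation parameter (see [build_corr_matrix()]).
#' @param phi scale parameter.
#' @return list with `U` (p-vector), `Phi` (p x p), and `cq`, the
#'   per-cluster quantities used downstream by the covariance estimators.
#' @export
score_and_information <- function(blocks, beta, corstr = "independence",
                                  alpha = NULL, phi = 1) {
  if (inherits(blocks, "gee_blocks")) blocks <- blocks$blocks
  n_max <- max(vapply(blocks, function(b) length(b$y), 0))
  cq <- cluster_quantities(blocks, beta, corstr, alpha, phi, n_max)
  p <- length(beta)
  U <- numeric(p); Phi <- matrix(0, p, p)
  for (q in cq) {
    U <- U + drop(q$B %*% q$eps)
    Phi <- Phi + q$B %*% q$D
  }
  Phi <- (Phi + t(Phi)) / 2
  list(U = U, Phi = Phi, cq = cq)
}

## One full nuisance refresh at the current beta: residuals -> phi -> alpha.
update_nuisance <- function(blocks, beta, corstr, p, scale_fix,
                            n_occasions) {
  eb <- lapply(blocks, function(b) {
    eta <- drop(b$X %*% beta)
    mu <- stats::plogis(eta)
    list(e = (b$y - mu) / sqrt(pmax(mu * (1 - mu), 1e-10)), occ = b$occ)
  })
  pearson <- unlist(lapply(eb, `[[`, "e"), use.names = FALSE)
  phi <- estimate_scale(pearson, p, scale_fix)
  alpha <- if (corstr == "independence") NULL else
    estimate_alpha(eb, corstr, phi, p, n_occasions)
  list(phi = phi, alpha = alpha)
}

## Fisher-scoring loop. `penalty` is NULL (GEE) or a function
## (beta, cq, Phi) -> p-vector g added to the score (PGEE).
gee_solve <- function(bl, init, corstr, maxitr, tol, scale_fix,
                      penalty = NULL) {
  blocks <- bl$blocks
  p <- bl$p
  n_occasions <- length(bl$occasion_levels)
  beta <- init
  converged <- FALSE
  iter <- 0
  separation_flagged <- FALSE

  nuis <- update_nuisance(blocks, beta, corstr, p, scale_fix, n_occasions)
  si <- score_and_information(blocks, beta, corstr, nuis$alpha, nuis$phi)
  g <- if (is.null(penalty)) 0 else penalty(beta, si$cq, si$Phi)
  score <- si$U + g

  while (iter < maxitr) {
    iter <- iter + 1
    step <- tryCatch(solve(si$Phi, score), error = function(e)
      stop("Fisher information is singular at iteration ", iter,
           "; check the design for rank deficiency or separation",
           call. = FALSE))

    ## step-halving: do not accept a step that inflates the score norm
    accepted <- FALSE
    for (h in 0:10) {
      cand <- beta + step / 2^h
      si_c <- score_and_information(blocks, cand, corstr, nuis$alpha,
                                    nuis$phi)
      g_c <- if (is.null(penalty)) 0 else penalty(cand, si_c$cq, si_c$Phi)
      score_c <- si_c$U + g_c
      ok <- all(is.finite(score_c)) &&
        max(abs(score_c)) <= max(abs(score))
      if (ok || h == 10) {
        accepted <- TRUE
        delta <- step / 2^h
        beta <- cand
        break
      }
    }

    if (!separation_flagged && any(abs(beta) > 50)) {
      separation_flagged <- TRUE
      warning("coefficients exceed 50 in absolute value; the data may be ",
              "separated - consider beta.method = \"PGEE\"", call. = FALSE)
    }

    ## refresh nuisance parameters at the new beta, then the score
    nuis <- update_nuisance(blocks, beta, corstr, p, scale_fix, n_occasions)
    si <- score_and_information(blocks, beta, corstr, nuis$alpha, nuis$phi)
    g <- if (is.null(penalty)) 0 else penalty(beta, si$cq, si$Phi)
    score <- si$U + g

    if (max(abs(delta)) < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("estimation did not converge in ", maxitr, " iterations",
            call. = FALSE)

  names(beta) <- bl$xnames
  list(beta = beta, phi = nuis$phi, alpha = nuis$alpha,
       U = si$U, Phi = si$Phi, cq = si$cq,
       iterations = iter, converged = converged)
}

## Ordinary logistic MLE used as the GEE/BCGEE starting value; plain IRLS
## so no glm object overhead. Non-finite drift is left to the caller's
## separation surveillance.
logistic_init <- function(blocks) {
  X <- do.call(rbind, lapply(blocks, `[[`, "X"))
  y <- unlist(lapply(blocks, `[[`, "y"), use.names = FALSE)
  fit <- suppressWarnings(
    stats::glm.fit(X, y, family = stats::binomial(),
                   control = list(maxit = 100)))
  beta <- fit$coefficients
  beta[!is.finite(beta)] <- 0
  beta
}

#' Firth-penalized logistic regression
#'
#' Maximizes the Jeffreys-penalized binomial likelihood
#' \eqn{\ell(\beta) + \frac12 \log\det(X^\top W X)} by Newton steps on the
#' modified score \eqn{X^\top\{y - \mu + h(\tfrac12 - \mu)\}}, where `h` is
#' the diagonal of the weighted hat matrix. Estimates are finite even under
#' complete separation. Used as the PGEE starting value and exported for
#' direct use on independent binary data.
#'
#' @param X design matrix (including intercept column).
#' @param y binary 0/1 response.
#' @param maxitr,tol iteration control.
#' @return list with `coefficients`, `iterations`, `converged`.
#' @export
firth_logistic <- function(X, y, maxitr = 100, tol = 1e-10) {
  p <- ncol(X)
  beta <- numeric(p)
  converged <- FALSE
  for (iter in seq_len(maxitr)) {
    mu <- stats::plogis(drop(X %*% beta))
    w <- mu * (1 - mu)
    XW <- X * w
    info <- crossprod(X, XW)
    ch <- chol(info)
    ## hat diagonal of the weighted regression
    h <- rowSums((X %*% chol2inv(ch)) * XW)
    score <- drop(crossprod(X, y - mu + h * (0.5 - mu)))
    step <- backsolve(ch, forwardsolve(t(ch), score))
    ## damp very large steps (separation makes early steps wild)
    if (max(abs(step)) > 5) step <- step * 5 / max(abs(step))
    beta <- beta + step
    if (max(abs(step)) < tol) { converged <- TRUE; break }
  }
  list(coefficients = beta, iterations = iter, converged = converged)
}
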