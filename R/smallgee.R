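## User-facing model fit: marginal logistic regression for clustered
## binary outcomes by GEE, BCGEE or PGEE, with a chosen small-sample
## covariance estimator.

#' Small-sample GEE for clustered binary outcomes
#'
#' Fits a marginal logistic regression to clustered or longitudinal binary
#' data by one of three estimating methods — conventional generalized
#' estimating equations (`"GEE"`), the second-order bias-corrected variant
#' (`"BCGEE"`), or the Firth-type penalized variant (`"PGEE"`, the
#' default, which stays finite under separation) — and estimates the
#' coefficient covariance by one of twelve sandwich-type estimators
#' (see [estimate_covariance()]; `"MB"`, the Morel estimator, by default).
#'
#' The mean model is \eqn{\mathrm{logit}\,\mu_{it} = x_{it}^\top\beta}
#' with working covariance
#' \eqn{V_i = \phi A_i^{1/2} R_i(\alpha) A_i^{1/2}},
#' \eqn{A_i = \mathrm{diag}(\mu_{it}(1-\mu_{it}))}. Coefficients solve
#' \eqn{\sum_i D_i^\top V_i^{-1}(Y_i-\mu_i) = 0} (plus the Firth-type
#' penalty for PGEE) by Fisher scoring with step-halving; the scale
#' \eqn{\phi} and correlation \eqn{\alpha} are refreshed by moment
#' estimators after every coefficient update. Starting values come from
#' ordinary logistic regression (GEE/BCGEE) or Firth logistic regression
#' (PGEE) treating all observations as independent, unless `b` is given.
#'
#' @param formula model formula; categorical covariates enter via
#'   `factor()` with the lowest-sorted level as reference.
#' @param data data frame in long format.
#' @param id cluster identifier: column name or vector.
#' @param repeated optional occasion identifier (column name or vector);
#'   treated as a categorical position label. When absent, rows of a
#'   cluster must be contiguous.
#' @param corstr working correlation structure: `"independence"`
#'   (default), `"exchangeable"`, `"ar1"` or `"unstructured"`.
#' @param beta.method `"GEE"`, `"BCGEE"` or `"PGEE"` (default).
#' @param SE.method covariance estimator name (default `"MB"`).
#' @param b optional starting values for the coefficients.
#' @param maxitr maximum number of iterations (50).
#' @param tol convergence tolerance on the max absolute coefficient update
#'   (1e-5).
#' @param scale.fix if `TRUE` the scale parameter is fixed at 1.
#' @param conf.level confidence level for interval estimates (0.95).
#' @param delta Fay-Graubard truncation bound (0.75).
#' @return an object of class `"smallgee"`; see [summary.smallgee()].
#'   Components include `coefficients`, `covb`, `se`, `phi`, `alpha`,
#'   `wcorr` (working correlation for the largest cluster), `iterations`,
#'   `converged`, `K`, `max.ni`, `linear.predictors`, `fitted.values`,
#'   `residuals` (raw), and for BCGEE the bias vector `bias`.
#' @examples
#' d <- simulate_binary_clusters(K = 30, n = 4, beta = c(-0.5, 1),
#'                               rho = 0.3, corstr = "exchangeable",
#'                               seed = 1)
#' f <- smallgee(y ~ x1, data = d, id = "id", repeated = "time",
#'               corstr = "exchangeable", beta.method = "GEE",
#'               SE.method = "KC")
#' summary(f)
#' @export
smallgee <- function(formula, data, id, repeated = NULL,
                     corstr = "independence", beta.method = "PGEE",
                     SE.method = "MB", b = NULL, maxitr = 50, tol = 1e-5,
                     scale.fix = FALSE, conf.level = 0.95, delta = 0.75) {
  cl <- match.call()
  corstr <- match.arg(corstr, CORSTR_CHOICES)
  beta.method <- match.arg(beta.method, c("GEE", "PGEE", "BCGEE"))
  SE.method <- match.arg(SE.method, SE_METHODS)
  stopifnot(conf.level > 0, conf.level < 1, maxitr >= 1, tol > 0)

  bl <- build_clusters(formula, data, id, repeated)
  fit <- fit_engine(bl, corstr, beta.method, b, maxitr, tol, scale.fix)

  cov <- estimate_covariance(fit, SE.method, delta)
  finalize_smallgee(fit, bl, cov, cl, formula, corstr, beta.method,
                    SE.method, conf.level, scale.fix, maxitr, tol, delta)
}

## Shared estimation core (no covariance); used by smallgee and
## smallgee_all. Returns the gee_solve result augmented with bookkeeping.
fit_engine <- function(bl, corstr, beta.method, b, maxitr, tol, scale.fix) {
  init <- if (!is.null(b)) {
    if (length(b) != bl$p)
      stop("initial value vector 'b' must have length ", bl$p,
           call. = FALSE)
    as.numeric(b)
  } else if (beta.method == "PGEE") {
    X <- do.call(rbind, lapply(bl$blocks, `[[`, "X"))
    y <- unlist(lapply(bl$blocks, `[[`, "y"), use.names = FALSE)
    firth_logistic(X, y)$coefficients
  } else {
    logistic_init(bl$blocks)
  }

  penalty <- if (beta.method == "PGEE") pgee_penalty else NULL
  fit <- gee_solve(bl, init, corstr, maxitr, tol, scale.fix, penalty)
  fit$bias <- NULL

  if (beta.method == "BCGEE") {
    bias <- tryCatch(
      bias_vector(compute_cumulants(fit$cq, fit$Phi)),
      error = function(e) {
        warning("bias correction failed (", conditionMessage(e),
                "); returning the uncorrected GEE estimate", call. = FALSE)
        NULL
      })
    if (!is.null(bias)) {
      fit$bias <- stats::setNames(bias, bl$xnames)
      beta_bc <- fit$beta - bias
      ## one-step correction: cluster quantities and Phi are re-evaluated
      ## at the corrected coefficients, with the nuisance parameters kept
      ## at their values from the converged uncorrected fit
      si <- score_and_information(bl$blocks, beta_bc, corstr, fit$alpha,
                                  fit$phi)
      fit$beta <- stats::setNames(beta_bc, bl$xnames)
      fit$U <- si$U; fit$Phi <- si$Phi; fit$cq <- si$cq
    }
  }
  fit$xnames <- bl$xnames
  fit$K <- bl$K
  fit
}

finalize_smallgee <- function(fit, bl, cov, cl, formula, corstr,
                              beta.method, SE.method, conf.level,
                              scale.fix, maxitr, tol, delta) {
  ni <- vapply(bl$blocks, function(b) length(b$y), 0)
  imax <- which.max(ni)
  wcorr <- build_corr_matrix(corstr, fit$alpha, bl$blocks[[imax]]$occ,
                             max(ni))
  eta <- unlist(lapply(fit$cq, function(q) drop(q$X %*% fit$beta)),
                use.names = FALSE)
  mu <- unlist(lapply(fit$cq, `[[`, "mu"), use.names = FALSE)
  res <- unlist(lapply(fit$cq, `[[`, "eps"), use.names = FALSE)

  structure(list(
    call = cl, formula = formula,
    coefficients = fit$beta,
    covb = cov$covb, se = cov$se,
    phi = fit$phi, alpha = fit$alpha, scale = fit$phi,
    wcorr = wcorr,
    linear.predictors = eta, fitted.values = mu, residuals = res,
    iterations = fit$iterations, converged = fit$converged,
    beta.method = beta.method, SE.method = SE.method, corstr = corstr,
    conf.level = conf.level, scale.fix = scale.fix,
    maxitr = maxitr, tol = tol, delta = delta,
    K = bl$K, max.ni = max(ni), n.obs = bl$n_obs, p = bl$p,
    model.matrix = do.call(rbind, lapply(bl$blocks, `[[`, "X")),
    xnames = bl$xnames,
    bias = fit$bias,
    U = fit$U, Phi = fit$Phi, cq = fit$cq, blocks = bl),
    class = "smallgee")
}

#' @export
print.smallgee <- function(x, digits = max(3L, getOption("digits") - 3L),
                           ...) {
  cat("Call:\n"); print(x$call)
  cat("\nModel:\n")
  cat("  Estimating method  :", x$beta.method, "\n")
  cat("  Covariance method  :", x$SE.method, "\n")
  cat("  Correlation struct :", x$corstr, "\n")
  cat("  Clusters (K)       :", x$K, " max cluster size:", x$max.ni, "\n")
  cat("\nCoefficients:\n")
  print(round(x$coefficients, digits))
  cat("\nScale parameter:", format(x$phi, digits = digits), "\n")
  cat("Iterations:", x$iterations, "\n")
  cat("\nWorking correlation matrix:\n")
  print(round(x$wcorr, digits))
  cat("\nConvergence:",
      if (x$converged) "converged" else "NOT converged", "\n")
  invisible(x)
}

#' Inference summary for a small-sample GEE fit
#'
#' Wald tests based on the chosen covariance estimator: per-coefficient
#' estimate, standard error, z statistic and two-sided p-value against the
#' standard normal reference, plus odds ratios with
#' \eqn{\exp(\hat\beta \pm z_{\alpha/2}\,\mathrm{SE})} confidence limits.
#'
#' @param object a `smallgee` fit.
#' @param conf.level confidence level; defaults to the one used at fit
#'   time.
#' @param ... unused.
#' @return object of class `"summary.smallgee"` with data-frame components
#'   `coefficients` (Estimate, Std.Error, z, p) and `odds.ratios`
#'   (OR, lower, upper).
#' @export
summary.smallgee <- function(object, conf.level = object$conf.level, ...) {
  est <- object$coefficients
  se <- object$se
  z <- est / se
  pval <- 2 * stats::pnorm(-abs(z))
  zc <- stats::qnorm(1 - (1 - conf.level) / 2)
  coefs <- data.frame(Estimate = est, Std.Error = se, z = z,
                      `p.value` = pval, row.names = names(est),
                      check.names = FALSE)
  ors <- data.frame(OR = exp(est),
                    lower = exp(est - zc * se),
                    upper = exp(est + zc * se),
                    row.names = names(est))
  structure(list(call = object$call, coefficients = coefs,
                 odds.ratios = ors, conf.level = conf.level,
                 beta.method = object$beta.method,
                 SE.method = object$SE.method, corstr = object$corstr,
                 converged = object$converged),
            class = "summary.smallgee")
}

#' @export
print.summary.smallgee <- function(x,
                                   digits = max(3L,
                                                getOption("digits") - 3L),
                                   ...) {
  cat("Call:\n"); print(x$call)
  cat("\nMethods:", x$beta.method, "/", x$SE.method,
      "(", x$corstr, ")\n\nCoefficients:\n")
  stats::printCoefmat(as.matrix(x$coefficients), digits = digits,
                      P.values = TRUE, has.Pvalue = TRUE)
  cat("\nOdds Ratios with", paste0(format(100 * x$conf.level), "%"),
      "Confidence Intervals:\n")
  print(round(x$odds.ratios, digits))
  if (!x$converged) cat("\nWarning: estimation did not converge\n")
  invisible(x)
}

#' @export
coef.smallgee <- function(object, ...) object$coefficients

#' @export
vcov.smallgee <- function(object, ...) object$covb

#' @export
fitted.smallgee <- function(object, ...) object$fitted.values

#' @export
residuals.smallgee <- function(object,
                               type = c("raw", "pearson"), ...) {
  type <- match.arg(type)
  if (type == "raw") return(object$residuals)
  mu <- object$fitted.values
  object$residuals / sqrt(mu * (1 - mu))
}

#' @export
model.matrix.smallgee <- function(object, ...) object$model.matrix

#' @export
confint.smallgee <- function(object, parm, level = object$conf.level,
                             ...) {
  est <- object$coefficients
  se <- object$se
  zc <- stats::qnorm(1 - (1 - level) / 2)
  ci <- cbind(est - zc * se, est + zc * se)
  colnames(ci) <- paste(format(100 * c((1 - level) / 2,
                                       1 - (1 - level) / 2),
                               trim = TRUE), "%")
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' Predicted probabilities from a small-sample GEE fit
#'
#' @param object a `smallgee` fit.
#' @param newdata optional data frame of covariates; when omitted,
#'   fitted values for the training data are returned.
#' @param type `"response"` for probabilities, `"link"` for linear
#'   predictors.
#' @param ... unused.
#' @export
predict.smallgee <- function(object, newdata = NULL,
                             type = c("response", "link"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    eta <- object$linear.predictors
  } else {
    tt <- stats::delete.response(object$blocks$terms)
    mf <- stats::model.frame(tt, newdata, xlev = object$blocks$xlev)
    X <- stats::model.matrix(tt, mf)
    eta <- drop(X %*% object$coefficients)
  }
  if (type == "link") eta else stats::plogis(eta)
}
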