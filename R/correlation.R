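## Working correlation structures R_i(alpha) and moment estimation of the
## nuisance parameters (scale phi, correlation alpha) from Pearson
## residuals. Structures: independence, exchangeable, ar1, unstructured.

CORSTR_CHOICES <- c("independence", "exchangeable", "ar1", "unstructured")

#' Build a working correlation matrix for one cluster
#'
#' @param corstr one of `"independence"`, `"exchangeable"`, `"ar1"`,
#'   `"unstructured"`.
#' @param alpha correlation parameter: ignored for independence, a scalar
#'   for exchangeable/ar1, a symmetric `T x T` matrix over the pooled
#'   occasion set for unstructured.
#' @param occ integer occasion positions of the cluster (indices into the
#'   pooled occasion set). For ar1 the correlation between positions `s`
#'   and `t` is `alpha^|s - t|`.
#' @param n_max largest cluster size (bounds the admissible exchangeable
#'   range `(-1/(n_max - 1), 1)`).
#' @return the `n_i x n_i` working correlation matrix.
#' @export
build_corr_matrix <- function(corstr, alpha, occ, n_max = length(occ)) {
  n <- length(occ)
  corstr <- match.arg(corstr, CORSTR_CHOICES)
  R <- switch(corstr,
    independence = diag(n),
    exchangeable = {
      check_alpha_range(alpha, corstr, n_max)
      M <- matrix(alpha, n, n); diag(M) <- 1; M
    },
    ar1 = {
      check_alpha_range(alpha, corstr, n_max)
      alpha^abs(outer(occ, occ, "-"))
    },
    unstructured = {
      if (!is.matrix(alpha) || max(occ) > nrow(alpha))
        stop("unstructured alpha must be a matrix covering all occasions",
             call. = FALSE)
      M <- alpha[occ, occ, drop = FALSE]; diag(M) <- 1; M
    })
  if (n > 1L) {
    ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 1e-10)
      stop("working correlation matrix is not positive definite",
           call. = FALSE)
  }
  R
}

check_alpha_range <- function(alpha, corstr, n_max) {
  if (length(alpha) != 1L || !is.finite(alpha))
    stop("alpha must be a finite scalar for ", corstr, call. = FALSE)
  lo <- if (corstr == "ar1") -1 else if (n_max > 1L) -1 / (n_max - 1) else -1
  if (alpha <= lo || alpha >= 1)
    stop("alpha = ", format(alpha), " outside the admissible range (",
         format(lo), ", 1) for ", corstr, call. = FALSE)
  invisible(alpha)
}

## Clamp a moment estimate into the interior of the admissible range
## (at 0.99 of the boundary), with a warning.
clamp_alpha <- function(alpha, corstr, n_max) {
  lo <- if (corstr == "ar1") -1 else if (n_max > 1L) -1 / (n_max - 1) else -1
  hi <- 1
  out <- min(max(alpha, 0.99 * lo), 0.99 * hi)
  if (out != alpha)
    warning("estimated alpha ", format(alpha), " outside (",
            format(lo), ", 1); clamped to ", format(out), call. = FALSE)
  out
}

#' Moment estimator of the scale parameter
#'
#' \eqn{\hat\phi = \sum e_{it}^2 / (\sum n_i - p)} from Pearson residuals
#' \eqn{e_{it} = \hat\varepsilon_{it} / \sqrt{\mu(1-\mu)}}, or exactly 1
#' when the scale is fixed.
#'
#' @param pearson numeric vector of Pearson residuals over all observations.
#' @param p number of regression parameters.
#' @param scale_fix if `TRUE` return 1.
#' @return positive scalar.
#' @export
estimate_scale <- function(pearson, p, scale_fix = FALSE) {
  if (scale_fix) return(1)
  df <- length(pearson) - p
  if (df <= 0)
    stop("too few observations to estimate the scale parameter",
         call. = FALSE)
  sum(pearson^2) / df
}

#' Moment estimator of the working correlation parameter
#'
#' Classical cross-product estimators with a `p` degrees-of-freedom
#' correction in the denominator:
#' exchangeable pools all within-cluster pairs, ar1 uses pairs at adjacent
#' occasion positions, unstructured estimates each occasion pair
#' separately. Estimates falling outside the admissible range are clamped
#' to 0.99 of the boundary with a warning.
#'
#' @param resid_blocks list with one element per cluster, each a list with
#'   `e` (Pearson residuals) and `occ` (occasion positions).
#' @param corstr correlation structure name.
#' @param phi scale estimate.
#' @param p number of regression parameters.
#' @param n_occasions size of the pooled occasion set (needed for
#'   unstructured).
#' @return scalar alpha (or `T x T` matrix for unstructured; `NULL` for
#'   independence).
#' @export
estimate_alpha <- function(resid_blocks, corstr, phi, p,
                           n_occasions = NULL) {
  corstr <- match.arg(corstr, CORSTR_CHOICES)
  if (corstr == "independence") return(NULL)
  n_max <- max(vapply(resid_blocks, function(b) length(b$e), 0))
  if (n_max < 2L)
    stop("all clusters have size 1; cannot estimate a ", corstr,
         " correlation", call. = FALSE)

  if (corstr == "exchangeable") {
    num <- 0; npairs <- 0
    for (b in resid_blocks) {
      n <- length(b$e)
      if (n < 2L) next
      num <- num + (sum(b$e)^2 - sum(b$e^2)) / 2
      npairs <- npairs + n * (n - 1) / 2
    }
    den <- phi * (npairs - p)
    if (den <= 0) stop("too few pairs to estimate alpha", call. = FALSE)
    return(clamp_alpha(num / den, corstr, n_max))
  }

  if (corstr == "ar1") {
    num <- 0; npairs <- 0
    for (b in resid_blocks) {
      adj <- which(diff(b$occ) == 1L)
      if (!length(adj)) next
      num <- num + sum(b$e[adj] * b$e[adj + 1L])
      npairs <- npairs + length(adj)
    }
    den <- phi * (npairs - p)
    if (den <= 0) stop("too few adjacent pairs to estimate alpha",
                       call. = FALSE)
    return(clamp_alpha(num / den, corstr, n_max))
  }

  ## unstructured
  if (is.null(n_occasions))
    n_occasions <- max(vapply(resid_blocks, function(b) max(b$occ), 0))
  Tn <- n_occasions
  num <- matrix(0, Tn, Tn); cnt <- matrix(0, Tn, Tn)
  for (b in resid_blocks) {
    ee <- tcrossprod(b$e)
    num[b$occ, b$occ] <- num[b$occ, b$occ] + ee
    cnt[b$occ, b$occ] <- cnt[b$occ, b$occ] + 1
  }
  den <- phi * (cnt - p)
  if (any(den[upper.tri(den)] <= 0 & cnt[upper.tri(cnt)] > 0))
    stop("too few clusters observed at some occasion pair to estimate an ",
         "unstructured correlation", call. = FALSE)
  A <- num / ifelse(den == 0, 1, den)
  A[cnt == 0] <- 0
  diag(A) <- 1
  A <- (A + t(A)) / 2
  off <- A[upper.tri(A)]
  if (any(abs(off) >= 1)) {
    warning("unstructured correlation entries outside (-1, 1); clamped",
            call. = FALSE)
    A[upper.tri(A)] <- pmin(pmax(off, -0.99), 0.99)
    A[lower.tri(A)] <- t(A)[lower.tri(A)]
  }
  A
}
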