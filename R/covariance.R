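## Sandwich covariance of the coefficient estimates: the unadjusted robust
## estimator (SA) and eleven small-sample adjustments. All are of the form
## Phi^-1 { meat } Phi^-1 and differ in how the per-cluster residual outer
## products are inflated or pooled.

SE_METHODS <- c("SA", "MK", "KC", "MD", "FG", "PA",
                "GS", "MB", "WL", "WB", "FW", "FZ")

#' Cluster leverage matrices
#'
#' \eqn{H_{ij} = D_i \Phi^{-1} D_j^\top V_j^{-1}}. The diagonal blocks
#' \eqn{H_{ii}} drive the KC/MD/WL/WB/FW inflations; the full grid is
#' needed only by the FZ estimator. The diagonal blocks satisfy
#' \eqn{\sum_i \mathrm{tr}(H_{ii}) = p}.
#'
#' @param cq per-cluster quantities from a fit.
#' @param Phi_inv inverse Fisher information.
#' @param pairs `"diagonal"` for the `H_ii` list, `"all"` for the full
#'   K x K grid (list of lists).
#' @return list of matrices (diagonal mode) or list of lists (all mode).
#' @export
leverage <- function(cq, Phi_inv, pairs = c("diagonal", "all")) {
  pairs <- match.arg(pairs)
  if (pairs == "diagonal")
    return(lapply(cq, function(q) q$D %*% Phi_inv %*% q$B))
  lapply(cq, function(qi)
    lapply(cq, function(qj) qi$D %*% Phi_inv %*% qj$B))
}

## Principal square root of (I - H)^{-1} via eigendecomposition; H is not
## symmetric in general so complex pairs may occur, but the product has
## real principal root on well-conditioned fits.
inv_sqrt_IH <- function(H, id) {
  M <- diag(nrow(H)) - H
  e <- eigen(M)
  if (any(Re(e$values) <= 1e-12))
    stop("(I - H) is singular for cluster ", id, call. = FALSE)
  Vinv <- solve(e$vectors)
  S <- e$vectors %*% (Vinv / sqrt(e$values))
  if (max(abs(Im(S))) > 1e-8)
    stop("matrix square root of (I - H)^{-1} is not real for cluster ",
         id, call. = FALSE)
  Re(S)
}

#' Covariance of the coefficient estimates under a named estimator
#'
#' Implements the unadjusted sandwich estimator (`"SA"`) and the eleven
#' small-sample adjustments: MacKinnon-White (`"MK"`), Kauermann-Carroll
#' (`"KC"`), Mancl-DeRouen (`"MD"`), Fay-Graubard (`"FG"`), Pan (`"PA"`),
#' Gosho (`"GS"`), Morel (`"MB"`), Wang-Long (`"WL"`),
#' Westgate-Burchett (`"WB"`), Ford-Westgate (`"FW"`) and Fan (`"FZ"`).
#'
#' @param fit a fitted `smallgee` object (or any list with elements `cq`,
#'   `Phi`, and cluster count `K`).
#' @param method estimator name, one of `"SA"`, `"MK"`, `"KC"`, `"MD"`,
#'   `"FG"`, `"PA"`, `"GS"`, `"MB"`, `"WL"`, `"WB"`, `"FW"`, `"FZ"`.
#' @param delta truncation bound for the Fay-Graubard diagonal inflation
#'   (0.75 by default).
#' @return object of class `"gee_covariance"`: list with `method`, `covb`
#'   (p x p), `se` (p-vector; `NaN` with a warning where a negative
#'   diagonal occurs, possible for `"FZ"`).
#' @export
estimate_covariance <- function(fit, method = "SA", delta = 0.75) {
  method <- match.arg(method, SE_METHODS)
  cq <- fit$cq
  Phi <- fit$Phi
  K <- length(cq)
  p <- ncol(Phi)
  Phi_inv <- chol2inv(chol(Phi))

  meat_from <- function(transform) {
    meat <- matrix(0, p, p)
    for (q in cq) {
      v <- drop(q$B %*% transform(q))
      meat <- meat + tcrossprod(v)
    }
    meat
  }

  ## pooled occasion-aligned middle matrix for PA/GS/WL/WB
  pooled_middle <- function(resid_transform) {
    Tn <- max(unlist(lapply(cq, `[[`, "occ")))
    Lam <- matrix(0, Tn, Tn)
    for (q in cq) {
      z <- resid_transform(q) / sqrt(q$a)
      Lam[q$occ, q$occ] <- Lam[q$occ, q$occ] + tcrossprod(z)
    }
    Lam / K
  }
  sandwich_pooled <- function(Lam) {
    meat <- matrix(0, p, p)
    for (q in cq) {
      s <- sqrt(q$a)
      mid <- t(Lam[q$occ, q$occ, drop = FALSE] * s) * s  # A^1/2 Lam A^1/2
      meat <- meat + q$B %*% mid %*% t(q$B)
    }
    meat
  }

  covb <- switch(method,
    SA = Phi_inv %*% meat_from(function(q) q$eps) %*% Phi_inv,
    MK = {
      sa <- Phi_inv %*% meat_from(function(q) q$eps) %*% Phi_inv
      K / (K - p) * sa
    },
    KC = {
      Hd <- leverage(cq, Phi_inv)
      i <- 0
      Phi_inv %*% meat_from(function(q) {
        i <<- i + 1
        inv_sqrt_IH(Hd[[i]], q$id) %*% q$eps
      }) %*% Phi_inv
    },
    MD = {
      Hd <- leverage(cq, Phi_inv)
      i <- 0
      Phi_inv %*% meat_from(function(q) {
        i <<- i + 1
        solve(diag(length(q$eps)) - Hd[[i]], q$eps)
      }) %*% Phi_inv
    },
    FG = {
      meat <- matrix(0, p, p)
      for (q in cq) {
        N <- q$B %*% q$D %*% Phi_inv
        f <- (1 - pmin(delta, diag(N)))^(-1/2)
        v <- f * drop(q$B %*% q$eps)
        meat <- meat + tcrossprod(v)
      }
      Phi_inv %*% meat %*% Phi_inv
    },
    PA = Phi_inv %*%
      sandwich_pooled(pooled_middle(function(q) q$eps)) %*% Phi_inv,
    GS = {
      pa <- Phi_inv %*%
        sandwich_pooled(pooled_middle(function(q) q$eps)) %*% Phi_inv
      K / (K - p) * pa
    },
    MB = {
      d <- vapply(cq, function(q) drop(q$B %*% q$eps), numeric(p))
      d <- matrix(d, nrow = p)
      dbar <- rowMeans(d)
      dc <- d - dbar
      n_tot <- sum(vapply(cq, function(q) length(q$eps), 0))
      Psi <- (n_tot - 1) / (n_tot - p) * K / (K - 1) * tcrossprod(dc)
      g1 <- min(0.5, p / (K - p))
      g2 <- max(1, sum(diag(Phi_inv %*% Psi)) / p)
      Phi_inv %*% (Psi + g1 * g2 * Phi) %*% Phi_inv
    },
    WL = {
      Hd <- leverage(cq, Phi_inv)
      i <- 0
      Lam <- pooled_middle(function(q) {
        i <<- i + 1
        solve(diag(length(q$eps)) - Hd[[i]], q$eps)
      })
      Phi_inv %*% sandwich_pooled(Lam) %*% Phi_inv
    },
    WB = {
      Hd <- leverage(cq, Phi_inv)
      i <- 0
      Lam <- pooled_middle(function(q) {
        i <<- i + 1
        inv_sqrt_IH(Hd[[i]], q$id) %*% q$eps
      })
      Phi_inv %*% sandwich_pooled(Lam) %*% Phi_inv
    },
    FW = {
      kc <- estimate_covariance(fit, "KC", delta)$covb
      md <- estimate_covariance(fit, "MD", delta)$covb
      (kc + md) / 2
    },
    FZ = {
      Hall <- leverage(cq, Phi_inv, "all")
      meat <- matrix(0, p, p)
      for (i in seq_len(K)) {
        q <- cq[[i]]
        mid <- tcrossprod(q$eps)
        for (j in seq_len(K)) {
          if (j == i) next
          Hij <- Hall[[i]][[j]]
          mid <- mid - Hij %*% tcrossprod(cq[[j]]$eps) %*% t(Hij)
        }
        IHinv <- solve(diag(length(q$eps)) - Hall[[i]][[i]])
        core <- IHinv %*% mid %*% t(IHinv)
        meat <- meat + q$B %*% core %*% t(q$B)
      }
      Phi_inv %*% meat %*% Phi_inv
    })

  covb <- (covb + t(covb)) / 2
  dg <- diag(covb)
  se <- sqrt(pmax(dg, 0))
  neg <- dg < -1e-12 * max(abs(dg), 1)  # tolerate roundoff-scale negatives
  if (any(neg)) {
    warning("negative variance estimate under method ", method,
            " for coefficient(s) ",
            paste(fit$xnames[neg], collapse = ", "),
            "; SE set to NaN", call. = FALSE)
    se[neg] <- NaN
  }
  names(se) <- colnames(covb) <- rownames(covb) <-
    if (!is.null(fit$xnames)) fit$xnames else colnames(cq[[1]]$X)
  structure(list(method = method, covb = covb, se = se),
            class = "gee_covariance")
}

#' @export
print.gee_covariance <- function(x, ...) {
  cat("Covariance estimator:", x$method, "\n")
  print(x$covb, ...)
  invisible(x)
}
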