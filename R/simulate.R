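## Correlated-binary data generation by latent-normal thresholding
## (Emrich-Piedmonte construction): marginal probabilities follow the
## logistic model exactly, and the latent pairwise correlation is solved
## numerically so the *binary-scale* correlation matches the target.

## P(Z1 <= h, Z2 <= k) for standard bivariate normal with correlation r,
## by one-dimensional quadrature.
pbivariate_normal <- function(h, k, r) {
  if (abs(r) < 1e-14) return(stats::pnorm(h) * stats::pnorm(k))
  s <- sqrt(1 - r^2)
  stats::integrate(function(z) stats::dnorm(z) *
                     stats::pnorm((k - r * z) / s),
                   -Inf, h, rel.tol = 1e-12, abs.tol = 1e-14)$value
}

## Attainable (Frechet) range of the correlation between Bernoulli(p1)
## and Bernoulli(p2).
frechet_range <- function(p1, p2) {
  s <- sqrt(p1 * (1 - p1) * p2 * (1 - p2))
  lo <- (max(0, p1 + p2 - 1) - p1 * p2) / s
  hi <- (min(p1, p2) - p1 * p2) / s
  c(lo, hi)
}

latent_cache <- new.env(parent = emptyenv())

## Latent normal correlation giving binary-scale correlation rho between
## Bernoulli(p1) and Bernoulli(p2); bisection to 1e-10.
solve_latent_corr <- function(p1, p2, rho) {
  if (abs(rho) < 1e-14) return(0)
  key <- sprintf("%.10f|%.10f|%.10f", p1, p2, rho)
  hit <- latent_cache[[key]]
  if (!is.null(hit)) return(hit)
  fr <- frechet_range(p1, p2)
  if (rho < fr[1] + 1e-12 || rho > fr[2] - 1e-12)
    stop(sprintf(
      "target correlation %.4f infeasible for margins (%.4f, %.4f); attainable range is (%.4f, %.4f)",
      rho, p1, p2, fr[1], fr[2]), call. = FALSE)
  target <- p1 * p2 + rho * sqrt(p1 * (1 - p1) * p2 * (1 - p2))
  z1 <- stats::qnorm(p1); z2 <- stats::qnorm(p2)
  f <- function(r) pbivariate_normal(z1, z2, r) - target
  lo <- -1 + 1e-9; hi <- 1 - 1e-9
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
    if (hi - lo < 1e-10) break
  }
  r <- (lo + hi) / 2
  latent_cache[[key]] <- r
  r
}

## Draw one cluster's binary vector with marginals mu and target binary
## correlation matrix Rho.
draw_correlated_binary <- function(mu, Rho) {
  n <- length(mu)
  if (n == 1L) return(as.numeric(stats::runif(1) < mu))
  L <- matrix(0, n, n)
  for (s in seq_len(n - 1)) for (t in (s + 1):n)
    L[s, t] <- L[t, s] <- solve_latent_corr(mu[s], mu[t], Rho[s, t])
  diag(L) <- 1
  ch <- tryCatch(chol(L), error = function(e)
    stop("implied latent correlation matrix is not positive definite; ",
         "lower the target correlation", call. = FALSE))
  z <- drop(crossprod(ch, stats::rnorm(n)))
  as.numeric(z <= stats::qnorm(mu))
}

#' Simulate clustered binary data with a known marginal logistic model
#'
#' Generates `K` clusters of longitudinal binary outcomes whose marginal
#' probabilities satisfy \eqn{\mathrm{logit}\,\mu_{it} = x_{it}^\top\beta}
#' exactly and whose within-cluster outcome correlation (on the binary
#' scale) follows an exchangeable or AR(1) pattern with parameter `rho`,
#' via a latent-normal threshold construction. Default covariates are a
#' cluster-level binary indicator plus, when `beta` has more than two
#' elements, occasion-level binary covariates; alternatively supply
#' `xfun`.
#'
#' @param K number of clusters.
#' @param n cluster size: a single integer or a length-`K` vector.
#' @param beta true coefficient vector; the first element is the
#'   intercept.
#' @param rho target within-cluster binary-scale correlation.
#' @param corstr `"exchangeable"` or `"ar1"` outcome correlation pattern.
#' @param seed integer seed; the seed fully determines the output
#'   (R's default Mersenne-Twister stream).
#' @param xfun optional covariate generator: `function(K, n_i)` returning
#'   a matrix with `sum(n_i)` rows and `length(beta) - 1` columns.
#' @return data frame with columns `id`, `time`, `y` and covariates
#'   `x1`, `x2`, ...
#' @export
simulate_binary_clusters <- function(K, n = 4, beta, rho = 0,
                                     corstr = c("exchangeable", "ar1"),
                                     seed = NULL, xfun = NULL) {
  corstr <- match.arg(corstr)
  if (!is.null(seed)) set.seed(seed)
  ni <- if (length(n) == 1L) rep.int(n, K) else {
    stopifnot(length(n) == K); as.integer(n)
  }
  p <- length(beta)

  X <- if (!is.null(xfun)) {
    x <- as.matrix(xfun(K, ni))
    stopifnot(nrow(x) == sum(ni), ncol(x) == p - 1)
    x
  } else if (p == 1L) {
    matrix(numeric(0), sum(ni), 0)
  } else {
    x1 <- rep(stats::rbinom(K, 1, 0.5), times = ni)     # cluster-level
    more <- if (p > 2L)
      matrix(stats::rbinom(sum(ni) * (p - 2L), 1, 0.5), ncol = p - 2L)
    else NULL
    cbind(x1, more)
  }
  colnames(X) <- if (p > 1L) paste0("x", seq_len(p - 1L)) else NULL

  out <- vector("list", K)
  row0 <- 0L
  for (i in seq_len(K)) {
    idx <- row0 + seq_len(ni[i]); row0 <- row0 + ni[i]
    eta <- beta[1] + if (p > 1L) drop(X[idx, , drop = FALSE] %*%
                                        beta[-1]) else 0
    mu <- stats::plogis(eta)
    Rho <- if (corstr == "exchangeable") {
      M <- matrix(rho, ni[i], ni[i]); diag(M) <- 1; M
    } else rho^abs(outer(seq_len(ni[i]), seq_len(ni[i]), "-"))
    y <- draw_correlated_binary(mu, Rho)
    out[[i]] <- data.frame(id = i, time = seq_len(ni[i]), y = y,
                           X[idx, , drop = FALSE], row.names = NULL)
  }
  do.call(rbind, out)
}

#' Synthetic dataset shaped like the classic wheeze study
#'
#' Sixteen children observed at ages 9-12 with columns `ID`, `Wheeze`,
#' `City` (binary, cluster-level), `Age` and `Smoke` (0/1/2,
#' occasion-level). The outcome is generated from a marginal logistic
#' model with an AR(1) within-child correlation of 0.3 and coefficients
#' chosen to mimic a modest city effect and wheeze risk declining with
#' age. Values are synthetic; the schema matches the real dataset so both
#' flow through the same reader path.
#'
#' @param seed integer seed.
#' @return 64-row data frame.
#' @export
wheeze_like_fixture <- function(seed = 1) {
  set.seed(seed)
  K <- 16; ages <- 9:12
  city <- rep(rep(0:1, each = 8), each = 4)
  smoke <- sample(0:2, K * 4, replace = TRUE, prob = c(0.5, 0.3, 0.2))
  age <- rep(ages, K)
  beta <- c(-0.2, 0.4, -0.3, -0.6, -0.9)  # intercept, City, Age 10/11/12
  agef <- factor(age)
  Xd <- cbind(city, stats::model.matrix(~ agef)[, -1])
  out <- numeric(0)
  for (i in seq_len(K)) {
    idx <- (i - 1) * 4 + 1:4
    mu <- stats::plogis(beta[1] + drop(Xd[idx, ] %*% beta[-1]))
    Rho <- 0.3^abs(outer(1:4, 1:4, "-"))
    out <- c(out, draw_correlated_binary(mu, Rho))
  }
  data.frame(ID = rep(seq_len(K), each = 4), Wheeze = out,
             City = city, Age = age, Smoke = smoke)
}

#' Small simulation study over methods and covariance estimators
#'
#' Repeatedly generates data with [simulate_binary_clusters()], fits the
#' requested estimating methods, evaluates the requested covariance
#' estimators, and summarizes per combination and coefficient: mean bias,
#' empirical SD of the estimates, mean standard error, and coverage of the
#' nominal-level Wald interval. Replicates whose fit fails are counted and
#' excluded.
#'
#' @param K,n,beta,rho,corstr,xfun passed to [simulate_binary_clusters()].
#' @param reps number of replicates.
#' @param methods estimating methods to fit.
#' @param estimators covariance estimators to evaluate.
#' @param working working correlation structure used for fitting
#'   (defaults to the generating structure).
#' @param conf.level nominal coverage level.
#' @param scale.fix fix the scale parameter at 1 during fitting.
#' @param seed integer seed.
#' @return object of class `"gee_simstudy"`: list with `summary` (data
#'   frame: beta.method, SE.method, term, true, bias, emp.sd, mean.se,
#'   coverage, n.ok) and `failures` (count of failed replicates).
#' @export
simulation_study <- function(K, n = 4, beta, rho = 0,
                             corstr = c("exchangeable", "ar1"),
                             reps = 100, methods = "GEE",
                             estimators = "SA", working = NULL,
                             conf.level = 0.95, scale.fix = FALSE,
                             seed = 1, xfun = NULL) {
  corstr <- match.arg(corstr)
  if (is.null(working)) working <- corstr
  set.seed(seed)
  p <- length(beta)
  zc <- stats::qnorm(1 - (1 - conf.level) / 2)
  form <- if (p > 1L)
    stats::as.formula(paste("y ~", paste0("x", seq_len(p - 1L),
                                          collapse = " + ")))
  else y ~ 1

  est_rec <- list(); se_rec <- list(); cov_rec <- list()
  failures <- 0L
  for (r in seq_len(reps)) {
    d <- simulate_binary_clusters(K, n, beta, rho, corstr, seed = NULL,
                                  xfun = xfun)
    bl <- tryCatch(build_clusters(form, d, "id", "time"),
                   error = function(e) NULL)
    if (is.null(bl)) { failures <- failures + 1L; next }
    for (m in methods) {
      fit <- tryCatch(suppressWarnings(
        fit_engine(bl, working, m, NULL, 50, 1e-5, scale.fix)),
        error = function(e) NULL)
      if (is.null(fit) || !fit$converged) { failures <- failures + 1L; next }
      est_rec[[length(est_rec) + 1L]] <-
        data.frame(rep = r, beta.method = m, term = seq_len(p),
                   estimate = as.numeric(fit$beta))
      for (sm in estimators) {
        cov <- tryCatch(suppressWarnings(estimate_covariance(fit, sm)),
                        error = function(e) NULL)
        if (is.null(cov)) next
        se_rec[[length(se_rec) + 1L]] <-
          data.frame(rep = r, beta.method = m, SE.method = sm,
                     term = seq_len(p), se = as.numeric(cov$se),
                     covered = as.numeric(
                       beta >= fit$beta - zc * cov$se &
                       beta <= fit$beta + zc * cov$se))
      }
    }
  }

  est <- do.call(rbind, est_rec)
  ses <- do.call(rbind, se_rec)
  rows <- list()
  for (m in unique(est$beta.method)) for (tm in seq_len(p)) {
    e <- est[est$beta.method == m & est$term == tm, "estimate"]
    for (sm in estimators) {
      s <- ses[ses$beta.method == m & ses$SE.method == sm &
                 ses$term == tm, ]
      rows[[length(rows) + 1L]] <- data.frame(
        beta.method = m, SE.method = sm, term = paste0("beta", tm - 1L),
        true = beta[tm], bias = mean(e) - beta[tm],
        emp.sd = stats::sd(e),
        mean.se = mean(s$se, na.rm = TRUE),
        coverage = mean(s$covered, na.rm = TRUE),
        n.ok = length(e))
    }
  }
  structure(list(summary = do.call(rbind, rows), failures = failures,
                 reps = reps, K = K, rho = rho, corstr = corstr),
            class = "gee_simstudy")
}

#' @export
print.gee_simstudy <- function(x, digits = 4L, ...) {
  cat("Simulation study: K =", x$K, ", reps =", x$reps, ", rho =", x$rho,
      "(", x$corstr, ")\n")
  if (x$failures > 0) cat("Failed replicates:", x$failures, "\n")
  df <- x$summary
  for (col in c("bias", "emp.sd", "mean.se", "coverage"))
    df[[col]] <- round(df[[col]], digits)
  print(df, row.names = FALSE)
  invisible(x)
}
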