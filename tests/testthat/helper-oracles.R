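# Independent numeric oracles and small fixtures. These deliberately avoid
# the package's own solution paths: root finding via numeric-Jacobian
# Newton on the score evaluated pointwise, Firth logistic via direct
# penalized-likelihood maximization, robust covariances via a
# per-observation HC implementation.

# Generic Newton root-finder with a numeric Jacobian; f: p-vector -> p-vector.
newton_root <- function(f, start, tol = 1e-12, maxit = 200) {
  x <- start
  for (i in seq_len(maxit)) {
    fx <- f(x)
    J <- num_jacobian(f, x)
    step <- solve(J, fx)
    x <- x - step
    if (max(abs(step)) < tol) break
  }
  x
}

num_jacobian <- function(f, x, h = 1e-6) {
  p <- length(x)
  f0 <- f(x)
  J <- matrix(0, length(f0), p)
  for (j in seq_len(p)) {
    e <- numeric(p); e[j] <- h
    J[, j] <- (f(x + e) - f(x - e)) / (2 * h)
  }
  J
}

central_diff <- function(f, x, j, h = 1e-5) {
  e <- numeric(length(x)); e[j] <- h
  (f(x + e) - f(x - e)) / (2 * h)
}

# Firth logistic regression by direct maximization of the penalized
# log-likelihood l(beta) + 0.5 * log det(X'WX), via optim.
firth_oracle <- function(X, y) {
  obj <- function(beta) {
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    w <- mu * (1 - mu)
    ll <- sum(y * eta - log1p(exp(eta)))
    -(ll + 0.5 * determinant(crossprod(X, X * w))$modulus)
  }
  optim(numeric(ncol(X)), obj, method = "BFGS",
        control = list(maxit = 1000, reltol = 1e-14))$par
}

# HC-family robust covariances for logistic scores on independent
# observations: bread = (X'WX)^-1, meat from per-observation residuals,
# with HC2/HC3 leverage inflation using the weighted hat diagonal.
hc_oracle <- function(X, y, beta, type = c("HC0", "HC2", "HC3")) {
  type <- match.arg(type)
  mu <- plogis(drop(X %*% beta))
  w <- mu * (1 - mu)
  info <- crossprod(X, X * w)
  bread <- solve(info)
  h <- rowSums((X %*% bread) * (X * w))
  r <- y - mu
  infl <- switch(type, HC0 = 1, HC2 = 1 / sqrt(1 - h), HC3 = 1 / (1 - h))
  sc <- X * (r * infl)
  bread %*% crossprod(sc) %*% bread
}

# Deterministic small clustered fixture (binary y, two covariates) used
# across oracle tests; constructed arithmetically so no RNG is involved.
toy_data <- function(K = 5, n = 2) {
  rows <- K * n
  data.frame(id = rep(seq_len(K), each = n), time = rep(seq_len(n), K),
             y = rep(c(1, 0, 0, 1, 1, 0), length.out = rows),
             x1 = rep(c(0, 1), length.out = rows),
             x2 = round(sin(seq_len(rows)), 3))
}

toy_blocks <- function(K = 5, n = 2) {
  build_clusters(y ~ x1 + x2, toy_data(K, n), "id", "time")
}

# Score evaluated on hand-built blocks with arbitrary (possibly
# non-binary) pseudo-outcomes: needed for finite-difference cumulant
# oracles where Y is frozen at fitted means.
blocks_with_y <- function(bl, ynew) {
  at <- 0L
  bl$blocks <- lapply(bl$blocks, function(b) {
    idx <- at + seq_along(b$y); at <<- at + length(b$y)
    b$y <- ynew[idx]; b
  })
  bl
}

wheeze_path <- function() {
  system.file("extdata", "wheeze.csv", package = "smallgee")
}
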