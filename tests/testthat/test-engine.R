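test_that("logit derivatives are exact at 0, saturate safely, match FD", {
  ld <- logit_derivatives(0)
  expect_equal(unlist(ld), c(mu = 0.5, d1 = 0.25, d2 = 0, d3 = -0.125))
  for (eta in c(-30, 30)) {
    ld <- logit_derivatives(eta)
    expect_lt(abs(ld$mu - (eta > 0)), 1e-12)
    expect_true(ld$d1 >= 0 && ld$d1 < 1e-12)
    expect_true(all(is.finite(unlist(ld))))
  }
  set.seed(3)
  eta <- rnorm(25, sd = 2)
  h <- 1e-5
  mu <- function(e) plogis(e)
  d1 <- function(e) logit_derivatives(e)$d1
  d2 <- function(e) logit_derivatives(e)$d2
  expect_equal(logit_derivatives(eta)$d1,
               (mu(eta + h) - mu(eta - h)) / (2 * h), tolerance = 1e-6)
  expect_equal(logit_derivatives(eta)$d2,
               (d1(eta + h) - d1(eta - h)) / (2 * h), tolerance = 1e-6)
  expect_equal(logit_derivatives(eta)$d3,
               (d2(eta + h) - d2(eta - h)) / (2 * h), tolerance = 1e-6)
})

test_that("score and information have their closed-form small cases", {
  # one cluster, n = 1, x = 1, y = 1, beta = 0
  bl <- build_clusters(y ~ 1, data.frame(y = 1, g = 1), "g")
  si <- score_and_information(bl, beta = 0)
  expect_equal(si$U, 0.5, ignore_attr = TRUE)
  expect_equal(drop(si$Phi), 0.25, ignore_attr = TRUE)

  # at the ordinary logistic MLE with independence the score vanishes
  set.seed(5)
  d <- simulate_binary_clusters(K = 12, n = 3, beta = c(-0.3, 0.8),
                                rho = 0, seed = 5)
  bl <- build_clusters(y ~ x1, d, "id", "time")
  X <- do.call(rbind, lapply(bl$blocks, `[[`, "X"))
  y <- unlist(lapply(bl$blocks, `[[`, "y"))
  mle <- glm.fit(X, y, family = binomial())$coefficients
  si <- score_and_information(bl, mle)
  expect_lt(max(abs(si$U)), 1e-8)

  # information matches a brute-force per-cluster summation
  si2 <- score_and_information(bl, c(0.2, -0.4), corstr = "exchangeable",
                               alpha = 0.25, phi = 1.4)
  brute <- matrix(0, 2, 2)
  for (b in bl$blocks) {
    mu <- plogis(drop(b$X %*% c(0.2, -0.4)))
    A <- diag(mu * (1 - mu))
    R <- build_corr_matrix("exchangeable", 0.25, b$occ, 3)
    V <- 1.4 * sqrt(A) %*% R %*% sqrt(A)
    D <- A %*% b$X
    brute <- brute + t(D) %*% solve(V) %*% D
  }
  expect_equal(si2$Phi, brute, tolerance = 1e-10)
})

test_that("GEE with independence and fixed scale equals ordinary logistic", {
  d <- simulate_binary_clusters(K = 25, n = 4, beta = c(0.3, -0.7),
                                rho = 0.2, seed = 9)
  f <- smallgee(y ~ x1, d, "id", "time", corstr = "independence",
                beta.method = "GEE", scale.fix = TRUE)
  X <- model.matrix(f)
  y <- d$y
  mle <- glm.fit(X, y, family = binomial())$coefficients
  expect_equal(unname(coef(f)), unname(mle), tolerance = 1e-6)
})

test_that("GEE solves the estimating equation found by an independent root-finder", {
  d <- simulate_binary_clusters(K = 3, n = 4, beta = c(0, 0.5),
                                rho = 0.3, corstr = "ar1", seed = 21)
  bl <- build_clusters(y ~ x1, d, "id", "time")
  f <- smallgee(y ~ x1, d, "id", "time", corstr = "ar1",
                beta.method = "GEE", SE.method = "SA", tol = 1e-10)
  # oracle: Newton with numeric Jacobian on U(beta) at the converged
  # nuisance values, started elsewhere
  root <- newton_root(function(b)
    score_and_information(bl, b, "ar1", f$alpha, f$phi)$U,
    start = c(0.1, 0.1))
  # the fit interleaves nuisance updates, so re-solve at its (alpha, phi)
  expect_equal(unname(coef(f)), root, tolerance = 1e-8)
  expect_lt(max(abs(f$U)), 1e-6)
})

test_that("fits are invariant to cluster order, labels and duplication", {
  d <- simulate_binary_clusters(K = 15, n = 3, beta = c(-0.2, 0.6),
                                rho = 0.25, seed = 13)
  f1 <- smallgee(y ~ x1, d, "id", "time", corstr = "exchangeable",
                 beta.method = "GEE", SE.method = "SA")
  # permute clusters and relabel ids
  perm <- sample(unique(d$id))
  d2 <- do.call(rbind, lapply(seq_along(perm), function(k) {
    b <- d[d$id == perm[k], ]; b$id <- paste0("c", k); b
  }))
  f2 <- smallgee(y ~ x1, d2, "id", "time", corstr = "exchangeable",
                 beta.method = "GEE", SE.method = "SA")
  expect_equal(coef(f1), coef(f2), tolerance = 1e-10)
  expect_equal(f1$alpha, f2$alpha, tolerance = 1e-10)

  # duplicating every cluster leaves the estimate unchanged
  d3 <- rbind(d, transform(d, id = id + 1000))
  f3 <- smallgee(y ~ x1, d3, "id", "time", corstr = "exchangeable",
                 beta.method = "GEE", SE.method = "SA")
  expect_equal(unname(coef(f1)), unname(coef(f3)), tolerance = 1e-6)
})

test_that("non-convergence warns and is flagged, not thrown", {
  # x2 varies within clusters, so the exchangeable solve moves away from
  # the independence start and cannot finish in one iteration
  d <- simulate_binary_clusters(K = 10, n = 4, beta = c(0.2, 0.4, -0.6),
                                rho = 0.2, seed = 17)
  expect_warning(
    f <- smallgee(y ~ x1 + x2, d, "id", "time", corstr = "exchangeable",
                  beta.method = "GEE", maxitr = 1, tol = 1e-12),
    "did not converge")
  expect_false(f$converged)
  expect_s3_class(f, "smallgee")
})
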