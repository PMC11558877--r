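# The cumulant plug-ins and the bias contraction. Finite-difference
# oracles freeze the outcomes at the fitted means so that the analytic
# "expectation" tensors can be differentiated directly.

# Fixed evaluation point for the cumulant identities and oracles; the
# plug-in relations hold at any beta with the nuisance held fixed, so no
# converged fit is needed.
toy_eval <- function() {
  bl <- toy_blocks(K = 5, n = 2)
  beta <- c(0.1, -0.2, 0.3)
  si <- score_and_information(bl, beta, "exchangeable", alpha = 0.3,
                              phi = 1.2)
  list(bl = bl, beta = beta, alpha = 0.3, phi = 1.2, si = si)
}

test_that("kappa_rs and kappa_r,s reduce to the known identities", {
  tv <- toy_eval()
  cum <- compute_cumulants(tv$si$cq, tv$si$Phi)
  # canonical-link identity: E[dU/dbeta] = -Phi
  expect_equal(cum$k_rs, -tv$si$Phi, tolerance = 1e-10)
  expect_equal(cum$k_inv %*% cum$k_rs, diag(3), tolerance = 1e-8,
               ignore_attr = TRUE)
  # kappa_{r,s} is the sandwich meat
  meat <- Reduce(`+`, lapply(tv$si$cq, function(q)
    tcrossprod(drop(q$B %*% q$eps))))
  expect_equal(cum$k_r_s, meat, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(cum$k_r_s, t(cum$k_r_s), ignore_attr = TRUE)
})

test_that("cumulant tensors match central finite differences", {
  tv <- toy_eval()
  bl <- tv$bl; beta <- tv$beta; p <- 3
  mu_hat <- unlist(lapply(tv$si$cq, `[[`, "mu"))
  bl_mu <- blocks_with_y(bl, mu_hat)
  # expectation-type score: U(beta) with Y frozen at mu(beta0)
  Ubar <- function(b) score_and_information(bl_mu, b, "exchangeable",
                                            tv$alpha, tv$phi)$U
  Phi_of <- function(b) score_and_information(bl, b, "exchangeable",
                                              tv$alpha, tv$phi)$Phi
  cum <- compute_cumulants(tv$si$cq, tv$si$Phi)
  # first derivative of Ubar is kappa_rs
  for (s in 1:p) {
    fd <- central_diff(Ubar, beta, s, h = 1e-5)
    expect_equal(cum$k_rs[, s], fd, tolerance = 1e-4,
                 ignore_attr = TRUE)
  }
  # second derivatives give kappa_rsu
  for (s in 1:p) for (u in 1:p) {
    fd2 <- central_diff(function(b) central_diff(Ubar, b, s, h = 1e-4),
                        beta, u, h = 1e-4)
    expect_equal(cum$k_rsu[, s, u], fd2, tolerance = 1e-3,
                 ignore_attr = TRUE)
  }
  # derivative of the information gives kappa_rs^(u) = -dPhi/dbeta_u
  for (u in 1:p) {
    fdP <- central_diff(function(b) as.vector(Phi_of(b)), beta, u,
                        h = 1e-5)
    expect_equal(as.vector(cum$k_rs_du[, , u]), -fdP, tolerance = 1e-4,
                 ignore_attr = TRUE)
  }
  # kappa_{rs,u}: empirical E[(centered dU/dbeta_s) U_u] oracle computed
  # cluster by cluster with numeric derivatives of the per-cluster score
  emp <- array(0, c(p, p, p))
  for (i in seq_along(bl$blocks)) {
    bi <- bl; bi$blocks <- bl$blocks[i]
    bi_mu <- bl_mu; bi_mu$blocks <- bl_mu$blocks[i]
    Ui <- function(bb) score_and_information(bi, bb, "exchangeable",
                                             tv$alpha, tv$phi)$U
    Ui_mu <- function(bb) score_and_information(bi_mu, bb, "exchangeable",
                                                tv$alpha, tv$phi)$U
    u_i <- Ui(beta)
    for (s in 1:p) {
      dUs <- central_diff(Ui, beta, s, h = 1e-5) -
        central_diff(Ui_mu, beta, s, h = 1e-5)
      emp[, s, ] <- emp[, s, ] + tcrossprod(dUs, u_i)
    }
  }
  expect_equal(cum$k_rs_u, emp, tolerance = 1e-4, ignore_attr = TRUE)
})

test_that("bias contraction matches a naive quadruple loop and scalar case", {
  tv <- toy_eval()
  cum <- compute_cumulants(tv$si$cq, tv$si$Phi)
  b_fast <- bias_vector(cum)
  p <- 3
  Kinv <- cum$k_inv
  b_naive <- numeric(p)
  for (r in 1:p) {
    acc <- 0
    for (s in 1:p) for (u in 1:p) for (v in 1:p) {
      inner <- cum$k_rs_u[s, u, v]
      for (k in 1:p) for (l in 1:p)
        inner <- inner - 0.5 * Kinv[k, l] * cum$k_rsu[s, v, l] *
          cum$k_r_s[u, k]
      acc <- acc + Kinv[r, s] * inner * Kinv[u, v]
    }
    b_naive[r] <- acc
  }
  expect_equal(b_fast, b_naive, tolerance = 1e-10)

  # all third-order tensors zero -> zero bias
  cum0 <- cum
  cum0$k_rsu[] <- 0; cum0$k_rs_u[] <- 0
  expect_equal(bias_vector(cum0), numeric(p))

  # p = 1 scalar reduction by hand substitution
  cum1 <- list(k_rs = matrix(-2), k_inv = matrix(-0.5),
               k_r_s = matrix(3), k_rsu = array(5, c(1, 1, 1)),
               k_rs_u = array(7, c(1, 1, 1)),
               k_rs_du = array(0, c(1, 1, 1)))
  hand <- -0.5 * (7 - 0.5 * (-0.5) * 5 * 3) * (-0.5)
  expect_equal(bias_vector(cum1), hand)

  # equivariance under permutation of coefficient indices
  pr <- c(2, 3, 1)
  cump <- list(k_rs = cum$k_rs[pr, pr], k_inv = cum$k_inv[pr, pr],
               k_r_s = cum$k_r_s[pr, pr],
               k_rsu = cum$k_rsu[pr, pr, pr],
               k_rs_u = cum$k_rs_u[pr, pr, pr],
               k_rs_du = cum$k_rs_du[pr, pr, pr])
  expect_equal(bias_vector(cump), bias_vector(cum)[pr], tolerance = 1e-10)
})

test_that("bias shrinks at rate 1/m under cluster replication", {
  d <- simulate_binary_clusters(K = 12, n = 3, beta = c(-0.4, 0.9),
                                rho = 0.25, seed = 31)
  f1 <- smallgee(y ~ x1, d, "id", "time", corstr = "exchangeable",
                 beta.method = "BCGEE", SE.method = "SA")
  m <- 10
  dm <- do.call(rbind, lapply(seq_len(m), function(k)
    transform(d, id = id + 1000 * k)))
  fm <- smallgee(y ~ x1, dm, "id", "time", corstr = "exchangeable",
                 beta.method = "BCGEE", SE.method = "SA")
  ratio <- sqrt(sum(fm$bias^2)) / sqrt(sum(f1$bias^2))
  expect_lt(abs(ratio - 1 / m), 0.1 / m)
})

test_that("the correction vanishes for many clusters", {
  d <- simulate_binary_clusters(K = 1000, n = 3, beta = c(-0.3, 0.7),
                                rho = 0.2, seed = 37)
  fg <- smallgee(y ~ x1, d, "id", "time", corstr = "exchangeable",
                 beta.method = "GEE", SE.method = "SA")
  fb <- smallgee(y ~ x1, d, "id", "time", corstr = "exchangeable",
                 beta.method = "BCGEE", SE.method = "SA")
  expect_lt(max(abs(coef(fb) - coef(fg))), 0.01)
})

test_that("the wheeze example reproduces the published corrected estimate", {
  w <- wheeze_data()
  f <- smallgee(Wheeze ~ City + factor(Age), w, "ID", "Age",
                corstr = "ar1", beta.method = "BCGEE", SE.method = "SA")
  expect_equal(round(unname(coef(f)["City"]), 3), 0.270)
})
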