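# dense multivariate-normal log-density, the independent oracle for the
# spectral likelihood
dense_mvn_loglik <- function(V, y) {
  ch <- chol(V)
  -0.5 * (2 * sum(log(diag(ch))) +
            sum(backsolve(ch, y, transpose = TRUE)^2) +
            length(y) * log(2 * pi))
}

test_that("spectral log-likelihood equals the dense MVN log-density", {
  for (s in 1:10) {
    G <- rand_pd(12, seed = 500 + s)
    y <- grmgwas:::.with_seed(600 + s, rnorm(12))
    e <- eigen_grm(as_grm(G))
    sg2 <- 0.7; se2 <- 0.4
    expect_equal(grm_loglik(e, y, sg2, se2),
                 dense_mvn_loglik(G * sg2 + diag(12) * se2, y),
                 tolerance = 1e-8)
  }
  # G = I: any split of the total gives the iid N(0, s) likelihood
  e_id <- eigen_grm(as_grm(diag(9)))
  y <- grmgwas:::.with_seed(1, rnorm(9))
  iid <- sum(dnorm(y, 0, sqrt(1.3), log = TRUE))
  expect_equal(grm_loglik(e_id, y, 0.5, 0.8), iid, tolerance = 1e-10)
  expect_equal(grm_loglik(e_id, y, 1.0, 0.3), iid, tolerance = 1e-10)
  expect_error(grm_loglik(e_id, y, 0, 0), "non-positive")
})

test_that("profile ML matches a dense two-parameter optimizer", {
  inst <- sim_instance(31, n = 80, p = 150, h2 = 0.4, scaling = "mean_diag")
  e <- eigen_grm(inst$grm)
  fit <- fit_ml(e, inst$y)
  # oracle: direct 2-parameter optimization of the dense likelihood on the
  # same contrast space (null-data null-variance directions removed)
  yc <- inst$y - mean(inst$y)
  keep <- !(e$lambda <= 1e-8 * max(e$lambda) &
              drop(crossprod(e$U, yc))^2 <= 1e-16 * sum(yc^2))
  yt <- drop(crossprod(e$U, yc))[keep]
  lam <- e$lambda[keep]
  nll <- function(th) {
    d <- lam * exp(th[1]) + exp(th[2])
    0.5 * sum(log(d) + yt^2 / d)
  }
  o <- optim(log(c(0.5, 0.5)), nll, method = "Nelder-Mead",
             control = list(reltol = 1e-12, maxit = 5000))
  expect_equal(fit$sigma_g2, exp(o$par[1]), tolerance = 1e-4)
  expect_equal(fit$sigma_e2, exp(o$par[2]), tolerance = 1e-4)
  expect_equal(fit$h2, fit$sigma_g2 / (fit$sigma_g2 + fit$sigma_e2),
               tolerance = 1e-12)
  expect_true(is.finite(fit$loglik))
  expect_true(fit$se_g2 > 0 && fit$se_e2 > 0)
})

test_that("ML scale equivariances hold", {
  inst <- sim_instance(32, n = 60, p = 120, h2 = 0.5, scaling = "mean_diag")
  e <- eigen_grm(inst$grm)
  f1 <- fit_ml(e, inst$y, compute_se = FALSE)
  f2 <- fit_ml(e, 2 * inst$y, compute_se = FALSE)
  expect_equal(f2$sigma_g2, 4 * f1$sigma_g2, tolerance = 1e-5)
  expect_equal(f2$sigma_e2, 4 * f1$sigma_e2, tolerance = 1e-5)

  # multiplying G by k rescales sigma_g2 by 1/k at the same likelihood
  grm_k <- inst$grm; grm_k$matrix <- grm_k$matrix * 3
  f3 <- fit_ml(eigen_grm(grm_k), inst$y, compute_se = FALSE)
  expect_equal(f3$sigma_g2, f1$sigma_g2 / 3, tolerance = 1e-5)
  expect_equal(f3$loglik, f1$loglik, tolerance = 1e-6)
})

test_that("degenerate inputs are flagged", {
  e_id <- eigen_grm(as_grm(diag(10)))
  y <- grmgwas:::.with_seed(2, rnorm(10))
  expect_error(fit_ml(e_id, y), "not identifiable")
  inst <- sim_instance(33, n = 20, p = 40)
  expect_error(fit_ml(eigen_grm(inst$grm), rep(1, 20)), "zero variance")
})

test_that("removing one marker from G barely moves the variance partition", {
  inst <- sim_instance(34, n = 100, p = 2000, h2 = 0.5, scaling = "mean_diag")
  e <- eigen_grm(inst$grm)
  base <- fit_ml(e, inst$y, compute_se = FALSE)
  vc_j <- refit_with_marker_removed(e, inst$g, inst$y, 17, vc_base = base)
  expect_lt(vc_j$delta_vg, 0.01 * base$sigma_g2)

  # a monomorphic marker contributes nothing: the refit is unchanged
  vals <- inst$graw$values; vals[, 1] <- 1
  g2 <- center_markers(genotype_matrix(vals))
  grm2 <- build_grm(g2, "mean_diag")
  e2 <- eigen_grm(grm2)
  base2 <- fit_ml(e2, inst$y, compute_se = FALSE)
  vc_mono <- refit_with_marker_removed(e2, g2, inst$y, 1, vc_base = base2)
  expect_lt(vc_mono$delta_vg, 1e-8)
})
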