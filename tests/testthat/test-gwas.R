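test_that("OLS scan: exact fits, orthogonality, and monomorphic handling", {
  g <- genotype_matrix(cbind(a = c(-1, 0, 1), b = c(1, -2, 1) / 2,
                             c = c(0, 0, 0)),
                       centered = TRUE, col_means = c(1, 1, 0))
  y <- c(-2, 0, 2)
  tab <- ols_scan(g, y)
  expect_equal(tab$beta[1], 2)
  expect_equal(tab$r2[1], 1)
  expect_equal(tab$beta[2], 0)              # y orthogonal to marker b
  expect_true(is.na(tab$beta[3]))           # monomorphic: undefined row
  expect_equal(attr(tab, "n_tested"), 2L)   # excluded from Bonferroni family
  expect_equal(attr(tab, "bonferroni_threshold"), 0.05 / 2)
})

test_that("OLS matches lm() per marker including t statistics and p-values", {
  inst <- sim_instance(41, n = 35, p = 8)
  yc <- inst$y - mean(inst$y)
  tab <- ols_scan(inst$g, inst$y)
  for (j in c(1, 4, 8)) {
    fit <- summary(lm(yc ~ inst$g$values[, j] - 1))
    # lm uses n-1 residual df for the no-intercept fit, as does the scan
    expect_equal(tab$beta[j], unname(coef(fit)[1, 1]), tolerance = 1e-10)
    expect_equal(tab$se[j], unname(coef(fit)[1, 2]), tolerance = 1e-10)
    expect_equal(tab$p_value[j], unname(coef(fit)[1, 4]), tolerance = 1e-10)
  }
})

test_that("GLS with V proportional to I reproduces OLS estimates", {
  inst <- sim_instance(42, n = 30, p = 12)
  pcv <- make_phenocov(as_grm(diag(30) * 0), 0, 1)  # V = I
  gls <- gls_scan(inst$g, inst$y, pcv)
  ols <- ols_scan(inst$g, inst$y)
  expect_equal(gls$beta, ols$beta, tolerance = 1e-10)
})

test_that("marker-out GLS estimates are invariant; the scan exposes both paths", {
  inst <- sim_instance(43, n = 40, p = 120, h2 = 0.25, scaling = "mean_diag")
  pcv <- make_phenocov(inst$grm, 0.25, 0.75)
  t_in <- gls_scan(inst$g, inst$y, pcv)
  t_out <- gls_scan(inst$g, inst$y, pcv, drop_tested = TRUE)
  expect_lt(max(abs(t_in$beta - t_out$beta), na.rm = TRUE), 1e-8)
  # the corrected marker-out SE is strictly below the naive SE
  expect_true(all(t_in$se_markerout < t_in$se, na.rm = TRUE))
})

test_that("corrected marker-out variance equals its closed form and stays positive", {
  for (s in 1:100) {
    n <- 8 + (s %% 4)
    V0 <- rand_pd(n, seed = 700 + s, ridge = 1.5)
    x <- grmgwas:::.with_seed(800 + s, rnorm(n) * 0.5)
    cs <- 0.2
    # V must actually contain cs * x x'
    pcv <- make_phenocov(as_grm(V0 + cs * tcrossprod(x) - diag(n)), 1, 1)
    v17 <- markerout_variance(pcv, x, cs)
    s_j <- drop(crossprod(x, pcv$Vinv %*% x))
    expect_equal(v17, 1 / s_j - cs, tolerance = 1e-10)
    expect_gt(v17, 0)
  }
  pcv0 <- make_phenocov(as_grm(rand_pd(6, seed = 1) - diag(6)), 1, 1)
  x0 <- grmgwas:::.with_seed(3, rnorm(6))
  expect_equal(markerout_variance(pcv0, x0, 0),
               1 / drop(crossprod(x0, pcv0$Vinv %*% x0)), tolerance = 1e-12)
})

test_that("multi-marker GLS: single-column case, sandwich identity, collinearity", {
  inst <- sim_instance(44, n = 40, p = 60, h2 = 0.25, scaling = "mean_diag")
  pcv <- make_phenocov(inst$grm, 0.25, 0.75)
  gls <- gls_scan(inst$g, inst$y, pcv)
  m1 <- mmr_gls(inst$g$values[, 5, drop = FALSE], inst$y, pcv)
  expect_equal(unname(m1$beta), gls$beta[5], tolerance = 1e-10)

  Xm <- inst$g$values[, c(2, 9, 30)]
  cs <- pcv$sigma_g2 * pcv$scale_c
  mm <- mmr_gls(Xm, inst$y, pcv, c_sigma = cs)
  # sandwich form with V[m out] equals (X'V^-1 X)^-1 - I c_sigma
  Vinv <- pcv$Vinv
  Vout <- pcv$V - cs * tcrossprod(Xm)
  A <- solve(crossprod(Xm, Vinv %*% Xm))
  sand <- A %*% crossprod(Xm, Vinv %*% Vout %*% Vinv %*% Xm) %*% A
  expect_lt(max(abs(sand - mm$cov)), 1e-9)

  Xbad <- cbind(Xm, Xm[, 1] + Xm[, 2])
  expect_error(mmr_gls(Xbad, inst$y, pcv), "collinear")
})

test_that("mixed-model equations agree with GLS plus strong-arm BLUP", {
  for (s in 1:10) {
    n <- 25
    G <- rand_pd(n, seed = 900 + s, ridge = 1)
    grm <- as_grm(G)
    sg2 <- 0.6; se2 <- 0.9
    pcv <- make_phenocov(grm, sg2, se2)
    dat <- grmgwas:::.with_seed(950 + s, list(y = rnorm(n), x = rnorm(n)))
    sol <- mme_solve(matrix(dat$x), dat$y, solve(G), se2 / sg2,
                     sigma_e2 = se2)
    beta_gls <- drop(crossprod(dat$x, pcv$Vinv %*% dat$y) /
                       crossprod(dat$x, pcv$Vinv %*% dat$x))
    expect_equal(sol$beta, beta_gls, tolerance = 1e-8)
    bl <- blup_strongarm(grm, pcv, dat$y, fitted_fixed = dat$x * beta_gls)
    expect_lt(max(abs(sol$g_hat - bl$g_hat)), 1e-8)
    # c_bb * sigma_e2 is the GLS variance (x'V^-1 x)^-1
    expect_equal(sol$c_bb[1, 1] * se2,
                 drop(1 / crossprod(dat$x, pcv$Vinv %*% dat$x)),
                 tolerance = 1e-8)
  }
})

test_that("MME limits: G = I ridge form at n = 2, and lambda_g -> infinity", {
  # G = I, n = 2: beta solves OLS of y on x since V is proportional to I
  x <- c(1, -1); y <- c(2, 0)
  sol <- mme_solve(matrix(x), y, diag(2), lambda_g = 4, sigma_e2 = 1)
  expect_equal(sol$beta, sum(x * y) / sum(x^2), tolerance = 1e-10)
  # hand-solved 4x4 system for the BLUP part: g = (I + I*4)^-1 (y - x beta)
  expect_equal(sol$g_hat, (y - x * sol$beta) / 5, tolerance = 1e-10)

  inst <- sim_instance(45, n = 20, p = 30)
  G <- rand_pd(20, seed = 1000)
  big <- mme_solve(inst$g$values[, 1, drop = FALSE], inst$y, solve(G),
                   lambda_g = 1e10)
  ols <- ols_scan(inst$g, inst$y)
  expect_equal(unname(big$beta), ols$beta[1], tolerance = 1e-5)
  expect_lt(max(abs(big$g_hat)), 1e-6)
})

test_that("BLUP is invariant to removing the tested marker from G and V", {
  for (s in 1:20) {
    inst <- sim_instance(1100 + s, n = 30, p = 80, h2 = 0.5)
    pcv <- make_phenocov(inst$grm, 0.5, 0.5)
    j <- 1 + (s %% 10)
    x <- inst$g$values[, j]
    beta <- drop(crossprod(x, pcv$Vinv %*% inst$y) /
                   crossprod(x, pcv$Vinv %*% x))
    b_full <- blup_strongarm(inst$grm, pcv, inst$y, fitted_fixed = x * beta)
    grm_j <- drop_markers_grm(inst$grm, inst$g, j)
    pcv_j <- rank1_downdate_inv(pcv, x, pcv$sigma_g2 * pcv$scale_c)
    b_out <- blup_strongarm(grm_j, pcv_j, inst$y, fitted_fixed = x * beta)
    expect_lt(max(abs(b_full$g_hat - b_out$g_hat)), 1e-8)
  }
  # sigma_g2 = 0 gives a null BLUP
  inst <- sim_instance(46, n = 15, p = 20)
  pcv0 <- make_phenocov(inst$grm, 0, 1)
  expect_equal(unname(blup_strongarm(inst$grm, pcv0, inst$y)$g_hat),
               rep(0, 15))
})

test_that("whitening turns GLS into OLS with matching standard errors", {
  inst <- sim_instance(47, n = 30, p = 40, h2 = 0.25, scaling = "mean_diag")
  pcv <- make_phenocov(inst$grm, 0.25, 0.75)
  wh <- whiten_gls(inst$g, inst$y, pcv)
  gls <- gls_scan(inst$g, inst$y, pcv)
  yc <- inst$y - mean(inst$y)
  ys <- drop(wh$W %*% yc)
  for (j in c(1, 7, 20)) {
    xs <- wh$X_star[, j]
    expect_equal(sum(xs * ys) / sum(xs^2), gls$beta[j], tolerance = 1e-10)
    # whitened residuals have unit variance by construction, so the OLS SE
    # with known sigma = 1 equals the GLS standard error
    expect_equal(sqrt(1 / sum(xs^2)), gls$se[j], tolerance = 1e-10)
  }
  pcv_id <- make_phenocov(as_grm(diag(30) * 0), 0, 1)
  wh_id <- whiten_gls(inst$g, inst$y, pcv_id)
  expect_lt(max(abs(wh_id$X_star - inst$g$values)), 1e-10)
})

test_that("single-marker variance follows the frequency-effect formula", {
  expect_equal(smv(0, 3), 0)
  expect_equal(smv(0.5, 1), 0.5)
  expect_equal(smv(0.5, 1, inbred = TRUE), 0.25)
  expect_equal(smv(c(0.1, 0.3), c(2, -1)), 2 * c(0.1, 0.3) * c(0.9, 0.7) * c(4, 1))
  expect_error(smv(1.2, 1), "\\[0, 1\\]")
})

test_that("PC-adjusted scan: no-PC case collapses to GLS; fixed-vc modes coincide", {
  inst <- sim_instance(48, n = 60, p = 100, h2 = 0.5, n_subpops = 2,
                       divergence = 0.4, scaling = "mean_diag")
  e <- eigen_grm(inst$grm)
  vc <- list(sigma_g2 = 0.5, sigma_e2 = 0.5)
  pcv <- make_phenocov(inst$grm, 0.5, 0.5)
  t0 <- pc_adjusted_scan(inst$g, inst$y, e, 0, vc)
  tg <- gls_scan(inst$g, inst$y, pcv)
  expect_equal(t0$beta, tg$beta, tolerance = 1e-10)

  # at fixed variance components the discounted PC term W B W' lies in the
  # fixed design's span, so (W'V2^-1 W)^-1 = (W'V^-1 W)^-1 - B: the point
  # estimates are identical across modes, and because B has a zero entry in
  # the marker position, so is the marker's standard error — the same
  # algebra as the marker-out invariance
  tk <- pc_adjusted_scan(inst$g, inst$y, e, 2, vc, mode = "keep_G")
  tr <- pc_adjusted_scan(inst$g, inst$y, e, 2, vc, mode = "remove_from_G")
  expect_lt(max(abs(tk$beta - tr$beta), na.rm = TRUE), 1e-8)
  expect_lt(max(abs(tk$se - tr$se), na.rm = TRUE), 1e-8)
  expect_error(pc_adjusted_scan(inst$g, inst$y, e, 60, vc), "smaller than")
})
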