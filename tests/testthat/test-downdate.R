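test_that("rank-one downdate: hand check, no-op, and direct-inversion oracle", {
  pc <- make_phenocov(as_grm(diag(c(1, 1))), 1, 1)  # V = diag(2, 2)
  out <- rank1_downdate_inv(pc, c(1, 0), 1)
  expect_equal(unname(out$Vinv), diag(c(1, 0.5)), tolerance = 1e-12)

  V0 <- rand_pd(8, seed = 1)
  pc0 <- make_phenocov(as_grm(V0 - diag(8) * 0.3), 1, 0.3)  # V = V0
  expect_identical(rank1_downdate_inv(pc0, rnorm(8), 0)$Vinv, pc0$Vinv)

  for (s in 1:20) {
    V <- rand_pd(8, seed = s)
    pc1 <- make_phenocov(as_grm(V - diag(8) * 0.2), 1, 0.2)
    x <- grmgwas:::.with_seed(s + 100, rnorm(8))
    cmax <- 1 / drop(crossprod(x, solve(V, x)))
    cc <- 0.5 * cmax
    out <- rank1_downdate_inv(pc1, x, cc)
    oracle <- solve(V - cc * tcrossprod(x))
    expect_rel_equal(out$Vinv, oracle, 1e-8)
    expect_rel_equal(out$V, V - cc * tcrossprod(x), 1e-12)
  }
})

test_that("low-rank downdate matches the oracle and degenerates to rank one", {
  for (s in 1:20) {
    V <- rand_pd(10, seed = 50 + s, ridge = 2)
    pcv <- make_phenocov(as_grm(V - diag(10)), 1, 1)
    Xm <- grmgwas:::.with_seed(s, matrix(rnorm(30), 10, 3) * 0.3)
    out <- lowrank_downdate_inv(pcv, Xm, 0.5)
    oracle <- solve(V - 0.5 * tcrossprod(Xm))
    expect_rel_equal(out$Vinv, oracle, 1e-8)

    r1a <- lowrank_downdate_inv(pcv, Xm[, 1, drop = FALSE], 0.5)
    r1b <- rank1_downdate_inv(pcv, Xm[, 1], 0.5)
    expect_rel_equal(r1a$Vinv, r1b$Vinv, 1e-12)
  }
  pcv <- make_phenocov(as_grm(rand_pd(6, seed = 7) - diag(6)), 1, 1)
  expect_identical(lowrank_downdate_inv(pcv, matrix(0, 6, 2), 1)$Vinv,
                   pcv$Vinv)
})

test_that("eigenvector-then-marker downdate equals one direct inversion", {
  for (s in 1:10) {
    G <- rand_pd(10, seed = 200 + s, ridge = 1)
    grm <- as_grm(G)
    sg2 <- 0.4
    pcv <- make_phenocov(grm, sg2, 1)
    e <- eigen_grm(grm)
    U12 <- cbind(pc_scores(e, 1), pc_scores(e, 2))
    x <- grmgwas:::.with_seed(s, rnorm(10) * 0.2)
    cc <- 0.1
    out <- eig_downdate_then_marker(pcv, U12, sg2, x_j = x, c = cc)
    target <- pcv$V - sg2 * tcrossprod(U12) - cc * tcrossprod(x)
    expect_rel_equal(out$Vinv, solve(target), 1e-8)

    # the two PC removals commute
    o1 <- eig_downdate_then_marker(pcv, U12[, c(2, 1)], sg2, x_j = x, c = cc)
    expect_rel_equal(o1$Vinv, out$Vinv, 1e-10)
    # empty PC set reduces to the rank-one path
    o2 <- eig_downdate_then_marker(pcv, NULL, sg2, x_j = x, c = cc)
    expect_rel_equal(o2$Vinv, rank1_downdate_inv(pcv, x, cc)$Vinv, 1e-12)
  }
})

test_that("every downdate path returns a true inverse (property over seeds)", {
  worst <- 0
  for (s in 1:100) {
    n <- 6 + (s %% 5)
    V <- rand_pd(n, seed = 300 + s, ridge = 1.5)
    pcv <- make_phenocov(as_grm(V - diag(n)), 1, 1)
    x <- grmgwas:::.with_seed(400 + s, rnorm(n) * 0.4)
    out <- rank1_downdate_inv(pcv, x, 0.3)
    resid <- max(abs(out$V %*% out$Vinv - diag(n)))
    worst <- max(worst, resid)
  }
  expect_lt(worst, 1e-6)
})

test_that("sequential rank-one downdates equal one block downdate, any order", {
  V <- rand_pd(9, seed = 77, ridge = 2)
  pcv <- make_phenocov(as_grm(V - diag(9)), 1, 1)
  Xm <- grmgwas:::.with_seed(78, matrix(rnorm(27), 9, 3) * 0.3)
  block <- lowrank_downdate_inv(pcv, Xm, 0.6)
  for (ord in list(c(1, 2, 3), c(3, 1, 2), c(2, 3, 1))) {
    seqd <- pcv
    for (j in ord) seqd <- rank1_downdate_inv(seqd, Xm[, j], 0.6)
    expect_rel_equal(seqd$Vinv, block$Vinv, 1e-9)
  }
})

test_that("downdates that would break positive definiteness are refused", {
  pcv <- make_phenocov(as_grm(diag(3)), 1, 1)  # V = 2I
  x <- c(1, 1, 1)
  expect_error(rank1_downdate_inv(pcv, x, 1), "not positive definite")
  expect_error(lowrank_downdate_inv(pcv, cbind(x, c(1, -1, 0)), 1),
               "not positive definite")
})

test_that("GRM inverses downdate with unit weight from one base inversion", {
  G <- rand_pd(8, seed = 90, ridge = 3)
  Xm <- grmgwas:::.with_seed(91, matrix(rnorm(16), 8, 2) * 0.4)
  got <- downdate_grm_inv(solve(G), Xm)
  expect_rel_equal(got, solve(G - tcrossprod(Xm)), 1e-8)
})
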