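# Shared fixture builders. Everything is generated in code; no stored data.

# random symmetric positive-definite matrix with eigenvalues bounded away
# from zero
rand_pd <- function(n, seed = NULL, ridge = 0.5) {
  build <- function() {
    A <- matrix(rnorm(n * n), n)
    crossprod(A) / n + diag(n) * ridge
  }
  if (is.null(seed)) build() else grmgwas:::.with_seed(seed, build())
}

# small centered genotype matrix + phenotype drawn under the mixed model
sim_instance <- function(seed, n = 50, p = 200, h2 = 0.5, n_subpops = 1,
                         divergence = 0, scaling = "raw") {
  cfg <- sim_config(n = n, p = p, n_subpops = n_subpops,
                    divergence = divergence, h2_true = h2, seed = seed)
  graw <- simulate_genotypes(cfg)
  gc <- center_markers(graw)
  grm <- build_grm(gc, scaling)
  vc <- list(sigma_g2 = h2, sigma_e2 = 1 - h2)
  y <- simulate_phenotypes(gc, grm, vc, seed = seed + 10000L)
  list(g = gc, graw = graw, grm = grm, y = y, vc = vc)
}

# write a small genotype CSV and return its path
write_geno_fixture <- function(lines, ext = ".csv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

expect_rel_equal <- function(a, b, tol) {
  expect_lt(max(abs(a - b)) / max(1, max(abs(b))), tol)
}
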