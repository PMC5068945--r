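# Run `expr` under a fixed seed (Mersenne-Twister) without touching the
# caller's RNG state. All stochastic entry points use this, so there is no
# hidden dependence on the global stream.
.with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion")
  expr
}

#' Configuration for the structured genotype/phenotype simulator
#'
#' The simulator draws individuals from `n_subpops` subpopulations whose
#' per-marker allele frequencies are dispersed around a common base
#' frequency. Base frequencies are Uniform(0.1, 0.9); subpopulation
#' frequencies add a Uniform(-divergence/2, +divergence/2) offset, clipped
#' to [0.02, 0.98]. With `n_subpops = 2` and moderate divergence this
#' reproduces the two-stratum structure typical of breeding panels (the
#' first MDS axis splits the groups); with many subpopulations and small
#' divergence it gives the diffuse family-like structure of natural
#' accession collections. It is a simple frequency-dispersal model, not a
#' calibrated F_ST model, and simulates no linkage disequilibrium.
#'
#' @param n number of individuals.
#' @param p number of markers.
#' @param n_subpops number of subpopulations (>= 1).
#' @param divergence between-group allele-frequency spread in `[0, 1)`.
#' @param h2_true heritability used when variance components are derived
#'   from the config.
#' @param beta_fixed optional numeric vector of length `p` of fixed marker
#'   effects (zero = no effect).
#' @param ploidy_code `"diploid012"` or `"binary01"`.
#' @param seed integer seed.
#' @return An object of class `"SimConfig"`.
#' @export
sim_config <- function(n, p, n_subpops = 1L, divergence = 0, h2_true = 0.5,
                       beta_fixed = NULL,
                       ploidy_code = c("diploid012", "binary01"),
                       seed = 1L) {
  ploidy_code <- match.arg(ploidy_code)
  stopifnot(n >= 2, p >= 1, n_subpops >= 1,
            divergence >= 0, divergence < 1,
            h2_true >= 0, h2_true <= 1)
  if (!is.null(beta_fixed) && length(beta_fixed) != p)
    stop("beta_fixed must have length p")
  structure(list(n = as.integer(n), p = as.integer(p),
                 n_subpops = as.integer(n_subpops),
                 divergence = divergence, h2_true = h2_true,
                 beta_fixed = beta_fixed, ploidy_code = ploidy_code,
                 seed = as.integer(seed)),
            class = "SimConfig")
}

#' Simulate structured genotypes
#'
#' Individuals are assigned to subpopulations in near-equal blocks; marker
#' `j` dosages in subpopulation `k` are Binomial(2, q_jk) (diploid) or
#' Bernoulli(q_jk) (binary). Deterministic given `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @return A `GenotypeMatrix` (uncentered) with a `subpop` attribute giving
#'   each sample's subpopulation label.
#' @export
simulate_genotypes <- function(cfg) {
  stopifnot(inherits(cfg, "SimConfig"))
  .with_seed(cfg$seed, {
    n <- cfg$n; p <- cfg$p; K <- cfg$n_subpops
    subpop <- sort(rep_len(seq_len(K), n))
    q_base <- stats::runif(p, 0.1, 0.9)
    qk <- matrix(q_base, nrow = K, ncol = p, byrow = TRUE)
    if (cfg$divergence > 0 && K > 1) {
      jit <- matrix(stats::runif(K * p, -cfg$divergence / 2,
                                 cfg$divergence / 2), nrow = K)
      qk <- pmin(pmax(qk + jit, 0.02), 0.98)
    }
    size <- if (cfg$ploidy_code == "diploid012") 2L else 1L
    vals <- matrix(0, n, p)
    for (k in seq_len(K)) {
      rows <- which(subpop == k)
      vals[rows, ] <- matrix(
        stats::rbinom(length(rows) * p, size, rep(qk[k, ], each = length(rows))),
        nrow = length(rows))
    }
    g <- genotype_matrix(vals,
                         sample_ids = sprintf("id_%03d", seq_len(n)),
                         marker_ids = sprintf("m_%04d", seq_len(p)),
                         ploidy_code = cfg$ploidy_code)
    attr(g, "subpop") <- subpop
    g
  })
}

#' Simulate phenotypes under the GRM mixed model
#'
#' Draws `y = X beta_fixed + g + e` with `g ~ N(0, G * sigma_g2)` via the
#' spectral factor of the GRM and `e ~ N(0, I * sigma_e2)`. This is the
#' generative model the GLS scan and the ML variance-component machinery
#' assume.
#'
#' @param g a `GenotypeMatrix` (used for the fixed-effect part; may be
#'   centered or raw).
#' @param grm a `GRM` for the random genomic effect (positive
#'   semi-definite).
#' @param vc a [VarComp] or list with `sigma_g2`, `sigma_e2`.
#' @param beta_fixed optional numeric vector of length p of fixed marker
#'   effects.
#' @param seed integer seed.
#' @return Named numeric phenotype vector ordered like `g$sample_ids`.
#' @export
simulate_phenotypes <- function(g, grm, vc, beta_fixed = NULL, seed = 1L) {
  stopifnot(inherits(g, "GenotypeMatrix"), inherits(grm, "GRM"))
  sg2 <- vc$sigma_g2; se2 <- vc$sigma_e2
  if (sg2 < 0 || se2 < 0) stop("negative variance components")
  n <- nrow(g$values)
  e_grm <- if (sg2 > 0) eigen_grm(grm) else NULL
  .with_seed(seed, {
    gvec <- if (sg2 > 0) {
      z <- stats::rnorm(n)
      drop(e_grm$U %*% (sqrt(pmax(e_grm$lambda, 0) * sg2) * z))
    } else rep(0, n)
    evec <- if (se2 > 0) stats::rnorm(n, sd = sqrt(se2)) else rep(0, n)
    fixed <- if (is.null(beta_fixed)) rep(0, n)
             else drop(g$values %*% beta_fixed)
    y <- fixed + gvec + evec
    names(y) <- g$sample_ids
    y
  })
}

#' One-call simulation of a genotype/phenotype pair
#'
#' Convenience wrapper: simulates genotypes from `cfg`, centers them, builds
#' a mean-diagonal GRM, and draws phenotypes with variance components
#' `sigma_g2 = h2_true`, `sigma_e2 = 1 - h2_true` (unit phenotypic
#' variance).
#'
#' @param cfg a [sim_config()].
#' @return List with `genotypes` (centered), `genotypes_raw`, `grm`,
#'   `phenotypes`, `vc_true`.
#' @export
simulate_dataset <- function(cfg) {
  graw <- simulate_genotypes(cfg)
  gc <- center_markers(graw)
  grm <- build_grm(gc, "mean_diag")
  vc <- list(sigma_g2 = cfg$h2_true, sigma_e2 = 1 - cfg$h2_true)
  y <- simulate_phenotypes(gc, grm, vc, beta_fixed = cfg$beta_fixed,
                           seed = cfg$seed + 1L)
  list(genotypes = gc, genotypes_raw = graw, grm = grm, phenotypes = y,
       vc_true = vc)
}
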