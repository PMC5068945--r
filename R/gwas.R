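#' Single-marker variance contribution
#'
#' The crude per-locus variance assessment `2 q (1 - q) beta^2` for diploid
#' 0/1/2 codes, or `q (1 - q) beta^2` for inbred / binary lines, where `q`
#' is the allele frequency and `beta` a single-marker regression estimate.
#' Assumes loci act independently (linkage equilibrium), so summing it over
#' markers overstates the variance explained in the presence of LD.
#'
#' @param q allele frequency in `[0, 1]` (vectorized).
#' @param beta regression estimate (vectorized).
#' @param inbred logical; `TRUE` for binary 0/1 lines.
#' @return Numeric single-marker variance(s).
#' @export
smv <- function(q, beta, inbred = FALSE) {
  if (any(q < 0 | q > 1, na.rm = TRUE)) stop("q must lie in [0, 1]")
  (if (inbred) 1 else 2) * q * (1 - q) * beta^2
}

.new_scan_table <- function(marker_ids, method) {
  p <- length(marker_ids)
  structure(
    data.frame(marker_id = marker_ids,
               beta = NA_real_, se = NA_real_, statistic = NA_real_,
               p_value = NA_real_, r2 = NA_real_, smv = NA_real_,
               significant = NA, method = method,
               stringsAsFactors = FALSE),
    class = c("scan_table", "data.frame"))
}

.finalize_scan <- function(tab, alpha) {
  tested <- !is.na(tab$p_value)
  thr <- alpha / max(1L, sum(tested))
  tab$significant[tested] <- tab$p_value[tested] < thr
  attr(tab, "alpha") <- alpha
  attr(tab, "bonferroni_threshold") <- thr
  attr(tab, "n_tested") <- sum(tested)
  tab
}

#' @export
print.scan_table <- function(x, n = 6L, ...) {
  cat(sprintf("Scan table (%s): %d markers, %d tested, %d significant at Bonferroni %.3g\n",
              x$method[1], nrow(x), attr(x, "n_tested"),
              sum(x$significant, na.rm = TRUE),
              attr(x, "bonferroni_threshold")))
  print.data.frame(utils::head(x, n), digits = 4)
  if (nrow(x) > n) cat("...\n")
  invisible(x)
}

#' Ordinary least-squares single-marker scan
#'
#' Regresses the centered phenotype on each centered marker column in turn:
#' `beta_j = x_j'y / x_j'x_j`, residual variance with n-1 degrees of
#' freedom (centered data, one slope, no intercept), Student-t two-sided
#' p-values, per-marker `R^2` as the fraction of the corrected sum of
#' squares explained, and the single-marker variance [smv()]. Monomorphic
#' markers yield undefined rows and are excluded from the Bonferroni
#' family size.
#'
#' @param g a centered `GenotypeMatrix`.
#' @param y numeric phenotype vector (centered internally).
#' @param alpha family-wise error rate for the Bonferroni flag.
#' @return A `scan_table` data.frame.
#' @export
ols_scan <- function(g, y, alpha = 0.05) {
  stopifnot(inherits(g, "GenotypeMatrix"))
  if (!g$centered) stop("ols_scan requires centered markers")
  y <- as.numeric(y)
  y <- y - mean(y)
  n <- length(y)
  if (n != nrow(g$values)) stop("length(y) must match samples")
  X <- g$values
  xx <- colSums(X^2)
  ok <- !g$monomorphic & xx > 0
  tab <- .new_scan_table(g$marker_ids, "OLS")
  yy <- sum(y^2)
  beta <- rep(NA_real_, ncol(X))
  beta[ok] <- drop(crossprod(X[, ok, drop = FALSE], y)) / xx[ok]
  rss <- yy - beta^2 * xx
  sigma_e2_hat <- rss / (n - 1)
  se <- sqrt(sigma_e2_hat / xx)
  tstat <- beta / se
  tab$beta <- beta
  tab$se <- ifelse(ok, se, NA_real_)
  tab$statistic <- ifelse(ok, tstat, NA_real_)
  tab$p_value <- ifelse(ok, 2 * stats::pt(-abs(tstat), df = n - 1), NA_real_)
  tab$r2 <- ifelse(ok, beta^2 * xx / yy, NA_real_)
  q <- allele_freq(g)
  tab$smv <- ifelse(ok, smv(q, beta, inbred = g$ploidy_code == "binary01"),
                    NA_real_)
  .finalize_scan(tab, alpha)
}

#' Symmetric whitening transform for GLS-via-OLS
#'
#' Computes `y* = V^{-1/2} y` and `X* = V^{-1/2} X` from the spectral
#' square root of `V`, so that ordinary least squares on the transformed
#' data reproduces the GLS estimates and their standard errors. This is
#' also how the scan computes its `R^2` on a common (whitened) scale.
#'
#' @param g a centered `GenotypeMatrix` (or numeric matrix).
#' @param y numeric phenotype vector.
#' @param pc a `PhenoCov`.
#' @return List with `y_star`, `X_star`, and the `W` = `V^{-1/2}` matrix.
#' @export
whiten_gls <- function(g, y, pc) {
  stopifnot(inherits(pc, "PhenoCov"))
  X <- if (inherits(g, "GenotypeMatrix")) g$values else as.matrix(g)
  es <- eigen((pc$V + t(pc$V)) / 2, symmetric = TRUE)
  if (any(es$values <= 0)) stop("V is not positive definite")
  W <- es$vectors %*% (t(es$vectors) / sqrt(es$values))
  list(y_star = drop(W %*% as.numeric(y)), X_star = W %*% X, W = W)
}

# Shared GLS per-marker computation. When drop_tested = TRUE the estimator
# is recomputed with marker j's own contribution removed from V via the
# rank-one downdate; by the marker-out invariance both routes agree to
# rounding error, and exposing both makes that verifiable.
.gls_core <- function(X, y, pc, drop_tested = FALSE) {
  Vinv <- pc$Vinv
  Vy <- drop(Vinv %*% y)
  T <- Vinv %*% X                       # t_j = V^{-1} x_j, all markers
  s <- colSums(X * T)                   # x_j' V^{-1} x_j
  num <- drop(crossprod(X, Vy))         # x_j' V^{-1} y
  if (!drop_tested) return(list(beta = num / s, s = s))
  cc <- pc$sigma_g2 * pc$scale_c
  ty <- drop(crossprod(T, y))           # t_j' y
  cap <- 1 - cc * s
  if (any(cap <= 0)) stop("downdate not positive definite for some marker")
  num_out <- num + cc * s * ty / cap
  den_out <- s + cc * s^2 / cap
  list(beta = num_out / den_out, s = den_out)
}

#' Generalized least-squares single-marker scan
#'
#' For each marker, `beta_j = x_j' V^{-1} y / x_j' V^{-1} x_j` with
#' sampling variance `(x_j' V^{-1} x_j)^{-1}`, where
#' `V = G sigma_g2 + I sigma_e2` accounts for genomic similarity among
#' individuals. One factorization of `V` (cached in the `PhenoCov`) serves
#' all p markers. Statistics are referred to the standard normal. The
#' reported `r2` is the fraction of the corrected sum of squares of the
#' whitened phenotype explained, so OLS and GLS scans are compared on a
#' common footing.
#'
#' `drop_tested = TRUE` recomputes every estimate with the tested marker's
#' own contribution removed from `V` (rank-one Woodbury downdate). The
#' marker-out invariance guarantees identical estimates; the option exists
#' so that the identity can be checked on any data set. The column
#' `se_markerout` always reports the corrected marker-out standard error
#' `sqrt((x'V^{-1}x)^{-1} - sigma_g2 * scale_c)` alongside the naive one.
#'
#' @param g a centered `GenotypeMatrix`.
#' @param y numeric phenotype vector (centered internally).
#' @param pc a `PhenoCov` built from a GRM on the same coding as `g`.
#' @param alpha family-wise error rate for the Bonferroni flag.
#' @param drop_tested compute estimates through the marker-out covariance.
#' @return A `scan_table` with extra column `se_markerout`.
#' @export
gls_scan <- function(g, y, pc, alpha = 0.05, drop_tested = FALSE) {
  stopifnot(inherits(g, "GenotypeMatrix"), inherits(pc, "PhenoCov"))
  if (!g$centered) stop("gls_scan requires centered markers")
  y <- as.numeric(y)
  y <- y - mean(y)
  if (length(y) != nrow(g$values)) stop("length(y) must match samples")
  X <- g$values
  ok <- !g$monomorphic & colSums(X^2) > 0
  tab <- .new_scan_table(g$marker_ids, "GLS")

  core <- .gls_core(X[, ok, drop = FALSE], y, pc, drop_tested = drop_tested)
  beta <- se <- rep(NA_real_, ncol(X))
  beta[ok] <- core$beta
  se[ok] <- sqrt(1 / core$s)
  z <- beta / se
  tab$beta <- beta
  tab$se <- se
  tab$statistic <- z
  tab$p_value <- ifelse(ok, 2 * stats::pnorm(-abs(z)), NA_real_)

  # corrected variance when the tested marker is treated as fixed-and-removed
  c_sigma <- pc$sigma_g2 * pc$scale_c
  vout <- 1 / core$s - c_sigma
  se_out <- rep(NA_real_, ncol(X))
  se_out[ok] <- sqrt(pmax(vout, 0))
  tab$se_markerout <- se_out

  # R^2 on the whitened scale
  wh <- whiten_gls(g, y, pc)
  ys <- wh$y_star - mean(wh$y_star)
  yy <- sum(ys^2)
  xs2 <- colSums(wh$X_star^2)
  bstar <- rep(NA_real_, ncol(X))
  bstar[ok] <- drop(crossprod(wh$X_star[, ok, drop = FALSE], ys)) / xs2[ok]
  tab$r2 <- ifelse(ok, bstar^2 * xs2 / yy, NA_real_)

  q <- allele_freq(g)
  tab$smv <- ifelse(ok, smv(q, beta, inbred = g$ploidy_code == "binary01"),
                    NA_real_)
  .finalize_scan(tab, alpha)
}

#' Corrected sampling variance of a marker-out GLS estimator
#'
#' When marker `j` is tested as a fixed effect while `V` still contains its
#' contribution `c_sigma * x x'`, the usual `(x'V^{-1}x)^{-1}` is not the
#' variance of the estimator under the fixed-marker model. The correct
#' variance is `s^{-2} x' V^{-1} V[-j] V^{-1} x` with `s = x'V^{-1}x` and
#' `V[-j] = V - c_sigma x x'`, which simplifies algebraically to
#' `(x'V^{-1}x)^{-1} - c_sigma`. Both forms are computed here (the sandwich
#' form explicitly), and they agree to rounding error.
#'
#' @param pc a `PhenoCov` containing the marker's contribution.
#' @param x the marker's centered column.
#' @param c_sigma weight of the marker in `V` (`sigma_g2 * scale_c`).
#' @return Scalar corrected variance (strictly positive on valid inputs).
#' @export
markerout_variance <- function(pc, x, c_sigma) {
  stopifnot(inherits(pc, "PhenoCov"))
  x <- as.numeric(x)
  t_j <- drop(pc$Vinv %*% x)
  s <- sum(x * t_j)
  if (s <= 0) stop("degenerate marker: x'V^{-1}x is not positive")
  if (1 - c_sigma * s <= 0)
    stop("marker-out covariance V[-j] is not positive definite")
  Vmj <- pc$V - c_sigma * tcrossprod(x)
  drop(crossprod(t_j, Vmj %*% t_j)) / s^2
}

#' Multi-marker GLS regression with marker-out covariance
#'
#' Joint GLS of `y` on `m` marker columns: `beta = (Xm'V^{-1}Xm)^{-1}
#' Xm'V^{-1}y`. By the m-marker generalization of the marker-out
#' invariance, the estimator is identical whether or not the tested block
#' is removed from `V`, so the full-`V` inverse suffices. The covariance
#' under the fixed-and-removed treatment is `(Xm'V^{-1}Xm)^{-1} -
#' I * c_sigma`. With `V = I` and `c_sigma = 0` this is ordinary multiple
#' regression, as used for the joint fit of scan-significant markers.
#'
#' @param Xm n x m numeric matrix (centered marker columns).
#' @param y numeric phenotype vector (centered internally).
#' @param pc a `PhenoCov`.
#' @param c_sigma per-marker weight inside `V` (0 to keep the naive
#'   covariance).
#' @return List with `beta`, `cov` (corrected), `cov_naive`, `se`, `z`,
#'   `p_value`, `r2` (whitened-scale model R^2).
#' @export
mmr_gls <- function(Xm, y, pc, c_sigma = 0) {
  stopifnot(inherits(pc, "PhenoCov"))
  Xm <- as.matrix(Xm)
  y <- as.numeric(y)
  y <- y - mean(y)
  qrX <- qr(Xm)
  if (qrX$rank < ncol(Xm)) {
    null_cols <- colnames(Xm)[qrX$pivot[(qrX$rank + 1):ncol(Xm)]]
    if (is.null(null_cols)) null_cols <- qrX$pivot[(qrX$rank + 1):ncol(Xm)]
    stop("collinear marker columns: ", paste(null_cols, collapse = ", "))
  }
  Vinv <- pc$Vinv
  XtVX <- crossprod(Xm, Vinv %*% Xm)
  XtVy <- drop(crossprod(Xm, Vinv %*% y))
  cov_naive <- solve((XtVX + t(XtVX)) / 2)
  beta <- drop(cov_naive %*% XtVy)
  cov_corr <- cov_naive - diag(c_sigma, ncol(Xm))
  se <- sqrt(pmax(diag(cov_corr), 0))
  z <- beta / sqrt(diag(cov_naive))
  wh <- whiten_gls(Xm, y, pc)
  ys <- wh$y_star - mean(wh$y_star)
  fit <- drop(wh$X_star %*% beta)
  r2 <- 1 - sum((ys - (fit - mean(fit)))^2) / sum(ys^2)
  list(beta = beta, cov = cov_corr, cov_naive = cov_naive, se = se, z = z,
       p_value = 2 * stats::pnorm(-abs(z)), r2 = r2)
}

#' Solve the mixed-model equations for a marker scan step
#'
#' Sets up and solves Henderson's equations for the model
#' `y = W beta + g + e` with `g ~ N(0, G sigma_g2)`:
#' `[W'W, W'; W, I + G^{-1} lambda_g] [beta; g] = [W'y; y]`, where
#' `lambda_g = sigma_e2 / sigma_g2`. The `beta` solution is the GLS
#' estimator and `g` its BLUP; the top-left block `c_bb` of the inverted
#' coefficient matrix gives `Var(beta) = c_bb * sigma_e2` and the test
#' statistic `z = beta / (sigma_e * sqrt(c_bb))`.
#'
#' @param W n x k design matrix (e.g. one centered marker column).
#' @param y numeric phenotype vector.
#' @param grm_inv inverse of the (possibly marker-out) GRM.
#' @param lambda_g variance ratio `sigma_e2 / sigma_g2` (> 0).
#' @param sigma_e2 residual variance used to scale the test statistic.
#' @return List with `beta`, `g_hat`, `c_bb` (k x k), `z`, `residual`
#'   (`y - W beta`).
#' @export
mme_solve <- function(W, y, grm_inv, lambda_g, sigma_e2 = 1) {
  W <- as.matrix(W)
  y <- as.numeric(y)
  n <- length(y)
  k <- ncol(W)
  if (lambda_g <= 0) stop("lambda_g must be positive")
  C <- rbind(cbind(crossprod(W), t(W)),
             cbind(W, diag(n) + grm_inv * lambda_g))
  rhs <- c(drop(crossprod(W, y)), y)
  sol <- tryCatch(solve(C, rhs),
                  error = function(e) stop("singular mixed-model coefficient matrix"))
  beta <- sol[seq_len(k)]
  g_hat <- sol[-seq_len(k)]
  Cinv_bb <- solve(C)[seq_len(k), seq_len(k), drop = FALSE]
  z <- beta / (sqrt(sigma_e2) * sqrt(diag(Cinv_bb)))
  list(beta = beta, g_hat = g_hat, c_bb = Cinv_bb, z = z,
       residual = y - drop(W %*% beta))
}

#' Genomic BLUP without the mixed-model equations
#'
#' The direct representation `g_hat = sigma_g2 * G * V^{-1} * (y -
#' fitted_fixed)`. Unique even when `G` is rank-deficient, because `V` is
#' invertible. Invariant to removing the tested marker from both `G` and
#' `V` (checked property), so one `G` and one `V` serve a whole scan.
#'
#' @param grm a `GRM`.
#' @param pc a `PhenoCov` consistent with `grm`.
#' @param y numeric phenotype vector.
#' @param fitted_fixed fitted fixed-effect part (e.g. `x_j * beta_j`);
#'   defaults to zero.
#' @return List of class `"BlupResult"` with `g_hat` and `residual`
#'   (`y - fitted_fixed`).
#' @export
blup_strongarm <- function(grm, pc, y, fitted_fixed = 0) {
  stopifnot(inherits(grm, "GRM"), inherits(pc, "PhenoCov"))
  y <- as.numeric(y)
  resid <- y - fitted_fixed
  g_hat <- pc$sigma_g2 * drop(grm$matrix %*% (pc$Vinv %*% resid))
  structure(list(g_hat = g_hat, residual = resid), class = "BlupResult")
}

#' Structure-adjusted single-marker scan with PCs as fixed covariates
#'
#' For each marker fits `y = x_j beta + U_1 a_1 + ... + U_npc a_npc +
#' g + e` by GLS, with the leading eigenvectors of `G` absorbing
#' population stratification. Two treatments of `G` are available:
#' `"keep_G"` leaves the covariance structure intact (the PCs are then
#' double-counted, fixed and random at once), while `"remove_from_G"`
#' discounts the fitted PCs' genetic contribution
#' `sigma_g2 * sum_i lambda_i U_i U_i'` from `V` via one low-rank Woodbury
#' downdate.
#'
#' A subtlety worth stating: at *fixed* variance components the two modes
#' return identical point estimates, because the discounted term lies in
#' the span of the fixed design — the same algebra behind the marker-out
#' invariance (only the sampling variances differ). What makes eigenvector
#' removal matter in practice is that the variance partition itself shifts,
#' often drastically, when dominant PCs leave `G`; re-estimate
#' `(sigma_g2, sigma_e2)` on the edited matrix with [fit_ml()] and pass
#' that `vc` with `mode = "remove_from_G"`, which is what the command-line
#' pipeline does by default.
#'
#' @param g a centered `GenotypeMatrix`.
#' @param y numeric phenotype vector (centered internally).
#' @param e an `EigenGRM` of the scan GRM.
#' @param n_pc number of leading eigenvectors fitted as fixed covariates.
#' @param vc a [var_comp()] (or list) with `sigma_g2`, `sigma_e2`.
#' @param mode `"keep_G"` or `"remove_from_G"`.
#' @param alpha family-wise error rate for the Bonferroni flag.
#' @return A `scan_table` for the marker coefficients (the PC coefficients
#'   are nuisance terms and are not tabulated).
#' @export
pc_adjusted_scan <- function(g, y, e, n_pc, vc,
                             mode = c("keep_G", "remove_from_G"),
                             alpha = 0.05) {
  mode <- match.arg(mode)
  stopifnot(inherits(g, "GenotypeMatrix"), inherits(e, "EigenGRM"))
  n <- nrow(g$values)
  if (n_pc >= n) stop("n_pc must be smaller than the sample size")
  y <- as.numeric(y)
  y <- y - mean(y)
  pc <- make_phenocov(e$parent, vc$sigma_g2, vc$sigma_e2)
  if (mode == "remove_from_G" && n_pc > 0) {
    pcs <- pc_scores(e, seq_len(n_pc))
    pc <- eig_downdate_then_marker(pc, as.matrix(pcs), vc$sigma_g2)
  }
  U <- if (n_pc > 0) e$U[, seq_len(n_pc), drop = FALSE] else NULL
  X <- g$values
  ok <- !g$monomorphic & colSums(X^2) > 0
  tab <- .new_scan_table(g$marker_ids, "GLS")
  Vinv <- pc$Vinv
  for (j in which(ok)) {
    W <- cbind(X[, j], U)
    A <- crossprod(W, Vinv %*% W)
    b <- drop(crossprod(W, Vinv %*% y))
    Ainv <- solve((A + t(A)) / 2)
    theta <- drop(Ainv %*% b)
    tab$beta[j] <- theta[1]
    tab$se[j] <- sqrt(Ainv[1, 1])
  }
  tab$statistic <- tab$beta / tab$se
  tab$p_value <- ifelse(ok, 2 * stats::pnorm(-abs(tab$statistic)), NA_real_)
  q <- allele_freq(g)
  tab$smv <- ifelse(ok, smv(q, tab$beta,
                            inbred = g$ploidy_code == "binary01"), NA_real_)
  .finalize_scan(tab, alpha)
}
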