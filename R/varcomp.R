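#' Variance-component estimates under the GRM mixed model
#'
#' Container for the genomic variance `sigma_g2`, residual variance
#' `sigma_e2`, genomic heritability `h2 = sigma_g2 / (sigma_g2 + sigma_e2)`,
#' the variance ratio `lambda_ratio = sigma_e2 / sigma_g2` used by the
#' mixed-model equations, the maximized log-likelihood, and optional
#' standard errors.
#'
#' @param sigma_g2,sigma_e2 non-negative variance components.
#' @param loglik log-likelihood at the estimates.
#' @param se_g2,se_e2 optional standard errors.
#' @param converged logical.
#' @param boundary logical; `TRUE` when the optimum sits on the edge of the
#'   heritability interval.
#' @param n_iter iterations / function evaluations used.
#' @return An object of class `"VarComp"`.
#' @export
var_comp <- function(sigma_g2, sigma_e2, loglik = NA_real_,
                     se_g2 = NA_real_, se_e2 = NA_real_,
                     converged = TRUE, boundary = FALSE, n_iter = 0L) {
  if (sigma_g2 < 0 || sigma_e2 < 0) stop("negative variance components")
  tot <- sigma_g2 + sigma_e2
  structure(list(sigma_g2 = sigma_g2, sigma_e2 = sigma_e2,
                 h2 = if (tot > 0) sigma_g2 / tot else NA_real_,
                 lambda_ratio = if (sigma_g2 > 0) sigma_e2 / sigma_g2
                                else Inf,
                 loglik = loglik, se_g2 = se_g2, se_e2 = se_e2,
                 converged = converged, boundary = boundary,
                 n_iter = as.integer(n_iter)),
            class = "VarComp")
}

#' @export
print.VarComp <- function(x, ...) {
  cat(sprintf(
    "VarComp: sigma_g2 = %.4g (SE %.3g), sigma_e2 = %.4g (SE %.3g), h2 = %.4g\n",
    x$sigma_g2, x$se_g2, x$sigma_e2, x$se_e2, x$h2))
  cat(sprintf("  loglik = %.6g, converged = %s%s\n", x$loglik, x$converged,
              if (isTRUE(x$boundary)) " (boundary)" else ""))
  invisible(x)
}

#' Log-likelihood of y ~ N(0, G sigma_g2 + I sigma_e2) via the spectrum
#'
#' With `G = U diag(lambda) U'` and the rotated data `ytilde = U'y`, the
#' covariance diagonalizes and the log-likelihood is
#' `-1/2 * sum_i [ log(lambda_i sigma_g2 + sigma_e2) +
#' ytilde_i^2 / (lambda_i sigma_g2 + sigma_e2) ] - (n/2) log(2*pi)`.
#' This equals the dense multivariate-normal log-density but costs O(n)
#' after one decomposition, which is what makes repeated fits (one per
#' removed marker or eigenvector) affordable.
#'
#' @param e an `EigenGRM`.
#' @param y numeric phenotype vector, mean already removed (see
#'   [fit_ml()]).
#' @param sigma_g2,sigma_e2 variance components (a `VarComp` can be passed
#'   as `sigma_g2`).
#' @return Scalar log-likelihood.
#' @export
grm_loglik <- function(e, y, sigma_g2, sigma_e2 = NULL) {
  stopifnot(inherits(e, "EigenGRM"))
  if (inherits(sigma_g2, "VarComp")) {
    sigma_e2 <- sigma_g2$sigma_e2
    sigma_g2 <- sigma_g2$sigma_g2
  }
  y <- as.numeric(y)
  n <- length(y)
  if (n != length(e$lambda)) stop("length(y) must match the decomposition")
  d <- e$lambda * sigma_g2 + sigma_e2
  if (any(d <= 0)) stop("non-positive variance lambda_i*sigma_g2 + sigma_e2")
  yt <- drop(crossprod(e$U, y))
  -0.5 * sum(log(d) + yt^2 / d) - (n / 2) * log(2 * pi)
}

# Profile log-likelihood over h2 with the total variance concentrated out:
# given h2, w_i = h2*lambda_i + (1-h2) and sigma_tot_hat = mean(yt^2 / w).
.profile_loglik <- function(h2, lam, yt2) {
  n <- length(lam)
  w <- h2 * lam + (1 - h2)
  if (any(w <= 0)) return(-Inf)
  s_tot <- mean(yt2 / w)
  if (s_tot <= 0) return(-Inf)
  -0.5 * (sum(log(w)) + n * log(s_tot) + n + n * log(2 * pi))
}

#' Maximum-likelihood variance components via the GRM spectrum
#'
#' Maximizes the likelihood of `y ~ N(0, G sigma_g2 + I sigma_e2)` by a
#' one-dimensional bounded search over heritability: for fixed
#' `h2`, the total-variance MLE is closed-form
#' (`sigma_tot_hat = mean(ytilde_i^2 / w_i)` with
#' `w_i = h2 lambda_i + 1 - h2`), so the profile likelihood is maximized by
#' Brent's method on `h2` in `[1e-6, 1 - 1e-6]` (tolerance 1e-8), with the
#' boundary values `h2 = 0` and `h2 = 1` evaluated explicitly and kept if
#' better. This sidesteps the convergence monitoring that iterative
#' two-parameter algorithms require. Phenotypes are mean-centered before
#' fitting; there is no fixed-effect design in the likelihood.
#'
#' Standard errors come from the observed information: a central
#' finite-difference Hessian of the log-likelihood in
#' `(sigma_g2, sigma_e2)` with step `1e-4 * estimate`. They are reported as
#' `NA` at boundary optima, where the quadratic approximation fails.
#'
#' @param e an `EigenGRM`.
#' @param y numeric phenotype vector (internally mean-centered).
#' @param compute_se logical; skip the Hessian when `FALSE`.
#' @return A [var_comp()] object.
#' @export
fit_ml <- function(e, y, compute_se = TRUE) {
  stopifnot(inherits(e, "EigenGRM"))
  y <- as.numeric(y)
  n <- length(y)
  if (n < 3) stop("need at least 3 observations")
  if (n != length(e$lambda)) stop("length(y) must match the decomposition")
  y <- y - mean(y)
  if (stats::sd(y) == 0) stop("phenotype has zero variance")
  lam <- e$lambda
  if (max(lam) - min(lam) < 1e-12 * max(1, max(lam)))
    stop("all eigenvalues equal (G proportional to I): h2 not identifiable")
  yt2 <- drop(crossprod(e$U, y))^2
  # Mean-centering y makes it exactly orthogonal to the constant vector,
  # which for a GRM built from column-centered markers is a null
  # eigenvector of G. Such directions carry neither data nor genomic
  # variance; keeping them makes the likelihood degenerate (unbounded as
  # sigma_e2 -> 0), so the fit is formed on the contrast space without
  # them — the REML-style accounting for the one estimated mean.
  keep <- !(lam <= 1e-8 * max(lam) & yt2 <= 1e-16 * sum(yt2))
  lam <- lam[keep]
  yt2 <- yt2[keep]

  opt <- stats::optimize(function(h) .profile_loglik(h, lam, yt2),
                         interval = c(1e-6, 1 - 1e-6), maximum = TRUE,
                         tol = 1e-8)
  cand_h2 <- c(opt$maximum, 0, 1)
  cand_ll <- c(opt$objective,
               .profile_loglik(0, lam, yt2),
               .profile_loglik(1, lam, yt2))
  best <- which.max(cand_ll)
  h2 <- cand_h2[best]
  ll <- cand_ll[best]
  w <- h2 * lam + (1 - h2)
  s_tot <- mean(yt2 / w)
  sg2 <- h2 * s_tot
  se2 <- (1 - h2) * s_tot
  boundary <- h2 <= 1e-5 || h2 >= 1 - 1e-5

  se_g <- se_e <- NA_real_
  if (compute_se && !boundary) {
    hess <- .obs_info_hessian(lam, yt2, sg2, se2, n)
    if (all(is.finite(hess))) {
      info <- -hess
      ok <- tryCatch({
        cov2 <- solve(info)
        all(diag(cov2) > 0)
      }, error = function(e) FALSE)
      if (ok) {
        cov2 <- solve(info)
        se_g <- sqrt(cov2[1, 1])
        se_e <- sqrt(cov2[2, 2])
      }
    }
  }
  var_comp(sg2, se2, loglik = ll, se_g2 = se_g, se_e2 = se_e,
           converged = TRUE, boundary = boundary, n_iter = 1L)
}

.ll_sig <- function(lam, yt2, sg2, se2) {
  d <- lam * sg2 + se2
  if (any(d <= 0)) return(-Inf)
  -0.5 * sum(log(d) + yt2 / d) - (length(lam) / 2) * log(2 * pi)
}

.obs_info_hessian <- function(lam, yt2, sg2, se2, n) {
  f <- function(th) .ll_sig(lam, yt2, th[1], th[2])
  th <- c(sg2, se2)
  h <- pmax(1e-4 * abs(th), 1e-8)
  H <- matrix(NA_real_, 2, 2)
  for (i in 1:2) for (j in 1:2) {
    ei <- ej <- c(0, 0); ei[i] <- h[i]; ej[j] <- h[j]
    H[i, j] <- (f(th + ei + ej) - f(th + ei - ej) -
                f(th - ei + ej) + f(th - ei - ej)) / (4 * h[i] * h[j])
  }
  (H + t(H)) / 2
}

#' Refit variance components with one marker removed from the GRM
#'
#' Rebuilds `G[-j]` by subtracting marker `j`'s outer product (scaling
#' constant frozen), re-decomposes, and refits by [fit_ml()]. Used to
#' measure how much the variance partition actually shifts when a tested
#' marker is discounted from the covariance structure — the quantity whose
#' smallness justifies scanning with a single set of variance components.
#'
#' @param e_base `EigenGRM` of the full GRM (its `parent` is downdated).
#' @param g the centered `GenotypeMatrix` the GRM was built from.
#' @param y phenotype vector.
#' @param j marker index or ID to remove.
#' @param vc_base optional [var_comp()] from the full fit; computed if
#'   missing.
#' @return A `VarComp` for `G[-j]` with an extra element `delta_vg
#'   = |sigma_g2(full) - sigma_g2(-j)|`.
#' @export
refit_with_marker_removed <- function(e_base, g, y, j, vc_base = NULL) {
  stopifnot(inherits(e_base, "EigenGRM"))
  if (is.null(vc_base)) vc_base <- fit_ml(e_base, y, compute_se = FALSE)
  grm_j <- drop_markers_grm(e_base$parent, g, j)
  e_j <- eigen_grm(grm_j)
  vc_j <- fit_ml(e_j, y, compute_se = FALSE)
  vc_j$delta_vg <- abs(vc_base$sigma_g2 - vc_j$sigma_g2)
  vc_j
}
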