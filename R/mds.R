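#' Pairwise Euclidean distances between genotype rows
#'
#' Condensed lower-triangle distances (`n(n-1)/2` of them) between the
#' p-dimensional genotype vectors of all individuals — the input to both
#' MDS variants.
#'
#' @param g a `GenotypeMatrix` or numeric matrix.
#' @return A `stats::dist` object.
#' @export
pairwise_distances <- function(g) {
  X <- if (inherits(g, "GenotypeMatrix")) g$values else as.matrix(g)
  stats::dist(X, method = "euclidean")
}

#' STRESS goodness-of-fit between observed and fitted distances
#'
#' `sqrt( sum (d_obs - d_fit)^2 / sum d_obs^2 )`: squared discrepancies
#' between observed and fitted distances, expressed relative to the sum of
#' all observed squared distances, square-rooted. Values below 5-10% are
#' conventionally taken as a satisfactory fit for the dimension in
#' question. Scale-invariant under a common rescaling of both arguments.
#'
#' @param d_obs,d_fit numeric vectors or `dist` objects of equal length.
#' @return Scalar STRESS value.
#' @export
stress <- function(d_obs, d_fit) {
  d_obs <- as.numeric(d_obs)
  d_fit <- as.numeric(d_fit)
  if (length(d_obs) != length(d_fit)) stop("distance sets differ in length")
  denom <- sum(d_obs^2)
  if (denom == 0) stop("all observed distances are zero")
  sqrt(sum((d_obs - d_fit)^2) / denom)
}

#' Classical (Torgerson) multidimensional scaling
#'
#' Double-centers the squared-distance matrix, `B = -1/2 J D2 J`, and takes
#' the top-K spectral configuration `U_k sqrt(lambda_k)`. Distances
#' computed from the configuration reproduce the input exactly when the
#' distances are Euclidean and K is at least the generating dimension.
#' Eigenvalues are reported for scree diagnostics (as fractions of the sum
#' of positive eigenvalues; negative eigenvalues flag non-Euclidean
#' distortion and are excluded from the denominator). A requested dimension
#' with non-positive eigenvalue is zeroed with a warning. The STRESS of the
#' configuration distances against the input is reported so the 5-10% rule
#' can be applied to the classical fit as well.
#'
#' @param D a `dist` object or condensed distance vector.
#' @param K embedding dimension (`< n`).
#' @return An object of class `"MdsResult"`: `coords` (n x K), `K`,
#'   `eigvals`, `eigval_fraction`, `stress`, `converged = TRUE`.
#' @export
classical_mds <- function(D, K = 2) {
  D <- stats::as.dist(D)
  n <- attr(D, "Size")
  if (K >= n) stop("K must be smaller than the number of objects")
  D2 <- as.matrix(D)^2
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% D2 %*% J
  es <- eigen((B + t(B)) / 2, symmetric = TRUE)
  lam <- es$values
  coords <- matrix(0, n, K)
  pos <- lam[seq_len(K)] > 0
  if (!all(pos))
    warning("non-positive eigenvalue(s) among the first K; coordinate(s) zeroed")
  for (k in seq_len(K)) if (pos[k])
    coords[, k] <- es$vectors[, k] * sqrt(lam[k])
  rn <- if (!is.null(attr(D, "Labels"))) attr(D, "Labels") else NULL
  rownames(coords) <- rn
  frac <- rep(0, n)
  possum <- sum(lam[lam > 0])
  if (possum > 0) frac[lam > 0] <- lam[lam > 0] / possum
  structure(list(coords = coords, K = K, eigvals = lam,
                 eigval_fraction = frac,
                 stress = stress(D, stats::dist(coords)),
                 converged = TRUE, method = "classical"),
            class = "MdsResult")
}

#' @export
print.MdsResult <- function(x, ...) {
  cat(sprintf("MdsResult (%s): %d objects in K = %d, STRESS = %.4g%s\n",
              x$method, nrow(x$coords), x$K, x$stress,
              if (isTRUE(x$converged)) "" else " (not converged)"))
  invisible(x)
}

# Kruskal stress-1 of a configuration: disparities are the isotonic
# regression of configuration distances on the rank order of the observed
# dissimilarities (primary approach to ties).
.stress1 <- function(dconf, dhat) {
  denom <- sum(dconf^2)
  if (denom == 0) return(1)
  sqrt(sum((dconf - dhat)^2) / denom)
}

.disparities <- function(dconf, ord) {
  dhat <- numeric(length(dconf))
  dhat[ord] <- stats::isoreg(dconf[ord])$yf
  dhat
}

# One Guttman majorization step toward the disparities.
.guttman <- function(X, dconf_mat, dhat_mat) {
  n <- nrow(X)
  ratio <- ifelse(dconf_mat > 0, dhat_mat / dconf_mat, 0)
  B <- -ratio
  diag(B) <- 0
  diag(B) <- -rowSums(B)
  (B %*% X) / n
}

#' Nonmetric (Kruskal) multidimensional scaling
#'
#' Minimizes Kruskal's stress-1 — configuration distances against their
#' monotone (isotonic, pool-adjacent-violators) regression on the observed
#' dissimilarity order — by SMACOF majorization (Guttman transform).
#' Initialization is the classical solution plus seeded random restarts;
#' the best final configuration is kept. Stress is non-increasing along
#' each run; iteration stops when the drop falls below `tol` or after
#' `max_iter` steps (then `converged = FALSE` with the last
#' configuration). Deterministic given `seed`.
#'
#' @param D a `dist` object or condensed distance vector.
#' @param K embedding dimension.
#' @param seed integer seed for the random restarts.
#' @param max_iter maximum majorization steps per start.
#' @param tol stop when the stress decrease is below this.
#' @param n_restarts number of additional random starts beyond the
#'   classical initialization.
#' @return An `MdsResult` with Kruskal stress-1 in `stress`.
#' @export
nonmetric_mds <- function(D, K = 2, seed = 1L, max_iter = 300L,
                          tol = 1e-7, n_restarts = 3L) {
  D <- stats::as.dist(D)
  n <- attr(D, "Size")
  if (K >= n) stop("K must be smaller than the number of objects")
  delta <- as.numeric(D)
  ord <- order(delta)
  idx <- which(lower.tri(matrix(0, n, n)), arr.ind = TRUE)

  run_one <- function(X0) {
    X <- X0
    dconf <- as.numeric(stats::dist(X))
    dhat <- .disparities(dconf, ord)
    s_prev <- .stress1(dconf, dhat)
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      dm <- matrix(0, n, n); dm[idx] <- dconf; dm <- dm + t(dm)
      hm <- matrix(0, n, n); hm[idx] <- dhat;  hm <- hm + t(hm)
      Xn <- .guttman(X, dm, hm)
      dconf_n <- as.numeric(stats::dist(Xn))
      dhat_n <- .disparities(dconf_n, ord)
      s_new <- .stress1(dconf_n, dhat_n)
      if (s_new > s_prev + 1e-12) { converged <- TRUE; break }
      X <- Xn; dconf <- dconf_n; dhat <- dhat_n
      if (s_prev - s_new < tol) { s_prev <- s_new; converged <- TRUE; break }
      s_prev <- s_new
    }
    list(X = X, stress = s_prev, converged = converged)
  }

  starts <- list(suppressWarnings(classical_mds(D, K)$coords))
  if (n_restarts > 0) {
    rand <- .with_seed(seed, lapply(seq_len(n_restarts), function(r)
      matrix(stats::rnorm(n * K), n, K)))
    starts <- c(starts, rand)
  }
  fits <- lapply(starts, run_one)
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "stress"))]]
  rn <- if (!is.null(attr(D, "Labels"))) attr(D, "Labels") else NULL
  rownames(best$X) <- rn
  structure(list(coords = best$X, K = K,
                 eigvals = NULL, eigval_fraction = NULL,
                 stress = best$stress, converged = best$converged,
                 method = "nonmetric"),
            class = "MdsResult")
}

#' STRESS across embedding dimensions
#'
#' Fits MDS for `K = 1, ..., K_max` and reports the STRESS of each fit —
#' the curve used to choose how many dimensions describe the genomic
#' structure (values under 5-10% are conventionally adequate).
#'
#' @param D a `dist` object.
#' @param K_max largest dimension to fit.
#' @param method `"classical"` or `"nonmetric"`.
#' @param seed seed for the nonmetric restarts.
#' @return data.frame with columns `K` and `stress`.
#' @export
stress_scan <- function(D, K_max, method = c("classical", "nonmetric"),
                        seed = 1L) {
  method <- match.arg(method)
  res <- vapply(seq_len(K_max), function(k) {
    fit <- if (method == "classical") classical_mds(D, k)
           else nonmetric_mds(D, k, seed = seed)
    fit$stress
  }, numeric(1))
  data.frame(K = seq_len(K_max), stress = res)
}
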