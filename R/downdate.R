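#' Phenotypic covariance matrix with a cached inverse
#'
#' Builds `V = G * sigma_g2 + I * sigma_e2` from a GRM and variance
#' components, and caches `V^{-1}` so that all marker-out and
#' eigenvector-out inverses can be obtained by Sherman-Morrison-Woodbury
#' downdates of this single inversion. The GRM's per-marker weight
#' `scale_c` is carried along: marker `j` contributes
#' `sigma_g2 * scale_c * x_j x_j'` to `V`, which is the rank-one term the
#' downdates remove.
#'
#' @param grm a `GRM`.
#' @param sigma_g2,sigma_e2 genomic and residual variance components; either
#'   scalars or a [VarComp] object passed as `sigma_g2`.
#' @return An object of class `"PhenoCov"`: `V`, `Vinv`, `sigma_g2`,
#'   `sigma_e2`, `scale_c`, `edits` (character log of applied downdates).
#' @export
make_phenocov <- function(grm, sigma_g2, sigma_e2 = NULL) {
  stopifnot(inherits(grm, "GRM"))
  if (inherits(sigma_g2, "VarComp")) {
    vc <- sigma_g2
    sigma_g2 <- vc$sigma_g2
    sigma_e2 <- vc$sigma_e2
  }
  if (sigma_g2 < 0 || sigma_e2 <= 0)
    stop("require sigma_g2 >= 0 and sigma_e2 > 0")
  n <- nrow(grm$matrix)
  V <- grm$matrix * sigma_g2
  diag(V) <- diag(V) + sigma_e2
  Vinv <- chol2inv(chol(V))
  structure(list(V = V, Vinv = Vinv, sigma_g2 = sigma_g2,
                 sigma_e2 = sigma_e2, scale_c = grm$scale_c,
                 sample_ids = grm$sample_ids, edits = character(0)),
            class = "PhenoCov")
}

#' @export
print.PhenoCov <- function(x, ...) {
  cat(sprintf("PhenoCov: %d x %d, sigma_g2 = %.4g, sigma_e2 = %.4g\n",
              nrow(x$V), ncol(x$V), x$sigma_g2, x$sigma_e2))
  if (length(x$edits)) cat("  edits:", paste(x$edits, collapse = "; "), "\n")
  invisible(x)
}

# Core Woodbury identity: inverse of A - c * U U' from Ainv.
# cap = I - c U' Ainv U must stay positive definite.
.woodbury_downdate <- function(Ainv, U, c, tol = 1e-10) {
  U <- as.matrix(U)
  if (c == 0 || ncol(U) == 0) return(Ainv)
  T <- Ainv %*% U
  S <- crossprod(U, T)
  cap <- diag(ncol(U)) - c * S
  capsym <- (cap + t(cap)) / 2
  ev <- eigen(capsym, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= tol * max(1, c * max(abs(diag(S)))))
    stop("downdate not positive definite")
  Ainv + c * T %*% solve(capsym, t(T))
}

#' Rank-one downdate of an inverse covariance matrix
#'
#' Given a `PhenoCov` holding `V` and `V^{-1}`, returns the `PhenoCov` for
#' `V - c * x x'` with its inverse obtained by the Sherman-Morrison
#' identity: `V^{-1} + c t t' / (1 - c x't)` where `t = V^{-1} x`. For a
#' marker removed from the GRM, `c = sigma_g2 * scale_c`. The downdate is
#' refused when the capacitance `1 - c x'V^{-1}x` is not safely positive,
#' since the target matrix would not be positive definite.
#'
#' @param pc a `PhenoCov`.
#' @param x numeric n-vector (e.g. a centered marker column).
#' @param c positive scalar weight of the removed outer product.
#' @return A `PhenoCov` for the downdated matrix.
#' @export
rank1_downdate_inv <- function(pc, x, c) {
  stopifnot(inherits(pc, "PhenoCov"))
  x <- as.numeric(x)
  if (length(x) != nrow(pc$V)) stop("length(x) must equal nrow(V)")
  if (c < 0) stop("c must be >= 0")
  if (c == 0) return(pc)
  t_j <- drop(pc$Vinv %*% x)
  s <- sum(x * t_j)
  cap <- 1 - c * s
  if (cap <= 1e-10 * max(1, c * s))
    stop("downdate not positive definite")
  pc$Vinv <- pc$Vinv + (c / cap) * tcrossprod(t_j)
  pc$V <- pc$V - c * tcrossprod(x)
  pc$edits <- c(pc$edits, sprintf("rank1(c=%.4g)", c))
  pc
}

#' Low-rank (m-column) downdate of an inverse covariance matrix
#'
#' Woodbury form for removing `c * Xm Xm'` from `V`:
#' `V^{-1} + c V^{-1} Xm [I - c Xm' V^{-1} Xm]^{-1} Xm' V^{-1}`. With
#' `m = 1` this reduces to [rank1_downdate_inv()]. The same identity, with
#' `c = 1` on a GRM and its inverse, gives `G[m out]^{-1}` from a single
#' inversion of `G` (see [downdate_grm_inv()]). A singular or indefinite
#' capacitance matrix is refused; for GRM downdates that occurs when the
#' reduced matrix loses full rank (n > p - m).
#'
#' @param pc a `PhenoCov`.
#' @param Xm n x m numeric matrix of removed columns.
#' @param c positive scalar weight.
#' @return A `PhenoCov` for the downdated matrix.
#' @export
lowrank_downdate_inv <- function(pc, Xm, c) {
  stopifnot(inherits(pc, "PhenoCov"))
  Xm <- as.matrix(Xm)
  if (nrow(Xm) != nrow(pc$V)) stop("nrow(Xm) must equal nrow(V)")
  if (c < 0) stop("c must be >= 0")
  if (c == 0 || ncol(Xm) == 0 || all(Xm == 0)) return(pc)
  pc$Vinv <- .woodbury_downdate(pc$Vinv, Xm, c)
  pc$V <- pc$V - c * tcrossprod(Xm)
  pc$edits <- c(pc$edits, sprintf("lowrank(m=%d,c=%.4g)", ncol(Xm), c))
  pc
}

#' Inverse of a GRM after removing m markers, from one base inversion
#'
#' Applies the Woodbury identity with unit weight to an already inverted
#' GRM: `G[m out]^{-1} = G^{-1} + G^{-1} Xm [I - Xm' G^{-1} Xm]^{-1} Xm'
#' G^{-1}`. Used by the mixed-model-equation path, where `G` needs to be
#' inverted only once per scan.
#'
#' @param Ginv inverse of the full (possibly scaled) GRM.
#' @param Xm n x m matrix of the removed markers' centered columns, already
#'   multiplied by `sqrt(scale_c)` if the GRM is scaled (equivalently pass
#'   `c = scale_c`).
#' @param c scalar weight of each removed outer product (default 1).
#' @return The downdated inverse matrix.
#' @export
downdate_grm_inv <- function(Ginv, Xm, c = 1) {
  .woodbury_downdate(as.matrix(Ginv), Xm, c)
}

#' Sequential eigenvector-then-marker downdate
#'
#' Removes the listed PC score vectors' genetic contributions
#' `sigma_g2 * sum_i pc_i pc_i'` from `V` via one low-rank downdate, then a
#' tested marker's contribution `c * x_j x_j'` via a rank-one downdate —
#' the workflow for a structure-adjusted scan where eigenvectors of `G` are
#' treated as fixed covariates and are therefore discounted from the
#' covariance structure. Only one base inversion of `V` is ever performed.
#'
#' @param pc a `PhenoCov`.
#' @param pcs list (or n x k matrix) of PC score vectors from [pc_scores()].
#' @param sigma_g2 genomic variance multiplying the PC outer products.
#' @param x_j optional marker column to remove afterwards.
#' @param c weight for the marker downdate (typically
#'   `sigma_g2 * scale_c`).
#' @return A `PhenoCov` with both stages applied.
#' @export
eig_downdate_then_marker <- function(pc, pcs, sigma_g2, x_j = NULL, c = NULL) {
  stopifnot(inherits(pc, "PhenoCov"))
  if (is.list(pcs)) pcs <- do.call(cbind, pcs)
  if (!is.null(pcs) && length(pcs)) {
    pc <- lowrank_downdate_inv(pc, as.matrix(pcs), sigma_g2)
  }
  if (!is.null(x_j)) {
    if (is.null(c)) c <- pc$sigma_g2 * pc$scale_c
    pc <- rank1_downdate_inv(pc, x_j, c)
  }
  pc
}
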