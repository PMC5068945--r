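#' Build a genomic relationship matrix from centered dosages
#'
#' With `X` the n x p matrix of centered dosages, the raw GRM is
#' `G = XX' = sum_j x_j x_j'`, the sum of per-marker outer products. The
#' `"mean_diag"` scaling divides by `p * dbar`, where `dbar` is the mean
#' diagonal of `XX'/p`, so that the scaled GRM has mean diagonal exactly 1 —
#' the construction used for case-study panels where phenotypes are on a
#' standardized scale. The per-marker weight `scale_c` (1 for raw,
#' `1/(p*dbar)` for scaled) is frozen at build time: marker removal subtracts
#' `scale_c * x_j x_j'` and never recomputes `dbar`, which is what makes the
#' marker-out invariance of the GLS estimator hold exactly for both scalings.
#'
#' @param g a centered [genotype_matrix()].
#' @param scaling `"raw"` or `"mean_diag"`.
#' @return An object of class `"GRM"` with elements `matrix` (n x n),
#'   `scale_c`, `source_markers`, `removed_eigs`, `sample_ids`.
#' @export
build_grm <- function(g, scaling = c("raw", "mean_diag")) {
  scaling <- match.arg(scaling)
  stopifnot(inherits(g, "GenotypeMatrix"))
  if (!g$centered) stop("build_grm requires centered markers")
  p <- ncol(g$values)
  if (p == 0) stop("no markers")
  XXt <- tcrossprod(g$values)
  scale_c <- 1
  if (scaling == "mean_diag") {
    dbar <- mean(diag(XXt)) / p
    if (dbar <= 0) stop("all markers monomorphic; mean diagonal is zero")
    scale_c <- 1 / (p * dbar)
    XXt <- XXt * scale_c
  }
  structure(list(matrix = XXt, scale_c = scale_c,
                 source_markers = g$marker_ids,
                 removed_eigs = integer(0),
                 sample_ids = g$sample_ids,
                 scaling = scaling),
            class = "GRM")
}

#' @export
print.GRM <- function(x, ...) {
  cat(sprintf("GRM: %d x %d (%s scaling, scale_c = %.6g, %d source markers)\n",
              nrow(x$matrix), ncol(x$matrix), x$scaling, x$scale_c,
              length(x$source_markers)))
  if (length(x$removed_eigs))
    cat("  eigenvectors removed:", paste(x$removed_eigs, collapse = ", "), "\n")
  invisible(x)
}

#' Wrap an existing relationship matrix as a GRM object
#'
#' For matrices imported from CSV or constructed outside [build_grm()]
#' (note that a GRM from column-centered markers always has the unit vector
#' in its null space, so a strictly positive-definite `G` must come from
#' elsewhere, e.g. a blended or synthetic matrix).
#'
#' @param M symmetric positive semi-definite numeric matrix.
#' @param scale_c per-marker weight associated with the matrix.
#' @param sample_ids optional sample identifiers.
#' @return A `GRM` object with an empty marker source set.
#' @export
as_grm <- function(M, scale_c = 1, sample_ids = rownames(M)) {
  M <- as.matrix(M)
  if (nrow(M) != ncol(M)) stop("matrix must be square")
  if (max(abs(M - t(M))) > 1e-8 * max(1, max(abs(M))))
    stop("matrix is not symmetric")
  if (is.null(sample_ids)) sample_ids <- paste0("id_", seq_len(nrow(M)))
  structure(list(matrix = (M + t(M)) / 2, scale_c = scale_c,
                 source_markers = character(0), removed_eigs = integer(0),
                 sample_ids = as.character(sample_ids), scaling = "external"),
            class = "GRM")
}

#' Remove markers from a GRM
#'
#' Subtracts each dropped marker's contribution `scale_c * x_j x_j'` from the
#' GRM, yielding `G[-j]` (or `G[m out]` for a set). The genotype matrix must
#' be the same centered matrix the GRM was built from, so that the marker
#' columns match the GRM's coding. The scaling constant is left untouched.
#'
#' @param grm a `GRM`.
#' @param g the centered `GenotypeMatrix` used to build `grm`.
#' @param drop marker indices or IDs to remove.
#' @return A `GRM` without the dropped markers' contributions.
#' @export
drop_markers_grm <- function(grm, g, drop) {
  stopifnot(inherits(grm, "GRM"), inherits(g, "GenotypeMatrix"))
  if (!g$centered) stop("genotype matrix must be centered")
  if (is.character(drop)) {
    idx <- match(drop, g$marker_ids)
    if (anyNA(idx)) stop("unknown marker id(s): ",
                         paste(drop[is.na(idx)], collapse = ", "))
  } else idx <- as.integer(drop)
  ids <- g$marker_ids[idx]
  if (!all(ids %in% grm$source_markers))
    stop("marker(s) not in the GRM source set")
  Xd <- g$values[, idx, drop = FALSE]
  grm$matrix <- grm$matrix - grm$scale_c * tcrossprod(Xd)
  grm$source_markers <- setdiff(grm$source_markers, ids)
  grm
}

#' Eigendecomposition of a GRM
#'
#' Full spectral decomposition `G = U diag(lambda) U'` with eigenvalues in
#' descending order. Eigenvalues in `[-tol, 0]` (numerical noise on a
#' positive semi-definite matrix) are clipped to zero; anything below `-tol`
#' with `tol = 1e-8 * lambda_1` signals a genuinely indefinite input and is
#' an error.
#'
#' @param grm a `GRM`.
#' @return An object of class `"EigenGRM"` with `U` (n x n orthonormal),
#'   `lambda` (descending), and `parent` (the `GRM`).
#' @export
eigen_grm <- function(grm) {
  stopifnot(inherits(grm, "GRM"))
  M <- grm$matrix
  if (max(abs(M - t(M))) > 1e-10 * max(1, max(abs(M))))
    stop("GRM is not symmetric")
  es <- eigen((M + t(M)) / 2, symmetric = TRUE)
  lam <- es$values
  tol <- 1e-8 * max(lam[1], .Machine$double.eps)
  if (any(lam < -tol))
    stop(sprintf("GRM is not positive semi-definite (min eigenvalue %.3g)",
                 min(lam)))
  lam[lam < 0] <- 0
  structure(list(U = es$vectors, lambda = lam, parent = grm),
            class = "EigenGRM")
}

#' @export
print.EigenGRM <- function(x, ...) {
  cat(sprintf("EigenGRM: %d eigenpairs, lambda in [%.4g, %.4g]\n",
              length(x$lambda), min(x$lambda), max(x$lambda)))
  invisible(x)
}

#' Remove eigenvectors from a GRM
#'
#' Returns `sum_{i not in drop} U_i U_i' lambda_i`, i.e. the GRM with the
#' listed eigenpairs' contributions removed — the similarity structure left
#' after dominant axes of stratification are absorbed into fixed regressions.
#'
#' @param e an `EigenGRM`.
#' @param drop eigen indices (1 = largest eigenvalue) to remove.
#' @return A `GRM` with `removed_eigs` recorded.
#' @export
drop_eigvecs_grm <- function(e, drop = integer(0)) {
  stopifnot(inherits(e, "EigenGRM"))
  drop <- as.integer(drop)
  n <- length(e$lambda)
  if (length(drop) && (any(drop < 1) || any(drop > n)))
    stop("eigen index out of range")
  grm <- e$parent
  if (length(drop)) {
    Ud <- e$U[, drop, drop = FALSE]
    grm$matrix <- grm$matrix -
      Ud %*% (e$lambda[drop] * t(Ud))
    grm$matrix <- (grm$matrix + t(grm$matrix)) / 2
  }
  grm$removed_eigs <- sort(unique(c(grm$removed_eigs, drop)))
  grm
}

#' Principal-component score vector(s) of a GRM
#'
#' The i-th PC score vector is `U_i * sqrt(lambda_i)`, so that the outer
#' products of all score vectors add back to `G` and `||pc_i||^2 = lambda_i`.
#' These are the covariates used when structure axes enter the model as
#' fixed regressions.
#'
#' @param e an `EigenGRM`.
#' @param i eigen index or vector of indices.
#' @return A numeric vector (single index) or n x length(i) matrix.
#' @export
pc_scores <- function(e, i) {
  stopifnot(inherits(e, "EigenGRM"))
  i <- as.integer(i)
  if (any(i < 1) || any(i > length(e$lambda))) stop("eigen index out of range")
  if (any(e$lambda[i] < 0)) stop("negative eigenvalue")
  sc <- e$U[, i, drop = FALSE] %*% diag(sqrt(e$lambda[i]),
                                        nrow = length(i))
  if (length(i) == 1L) drop(sc) else sc
}

#' Export / import a GRM as CSV with a sample-ID header
#'
#' @param grm a `GRM`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_grm <- function(grm, path) {
  df <- data.frame(id = grm$sample_ids, grm$matrix, check.names = FALSE)
  colnames(df) <- c("id", grm$sample_ids)
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}
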