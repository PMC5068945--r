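#' Construct a genotype matrix object
#'
#' A `GenotypeMatrix` holds an n x p dosage matrix `X` together with sample
#' and marker identifiers, the dosage coding, and the centering state. Before
#' centering, dosages lie in \{0, 1, 2\} for biallelic diploid codes
#' (`"diploid012"`) or \{0, 1\} for inbred-line / presence-absence markers
#' such as DArT (`"binary01"`). After [center_markers()] each column has mean
#' zero and the original column means are retained in `col_means`, so allele
#' frequencies remain recoverable.
#'
#' @param values numeric n x p matrix of allele dosages (rows = samples).
#' @param sample_ids character vector of length n; defaults to rownames.
#' @param marker_ids character vector of length p; defaults to colnames.
#' @param ploidy_code `"diploid012"` or `"binary01"`.
#' @param centered logical; `TRUE` only when columns have already been
#'   centered and `col_means` holds the subtracted means.
#' @param col_means numeric vector of length p of original column means
#'   (required when `centered = TRUE`).
#'
#' @return An object of class `"GenotypeMatrix"`.
#' @export
genotype_matrix <- function(values, sample_ids = rownames(values),
                            marker_ids = colnames(values),
                            ploidy_code = c("diploid012", "binary01"),
                            centered = FALSE, col_means = NULL) {
  ploidy_code <- match.arg(ploidy_code)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  n <- nrow(values)
  p <- ncol(values)
  if (is.null(sample_ids)) sample_ids <- sprintf("id_%d", seq_len(n))
  if (is.null(marker_ids)) marker_ids <- sprintf("m_%d", seq_len(p))
  sample_ids <- as.character(sample_ids)
  marker_ids <- as.character(marker_ids)
  stopifnot(length(sample_ids) == n, length(marker_ids) == p)
  if (anyDuplicated(sample_ids)) stop("duplicated sample ids")
  if (anyNA(values)) stop("genotype matrix contains missing values")
  if (!centered) {
    .check_dosage_range(values, ploidy_code)
    col_means <- colMeans(values)
  } else {
    if (is.null(col_means) || length(col_means) != p)
      stop("centered GenotypeMatrix requires 'col_means' of length p")
    cm <- colMeans(values)
    if (p > 0 && max(abs(cm)) > 1e-10)
      stop("claimed centered but column means exceed 1e-10")
  }
  dimnames(values) <- list(sample_ids, marker_ids)
  structure(list(values = values, sample_ids = sample_ids,
                 marker_ids = marker_ids, ploidy_code = ploidy_code,
                 centered = centered, col_means = as.numeric(col_means),
                 monomorphic = .find_monomorphic(values, centered, col_means,
                                                 ploidy_code)),
            class = "GenotypeMatrix")
}

.legal_dosages <- function(ploidy_code) {
  if (ploidy_code == "diploid012") c(0, 1, 2) else c(0, 1)
}

.check_dosage_range <- function(values, ploidy_code) {
  legal <- .legal_dosages(ploidy_code)
  bad <- which(!(values %in% legal))
  if (length(bad)) {
    i <- ((bad[1] - 1) %% nrow(values)) + 1
    j <- ((bad[1] - 1) %/% nrow(values)) + 1
    stop(sprintf(
      "dosage %g at row %d, column %d is not a legal %s code",
      values[bad[1]], i, j, ploidy_code))
  }
  invisible(TRUE)
}

.find_monomorphic <- function(values, centered, col_means, ploidy_code) {
  if (ncol(values) == 0) return(logical(0))
  if (centered) {
    apply(values, 2, function(x) all(abs(x) < 1e-12))
  } else {
    apply(values, 2, function(x) length(unique(x)) == 1L)
  }
}

#' @export
print.GenotypeMatrix <- function(x, ...) {
  cat(sprintf("GenotypeMatrix: %d samples x %d markers (%s, %s)\n",
              nrow(x$values), ncol(x$values), x$ploidy_code,
              if (x$centered) "centered" else "raw dosages"))
  if (any(x$monomorphic))
    cat(sprintf("  %d monomorphic marker(s) flagged\n", sum(x$monomorphic)))
  invisible(x)
}

#' @export
dim.GenotypeMatrix <- function(x) dim(x$values)

#' Read a genotype dosage matrix from delimited text
#'
#' Expects a header row of marker IDs and a first column of sample IDs;
#' remaining cells are allele dosages. Missing cells (empty or `NA`) are
#' mean-imputed column by column under `missing_policy = "mean_impute"`,
#' the common practice before GRM construction, or rejected under `"fail"`.
#' Imputation happens before any centering.
#'
#' @param path file path to a CSV or TSV file.
#' @param dialect `"csv"`, `"tsv"`, or `"auto"` (by file extension).
#' @param ploidy_code dosage coding; `"auto"` infers `"diploid012"` when any
#'   dosage of 2 is present and `"binary01"` otherwise.
#' @param missing_policy `"mean_impute"` or `"fail"`.
#'
#' @return A [genotype_matrix()] in file row/column order.
#' @seealso [write_genotypes()], [center_markers()]
#' @export
read_genotypes <- function(path, dialect = c("auto", "csv", "tsv"),
                           ploidy_code = c("auto", "diploid012", "binary01"),
                           missing_policy = c("mean_impute", "fail")) {
  dialect <- match.arg(dialect)
  ploidy_code <- match.arg(ploidy_code)
  missing_policy <- match.arg(missing_policy)
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- switch(dialect,
                csv = ",", tsv = "\t",
                auto = if (grepl("\\.tsv$|\\.txt$", path)) "\t" else ",")
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (ncol(df) < 2) stop("expected sample-ID column plus marker columns")
  sample_ids <- df[[1]]
  marker_ids <- colnames(df)[-1]
  raw <- as.matrix(df[, -1, drop = FALSE])
  vals <- suppressWarnings(matrix(as.numeric(raw), nrow = nrow(raw)))
  nonnum <- is.na(vals) & !is.na(raw) & !(raw %in% c("", "NA", "na", "."))
  if (any(nonnum)) {
    k <- which(nonnum)[1]
    i <- ((k - 1) %% nrow(vals)) + 1
    j <- ((k - 1) %/% nrow(vals)) + 1
    stop(sprintf("non-numeric genotype '%s' for sample '%s', marker '%s'",
                 raw[k], sample_ids[i], marker_ids[j]))
  }
  if (anyNA(vals)) {
    if (missing_policy == "fail")
      stop("missing genotypes present and missing_policy = 'fail'")
    for (j in seq_len(ncol(vals))) {
      miss <- is.na(vals[, j])
      if (all(miss))
        stop(sprintf("marker '%s' has no observed genotypes", marker_ids[j]))
      if (any(miss)) vals[miss, j] <- mean(vals[!miss, j])
    }
  }
  if (ploidy_code == "auto")
    ploidy_code <- if (any(vals > 1)) "diploid012" else "binary01"
  # imputed cells may be fractional; range-check only the observed dosages
  observed <- vals[!is.na(suppressWarnings(matrix(as.numeric(raw),
                                                  nrow = nrow(raw))))]
  legal <- .legal_dosages(ploidy_code)
  if (length(observed) && !all(observed %in% legal)) {
    g_chk <- matrix(suppressWarnings(as.numeric(raw)), nrow = nrow(raw))
    bad <- which(!(g_chk %in% c(legal, NA)) & !is.na(g_chk))
    i <- ((bad[1] - 1) %% nrow(g_chk)) + 1
    j <- ((bad[1] - 1) %/% nrow(g_chk)) + 1
    stop(sprintf("dosage %g for sample '%s', marker '%s' out of range for %s",
                 g_chk[bad[1]], sample_ids[i], marker_ids[j], ploidy_code))
  }
  rownames(vals) <- sample_ids
  colnames(vals) <- marker_ids
  g <- structure(list(values = vals, sample_ids = sample_ids,
                      marker_ids = marker_ids, ploidy_code = ploidy_code,
                      centered = FALSE, col_means = as.numeric(colMeans(vals)),
                      monomorphic = .find_monomorphic(vals, FALSE, NULL,
                                                      ploidy_code)),
                 class = "GenotypeMatrix")
  g
}

#' Write a genotype matrix as delimited text
#'
#' Inverse of [read_genotypes()] for the supported dialect; round-trips
#' dosage values exactly for integer-coded data.
#'
#' @param g a `GenotypeMatrix`.
#' @param path output path.
#' @param dialect `"csv"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(g, path, dialect = c("csv", "tsv")) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "csv") "," else "\t"
  df <- data.frame(id = g$sample_ids, g$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c("id", g$marker_ids)
  utils::write.table(df, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Center marker dosages column by column
#'
#' Subtracts each marker's mean dosage so every column of `X` has mean zero,
#' the coding under which the GRM `G = XX'` measures similarity in state.
#' Original means are kept in `col_means`; monomorphic markers become exact
#' zero columns and stay flagged (they contribute nothing to `G` and are
#' skipped by the scans).
#'
#' @param g an uncentered `GenotypeMatrix`.
#' @return A centered `GenotypeMatrix`.
#' @export
center_markers <- function(g) {
  stopifnot(inherits(g, "GenotypeMatrix"))
  if (g$centered) stop("GenotypeMatrix is already centered")
  cm <- colMeans(g$values)
  vals <- sweep(g$values, 2, cm, "-")
  if (any(g$monomorphic)) vals[, g$monomorphic] <- 0
  dimnames(vals) <- dimnames(g$values)
  g$values <- vals
  g$centered <- TRUE
  g$col_means <- as.numeric(cm)
  g
}

#' Undo marker centering
#'
#' @param g a centered `GenotypeMatrix`.
#' @return The `GenotypeMatrix` on the original dosage scale.
#' @export
uncenter_markers <- function(g) {
  stopifnot(inherits(g, "GenotypeMatrix"))
  if (!g$centered) stop("GenotypeMatrix is not centered")
  vals <- sweep(g$values, 2, g$col_means, "+")
  dimnames(vals) <- dimnames(g$values)
  g$values <- vals
  g$centered <- FALSE
  g
}

#' Allele frequency of one or all markers
#'
#' Computed from the original (uncentered) mean dosage, which is preserved in
#' `col_means` after centering: `q = mean/2` for diploid 0/1/2 codes and
#' `q = mean` for binary 0/1 codes.
#'
#' @param g a `GenotypeMatrix`.
#' @param j marker index or marker ID; `NULL` returns all frequencies.
#' @return Numeric frequency (or vector of frequencies) in `[0, 1]`.
#' @export
allele_freq <- function(g, j = NULL) {
  stopifnot(inherits(g, "GenotypeMatrix"))
  m <- g$col_means
  q <- if (g$ploidy_code == "diploid012") m / 2 else m
  names(q) <- g$marker_ids
  if (is.null(j)) return(q)
  if (is.character(j)) j <- match(j, g$marker_ids)
  if (anyNA(j) || any(j < 1) || any(j > length(q)))
    stop("unknown marker index/id")
  unname(q[j])
}

#' Read a two-column phenotype file (id, value)
#'
#' @param path CSV/TSV path with a header; first column sample IDs, second
#'   phenotypic values.
#' @param dialect `"auto"`, `"csv"` or `"tsv"`.
#' @return A data.frame with columns `id` and `value`.
#' @export
read_phenotypes <- function(path, dialect = c("auto", "csv", "tsv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- switch(dialect,
                csv = ",", tsv = "\t",
                auto = if (grepl("\\.tsv$|\\.txt$", path)) "\t" else ",")
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("expected (id, value) columns")
  out <- data.frame(id = as.character(df[[1]]), value = as.numeric(df[[2]]),
                    stringsAsFactors = FALSE)
  if (anyNA(out$value)) stop("missing phenotype values are not supported")
  out
}

#' Align a phenotype table to the sample order of a genotype matrix
#'
#' Matching is strictly by sample ID; a missing or duplicated ID is an error
#' rather than a silent reorder or drop.
#'
#' @param g a `GenotypeMatrix`.
#' @param pheno data.frame with `id` and `value` columns (from
#'   [read_phenotypes()]) or a named numeric vector.
#' @return Named numeric vector ordered like `g$sample_ids`.
#' @export
align_phenotypes <- function(g, pheno) {
  stopifnot(inherits(g, "GenotypeMatrix"))
  if (is.numeric(pheno) && !is.null(names(pheno)))
    pheno <- data.frame(id = names(pheno), value = as.numeric(pheno),
                        stringsAsFactors = FALSE)
  if (anyDuplicated(pheno$id)) stop("duplicated phenotype ids")
  idx <- match(g$sample_ids, pheno$id)
  if (anyNA(idx))
    stop("phenotype missing for sample(s): ",
         paste(utils::head(g$sample_ids[is.na(idx)], 5), collapse = ", "))
  y <- pheno$value[idx]
  names(y) <- g$sample_ids
  y
}
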