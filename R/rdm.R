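#' Representational dissimilarity matrices
#'
#' An `rdm` is a symmetric, zero-diagonal condition-by-condition matrix of
#' pattern dissimilarities. RDMs are the common currency of representational
#' similarity analysis: the same container holds dissimilarities derived from
#' stimulus features (Euclidean distances between feature vectors, absolute
#' rating differences, inverted similarity judgments), from fMRI multivoxel
#' patterns (1 - Pearson correlation), or from time-resolved EEG decoding
#' accuracies.
#'
#' @param x square numeric matrix of dissimilarities.
#' @param conditions character vector of condition identifiers; defaults to
#'   the matrix dimnames or `"cond_1"`, ... when absent.
#' @param method optional string recording how the RDM was constructed.
#' @param validate if `TRUE` (default), check symmetry, zero diagonal and
#'   finiteness.
#'
#' @return An object of class `rdm`: the numeric matrix with dimnames set to
#'   the condition ids and attributes `conditions` and `method`.
#' @export
#'
#' @examples
#' m <- as.matrix(dist(matrix(rnorm(12), 4, 3)))
#' r <- rdm(m)
#' n_conditions(r)
rdm <- function(x, conditions = NULL, method = NULL, validate = TRUE) {
  x <- as.matrix(x)
  if (nrow(x) != ncol(x)) stop("an RDM must be square", call. = FALSE)
  if (is.null(conditions)) {
    conditions <- rownames(x) %||% paste0("cond_", seq_len(nrow(x)))
  }
  if (length(conditions) != nrow(x)) {
    stop("`conditions` length must match the matrix dimension", call. = FALSE)
  }
  if (validate) {
    if (any(!is.finite(x))) stop("RDM entries must be finite", call. = FALSE)
    if (max(abs(x - t(x))) > 1e-8 * max(1, max(abs(x)))) {
      stop("RDM must be symmetric", call. = FALSE)
    }
    if (any(abs(diag(x)) > 1e-10)) stop("RDM diagonal must be zero", call. = FALSE)
  }
  x <- (x + t(x)) / 2
  diag(x) <- 0
  dimnames(x) <- list(conditions, conditions)
  structure(x, class = c("rdm", "matrix", "array"),
            conditions = as.character(conditions), method = method)
}

#' @rdname rdm
#' @export
is_rdm <- function(x) inherits(x, "rdm")

#' @rdname rdm
#' @export
n_conditions <- function(x) nrow(x)

#' @export
print.rdm <- function(x, ...) {
  cat(sprintf("<rdm> %d conditions%s\n", nrow(x),
              if (!is.null(attr(x, "method"))) paste0(" [", attr(x, "method"), "]") else ""))
  print(unclass(x)[seq_len(min(6L, nrow(x))), seq_len(min(6L, ncol(x))), drop = FALSE])
  if (nrow(x) > 6L) cat(sprintf("... %d more conditions\n", nrow(x) - 6L))
  invisible(x)
}

#' Vectorize an RDM to its upper triangle
#'
#' Extracts the strictly upper triangular entries in row-major order
#' (d12, d13, ..., d1n, d23, ...), the canonical vector form used by every
#' RSA, regression and variance-partitioning stage. `devectorize_rdm()`
#' restores the symmetric matrix.
#'
#' @param rdm an [rdm] or square symmetric matrix.
#' @return Numeric vector of length `n * (n - 1) / 2`.
#' @export
#'
#' @examples
#' r <- rdm(matrix(c(0, 1, 2, 1, 0, 3, 2, 3, 0), 3, 3))
#' vectorize_rdm(r)  # d12, d13, d23
vectorize_rdm <- function(rdm) {
  m <- as.matrix(rdm)
  if (nrow(m) != ncol(m) || max(abs(m - t(m))) > 1e-8 * max(1, max(abs(m)))) {
    stop("input must be a square symmetric matrix", call. = FALSE)
  }
  # row-major upper triangle == column-major lower triangle of the transpose
  tm <- t(m)
  tm[lower.tri(tm)]
}

#' @param v numeric vector as produced by [vectorize_rdm()].
#' @param conditions optional condition ids for the restored matrix.
#' @rdname vectorize_rdm
#' @export
devectorize_rdm <- function(v, conditions = NULL) {
  n <- (1 + sqrt(1 + 8 * length(v))) / 2
  if (abs(n - round(n)) > 1e-8) {
    stop("vector length is not n*(n-1)/2 for any integer n", call. = FALSE)
  }
  n <- round(n)
  m <- matrix(0, n, n)
  tm <- t(m)
  tm[lower.tri(tm)] <- v
  m <- t(tm)
  m <- m + t(m)
  rdm(m, conditions = conditions, validate = FALSE)
}

#' Read and write RDMs as square CSV files
#'
#' The on-disk format is a square numeric CSV with condition ids as both the
#' header row and the first column, so files interoperate with spreadsheet
#' tools and pandas/numpy readers.
#'
#' @param x an [rdm].
#' @param path file path.
#' @return `read_rdm_csv()` returns an [rdm]; `write_rdm_csv()` returns
#'   `path` invisibly.
#' @export
write_rdm_csv <- function(x, path) {
  write.csv(as.data.frame(unclass(x)), path, row.names = TRUE)
  invisible(path)
}

#' @rdname write_rdm_csv
#' @export
read_rdm_csv <- function(path) {
  df <- read.csv(path, row.names = 1, check.names = FALSE)
  rdm(as.matrix(df), conditions = rownames(df))
}
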