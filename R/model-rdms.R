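#' Model RDM from Euclidean distances between feature vectors
#'
#' Entry (i, j) is the Euclidean distance between the feature vectors of
#' conditions i and j. Used for convolutional-layer features and per-frame
#' motion-energy vectors.
#'
#' @param features numeric matrix `[conditions, features]` (one row per
#'   condition) or a data.frame of numeric columns; rownames are taken as
#'   condition ids.
#' @return An [rdm].
#' @export
#'
#' @examples
#' euclidean_rdm(rbind(a = c(0, 0), b = c(3, 4)))  # d(a, b) = 5
euclidean_rdm <- function(features) {
  m <- as.matrix(features)
  if (!is.numeric(m)) stop("features must be numeric", call. = FALSE)
  if (any(!is.finite(m))) stop("features must be finite", call. = FALSE)
  rdm(as.matrix(dist(m)), conditions = rownames(m), method = "euclidean")
}

#' Binary category model RDM
#'
#' Distance 0 for condition pairs sharing a category label, 1 otherwise
#' (e.g. the sociality feature: social vs nonsocial touch).
#'
#' @param labels vector of category labels, one per condition; names are
#'   taken as condition ids.
#' @return An [rdm].
#' @export
#'
#' @examples
#' binary_category_rdm(c(v1 = "social", v2 = "social", v3 = "nonsocial"))
binary_category_rdm <- function(labels) {
  if (length(labels) < 1L || anyNA(labels)) {
    stop("labels must be non-missing", call. = FALSE)
  }
  m <- 1 * outer(labels, labels, FUN = "!=")
  rdm(m, conditions = names(labels), method = "binary_category")
}

#' Rating-difference model RDM
#'
#' Entry (i, j) is the absolute difference between per-condition scalar
#' ratings (e.g. valence or arousal averaged across raters).
#'
#' @param ratings numeric vector, one scalar per condition; names are taken
#'   as condition ids.
#' @return An [rdm].
#' @export
rating_difference_rdm <- function(ratings) {
  if (any(!is.finite(ratings))) stop("ratings must be finite", call. = FALSE)
  m <- abs(outer(ratings, ratings, FUN = "-"))
  rdm(m, conditions = names(ratings), method = "rating_difference")
}

#' Model RDM from pairwise similarity judgments
#'
#' Converts pairwise similarity judgments on a 1-7 Likert scale
#' (1 = very distinct, 7 = identical), collected per rater, into a
#' dissimilarity matrix: judgments are averaged across raters per pair and
#' subtracted from 7, so identical-looking pairs get dissimilarity 0 and
#' maximally distinct pairs get 6. The diagonal is 0 by definition.
#'
#' @param judgments long-format data.frame with columns `cond_i`, `cond_j`,
#'   `rater`, `score` (scores in `[1, 7]`); every unordered off-diagonal
#'   pair must be judged by at least one rater.
#' @param conditions optional condition ids fixing the matrix order;
#'   defaults to the sorted ids present in `judgments`.
#' @return An [rdm].
#' @export
similarity_inversion_rdm <- function(judgments, conditions = NULL) {
  need <- c("cond_i", "cond_j", "rater", "score")
  if (!all(need %in% names(judgments))) {
    stop("judgments needs columns cond_i, cond_j, rater, score", call. = FALSE)
  }
  if (any(judgments$score < 1 | judgments$score > 7)) {
    stop("similarity judgments must lie in [1, 7]", call. = FALSE)
  }
  conditions <- conditions %||% sort(unique(c(judgments$cond_i, judgments$cond_j)))
  n <- length(conditions)
  i <- match(judgments$cond_i, conditions)
  j <- match(judgments$cond_j, conditions)
  if (anyNA(i) || anyNA(j)) stop("judgments refer to unknown conditions", call. = FALSE)
  key <- paste(pmin(i, j), pmax(i, j))
  mean_sim <- tapply(judgments$score, key, mean)
  m <- matrix(NA_real_, n, n)
  diag(m) <- 7
  idx <- do.call(rbind, strsplit(names(mean_sim), " "))
  ii <- as.integer(idx[, 1]); jj <- as.integer(idx[, 2])
  m[cbind(ii, jj)] <- mean_sim
  m[cbind(jj, ii)] <- mean_sim
  if (anyNA(m)) stop("every condition pair must have at least one judgment", call. = FALSE)
  rdm(7 - m, conditions = conditions, method = "similarity_inversion")
}

#' fMRI ROI patterns
#'
#' A voxel-by-condition multivoxel response matrix for one region of
#' interest, the input to [correlation_distance_rdm()].
#'
#' @param patterns numeric matrix `[voxels, conditions]`.
#' @param roi name of the region.
#' @param conditions optional condition ids (defaults to colnames).
#' @export
roi_patterns <- function(patterns, roi = "roi", conditions = NULL) {
  patterns <- as.matrix(patterns)
  if (nrow(patterns) < 2L) stop("need at least 2 voxels", call. = FALSE)
  if (ncol(patterns) < 3L) stop("need at least 3 conditions", call. = FALSE)
  conditions <- conditions %||% colnames(patterns) %||%
    paste0("cond_", seq_len(ncol(patterns)))
  colnames(patterns) <- conditions
  structure(list(patterns = patterns, roi = roi, conditions = conditions),
            class = "roi_patterns")
}

#' Correlation-distance RDM from multivoxel patterns
#'
#' Entry (i, j) is 1 minus the Pearson correlation between the voxel
#' response vectors of conditions i and j, the standard fMRI pattern
#' dissimilarity. Values lie in `[0, 2]`.
#'
#' @param patterns a [roi_patterns()] or a numeric `[voxels, conditions]`
#'   matrix.
#' @return An [rdm] with `method = "1-correlation"`.
#' @export
correlation_distance_rdm <- function(patterns) {
  if (inherits(patterns, "roi_patterns")) {
    roi <- patterns$roi
    m <- patterns$patterns
    conditions <- patterns$conditions
  } else {
    roi <- NULL
    m <- as.matrix(patterns)
    conditions <- colnames(m)
  }
  if (nrow(m) < 2L) stop("need at least 2 voxels", call. = FALSE)
  sds <- apply(m, 2, sd)
  if (any(sds == 0)) {
    stop("zero-variance condition vector: correlation undefined", call. = FALSE)
  }
  d <- 1 - cor(m)
  diag(d) <- 0
  out <- rdm(d, conditions = conditions, method = "1-correlation")
  attr(out, "roi") <- roi
  out
}
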