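#' Coefficient of determination for a predictor subset
#'
#' Ordinary least-squares R-squared of `y` on the given predictor columns
#' (with intercept): `1 - RSS / TSS`. Rank-deficient designs are fitted on
#' the pivoted full-rank subspace (equivalent to a pseudoinverse fit in
#' fitted values) with a warning.
#'
#' @param y numeric response vector.
#' @param x numeric matrix of predictors (columns), or `NULL`/zero-column
#'   for the intercept-only model (R-squared 0).
#' @return R-squared in `[0, 1]`.
#' @export
fit_r2 <- function(y, x = NULL) {
  y <- as.numeric(y)
  tss <- sum((y - mean(y))^2)
  if (tss == 0) stop("response is constant; R^2 undefined", call. = FALSE)
  if (is.null(x) || NCOL(x) == 0L) return(0)
  x <- as.matrix(x)
  stopifnot(nrow(x) == length(y))
  fit <- lm.fit(cbind(1, x), y)
  if (fit$rank < ncol(x) + 1L) {
    warning("rank-deficient predictor subset; R^2 from pivoted fit", call. = FALSE)
  }
  max(0, min(1, 1 - sum(fit$residuals^2) / tss))
}

# All seven subset R^2 values for 3 predictors (or three for 2 predictors),
# keyed "1", "2", "12", ... in predictor-index order.
subset_r2 <- function(y, xmat) {
  p <- ncol(xmat)
  subsets <- unlist(lapply(seq_len(p), function(k) {
    combn(p, k, paste, collapse = "", simplify = FALSE)
  }))
  vapply(subsets, function(s) {
    idx <- as.integer(strsplit(s, "")[[1]])
    fit_r2(y, xmat[, idx, drop = FALSE])
  }, numeric(1))
}

#' Unique variance of a predictor of interest
#'
#' `UV_POI = R2_full - R2_without_POI`: the drop in explained variance when
#' the predictor of interest is removed from the full model.
#'
#' @param r2 named vector of subset R-squared values as returned by the
#'   internal subset enumeration (names like `"1"`, `"23"`, `"123"`).
#' @param poi index of the predictor of interest.
#' @return Unique variance (nonnegative up to floating point).
#' @export
unique_variance <- function(r2, poi) {
  p <- max(nchar(names(r2)))
  full <- paste(seq_len(p), collapse = "")
  rest <- paste(setdiff(seq_len(p), poi), collapse = "")
  if (!full %in% names(r2) || !rest %in% names(r2)) {
    stop("missing subset R^2 values", call. = FALSE)
  }
  unname(r2[full] - r2[rest])
}

#' Shared (common) variance components for three predictors
#'
#' Commonality analysis for three predictors. Given the seven subset
#' R-squared values, the pairwise and three-way shared components are
#' \deqn{SV_{12} = R^2_{13} + R^2_{23} - R^2_3 - R^2_{123}}
#' \deqn{SV_{13} = R^2_{12} + R^2_{23} - R^2_2 - R^2_{123}}
#' \deqn{SV_{23} = R^2_{12} + R^2_{13} - R^2_1 - R^2_{123}}
#' \deqn{SV_{123} = R^2_1 + R^2_2 + R^2_3 - R^2_{12} - R^2_{13} - R^2_{23} + R^2_{123}}
#' With the unique variances these components sum to `R2_123` exactly
#' (algebraic identity). Shared components can be legitimately negative
#' (suppression) and are reported as-is.
#'
#' @param r2 named vector of the seven subset R-squared values.
#' @return Named vector `c(sv_12, sv_13, sv_23, sv_123)`.
#' @export
shared_variance <- function(r2) {
  need <- c("1", "2", "3", "12", "13", "23", "123")
  if (!all(need %in% names(r2))) stop("all seven subset R^2 required", call. = FALSE)
  c(sv_12 = unname(r2["13"] + r2["23"] - r2["3"] - r2["123"]),
    sv_13 = unname(r2["12"] + r2["23"] - r2["2"] - r2["123"]),
    sv_23 = unname(r2["12"] + r2["13"] - r2["1"] - r2["123"]),
    sv_123 = unname(r2["1"] + r2["2"] + r2["3"] -
                      r2["12"] - r2["13"] - r2["23"] + r2["123"]))
}

#' Time-resolved variance partitioning of an EEG RDM
#'
#' Per window, regresses the (standardized) group-average EEG RDM vector on
#' every subset of two or three predictor RDMs, then decomposes the full
#' model's R-squared into unique variances (one per predictor) and shared
#' variances (one per predictor combination) by commonality analysis.
#' Typical predictor triples are the three fMRI ROIs (EVC, TPJ/pSTS,
#' somatosensory cortex) or sociality with the two key ROIs.
#'
#' @param eeg a [time_resolved_rdm()] (group-average EEG RDMs), or a
#'   numeric `[pairs, windows]` matrix of RDM vectors.
#' @param predictors named list of 2 or 3 [rdm]s (or RDM vectors).
#' @return A `variance_decomposition`: data.frame with one row per window:
#'   `window_ms`, subset R-squareds (`r2_1` ... `r2_123`), unique variances
#'   (`uv_<name>`) and shared variances (`sv_*`), plus attribute
#'   `predictors`. Components satisfy
#'   `sum(uv, sv) == r2_full` at machine precision.
#' @export
decompose_timecourse <- function(eeg, predictors) {
  p <- length(predictors)
  if (p < 2L || p > 3L) stop("need 2 or 3 predictors", call. = FALSE)
  ev <- if (inherits(eeg, "time_resolved_rdm")) trrdm_vectors(eeg) else as.matrix(eeg)
  window_ms <- if (inherits(eeg, "time_resolved_rdm")) eeg$window_ms else seq_len(ncol(ev))
  pnames <- names(predictors) %||% paste0("p", seq_len(p))
  xmat <- vapply(predictors, function(m) {
    v <- if (is_rdm(m) || is.matrix(m)) vectorize_rdm(m) else as.numeric(m)
    as.numeric(scale(v))
  }, numeric(nrow(ev)))

  rows <- lapply(seq_len(ncol(ev)), function(w) {
    y <- as.numeric(scale(ev[, w]))
    r2 <- subset_r2(y, xmat)
    uv <- vapply(seq_len(p), function(k) unique_variance(r2, k), numeric(1))
    names(uv) <- paste0("uv_", pnames)
    if (p == 3L) {
      sv <- shared_variance(r2)
    } else {
      sv <- c(sv_12 = unname(r2["1"] + r2["2"] - r2["12"]))
    }
    c(window_ms = window_ms[w], setNames(r2, paste0("r2_", names(r2))), uv, sv)
  })
  out <- as.data.frame(do.call(rbind, rows))
  attr(out, "predictors") <- pnames
  class(out) <- c("variance_decomposition", "data.frame")
  out
}

#' Write a variance decomposition as long-format delimited text
#'
#' One row per window x component (`r2_*`, `uv_*`, `sv_*`).
#'
#' @param x a `variance_decomposition`.
#' @param path output file path (tab-separated).
#' @return `path`, invisibly.
#' @export
write_variance_decomposition <- function(x, path) {
  stopifnot(inherits(x, "variance_decomposition"))
  comp <- setdiff(names(x), "window_ms")
  long <- do.call(rbind, lapply(comp, function(cn) {
    data.frame(window_ms = x$window_ms, component = cn, value = x[[cn]])
  }))
  utils::write.table(long, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
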