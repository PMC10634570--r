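#' Rank-correlation RSA timecourse
#'
#' Per window, the Spearman rank correlation (average ranks for ties)
#' between the vectorized upper triangles of the time-resolved EEG RDM and
#' a model RDM (a stimulus-feature RDM or an fMRI ROI RDM — the latter is
#' EEG-fMRI fusion). Windows where either vector is constant have an
#' undefined correlation and are returned as `NA` and flagged.
#'
#' @param eeg a [time_resolved_rdm()].
#' @param model an [rdm] over the same conditions.
#' @return An `rsa_timecourse`: list with `stat` (r per window),
#'   `window_ms`, `predictor`, `mode = "spearman"` and `flagged` (logical,
#'   constant-vector windows).
#' @export
rank_correlation_timecourse <- function(eeg, model) {
  stopifnot(inherits(eeg, "time_resolved_rdm"), nrow(model) == length(eeg$conditions))
  mv <- vectorize_rdm(model)
  ev <- trrdm_vectors(eeg)
  flagged <- apply(ev, 2, sd) == 0 | sd(mv) == 0
  r <- rep(NA_real_, ncol(ev))
  ok <- !flagged
  if (any(ok)) {
    r[ok] <- as.numeric(cor(ev[, ok, drop = FALSE], mv, method = "spearman"))
  }
  structure(list(stat = r, window_ms = eeg$window_ms,
                 predictor = attr(model, "method") %||% "model",
                 mode = "spearman", flagged = flagged),
            class = "rsa_timecourse")
}

# Rank-transform then z-score a vector (the regression default, so a
# single-predictor regression degrades gracefully to the rank correlation).
rank_z <- function(x) {
  r <- rank(x, ties.method = "average")
  as.numeric(scale(r))
}

#' Multiple-regression RSA timecourse
#'
#' Per window, ordinary least squares of the EEG RDM vector on all model
#' RDM vectors jointly, returning one beta per model: each feature's
#' contribution while accounting for the variance explained by the others.
#' By default all vectors are rank-transformed and standardized before
#' fitting (`rank_transform = FALSE` fits the raw standardized values).
#'
#' @param eeg a [time_resolved_rdm()].
#' @param models named list of [rdm]s (the predictors).
#' @param rank_transform rank-transform vectors before standardizing
#'   (default TRUE).
#' @return An `rsa_timecourse` with `stat` a `[models, windows]` matrix of
#'   betas and `mode = "regression"`.
#' @export
regression_timecourse <- function(eeg, models, rank_transform = TRUE) {
  stopifnot(inherits(eeg, "time_resolved_rdm"), length(models) >= 1L)
  prep <- if (rank_transform) rank_z else function(x) as.numeric(scale(x))
  xmat <- vapply(models, function(m) prep(vectorize_rdm(m)),
                 numeric(length(vectorize_rdm(models[[1]]))))
  if (qr(xmat)$rank < ncol(xmat)) {
    stop("rank-deficient design: predictors are exactly collinear", call. = FALSE)
  }
  ev <- trrdm_vectors(eeg)
  betas <- vapply(seq_len(ncol(ev)), function(w) {
    y <- prep(ev[, w])
    fit <- lm.fit(cbind(1, xmat), y)
    fit$coefficients[-1]
  }, numeric(ncol(xmat)))
  betas <- matrix(betas, nrow = ncol(xmat),
                  dimnames = list(names(models) %||% paste0("model_", seq_along(models)), NULL))
  structure(list(stat = betas, window_ms = eeg$window_ms,
                 predictor = rownames(betas), mode = "regression",
                 rank_transform = rank_transform),
            class = "rsa_timecourse")
}

#' Leave-one-subject-out noise ceiling
#'
#' Per window, each subject's EEG RDM vector is Spearman-correlated with
#' the average RDM of all other subjects, and the correlations are averaged
#' across subjects. This estimates the best correlation any model could
#' achieve given between-subject consistency, and is plotted as the ceiling
#' band over model timecourses.
#'
#' @param subject_rdms list of [time_resolved_rdm()]s, one per subject,
#'   with identical windows and conditions.
#' @return Numeric vector of per-window ceiling values.
#' @export
noise_ceiling <- function(subject_rdms) {
  n_sub <- length(subject_rdms)
  if (n_sub < 2L) stop("need at least 2 subjects", call. = FALSE)
  vecs <- lapply(subject_rdms, trrdm_vectors)  # each pairs x windows
  n_win <- ncol(vecs[[1]])
  total <- Reduce(`+`, vecs)
  per_sub <- vapply(seq_len(n_sub), function(s) {
    loo <- (total - vecs[[s]]) / (n_sub - 1)
    vapply(seq_len(n_win), function(w) {
      suppressWarnings(cor(vecs[[s]][, w], loo[, w], method = "spearman"))
    }, numeric(1))
  }, numeric(n_win))
  rowMeans(matrix(per_sub, nrow = n_win))
}

#' Onset latency from a significance mask
#'
#' The onset is the center time of the first window of the earliest
#' significant cluster. With an empty mask the onset is undefined (`NA`),
#' not an error.
#'
#' @param timecourse an `rsa_timecourse` (or any object with `window_ms`),
#'   or a numeric vector of window centers.
#' @param mask logical significance mask aligned to the windows, e.g. from
#'   [cluster_correct()].
#' @return A `latency_estimate`: list with `onset_ms` (or `NA`),
#'   `predictor` and `definition`.
#' @export
onset_latency <- function(timecourse, mask) {
  window_ms <- if (is.numeric(timecourse)) timecourse else timecourse$window_ms
  if (length(mask) != length(window_ms)) {
    stop("mask and timecourse must have the same number of windows", call. = FALSE)
  }
  onset <- if (any(mask)) window_ms[which(mask)[1]] else NA_real_
  structure(list(onset_ms = onset,
                 predictor = if (is.numeric(timecourse)) NA_character_
                             else (timecourse$predictor[1] %||% NA_character_),
                 definition = "first window of first significant cluster"),
            class = "latency_estimate")
}

#' Compare two sets of onset latencies
#'
#' Two-sided Mann-Whitney U test between two samples of onset latencies
#' (e.g. subject-level onsets for two regions): exact for small samples
#' without ties, normal approximation otherwise.
#'
#' @param samples_a,samples_b numeric latency samples (>= 3 each).
#' @return List with `U` (the Mann-Whitney U statistic for `samples_a`),
#'   `p`, and `method`.
#' @export
latency_difference_test <- function(samples_a, samples_b) {
  samples_a <- samples_a[is.finite(samples_a)]
  samples_b <- samples_b[is.finite(samples_b)]
  if (length(samples_a) < 3L || length(samples_b) < 3L) {
    stop("need at least 3 finite latencies per group", call. = FALSE)
  }
  ties <- any(duplicated(c(samples_a, samples_b)))
  exact <- !ties && length(samples_a) < 50 && length(samples_b) < 50
  wt <- suppressWarnings(
    wilcox.test(samples_a, samples_b, exact = exact, correct = !exact)
  )
  list(U = unname(wt$statistic), p = wt$p.value,
       method = if (exact) "exact" else "normal approximation")
}

#' Subject-level onset latencies from per-subject timecourses
#'
#' Derives one onset latency per subject by thresholding each subject's
#' timecourse at the given quantile of a sign-flip null of that subject's
#' values pooled over windows, taking the first window of the first
#' suprathreshold run. Provides the latency samples consumed by
#' [latency_difference_test()] when comparing regions. A bootstrap mode
#' (resampling subjects and recomputing group onsets) is available via
#' `mode = "bootstrap"`.
#'
#' @param subject_stats `[subjects, windows]` matrix of per-subject
#'   statistics (e.g. Spearman r per window).
#' @param window_ms window centers.
#' @param group_null_q quantile of the group-level sign-flip null used as
#'   the per-window threshold (default 0.95).
#' @param mode `"subject"` (default) or `"bootstrap"`.
#' @param n_boot bootstrap resamples when `mode = "bootstrap"`.
#' @param n_permutations sign-flip iterations for the null threshold.
#' @param seed integer seed.
#' @return Numeric vector of latencies (ms; `NA` when a subject/resample
#'   never exceeds threshold).
#' @export
subject_onsets <- function(subject_stats, window_ms, group_null_q = 0.95,
                           mode = c("subject", "bootstrap"), n_boot = 100L,
                           n_permutations = 1000L, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(is.matrix(subject_stats), ncol(subject_stats) == length(window_ms))
  n_sub <- nrow(subject_stats)
  thr <- with_seed(child_seed(seed, 7L), {
    perm <- vapply(seq_len(n_permutations), function(i) {
      signs <- sample(c(-1, 1), n_sub, replace = TRUE)
      colMeans(subject_stats * signs)
    }, numeric(ncol(subject_stats)))
    apply(perm, 1, quantile, probs = group_null_q)
  })
  first_cross <- function(v) {
    hit <- which(v > thr)
    if (length(hit)) window_ms[hit[1]] else NA_real_
  }
  if (mode == "subject") {
    apply(subject_stats, 1, first_cross)
  } else {
    with_seed(child_seed(seed, 8L), {
      vapply(seq_len(n_boot), function(b) {
        first_cross(colMeans(subject_stats[sample(n_sub, replace = TRUE), , drop = FALSE]))
      }, numeric(1))
    })
  }
}
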