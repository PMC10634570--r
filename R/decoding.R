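#' Sliding analysis windows over an epoch's time axis
#'
#' Defines the time windows used by decoding and all downstream
#' time-resolved analyses: by default 10-ms windows advanced in 4-ms steps
#' (6 ms overlap), i.e. 5 samples per window and a 2-sample step at 500 Hz.
#' Window timestamps are the window centers.
#'
#' @param times epoch time axis in ms (uniform spacing).
#' @param width_ms window width, ms.
#' @param step_ms step between window starts, ms.
#' @param range_ms optional `c(min, max)` restriction on window centers.
#' @return data.frame with columns `start` and `end` (sample indices,
#'   inclusive) and `center_ms`.
#' @export
sliding_windows <- function(times, width_ms = 10, step_ms = 4, range_ms = NULL) {
  fs <- 1000 / diff(times[1:2])
  w <- max(1L, round(width_ms * fs / 1000))
  s <- max(1L, round(step_ms * fs / 1000))
  starts <- seq(1L, length(times) - w + 1L, by = s)
  out <- data.frame(start = starts, end = starts + w - 1L)
  out$center_ms <- (times[out$start] + times[out$end]) / 2
  if (!is.null(range_ms)) {
    out <- out[out$center_ms >= range_ms[1] & out$center_ms <= range_ms[2], ]
    rownames(out) <- NULL
  }
  out
}

#' Average same-condition trials into pseudo-trials
#'
#' Splits each condition's source trials at random into `n_folds`
#' cross-validation folds (the split is over source trials, before
#' averaging, so no source trial leaks across folds), then partitions each
#' condition x fold cell into disjoint groups of about `group_size` trials
#' and averages each group into one pseudo-trial. Averaging same-condition
#' trials raises the signal-to-noise ratio of the condition patterns. When
#' a cell holds fewer than `group_size` trials the group size is lowered to
#' the largest feasible value (at least 2), with a message.
#'
#' @param epochs an [epoch_set]; every condition needs at least 2 trials
#'   per fold.
#' @param n_folds number of folds (default 2).
#' @param group_size target trials per pseudo-trial (default 7, the middle
#'   of the six-to-eight range; cells are split into
#'   `floor(n / group_size)` groups of near-equal size, so actual group
#'   sizes stay within one of the target).
#' @param seed integer seed; the grouping is deterministic given it.
#' @return A `pseudo_trial_set`: list with `data`
#'   `[pseudo_trials, channels, samples]`, `labels`, `fold`, `times`,
#'   `sample_rate`, `group_size`, `seed`.
#' @export
make_pseudotrials <- function(epochs, n_folds = 2L, group_size = 7L, seed = 1L) {
  stopifnot(inherits(epochs, "epoch_set"))
  stopifnot_scalar_count(n_folds, "n_folds", min = 1L)
  stopifnot_scalar_count(group_size, "group_size", min = 2L)
  conds <- unique(epochs$labels)
  with_seed(as.integer(seed), {
    rows <- list(); labs <- list(); folds <- list()
    lowered <- FALSE
    for (cond in conds) {
      idx <- sample(which(epochs$labels == cond))
      fold_of <- rep_len(seq_len(n_folds), length(idx))
      for (f in seq_len(n_folds)) {
        cell <- idx[fold_of == f]
        n <- length(cell)
        if (n < 2L) {
          stop(sprintf("condition %s has fewer than 2 trials in a fold", cond),
               call. = FALSE)
        }
        g <- group_size
        if (n < g) { g <- n; lowered <- TRUE }
        k <- max(1L, n %/% g)
        grp <- rep_len(seq_len(k), n)  # near-equal group sizes, all trials used
        for (gi in seq_len(k)) {
          rows[[length(rows) + 1L]] <- cell[grp == gi]
          labs[[length(labs) + 1L]] <- cond
          folds[[length(folds) + 1L]] <- f
        }
      }
    }
    if (lowered) message("group size lowered for cells with few trials")
    n_ps <- length(rows)
    d <- dim(epochs$data)
    data <- array(0, c(n_ps, d[2], d[3]))
    trial_fold <- rep(NA_integer_, d[1])
    for (p in seq_len(n_ps)) {
      data[p, , ] <- apply(epochs$data[rows[[p]], , , drop = FALSE], c(2, 3), mean)
      trial_fold[rows[[p]]] <- unlist(folds)[p]
    }
    structure(list(data = data, labels = unlist(labs), fold = unlist(folds),
                   times = epochs$times, sample_rate = epochs$sample_rate,
                   group_size = group_size, seed = as.integer(seed),
                   source_trials = rows, trial_fold = trial_fold),
              class = "pseudo_trial_set")
  })
}

# Shrinkage-regularized channel noise covariance from within-condition
# residuals, averaged over timepoints. Returns the covariance matrix.
noise_covariance <- function(pseudo, shrinkage) {
  d <- dim(pseudo$data)
  acc <- matrix(0, d[2], d[2])
  dof <- 0
  for (cond in unique(pseudo$labels)) {
    sel <- which(pseudo$labels == cond)
    if (length(sel) < 2L) next
    for (s in seq_len(d[3])) {
      x <- pseudo$data[sel, , s, drop = TRUE]
      x <- sweep(matrix(x, length(sel), d[2]), 2L, colMeans(matrix(x, length(sel), d[2])))
      acc <- acc + crossprod(x)
      dof <- dof + length(sel) - 1L
    }
  }
  if (dof == 0) {
    stop("no within-condition replication to estimate the noise covariance",
         call. = FALSE)
  }
  sigma <- acc / dof
  (1 - shrinkage) * sigma + shrinkage * diag(diag(sigma), d[2])
}

# Inverse matrix square root with an eigenvalue floor.
inv_sqrtm <- function(sigma) {
  e <- eigen(sigma, symmetric = TRUE)
  lam <- e$values
  floor_val <- max(lam) * 1e-10
  if (max(lam) <= 0) stop("noise covariance is singular; increase shrinkage",
                          call. = FALSE)
  if (any(lam < floor_val)) {
    stop("noise covariance is numerically singular; increase shrinkage",
         call. = FALSE)
  }
  e$vectors %*% (t(e$vectors) / sqrt(lam))
}

# Apply a channels x channels transform to every pseudo-trial.
whiten_data <- function(data, w) {
  d <- dim(data)
  flat <- matrix(aperm(data, c(2, 1, 3)), d[2], d[1] * d[3])
  out <- w %*% flat
  aperm(array(out, c(d[2], d[1], d[3])), c(2, 1, 3))
}

#' Multivariate noise normalization
#'
#' Whitens channel data by the inverse square root of a
#' shrinkage-regularized noise covariance estimated from the *training*
#' fold only: within-condition residual covariances across pseudo-trials
#' are pooled over conditions and timepoints, shrunk toward their diagonal
#' by `shrinkage`, inverted through the matrix square root, and the
#' resulting transform is applied to `apply_to` (typically the held-out
#' fold, transformed with the training-fold matrix so no test information
#' leaks into the whitener).
#'
#' @param train `pseudo_trial_set` providing the covariance estimate.
#' @param apply_to `pseudo_trial_set` to transform (default `train`).
#' @param shrinkage shrinkage weight in `[0, 1]` toward the diagonal target
#'   (default 0.1); 1 gives pure per-channel scaling, 0 the raw (possibly
#'   singular) covariance.
#' @return `apply_to` with whitened data and attribute `whitener`.
#' @export
noise_normalize <- function(train, apply_to = train, shrinkage = 0.1) {
  stopifnot(inherits(train, "pseudo_trial_set"),
            inherits(apply_to, "pseudo_trial_set"))
  if (shrinkage < 0 || shrinkage > 1) stop("shrinkage must be in [0, 1]", call. = FALSE)
  w <- inv_sqrtm(noise_covariance(train, shrinkage))
  out <- apply_to
  out$data <- whiten_data(apply_to$data, w)
  attr(out, "whitener") <- w
  out
}

#' Time-resolved pairwise decoding of conditions
#'
#' For every unordered condition pair and sliding window, trains a linear
#' maximum-margin classifier (soft-margin SVM, cost 1) on the training
#' fold's pseudo-trials and tests it on the held-out fold, using the
#' voltages of all channels at all window samples as features. Fold roles
#' are swapped, the whole procedure (fold split, pseudo-trial averaging,
#' noise normalization) is repeated `n_reps` times with fresh
#' randomization, and accuracies are averaged over folds and repetitions.
#'
#' @param epochs an [epoch_set] (one participant's data).
#' @param windows data.frame from [sliding_windows()]; defaults to 10-ms
#'   windows stepped by 4 ms over the whole epoch.
#' @param n_folds,n_reps cross-validation folds (default 2) and repetitions
#'   (default 10).
#' @param group_size pseudo-trial group size, see [make_pseudotrials()].
#' @param noise_norm apply multivariate noise normalization (default TRUE).
#' @param shrinkage covariance shrinkage for the noise normalization.
#' @param cost SVM soft-margin cost (default 1).
#' @param seed integer seed controlling fold splits and grouping.
#' @return A `decoding_result`: list with `accuracy`
#'   `[condition, condition, window]` in `[0, 1]` (diagonal `NA`),
#'   `window_ms`, `conditions`, `n_reps`, `n_folds`.
#' @export
pairwise_decode <- function(epochs, windows = NULL, n_folds = 2L, n_reps = 10L,
                            group_size = 7L, noise_norm = TRUE, shrinkage = 0.1,
                            cost = 1, seed = 1L) {
  stopifnot(inherits(epochs, "epoch_set"))
  windows <- windows %||% sliding_windows(epochs$times)
  if (any(windows$end > length(epochs$times))) {
    stop("window extends beyond the epoch", call. = FALSE)
  }
  conds <- sort(unique(epochs$labels))
  n_cond <- length(conds)
  if (n_cond < 2L) stop("need at least 2 conditions", call. = FALSE)
  n_win <- nrow(windows)
  acc_sum <- array(0, c(n_cond, n_cond, n_win))
  n_obs <- array(0, c(n_cond, n_cond, n_win))

  for (rep in seq_len(n_reps)) {
    pseudo <- make_pseudotrials(epochs, n_folds = n_folds,
                                group_size = group_size,
                                seed = child_seed(seed, 100L + rep))
    lab <- match(pseudo$labels, conds)
    for (test_fold in seq_len(n_folds)) {
      tr <- pseudo$fold != test_fold
      te <- pseudo$fold == test_fold
      if (length(unique(lab[tr])) < n_cond || length(unique(lab[te])) < n_cond) {
        stop("degenerate fold: a condition is missing from a fold", call. = FALSE)
      }
      if (noise_norm) {
        # covariance from the training fold's *source* trials: maximal
        # within-condition replication without touching the test fold
        src <- which(pseudo$trial_fold != test_fold)
        train_set <- list(data = epochs$data[src, , , drop = FALSE],
                          labels = epochs$labels[src])
        w <- inv_sqrtm(noise_covariance(train_set, shrinkage))
        data <- whiten_data(pseudo$data, w)
      } else {
        data <- pseudo$data
      }
      for (wi in seq_len(n_win)) {
        idx <- windows$start[wi]:windows$end[wi]
        feat <- matrix(data[, , idx, drop = FALSE],
                       nrow = dim(data)[1])
        for (i in seq_len(n_cond - 1L)) {
          for (j in (i + 1L):n_cond) {
            tr_rows <- which(tr & (lab == i | lab == j))
            te_rows <- which(te & (lab == i | lab == j))
            y_tr <- factor(lab[tr_rows], levels = c(i, j))
            fit <- e1071::svm(feat[tr_rows, , drop = FALSE], y_tr,
                              kernel = "linear", cost = cost, scale = FALSE)
            pred <- predict(fit, feat[te_rows, , drop = FALSE])
            acc <- mean(pred == factor(lab[te_rows], levels = c(i, j)))
            acc_sum[i, j, wi] <- acc_sum[i, j, wi] + acc
            n_obs[i, j, wi] <- n_obs[i, j, wi] + 1
          }
        }
      }
    }
  }
  accuracy <- acc_sum / n_obs
  for (wi in seq_len(n_win)) {
    m <- accuracy[, , wi]
    m[lower.tri(m)] <- t(m)[lower.tri(m)]
    diag(m) <- NA_real_
    accuracy[, , wi] <- m
  }
  dimnames(accuracy) <- list(conds, conds, NULL)
  structure(list(accuracy = accuracy, window_ms = windows$center_ms,
                 conditions = conds, n_reps = n_reps, n_folds = n_folds),
            class = "decoding_result")
}

#' Time-resolved RDM stack
#'
#' A condition x condition x window array of dissimilarities with zero
#' diagonals, plus the window-center time axis.
#'
#' @param dissim numeric array `[n, n, windows]`.
#' @param window_ms window centers, ms.
#' @param conditions optional condition ids.
#' @export
time_resolved_rdm <- function(dissim, window_ms, conditions = NULL) {
  stopifnot(length(dim(dissim)) == 3L, dim(dissim)[1] == dim(dissim)[2],
            dim(dissim)[3] == length(window_ms))
  conditions <- conditions %||% dimnames(dissim)[[1]] %||%
    paste0("cond_", seq_len(dim(dissim)[1]))
  structure(list(dissim = dissim, window_ms = as.numeric(window_ms),
                 conditions = as.character(conditions)),
            class = "time_resolved_rdm")
}

#' @export
print.time_resolved_rdm <- function(x, ...) {
  cat(sprintf("<time_resolved_rdm> %d conditions x %d windows (%g..%g ms)\n",
              length(x$conditions), length(x$window_ms),
              min(x$window_ms), max(x$window_ms)))
  invisible(x)
}

#' @param x a `time_resolved_rdm`.
#' @param w window index.
#' @rdname time_resolved_rdm
#' @export
window_rdm <- function(x, w) {
  rdm(x$dissim[, , w], conditions = x$conditions, validate = FALSE)
}

#' @rdname time_resolved_rdm
#' @export
trrdm_vectors <- function(x) {
  vapply(seq_along(x$window_ms), function(w) vectorize_rdm(x$dissim[, , w]),
         numeric(length(x$conditions) * (length(x$conditions) - 1) / 2))
}

#' Convert decoding accuracies into a time-resolved EEG RDM
#'
#' Per window, the RDM entry for a condition pair is its decoding accuracy:
#' pairs decoded with high accuracy have more dissimilar neural patterns.
#' The diagonal is set to 0.
#'
#' @param result a `decoding_result` from [pairwise_decode()].
#' @return A [time_resolved_rdm()].
#' @export
decoding_to_rdms <- function(result) {
  stopifnot(inherits(result, "decoding_result"))
  acc <- result$accuracy
  if (any(acc < 0 | acc > 1, na.rm = TRUE)) {
    stop("accuracies must lie in [0, 1]", call. = FALSE)
  }
  for (wi in seq_len(dim(acc)[3])) diag(acc[, , wi]) <- 0
  time_resolved_rdm(acc, result$window_ms, result$conditions)
}
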