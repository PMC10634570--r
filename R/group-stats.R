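#' Sign-permutation null distribution of maximum cluster sums
#'
#' Group-level one-tailed (positive) sign-permutation test: under the null
#' each subject's whole timecourse has a symmetric sign, so each iteration
#' flips every subject's entire timecourse with probability 0.5 (preserving
#' within-subject autocorrelation) and recomputes the group mean. The
#' identity permutation is always included as iteration 0, so permutation
#' p values are never exactly zero. Cluster-forming thresholds are the
#' per-window `1 - cluster_forming_p` quantiles of the permuted group
#' means; for each iteration, suprathreshold windows are grouped into
#' contiguous clusters and the maximum cluster sum (sum of the group-mean
#' statistic over the cluster's windows) is recorded.
#'
#' @param subject_timecourses numeric `[subjects, windows]` matrix of
#'   per-subject statistics (e.g. Spearman correlations per window).
#' @param n_permutations number of random sign flips (default 5000).
#' @param cluster_forming_p per-window tail probability forming clusters
#'   (default 0.05).
#' @param seed integer seed; the null is deterministic given it.
#' @return A `permutation_null`: list with `max_cluster_sums` (length
#'   `n_permutations + 1`, iteration 0 first), per-window `thresholds`,
#'   the observed group `mean`, and the configuration.
#' @export
sign_permutation_null <- function(subject_timecourses, n_permutations = 5000L,
                                  cluster_forming_p = 0.05, seed = 1L) {
  x <- as.matrix(subject_timecourses)
  n_sub <- nrow(x)
  n_win <- ncol(x)
  if (n_sub < 2L) stop("need at least 2 subjects", call. = FALSE)
  stopifnot_scalar_count(n_permutations, "n_permutations", min = 100L)
  if (all(x > 0) || all(x < 0)) {
    warning("all values share one sign; the sign-symmetric null is degenerate",
            call. = FALSE)
  }
  signs <- with_seed(as.integer(seed), {
    matrix(sample(c(-1, 1), n_permutations * n_sub, replace = TRUE),
           n_permutations, n_sub)
  })
  signs <- rbind(rep(1, n_sub), signs)  # iteration 0 = identity
  perm_means <- (signs %*% x) / n_sub   # (P+1) x windows
  thresholds <- apply(perm_means, 2, quantile, probs = 1 - cluster_forming_p,
                      names = FALSE)
  exceed <- sweep(perm_means, 2L, thresholds, ">")
  max_sums <- vapply(seq_len(nrow(perm_means)), function(i) {
    max_cluster_sum(perm_means[i, ], exceed[i, ])
  }, numeric(1))
  structure(list(max_cluster_sums = max_sums, thresholds = thresholds,
                 mean = perm_means[1, ], n_permutations = n_permutations,
                 cluster_forming_p = cluster_forming_p, seed = seed),
            class = "permutation_null")
}

# Largest sum of the statistic over a contiguous suprathreshold run.
max_cluster_sum <- function(stat, above) {
  if (!any(above)) return(0)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  sums <- vapply(which(r$values), function(k) sum(stat[starts[k]:ends[k]]),
                 numeric(1))
  max(sums)
}

#' Cluster-corrected significance of an observed timecourse
#'
#' Forms suprathreshold clusters of the observed group-mean timecourse at
#' the null's per-window thresholds, and compares each cluster's sum with
#' the null distribution of maximum cluster sums: the corrected p value is
#' the fraction of iterations (identity included) whose maximum cluster sum
#' is at least as large. Clusters with `p <= alpha` are significant; the
#' mask covers exactly their windows.
#'
#' @param observed observed group-mean timecourse; defaults to the group
#'   mean stored in `null`.
#' @param null a `permutation_null` from [sign_permutation_null()].
#' @param alpha family-wise error level (default 0.05).
#' @return A `cluster_result`: list with `mean`, logical `mask`, and
#'   `clusters` (data.frame: `start`, `end` window indices, `cluster_sum`,
#'   `p`, `significant`).
#' @export
cluster_correct <- function(null, observed = NULL, alpha = 0.05) {
  stopifnot(inherits(null, "permutation_null"))
  observed <- observed %||% null$mean
  if (length(observed) != length(null$thresholds)) {
    stop("observed timecourse and null have different window counts", call. = FALSE)
  }
  if (length(null$max_cluster_sums) == 0L) stop("empty null distribution", call. = FALSE)
  above <- observed > null$thresholds
  clusters <- data.frame(start = integer(0), end = integer(0),
                         cluster_sum = numeric(0), p = numeric(0),
                         significant = logical(0))
  mask <- rep(FALSE, length(observed))
  if (any(above)) {
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- which(r$values)
    cs <- vapply(keep, function(k) sum(observed[starts[k]:ends[k]]), numeric(1))
    p <- vapply(cs, function(s) mean(null$max_cluster_sums >= s), numeric(1))
    sig <- p <= alpha
    clusters <- data.frame(start = starts[keep], end = ends[keep],
                           cluster_sum = cs, p = p, significant = sig)
    for (i in which(sig)) {
      mask[clusters$start[i]:clusters$end[i]] <- TRUE
    }
  }
  structure(list(mean = observed, mask = mask, clusters = clusters,
                 alpha = alpha),
            class = "cluster_result")
}

#' One-call group-level cluster test
#'
#' Convenience wrapper running [sign_permutation_null()] then
#' [cluster_correct()] on a subjects x windows matrix.
#'
#' @inheritParams sign_permutation_null
#' @inheritParams cluster_correct
#' @return A `cluster_result`.
#' @export
group_cluster_test <- function(subject_timecourses, n_permutations = 5000L,
                               alpha = 0.05, cluster_forming_p = 0.05,
                               seed = 1L) {
  null <- sign_permutation_null(subject_timecourses,
                                n_permutations = n_permutations,
                                cluster_forming_p = cluster_forming_p,
                                seed = seed)
  cluster_correct(null, alpha = alpha)
}
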