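#' Condition event-related potential
#'
#' Pointwise mean across all trials of one condition, giving a channels x
#' samples ERP map for one participant.
#'
#' @param epochs an [epoch_set].
#' @param condition a condition label present in `epochs$labels`; may also
#'   be a vector of labels to pool (e.g. all social conditions).
#' @return An `erp_map`: list with `data` (channels x samples matrix),
#'   `times`, `channels`, `n_trials` and `condition`.
#' @export
condition_erp <- function(epochs, condition) {
  stopifnot(inherits(epochs, "epoch_set"))
  sel <- epochs$labels %in% condition
  if (!any(sel)) stop("unknown condition label", call. = FALSE)
  m <- apply(epochs$data[sel, , , drop = FALSE], c(2, 3), mean)
  structure(list(data = m, times = epochs$times, channels = epochs$channels,
                 n_trials = sum(sel), condition = condition),
            class = "erp_map")
}

#' Grand-average ERP across participants
#'
#' Unweighted mean of per-participant ERP maps, restricted to the channels
#' present in every participant's map (participants with rejected channels
#' contribute only their retained channels, so group analysis runs on the
#' common channel set).
#'
#' @param erps list of `erp_map` objects (one per participant).
#' @param common_channels optional explicit channel subset; defaults to the
#'   intersection of all participants' channels.
#' @return An `erp_map` over the common channels with `n_trials` = number
#'   of participants.
#' @export
grand_average <- function(erps, common_channels = NULL) {
  stopifnot(length(erps) >= 1L, all(vapply(erps, inherits, logical(1), "erp_map")))
  common_channels <- common_channels %||%
    Reduce(intersect, lapply(erps, `[[`, "channels"))
  if (length(common_channels) == 0L) {
    stop("no channel is common to all participants", call. = FALSE)
  }
  mats <- lapply(erps, function(e) {
    idx <- match(common_channels, e$channels)
    if (anyNA(idx)) stop("a participant lacks a requested common channel", call. = FALSE)
    e$data[idx, , drop = FALSE]
  })
  m <- Reduce(`+`, mats) / length(mats)
  structure(list(data = m, times = erps[[1]]$times, channels = common_channels,
                 n_trials = length(erps), condition = "grand_average"),
            class = "erp_map")
}

#' Channel-by-time-slice contrast between two conditions
#'
#' For each channel and successive time slice (default 100 ms wide,
#' spanning the whole epoch), amplitudes are averaged within the slice per
#' participant and the two conditions are compared with a paired t test
#' across participants. The resulting t map is z-scored (mean 0, SD 1
#' across all channel x slice cells by default) for display, and
#' significance is assessed on the t-test p values with Bonferroni
#' correction over channels x slices (over channels only via
#' `correct_over`).
#'
#' @param erps_a,erps_b lists of `erp_map` objects, one per participant, in
#'   matched order (condition A and condition B).
#' @param slice_width_ms slice width in ms (default 100).
#' @param alpha family-wise error level (default 0.05).
#' @param correct_over `"cells"` (channels x slices, default) or
#'   `"channels"`.
#' @return A `contrast_result`: list with matrices `t`, `z`, `p`,
#'   `significant` (channels x slices), `slices` (data.frame of slice
#'   start/end ms) and `channels`. Cells whose paired differences have zero
#'   variance across participants carry an undefined t statistic; they are
#'   reported as 0 and never significant.
#' @export
contrast_slices <- function(erps_a, erps_b, slice_width_ms = 100, alpha = 0.05,
                            correct_over = c("cells", "channels")) {
  correct_over <- match.arg(correct_over)
  stopifnot(length(erps_a) == length(erps_b))
  n_sub <- length(erps_a)
  if (n_sub < 2L) stop("need at least 2 participants", call. = FALSE)
  channels <- Reduce(intersect, lapply(c(erps_a, erps_b), `[[`, "channels"))
  if (length(channels) == 0L) stop("no common channels", call. = FALSE)
  times <- erps_a[[1]]$times
  dt <- 1000 / diff(times[1:2])  # not used; slices defined on times directly
  edges <- seq(times[1], max(times) + 1e-9, by = slice_width_ms)
  if (max(edges) < max(times)) edges <- c(edges, max(edges) + slice_width_ms)
  n_slice <- length(edges) - 1L
  slice_of <- findInterval(times, edges, rightmost.closed = TRUE)

  slice_means <- function(e) {
    idx <- match(channels, e$channels)
    m <- e$data[idx, , drop = FALSE]
    vapply(seq_len(n_slice), function(s) rowMeans(m[, slice_of == s, drop = FALSE]),
           numeric(length(channels)))
  }
  a <- lapply(erps_a, slice_means)
  b <- lapply(erps_b, slice_means)

  tmat <- matrix(0, length(channels), n_slice)
  pmat <- matrix(1, length(channels), n_slice)
  for (ch in seq_along(channels)) {
    for (s in seq_len(n_slice)) {
      da <- vapply(a, function(m) m[ch, s], numeric(1))
      db <- vapply(b, function(m) m[ch, s], numeric(1))
      diffs <- da - db
      if (sd(diffs) <= 1e-12 * (abs(mean(diffs)) + 1)) {
        tmat[ch, s] <- 0
        pmat[ch, s] <- 1
      } else {
        tt <- t.test(diffs)
        tmat[ch, s] <- unname(tt$statistic)
        pmat[ch, s] <- tt$p.value
      }
    }
  }
  s_t <- sd(tmat)
  z <- if (s_t > 0) (tmat - mean(tmat)) / s_t else tmat * 0
  n_tests <- if (correct_over == "cells") length(tmat) else length(channels)
  sig <- pmat * n_tests < alpha
  slices <- data.frame(start_ms = edges[-length(edges)], end_ms = edges[-1])
  dimnames(z) <- dimnames(tmat) <- dimnames(pmat) <- dimnames(sig) <-
    list(channels, paste0("slice_", seq_len(n_slice)))
  structure(list(t = tmat, z = z, p = pmat, significant = sig,
                 slices = slices, channels = channels, alpha = alpha,
                 correct_over = correct_over),
            class = "contrast_result")
}

#' Write a contrast result as long-format delimited text
#'
#' One row per channel x slice with the z-scored t value and significance
#' flag.
#'
#' @param x a `contrast_result`.
#' @param path output file path (tab-separated).
#' @return `path`, invisibly.
#' @export
write_contrast_result <- function(x, path) {
  stopifnot(inherits(x, "contrast_result"))
  long <- do.call(rbind, lapply(seq_len(nrow(x$slices)), function(s) {
    data.frame(channel = x$channels,
               slice_start = x$slices$start_ms[s],
               slice_end = x$slices$end_ms[s],
               z = x$z[, s], t = x$t[, s],
               significant = x$significant[, s])
  }))
  utils::write.table(long, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
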