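#' Epoched EEG data
#'
#' Container for segmented EEG: a trials x channels x samples voltage array
#' (microvolts) with a time axis in milliseconds relative to stimulus onset,
#' per-trial condition labels, and optional rejection masks supplied by
#' external artifact screening.
#'
#' @param data numeric array `[trials, channels, samples]`.
#' @param times numeric vector of sample times in ms, strictly increasing
#'   with uniform spacing `1000 / sample_rate`.
#' @param sample_rate sampling rate in Hz.
#' @param labels per-trial condition labels (length = number of trials).
#' @param channels optional channel names.
#' @param bad_channels,bad_trials optional logical rejection masks
#'   (externally supplied, e.g. from visual inspection or ICA).
#'
#' @return An object of class `epoch_set`.
#' @export
epoch_set <- function(data, times, sample_rate, labels,
                      channels = NULL, bad_channels = NULL, bad_trials = NULL) {
  stopifnot(is.array(data), length(dim(data)) == 3L)
  d <- dim(data)
  if (length(times) != d[3]) stop("`times` length must equal sample count", call. = FALSE)
  dt <- diff(times)
  if (any(dt <= 0) || max(abs(dt - 1000 / sample_rate)) > 1e-6) {
    stop("`times` must increase uniformly by 1000/sample_rate ms", call. = FALSE)
  }
  if (length(labels) != d[1]) stop("one label per trial required", call. = FALSE)
  channels <- channels %||% paste0("ch_", seq_len(d[2]))
  if (length(channels) != d[2]) stop("one name per channel required", call. = FALSE)
  structure(list(data = data, times = as.numeric(times),
                 sample_rate = as.numeric(sample_rate),
                 labels = labels, channels = as.character(channels),
                 bad_channels = bad_channels %||% rep(FALSE, d[2]),
                 bad_trials = bad_trials %||% rep(FALSE, d[1])),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoch_set> %d trials x %d channels x %d samples @ %g Hz\n",
              d[1], d[2], d[3], x$sample_rate))
  cat(sprintf("  window %g..%g ms, %d conditions\n", min(x$times), max(x$times),
              length(unique(x$labels))))
  invisible(x)
}

#' @rdname epoch_set
#' @export
n_trials <- function(x) dim(x$data)[1]

#' Serialize an epoch set
#'
#' Round-trips the full `epoch_set` (data, times, labels, sample rate,
#' rejection masks) through a single self-contained file. For
#' interoperability with other EEG toolchains see [write_brainvision()].
#'
#' @param x an [epoch_set].
#' @param path file path.
#' @return `read_epoch_set()` returns the [epoch_set]; `write_epoch_set()`
#'   returns `path` invisibly.
#' @export
write_epoch_set <- function(x, path) {
  stopifnot(inherits(x, "epoch_set"))
  saveRDS(unclass(x), path)
  invisible(path)
}

#' @rdname write_epoch_set
#' @export
read_epoch_set <- function(path) {
  x <- readRDS(path)
  epoch_set(x$data, x$times, x$sample_rate, x$labels, x$channels,
            x$bad_channels, x$bad_trials)
}
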