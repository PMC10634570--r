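#' @importFrom signal butter filtfilt
NULL

# Zero-phase 4th-order Butterworth filter of one numeric vector.
# type: "low", "high", "pass" (band); cutoffs in Hz.
butter_filtfilt <- function(x, sample_rate, cutoff, type) {
  w <- cutoff / (sample_rate / 2)
  if (any(w <= 0) || any(w >= 1)) {
    stop("filter cutoff must lie strictly below the Nyquist frequency", call. = FALSE)
  }
  flt <- signal::butter(4, w, type = type)
  as.numeric(signal::filtfilt(flt, x))
}

# Envelope of the analytic signal (Hilbert transform via FFT).
hilbert_envelope <- function(x) {
  n <- length(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  Mod(fft(fft(x) * h, inverse = TRUE) / n)
}

#' Zero-phase Butterworth filtering of epoched data
#'
#' Applies a forward-backward (zero-phase) 4th-order Butterworth filter to
#' every trial and channel. Cutoffs are contracts, not coefficients: a
#' high-pass at 0.1 Hz removes slow drift, a low-pass at 100 Hz
#' anti-aliases before downsampling, and a 110-140 Hz band-pass isolates
#' the muscle-artifact band.
#'
#' @param epochs an [epoch_set].
#' @param low low cutoff in Hz (`NULL` for none).
#' @param high high cutoff in Hz (`NULL` for none).
#' @return A filtered [epoch_set].
#' @export
filter_epochs <- function(epochs, low = NULL, high = NULL) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (is.null(low) && is.null(high)) return(epochs)
  type <- if (!is.null(low) && !is.null(high)) "pass"
          else if (!is.null(low)) "high" else "low"
  cutoff <- switch(type, pass = c(low, high), high = low, low = high)
  d <- dim(epochs$data)
  out <- epochs
  for (t in seq_len(d[1])) {
    for (ch in seq_len(d[2])) {
      out$data[t, ch, ] <- butter_filtfilt(epochs$data[t, ch, ],
                                           epochs$sample_rate, cutoff, type)
    }
  }
  out
}

#' Segment a continuous recording into baseline-corrected epochs
#'
#' Cuts a continuous channels x samples recording into epochs around
#' stimulus-onset events, after applying per-event photodiode timing
#' offsets (the measured lag between the software trigger and the actual
#' on-screen stimulus onset). Each epoch covers `[window[1], window[2])` ms
#' around the corrected onset and is baseline-corrected by subtracting the
#' per-channel mean over the prestimulus interval `[window[1], 0)` ms.
#' Events whose epoch would extend beyond the recording are dropped with a
#' message.
#'
#' @param continuous numeric matrix `[channels, samples]` in microvolts.
#' @param events integer sample indices of the stimulus triggers.
#' @param sample_rate sampling rate, Hz.
#' @param window epoch limits in ms relative to onset, default
#'   `c(-200, 1000)` (a 1.2 s epoch).
#' @param photodiode_offset_ms scalar or per-event offsets in ms added to
#'   the trigger time to obtain the true onset.
#' @param labels optional per-event condition labels (dropped events drop
#'   their labels too).
#' @param channels optional channel names.
#' @return An [epoch_set].
#' @export
epoch_and_baseline <- function(continuous, events, sample_rate,
                               window = c(-200, 1000),
                               photodiode_offset_ms = 0,
                               labels = NULL, channels = NULL) {
  continuous <- as.matrix(continuous)
  n_ch <- nrow(continuous)
  n_total <- ncol(continuous)
  labels <- labels %||% seq_along(events)
  stopifnot(length(labels) == length(events))
  offs <- rep_len(photodiode_offset_ms, length(events))
  onset <- round(events + offs * sample_rate / 1000)

  n_samp <- round((window[2] - window[1]) * sample_rate / 1000)
  rel <- round(window[1] * sample_rate / 1000) + seq_len(n_samp) - 1L
  times <- rel * 1000 / sample_rate

  keep <- (onset + min(rel)) >= 1L & (onset + max(rel)) <= n_total
  if (any(!keep)) {
    message(sprintf("dropping %d event(s) too close to the recording edge",
                    sum(!keep)))
  }
  onset <- onset[keep]
  labels <- labels[keep]
  if (length(onset) == 0L) stop("no events fit inside the recording", call. = FALSE)

  data <- array(0, c(length(onset), n_ch, n_samp))
  base_idx <- which(times >= window[1] & times < 0)
  for (t in seq_along(onset)) {
    seg <- continuous[, onset[t] + rel, drop = FALSE]
    if (length(base_idx) > 0L) {
      seg <- seg - rowMeans(seg[, base_idx, drop = FALSE])
    }
    data[t, , ] <- seg
  }
  epoch_set(data, times, sample_rate, labels, channels = channels)
}

#' Flag trials containing high-frequency muscle artifacts
#'
#' Band-pass filters each trial in the muscle band (default 110-140 Hz),
#' takes the magnitude of the analytic (Hilbert) envelope, z-scores it per
#' channel against the pooled mean and standard deviation across all trials
#' and timepoints, and flags any trial in which any channel's envelope
#' exceeds `z_threshold` at any timepoint. Whole trials are flagged (the
#' analysis discards trials, never interpolates). Samples within
#' `edge_exclude_ms` of the epoch edges are ignored to avoid zero-phase
#' filter edge transients; channels whose envelope is numerically constant
#' are treated as artifact-free.
#'
#' @param epochs an [epoch_set]; `sample_rate` must exceed twice the upper
#'   band edge.
#' @param band muscle band in Hz, default `c(110, 140)`.
#' @param z_threshold envelope z-value above which a timepoint counts as
#'   muscle activity (default 15).
#' @param edge_exclude_ms guard interval at each epoch edge, default 50 ms.
#' @return Logical vector, `TRUE` for flagged trials, with attribute
#'   `z_max` giving each trial's maximum envelope z.
#' @export
detect_muscle_artifacts <- function(epochs, band = c(110, 140),
                                    z_threshold = 15, edge_exclude_ms = 50) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (band[2] >= epochs$sample_rate / 2) {
    stop("muscle band must lie below the Nyquist frequency", call. = FALSE)
  }
  d <- dim(epochs$data)
  env <- array(0, d)
  for (t in seq_len(d[1])) {
    for (ch in seq_len(d[2])) {
      bp <- butter_filtfilt(epochs$data[t, ch, ], epochs$sample_rate, band, "pass")
      env[t, ch, ] <- hilbert_envelope(bp)
    }
  }
  guard <- round(edge_exclude_ms * epochs$sample_rate / 1000)
  interior <- seq_len(d[3]) > guard & seq_len(d[3]) <= d[3] - guard
  if (!any(interior)) interior <- rep(TRUE, d[3])

  z_max <- rep(-Inf, d[1])
  for (ch in seq_len(d[2])) {
    vals <- env[, ch, interior, drop = FALSE]
    mu <- mean(vals)
    s <- sd(vals)
    if (!is.finite(s) || s <= 1e-12 + 1e-8 * abs(mu)) next  # numerically constant
    z <- (vals - mu) / s
    z_max <- pmax(z_max, apply(z, 1, max))
  }
  flags <- is.finite(z_max) & z_max > z_threshold
  attr(flags, "z_max") <- z_max
  flags
}

#' Median re-reference and downsample epoched data
#'
#' Re-references every sample to the median across channels (so the
#' cross-channel median is exactly zero at every timepoint and any
#' common-mode offset is removed), optionally applies a zero-phase
#' anti-alias low-pass, and decimates to `new_rate`. The original rate must
#' be an integer multiple of `new_rate`.
#'
#' @param epochs an [epoch_set].
#' @param new_rate target sampling rate in Hz (default 500).
#' @param lowpass anti-alias low-pass cutoff in Hz (default 100; `NULL` to
#'   skip filtering, e.g. when not decimating).
#' @return An [epoch_set] at `new_rate`.
#' @export
rereference_and_resample <- function(epochs, new_rate = 500, lowpass = 100) {
  stopifnot(inherits(epochs, "epoch_set"))
  q <- epochs$sample_rate / new_rate
  if (abs(q - round(q)) > 1e-9 || q < 1) {
    stop("new_rate must divide the current sample rate", call. = FALSE)
  }
  q <- as.integer(round(q))
  d <- dim(epochs$data)
  out <- epochs
  for (t in seq_len(d[1])) {
    med <- apply(out$data[t, , , drop = TRUE], 2, median)
    out$data[t, , ] <- sweep(out$data[t, , , drop = TRUE], 2L, med)
  }
  if (!is.null(lowpass)) {
    out <- filter_epochs(out, high = lowpass)
  }
  if (q > 1L) {
    idx <- seq(1L, d[3], by = q)
    out <- epoch_set(out$data[, , idx, drop = FALSE], out$times[idx], new_rate,
                     out$labels, out$channels, out$bad_channels, out$bad_trials)
  }
  out
}
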