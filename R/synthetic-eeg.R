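#' Embed an RDM as a point configuration
#'
#' Inverts RDM construction by classical (Torgerson) multidimensional
#' scaling: returns a `conditions x dim` coordinate matrix whose pairwise
#' Euclidean distances approximate the RDM. Used by the synthetic EEG
#' generator to turn a target representational geometry into condition
#' patterns, and useful for visualisation. For a Euclidean RDM of intrinsic
#' dimensionality `<= dim` the distances are recovered exactly (up to
#' rotation); otherwise the best rank-`dim` embedding is returned and the
#' residual misfit is reported as `attr(, "stress")`,
#' `sqrt(sum((d - dhat)^2) / sum(d^2))`.
#'
#' @param rdm an [rdm] (symmetric, zero diagonal).
#' @param dim embedding dimensionality (>= 1).
#' @return Numeric matrix `[n_conditions, dim]` with attribute `stress`.
#' @export
#'
#' @examples
#' r <- rdm(matrix(c(0, 1, 1, 0), 2, 2))
#' p <- embed_rdm(r, dim = 1)
#' abs(dist(p) - 1) < 1e-12
embed_rdm <- function(rdm, dim) {
  stopifnot_scalar_count(dim, "dim", min = 1L)
  m <- as.matrix(rdm)
  n <- nrow(m)
  k <- min(dim, n - 1L)
  # cmdscale warns when fewer than k eigenvalues are positive; the trailing
  # dimensions are legitimately zero and padded below
  pts <- suppressWarnings(cmdscale(m, k = k))
  if (ncol(pts) < dim) {
    pts <- cbind(pts, matrix(0, n, dim - ncol(pts)))
  }
  dhat <- as.matrix(dist(pts))
  denom <- sum(m^2)
  stress <- if (denom > 0) sqrt(sum((m - dhat)^2) / denom) else 0
  rownames(pts) <- rownames(m)
  attr(pts, "stress") <- stress
  pts
}

#' Latent feature with a target geometry, onset and strength
#'
#' One entry of a [ground_truth()]: a named representational geometry that
#' the synthetic EEG's condition means will express from `onset_ms` onward
#' at signal-to-noise ratio `snr` (pattern RMS amplitude in units of the
#' unit-variance noise).
#'
#' @param name feature name.
#' @param rdm target [rdm] over the design's conditions.
#' @param onset_ms latency (ms after stimulus onset) at which the geometry
#'   becomes expressed.
#' @param snr nonnegative signal-to-noise ratio; 0 means the feature is
#'   never expressed.
#' @export
latent_feature <- function(name, rdm, onset_ms, snr) {
  stopifnot(is_rdm(rdm), length(onset_ms) == 1L, is.finite(onset_ms))
  if (snr < 0) stop("snr must be >= 0", call. = FALSE)
  structure(list(name = name, rdm = rdm, onset_ms = onset_ms, snr = snr),
            class = "latent_feature")
}

#' Ground truth for synthetic EEG generation
#'
#' Collects the latent features (target RDMs, onset latencies, SNRs), the
#' noise model, and the master seed. The noise is spatially correlated
#' Gaussian with exponentially decaying channel covariance
#' `cov(i, j) = exp(-|i - j| / spatial_decay)` and temporal AR(1) structure
#' with coefficient `ar_phi` (stationary unit variance), so that
#' multivariate noise normalization during decoding is non-trivial.
#'
#' @param features list of [latent_feature()] objects.
#' @param spatial_decay channel-covariance length constant (channels); larger
#'   values give more correlated channels.
#' @param ar_phi temporal AR(1) coefficient in `[0, 1)`.
#' @param ramp_ms signal onset ramp: condition means rise linearly from zero
#'   to full expression over this many ms after onset (default 10, one
#'   analysis window), avoiding step discontinuities.
#' @param seed master seed; all child seeds are derived from it.
#' @export
ground_truth <- function(features, spatial_decay = 3, ar_phi = 0.3,
                         ramp_ms = 10, seed = 1L) {
  stopifnot(is.list(features), length(features) >= 1L,
            all(vapply(features, inherits, logical(1), "latent_feature")))
  if (ar_phi < 0 || ar_phi >= 1) stop("ar_phi must be in [0, 1)", call. = FALSE)
  structure(list(features = features, spatial_decay = spatial_decay,
                 ar_phi = ar_phi, ramp_ms = ramp_ms, seed = as.integer(seed)),
            class = "ground_truth")
}

# Spatially and temporally correlated unit-variance noise for one trial.
correlated_noise <- function(n_channels, n_samples, chol_spatial, ar_phi) {
  w <- matrix(rnorm(n_channels * n_samples), n_channels, n_samples)
  x <- chol_spatial %*% w
  if (ar_phi > 0) {
    x <- t(apply(x, 1, function(row) {
      as.numeric(stats::filter(row * sqrt(1 - ar_phi^2), ar_phi,
                               method = "recursive"))
    }))
  }
  x
}

#' Generate synthetic EEG epochs with known representational geometry
#'
#' Produces an [epoch_set] in which, for every latent feature, the
#' between-condition pattern geometry follows the feature's target RDM
#' beginning at its onset latency, riding on spatially correlated AR(1)
#' Gaussian noise. Before a feature's onset the condition means carry no
#' trace of that feature (no decodable signal); at onset the feature's
#' condition patterns ramp in linearly over `ramp_ms`. Condition patterns
#' are obtained by classical MDS embedding of the target RDM
#' ([embed_rdm()]), projected into channel space through a seeded random
#' orthonormal projection and scaled so the root-mean-square channel
#' amplitude equals the feature's SNR (noise has unit variance).
#'
#' @param truth a [ground_truth()].
#' @param design a trial sequence from [generate_design()].
#' @param n_channels number of EEG channels.
#' @param sample_rate sampling rate, Hz.
#' @param epoch_window `c(start_ms, end_ms)` epoch limits relative to
#'   stimulus onset; samples cover `[start, end)`.
#' @param exclude_catch drop catch trials (the default, matching their
#'   exclusion from analysis).
#'
#' @return An [epoch_set] whose labels are the design's condition ids.
#' @export
generate_eeg_trials <- function(truth, design, n_channels, sample_rate = 500,
                                epoch_window = c(-200, 1000),
                                exclude_catch = TRUE) {
  stopifnot(inherits(truth, "ground_truth"), inherits(design, "trial_sequence"))
  n_cond <- max(design$condition)
  for (f in truth$features) {
    if (n_conditions(f$rdm) != n_cond) {
      stop("feature RDM size must match the design's condition count", call. = FALSE)
    }
    if (f$onset_ms < epoch_window[1] || f$onset_ms >= epoch_window[2]) {
      stop(sprintf("onset %g ms lies outside the epoch window", f$onset_ms),
           call. = FALSE)
    }
  }
  trials <- if (exclude_catch) design[!design$is_catch, ] else design
  n_tr <- nrow(trials)
  n_samp <- round((epoch_window[2] - epoch_window[1]) * sample_rate / 1000)
  times <- epoch_window[1] + (seq_len(n_samp) - 1L) * 1000 / sample_rate

  with_seed(child_seed(truth$seed, 2L), {
    # per-feature condition patterns in channel space
    cond_patterns <- lapply(truth$features, function(f) {
      k <- min(n_cond - 1L, n_channels)
      emb <- embed_rdm(f$rdm, dim = k)
      if (ncol(emb) > n_channels) {
        stop("n_channels is smaller than the embedding dimensionality", call. = FALSE)
      }
      proj <- qr.Q(qr(matrix(rnorm(n_channels * ncol(emb)), n_channels)))[, seq_len(ncol(emb)), drop = FALSE]
      pat <- emb %*% t(proj)            # conditions x channels
      pat <- scale(pat, center = TRUE, scale = FALSE)
      rms <- sqrt(mean(pat^2))
      if (rms > 0) pat <- pat / rms
      pat * f$snr
    })
    # temporal envelopes, one per feature
    envelopes <- lapply(truth$features, function(f) {
      env <- (times - f$onset_ms) / max(truth$ramp_ms, 1e-9)
      pmin(pmax(env, 0), 1)
    })
    # condition-mean signal: conditions x channels x samples, built lazily
    mean_signal <- array(0, c(n_cond, n_channels, n_samp))
    for (i in seq_along(truth$features)) {
      pat <- cond_patterns[[i]]
      env <- envelopes[[i]]
      for (ch in seq_len(n_channels)) {
        mean_signal[, ch, ] <- mean_signal[, ch, ] + outer(pat[, ch], env)
      }
    }
    sigma <- outer(seq_len(n_channels), seq_len(n_channels),
                   function(i, j) exp(-abs(i - j) / truth$spatial_decay))
    ch_l <- t(chol(sigma))
    data <- array(0, c(n_tr, n_channels, n_samp))
    for (t in seq_len(n_tr)) {
      noise <- correlated_noise(n_channels, n_samp, ch_l, truth$ar_phi)
      data[t, , ] <- mean_signal[trials$condition[t], , ] + noise
    }
    epoch_set(data, times, sample_rate, labels = trials$condition)
  })
}
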