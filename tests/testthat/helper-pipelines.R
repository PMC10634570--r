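# End-to-end simulation pipelines reused by property and acceptance tests.

# Full latency-recovery run: simulate one multi-subject EEG study with a
# single latent binary-geometry feature at `onset_ms`, decode each subject,
# correlate the time-resolved EEG RDMs with the target feature RDM, run the
# group sign-permutation cluster test, and return the estimated onset (ms).
recover_onset <- function(onset_ms, seed, snr = 2.5, n_subjects = 5,
                          n_conditions = 8, n_blocks = 28, n_channels = 10,
                          win_halfspan_ms = 30, n_permutations = 1000) {
  target <- binary_category_rdm(rep(0:1, length.out = n_conditions))
  win_range <- c(onset_ms - win_halfspan_ms, onset_ms + win_halfspan_ms)
  win <- NULL
  stats <- sapply(seq_len(n_subjects), function(s) {
    gt <- ground_truth(list(latent_feature("f", target, onset_ms, snr)),
                       seed = seed * 1000 + s)
    des <- generate_design(design_spec(
      n_videos = n_conditions, n_social = n_conditions %/% 2,
      n_blocks = n_blocks, n_catch_events_per_block = 0,
      seed = seed * 1000 + s + 500))
    ep <- generate_eeg_trials(gt, des, n_channels = n_channels,
                              sample_rate = 500, epoch_window = c(-50, 250))
    win <<- sliding_windows(ep$times, range_ms = win_range)
    dr <- pairwise_decode(ep, windows = win, n_reps = 1,
                          seed = seed * 1000 + s + 900)
    rc <- rank_correlation_timecourse(decoding_to_rdms(dr), target)
    ifelse(is.finite(rc$stat), rc$stat, 0)  # saturated windows: no evidence
  })
  res <- group_cluster_test(t(stats), n_permutations = n_permutations,
                            seed = seed + 77)
  onset_latency(win$center_ms, res$mask)$onset_ms
}

# Synthetic variance-partitioning dataset with known unique-variance order:
# three ROI RDMs built from one shared and three unique latents, and a
# target timecourse whose signal windows mix the latents with graded unique
# contributions b (so true UV rank order = order of b).
vp_recovery_dataset <- function(seed, n_cond = 12, n_windows = 30,
                                n_signal = 20, b = c(0.8, 0.4, 0),
                                noise_sd = 0.1) {
  set.seed(seed)
  shared <- rand_rdm(n_cond, 3)
  uniques <- list(rand_rdm(n_cond, 3), rand_rdm(n_cond, 3), rand_rdm(n_cond, 3))
  rois <- generate_roi_rdm_set(shared, uniques,
                               weights = cbind(rep(1, 3), rep(1, 3)),
                               noise_sd = 0.02, seed = seed)
  n_pairs <- n_cond * (n_cond - 1) / 2
  sv <- vectorize_rdm(shared)
  uv <- lapply(uniques, vectorize_rdm)
  target <- sapply(seq_len(n_windows), function(w) {
    y <- rnorm(n_pairs, sd = noise_sd)
    if (w > n_windows - n_signal) {
      y <- y + scale(sv)[, 1] + b[1] * scale(uv[[1]])[, 1] +
        b[2] * scale(uv[[2]])[, 1] + b[3] * scale(uv[[3]])[, 1]
    }
    y
  })
  list(target = target, rois = rois$rdms,
       signal_windows = seq(n_windows - n_signal + 1, n_windows),
       true_order = order(b, decreasing = TRUE))
}

# One null AR(1) group dataset for family-wise-error simulations.
null_group_dataset <- function(n_subjects = 12, n_windows = 100, phi = 0.3) {
  t(vapply(seq_len(n_subjects), function(s) {
    as.numeric(stats::filter(rnorm(n_windows) * sqrt(1 - phi^2), phi,
                             method = "recursive"))
  }, numeric(n_windows)))
}
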