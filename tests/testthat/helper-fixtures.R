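# Shared fixtures: small synthetic objects built in code.

# Random Euclidean RDM from an n x d point cloud.
rand_rdm <- function(n, d = 3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rdm(as.matrix(dist(matrix(rnorm(n * d), n, d))))
}

# Epoch set built directly from explicit condition means plus iid noise.
# means: list (one per condition) of channels x samples matrices.
epochs_from_means <- function(means, n_trials_per_cond, sample_rate = 500,
                              t0_ms = -100, noise_sd = 1, seed = 1) {
  set.seed(seed)
  n_cond <- length(means)
  n_ch <- nrow(means[[1]])
  n_samp <- ncol(means[[1]])
  n_tr <- n_cond * n_trials_per_cond
  labels <- rep(seq_len(n_cond), each = n_trials_per_cond)
  data <- array(0, c(n_tr, n_ch, n_samp))
  for (t in seq_len(n_tr)) {
    data[t, , ] <- means[[labels[t]]] +
      matrix(rnorm(n_ch * n_samp, sd = noise_sd), n_ch, n_samp)
  }
  times <- t0_ms + (seq_len(n_samp) - 1L) * 1000 / sample_rate
  epoch_set(data, times, sample_rate, labels)
}

# Time-resolved RDM stack with given per-window RDMs.
trrdm_from_list <- function(rdms, window_ms) {
  n <- nrow(rdms[[1]])
  arr <- array(0, c(n, n, length(rdms)))
  for (w in seq_along(rdms)) arr[, , w] <- unclass(rdms[[w]])
  time_resolved_rdm(arr, window_ms)
}
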