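# trfusion

Time-resolved representational similarity analysis (RSA) and EEG–fMRI
fusion for studying how quickly visual and social-affective information is
extracted from naturalistic stimuli — for cognitive neuroscientists who
record multichannel EEG while participants view a fixed stimulus set, and
who want to link the evolving EEG activity patterns to stimulus features
and to fMRI region-of-interest (ROI) patterns.

## What it computes

The pipeline follows the now-standard fusion logic:

1. **Pairwise decoding → EEG RDMs.** For every pair of stimulus conditions
   and every 10-ms sliding window (4-ms step), a linear SVM is trained and
   tested across two cross-validation folds of pseudo-trials (averages of
   ~7 same-condition trials, multivariately noise-normalized by the inverse
   square root of a shrinkage-regularized channel covariance estimated on
   the training fold). Decoding accuracy becomes the entry of a
   time-resolved representational dissimilarity matrix (RDM): pairs decoded
   well have dissimilar neural patterns.
2. **Model RDMs.** Stimulus features become condition × condition model
   RDMs: Euclidean distances between convolutional-layer feature vectors or
   per-frame motion-energy vectors, binary category distances (e.g. social
   vs nonsocial), absolute rating differences (valence, arousal), and
   inverted pairwise similarity judgments (7 − mean rating). fMRI ROI
   patterns become 1 − Pearson-correlation RDMs.
3. **RSA and fusion.** Per window, the vectorized EEG RDM is
   Spearman-correlated with each model RDM (`rank_correlation_timecourse`),
   or regressed on all models jointly (`regression_timecourse`), with a
   leave-one-subject-out noise ceiling (`noise_ceiling`).
4. **Variance partitioning.** The group-average EEG RDM is regressed on all
   subsets of up to three predictors; commonality analysis splits the full
   model's R² into unique variances
   `UV_i = R²_123 − R²_(without i)` and shared components, e.g.
   `SV_123 = R²_1 + R²_2 + R²_3 − R²_12 − R²_13 − R²_23 + R²_123`,
   which sum to `R²_123` exactly.
5. **Group statistics and latencies.** Timecourses are tested against zero
   with a one-tailed sign-permutation test (whole-timecourse sign flips per
   subject, 5000 iterations by default) with maximum-cluster-sum
   correction; onset latency is the first window of the earliest
   significant cluster, and onsets are compared with a Mann–Whitney U test.

A synthetic-data module generates the full study scaffolding with known
ground truth: pseudo-randomized block designs with one-back catch trials,
EEG epochs whose condition geometry follows target RDMs from specified
onset latencies under spatially correlated AR(1) noise, and ROI RDM sets
with controlled shared/unique variance.

## Worked example

```r
library(trfusion)

## a small synthetic study: 8 conditions in two categories, the binary
## category geometry appears in the EEG at 150 ms
target <- binary_category_rdm(rep(c("social", "nonsocial"), each = 4))
truth  <- ground_truth(list(latent_feature("category", target,
                                           onset_ms = 150, snr = 2.5)),
                       seed = 1)
design <- generate_design(design_spec(n_videos = 8, n_social = 4,
                                      n_blocks = 28,
                                      n_catch_events_per_block = 0, seed = 1))
epochs <- generate_eeg_trials(truth, design, n_channels = 10,
                              sample_rate = 500, epoch_window = c(-50, 250))

win <- sliding_windows(epochs$times, range_ms = c(120, 180))
dec <- pairwise_decode(epochs, windows = win, n_reps = 2, seed = 1)
rsa <- rank_correlation_timecourse(decoding_to_rdms(dec), target)
round(rbind(ms = rsa$window_ms, r = rsa$stat), 2)
```

```
     [,1]   [,2]   [,3]   [,4] [,5]   [,6]   [,7]   [,8]   [,9]  [,10]  [,11]
ms 122.00 126.00 130.00 134.00  138 142.00 146.00 150.00 154.00 158.00 162.00
r   -0.09  -0.11  -0.04  -0.14    0  -0.14  -0.22   0.95   0.95   0.95   0.95
    [,12]  [,13]  [,14]  [,15]
ms 166.00 170.00 174.00 178.00
r    0.95   0.95   0.95   0.95
```

The Spearman correlation between the time-resolved EEG RDM and the
category model hovers around zero before the injected 150-ms onset and
jumps to 0.95 from the first window containing post-onset samples — the
category geometry is decodable from the simulated EEG exactly when it was
injected. With several subjects,
`group_cluster_test()` turns such timecourses into cluster-corrected
significance masks and `onset_latency()` reads off the latency.

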