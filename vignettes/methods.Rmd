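---
title: "Methods: time-resolved RSA, fusion, and variance partitioning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: time-resolved RSA, fusion, and variance partitioning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(trfusion)
```

This vignette documents the models and procedures implemented in
`trfusion`, the assumptions behind them, the defaults and why they were
chosen, and what the synthetic-data validation does and does not establish
about real recordings.

## The analysis model

The package addresses a common question in visual and social neuroscience:
*when* does the brain extract a given stimulus property, and *which*
cortical regions carry that information at each moment? EEG has the
temporal resolution but poor spatial specificity; fMRI has the opposite
profile. Representational similarity analysis (RSA) links the two through
a common abstraction, the representational dissimilarity matrix (RDM): a
symmetric condition × condition matrix of pattern dissimilarities, with a
zero diagonal. Any measurement space — EEG channel patterns in a 10-ms
window, fMRI voxel patterns in a region, a feature vector computed from
the stimulus — induces an RDM, and RDMs from different spaces can be
compared directly.

### From EEG to time-resolved RDMs

Per participant, preprocessed epochs (trials × channels × samples) are
decoded pairwise:

- **Fold split and pseudo-trials.** Source trials of each condition are
  randomly split into two cross-validation folds *before* any averaging,
  so no source trial contributes to both folds. Within each condition ×
  fold cell, disjoint groups of about 7 trials (the middle of the
  six-to-eight range; cells are split into `floor(n/7)` near-equal groups,
  so realized sizes stay in 6–8 for typical trial counts) are averaged
  into pseudo-trials, raising SNR roughly by the square root of the group
  size.
- **Multivariate noise normalization.** Channels are whitened by
  `Σ^{-1/2}`, where `Σ` is the within-condition residual channel
  covariance averaged over timepoints, estimated from the *training* fold
  only and shrunk toward its diagonal (default shrinkage 0.1). Inside
  `pairwise_decode()` the covariance is estimated from the training fold's
  source trials rather than its pseudo-trials: with two folds and ~2
  pseudo-trials per condition per cell, pseudo-trial-level replication is
  often degenerate, while source trials give the same estimator with far
  more degrees of freedom and identical fold hygiene.
- **Classification.** For each unordered condition pair and each sliding
  window (10 ms wide, 4-ms step; at 500 Hz, 5 samples per window and a
  2-sample step), a linear soft-margin SVM (cost 1, libsvm via `e1071`)
  is trained on the training fold using all channels at all window samples
  as features, and tested on the held-out fold. Fold roles are swapped and
  the whole procedure is repeated (default 10 times) with fresh
  randomization; accuracies are averaged. The cost constant is fixed
  because pairwise accuracy at these sample sizes is insensitive to it;
  all contracts on the classifier are tolerance-based accuracy contracts,
  not coefficient contracts.

Accuracy is the dissimilarity: `decoding_to_rdms()` stacks the per-window
accuracy matrices into a time-resolved RDM.

### Model RDMs

Six feature constructions are provided: Euclidean distance between
numeric feature vectors (`euclidean_rdm`, used for convolutional-layer
activations and per-frame motion-energy vectors), binary category
distance (`binary_category_rdm`), absolute rating difference
(`rating_difference_rdm`), inverted pairwise similarity judgments
(`similarity_inversion_rdm`: mean across raters on a 1–7 scale,
subtracted from 7), and 1 − Pearson correlation between ROI voxel
patterns (`correlation_distance_rdm`). Convolutional features
(`extract_conv_features`) accept any supplied kernel weights; only the
layer geometry (`out = floor((in + 2·pad − kernel)/stride) + 1`) and
linearity are asserted, and rectified (post-activation) outputs are the
default. "Sum of optic flow" is implemented as the sum of flow-vector
*magnitudes*: componentwise sums cancel opposing motion, which would make
the measure blind to symmetric expansion. Flow estimation itself is
pluggable — the package consumes flow fields.

### RSA, regression, noise ceiling, latencies

`rank_correlation_timecourse()` uses Spearman correlation (average ranks
for ties) between vectorized upper triangles (row-major, diagonal
excluded). `regression_timecourse()` rank-transforms and z-scores all
vectors by default before ordinary least squares, so the single-predictor
case degrades exactly to the rank correlation; a raw-value option exists
because published variants differ on this point. The noise ceiling is the
leave-one-subject-out mean Spearman correlation between each subject's
RDM and the average of the others.

Onset latency is defined as the center of the first window of the
earliest significant cluster. For comparing two latency distributions,
`latency_difference_test()` runs a two-sided Mann–Whitney U test, exact
for small tie-free samples. Because the sampling unit for latencies is a
genuine design choice (the literature is not uniform), `subject_onsets()`
implements both a subject-level mode (each subject's timecourse
thresholded at the group-null 95th percentile) and a bootstrap mode
(resampling subjects and recomputing group onsets); the bootstrap mode
has the better-matched threshold scale and is what the package's own
tests exercise quantitatively.

### Variance partitioning

With two or three predictor RDMs, `decompose_timecourse()` fits, per
window, ordinary least squares of the standardized group-average EEG RDM
vector on every predictor subset, and applies commonality analysis:

- `UV_i = R²_123 − R²_(subsets without i)`
- `SV_12 = R²_13 + R²_23 − R²_3 − R²_123` (and permutations)
- `SV_123 = R²_1 + R²_2 + R²_3 − R²_12 − R²_13 − R²_23 + R²_123`

These formulas are the unique reading under which the seven components sum
*exactly* to `R²_123`; the identity is asserted at `1e-10` for a thousand
random draws in the test suite. Unadjusted R² is used throughout — the
identity requires it. Negative shared components (suppression) are
mathematically legitimate and reported as-is, never clipped.

### Group inference

All timecourses are tested with a one-tailed (positive) sign-permutation
test: under the null hypothesis each subject's statistic is symmetric
about zero, so each of the 5000 default iterations flips every subject's
*entire* timecourse with probability one half — flipping whole
timecourses preserves within-subject autocorrelation, which pointwise
flips would destroy. The identity permutation is always included, so
p-values are bounded away from zero by 1/(N+1). The cluster-forming
threshold is the per-window 95th percentile of the permuted group means
(the group *mean* is the statistic, matching what is plotted); maximal
runs of suprathreshold windows form clusters, and a cluster is significant
when its statistic sum exceeds the 1 − α quantile of the permutation
distribution of maximum cluster sums. The field-standard parameters
(5000 iterations, α = 0.05) are defaults; the cluster-forming rule is
configurable because published pipelines differ and no single convention
is universal.

## The synthetic-data generator

`generate_design()` produces the block design: every condition once per
block in pseudo-random order, plus catch events for a one-back task. A
catch event is modeled as an *inserted immediate-repeat pair* — two extra
presentations of a just-shown condition — because that is the unique
reading under which 75 conditions with 4 catch events per block give 83
trials per block and 1245 in total; catch trials are flagged and excluded
from analysis, as they carry motor responses.

`generate_eeg_trials()` injects known representational geometry:
each latent feature's target RDM is embedded as a point configuration by
classical multidimensional scaling (`embed_rdm`), projected into channel
space through a seeded random orthonormal map, scaled so the pattern RMS
equals the feature's SNR, and added to every trial of the corresponding
condition from the feature's onset latency onward. The onset ramps in
linearly over 10 ms (one analysis window) rather than as a step, to avoid
confusing filter ringing with genuine latency effects. Noise is Gaussian
with exponentially decaying channel covariance
(`cov(i,j) = exp(−|i−j|/3)` by default) and temporal AR(1) structure
(φ = 0.3, stationary unit variance) — correlated enough that multivariate
noise normalization is non-trivial, which is the property the decoding
contracts need. One master seed drives deterministic per-stage child
seeds; regeneration is byte-identical.

What the generator does *not* emulate: biophysical dipole geometry,
eye/muscle artifact morphology, electrode drift, inter-subject anatomical
variability, or overlapping responses from rapid stimulus streams (epochs
are independent, consistent with the 1–1.5 s fixation jitter of the
emulated paradigm). Passing the synthetic suite therefore demonstrates
that the *analysis code* recovers known ground truth under a plausible
noise model — not that any particular real dataset satisfies that model.

`generate_roi_rdm_set()` builds ROI RDMs as nonnegative mixtures of one
shared and one per-ROI unique latent RDM plus symmetric noise, rescaled to
the unit interval, storing the mixing weights as ground truth for
variance-partitioning recovery tests.

## Validation designs and problem sizes

The test suite runs everything at desk scale, with sizes chosen to keep
each check sharp while the full suite stays comfortably runnable on a
laptop core:

- **Family-wise error:** 500 null group datasets (12 subjects ×
  100 windows, AR(1) noise), 1000 permutations each. The acceptance
  script repeats this measurement from scratch.
- **Chance calibration:** 20 conditions × 10 channels of pure-noise
  epochs; the grand-mean pairwise accuracy must fall in the 95% binomial
  interval around 0.5 with n equal to the number of pair × window cells.
  Cell count is the right n: the ~16 individual predictions inside a cell
  share pseudo-trials and collapse to about one effective independent
  observation (verified by matching the across-seed standard deviation of
  the grand mean).
- **Latency recovery:** onsets of 90, 150 and 190 ms, each injected as a
  *single* binary-geometry feature into its own dataset (8 conditions,
  28 trials per condition, 10 channels, 5 subjects, SNR 2.5), recovered
  end-to-end (decode → RSA → cluster test → onset) to within one 4-ms
  window step. A single dataset carrying all three features jointly is
  not identifiable at high SNR: the earliest feature saturates pairwise
  accuracies at ceiling, erasing later onsets, and random model RDMs at
  28 pairs intercorrelate enough (|r| ≈ 0.2) to smear latencies. One
  feature per dataset with a two-cluster geometry is immune to both
  effects (a saturated accuracy RDM still correlates ~0.95 with a binary
  model), so it isolates exactly the property under test — onset timing.
- **Variance-partitioning recovery:** ROI sets from
  `generate_roi_rdm_set()` with graded unique contributions (0.8, 0.4, 0)
  mixed into the target during signal windows; the recovered unique
  variances must reproduce that ordering in ≥90% of signal windows.

## Numerical choices and degenerate inputs

- Filters are zero-phase forward–backward 4th-order Butterworth
  (`signal::filtfilt`); only cutoff attenuation is contracted, not
  coefficients. Muscle-artifact detection (110–140 Hz band, Hilbert
  envelope via FFT, z > 15 across pooled timepoints) excludes 50 ms at
  each epoch edge to avoid filter transients, and treats numerically
  constant envelopes as artifact-free (otherwise a pure out-of-band tone
  would be z-scored against its own rounding error).
- Correlation-distance RDMs reject zero-variance condition vectors
  (undefined correlation) rather than imputing.
- Spearman timecourse windows with constant RDM vectors (e.g. all pairs
  decoded perfectly) are returned as `NA` and flagged; downstream
  simulations treat them as zero evidence.
- The whitening transform floors eigenvalues at `1e-10` of the largest and
  refuses numerically singular covariances instead of silently
  regularizing: the user should raise the shrinkage deliberately.
- `fit_r2()` fits rank-deficient subsets on the pivoted subspace
  (equivalent fitted values to a pseudoinverse fit) with a warning, so
  duplicated predictors yield well-defined zero unique variance instead of
  an error.
- ERP contrast cells whose paired differences have zero variance are
  reported as t = 0 and never significant (the statistic is undefined);
  the Bonferroni family defaults to channels × slices, the stricter of
  the two readings, and is configurable.

## Known limitations

- The fusion logic is correlational; onsets order regions in time but do
  not by themselves establish directed information flow.
- No searchlight or channel-subset decoding; the decoder always uses all
  channels.
- Commonality analysis is implemented for at most three predictors (the
  2^k − 1 expansion beyond three is out of scope).
- ICA-based artifact removal and manual channel/trial rejection are
  consumed as externally supplied masks, never computed.
- The BrainVision writer emits IEEE float-32 multiplexed data only (the
  reader also accepts 16-bit integer data with per-channel resolutions).
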