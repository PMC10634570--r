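test_that("epoching around events yields baseline-corrected windows of the right length", {
  fs <- 1000
  cont <- matrix(rnorm(3 * 5000), 3, 5000)
  cont[2, ] <- 7.5  # constant channel
  ep <- epoch_and_baseline(cont, events = c(1000, 2500), sample_rate = fs)
  expect_equal(dim(ep$data), c(2, 3, 1200))  # 1.2 s at 1000 Hz
  expect_true(all(abs(ep$data[, 2, ]) < 1e-12))  # constant removed by baseline
  # per-channel baseline mean is zero for every epoch
  base <- ep$times >= -200 & ep$times < 0
  for (t in 1:2) {
    expect_lt(max(abs(rowMeans(ep$data[t, , base]))), 1e-12)
  }
})

test_that("photodiode offsets shift epoch content by the offset in samples", {
  fs <- 1000
  cont <- matrix(seq_len(4000), 1, 4000)  # ramp encodes the sample index
  ep0 <- epoch_and_baseline(cont, events = 2000, sample_rate = fs,
                            window = c(0, 100))  # no prestimulus: no baseline
  ep30 <- epoch_and_baseline(cont, events = 2000, sample_rate = fs,
                             window = c(0, 100), photodiode_offset_ms = 30)
  expect_equal(ep30$data[1, 1, ] - ep0$data[1, 1, ], rep(30, 100))
})

test_that("events too close to the recording edge are dropped with a message", {
  cont <- matrix(rnorm(2 * 1000), 2, 1000)
  expect_message(
    ep <- epoch_and_baseline(cont, events = c(100, 500), sample_rate = 1000,
                             window = c(-200, 400), labels = c("a", "b")),
    "dropping")
  expect_equal(n_trials(ep), 1)
  expect_equal(ep$labels, "b")
})

test_that("muscle-band artifact detection flags only contaminated trials", {
  fs <- 1000
  n_samp <- 600
  n_tr <- 30
  tt <- seq_len(n_samp) / fs
  clean <- sin(2 * pi * 10 * tt)
  pure <- array(rep(clean, each = 5 * 2), c(5, 2, n_samp))
  ep <- epoch_set(pure, (seq_len(n_samp) - 1), fs, labels = 1:5)
  expect_false(any(detect_muscle_artifacts(ep)))

  set.seed(55)
  data <- array(rnorm(n_tr * 2 * n_samp, sd = 0.05), c(n_tr, 2, n_samp))
  for (tr in seq_len(n_tr)) for (ch in 1:2) data[tr, ch, ] <- data[tr, ch, ] + clean
  burst <- data
  mid <- 280:320
  burst[3, 1, mid] <- burst[3, 1, mid] + 40 * sin(2 * pi * 125 * tt[mid])
  epb <- epoch_set(burst, (seq_len(n_samp) - 1), fs, labels = seq_len(n_tr))
  flags <- detect_muscle_artifacts(epb)
  expect_equal(which(flags), 3)
  expect_false(any(detect_muscle_artifacts(epb, z_threshold = Inf)))
  expect_error(detect_muscle_artifacts(epoch_set(pure, (seq_len(n_samp) - 1) * 4,
                                                 250, labels = 1:5)),
               "Nyquist")
})

test_that("median re-reference zeroes the channel median and ignores common offsets", {
  set.seed(51)
  fs <- 1000
  data <- array(rnorm(4 * 5 * 400), c(4, 5, 400))
  ep <- epoch_set(data, (seq_len(400) - 1), fs, labels = 1:4)
  ref <- rereference_and_resample(ep, new_rate = fs, lowpass = NULL)
  for (t in 1:4) {
    expect_lt(max(abs(apply(ref$data[t, , ], 2, median))), 1e-12)
  }
  shifted <- ep
  shifted$data <- ep$data + 42
  ref2 <- rereference_and_resample(shifted, new_rate = fs, lowpass = NULL)
  expect_equal(ref$data, ref2$data, tolerance = 1e-12)
})

test_that("downsampling 1000 to 500 Hz halves the sample count", {
  set.seed(52)
  data <- array(rnorm(2 * 3 * 1200), c(2, 3, 1200))
  ep <- epoch_set(data, -200 + (seq_len(1200) - 1), 1000, labels = 1:2)
  down <- rereference_and_resample(ep, new_rate = 500, lowpass = 100)
  expect_equal(dim(down$data)[3], 600)
  expect_equal(down$sample_rate, 500)
  expect_equal(diff(down$times[1:2]), 2)
  expect_error(rereference_and_resample(ep, new_rate = 300), "divide")
})

test_that("zero-phase filters attenuate at their stated cutoffs", {
  fs <- 1000
  tt <- seq_len(2000) / fs
  probe <- function(freq, low = NULL, high = NULL) {
    x <- sin(2 * pi * freq * tt)
    data <- array(x, c(1, 1, length(x)))
    ep <- epoch_set(data, (seq_along(x) - 1), fs, labels = 1)
    y <- filter_epochs(ep, low = low, high = high)$data[1, 1, ]
    core <- 500:1500  # avoid edge transients
    sqrt(mean(y[core]^2)) / sqrt(mean(x[core]^2))
  }
  expect_gt(probe(30, high = 100), 0.95)   # passband of the 100 Hz low-pass
  expect_lt(probe(300, high = 100), 0.05)  # stopband
  expect_gt(probe(125, low = 110, high = 140), 0.9)  # muscle band passes
  expect_lt(probe(50, low = 110, high = 140), 0.05)
})

test_that("preprocessing commutes with trial permutation", {
  set.seed(53)
  data <- array(rnorm(6 * 3 * 300), c(6, 3, 300))
  ep <- epoch_set(data, -100 + (seq_len(300) - 1) * 2, 500, labels = rep(1:2, 3))
  perm <- sample(6)
  ep_perm <- epoch_set(data[perm, , ], ep$times, 500, labels = ep$labels[perm])
  a <- rereference_and_resample(ep, lowpass = NULL, new_rate = 500)
  b <- rereference_and_resample(ep_perm, lowpass = NULL, new_rate = 500)
  expect_equal(a$data[perm, , ], b$data, tolerance = 1e-12)
})
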