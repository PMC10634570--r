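test_that("two conditions at distance 1 embed as two points 1 apart", {
  r <- rdm(matrix(c(0, 1, 1, 0), 2, 2))
  p <- embed_rdm(r, dim = 1)
  expect_equal(as.numeric(dist(p)), 1, tolerance = 1e-12)
})

test_that("a Euclidean RDM is recovered exactly at its intrinsic dimension", {
  set.seed(5)
  pts <- matrix(rnorm(24), 8, 3)
  r <- rdm(as.matrix(dist(pts)))
  emb <- embed_rdm(r, dim = 3)
  expect_lt(max(abs(as.matrix(dist(emb)) - unclass(r))), 1e-6)
  expect_lt(attr(emb, "stress"), 1e-8)
})

test_that("non-Euclidean RDMs yield the best low-rank embedding with reported stress", {
  # an RDM violating Euclidean embeddability in 2 dimensions
  set.seed(8)
  m <- as.matrix(dist(matrix(rnorm(50), 10, 5)))
  r <- rdm(m)
  emb <- embed_rdm(r, dim = 2)
  expect_gt(attr(emb, "stress"), 0)
  # oracle: eigendecomposition of the doubly centred Gram matrix
  n <- nrow(m)
  j <- diag(n) - 1 / n
  b <- -0.5 * j %*% (m^2) %*% j
  e <- eigen(b, symmetric = TRUE)
  oracle <- e$vectors[, 1:2] %*% diag(sqrt(pmax(e$values[1:2], 0)))
  d_oracle <- as.matrix(dist(oracle))
  stress_oracle <- sqrt(sum((m - d_oracle)^2) / sum(m^2))
  expect_equal(attr(emb, "stress"), stress_oracle, tolerance = 1e-8)
  expect_error(embed_rdm(r, dim = 0), "dim")
})

test_that("zero-SNR features leave condition means identical before and after onset", {
  target <- rand_rdm(4, seed = 1)
  gt <- ground_truth(list(latent_feature("f", target, 100, 0)), seed = 9)
  des <- generate_design(design_spec(n_videos = 4, n_social = 2, n_blocks = 4,
                                     n_catch_events_per_block = 0, seed = 2))
  ep1 <- generate_eeg_trials(gt, des, n_channels = 5, sample_rate = 500,
                             epoch_window = c(-100, 200))
  # with snr 0 the generated data are pure noise: regenerating with a
  # different target RDM but the same seed gives identical data
  gt2 <- ground_truth(list(latent_feature("f", rand_rdm(4, seed = 99), 100, 0)),
                      seed = 9)
  ep2 <- generate_eeg_trials(gt2, des, n_channels = 5, sample_rate = 500,
                             epoch_window = c(-100, 200))
  expect_identical(ep1$data, ep2$data)
})

test_that("condition means separate only after the onset latency", {
  target <- rand_rdm(4, seed = 3)
  gt <- ground_truth(list(latent_feature("f", target, 100, snr = 50)), seed = 10)
  des <- generate_design(design_spec(n_videos = 4, n_social = 2, n_blocks = 30,
                                     n_catch_events_per_block = 0, seed = 4))
  ep <- generate_eeg_trials(gt, des, n_channels = 6, sample_rate = 500,
                            epoch_window = c(-100, 200))
  cond_mean <- function(idx) {
    sapply(1:4, function(c) {
      mean_map <- apply(ep$data[ep$labels == c, , idx, drop = FALSE], c(2, 3), mean)
      mean_map
    })
  }
  spread <- function(idx) {
    mm <- cond_mean(idx)
    mean(apply(mm, 1, var))
  }
  pre <- spread(which(ep$times < 95))
  post <- spread(which(ep$times > 115))
  expect_gt(post, 100 * pre)
})

test_that("the generator is byte-identical under a fixed seed", {
  target <- rand_rdm(3, seed = 6)
  gt <- ground_truth(list(latent_feature("f", target, 50, 1)), seed = 123)
  des <- generate_design(design_spec(n_videos = 3, n_social = 1, n_blocks = 4,
                                     n_catch_events_per_block = 0, seed = 5))
  a <- generate_eeg_trials(gt, des, 4, 500, c(-50, 150))
  b <- generate_eeg_trials(gt, des, 4, 500, c(-50, 150))
  expect_identical(a, b)
})

test_that("onsets outside the epoch window are rejected", {
  target <- rand_rdm(3, seed = 6)
  gt <- ground_truth(list(latent_feature("f", target, 500, 1)), seed = 1)
  des <- generate_design(design_spec(n_videos = 3, n_social = 1, n_blocks = 4,
                                     n_catch_events_per_block = 0, seed = 5))
  expect_error(generate_eeg_trials(gt, des, 4, 500, c(-50, 150)), "outside")
  expect_error(latent_feature("f", target, 100, snr = -1), "snr")
})

test_that("synthetic ROI RDMs are valid and share structure as weighted", {
  shared <- rand_rdm(10, seed = 1)
  uniques <- list(rand_rdm(10, seed = 2), rand_rdm(10, seed = 3))
  # all weight on the shared component, no noise: identical RDMs
  s <- generate_roi_rdm_set(shared, uniques, weights = cbind(c(1, 1), c(0, 0)),
                            noise_sd = 0, seed = 4)
  v1 <- vectorize_rdm(s$rdms[[1]]); v2 <- vectorize_rdm(s$rdms[[2]])
  expect_equal(cor(v1, v2, method = "spearman"), 1)
  for (r in s$rdms) {
    m <- unclass(r)
    expect_equal(m, t(m))
    expect_true(all(diag(m) == 0))
    expect_true(all(m >= 0))
  }
})

test_that("latent recovery degrades monotonically with ROI noise", {
  shared <- rand_rdm(12, seed = 5)
  uniques <- list(rand_rdm(12, seed = 6))
  cors <- sapply(c(0.05, 0.5, 5), function(ns) {
    s <- generate_roi_rdm_set(shared, uniques, weights = cbind(1, 0),
                              noise_sd = ns, seed = 7)
    cor(vectorize_rdm(s$rdms[[1]]), vectorize_rdm(shared))
  })
  expect_true(all(diff(cors) < 0))
})

test_that("mismatched ROI RDM sizes are rejected", {
  expect_error(generate_roi_rdm_set(rand_rdm(5, seed = 1),
                                    list(rand_rdm(6, seed = 2)),
                                    weights = cbind(1, 1)), "size")
  expect_error(generate_roi_rdm_set(rand_rdm(5, seed = 1),
                                    list(rand_rdm(5, seed = 2)),
                                    weights = cbind(-1, 1)), ">= 0")
})
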