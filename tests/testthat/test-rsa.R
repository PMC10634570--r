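test_that("rank correlation is exact for identical and monotone-transformed RDMs", {
  r1 <- rand_rdm(10, seed = 81)
  r2 <- rand_rdm(10, seed = 82)
  trr <- trrdm_from_list(list(r1, r2), window_ms = c(0, 4))
  rc <- rank_correlation_timecourse(trr, r1)
  expect_equal(rc$stat[1], 1)
  # strictly monotone transform leaves Spearman at exactly 1
  mono <- rdm(sqrt(unclass(r1)) + unclass(r1)^2)
  rc2 <- rank_correlation_timecourse(trr, mono)
  expect_equal(rc2$stat[1], 1)
})

test_that("independent RDMs at 75 conditions correlate near zero", {
  hits <- 0
  set.seed(95)
  for (seed in 1:20) {
    # independent dissimilarity vectors over the 75-condition pair set
    a <- devectorize_rdm(rnorm(2775))
    b <- devectorize_rdm(rnorm(2775))
    r <- cor(vectorize_rdm(a), vectorize_rdm(b), method = "spearman")
    hits <- hits + (abs(r) < 0.06)
  }
  expect_gte(hits, 17)  # |r| < 0.06 in the vast majority of draws
})

test_that("constant RDM windows are flagged as undefined", {
  flat <- rdm(matrix(1, 5, 5) - diag(5), validate = FALSE)
  varying <- rand_rdm(5, seed = 83)
  trr <- trrdm_from_list(list(flat, varying), window_ms = c(0, 4))
  rc <- rank_correlation_timecourse(trr, varying)
  expect_true(rc$flagged[1])
  expect_true(is.na(rc$stat[1]))
  expect_false(rc$flagged[2])
})

test_that("multiple regression recovers betas from the normal equations", {
  set.seed(84)
  n <- 12
  models <- list(m1 = rand_rdm(n, seed = 85), m2 = rand_rdm(n, seed = 86),
                 m3 = rand_rdm(n, seed = 87))
  target <- rand_rdm(n, seed = 88)
  trr <- trrdm_from_list(list(target), window_ms = 0)
  res <- regression_timecourse(trr, models)
  # brute-force normal equations on the same rank-z-transformed vectors
  rz <- function(x) { r <- rank(x); (r - mean(r)) / sd(r) }
  x <- cbind(1, sapply(models, function(m) rz(vectorize_rdm(m))))
  y <- rz(vectorize_rdm(target))
  beta <- solve(t(x) %*% x, t(x) %*% y)
  expect_equal(as.numeric(res$stat), as.numeric(beta[-1]), tolerance = 1e-8)
})

test_that("single-predictor regression reduces to the simple slope and nulls vanish", {
  n <- 15
  m1 <- rand_rdm(n, seed = 89)
  target <- rand_rdm(n, seed = 90)
  trr <- trrdm_from_list(list(target), window_ms = 0)
  res <- regression_timecourse(trr, list(m = m1))
  # for rank-z vectors the simple OLS slope is the Spearman correlation
  want <- cor(vectorize_rdm(target), vectorize_rdm(m1), method = "spearman")
  expect_equal(unname(res$stat[1, 1]), want, tolerance = 1e-10)
  dup <- list(a = m1, b = m1)
  expect_error(regression_timecourse(trr, dup), "collinear")
})

test_that("noise ceiling is 1 for identical subjects and near 0 for independent ones", {
  r <- rand_rdm(8, seed = 91)
  trr <- trrdm_from_list(list(r, r), window_ms = c(0, 4))
  expect_equal(noise_ceiling(list(trr, trr, trr)), c(1, 1))
  indep <- lapply(1:6, function(s)
    trrdm_from_list(list(rand_rdm(20, seed = 500 + s)), window_ms = 0))
  expect_lt(abs(noise_ceiling(indep)), 0.25)
  expect_error(noise_ceiling(indep[1]), "2 subjects")
})

test_that("two-subject noise ceiling expands to the cross-subject correlation", {
  a <- trrdm_from_list(list(rand_rdm(10, seed = 92)), window_ms = 0)
  b <- trrdm_from_list(list(rand_rdm(10, seed = 93)), window_ms = 0)
  want <- cor(vectorize_rdm(window_rdm(a, 1)), vectorize_rdm(window_rdm(b, 1)),
              method = "spearman")
  expect_equal(noise_ceiling(list(a, b)), want, tolerance = 1e-12)
})

test_that("onset latency reads the first significant window", {
  ms <- seq(0, 390, by = 10)
  mask <- ms >= 150
  est <- onset_latency(ms, mask)
  expect_equal(est$onset_ms, 150)
  expect_true(is.na(onset_latency(ms, rep(FALSE, length(ms)))$onset_ms))
  expect_error(onset_latency(ms, mask[-1]), "same number")
})

test_that("the Mann-Whitney latency test matches exhaustive permutation enumeration", {
  a <- c(3.1, 5.2, 7.4)
  b <- c(4.3, 6.5, 8.1, 2.2)
  got <- latency_difference_test(a, b)
  # oracle: enumerate all assignments of the pooled values to group A
  pooled <- c(a, b)
  u_stat <- function(x, y) sum(outer(x, y, ">"))
  obs <- u_stat(a, b)
  combos <- combn(length(pooled), length(a))
  us <- apply(combos, 2, function(ix) u_stat(pooled[ix], pooled[-ix]))
  m <- length(a) * length(b)
  p_oracle <- mean(abs(us - m / 2) >= abs(obs - m / 2))
  expect_equal(got$p, p_oracle, tolerance = 1e-12)
  expect_equal(got$U, obs)
})

test_that("degenerate latency comparisons behave sensibly", {
  same <- c(10, 20, 30, 40)
  res <- latency_difference_test(same, same)
  expect_equal(res$U, length(same)^2 / 2)
  expect_gt(res$p, 0.9)
  sep <- latency_difference_test(c(1, 2, 3), c(10, 11, 12))
  expect_equal(sep$U, 0)
  expect_error(latency_difference_test(c(1, 2), c(1, 2, 3)), "3 finite")
})

test_that("bootstrapped onsets respond to injected latency shifts", {
  set.seed(94)
  ms <- seq(0, 200, by = 4)
  mk <- function(onset) {
    t(sapply(1:8, function(s) ifelse(ms >= onset, 0.5, 0) + rnorm(length(ms), sd = 0.05)))
  }
  early <- subject_onsets(mk(60), ms, mode = "bootstrap", n_boot = 30, seed = 1)
  late <- subject_onsets(mk(140), ms, mode = "bootstrap", n_boot = 30, seed = 1)
  expect_true(all(is.finite(early)))
  expect_true(all(is.finite(late)))
  expect_gt(median(late), median(early))
  # subject mode returns one latency per subject
  expect_length(subject_onsets(mk(100), ms, seed = 2), 8)
})
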