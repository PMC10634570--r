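test_that("R-squared matches explicit residual computation", {
  set.seed(101)
  n <- 60
  x <- matrix(rnorm(n * 3), n, 3)
  expect_equal(fit_r2(x[, 1], x[, 1, drop = FALSE]), 1, tolerance = 1e-12)
  # y orthogonal to the predictors
  y <- rnorm(n)
  y_orth <- lm.fit(cbind(1, x), y)$residuals
  expect_lt(fit_r2(y_orth, x), 1e-10)
  # brute force 1 - RSS/TSS
  y <- x %*% c(1, -2, 0.5) + rnorm(n)
  fit <- lm(y ~ x)
  want <- 1 - sum(residuals(fit)^2) / sum((y - mean(y))^2)
  expect_equal(fit_r2(y, x), want, tolerance = 1e-10)
  expect_equal(fit_r2(y, NULL), 0)
  expect_error(fit_r2(rep(1, 10), x[1:10, ]), "constant")
  expect_warning(fit_r2(y, cbind(x[, 1], x[, 1])), "rank-deficient")
})

test_that("unique variance vanishes for redundant or irrelevant predictors", {
  set.seed(102)
  n <- 80
  x1 <- rnorm(n); x2 <- rnorm(n); noise <- rnorm(n)
  y <- x1 + 0.5 * x2 + rnorm(n, sd = 0.3)
  # predictor 3 is pure noise
  xmat <- cbind(x1, x2, noise)
  r2 <- trfusion:::subset_r2(y, xmat)
  expect_lt(unique_variance(r2, 3), 0.05)
  expect_gt(unique_variance(r2, 1), 0.2)
  # duplicated predictors have no unique variance
  xdup <- cbind(x1, x1, x2)
  r2d <- suppressWarnings(trfusion:::subset_r2(y, xdup))
  expect_lt(abs(unique_variance(r2d, 1)), 1e-10)
  expect_lt(abs(unique_variance(r2d, 2)), 1e-10)
})

test_that("orthogonal predictors have UV equal to their solo R-squared", {
  set.seed(103)
  n <- 90
  q <- qr.Q(qr(matrix(rnorm(n * 3), n, 3)))  # exactly orthogonal columns
  y <- q %*% c(2, 1, 0.5) + rnorm(n, sd = 0.5)
  r2 <- trfusion:::subset_r2(y, q)
  for (k in 1:3) {
    expect_lt(abs(unique_variance(r2, k) - r2[[as.character(k)]]), 0.02)
  }
  sv <- shared_variance(r2)
  expect_lt(max(abs(sv)), 0.02)
})

test_that("duplicated predictors shift their variance into the shared component", {
  set.seed(104)
  n <- 100
  x1 <- rnorm(n)
  x3 <- lm.fit(cbind(1, x1), rnorm(n))$residuals  # orthogonal to x1
  y <- x1 + 0.8 * x3 + rnorm(n, sd = 0.2)
  r2 <- suppressWarnings(trfusion:::subset_r2(y, cbind(x1, x1, x3)))
  sv <- shared_variance(r2)
  expect_equal(sv[["sv_12"]], unname(r2["1"]), tolerance = 1e-10)
  expect_lt(abs(sv[["sv_13"]]), 1e-10)
  expect_lt(abs(sv[["sv_23"]]), 1e-10)
  expect_lt(abs(sv[["sv_123"]]), 1e-10)
})

test_that("UV and SV components sum exactly to the full-model R-squared", {
  set.seed(105)
  for (i in 1:25) {
    n <- 40
    xmat <- matrix(rnorm(n * 3), n, 3)
    y <- rnorm(n)
    r2 <- trfusion:::subset_r2(y, xmat)
    total <- sum(sapply(1:3, function(k) unique_variance(r2, k))) +
      sum(shared_variance(r2))
    expect_equal(total, unname(r2["123"]), tolerance = 1e-12)
    # monotonicity in subset inclusion
    expect_gte(r2[["12"]], r2[["1"]] - 1e-12)
    expect_gte(r2[["12"]], r2[["2"]] - 1e-12)
    expect_gte(r2[["123"]], max(r2[c("12", "13", "23")]) - 1e-12)
  }
})

test_that("timecourse decomposition tracks injected structure and predictor order", {
  set.seed(106)
  n_cond <- 12
  shared <- rand_rdm(n_cond, seed = 107)
  u1 <- rand_rdm(n_cond, seed = 108)
  preds <- list(a = rdm(unclass(shared) + unclass(u1), validate = FALSE),
                b = rdm(unclass(shared) + unclass(rand_rdm(n_cond, seed = 109)),
                        validate = FALSE),
                c = rand_rdm(n_cond, seed = 110))
  n_pairs <- n_cond * (n_cond - 1) / 2
  # target shares the latent `shared` with predictors a and b
  target <- sapply(1:5, function(w) vectorize_rdm(shared) + rnorm(n_pairs, sd = 0.1))
  dec <- decompose_timecourse(target, preds)
  expect_true(all(dec$sv_12 > 0.1))
  # permuting predictors permutes the outputs consistently
  dec_perm <- decompose_timecourse(target, preds[c(2, 1, 3)])
  expect_equal(dec$uv_a, dec_perm$uv_a, tolerance = 1e-10)
  expect_equal(dec$sv_12, dec_perm$sv_12, tolerance = 1e-10)
  expect_equal(dec$r2_123, dec_perm$r2_123, tolerance = 1e-10)
  expect_error(decompose_timecourse(target, preds[1]), "2 or 3")
})

test_that("two-predictor decomposition uses the classical commonality identity", {
  set.seed(111)
  n <- 50
  x1 <- rnorm(n); x2 <- 0.7 * x1 + rnorm(n)
  y <- x1 + x2 + rnorm(n)
  dec <- decompose_timecourse(matrix(y, ncol = 1), list(p = x1, q = x2))
  expect_equal(dec$uv_p + dec$uv_q + dec$sv_12, dec$r2_12, tolerance = 1e-12)
  expect_gt(dec$sv_12, 0)
})

test_that("variance decompositions export as long-format text", {
  set.seed(112)
  target <- matrix(rnorm(45 * 3), 45, 3)
  preds <- list(a = rnorm(45), b = rnorm(45), c = rnorm(45))
  dec <- decompose_timecourse(target, preds)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_variance_decomposition(dec, path)
  tab <- read.delim(path)
  expect_setequal(unique(tab$component),
                  setdiff(names(dec), "window_ms"))
  expect_equal(nrow(tab), 3 * (ncol(dec) - 1))
})
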