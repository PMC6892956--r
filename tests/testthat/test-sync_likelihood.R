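test_that("frequency-adaptive parameter derivation follows the stated rules", {
  p <- derive_sl_params(eeg_bands("lower_alpha"), 256)
  expect_equal(p$tau, 9)        # round(256 / 30)
  expect_equal(p$m, 5)          # round(30 / 8) + 1
  expect_equal(p$w1, 72)        # 2 * 9 * 4
  expect_equal(p$w2, 272)       # 72 + 10 / 0.05
  expect_equal(derive_sl_params(eeg_bands("gamma"), 256)$tau, 2)
  expect_error(derive_sl_params(eeg_bands("theta"), 256, p_ref = 0),
               class = "nvf_parameter_error")
  expect_error(sl_params(m = 5, tau = 9, w1 = 10, w2 = 272),
               class = "nvf_parameter_error")
  expect_error(sl_params(m = 5, tau = 9, w1 = 72, w2 = 50),
               class = "nvf_parameter_error")
})

test_that("SL reaches its synchronization ceiling and affine invariance", {
  p <- sl_params(5, 9, 72, 272, 0.05)
  set.seed(20)
  x <- nvfusion:::band_noise_source(5120, 256, eeg_bands("lower_alpha"))
  expect_equal(sl_pair(x, x, p), 1, tolerance = 0.02)
  expect_identical(sl_pair(x, 2 * x + 5, p), sl_pair(x, x, p))
  expect_error(sl_pair(x, rep(1, 5120), p), class = "nvf_undefined_distance")
  # too-short series advise concatenation
  expect_error(sl_pair(x[1:512], x[1:512], p), class = "nvf_parameter_error")
})

test_that("independent series sit at the p_ref floor", {
  p <- sl_params(5, 9, 72, 272, 0.05)
  set.seed(21)
  vals <- replicate(10, sl_pair(rnorm(5120), rnorm(5120), p))
  expect_equal(mean(vals), 0.05, tolerance = 0.015)
})

test_that("optimized core matches the naive double-loop oracle to 1e-12", {
  p <- sl_params(m = 3, tau = 2, w1 = 8, w2 = 50, p_ref = 0.1)
  set.seed(22)
  for (case in 1:3) {
    x <- rnorm(200)
    y <- if (case == 1) rnorm(200) else if (case == 2) x + rnorm(200) else
      sin(seq(0, 20, length.out = 200)) + rnorm(200, sd = 0.3)
    fast <- sl_pair(x, y, p)
    slow <- sl_pair_naive(x, y, p$m, p$tau, p$w1, p$w2, p$p_ref)
    expect_equal(fast, slow, tolerance = 1e-12)
  }
})

test_that("sl_pair is exactly symmetric", {
  p <- sl_params(3, 2, 8, 50, 0.1)
  set.seed(23)
  x <- rnorm(300); y <- rnorm(300)
  expect_identical(sl_pair(x, y, p), sl_pair(y, x, p))
})

test_that("sl_matrix orders duplicated channels above independent ones", {
  p <- sl_params(5, 9, 72, 272, 0.05)
  set.seed(24)
  base <- nvfusion:::band_noise_source(5120, 256, eeg_bands("lower_alpha"))
  dat <- array(0, dim = c(10, 3, 512))
  ch3 <- rnorm(5120)
  for (e in 1:10) {
    idx <- (e - 1) * 512 + 1:512
    dat[e, 1, ] <- base[idx]
    dat[e, 2, ] <- base[idx]
    dat[e, 3, ] <- ch3[idx]
  }
  ep <- epoched_data(dat, 256, 2, eeg_bands("lower_alpha"), 0:9, c("a", "b", "c"))
  cm <- sl_matrix(ep, p, mode = "concatenate")
  expect_s3_class(cm, "connectivity_matrix")
  expect_equal(diag(cm$values), c(a = 1, b = 1, c = 1))
  expect_equal(cm$values, t(cm$values))
  expect_gt(cm$values[1, 2], 0.95)
  expect_gt(cm$values[1, 2], cm$values[1, 3])
})

test_that("per-epoch mode needs windows that fit in one epoch", {
  p_big <- sl_params(5, 9, 72, 272, 0.05)
  dat <- array(rnorm(2 * 2 * 512), dim = c(2, 2, 512))
  ep <- epoched_data(dat, 256, 2, NULL, 0:1, c("a", "b"))
  expect_error(sl_matrix(ep, p_big, mode = "per_epoch_mean"),
               class = "nvf_parameter_error")
  # with a window that fits, a single epoch gives identical results in both
  # modes
  p_small <- sl_params(3, 2, 8, 60, 0.1)
  ep1 <- epoched_data(dat[1, , , drop = FALSE], 256, 2, NULL, 0L, c("a", "b"))
  m1 <- sl_matrix(ep1, p_small, mode = "per_epoch_mean")
  m2 <- sl_matrix(ep1, p_small, mode = "concatenate")
  expect_equal(m1$values, m2$values, tolerance = 1e-12)
})

test_that("mean_sl averages the strict upper triangle", {
  cm <- connectivity_matrix(matrix(c(1, 0.3, 0.3, 1), 2), "sl", c("a", "b"))
  expect_equal(mean_sl(cm), 0.3)
  v <- matrix(0.42, 5, 5); diag(v) <- 1
  expect_equal(mean_sl(connectivity_matrix(v, "sl", letters[1:5])), 0.42)
  set.seed(25)
  r <- matrix(runif(64 * 64), 64); r <- (r + t(r)) / 2; diag(r) <- 1
  cm64 <- connectivity_matrix(r, "sl", sprintf("E%02d", 1:64))
  expect_equal(mean_sl(cm64), (sum(r) - 64) / 2 / 2016)
  expect_error(mean_sl(connectivity_matrix(matrix(1, 1, 1), "sl", "a")),
               class = "nvf_validation_error")
})
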