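test_that("feature extraction aligns counts and windows", {
  set.seed(60)
  dat <- array(rnorm(12 * 4 * 512), dim = c(12, 4, 512))
  ep <- epoched_data(dat, 256, 2, eeg_bands("lower_alpha"), 0:11,
                     sprintf("e%d", 1:4))
  hbo <- matrix(rnorm(14 * 150), 14)
  h <- hemodynamic_series(hbo, -0.3 * hbo, fs = 5,
                          channel_labels = sprintf("ch%d", 1:14))
  fs10 <- extract_features(ep, h, n_epochs = 10)
  expect_length(fs10$eeg_epoch_covs, 10)
  expect_equal(dim(fs10$fnirs_samples), c(10, 14))
  # lag shifts the hemodynamic window forward in time
  fs_lag <- extract_features(ep, h, n_epochs = 10, lag_epochs = 1)
  expect_equal(fs_lag$fnirs_samples[1, ], rowMeans(hbo[, 11:20]))
  expect_equal(fs10$fnirs_samples[1, ], rowMeans(hbo[, 1:10]))
  # insufficient aligned windows
  h_short <- hemodynamic_series(hbo[, 1:40], hbo[, 1:40], 5,
                                sprintf("ch%d", 1:14))
  expect_error(extract_features(ep, h_short, n_epochs = 10),
               class = "nvf_insufficient_data")
})

test_that("unit-variance white noise gives a near-identity epoch covariance", {
  set.seed(61)
  dat <- array(rnorm(1 * 6 * 512), dim = c(1, 6, 512))
  ep <- epoched_data(dat, 256, 2, NULL, 0L, sprintf("e%d", 1:6))
  h <- hemodynamic_series(matrix(rnorm(2 * 10), 2), matrix(rnorm(2 * 10), 2),
                          5, c("ch1", "ch2"))
  fs <- extract_features(ep, h, n_epochs = 1)
  C <- fs$eeg_epoch_covs[[1]]
  expect_lt(max(abs(diag(C) - 1)), 0.25)
  expect_lt(max(abs(C[upper.tri(C)])), 0.2)
})

test_that("activation patterns follow a = Cw / (w'Cw)", {
  set.seed(62)
  w <- rnorm(5)
  # identity covariance: pattern proportional to the filter
  a_id <- activation_pattern(w, diag(5))
  expect_lt(1 - cosine_sim(a_id, w), 1e-12)
  # invariance to positive rescaling of w
  C <- crossprod(matrix(rnorm(40), 8, 5)) / 8
  expect_equal(activation_pattern(w, C), activation_pattern(3.7 * w, C),
               tolerance = 1e-12)
  # sign convention
  a <- activation_pattern(w, C)
  expect_gt(a[which.max(abs(a))], 0)
  expect_error(activation_pattern(rep(0, 5), C),
               class = "nvf_validation_error")
})

test_that("noise-free planted comodulation reaches r ~ 1", {
  toy <- make_mspoc_toy(n_eeg = 4, n_fnirs = 3, n_epochs = 30, noise_mix = 0,
                        seed = 7)
  fit <- mspoc_fit(toy$fs, n_restarts = 5, B_perm = 0, seed = 1)[[1]]
  expect_gte(fit$r, 0.99)
  expect_true(fit$converged)
})

test_that("the comodulation objective is non-decreasing across iterations", {
  toy <- make_mspoc_toy(n_eeg = 5, n_fnirs = 4, n_epochs = 25, noise_mix = 0.5,
                        seed = 8)
  fit <- mspoc_fit(toy$fs, n_restarts = 3, B_perm = 0, seed = 2)[[1]]
  expect_true(all(diff(fit$trace_r) > -1e-6))
})

test_that("the alternating solver matches an exhaustive 2x2 grid search", {
  for (seed in 1:3) {
    toy <- make_mspoc_toy(n_eeg = 2, n_fnirs = 2, n_epochs = 20,
                          noise_mix = 0.4, seed = seed)
    r_grid <- mspoc_grid_2x2(toy$fs$eeg_epoch_covs, toy$fs$fnirs_samples)
    fit <- mspoc_fit(toy$fs, n_restarts = 10, B_perm = 0, polish = TRUE,
                     seed = seed)[[1]]
    expect_equal(fit$r, r_grid, tolerance = 1e-3)
  }
})

test_that("fits are deterministic under a fixed seed", {
  toy <- make_mspoc_toy(seed = 9)
  f1 <- mspoc_fit(toy$fs, n_restarts = 3, B_perm = 20, perm_restarts = 1,
                  seed = 5)[[1]]
  f2 <- mspoc_fit(toy$fs, n_restarts = 3, B_perm = 20, perm_restarts = 1,
                  seed = 5)[[1]]
  expect_identical(f1$r, f2$r)
  expect_identical(f1$null_r, f2$null_r)
  expect_identical(f1$w_eeg, f2$w_eeg)
})

test_that("group fusion summarizes r with its standard error", {
  toys <- lapply(1:4, function(s) make_mspoc_toy(n_epochs = 25, seed = 20 + s)$fs)
  g <- fuse_group(toys, roi = "whole_pfc", n_restarts = 3, B_perm = 0, seed = 1)
  expect_equal(g$n, 4)
  expect_length(g$r, 4)
  expect_equal(g$sem_r, sd(g$r) / 2, tolerance = 1e-12)
  # identical subjects: zero dispersion
  g2 <- fuse_group(toys[c(1, 1, 1)], n_restarts = 3, B_perm = 0, seed = 1)
  expect_equal(g2$sem_r, 0, tolerance = 1e-10)
  # degenerate ROI skipped with a warning
  tiny <- make_mspoc_toy(n_eeg = 1, n_fnirs = 3, seed = 1)$fs
  expect_warning(gn <- fuse_group(list(tiny), roi = "L-FP", B_perm = 0),
                 "skipped")
  expect_null(gn)
})
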