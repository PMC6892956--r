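test_that("canonical band registry tiles 1.5-50 Hz without overlap", {
  reg <- eeg_bands()
  expect_named(reg, c("delta", "theta", "lower_alpha", "upper_alpha", "beta",
                      "gamma"))
  expect_equal(reg$delta$low_hz, 1.5)
  expect_equal(reg$gamma$high_hz, 50)
  edges <- t(vapply(reg, function(b) c(b$low_hz, b$high_hz), numeric(2)))
  ord <- order(edges[, 1])
  expect_true(all(diff(edges[ord, 1]) > 0))
  # contiguous except for the documented 13-14 Hz gap between upper alpha
  # and beta
  gaps <- edges[ord, 1][-1] - edges[ord, 2][-nrow(edges)]
  expect_true(all(gaps >= 0))
  expect_error(band_definition("x", 10, 8), class = "nvf_validation_error")
})

test_that("ocular regression removes a planted EOG component", {
  set.seed(10)
  n <- 256 * 8
  veog <- 40 * nvfusion:::pink_noise(n)
  heog <- 25 * nvfusion:::pink_noise(n)
  brain <- matrix(rnorm(4 * n, sd = 10), 4)
  scalp <- brain
  scalp[1, ] <- scalp[1, ] + 0.7 * veog
  scalp[3, ] <- scalp[3, ] - 0.4 * heog
  rec <- ts_recording(scalp, 256, sprintf("C%d", 1:4), "eeg")
  eog <- ts_recording(rbind(heog, veog), 256, c("HEOG", "VEOG"), "eog")
  out <- correct_ocular(rec, eog)
  expect_lt(abs(cor(out$data[1, ], veog)), 0.01)
  expect_lt(abs(cor(out$data[3, ], heog)), 0.01)
  # residuals orthogonal to every EOG channel
  for (i in 1:4) {
    centered <- out$data[i, ] - mean(out$data[i, ])
    expect_lt(abs(sum(centered * veog)) / sqrt(sum(centered^2) * sum(veog^2)),
              1e-6)
  }
})

test_that("zero EOG leaves the recording unchanged; fs mismatch errors", {
  rec <- ts_recording(matrix(rnorm(2 * 512), 2), 256, c("a", "b"), "eeg")
  eog0 <- ts_recording(matrix(0, 1, 512), 256, "VEOG", "eog")
  expect_warning(out0 <- correct_ocular(rec, eog0), "rank-deficient")
  expect_equal(out0$data, rec$data, tolerance = 1e-9)
  eog_bad <- ts_recording(matrix(rnorm(512), 1), 2048, "VEOG", "eog")
  expect_error(correct_ocular(rec, eog_bad), class = "nvf_validation_error")
})

test_that("band-pass meets its gain contract at 256 and 2048 Hz", {
  for (fs in c(256, 2048)) {
    bp <- function(x) {
      rec <- ts_recording(matrix(x, 1), fs, "a", "eeg")
      bandpass_band(rec, eeg_bands("lower_alpha"))$data[1, ]
    }
    g_pass <- measured_gain(bp, fs, 9)
    g_stop <- measured_gain(bp, fs, 20)
    expect_gt(g_pass, 0.95); expect_lt(g_pass, 1.05)
    expect_lt(g_stop, 0.05)
  }
  # DC rejection and zero phase
  rec <- ts_recording(matrix(rep(1, 2560), 1), 256, "a", "eeg")
  expect_lt(max(abs(bandpass_band(rec, eeg_bands("lower_alpha"))$data)), 1e-6)
  n <- 2560; x <- sin(2 * pi * 9 * (0:(n - 1)) / 256)
  y <- bandpass_band(ts_recording(matrix(x, 1), 256, "a", "eeg"),
                     eeg_bands("lower_alpha"))$data[1, ]
  cc <- ccf(x[500:2000], y[500:2000], lag.max = 5, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
  # edge above Nyquist
  rec <- ts_recording(matrix(rnorm(512), 1), 64, "a", "eeg")
  expect_error(bandpass_band(rec, eeg_bands("gamma")),
               class = "nvf_validation_error")
})

test_that("resampling decimates with anti-aliasing and exact lengths", {
  rec <- ts_recording(matrix(rnorm(2048), 1), 2048, "a", "eeg")
  out <- resample(rec, 256)
  expect_equal(out$fs, 256)
  expect_equal(ncol(out$data), 256)
  rec <- ts_recording(matrix(rnorm(500), 1), 50, "a", "eeg")
  expect_equal(ncol(resample(rec, 5)$data), 50)
  expect_identical(resample(rec, 50), rec)
  expect_error(resample(rec, 100), class = "nvf_validation_error")
  # a 9 Hz sine survives 2048 -> 256 within 2%
  n <- 2048 * 8; x <- sin(2 * pi * 9 * (0:(n - 1)) / 2048)
  y <- resample(ts_recording(matrix(x, 1), 2048, "a", "eeg"), 256)$data[1, ]
  mid <- y[round(length(y) * 0.3):round(length(y) * 0.7)]
  expect_lt(abs(max(abs(mid)) - 1), 0.02)
})

test_that("epoching keeps the first clean epochs and demeans them", {
  fs <- 256
  set.seed(11)
  n <- fs * 150
  x <- matrix(rnorm(3 * n, sd = 20), 3)
  rec <- ts_recording(x, fs, c("a", "b", "c"), "eeg")
  ep <- epoch_and_reject(rec)
  expect_equal(dim(ep$data), c(10, 3, 512))
  expect_equal(10 * 512, 5120)                     # 20 s of retained signal
  expect_equal(ep$kept_epoch_indices, 0:9)
  expect_lt(max(abs(apply(ep$data, c(1, 2), mean))), 1e-9)

  # a 200-uV spike in epoch 2 (0-based) excludes exactly that epoch
  x2 <- x
  x2[2, fs * 120 + 2 * 512 + 10] <- 200
  ep2 <- epoch_and_reject(ts_recording(x2, fs, c("a", "b", "c"), "eeg"))
  expect_false(2 %in% ep2$kept_epoch_indices)
  expect_equal(ep2$kept_epoch_indices, c(0, 1, 3:10))

  # all-zero recording: nothing rejected
  ep0 <- epoch_and_reject(ts_recording(matrix(0, 2, n), fs, c("a", "b"), "eeg"))
  expect_equal(ep0$kept_epoch_indices, 0:9)
  expect_true(all(ep0$data == 0))

  # too short: error names the shortfall
  short <- ts_recording(x[, 1:(fs * 125)], fs, c("a", "b", "c"), "eeg")
  err <- tryCatch(epoch_and_reject(short), error = identity)
  expect_s3_class(err, "nvf_insufficient_data")
})

test_that("epoching is deterministic and epoch_extract matches the grid", {
  set.seed(12)
  rec <- ts_recording(matrix(rnorm(2 * 256 * 150), 2), 256, c("a", "b"), "eeg")
  e1 <- epoch_and_reject(rec); e2 <- epoch_and_reject(rec)
  expect_identical(e1$kept_epoch_indices, e2$kept_epoch_indices)
  ex <- epoch_extract(rec, e1$kept_epoch_indices)
  expect_equal(ex$data, e1$data, tolerance = 1e-12)
})
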