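test_that("MBLL inversion is the exact linear inverse of the forward map", {
  set.seed(30)
  h <- hemodynamic_series(matrix(rnorm(3 * 500, sd = 0.3), 3),
                          matrix(rnorm(3 * 500, sd = 0.1), 3),
                          fs = 50, channel_labels = c("ch1", "ch2", "ch3"))
  od <- forward_mbll(h)
  back <- mbll_invert(od)
  expect_equal(back$hbo, h$hbo, tolerance = 1e-10)
  expect_equal(back$hb, h$hb, tolerance = 1e-10)

  # zero optical density maps to zero concentrations
  od0 <- od; od0$data[] <- 0
  z <- mbll_invert(od0)
  expect_true(all(z$hbo == 0) && all(z$hb == 0))

  # linearity
  od2 <- od; od2$data <- 2 * od$data + 0.5 * od$data
  lin <- mbll_invert(od2)
  expect_equal(lin$hbo, 2.5 * back$hbo, tolerance = 1e-10)

  # doubling concentrations doubles optical density
  h2 <- h; h2$hbo <- 2 * h$hbo; h2$hb <- 2 * h$hb
  expect_equal(forward_mbll(h2)$data, 2 * od$data, tolerance = 1e-12)
})

test_that("wavelengths other than 690/830 are refused", {
  rec <- ts_recording(matrix(rnorm(4 * 100), 4), 50,
                      c("a@690", "a@830", "b@690", "b@830"), "fnirs_od")
  rec$channel_labels <- c("a@700", "a@830", "b@700", "b@830")  # tampered
  expect_error(mbll_invert(rec), class = "nvf_configuration_error")
  expect_error(mbll_coefficients(extinction = matrix(c(1, 1, 1, 1), 2)),
               class = "nvf_configuration_error")
})

test_that("hemodynamic band-pass passes 0.05 Hz and rejects 0.5 Hz", {
  fs <- 50
  n <- fs * 1200
  mk <- function(f) {
    x <- sin(2 * pi * f * (0:(n - 1)) / fs)
    h <- hemodynamic_series(matrix(x, 1), matrix(x, 1), fs, "ch1")
    filter_detrend(h)$hbo[1, ]
  }
  mid <- function(y) max(abs(y[round(n * 0.3):round(n * 0.7)]))
  expect_gt(mid(mk(0.05)), 0.9)
  expect_lt(mid(mk(0.05)), 1.1)
  expect_lt(mid(mk(0.5)), 0.1)
  # a pure linear ramp is annihilated
  ramp <- hemodynamic_series(matrix(seq(0, 10, length.out = n), 1),
                             matrix(0, 1, n), fs, "ch1")
  expect_lt(max(abs(filter_detrend(ramp)$hbo)), 1e-6 * 10)
  # short series: high-pass edge relaxed with a warning
  short <- hemodynamic_series(matrix(rnorm(fs * 100), 1),
                              matrix(rnorm(fs * 100), 1), fs, "ch1")
  expect_warning(filter_detrend(short), "relaxing")
})

test_that("spline motion correction touches only artifact segments", {
  fs <- 50
  set.seed(31)
  n <- fs * 300
  clean <- 0.2 * sin(2 * pi * 0.05 * (0:(n - 1)) / fs) + 0.02 * rnorm(n)
  h <- hemodynamic_series(matrix(clean, 1), matrix(clean / 2, 1), fs, "ch1")
  out <- spline_motion_correct(h)
  expect_equal(out$hbo, h$hbo, tolerance = 1e-9)
  expect_length(out$excluded_channels, 0)

  # one 1-s step spike at 10x the quiet SD is mostly removed
  spike <- clean
  at <- (fs * 150):(fs * 151)
  amp <- 10 * sd(clean)
  spike[at] <- spike[at] + amp
  h2 <- hemodynamic_series(matrix(spike, 1), matrix(clean / 2, 1), fs, "ch1")
  out2 <- spline_motion_correct(h2)
  resid_at_spike <- max(abs(out2$hbo[1, at] - clean[at]))
  expect_lt(resid_at_spike, 0.2 * amp)
  away <- c(1:(fs * 140), (fs * 160):n)
  expect_equal(out2$hbo[1, away], spike[away], tolerance = 1e-9)

  # constant series untouched
  hc <- hemodynamic_series(matrix(1, 1, n), matrix(1, 1, n), fs, "ch1")
  outc <- spline_motion_correct(hc)
  expect_equal(outc$hbo, hc$hbo)
  expect_length(outc$excluded_channels, 0)
})

test_that("the 5-SD moving-average rule flags sustained excursions only", {
  fs <- 50
  set.seed(32)
  n <- fs * 200
  flagged <- 0
  for (s in 1:10) {
    x <- rnorm(n)
    h <- hemodynamic_series(matrix(x, 1), matrix(rnorm(n), 1), fs, "ch1")
    flagged <- flagged + length(flag_low_snr(h)$excluded_channels)
  }
  expect_lte(flagged, 1)

  x <- rnorm(n)
  x[(fs * 100):(fs * 102)] <- x[(fs * 100):(fs * 102)] + 8 * sd(x)
  h <- hemodynamic_series(matrix(x, 1), matrix(rnorm(n), 1), fs, "ch1")
  out <- flag_low_snr(h)
  expect_equal(out$excluded_channels, "ch1")
  expect_match(out$exclusion_reasons[["ch1"]], "low SNR")
})

test_that("full cleaning chain recovers a planted HRF-coupled signal", {
  p <- sim_params(n_eeg = 4, n_eog = 0, n_fnirs = 6, duration_s = 300,
                  noise_mix = 0.15)
  subj <- generate_subject(p, 99)
  h <- suppressWarnings(fnirs_preprocess(subj$fnirs_od))
  sos <- nvfusion:::butter_sos_bandpass(3, 0.01, 0.1, 50)
  target <- as.numeric(nvfusion:::sos_filtfilt(sos, subj$truth$hemodynamic_drive))
  cors <- apply(h$hbo, 1, cor, y = target)
  expect_gt(max(abs(cors)), 0.95)
})
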