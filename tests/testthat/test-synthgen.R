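test_that("the HRF kernel has the canonical double-gamma shape", {
  p <- sim_params(duration_s = 180)
  k <- hrf_kernel(p)
  t <- seq(0, 32, by = 1 / p$fs_fnirs)
  expect_equal(k[1], 0, tolerance = 1e-9)
  expect_equal(max(k), 1)
  expect_lt(abs(t[which.max(k)] - 6), 1 / p$fs_fnirs + 1e-9)
  expect_lt(min(k), 0)                                   # undershoot exists
  expect_lte(abs(min(k)), p$hrf$ratio * 1.1)
  expect_gt(sum(k), 0)
})

test_that("generated recordings have the configured shapes at the defaults", {
  p <- sim_params()                                      # 660 s, 64/2/14
  subj <- generate_subject(p, 1234)
  expect_equal(dim(subj$eeg$data), c(64, 660 * 256))
  expect_equal(dim(subj$eog$data), c(2, 660 * 256))
  expect_equal(dim(subj$fnirs_od$data), c(28, 660 * 50))
  expect_equal(subj$fnirs_od$channel_labels[1:2], c("ch1@690", "ch1@830"))
  # physiological EEG scale
  rms <- sqrt(rowMeans(subj$eeg$data^2))
  expect_true(all(rms > 10 & rms < 50))
})

test_that("generation is bit-identical under a repeated seed", {
  p <- sim_params(n_eeg = 6, n_fnirs = 4, duration_s = 150)
  s1 <- generate_subject(p, 77)
  s2 <- generate_subject(p, 77)
  expect_identical(s1$eeg$data, s2$eeg$data)
  expect_identical(s1$fnirs_od$data, s2$fnirs_od$data)
  expect_identical(s1$truth$fnirs_pattern, s2$truth$fnirs_pattern)
  s3 <- generate_subject(p, 78)
  expect_false(identical(s1$eeg$data, s3$eeg$data))
})

test_that("planted band power concentrates in the configured band", {
  p <- sim_params(n_eeg = 6, duration_s = 150, noise_mix = 0)
  subj <- generate_subject(p, 5)
  x <- subj$eeg$data[1, ]                                # community member
  sp <- Mod(fft(x))^2
  f <- (seq_along(x) - 1) * 256 / length(x)
  in_band <- sum(sp[f >= 8 & f <= 10])
  broad <- sum(sp[f >= 1.5 & f <= 50])
  expect_gt(in_band / broad, 0.6)
})

test_that("zero coupling leaves hemodynamics unrelated to the drive", {
  # The drive and the pink noise are both slow, so even independent series
  # share only a few dozen effective degrees of freedom per record and
  # chance correlations of ~0.15 occur; the planted-coupling preset must
  # sit far above that chance level.
  max_cor <- function(beta, s) {
    p <- sim_params(n_eeg = 4, n_eog = 0, n_fnirs = 4, duration_s = 300,
                    coupling_beta = beta)
    subj <- generate_subject(p, 800 + s)
    h <- mbll_invert(subj$fnirs_od)
    max(abs(apply(h$hbo, 1, cor, y = subj$truth$hemodynamic_drive)))
  }
  null_cors <- vapply(1:12, function(s) max_cor(0, s), 0)
  coupled_cors <- vapply(1:5, function(s) max_cor(1, 100 + s), 0)
  expect_lt(mean(null_cors), 0.2)
  expect_gt(min(coupled_cors), 0.5)
  expect_gt(min(coupled_cors), 2 * quantile(null_cors, 0.95))
})

test_that("cohorts carry group labels and the patient-like effect", {
  p <- sim_params(n_eeg = 6, n_fnirs = 4, duration_s = 150)
  coh <- generate_cohort(p, n_a = 11, n_b = 8, seed = 3)
  expect_length(coh, 19)
  expect_equal(sum(vapply(coh, `[[`, "", "group") == "A"), 11)
  expect_equal(sum(vapply(coh, `[[`, "", "group") == "B"), 8)
  kA <- max(coh[[1]]$truth$kappa)
  kB <- max(coh[[19]]$truth$kappa)
  expect_equal(kB, kA * p$group_effect$kappa_factor, tolerance = 1e-12)
  expect_error(generate_cohort(p, n_a = 1, n_b = 8),
               class = "nvf_parameter_error")
})

test_that("parameter validation rejects out-of-range settings", {
  expect_error(sim_params(duration_s = 60), class = "nvf_parameter_error")
  expect_error(sim_params(sync_kappa = 1.2), class = "nvf_parameter_error")
  expect_error(sim_params(fs_eeg = 512), class = "nvf_parameter_error")
  expect_error(sim_params(noise_mix = -0.1), class = "nvf_parameter_error")
})

test_that("blink artifacts land on frontal electrodes and EOG", {
  p <- sim_params(n_eeg = 10, duration_s = 150, blinks = TRUE)
  subj <- generate_subject(p, 9)
  expect_gt(length(subj$truth$blink_times), 0)
  bt <- subj$truth$blink_times[1]
  idx <- round(bt * 256) + 1:75
  # the blink is visible on the EOG well above its background
  expect_gt(max(abs(subj$eog$data[1, idx])), 100)
})

test_that("motion spikes perturb the optical density series", {
  p <- sim_params(n_eeg = 4, n_eog = 0, n_fnirs = 4, duration_s = 150)
  p_spk <- p; p_spk$motion_spikes <- TRUE
  s0 <- generate_subject(p, 10)
  s1 <- generate_subject(p_spk, 10)
  expect_false(identical(s0$fnirs_od$data, s1$fnirs_od$data))
  expect_gt(max(abs(s1$fnirs_od$data - s0$fnirs_od$data)), 0)
})
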