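library(nvfusion)
prep_subject <- function(subj, n_epochs) {
  band <- bandpass_band(subj$eeg, eeg_bands("lower_alpha"))
  ep_bb <- epoch_and_reject(subj$eeg, n_keep = n_epochs)
  ep <- epoch_extract(band, ep_bb$kept_epoch_indices,
                      band = eeg_bands("lower_alpha"))
  h <- suppressWarnings(fnirs_preprocess(subj$fnirs_od))
  h5 <- nvfusion:::resample_hemo(nvfusion:::crop_hemo(h, 120), 5)
  extract_features(ep, h5, n_epochs = n_epochs, lag_epochs = 3)
}

## (a) null calibration: coupling_beta = 0
p0 <- sim_params(n_eeg = 6, n_eog = 0, n_fnirs = 4, duration_s = 180,
                 coupling_beta = 0)
t0 <- Sys.time()
n_subj <- 60   # pilot subset
pvals <- numeric(n_subj)
for (i in seq_len(n_subj)) {
  subj <- generate_subject(p0, 5000 + i)
  fs <- prep_subject(subj, 25)
  fit <- mspoc_fit(fs, n_restarts = 2, B_perm = 79, perm_restarts = 2,
                   seed = i)[[1]]
  pvals[i] <- fit$p_value
}
cat("null: frac p<0.05 =", mean(pvals < 0.05), " time/subj:",
    as.numeric(Sys.time() - t0, units = "secs") / n_subj, "s\n")

## (b) planted detection: beta = 1, noise_mix = 0.5
p1 <- sim_params(n_eeg = 6, n_eog = 0, n_fnirs = 4, duration_s = 180,
                 coupling_beta = 1, noise_mix = 0.5)
det <- logical(20); rs <- numeric(20)
t0 <- Sys.time()
for (i in 1:20) {
  subj <- generate_subject(p1, 6000 + i)
  fs <- prep_subject(subj, 25)
  fit <- mspoc_fit(fs, n_restarts = 2, B_perm = 79, perm_restarts = 2,
                   seed = i)[[1]]
  det[i] <- fit$p_value < 0.05; rs[i] <- fit$r
}
cat("planted: det rate =", mean(det), " mean r =", mean(rs), " time:",
    as.numeric(Sys.time() - t0, units = "secs"), "s\n")

## (c) fNIRS pattern recovery vs truth across noise mixes
for (nm in c(0, 0.25, 0.5)) {
  cs <- numeric(20)
  for (i in 1:20) {
    pp <- sim_params(n_eeg = 6, n_eog = 0, n_fnirs = 4, duration_s = 180,
                     coupling_beta = 1, noise_mix = nm)
    subj <- generate_subject(pp, 7000 + i)
    fs <- prep_subject(subj, 25)
    fit <- mspoc_fit(fs, n_restarts = 2, B_perm = 0, seed = i)[[1]]
    tru <- subj$truth$fnirs_pattern
    cs[i] <- abs(sum(fit$a_fnirs * tru)) / sqrt(sum(fit$a_fnirs^2) * sum(tru^2))
  }
  cat("noise", nm, ": mean cosine =", mean(cs), " min =", min(cs), "\n")
}
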