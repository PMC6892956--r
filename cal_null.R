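library(nvfusion)
p <- sim_params(n_eeg = 8, duration_s = 150,
                group_effect = list(kappa_factor = 1, beta_factor = 1))  # null
params <- derive_sl_params(eeg_bands("lower_alpha"), 256, n_rec = 5)
cat("params:", params$m, params$tau, params$w1, params$w2, "\n")
subj_sl <- function(subj, n_keep = 5) {
  band <- bandpass_band(subj$eeg, eeg_bands("lower_alpha"))
  ep_bb <- epoch_and_reject(subj$eeg, n_keep = n_keep)
  ep <- epoch_extract(band, ep_bb$kept_epoch_indices, band = eeg_bands("lower_alpha"))
  sl_matrix(ep, params, mode = "concatenate")
}
t0 <- Sys.time()
n_coh <- 30
any_sig <- logical(n_coh); edge_frac <- numeric(n_coh)
for (ci in seq_len(n_coh)) {
  coh <- generate_cohort(p, 11, 8, seed = 3000 + ci)
  coh <- lapply(coh, function(s) { s$eog <- NULL; s })
  mats <- lapply(coh, subj_sl)
  g <- vapply(coh, `[[`, "", "group")
  et <- edgewise_t(mats[g=="A"], mats[g=="B"])
  edge_frac[ci] <- mean(et$p[upper.tri(et$p)] < 0.05, na.rm = TRUE)
  cr <- cbpt(mats[g=="A"], mats[g=="B"], B = 299, seed = ci)
  any_sig[ci] <- length(cr$cluster_p) && min(cr$cluster_p) < 0.05
}
cat("edge-level type I:", mean(edge_frac), "\n")
cat("FW false positive rate:", mean(any_sig), "\n")
cat("time/cohort:", as.numeric(Sys.time()-t0, units="secs")/n_coh, "s\n")
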