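library(nvfusion)
p <- sim_params(n_eeg = 8, n_eog = 0, duration_s = 150,
                group_effect = list(kappa_factor = 1, beta_factor = 1))
params <- derive_sl_params(eeg_bands("lower_alpha"), 256, n_rec = 5)
subj_sl <- function(subj, n_keep) {
  band <- bandpass_band(subj$eeg, eeg_bands("lower_alpha"))
  ep_bb <- epoch_and_reject(subj$eeg, n_keep = n_keep)
  ep <- epoch_extract(band, ep_bb$kept_epoch_indices,
                      band = eeg_bands("lower_alpha"))
  sl_matrix(ep, params, mode = "concatenate")
}
t0 <- Sys.time()
set.seed(11)
pool_seeds <- sample.int(2^31 - 2, 200)
pool <- lapply(pool_seeds, function(sd) subj_sl(generate_subject(p, sd), 5))
cat("pool time:", as.numeric(Sys.time() - t0, units = "secs"), "s\n")
t0 <- Sys.time()
n_coh <- 100
any_sig <- logical(n_coh); edge_frac <- numeric(n_coh)
set.seed(12)
for (ci in seq_len(n_coh)) {
  idx <- sample(200, 19)
  A <- pool[idx[1:11]]; B <- pool[idx[12:19]]
  et <- edgewise_t(A, B)
  edge_frac[ci] <- mean(et$p[upper.tri(et$p)] < 0.05, na.rm = TRUE)
  cr <- cbpt(A, B, B = 299, seed = ci)
  any_sig[ci] <- length(cr$cluster_p) && min(cr$cluster_p) < 0.05
}
cat("edge type-I:", mean(edge_frac), " FW rate:", mean(any_sig),
    " cohort loop:", as.numeric(Sys.time() - t0, units = "secs"), "s\n")
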