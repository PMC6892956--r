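library(nvfusion)
# planted 6-edge star: hub electrode 1 with six leaves, kappa reduced in the
# patient group only
star_sets <- list(list(members = 1:7, kappa = c(0.95, rep(0.6, 6))))
p <- sim_params(n_eeg = 8, n_eog = 0, duration_s = 150, sync_sets = star_sets,
                group_effect = list(kappa_factor = 0.5, beta_factor = 1))
params <- derive_sl_params(eeg_bands("lower_alpha"), 256, n_rec = 5)
subj_sl <- function(subj) {
  band <- bandpass_band(subj$eeg, eeg_bands("lower_alpha"))
  ep_bb <- epoch_and_reject(subj$eeg)
  ep <- epoch_extract(band, ep_bb$kept_epoch_indices,
                      band = eeg_bands("lower_alpha"))
  sl_matrix(ep, params, mode = "concatenate")
}
t0 <- Sys.time()
hits <- logical(20)
for (ci in 1:20) {
  coh <- generate_cohort(p, 11, 8, seed = 4000 + ci)
  mats <- lapply(coh, subj_sl)
  g <- vapply(coh, `[[`, "", "group")
  cr <- cbpt(mats[g == "A"], mats[g == "B"], B = 299, seed = ci)
  ok <- FALSE
  if (length(cr$cluster_p) && min(cr$cluster_p) < 0.05) {
    cl <- cr$clusters[[which.min(cr$cluster_p)]]
    planted <- sum((cl[, 1] == 1 & cl[, 2] %in% 2:7))
    ok <- planted >= 4
  }
  hits[ci] <- ok
  cat(ci, ok, "\n")
}
cat("star recovery:", mean(hits), " time:",
    as.numeric(Sys.time() - t0, units = "secs"), "s\n")
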