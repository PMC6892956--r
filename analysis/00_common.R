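# Shared configuration for the analysis drivers.  Every script can be run on
# its own: intermediates are cached under scratch/ and regenerated on demand.
library(nvfusion)

COHORT_SEED <- 20190901
N_CONTROLS <- 11
N_PATIENTS <- 8

# Study-shaped simulation: 64 electrodes + 2 EOG at 256 Hz, 14 prefrontal
# fNIRS channels at 50 Hz, patient-like group effect (kappa x 0.6,
# beta x 0.5).  Records are 180 s (the test preset): long enough for the
# 120-s settling discard plus the 20-s analysis window on every subject,
# short enough to iterate on a laptop.
sim_preset <- function() sim_params(duration_s = 180)

pipeline_config <- function() {
  run_config(sim = sim_preset(), n_a = N_CONTROLS, n_b = N_PATIENTS,
             montage = read_montage(), B = 1000, lag_epochs = 3,
             n_restarts = 10, B_perm = 199, perm_restarts = 2,
             seed = COHORT_SEED)
}

cache <- function(name, expr) {
  dir.create("scratch", showWarnings = FALSE)
  path <- file.path("scratch", paste0(name, ".rds"))
  if (file.exists(path)) return(readRDS(path))
  val <- expr
  saveRDS(val, path)
  val
}

results_dir <- function() {
  dir.create("results", showWarnings = FALSE)
  "results"
}

write_tsv <- function(df, name) {
  path <- file.path(results_dir(), name)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  message("wrote ", path)
  path
}
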