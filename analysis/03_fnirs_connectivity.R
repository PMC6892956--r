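#!/usr/bin/env Rscript
# fNIRS arm: modified Beer-Lambert conversion, detrend + 0.01-0.1 Hz
# band-pass, spline motion correction, 5-SD SNR screening; then HbO (and Hb)
# Pearson matrices, Fisher-z group means, the control-derived top-5% network
# threshold, and per-channel degree strengths.

source("analysis/00_common.R")

cohort <- cache("cohort", generate_cohort(sim_preset(), N_CONTROLS,
                                          N_PATIENTS, seed = COHORT_SEED))
groups <- vapply(cohort, `[[`, "", "group")

hemo <- cache("hemo", lapply(cohort, function(s)
  suppressWarnings(fnirs_preprocess(s$fnirs_od))))

r_hbo <- lapply(hemo, pearson_matrix, chromophore = "hbo")
r_hb <- lapply(hemo, pearson_matrix, chromophore = "hb")

ctrl <- nvfusion:::mean_r_matrix(r_hbo[groups == "A"])
pat <- nvfusion:::mean_r_matrix(r_hbo[groups == "B"])
nvfusion:::write_matrix_tsv(ctrl, file.path(results_dir(), "hbo_r_controls.tsv"))
nvfusion:::write_matrix_tsv(pat, file.path(results_dir(), "hbo_r_patients.tsv"))

g_ctrl <- threshold_top_fraction(ctrl, 0.05, reference = ctrl)
g_pat <- threshold_top_fraction(pat, 0.05, reference = ctrl)
message(sprintf("top-5%% threshold from the control mean: r_T = %.3f", 
                g_ctrl$threshold_value))
message(sprintf("edges retained: controls %d, patients %d",
                nrow(g_ctrl$edges), nrow(g_pat$edges)))

sigma <- t(vapply(r_hbo, degree_strength, numeric(14)))
deg <- data.frame(channel = ctrl$labels,
                  controls = colMeans(sigma[groups == "A", ]),
                  controls_sem = apply(sigma[groups == "A", ], 2, sd) / sqrt(sum(groups == "A")),
                  patients = colMeans(sigma[groups == "B", ]),
                  patients_sem = apply(sigma[groups == "B", ], 2, sd) / sqrt(sum(groups == "B")))
write_tsv(deg, "degree_strength.tsv")
print(deg, row.names = FALSE)
cache("connectivity", list(r_hbo = r_hbo, r_hb = r_hb, sigma = sigma,
                           graphs = list(A = g_ctrl, B = g_pat)))
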