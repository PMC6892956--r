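#' Pipeline run configuration
#'
#' Collects every stage parameter with the pipeline defaults.  Unknown
#' arguments are rejected by name.  The configuration is echoed into the
#' result bundle's provenance together with a content hash.
#'
#' @param sim `sim_params` for a simulated cohort (the supported input mode).
#' @param n_a,n_b group sizes.
#' @param bands character vector of band names to analyze.
#' @param montage a `montage` (default: the shipped one when the electrode
#'   count matches, else `NULL` which disables ROI-wise fusion).
#' @param sl_mode SL computation mode (see [sl_matrix()]).
#' @param p_ref,n_rec SL parameter-derivation inputs.
#' @param fraction top-fraction network threshold.
#' @param B permutations for group statistics.
#' @param fusion_band band override for fusion (`NULL`: data-driven
#'   selection via [feature_select()]).
#' @param n_epochs,lag_epochs,n_restarts,B_perm,perm_restarts fusion settings.
#' @param epoch_len_s,reject_uv,n_keep,discard_lead_s epoching settings.
#' @param seed master seed for generation, statistics and fusion.
#' @export
run_config <- function(sim = sim_params(), n_a = 11, n_b = 8,
                       bands = names(eeg_bands()),
                       montage = NULL, sl_mode = "concatenate",
                       p_ref = 0.05, n_rec = 10, fraction = 0.05, B = 1000,
                       fusion_band = NULL, n_epochs = 10, lag_epochs = 0,
                       n_restarts = 20, B_perm = 200, perm_restarts = 3,
                       epoch_len_s = 2, reject_uv = 150, n_keep = 10,
                       discard_lead_s = 120, seed = 1) {
  cfg <- as.list(environment())
  cfg$config_hash <- config_hash(cfg)
  class(cfg) <- "run_config"
  cfg
}

# polynomial content hash over the deparsed configuration (stable under
# key reordering: fields are serialized in sorted-name order)
config_hash <- function(cfg) {
  cfg$config_hash <- NULL
  txt <- paste(deparse(cfg[order(names(cfg))]), collapse = "")
  h <- 0
  for (b in utf8ToInt(txt)) h <- (h * 31 + b) %% 999999937
  sprintf("%08x", h)
}

# EEG arm for one subject: ocular correction at native rate, per-band
# zero-phase filtering before decimation, epoch selection on the broadband
# 256-Hz signal shared across bands.
preprocess_eeg_subject <- function(subj, cfg) {
  rec <- subj$eeg
  if (!is.null(subj$eog)) rec <- correct_ocular(rec, subj$eog)
  broadband <- resample(rec, 256)
  ep_bb <- epoch_and_reject(broadband, epoch_len_s = cfg$epoch_len_s,
                            reject_uv = cfg$reject_uv, n_keep = cfg$n_keep,
                            discard_lead_s = cfg$discard_lead_s)
  per_band <- list()
  for (bn in cfg$bands) {
    band <- eeg_bands(bn)
    filt <- resample(bandpass_band(rec, band), 256)
    per_band[[bn]] <- epoch_extract(filt, ep_bb$kept_epoch_indices,
                                    epoch_len_s = cfg$epoch_len_s,
                                    discard_lead_s = cfg$discard_lead_s,
                                    band = band)
  }
  list(broadband = ep_bb, bands = per_band)
}

# decimate a hemodynamic series (anti-aliased), e.g. 50 -> 5 Hz
resample_hemo <- function(h, fs_new) {
  if (fs_new == h$fs) return(h)
  q <- h$fs / fs_new
  stopifnot(abs(q - round(q)) < 1e-9)
  sos <- butter_sos_lowpass(8, 0.8 * fs_new / 2, h$fs)
  idx <- 1 + (seq_len(floor(ncol(h$hbo) * fs_new / h$fs)) - 1) * round(q)
  out <- h
  out$hbo <- sos_filtfilt(sos, h$hbo)[, idx, drop = FALSE]
  out$hb <- sos_filtfilt(sos, h$hb)[, idx, drop = FALSE]
  out$fs <- fs_new
  out
}

crop_hemo <- function(h, from_s) {
  i0 <- round(from_s * h$fs)
  out <- h
  out$hbo <- h$hbo[, (i0 + 1):ncol(h$hbo), drop = FALSE]
  out$hb <- h$hb[, (i0 + 1):ncol(h$hb), drop = FALSE]
  out
}

#' Select the fusion features from the group statistics
#'
#' Chooses the band whose cluster-based permutation test produced the most
#' significant cluster (ties: lower cluster mass rank, then the lower band);
#' the chromophore is fixed to HbO.  With no significant cluster the
#' configured default band is used with a warning.  A manual override wins
#' unconditionally.
#'
#' @param cbpt_by_band named list of `cluster_result`.
#' @param default fallback band name.
#' @param override optional manual band name.
#' @return list(band, chromophore, reason).
#' @export
feature_select <- function(cbpt_by_band, default = "lower_alpha", override = NULL) {
  if (!is.null(override)) {
    return(list(band = override, chromophore = "hbo", reason = "manual override"))
  }
  ps <- vapply(cbpt_by_band, function(cr) {
    if (length(cr$cluster_p)) min(cr$cluster_p) else Inf
  }, 0)
  ord <- names(eeg_bands())
  ps <- ps[order(match(names(ps), ord))]   # lower band wins ties
  if (all(!is.finite(ps)) || min(ps) >= 0.05) {
    warning("no band with a significant cluster; falling back to ", default)
    return(list(band = default, chromophore = "hbo",
                reason = "fallback: no significant cluster"))
  }
  best <- names(ps)[which.min(ps)]
  list(band = best, chromophore = "hbo",
       reason = sprintf("most significant CBPT cluster (p = %.4g)", min(ps)))
}

# average correlation matrices on the Fisher-z scale, return r units
mean_r_matrix <- function(mats) {
  zs <- lapply(mats, function(cm) fisher_z(cm)$values)
  zbar <- Reduce(`+`, zs) / length(zs)
  r <- tanh(zbar)
  diag(r) <- 1
  connectivity_matrix(r, metric = "pearson_r", labels = mats[[1]]$labels)
}

#' Run the full bimodal pipeline on a simulated cohort
#'
#' Executes the two arms and their fusion: EEG (ocular correction, band
#' filtering, decimation, epoch selection, SL matrices, mean-SL permutation
#' test and CBPT per band) and fNIRS (MBLL, cleaning, Pearson/Fisher-z
#' connectivity, control-derived top-fraction network, degree strength,
#' permutation test), then data-driven feature selection and per-subject
#' mSPoC fusion summarized per group.
#'
#' @param cfg a `run_config`.
#' @param cohort optional pre-generated cohort (as from [generate_cohort()]);
#'   by default one is generated from `cfg$sim` and `cfg$seed`.
#' @return a result bundle (list): per-subject and group matrices, test
#'   results, fusion summaries, provenance.
#' @export
run_pipeline <- function(cfg, cohort = NULL) {
  if (is.null(cohort)) {
    cohort <- generate_cohort(cfg$sim, n_a = cfg$n_a, n_b = cfg$n_b,
                              seed = cfg$seed)
  }
  groups <- vapply(cohort, `[[`, "", "group")
  ids <- vapply(cohort, `[[`, "", "id")

  ## --- EEG arm ---------------------------------------------------------
  sl_by_band <- lapply(cfg$bands, function(bn) vector("list", length(cohort)))
  names(sl_by_band) <- cfg$bands
  preps <- vector("list", length(cohort))
  hemo <- vector("list", length(cohort))
  for (si in seq_along(cohort)) {
    prep <- preprocess_eeg_subject(cohort[[si]], cfg)
    prep$broadband <- NULL
    preps[[si]] <- prep
    for (bn in cfg$bands) {
      params <- derive_sl_params(eeg_bands(bn), 256, p_ref = cfg$p_ref,
                                 n_rec = cfg$n_rec)
      sl_by_band[[bn]][[si]] <- sl_matrix(prep$bands[[bn]], params,
                                          mode = cfg$sl_mode)
    }
    hemo[[si]] <- fnirs_preprocess(cohort[[si]]$fnirs_od)
    # raw recordings are no longer needed: keep the footprint small so the
    # remaining stages are not dominated by garbage collection
    cohort[[si]]$eeg <- cohort[[si]]$eog <- cohort[[si]]$fnirs_od <- NULL
  }
  mean_sl_tests <- list(); cbpt_by_band <- list(); mean_sl_subj <- list()
  for (bn in cfg$bands) {
    ms <- vapply(sl_by_band[[bn]], mean_sl, 0)
    mean_sl_subj[[bn]] <- ms
    mean_sl_tests[[bn]] <- permutation_mean_diff(ms[groups == "A"],
                                                 ms[groups == "B"],
                                                 B = cfg$B, seed = cfg$seed)
    cbpt_by_band[[bn]] <- cbpt(sl_by_band[[bn]][groups == "A"],
                               sl_by_band[[bn]][groups == "B"],
                               B = cfg$B, seed = cfg$seed)
  }

  ## --- fNIRS arm -------------------------------------------------------
  r_mats <- lapply(hemo, pearson_matrix, chromophore = "hbo")
  r_mats_hb <- lapply(hemo, pearson_matrix, chromophore = "hb")
  ctrl_mean <- mean_r_matrix(r_mats[groups == "A"])
  pat_mean <- mean_r_matrix(r_mats[groups == "B"])
  graph_a <- threshold_top_fraction(ctrl_mean, cfg$fraction, reference = ctrl_mean)
  graph_b <- threshold_top_fraction(pat_mean, cfg$fraction, reference = ctrl_mean)
  sigma_subj <- t(vapply(r_mats, degree_strength, numeric(nrow(ctrl_mean$values))))
  sigma_mean <- rowMeans(sigma_subj)
  degree_test <- permutation_mean_diff(sigma_mean[groups == "A"],
                                       sigma_mean[groups == "B"],
                                       B = cfg$B, seed = cfg$seed)

  ## --- fusion ----------------------------------------------------------
  sel <- feature_select(cbpt_by_band, override = cfg$fusion_band)
  fusion <- list()
  if (sel$band %in% cfg$bands) {
    feats <- vector("list", length(cohort))
    for (si in seq_along(cohort)) {
      prep <- preps[[si]]
      h5 <- resample_hemo(crop_hemo(hemo[[si]], cfg$discard_lead_s), 5)
      eeg_sel <- if (is.null(cfg$montage)) NULL else
        roi_labels(cfg$montage, "whole_pfc", "eeg")
      feats[[si]] <- extract_features(prep$bands[[sel$band]], h5,
                                      n_epochs = cfg$n_epochs,
                                      lag_epochs = cfg$lag_epochs,
                                      eeg_channels = eeg_sel)
    }
    for (g in c("A", "B")) {
      fusion[[g]] <- fuse_group(feats[groups == g], roi = "whole_pfc",
                                n_restarts = cfg$n_restarts, B_perm = cfg$B_perm,
                                perm_restarts = cfg$perm_restarts,
                                seed = cfg$seed)
    }
  }

  band_sel <- sel$band
  list(
    config = cfg,
    groups = groups, ids = ids,
    sl_matrices = sl_by_band,
    mean_sl = mean_sl_subj,
    mean_sl_tests = mean_sl_tests,
    cbpt = cbpt_by_band,
    hemo = hemo,
    r_matrices_hbo = r_mats,
    r_matrices_hb = r_mats_hb,
    group_mean_r = list(A = ctrl_mean, B = pat_mean),
    graphs = list(A = graph_a, B = graph_b),
    degree_strength = sigma_subj,
    degree_test = degree_test,
    feature_selection = sel,
    fusion = fusion,
    provenance = list(config_hash = cfg$config_hash, seed = cfg$seed,
                      version = as.character(packageVersion("nvfusion")),
                      feature_band = band_sel))
}

#' Bundle the headline pipeline outputs for writing
#'
#' Flattens a [run_pipeline()] result into the matrices/graphs/scalars/
#' provenance layout consumed by [write_results()].
#' @param res result of [run_pipeline()].
#' @return a bundle list.
#' @export
bundle_results <- function(res) {
  mats <- list()
  for (bn in names(res$sl_matrices)) {
    groups <- res$groups
    for (g in c("A", "B")) {
      vals <- Reduce(`+`, lapply(res$sl_matrices[[bn]][groups == g], `[[`, "values")) /
        sum(groups == g)
      diag(vals) <- 1
      mats[[paste0("sl_", bn, "_group", g)]] <-
        connectivity_matrix(vals, "sl", res$sl_matrices[[bn]][[1]]$labels, band = bn)
    }
  }
  mats$hbo_r_groupA <- res$group_mean_r$A
  mats$hbo_r_groupB <- res$group_mean_r$B
  scalars <- c(
    setNames(vapply(res$mean_sl_tests, `[[`, 0, "p_value"),
             paste0("mean_sl_p_", names(res$mean_sl_tests))),
    degree_p = res$degree_test$p_value,
    r_threshold = res$graphs$A$threshold_value)
  if (length(res$fusion)) {
    scalars <- c(scalars,
                 fusion_r_groupA = res$fusion$A$mean_r,
                 fusion_r_groupB = res$fusion$B$mean_r,
                 fusion_sem_groupA = res$fusion$A$sem_r,
                 fusion_sem_groupB = res$fusion$B$sem_r)
  }
  list(matrices = mats, graphs = res$graphs, scalars = as.list(scalars),
       provenance = res$provenance)
}

#' Demographic comparison table
#'
#' Two-sample Welch t tests per variable with Bonferroni correction across
#' variables; the standard companion table for a two-group cohort.
#'
#' @param df data.frame of subject rows.
#' @param group_col name of the group column (two levels).
#' @param vars numeric columns to compare.
#' @return data.frame with means, SDs, t, raw and Bonferroni p.
#' @export
demographics_table <- function(df, group_col, vars) {
  g <- factor(df[[group_col]])
  stopifnot(nlevels(g) == 2)
  rows <- lapply(vars, function(v) {
    a <- df[[v]][g == levels(g)[1]]; b <- df[[v]][g == levels(g)[2]]
    tt <- t.test(a, b)
    data.frame(variable = v, mean_a = mean(a), sd_a = sd(a), mean_b = mean(b),
               sd_b = sd(b), t = unname(tt$statistic), p = tt$p.value)
  })
  out <- do.call(rbind, rows)
  out$p_bonferroni <- pmin(out$p * length(vars), 1)
  out
}
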