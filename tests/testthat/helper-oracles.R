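# Independent reference implementations used as oracles.  These are kept
# deliberately naive (double loops, dense grids) and separate from the
# package's optimized code paths.

# Naive O(M^2) bivariate synchronization likelihood: delay embedding,
# per-reference-vector quantile critical distances, coincident-recurrence
# counting.  Mirrors the published definition directly.
sl_pair_naive <- function(x, y, m, tau, w1, w2, p_ref) {
  M <- length(x) - (m - 1) * tau
  embed_of <- function(v, i) v[i + (0:(m - 1)) * tau]
  q_type7 <- function(v, p) {
    v <- sort(v)
    h <- (length(v) - 1) * p
    lo <- floor(h)
    if (lo + 2 <= length(v) && h > lo) {
      v[lo + 1] + (h - lo) * (v[lo + 2] - v[lo + 1])
    } else v[lo + 1]
  }
  acc <- 0
  for (i in seq_len(M)) {
    js <- seq_len(M)
    js <- js[abs(js - i) > w1 & abs(js - i) <= w2]
    dx <- vapply(js, function(j) sqrt(sum((embed_of(x, i) - embed_of(x, j))^2)), 0)
    dy <- vapply(js, function(j) sqrt(sum((embed_of(y, i) - embed_of(y, j))^2)), 0)
    ex <- q_type7(dx, p_ref)
    ey <- q_type7(dy, p_ref)
    joint <- sum(dx <= ex & dy <= ey)
    acc <- acc + joint / (p_ref * length(js))
  }
  acc / M
}

# Exhaustive grid search over unit-circle spatial filters for a 2-channel x
# 2-channel mSPoC problem: maximizes cor(w_e' C_e w_e, w_f' y_e) over a
# 0.5-degree grid of filter angles.
mspoc_grid_2x2 <- function(covs, Y, step_deg = 0.5) {
  th <- seq(0, 180 - step_deg, by = step_deg) * pi / 180
  E <- length(covs)
  c11 <- vapply(covs, function(C) C[1, 1], 0)
  c12 <- vapply(covs, function(C) C[1, 2], 0)
  c22 <- vapply(covs, function(C) C[2, 2], 0)
  # phi for every EEG angle: rows = angles, cols = epochs
  Phi <- outer(cos(th)^2, c11) + outer(2 * cos(th) * sin(th), c12) +
    outer(sin(th)^2, c22)
  Tm <- outer(cos(th), Y[, 1]) + outer(sin(th), Y[, 2])
  zrow <- function(M) {
    M <- M - rowMeans(M)
    M / sqrt(rowSums(M^2))
  }
  R <- zrow(Phi) %*% t(zrow(Tm))
  max(R)
}

# Focused planted-coupling simulation for filter/pattern recovery: one
# band-limited source with per-epoch power drawn lognormally, mixed into the
# EEG sensors through a known column; the fNIRS samples follow the z-scored
# log-power through a known pattern.  `noise_mix` is the fraction of sensor
# noise in both modalities.
make_mspoc_toy <- function(n_eeg = 6, n_fnirs = 5, n_epochs = 40,
                           n_samp = 512, fs = 256, noise_mix = 0.5,
                           seed = 1) {
  set.seed(seed)
  a_true <- rnorm(n_eeg); a_true <- a_true / sqrt(sum(a_true^2))
  pattern <- runif(n_fnirs, 0.3, 1)
  log_pow <- rnorm(n_epochs, sd = 1)
  covs <- vector("list", n_epochs)
  band <- eeg_bands("lower_alpha")
  realized_pow <- numeric(n_epochs)
  for (e in seq_len(n_epochs)) {
    src <- nvfusion:::band_noise_source(n_samp, fs, band) * exp(log_pow[e] / 2)
    realized_pow[e] <- mean(src^2)      # the power the sensors actually see
    S <- outer(a_true, src)
    N <- matrix(rnorm(n_eeg * n_samp), n_eeg)
    X <- (1 - noise_mix) * S + noise_mix * N
    X <- X - rowMeans(X)
    covs[[e]] <- tcrossprod(X) / (n_samp - 1)
  }
  z <- (realized_pow - mean(realized_pow)) / sd(realized_pow)
  Y <- outer(z, pattern) * (1 - noise_mix) +
    noise_mix * matrix(rnorm(n_epochs * n_fnirs), n_epochs)
  list(fs = feature_set(covs, Y, epoch_len_s = n_samp / fs, lag_epochs = 0,
                        eeg_labels = sprintf("e%d", seq_len(n_eeg)),
                        fnirs_labels = sprintf("f%d", seq_len(n_fnirs))),
       a_true = a_true, pattern = pattern, log_pow = log_pow)
}

cosine_sim <- function(a, b) abs(sum(a * b)) / sqrt(sum(a^2) * sum(b^2))

# measured mid-signal gain of a filtering function at one frequency
measured_gain <- function(filter_fun, fs, f_test, dur = 30) {
  n <- round(fs * dur)
  y <- filter_fun(sin(2 * pi * f_test * (0:(n - 1)) / fs))
  max(abs(y[round(n * 0.3):round(n * 0.7)]))
}

# EEG/fNIRS preprocessing shorthand used across calibration tests: band
# filter, epoch on the broadband signal, slice the same epochs
calib_sl_matrix <- function(subj, params, band = eeg_bands("lower_alpha"),
                            n_keep = 10) {
  filt <- bandpass_band(subj$eeg, band)
  ep_bb <- epoch_and_reject(subj$eeg, n_keep = n_keep)
  ep <- epoch_extract(filt, ep_bb$kept_epoch_indices, band = band)
  sl_matrix(ep, params, mode = "concatenate")
}
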