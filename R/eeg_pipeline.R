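#' Canonical EEG frequency bands
#'
#' The six-band registry used throughout: delta (1.5-4 Hz), theta (4-8),
#' lower alpha (8-10), upper alpha (10-13), beta (14-30), gamma (30-50).
#' Splitting alpha at 10 Hz narrows the range of interest around the
#' posterior resting rhythm.
#'
#' @param name band name; with no argument the full registry is returned.
#' @return a `band_definition` (list with `name`, `low_hz`, `high_hz`) or,
#'   with no argument, a named list of all six.
#' @export
eeg_bands <- function(name = NULL) {
  reg <- list(
    delta       = band_definition("delta", 1.5, 4),
    theta       = band_definition("theta", 4, 8),
    lower_alpha = band_definition("lower_alpha", 8, 10),
    upper_alpha = band_definition("upper_alpha", 10, 13),
    beta        = band_definition("beta", 14, 30),
    gamma       = band_definition("gamma", 30, 50))
  if (is.null(name)) return(reg)
  if (!name %in% names(reg)) nvf_stop("nvf_validation_error", "unknown band '", name, "'")
  reg[[name]]
}

#' @rdname eeg_bands
#' @param low_hz,high_hz band edges in Hz, `0 < low_hz < high_hz`.
#' @export
band_definition <- function(name, low_hz, high_hz) {
  if (!(low_hz > 0 && high_hz > low_hz)) {
    nvf_stop("nvf_validation_error", "need 0 < low_hz < high_hz")
  }
  structure(list(name = name, low_hz = low_hz, high_hz = high_hz),
            class = "band_definition")
}

#' Regress EOG activity out of scalp channels
#'
#' Ordinary least-squares projection of each scalp channel onto the EOG
#' channels (plus intercept), subtracted.  Residuals are orthogonal to every
#' EOG channel by construction.  A rank-deficient EOG set falls back to the
#' pseudo-inverse with a warning.
#'
#' @param rec scalp recording (`eeg`).
#' @param eog EOG recording at the same rate and length.
#' @return corrected `ts_recording`.
#' @export
correct_ocular <- function(rec, eog) {
  if (rec$fs != eog$fs) nvf_stop("nvf_validation_error",
                                 "fs mismatch: ", rec$fs, " vs ", eog$fs)
  if (ncol(rec$data) != ncol(eog$data)) {
    nvf_stop("nvf_validation_error", "sample count mismatch")
  }
  if (nrow(eog$data) < 1) nvf_stop("nvf_validation_error", "need >= 1 EOG channel")
  X <- cbind(1, t(eog$data))
  xtx <- crossprod(X)
  beta <- tryCatch(solve(xtx, crossprod(X, t(rec$data))),
                   error = function(e) {
                     warning("rank-deficient EOG set; using pseudo-inverse")
                     sv <- svd(X)
                     pos <- sv$d > max(sv$d) * 1e-12
                     (sv$v[, pos, drop = FALSE] %*%
                        ((t(sv$u[, pos, drop = FALSE]) %*% t(rec$data)) / sv$d[pos]))
                   })
  resid_ <- t(rec$data) - X %*% beta
  # keep each channel's mean (the intercept is not an ocular component)
  resid_ <- sweep(resid_, 2, beta[1, ], "+")
  out <- rec
  out$data <- t(resid_)
  out
}

#' Zero-phase band-pass filter
#'
#' 4th-order Butterworth applied forward-backward (cascaded biquads, see
#' package vignette for the numerical rationale).  Passband-centre gain is
#' within [0.95, 1.05]; a sine one octave outside the band is attenuated to
#' <= 0.05; no phase shift.
#'
#' @param rec a `ts_recording`.
#' @param band a `band_definition`.
#' @param order filter order (default 4).
#' @return filtered recording.
#' @export
bandpass_band <- function(rec, band, order = 4) {
  if (band$high_hz >= rec$fs / 2) {
    nvf_stop("nvf_validation_error", "band edge ", band$high_hz,
             " Hz >= Nyquist (", rec$fs / 2, " Hz)")
  }
  sos <- butter_sos_bandpass(order, band$low_hz, band$high_hz, rec$fs)
  out <- rec
  out$data <- sos_filtfilt(sos, rec$data)
  out
}

#' Downsample a recording
#'
#' Anti-alias low-pass (8th-order Butterworth at 0.8 x new Nyquist, zero
#' phase) followed by integer decimation.  Output length is
#' `floor(n * fs_new / fs)`.
#'
#' @param rec a `ts_recording`.
#' @param fs_new target rate; must divide `rec$fs`.
#' @return resampled recording.
#' @export
resample <- function(rec, fs_new) {
  if (fs_new > rec$fs) nvf_stop("nvf_validation_error", "upsampling not supported")
  if (fs_new == rec$fs) return(rec)
  q <- rec$fs / fs_new
  if (abs(q - round(q)) > 1e-9) {
    nvf_stop("nvf_validation_error", "fs (", rec$fs, ") not divisible by fs_new (",
             fs_new, ")")
  }
  q <- round(q)
  sos <- butter_sos_lowpass(8, 0.8 * fs_new / 2, rec$fs)
  filt <- sos_filtfilt(sos, rec$data)
  n_out <- floor(ncol(rec$data) * fs_new / rec$fs)
  idx <- 1 + (seq_len(n_out) - 1) * q
  out <- rec
  out$data <- filt[, idx, drop = FALSE]
  out$fs <- fs_new
  out
}

#' Segment a recording into clean, baseline-corrected epochs
#'
#' Drops the first `discard_lead_s` seconds (instrument settling), cuts the
#' remainder into contiguous non-overlapping epochs of `epoch_len_s`
#' seconds, rejects every epoch in which any channel exceeds
#' `± reject_uv` microvolts, demeans each surviving epoch per channel, and
#' keeps the first `n_keep` survivors.
#'
#' @param rec broadband recording in microvolts.
#' @param epoch_len_s epoch length in seconds (default 2).
#' @param reject_uv amplitude rejection threshold in microvolts (default 150).
#' @param n_keep number of artifact-free epochs to retain (default 10).
#' @param discard_lead_s leading seconds to discard (default 120).
#' @return an `epoched_data` object: `data` is epochs x channels x samples,
#'   `kept_epoch_indices` are 0-based indices into the post-discard epoch
#'   grid.
#' @export
epoch_and_reject <- function(rec, epoch_len_s = 2, reject_uv = 150,
                             n_keep = 10, discard_lead_s = 120) {
  L <- round(rec$fs * epoch_len_s)
  lead <- round(rec$fs * discard_lead_s)
  need <- lead + n_keep * L
  if (ncol(rec$data) < need) {
    nvf_stop("nvf_insufficient_data", "recording too short: ", ncol(rec$data),
             " samples < ", need, " required")
  }
  x <- rec$data[, (lead + 1):ncol(rec$data), drop = FALSE]
  n_ep <- floor(ncol(x) / L)
  kept <- integer(0)
  out <- array(0, dim = c(n_keep, nrow(x), L))
  for (e in seq_len(n_ep)) {
    seg <- x[, ((e - 1) * L + 1):(e * L), drop = FALSE]
    if (max(abs(seg)) > reject_uv) next
    kept <- c(kept, e - 1L)
    out[length(kept), , ] <- seg - rowMeans(seg)
    if (length(kept) == n_keep) break
  }
  if (length(kept) < n_keep) {
    nvf_stop("nvf_insufficient_data", "only ", length(kept),
             " clean epochs found; ", n_keep, " required")
  }
  epoched_data(out, fs = rec$fs, epoch_len_s = epoch_len_s, band = NULL,
               kept_epoch_indices = kept, channel_labels = rec$channel_labels)
}

#' Extract a predetermined set of epochs
#'
#' Cuts epochs at the indices previously selected by [epoch_and_reject()] on
#' the broadband signal, demeaning each.  Used to slice band-filtered
#' continuous data on the same epoch grid so that every band shares one set
#' of kept epochs.
#'
#' @param rec (band-filtered) recording at the epoching rate.
#' @param kept_epoch_indices 0-based epoch indices on the post-discard grid.
#' @param band `band_definition` tag for the result (or `NULL`).
#' @inheritParams epoch_and_reject
#' @return an `epoched_data`.
#' @export
epoch_extract <- function(rec, kept_epoch_indices, epoch_len_s = 2,
                          discard_lead_s = 120, band = NULL) {
  L <- round(rec$fs * epoch_len_s)
  lead <- round(rec$fs * discard_lead_s)
  n_keep <- length(kept_epoch_indices)
  out <- array(0, dim = c(n_keep, nrow(rec$data), L))
  for (k in seq_len(n_keep)) {
    e <- kept_epoch_indices[k]
    idx <- (lead + e * L + 1):(lead + (e + 1) * L)
    if (max(idx) > ncol(rec$data)) nvf_stop("nvf_insufficient_data",
                                            "epoch index beyond recording end")
    seg <- rec$data[, idx, drop = FALSE]
    out[k, , ] <- seg - rowMeans(seg)
  }
  epoched_data(out, fs = rec$fs, epoch_len_s = epoch_len_s, band = band,
               kept_epoch_indices = kept_epoch_indices,
               channel_labels = rec$channel_labels)
}

#' Epoched multichannel data
#' @param data epochs x channels x samples array (microvolts).
#' @param fs sampling rate.
#' @param epoch_len_s epoch length in seconds.
#' @param band `band_definition` or `NULL` for broadband.
#' @param kept_epoch_indices 0-based original indices of retained epochs.
#' @param channel_labels channel labels.
#' @export
epoched_data <- function(data, fs, epoch_len_s, band, kept_epoch_indices,
                         channel_labels) {
  stopifnot(length(dim(data)) == 3,
            dim(data)[3] == round(fs * epoch_len_s),
            dim(data)[2] == length(channel_labels))
  structure(list(data = data, fs = fs, epoch_len_s = epoch_len_s, band = band,
                 kept_epoch_indices = as.integer(kept_epoch_indices),
                 channel_labels = as.character(channel_labels)),
            class = "epoched_data")
}

#' @export
print.epoched_data <- function(x, ...) {
  cat(sprintf("<epoched_data> %d epochs x %d channels x %d samples @ %g Hz [%s]\n",
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3], x$fs,
              if (is.null(x$band)) "broadband" else x$band$name))
  invisible(x)
}

#' Band-filter already-epoched data
#'
#' Applies [bandpass_band()] to each epoch.  Rejection happens on the
#' broadband signal before this step, so all bands share one set of kept
#' epochs.
#' @param ep an `epoched_data`.
#' @param band a `band_definition`.
#' @export
filter_epochs <- function(ep, band) {
  sos <- butter_sos_bandpass(4, band$low_hz, band$high_hz, ep$fs)
  out <- ep
  for (e in seq_len(dim(ep$data)[1])) {
    out$data[e, , ] <- sos_filtfilt(sos, ep$data[e, , ])
  }
  out$band <- band
  out
}
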