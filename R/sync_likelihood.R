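#' Embedding parameters for synchronization likelihood
#'
#' Frequency-adaptive derivation of the five SL parameters from the band of
#' interest: embedding lag `tau = round(fs / (3 * high_hz))`, dimension
#' `m = round(3 * high_hz / low_hz) + 1`, Theiler window
#' `w1 = 2 * tau * (m - 1)`, outer window `w2 = w1 + round(n_rec / p_ref)`.
#' All five are overridable downstream.
#'
#' @param band a `band_definition`.
#' @param fs sampling rate in Hz.
#' @param p_ref reference recurrence probability (the estimator's floor under
#'   independence), default 0.05.
#' @param n_rec nominal number of recurrences sought per reference vector,
#'   default 10.
#' @return an `sl_params` object (fields `m`, `tau`, `w1`, `w2`, `p_ref`).
#' @export
derive_sl_params <- function(band, fs, p_ref = 0.05, n_rec = 10) {
  if (!(p_ref > 0 && p_ref < 1)) {
    nvf_stop("nvf_parameter_error", "p_ref must lie in (0, 1)")
  }
  tau <- max(1L, as.integer(round(fs / (3 * band$high_hz))))
  m <- max(2L, as.integer(round(3 * band$high_hz / band$low_hz)) + 1L)
  w1 <- 2L * tau * (m - 1L)
  w2 <- w1 + as.integer(round(n_rec / p_ref))
  sl_params(m = m, tau = tau, w1 = w1, w2 = w2, p_ref = p_ref)
}

#' @rdname derive_sl_params
#' @param m,tau,w1,w2 embedding dimension, lag, Theiler window and outer
#'   window, all in samples.
#' @export
sl_params <- function(m, tau, w1, w2, p_ref = 0.05) {
  if (m < 2 || tau < 1) nvf_stop("nvf_parameter_error", "need m >= 2, tau >= 1")
  if (w1 < 2 * tau * (m - 1)) {
    nvf_stop("nvf_parameter_error", "w1 must be >= 2*tau*(m-1) to exclude ",
             "autocorrelation-inflated recurrences")
  }
  if (w2 <= w1) nvf_stop("nvf_parameter_error", "w2 must exceed w1")
  if (!(p_ref > 0 && p_ref < 1)) nvf_stop("nvf_parameter_error", "p_ref must lie in (0, 1)")
  structure(list(m = as.integer(m), tau = as.integer(tau), w1 = as.integer(w1),
                 w2 = as.integer(w2), p_ref = p_ref),
            class = "sl_params")
}

# usable embedded vectors for a series of length n
sl_usable <- function(n, p) n - (p$m - 1L) * p$tau

sl_check_length <- function(n, p) {
  M <- sl_usable(n, p)
  if (M < 2 * (p$w2 + 1)) {
    nvf_stop("nvf_parameter_error", "series gives M = ", M,
             " embedded vectors < 2*(w2+1) = ", 2 * (p$w2 + 1),
             "; use longer epochs or mode = 'concatenate'")
  }
  invisible(M)
}

#' Synchronization likelihood between two series
#'
#' Delay-embeds both series and counts coincident recurrences: for each
#' reference vector the critical distance is the `p_ref` quantile of its
#' Euclidean distances to vectors inside the (Theiler-excluded) comparison
#' window, and SL is the normalized rate at which both channels recur
#' simultaneously.  Independent series give ~`p_ref`; identical (or affinely
#' related) series give ~1.
#'
#' @param x,y numeric series of equal length.
#' @param p an `sl_params`.
#' @return scalar SL value in `[0, ~1]`.
#' @export
sl_pair <- function(x, y, p) {
  if (length(x) != length(y)) nvf_stop("nvf_validation_error", "length mismatch")
  if (sd(x) == 0 || sd(y) == 0) {
    nvf_stop("nvf_undefined_distance", "constant series: all embedding distances 0")
  }
  sl_check_length(length(x), p)
  sl_matrix_cpp(rbind(x, y), p$m, p$tau, p$w1, p$w2, p$p_ref)[1, 2]
}

#' Whole-montage SL matrix
#'
#' @param ep band-filtered `epoched_data`.
#' @param p an `sl_params`.
#' @param mode `"per_epoch_mean"` computes SL per epoch and averages (each
#'   epoch must satisfy the window invariant); `"concatenate"` joins the kept
#'   epochs into one series first, which admits wider comparison windows than
#'   a single 2-s epoch allows.
#' @return a `connectivity_matrix` with `metric = "sl"`, diagonal 1.
#' @export
sl_matrix <- function(ep, p, mode = c("per_epoch_mean", "concatenate")) {
  mode <- match.arg(mode)
  n_ep <- dim(ep$data)[1]
  nch <- dim(ep$data)[2]
  sds <- apply(ep$data, 2, sd)
  if (any(sds == 0)) {
    nvf_stop("nvf_undefined_distance", "constant channel: ",
             paste(ep$channel_labels[sds == 0], collapse = ", "))
  }
  if (mode == "concatenate") {
    X <- matrix(aperm(ep$data, c(2, 3, 1)), nrow = nch)  # channels x (samples*epochs)
    sl_check_length(ncol(X), p)
    vals <- sl_matrix_cpp(X, p$m, p$tau, p$w1, p$w2, p$p_ref)
  } else {
    sl_check_length(dim(ep$data)[3], p)
    vals <- matrix(0, nch, nch)
    for (e in seq_len(n_ep)) {
      vals <- vals + sl_matrix_cpp(ep$data[e, , ], p$m, p$tau, p$w1, p$w2, p$p_ref)
    }
    vals <- vals / n_ep
  }
  connectivity_matrix(vals, metric = "sl", labels = ep$channel_labels,
                      band = if (is.null(ep$band)) NULL else ep$band$name)
}

#' Mean SL over all electrode pairs
#'
#' Global functional connectivity index: the mean of the strict upper
#' triangle of an SL matrix (diagonal excluded).
#' @param cm a `connectivity_matrix` with `metric = "sl"`.
#' @return scalar.
#' @export
mean_sl <- function(cm) {
  stopifnot(cm$metric == "sl")
  n <- nrow(cm$values)
  if (n < 2) nvf_stop("nvf_validation_error", "need >= 2 channels")
  mean(cm$values[upper.tri(cm$values)])
}
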