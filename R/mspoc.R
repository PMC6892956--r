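#' Aligned EEG band-power / fNIRS feature set
#'
#' One EEG channel covariance per 2-s epoch and one fNIRS sample (window
#' mean of the hemoglobin concentration per channel) per epoch, aligned
#' one-to-one.  `lag_epochs` shifts the hemodynamic stream relative to the
#' electrophysiological one in whole epochs to absorb neurovascular delay.
#'
#' @param eeg_epoch_covs list of symmetric PSD matrices, one per epoch.
#' @param fnirs_samples epochs x fNIRS-channels matrix.
#' @param epoch_len_s epoch length in seconds.
#' @param lag_epochs applied lag in epochs.
#' @param eeg_labels,fnirs_labels channel labels.
#' @export
feature_set <- function(eeg_epoch_covs, fnirs_samples, epoch_len_s, lag_epochs,
                        eeg_labels, fnirs_labels) {
  n <- length(eeg_epoch_covs)
  if (n != nrow(fnirs_samples)) {
    nvf_stop("nvf_validation_error", "EEG epoch count (", n,
             ") != fNIRS sample count (", nrow(fnirs_samples), ")")
  }
  mean_cov <- Reduce(`+`, eeg_epoch_covs) / n
  structure(list(eeg_epoch_covs = eeg_epoch_covs, mean_cov = mean_cov,
                 fnirs_samples = fnirs_samples, epoch_len_s = epoch_len_s,
                 n_epochs = n, lag_epochs = lag_epochs,
                 eeg_labels = eeg_labels, fnirs_labels = fnirs_labels),
            class = "feature_set")
}

#' Extract aligned fusion features
#'
#' EEG side: the channel covariance of each kept band-filtered 2-s epoch
#' (band power and its cross-channel structure).  fNIRS side: the 5-Hz
#' hemodynamic series averaged over the 2-s window that is `lag_epochs`
#' epochs behind the EEG epoch; the first `lag_epochs` EEG epochs are
#' dropped so counts match.
#'
#' @param ep band-filtered `epoched_data` (kept epochs, 256 Hz); the
#'   hemodynamic sample grid is assumed aligned with the epoch grid (sample
#'   1 of `h` simultaneous with epoch index 0).
#' @param h `hemodynamic_series` already resampled to the feature rate
#'   (5 Hz in the standard pipeline).
#' @param n_epochs number of aligned feature pairs to keep (default 10).
#' @param window_s feature window in seconds (default 2, the epoch length).
#' @param lag_epochs hemodynamic lag in whole epochs: the fNIRS window for
#'   epoch k sits `lag_epochs` epochs *after* k (default 0; 3 covers the
#'   canonical ~6-s response peak).
#' @param channels optional subset of fNIRS channel labels.
#' @param eeg_channels optional subset of EEG electrode labels.
#' @return a `feature_set`.
#' @export
extract_features <- function(ep, h, n_epochs = 10, window_s = 2, lag_epochs = 0,
                             channels = NULL, eeg_channels = NULL) {
  keep <- if (is.null(channels)) !(h$channel_labels %in% h$excluded_channels)
          else h$channel_labels %in% setdiff(channels, h$excluded_channels)
  hbo <- h$hbo[keep, , drop = FALSE]
  ekeep <- if (is.null(eeg_channels)) rep(TRUE, length(ep$channel_labels))
           else ep$channel_labels %in% eeg_channels
  if (nrow(hbo) < 1) {
    nvf_stop("nvf_insufficient_data", "no usable fNIRS channels after exclusions")
  }
  wlen <- round(h$fs * window_s)
  pos <- ep$kept_epoch_indices                  # 0-based grid positions
  n_avail_fn <- floor(ncol(hbo) / wlen)
  usable <- which((pos + lag_epochs + 1) <= n_avail_fn)
  if (length(usable) < n_epochs || dim(ep$data)[1] < n_epochs) {
    nvf_stop("nvf_insufficient_data", "need ", n_epochs, " aligned epochs, have ",
             min(length(usable), dim(ep$data)[1]))
  }
  covs <- vector("list", n_epochs)
  fn <- matrix(0, n_epochs, nrow(hbo))
  for (e in seq_len(n_epochs)) {
    k <- usable[e]
    seg <- ep$data[k, ekeep, , drop = TRUE]
    seg <- seg - rowMeans(seg)
    covs[[e]] <- tcrossprod(seg) / (ncol(seg) - 1)
    w0 <- (pos[k] + lag_epochs) * wlen          # fNIRS window lags epoch k
    fn[e, ] <- rowMeans(hbo[, (w0 + 1):(w0 + wlen), drop = FALSE])
  }
  feature_set(covs, fn, epoch_len_s = window_s, lag_epochs = lag_epochs,
              eeg_labels = ep$channel_labels[ekeep],
              fnirs_labels = h$channel_labels[keep])
}

zscore <- function(x) {
  s <- sd(x)
  if (s == 0) return(x - mean(x))
  (x - mean(x)) / s
}

# leading generalized eigenvector of (A, B), B symmetric positive definite:
# whiten with the Cholesky factor of B and take the top eigenvector.
lead_geneig <- function(A, B) {
  eps <- 1e-10 * mean(diag(B))
  R <- chol(B + diag(eps, nrow(B)))
  Aw <- backsolve(R, t(backsolve(R, t(A), transpose = TRUE)), transpose = TRUE)
  Aw <- (Aw + t(Aw)) / 2
  v <- eigen(Aw, symmetric = TRUE)$vectors[, 1]
  w <- backsolve(R, v)
  w / sqrt(drop(crossprod(w, B %*% w)))
}

mspoc_once <- function(covs, Y, mean_cov, w0, tol, max_iter, lambda_scale = 1e-6) {
  n <- length(covs)
  Yc <- scale(Y, scale = FALSE)
  Cyy <- crossprod(Yc) / (n - 1)
  lambda <- lambda_scale * mean(diag(Cyy))
  if (!is.finite(lambda) || lambda <= 0) lambda <- 1e-12
  Cyy_r <- Cyy + diag(lambda, ncol(Y))
  w_eeg <- w0 / sqrt(drop(crossprod(w0, mean_cov %*% w0)))
  r_prev <- -Inf; r <- -Inf; w_fn <- NULL
  trace_r <- numeric()
  for (it in seq_len(max_iter)) {
    phi <- vapply(covs, function(C) drop(crossprod(w_eeg, C %*% w_eeg)), 0)
    phi_z <- zscore(phi)
    cyx <- crossprod(Yc, phi_z) / (n - 1)
    w_fn <- drop(solve(Cyy_r, cyx))
    nrm <- sqrt(sum(w_fn^2))
    if (nrm == 0) break
    w_fn <- w_fn / nrm
    t_z <- zscore(drop(Yc %*% w_fn))
    A <- Reduce(`+`, Map(`*`, covs, t_z)) / n
    w_eeg <- lead_geneig(A, mean_cov)
    phi <- vapply(covs, function(C) drop(crossprod(w_eeg, C %*% w_eeg)), 0)
    r <- suppressWarnings(cor(phi, drop(Yc %*% w_fn)))
    if (!is.finite(r)) r <- 0
    trace_r <- c(trace_r, r)
    if (is.finite(r_prev) && abs(r - r_prev) < tol) {
      return(list(w_eeg = w_eeg, w_fnirs = w_fn, r = r, converged = TRUE,
                  iters = it, trace_r = trace_r))
    }
    r_prev <- r
  }
  list(w_eeg = w_eeg, w_fnirs = w_fn, r = r, converged = FALSE,
       iters = max_iter, trace_r = trace_r)
}

# Direct ascent on r over the EEG filter (the fNIRS filter has a closed
# form given phi), polishing the alternating fixed point: the eigenvector
# step maximizes a covariance surrogate, whose optimum can sit slightly
# below the correlation optimum.
mspoc_polish <- function(fit, covs, Y, mean_cov, tol) {
  Yc <- scale(Y, scale = FALSE)
  Cyy <- crossprod(Yc) / (nrow(Y) - 1)
  lambda <- 1e-6 * mean(diag(Cyy))
  if (!is.finite(lambda) || lambda <= 0) lambda <- 1e-12
  Cyy_r <- Cyy + diag(lambda, ncol(Y))
  objective <- function(we) {
    phi <- vapply(covs, function(C) drop(crossprod(we, C %*% we)), 0)
    if (sd(phi) == 0) return(0)
    wf <- drop(solve(Cyy_r, crossprod(Yc, zscore(phi)) / (nrow(Y) - 1)))
    t <- drop(Yc %*% wf)
    if (sd(t) == 0) return(0)
    -cor(phi, t)
  }
  opt <- tryCatch(
    stats::optim(fit$w_eeg, objective, method = "BFGS",
                 control = list(maxit = 60, reltol = tol)),
    error = function(e) NULL)
  if (is.null(opt) || -opt$value <= fit$r) return(fit)
  we <- opt$par / sqrt(drop(crossprod(opt$par, mean_cov %*% opt$par)))
  phi <- vapply(covs, function(C) drop(crossprod(we, C %*% we)), 0)
  wf <- drop(solve(Cyy_r, crossprod(Yc, zscore(phi)) / (nrow(Y) - 1)))
  wf <- wf / sqrt(sum(wf^2))
  fit$w_eeg <- we
  fit$w_fnirs <- wf
  fit$r <- cor(phi, drop(Yc %*% wf))
  fit$trace_r <- c(fit$trace_r, fit$r)
  fit
}

mspoc_best_of <- function(covs, Y, mean_cov, n_restarts, tol, max_iter,
                          polish = FALSE) {
  nch <- nrow(mean_cov)
  fits <- vector("list", n_restarts)
  for (s in seq_len(n_restarts)) {
    fits[[s]] <- mspoc_once(covs, Y, mean_cov, rnorm(nch), tol, max_iter)
  }
  ord <- order(vapply(fits, `[[`, TRUE, "converged"),
               vapply(fits, `[[`, 0, "r"), decreasing = TRUE)
  fits <- fits[ord]
  if (polish) {
    k <- min(3L, length(fits))
    cand <- fits[seq_len(k)]
    # also ascend from fresh random directions: the alternating map's
    # basin of attraction can miss the correlation optimum entirely
    for (s in seq_len(min(3L, n_restarts))) {
      seed_fit <- fits[[1]]
      seed_fit$w_eeg <- rnorm(nch)
      seed_fit$r <- -Inf
      cand[[length(cand) + 1L]] <- seed_fit
    }
    cand <- lapply(cand, mspoc_polish, covs = covs, Y = Y,
                   mean_cov = mean_cov, tol = tol)
    best <- cand[[which.max(vapply(cand, `[[`, 0, "r"))]]
    if (best$r > fits[[1]]$r) return(best)
  }
  fits[[1]]
}

#' Activation pattern of a spatial filter
#'
#' `a = C w / sqrt(w' C w)`: the forward projection of the extracted source
#' onto the sensors, the physiologically interpretable counterpart of the
#' filter.  The square-root normalization makes the pattern invariant to
#' rescaling of `w` (for a filter normalized to unit source variance the
#' two conventions coincide).  Sign-fixed so the largest-magnitude entry is
#' positive.
#'
#' @param w spatial filter.
#' @param covariance sensor covariance (PSD).
#' @return pattern vector, same length as `w`.
#' @export
activation_pattern <- function(w, covariance) {
  q <- drop(crossprod(w, covariance %*% w))
  if (!is.finite(q) || q <= 0) {
    nvf_stop("nvf_validation_error", "degenerate normalization w'Cw <= 0")
  }
  a <- drop(covariance %*% w) / sqrt(q)
  if (a[which.max(abs(a))] < 0) a <- -a
  a
}

#' Fit multimodal source power comodulation (mSPoC)
#'
#' Alternating optimization of a spatial-filter pair: (i) the EEG filter's
#' per-epoch band power phi(e) = w' C_e w; (ii) the fNIRS filter as
#' regularized regression of the hemodynamic samples onto phi; (iii) the EEG
#' filter as the leading generalized eigenvector of (sum_e t(e) C_e,
#' mean covariance) given the hemodynamic target t.  The comodulation
#' correlation r = cor(phi, t) is non-decreasing across iterations up to
#' `tol`.  The best of `n_restarts` random initializations is kept.
#' Significance: the epoch pairing is circularly shifted `B_perm` times and
#' the full fit repeated, giving a null distribution of r.
#'
#' @param fs a `feature_set`.
#' @param n_components number of deflated components (default 1).
#' @param n_restarts random initializations per fit (default 20).
#' @param tol convergence tolerance on |delta r| (default 1e-6).
#' @param max_iter iteration cap per restart (default 200).
#' @param B_perm permutations for the null (default 1000; 0 skips).
#' @param perm_restarts restarts used inside each permutation refit
#'   (default `n_restarts`).
#' @param min_shift_s smallest admissible circular shift in seconds
#'   (default 20, about twice the hemodynamic response span): smaller
#'   shifts leave genuine coupling aligned through the autocorrelation of
#'   the slow hemodynamics and would leak it into the null.  Capped at a
#'   third of the record so short feature sets keep admissible shifts.
#' @param polish refine the best restarts by direct ascent on r (the
#'   alternating iteration optimizes a covariance surrogate whose optimum
#'   can sit slightly below the correlation optimum).  Applied identically
#'   inside permutation refits, so the null stays exchangeable with the
#'   observed fit; off by default because it multiplies the cost of
#'   permutation runs.
#' @param seed RNG seed.
#' @return list of `fusion_result` (length `n_components`).
#' @export
mspoc_fit <- function(fs, n_components = 1, n_restarts = 20, tol = 1e-6,
                      max_iter = 200, B_perm = 1000, perm_restarts = n_restarts,
                      min_shift_s = 20, polish = FALSE, seed = 1) {
  if (fs$n_epochs < 5) nvf_stop("nvf_validation_error", "need >= 5 epochs")
  covs <- fs$eeg_epoch_covs
  Y <- fs$fnirs_samples
  old <- get0(".Random.seed", globalenv())
  set.seed(seed)
  results <- vector("list", n_components)
  for (comp in seq_len(n_components)) {
    mean_cov <- Reduce(`+`, covs) / length(covs)
    fit <- mspoc_best_of(covs, Y, mean_cov, n_restarts, tol, max_iter,
                         polish = polish)
    if (!fit$converged) warning("no restart converged; returning best effort")
    a_eeg <- activation_pattern(fit$w_eeg, mean_cov)
    Yc <- scale(Y, scale = FALSE)
    Cyy <- crossprod(Yc) / (nrow(Y) - 1)
    a_fn <- activation_pattern(fit$w_fnirs, Cyy)

    null_r <- numeric(0); p_value <- NA_real_
    if (B_perm > 0) {
      n <- length(covs)
      min_shift <- max(1, ceiling(min_shift_s / fs$epoch_len_s))
      min_shift <- min(min_shift, max(1, floor((n - 1) / 3)))
      shifts <- sample(seq(min_shift, n - min_shift), B_perm, replace = TRUE)
      null_r <- vapply(shifts, function(s) {
        Yp <- Y[c((s + 1):n, seq_len(s)), , drop = FALSE]
        mspoc_best_of(covs, Yp, mean_cov, perm_restarts, tol, max_iter,
                      polish = polish)$r
      }, 0)
      p_value <- perm_p_value(fit$r, null_r, "greater")
    }
    results[[comp]] <- structure(
      list(w_eeg = fit$w_eeg, w_fnirs = fit$w_fnirs, a_eeg = a_eeg,
           a_fnirs = a_fn, r = fit$r, null_r = null_r, p_value = p_value,
           n_restarts_used = n_restarts, converged = fit$converged,
           component_index = comp, trace_r = fit$trace_r,
           eeg_labels = fs$eeg_labels, fnirs_labels = fs$fnirs_labels),
      class = "fusion_result")

    if (comp < n_components) {
      # deflate: project sensor spaces onto the complements of the patterns
      P_e <- diag(length(a_eeg)) - tcrossprod(a_eeg) / sum(a_eeg^2)
      covs <- lapply(covs, function(C) P_e %*% C %*% t(P_e))
      P_f <- diag(length(a_fn)) - tcrossprod(a_fn) / sum(a_fn^2)
      Y <- Y %*% t(P_f)
    }
  }
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  results
}

#' @export
print.fusion_result <- function(x, ...) {
  cat(sprintf("<fusion_result> component %d: r = %.3f%s%s\n", x$component_index,
              x$r, if (is.na(x$p_value)) "" else sprintf(", p = %.4g", x$p_value),
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' Group-level fusion summary over a cohort
#'
#' Fits mSPoC per subject on the electrodes/channels of one ROI (or the
#' whole PFC) and summarizes: mean comodulation r, its standard error, and
#' the sign-aligned average activation patterns.  ROIs with fewer than two
#' electrodes or two channels are skipped with a warning.
#'
#' @param subject_features list of `feature_set`, one per subject (already
#'   restricted to the ROI).
#' @param roi label for the summary row.
#' @param ... passed to [mspoc_fit()].
#' @return list with `roi`, `n`, `mean_r`, `sem_r`, per-subject `r` and
#'   `p_value`, and averaged patterns.
#' @export
fuse_group <- function(subject_features, roi = "whole_pfc", ...) {
  fs1 <- subject_features[[1]]
  if (length(fs1$eeg_labels) < 2 || length(fs1$fnirs_labels) < 2) {
    warning("ROI '", roi, "' has < 2 electrodes or < 2 channels; skipped")
    return(NULL)
  }
  fits <- lapply(subject_features, function(fs) mspoc_fit(fs, ...)[[1]])
  rs <- vapply(fits, `[[`, 0, "r")
  ps <- vapply(fits, function(f) if (is.na(f$p_value)) NA_real_ else f$p_value, 0)
  ref_e <- fits[[1]]$a_eeg; ref_f <- fits[[1]]$a_fnirs
  avg_e <- Reduce(`+`, lapply(fits, function(f) f$a_eeg * sign(sum(f$a_eeg * ref_e)))) /
    length(fits)
  avg_f <- Reduce(`+`, lapply(fits, function(f) f$a_fnirs * sign(sum(f$a_fnirs * ref_f)))) /
    length(fits)
  list(roi = roi, n = length(fits), mean_r = mean(rs),
       sem_r = sd(rs) / sqrt(length(rs)), r = rs, p_value = ps,
       mean_a_eeg = avg_e, mean_a_fnirs = avg_f, fits = fits)
}
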