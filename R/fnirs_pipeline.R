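#' Modified Beer-Lambert coefficients
#'
#' Molar extinction coefficients of HbO and Hb at 690 and 830 nm (a standard
#' compiled table, base-10, scaled to 1/(uM*cm)), differential pathlength
#' factor and source-detector separation.  Absolute micromolar scales depend
#' on this table and on the DPF; every downstream correlation is invariant
#' to that overall scale.
#'
#' @param extinction 2x2 matrix, rows = wavelengths (690, 830 nm), columns =
#'   chromophores (HbO, Hb), units 1/(uM*cm).
#' @param dpf differential pathlength factor, one value per wavelength
#'   (dimensionless, default 6 at both).
#' @param distance_cm source-detector separation in cm (default 3).
#' @export
mbll_coefficients <- function(extinction = default_extinction(),
                              dpf = c(6, 6), distance_cm = 3) {
  extinction <- as.matrix(extinction)
  stopifnot(all(dim(extinction) == c(2, 2)))
  if (any(dpf <= 0) || distance_cm <= 0) {
    nvf_stop("nvf_configuration_error", "dpf and distance_cm must be positive")
  }
  if (kappa(extinction, exact = TRUE) >= 100) {
    nvf_stop("nvf_configuration_error",
             "extinction matrix ill-conditioned; wavelengths not separable")
  }
  structure(list(extinction = extinction, dpf = as.numeric(dpf),
                 distance_cm = distance_cm, wavelengths = c(690, 830)),
            class = "mbll_coefficients")
}

# Compiled molar extinction values at 690/830 nm in 1/(uM*cm):
# Hb dominates absorption at 690 nm, HbO at 830 nm.
default_extinction <- function() {
  matrix(c(2.7600e-4, 2.0520e-3,    # 690 nm: HbO, Hb
           9.7400e-4, 6.9304e-4),   # 830 nm: HbO, Hb
         nrow = 2, byrow = TRUE,
         dimnames = list(c("690", "830"), c("hbo", "hb")))
}

#' Per-channel hemodynamic concentration series
#' @param hbo,hb channels x samples matrices of concentration change in uM.
#' @param fs sampling rate in Hz.
#' @param channel_labels channel labels.
#' @param excluded_channels labels flagged for exclusion.
#' @param exclusion_reasons named character vector of reasons.
#' @export
hemodynamic_series <- function(hbo, hb, fs, channel_labels,
                               excluded_channels = character(),
                               exclusion_reasons = character()) {
  stopifnot(all(dim(hbo) == dim(hb)), nrow(hbo) == length(channel_labels))
  if (!all(is.finite(hbo)) || !all(is.finite(hb))) {
    nvf_stop("nvf_validation_error", "non-finite concentration values")
  }
  if (!all(excluded_channels %in% channel_labels)) {
    nvf_stop("nvf_validation_error", "excluded channel not among labels")
  }
  structure(list(hbo = hbo, hb = hb, fs = fs,
                 channel_labels = as.character(channel_labels),
                 excluded_channels = as.character(excluded_channels),
                 exclusion_reasons = exclusion_reasons),
            class = "hemodynamic_series")
}

#' @export
print.hemodynamic_series <- function(x, ...) {
  cat(sprintf("<hemodynamic_series> %d channels x %d samples @ %g Hz (%d excluded)\n",
              nrow(x$hbo), ncol(x$hbo), x$fs, length(x$excluded_channels)))
  invisible(x)
}

od_channel_names <- function(labels) {
  m <- regmatches(labels, regexec("^(.*)@(690|830)$", labels))
  list(chan = vapply(m, `[`, "", 2), wl = vapply(m, `[`, "", 3))
}

#' Convert optical density to hemoglobin concentration changes
#'
#' Solves, per channel and time point, the 2x2 modified Beer-Lambert system
#' `dOD(lambda) = (eps_HbO(lambda) dHbO + eps_Hb(lambda) dHb) * d * DPF(lambda)`
#' for the concentration changes in uM.
#'
#' @param od a `modality = "fnirs_od"` recording with `<chan>@690` /
#'   `<chan>@830` rows.
#' @param coeffs an `mbll_coefficients`.
#' @return a `hemodynamic_series`.
#' @export
mbll_invert <- function(od, coeffs = mbll_coefficients()) {
  stopifnot(od$modality == "fnirs_od")
  parts <- od_channel_names(od$channel_labels)
  if (any(is.na(parts$chan)) || any(parts$chan == "")) {
    nvf_stop("nvf_configuration_error",
             "fNIRS rows must be named <chan>@690 / <chan>@830")
  }
  if (!setequal(unique(parts$wl), c("690", "830"))) {
    nvf_stop("nvf_configuration_error", "wavelengths must be exactly 690 and 830 nm")
  }
  channels <- unique(parts$chan)
  # pathlength-scaled forward matrix: OD = A %*% c(hbo, hb)
  A <- coeffs$extinction * coeffs$distance_cm * coeffs$dpf
  Ainv <- solve(A)
  hbo <- matrix(0, length(channels), ncol(od$data))
  hb <- matrix(0, length(channels), ncol(od$data))
  for (ci in seq_along(channels)) {
    i690 <- which(parts$chan == channels[ci] & parts$wl == "690")
    i830 <- which(parts$chan == channels[ci] & parts$wl == "830")
    if (length(i690) != 1 || length(i830) != 1) {
      nvf_stop("nvf_format_error", "channel '", channels[ci],
               "' lacks a wavelength pair")
    }
    conc <- Ainv %*% od$data[c(i690, i830), , drop = FALSE]
    hbo[ci, ] <- conc[1, ]
    hb[ci, ] <- conc[2, ]
  }
  hemodynamic_series(hbo, hb, fs = od$fs, channel_labels = channels)
}

#' Detrend and band-pass the hemodynamic series
#'
#' Per channel and chromophore: removes a least-squares linear trend, then
#' applies a zero-phase 3rd-order Butterworth band-pass (default
#' 0.01-0.1 Hz, the resting-state hemodynamic band).  Series shorter than
#' three time constants of the high-pass edge trigger a warning and an
#' automatic relaxation of that edge.
#'
#' @param h a `hemodynamic_series`.
#' @param low,high band edges in Hz.
#' @param order filter order.
#' @return filtered `hemodynamic_series`.
#' @export
filter_detrend <- function(h, low = 0.01, high = 0.1, order = 3) {
  if (high >= h$fs / 2) nvf_stop("nvf_parameter_error", "high edge >= Nyquist")
  dur <- ncol(h$hbo) / h$fs
  if (dur < 3 / low) {
    low_new <- 3 / dur
    warning(sprintf(
      "series (%.0f s) shorter than 3 high-pass time constants; relaxing %g -> %.4g Hz",
      dur, low, low_new))
    low <- low_new
  }
  sos <- butter_sos_bandpass(order, low, high, h$fs)
  detrend_bp <- function(x) {
    n <- length(x)
    t <- seq_len(n)
    fit <- stats::lm.fit(cbind(1, t), x)
    sos_filtfilt(sos, fit$residuals)
  }
  out <- h
  out$hbo <- t(apply(h$hbo, 1, detrend_bp))
  out$hb <- t(apply(h$hb, 1, detrend_bp))
  out
}

moving_sd <- function(x, w) {
  # centered moving SD via cumulative sums; window truncated at the edges
  n <- length(x)
  cs <- cumsum(c(0, x)); cs2 <- cumsum(c(0, x^2))
  half <- floor(w / 2)
  lo <- pmax(seq_len(n) - half, 1)
  hi <- pmin(seq_len(n) + half, n)
  cnt <- hi - lo + 1
  s <- cs[hi + 1] - cs[lo]
  s2 <- cs2[hi + 1] - cs2[lo]
  v <- (s2 - s^2 / cnt) / pmax(cnt - 1, 1)
  sqrt(pmax(v, 0))
}

moving_mean <- function(x, w) {
  n <- length(x)
  cs <- cumsum(c(0, x))
  half <- floor(w / 2)
  lo <- pmax(seq_len(n) - half, 1)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Spline-interpolation motion correction
#'
#' Detects motion segments as samples whose moving standard deviation (in
#' `window_s` windows, computed on the sample-to-sample differences so that
#' smooth hemodynamic excursions are not mistaken for artifacts) exceeds
#' `sigma_mult` times the median moving SD; gaps shorter than 0.5 s between
#' segments are merged.  Each artifact
#' segment is modelled by a smoothing spline (parameter `smooth`, csaps
#' convention: values near 1 follow the data) which is subtracted, and the
#' corrected segment is re-levelled so that its mean matches the 1-s
#' neighborhoods on both sides.  A channel whose artifact fraction exceeds
#' 50% is flagged for exclusion instead of corrected.
#'
#' @param h a `hemodynamic_series`.
#' @param window_s moving-SD window in seconds (default 2).
#' @param sigma_mult threshold multiplier on the median moving SD (default 3).
#' @param smooth spline smoothing parameter in (0, 1) (default 0.99).
#' @return corrected `hemodynamic_series`.
#' @export
spline_motion_correct <- function(h, window_s = 2, sigma_mult = 3, smooth = 0.99) {
  w <- round(h$fs * window_s)
  if (w < 4) nvf_stop("nvf_parameter_error", "window too short: fs*window_s < 4 samples")
  merge_gap <- round(0.5 * h$fs)
  nbh <- round(1 * h$fs)
  out <- h
  flagged <- character()
  for (ci in seq_len(nrow(h$hbo))) {
    for (chrom in c("hbo", "hb")) {
      x <- out[[chrom]][ci, ]
      dx <- c(0, diff(x))
      msd <- moving_sd(dx, w)
      # threshold floored at the global diff SD: motion spikes dwarf it,
      # smooth physiological excursions do not
      thr <- sigma_mult * max(median(msd), sd(dx))
      bad <- if (thr > 0) msd > thr else rep(FALSE, length(x))
      if (!any(bad)) next
      # dilate by half a window so both edges of a step artifact join into
      # one segment spanning its plateau
      half <- floor(w / 2)
      ext <- stats::filter(as.numeric(bad), rep(1, 2 * half + 1), sides = 2)
      ext[is.na(ext)] <- as.numeric(bad)[is.na(ext)]
      bad <- as.vector(ext > 0)
      segs <- bad_segments(bad, merge_gap)
      if (sum(segs$len) > 0.5 * length(x)) {
        flagged <- c(flagged, h$channel_labels[ci])
        reason <- paste0("motion artifact fraction > 50% (", chrom, ")")
        out$exclusion_reasons[h$channel_labels[ci]] <- reason
        next
      }
      for (s in seq_len(nrow(segs))) {
        idx <- segs$from[s]:segs$to[s]
        if (length(idx) >= 4) {
          fit <- smooth.spline(idx, x[idx], spar = max(1 - smooth, 1e-3),
                               all.knots = TRUE)
          x[idx] <- x[idx] - predict(fit, idx)$y
        } else {
          x[idx] <- x[idx] - mean(x[idx])
        }
        # re-level along a ramp between the 1-s flank means, so the local
        # hemodynamic trend is preserved to first order
        left <- max(1, segs$from[s] - nbh):max(1, segs$from[s] - 1)
        right <- min(length(x), segs$to[s] + 1):min(length(x), segs$to[s] + nbh)
        ramp <- seq(mean(x[left]), mean(x[right]), length.out = length(idx))
        x[idx] <- x[idx] - mean(x[idx]) + ramp
      }
      out[[chrom]][ci, ] <- x
    }
  }
  out$excluded_channels <- union(out$excluded_channels, flagged)
  out
}

bad_segments <- function(bad, merge_gap) {
  r <- rle(bad)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  segs <- data.frame(from = starts[r$values], to = ends[r$values])
  if (nrow(segs) > 1) {
    keep <- list(segs[1, ])
    for (s in 2:nrow(segs)) {
      last <- keep[[length(keep)]]
      if (segs$from[s] - last$to - 1 < merge_gap) {
        keep[[length(keep)]]$to <- segs$to[s]
      } else {
        keep[[length(keep) + 1]] <- segs[s, ]
      }
    }
    segs <- do.call(rbind, keep)
  }
  segs$len <- segs$to - segs$from + 1
  segs
}

#' Flag channels with low signal-to-noise ratio
#'
#' A channel is flagged when, in either chromophore, its 1-s moving average
#' deviates from the channel mean by more than `sd_mult` channel standard
#' deviations for a run of at least `min_run_s` seconds -- a sustained
#' excursion no hemodynamic signal produces.
#'
#' @param h a `hemodynamic_series`.
#' @param sd_mult deviation threshold in channel SDs (default 5).
#' @param min_run_s minimum run length in seconds (default 1).
#' @return `h` with `excluded_channels`/`exclusion_reasons` updated.
#' @export
flag_low_snr <- function(h, sd_mult = 5, min_run_s = 1) {
  w <- max(2, round(h$fs * 1))
  min_run <- round(h$fs * min_run_s)
  out <- h
  for (ci in seq_len(nrow(h$hbo))) {
    for (chrom in c("hbo", "hb")) {
      x <- h[[chrom]][ci, ]
      dev <- abs(moving_mean(x, w) - mean(x)) > sd_mult * sd(x)
      r <- rle(dev)
      if (any(r$values & r$lengths >= min_run)) {
        lab <- h$channel_labels[ci]
        out$excluded_channels <- union(out$excluded_channels, lab)
        out$exclusion_reasons[lab] <- paste0(
          "low SNR: ", chrom, " moving average beyond ", sd_mult, " SD for >= ",
          min_run_s, " s")
      }
    }
  }
  out
}

#' Full fNIRS cleaning chain
#'
#' Conversion (MBLL) -> detrend + band-pass -> motion correction -> SNR
#' screening, in that order.  `strict_order = TRUE` applies the band-pass
#' before the detrend inside the filtering stage instead (the printed
#' pipeline order); the default folds the linear detrend first, which is
#' numerically safer ahead of a 0.01 Hz high-pass edge.
#'
#' @param od optical-density recording.
#' @param coeffs `mbll_coefficients`.
#' @param low,high band edges in Hz.
#' @param strict_order see description.
#' @return a cleaned `hemodynamic_series`.
#' @export
fnirs_preprocess <- function(od, coeffs = mbll_coefficients(), low = 0.01,
                             high = 0.1, strict_order = FALSE) {
  h <- mbll_invert(od, coeffs)
  if (strict_order) {
    sos <- butter_sos_bandpass(3, low, high, h$fs)
    h$hbo <- sos_filtfilt(sos, h$hbo)
    h$hb <- sos_filtfilt(sos, h$hb)
    detr <- function(x) stats::lm.fit(cbind(1, seq_along(x)), x)$residuals
    h$hbo <- t(apply(h$hbo, 1, detr))
    h$hb <- t(apply(h$hb, 1, detr))
  } else {
    h <- filter_detrend(h, low = low, high = high)
  }
  h <- spline_motion_correct(h)
  flag_low_snr(h)
}
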