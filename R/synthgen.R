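#' Simulation parameters for a bimodal cohort
#'
#' Defaults emulate the acquisition regime of the target study design:
#' 64 scalp electrodes + 2 EOG channels at 256 Hz (a 2048 Hz preset
#' exercises the decimation path), 14 prefrontal fNIRS channels at 50 Hz,
#' 11-minute (660 s) eyes-closed records; `duration_s = 180` is the test
#' preset (still covering the 120-s lead-in discard plus the 20-s analysis
#' window).
#'
#' @param n_eeg,n_eog,n_fnirs channel counts.
#' @param fs_eeg EEG rate (256 or 2048 Hz).
#' @param fs_fnirs fNIRS rate in Hz.
#' @param duration_s record length in seconds (>= 150).
#' @param band `band_definition` of the planted oscillatory sources.
#' @param sync_kappa common-source mixing weight for synchronized electrode
#'   communities, in [0, 1].
#' @param coupling_beta signed scale of the envelope-to-HbO drive.
#' @param noise_mix fraction of background (1/f + sensor) noise mixed into
#'   both modalities, in [0, 1].
#' @param hrf list `(peak_s, undershoot_s, ratio)` of the double-gamma
#'   hemodynamic response.
#' @param hb_ratio Hb/HbO amplitude ratio (negative: deoxygenation mirrors
#'   oxygenation).
#' @param blinks,motion_spikes artifact flags.
#' @param group_effect multiplicative factors applied to group B
#'   (`kappa_factor`, `beta_factor`); the default is the patient-like
#'   desynchronized, hypo-coupled preset.
#' @param envelope_band_hz frequency band of the log-envelope fluctuations
#'   in Hz; resting band power is modulated infra-slowly, inside the
#'   hemodynamic analysis band (default c(0.02, 0.1)).
#' @param sync_sets optional explicit synchronization communities: a list of
#'   `list(members = <electrode indices>, kappa = <scalar or per-member>)`.
#'   `NULL` plants one frontal community (first quarter of the electrodes,
#'   which also drives the hemodynamics) and one posterior community (last
#'   fifth).
#' @param eeg_rms_uv target per-channel EEG RMS in microvolts.
#' @export
sim_params <- function(n_eeg = 64, n_eog = 2, n_fnirs = 14, fs_eeg = 256,
                       fs_fnirs = 50, duration_s = 660,
                       band = eeg_bands("lower_alpha"), sync_kappa = 0.6,
                       coupling_beta = 1, noise_mix = 0.5,
                       hrf = list(peak_s = 6, undershoot_s = 16, ratio = 1 / 6),
                       hb_ratio = -0.3, blinks = FALSE, motion_spikes = FALSE,
                       group_effect = list(kappa_factor = 0.6, beta_factor = 0.5),
                       envelope_band_hz = c(0.02, 0.1), sync_sets = NULL,
                       eeg_rms_uv = 20) {
  if (!fs_eeg %in% c(256, 2048)) nvf_stop("nvf_parameter_error", "fs_eeg must be 256 or 2048")
  if (duration_s < 150) {
    nvf_stop("nvf_parameter_error",
             "duration_s must be >= 150 (120-s discard + 20-s analysis window)")
  }
  if (sync_kappa < 0 || sync_kappa > 1 || noise_mix < 0 || noise_mix > 1) {
    nvf_stop("nvf_parameter_error", "sync_kappa and noise_mix must lie in [0, 1]")
  }
  if (n_eeg < 4 || n_fnirs < 2 || n_eog < 0 || fs_fnirs <= 0) {
    nvf_stop("nvf_parameter_error", "invalid channel counts or rates")
  }
  structure(list(n_eeg = n_eeg, n_eog = n_eog, n_fnirs = n_fnirs,
                 fs_eeg = fs_eeg, fs_fnirs = fs_fnirs, duration_s = duration_s,
                 band = band, sync_kappa = sync_kappa,
                 coupling_beta = coupling_beta, noise_mix = noise_mix,
                 hrf = hrf, hb_ratio = hb_ratio, blinks = blinks,
                 motion_spikes = motion_spikes, group_effect = group_effect,
                 envelope_band_hz = envelope_band_hz, sync_sets = sync_sets,
                 eeg_rms_uv = eeg_rms_uv),
            class = "sim_params")
}

#' Double-gamma hemodynamic response kernel
#'
#' Difference of two gamma densities (shape `peak_s + 1` / `undershoot_s + 1`,
#' rate 1), scaled to unit peak; 32 s long, sampled at the fNIRS rate.
#' `kernel[t = 0] = 0`, peak at `peak_s`, negative undershoot bounded by
#' `ratio` x peak.
#'
#' @param p a `sim_params` (uses `hrf` and `fs_fnirs`).
#' @return numeric kernel vector.
#' @export
hrf_kernel <- function(p) {
  t <- seq(0, 32, by = 1 / p$fs_fnirs)
  h <- stats::dgamma(t, shape = p$hrf$peak_s + 1, rate = 1) -
    p$hrf$ratio * stats::dgamma(t, shape = p$hrf$undershoot_s + 1, rate = 1)
  h / max(h)
}

# 1/f (power slope -1) noise via spectral shaping, unit SD
pink_noise <- function(n) {
  nf <- floor(n / 2)
  f <- c(1, seq_len(nf), rev(seq_len(n - nf - 1)))
  x <- Re(fft(fft(rnorm(n)) / sqrt(f), inverse = TRUE)) / n
  x / sd(x)
}

# positive log-normal envelope whose log fluctuates in the infra-slow band
# (resting band power is modulated at 0.01-0.1 Hz, the same band the
# hemodynamic analysis reads out)
source_envelope <- function(n, fs, band_hz = c(0.02, 0.1)) {
  fs_lo <- 10
  n_lo <- ceiling(n * fs_lo / fs) + 2 * fs_lo
  sos <- butter_sos_bandpass(2, band_hz[1], band_hz[2], fs_lo)
  z <- sos_filtfilt(sos, rnorm(n_lo))
  z <- (z - mean(z)) / max(sd(z), 1e-12)
  # soft-bounded log-normal modulation: power waxes and wanes ~7-fold
  # between quiet stretches and bursts without pathological extremes
  env_lo <- exp(2 * tanh(z / 2) * 0.5)
  t_lo <- (seq_along(env_lo) - 1) / fs_lo
  approx(t_lo, env_lo, xout = (seq_len(n) - 1) / fs, rule = 2)$y
}

# band-limited Gaussian noise via spectral shaping with the analytic
# Butterworth band-pass magnitude (order 4) -- equivalent in spectrum to
# filtering white noise, at FFT cost
band_noise_source <- function(n, fs, band) {
  f <- c(0, seq_len(n - 1)) * fs / n
  f <- pmin(f, fs - f)                      # two-sided frequency axis
  w <- 2 * pi * pmax(f, 1e-9)
  w0sq <- (2 * pi)^2 * band$low_hz * band$high_hz
  bw <- 2 * pi * (band$high_hz - band$low_hz)
  H <- 1 / sqrt(1 + ((w^2 - w0sq) / (bw * w))^8)
  x <- Re(fft(fft(rnorm(n)) * H, inverse = TRUE)) / n
  x / sd(x)
}

default_sync_sets <- function(p) {
  n1 <- max(2, round(0.35 * p$n_eeg))
  n2 <- max(2, round(0.30 * p$n_eeg))
  list(list(members = seq_len(n1), kappa = p$sync_kappa),
       list(members = (p$n_eeg - n2 + 1):p$n_eeg, kappa = p$sync_kappa))
}

# standard 64-electrode labels, front to back (10-10 system); generic labels
# otherwise
eeg_labels_for <- function(n) {
  if (n == 64) {
    c("Fp1", "Fpz", "Fp2", "AF7", "AF3", "AFz", "AF4", "AF8",
      "F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8",
      "FT7", "FC5", "FC3", "FC1", "FCz", "FC2", "FC4", "FC6", "FT8",
      "T7", "C5", "C3", "C1", "Cz", "C2", "C4", "C6", "T8",
      "TP7", "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6", "TP8",
      "P9", "P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8", "P10",
      "PO7", "PO3", "POz", "PO4", "PO8", "O1", "Oz", "O2", "Iz")
  } else sprintf("E%02d", seq_len(n))
}

#' Generate one synthetic bimodal subject
#'
#' Band-limited oscillatory sources with smoothed positive random-walk
#' envelopes; electrodes inside a synchronization community mix the shared
#' community source (weight kappa) with a private source (weight 1 - kappa);
#' 1/f background and white sensor noise are added and channels scaled to
#' the target RMS.  Hemodynamics: the frontal community's envelope,
#' HRF-convolved, drives Delta-HbO over a positive spatial pattern scaled by
#' `coupling_beta`, with pink noise mixed in; Delta-Hb mirrors HbO by
#' `hb_ratio`; optical density is emitted through the forward modified
#' Beer-Lambert operator.  Optional blink transients (frontal + EOG) and
#' fNIRS motion spikes.
#'
#' @param p a `sim_params`.
#' @param subject_seed integer seed; identical seeds give bit-identical
#'   subjects.
#' @return list with `eeg`, `eog`, `fnirs_od` (`ts_recording`s) and `truth`
#'   (a `ground_truth` list).
#' @export
generate_subject <- function(p, subject_seed) {
  old <- get0(".Random.seed", globalenv())
  set.seed(subject_seed)
  fs <- p$fs_eeg
  n <- round(p$duration_s * fs)
  n50 <- round(p$duration_s * p$fs_fnirs)
  sets <- if (is.null(p$sync_sets)) default_sync_sets(p) else p$sync_sets

  # shared community sources (carrier x envelope), envelopes kept
  shared <- vector("list", length(sets))
  for (s in seq_along(sets)) {
    env <- source_envelope(n, fs, p$envelope_band_hz)
    shared[[s]] <- list(env = env, sig = band_noise_source(n, fs, p$band) * env)
  }

  kappa_of <- rep(0, p$n_eeg)
  set_of <- rep(NA_integer_, p$n_eeg)
  for (s in seq_along(sets)) {
    kap <- rep(sets[[s]]$kappa, length.out = length(sets[[s]]$members))
    kappa_of[sets[[s]]$members] <- kap
    set_of[sets[[s]]$members] <- s
  }

  eeg <- matrix(0, p$n_eeg, n)
  for (e in seq_len(p$n_eeg)) {
    priv <- band_noise_source(n, fs, p$band) * source_envelope(n, fs, p$envelope_band_hz)
    osc <- if (is.na(set_of[e])) priv else
      kappa_of[e] * shared[[set_of[e]]]$sig + (1 - kappa_of[e]) * priv
    bg <- 0.8 * pink_noise(n) + 0.2 * rnorm(n)
    x <- (1 - p$noise_mix) * osc + p$noise_mix * bg
    eeg[e, ] <- x / sd(x) * p$eeg_rms_uv
  }

  eog <- matrix(0, max(p$n_eog, 0), n)
  if (p$n_eog > 0) {
    for (e in seq_len(p$n_eog)) {
      eog[e, ] <- 30 * pink_noise(n) + 5 * rnorm(n)
    }
  }

  blink_times <- numeric(0)
  if (p$blinks && p$n_eog > 0) {
    blink_times <- sort(runif(max(1, round(p$duration_s / 5)), 1, p$duration_s - 1))
    bl_len <- round(0.3 * fs)                      # 300-ms biphasic transient
    tt <- seq_len(bl_len) / bl_len
    wave <- sin(2 * pi * tt) * exp(-3 * tt)
    wave <- wave / max(abs(wave)) * 100            # 100-uV leading lobe
    frontal <- seq_len(min(8, p$n_eeg))
    leak <- seq(1, 0.3, length.out = length(frontal))
    for (bt in blink_times) {
      idx <- round(bt * fs) + seq_len(bl_len)
      idx <- idx[idx <= n]
      for (fi in seq_along(frontal)) {
        eeg[frontal[fi], idx] <- eeg[frontal[fi], idx] + leak[fi] * wave[seq_along(idx)]
      }
      eog[, idx] <- sweep(eog[, idx, drop = FALSE], 2, 2 * wave[seq_along(idx)], "+")
    }
  }

  # hemodynamics driven by the instantaneous band power of community 1's
  # shared source (neurovascular coupling follows actual neural activity,
  # fast fluctuations included, not just the latent envelope)
  inst_pow <- shared[[1]]$sig^2
  k_sm <- max(1, round(fs * 2))                # 2-s power integration window
  inst_pow <- as.numeric(stats::filter(inst_pow, rep(1 / k_sm, k_sm), sides = 2))
  inst_pow[is.na(inst_pow)] <- mean(inst_pow, na.rm = TRUE)
  pow50 <- approx((seq_len(n) - 1) / fs, inst_pow,
                  xout = (seq_len(n50) - 1) / p$fs_fnirs, rule = 2)$y
  env50 <- approx((seq_len(n) - 1) / fs, shared[[1]]$env,
                  xout = (seq_len(n50) - 1) / p$fs_fnirs, rule = 2)$y
  kern <- hrf_kernel(p)
  drive <- convolve(pow50 - mean(pow50), rev(kern), type = "open")[seq_len(n50)]
  drive <- drive / max(sd(drive), 1e-12)
  drive <- 4 * tanh(drive / 4)        # vascular saturation of extreme bursts
  pattern <- 0.4 + 0.6 * runif(p$n_fnirs)
  sig_uM <- 0.3                                    # nominal Delta-HbO scale, uM
  hbo <- matrix(0, p$n_fnirs, n50)
  for (ch in seq_len(p$n_fnirs)) {
    noise <- pink_noise(n50)
    hbo[ch, ] <- sig_uM * (p$coupling_beta * (1 - p$noise_mix) * pattern[ch] * drive +
                             p$noise_mix * noise)
  }
  hb <- p$hb_ratio * hbo + 0.05 * sig_uM * matrix(rnorm(p$n_fnirs * n50), p$n_fnirs)

  fn_labels <- sprintf("ch%d", seq_len(p$n_fnirs))
  h <- hemodynamic_series(hbo, hb, fs = p$fs_fnirs, channel_labels = fn_labels)
  od <- forward_mbll(h, mbll_coefficients())

  if (p$motion_spikes) {
    n_spk <- max(1, round(p$duration_s / 60))
    for (s in seq_len(n_spk)) {
      ch <- sample(nrow(od$data), 1)
      at <- sample(n50 - p$fs_fnirs, 1)
      idx <- at + seq_len(round(p$fs_fnirs * 1))
      od$data[ch, idx] <- od$data[ch, idx] + 8 * sd(od$data[ch, ])
    }
  }

  labels <- eeg_labels_for(p$n_eeg)
  truth <- structure(list(
    kappa = kappa_of, sync_set = set_of,
    sync_sets = sets, band = p$band,
    coupling_beta = p$coupling_beta,
    designated_envelope_fs50 = env50,
    hemodynamic_drive = drive,
    fnirs_pattern = pattern,
    blink_times = blink_times,
    seed = subject_seed), class = "ground_truth")

  out <- list(
    eeg = ts_recording(eeg, fs = fs, channel_labels = labels, modality = "eeg"),
    eog = if (p$n_eog > 0)
      ts_recording(eog, fs = fs, channel_labels = c("HEOG", "VEOG",
                                                    sprintf("EOG%d", seq_len(max(0, p$n_eog - 2))))[seq_len(p$n_eog)],
                   modality = "eog") else NULL,
    fnirs_od = od,
    truth = truth)
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  out
}

#' Forward modified Beer-Lambert operator
#'
#' Maps concentration changes to dual-wavelength optical density:
#' `dOD(lambda) = (eps_HbO dHbO + eps_Hb dHb) * d * DPF(lambda)`.  Exact
#' linear inverse of [mbll_invert()] (round trip to 1e-10).
#'
#' @param h a `hemodynamic_series`.
#' @param coeffs an `mbll_coefficients`.
#' @return `modality = "fnirs_od"` recording, rows channel-major
#'   (`ch@690`, `ch@830`, ...).
#' @export
forward_mbll <- function(h, coeffs = mbll_coefficients()) {
  A <- coeffs$extinction * coeffs$distance_cm * coeffs$dpf
  nch <- nrow(h$hbo)
  od <- matrix(0, 2 * nch, ncol(h$hbo))
  labels <- character(2 * nch)
  for (ch in seq_len(nch)) {
    conc <- rbind(h$hbo[ch, ], h$hb[ch, ])
    od[(2 * ch - 1):(2 * ch), ] <- A %*% conc
    labels[2 * ch - 1] <- paste0(h$channel_labels[ch], "@690")
    labels[2 * ch] <- paste0(h$channel_labels[ch], "@830")
  }
  ts_recording(od, fs = h$fs, channel_labels = labels, modality = "fnirs_od")
}

#' Generate a two-group cohort
#'
#' Group A at nominal parameters; group B with the `group_effect` factors
#' applied to every community kappa and to `coupling_beta` (default: the
#' patient-like desynchronized, hypo-coupled preset).  Per-subject seeds are
#' drawn deterministically from the cohort seed.
#'
#' @param p a `sim_params`.
#' @param n_a,n_b group sizes (defaults 11 controls vs 8 patients).
#' @param seed cohort seed.
#' @return list of per-subject entries (`generate_subject()` output plus
#'   `group` and `id`).
#' @export
generate_cohort <- function(p, n_a = 11, n_b = 8, seed = 1) {
  if (n_a < 2 || n_b < 2) nvf_stop("nvf_parameter_error", "need >= 2 subjects per group")
  old <- get0(".Random.seed", globalenv())
  set.seed(seed)
  seeds <- sample.int(2^31 - 2, n_a + n_b)
  if (!is.null(old)) assign(".Random.seed", old, globalenv())

  pb <- p
  pb$sync_kappa <- p$sync_kappa * p$group_effect$kappa_factor
  pb$coupling_beta <- p$coupling_beta * p$group_effect$beta_factor
  if (!is.null(p$sync_sets)) {
    pb$sync_sets <- lapply(p$sync_sets, function(s) {
      s$kappa <- s$kappa * p$group_effect$kappa_factor
      s
    })
  }

  subjects <- vector("list", n_a + n_b)
  for (i in seq_len(n_a + n_b)) {
    pp <- if (i <= n_a) p else pb
    subj <- generate_subject(pp, seeds[i])
    subj$group <- if (i <= n_a) "A" else "B"
    subj$id <- sprintf("S%02d", i)
    subjects[[i]] <- subj
  }
  subjects
}
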