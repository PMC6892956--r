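# Zero-phase Butterworth filtering in second-order-section (biquad) form.
#
# signal::butter() returns single transfer-function polynomials whose roots
# collide numerically for narrow bands at high sampling rates (an order-4
# 8-10 Hz band-pass at 2048 Hz overflows through filtfilt).  Designing in
# zero-pole form and applying one biquad at a time keeps every section
# well-conditioned at any rate used here (50-2048 Hz).

# Analog Butterworth low-pass prototype poles (unit cutoff, left half-plane).
butter_proto <- function(order) {
  k <- seq_len(order)
  exp(1i * pi * (2 * k + order - 1) / (2 * order))
}

bilinear_z <- function(s, fs) (1 + s / (2 * fs)) / (1 - s / (2 * fs))

# Group discrete poles into biquads: conjugate pairs together, real poles
# paired smallest-with-largest.  `zeros` is the (b0,b1,b2) template shared by
# every section (band-pass: zeros at z = +1 and -1).
pole_sos <- function(z, zeros) {
  is_real <- abs(Im(z)) < 1e-10 * pmax(Mod(z), 1)
  zre <- sort(Re(z[is_real]))
  zcx <- z[!is_real & Im(z) > 0]
  zcx <- zcx[order(-Re(zcx))]
  sos <- list()
  for (p in zcx) {
    sos[[length(sos) + 1L]] <- list(b = zeros, a = c(1, -2 * Re(p), Mod(p)^2))
  }
  while (length(zre) >= 2) {
    p1 <- zre[1]; p2 <- zre[length(zre)]
    zre <- zre[-c(1, length(zre))]
    sos[[length(sos) + 1L]] <- list(b = zeros, a = c(1, -(p1 + p2), p1 * p2))
  }
  if (length(zre) == 1) {          # odd low/high-pass leaves one real pole
    sos[[length(sos) + 1L]] <- list(b = zeros, a = c(1, -zre[1], 0))
  }
  sos
}

sos_gain_at <- function(sos, f, fs) {
  zc <- exp(1i * 2 * pi * f / fs)
  g <- 1 + 0i
  for (s in sos) {
    g <- g * (s$b[1] + s$b[2] / zc + s$b[3] / zc^2) /
      (s$a[1] + s$a[2] / zc + s$a[3] / zc^2)
  }
  g
}

sos_normalize <- function(sos, f, fs) {
  sos[[1]]$b <- sos[[1]]$b / Mod(sos_gain_at(sos, f, fs))
  sos
}

# Band-pass: analog prototype -> band transform -> bilinear.
butter_sos_bandpass <- function(order, low_hz, high_hz, fs) {
  stopifnot(order >= 1, low_hz > 0, high_hz > low_hz, high_hz < fs / 2)
  w1 <- 2 * fs * tan(pi * low_hz / fs)
  w2 <- 2 * fs * tan(pi * high_hz / fs)
  w0 <- sqrt(w1 * w2); bw <- w2 - w1
  pb <- butter_proto(order) * bw / 2
  p_bp <- c(pb + sqrt(pb^2 - w0^2), pb - sqrt(pb^2 - w0^2))
  sos <- pole_sos(bilinear_z(p_bp, fs), zeros = c(1, 0, -1))
  sos_normalize(sos, sqrt(low_hz * high_hz), fs)
}

butter_sos_lowpass <- function(order, cutoff_hz, fs) {
  stopifnot(order >= 1, cutoff_hz > 0, cutoff_hz < fs / 2)
  wc <- 2 * fs * tan(pi * cutoff_hz / fs)
  z <- bilinear_z(butter_proto(order) * wc, fs)
  sos <- pole_sos(z, zeros = c(1, 2, 1))
  sos_normalize(sos, 0, fs)
}

butter_sos_highpass <- function(order, cutoff_hz, fs) {
  stopifnot(order >= 1, cutoff_hz > 0, cutoff_hz < fs / 2)
  wc <- 2 * fs * tan(pi * cutoff_hz / fs)
  z <- bilinear_z(wc / butter_proto(order), fs)
  sos <- pole_sos(z, zeros = c(1, -2, 1))
  sos_normalize(sos, fs / 2, fs)
}

# Forward-backward (zero-phase) application of an SOS cascade to a vector or
# to the rows of a matrix.  Edge transients are tamed with odd-reflection
# padding (one eighth of the series, capped at 4096 samples) and
# steady-state initial conditions, per the conventional filtfilt recipe.
sos_filtfilt <- function(sos, x) {
  vec <- !is.matrix(x)
  if (vec) x <- matrix(x, nrow = 1)
  m <- do.call(rbind, lapply(sos, function(s) c(s$b, s$a[2:3])))
  pad <- max(9L, min(4096L, ncol(x) %/% 8L))
  out <- sosfiltfilt_cpp(x, m, pad)
  if (vec) drop(out) else out
}
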