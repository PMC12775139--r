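# Zero-phase IIR filtering helpers shared by preprocessing and the filter
# bank. All filters are applied forward-backward (signal::filtfilt) so event
# latencies are preserved.

# 4th-order (4-pole) Butterworth bandpass, zero phase.
butter_bandpass <- function(low, high, rate) {
  nyq <- rate / 2
  assert_that(low > 0 && high > low, "band edges must satisfy 0 < low < high")
  assert_that(high < nyq, sprintf(
    "band upper edge %.6g Hz must be below the Nyquist frequency %.6g Hz", high, nyq))
  signal::butter(2, c(low, high) / nyq, type = "pass")
}

filtfilt_mat <- function(filt, x) {
  out <- t(apply(x, 1, function(ch) signal::filtfilt(filt, ch)))
  dimnames(out) <- dimnames(x)
  out
}

# Biquad notch (quality factor q), the classic second-order IIR notch.
notch_coef <- function(f0, rate, q = 30) {
  nyq <- rate / 2
  assert_that(f0 > 0 && f0 < nyq, sprintf(
    "notch frequency %.6g Hz must lie inside (0, Nyquist = %.6g Hz)", f0, nyq))
  w0 <- 2 * pi * f0 / rate
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  signal::Arma(b = b / a[1], a = a / a[1])
}

notch_filtfilt <- function(x, f0, rate, q = 30) {
  flt <- notch_coef(f0, rate, q)
  filtfilt_mat(flt, x)
}

bandpass_filtfilt <- function(x, band, rate) {
  flt <- butter_bandpass(band[1], band[2], rate)
  filtfilt_mat(flt, x)
}
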