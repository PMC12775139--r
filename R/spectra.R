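#' Welch power spectral density
#'
#' Averaged-periodogram PSD estimate with Hann-windowed segments, 50% overlap
#' and one-sided density scaling (power per Hz), the convention used throughout
#' the band-power statistics in this package. Segment means are removed before
#' windowing.
#'
#' @param x Numeric vector (one channel, microvolts).
#' @param rate Sampling rate in Hz.
#' @param seg_len Segment length in samples; defaults to one second of data
#'   (or the full signal if shorter).
#' @param overlap Fractional overlap between consecutive segments.
#' @return A tibble with columns `freq` (Hz) and `psd` (uV^2/Hz).
#' @export
welch_psd <- function(x, rate, seg_len = NULL, overlap = 0.5) {
  assert_that(rate > 0, "rate must be positive")
  n <- length(x)
  seg_len <- as.integer(seg_len %||% min(n, rate))
  assert_that(seg_len >= 8, "segment length too short for a PSD estimate")
  seg_len <- min(seg_len, n)
  step <- max(1L, as.integer(round(seg_len * (1 - overlap))))
  starts <- seq(1L, n - seg_len + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(seg_len) / (seg_len + 1))  # Hann
  u <- sum(w^2)
  nf <- seg_len %/% 2L + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + seg_len - 1L)]
    seg <- (seg - mean(seg)) * w
    sp <- Mod(stats::fft(seg))^2
    acc <- acc + sp[seq_len(nf)]
  }
  psd <- acc / (length(starts) * rate * u)
  # one-sided: double everything except DC and (for even seg_len) Nyquist
  dbl <- rep(2, nf)
  dbl[1] <- 1
  if (seg_len %% 2L == 0L) dbl[nf] <- 1
  tibble::tibble(freq = (seq_len(nf) - 1L) * rate / seg_len, psd = psd * dbl)
}

#' Integrated band power from a PSD
#'
#' @param psd A tibble as returned by [welch_psd()].
#' @param band Numeric `c(low, high)` in Hz.
#' @return Band power in uV^2 (PSD integrated over the band).
#' @export
band_power <- function(psd, band) {
  assert_that(length(band) == 2 && band[1] < band[2], "band must be c(low, high)")
  df <- psd$freq[2] - psd$freq[1]
  sel <- psd$freq >= band[1] & psd$freq <= band[2]
  assert_that(any(sel), "band contains no PSD bins")
  sum(psd$psd[sel]) * df
}

#' Canonical EEG frequency bands
#'
#' Delta 1-4, Theta 4-8, Alpha 8-12, Beta 12-30 and Gamma 30-45 Hz.
#'
#' @return A tibble with columns `band`, `low_hz`, `high_hz`.
#' @export
eeg_bands <- function() {
  tibble::tibble(
    band    = c("Delta", "Theta", "Alpha", "Beta", "Gamma"),
    low_hz  = c(1, 4, 8, 12, 30),
    high_hz = c(4, 8, 12, 30, 45)
  )
}
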