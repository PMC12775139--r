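#' Preprocess a continuous EEG record
#'
#' Applies, in order: (1) per-channel mean removal over the whole record
#' (baseline correction), (2) a zero-phase notch at `notch_hz` (biquad,
#' quality factor 30), (3) a zero-phase 4th-order Butterworth bandpass over
#' `band`. Zero-phase (forward-backward) filtering preserves event latencies.
#'
#' @param record A [signal_record()].
#' @param notch_hz Mains frequency to notch out, Hz.
#' @param band Numeric `c(low, high)` bandpass edges in Hz.
#' @return A new, preprocessed [signal_record()]; the input is unmodified.
#' @export
preprocess_record <- function(record, notch_hz = 50, band = c(1, 40)) {
  nyq <- record$rate / 2
  assert_that(length(band) == 2 && band[1] < band[2],
              "band edges must satisfy low < high")
  assert_that(band[2] < nyq,
              sprintf("band upper edge %.6g Hz is not below Nyquist (%.6g Hz)",
                      band[2], nyq))
  assert_that(notch_hz > 0 && notch_hz < nyq,
              sprintf("notch frequency %.6g Hz is not below Nyquist (%.6g Hz)",
                      notch_hz, nyq))
  x <- record$data - rowMeans(record$data)
  x <- notch_filtfilt(x, notch_hz, record$rate)
  x <- bandpass_filtfilt(x, band, record$rate)
  signal_record(x, record$rate, record$channel_names, record$events)
}

# same chain on a bare epoch matrix (used by the cohort pipeline)
preprocess_epoch <- function(x, rate, notch_hz = 50, band = c(1, 40)) {
  x <- x - rowMeans(x)
  x <- notch_filtfilt(x, notch_hz, rate)
  bandpass_filtfilt(x, band, rate)
}

#' Number of sliding windows in an epoch
#'
#' `floor((L - window_len) / step) + 1` for epoch length `L >= window_len`.
#'
#' @param len Epoch length in samples.
#' @param window_len Window length in samples.
#' @param step Step size in samples.
#' @return Integer window count.
#' @export
n_windows <- function(len, window_len, step) {
  as.integer(floor((len - window_len) / step) + 1L)
}

#' Segment epochs into fixed-length sliding windows
#'
#' Cuts each epoch into windows of `window_len` samples advancing by `step`
#' samples, strictly within the epoch (windows never cross trial boundaries).
#' Each window inherits its epoch's labels and `trial_id`, and is mean-removed
#' per channel.
#'
#' @param epochs Either an epochs tibble from [extract_trials()] /
#'   [simulate_cohort()] (list-column `data`, label columns) or a single
#'   channels x samples matrix.
#' @param window_len Window length in samples.
#' @param step Step size in samples.
#' @param rate Sampling rate; required when `epochs` is a bare matrix.
#' @param ... For a bare matrix: optional `subject_id`, `trial_id`,
#'   `mi_label`, `state_label`, `stage` to attach.
#' @return A `window_set`: list with `windows` (list of matrices), `meta`
#'   (tibble, one row per window), `window_len`, `step`, `rate`.
#' @export
segment_windows <- function(epochs, window_len = 3000, step = 100,
                            rate = NULL, ...) {
  assert_that(window_len >= 1 && step >= 1, "window_len and step must be >= 1")
  if (is.matrix(epochs)) {
    extra <- list(...)
    epochs <- tibble::tibble(
      subject_id = extra$subject_id %||% "s1",
      trial_id = extra$trial_id %||% "t1",
      mi_label = extra$mi_label %||% NA_character_,
      state_label = extra$state_label %||% NA_character_,
      stage = extra$stage %||% NA_integer_,
      data = list(epochs),
      rate = rate %||% stop_frustbci("rate is required for a bare matrix",
                                     "param_error"))
  }
  assert_that("data" %in% names(epochs), "epochs need a 'data' list-column")
  windows <- list()
  meta <- list()
  for (i in seq_len(nrow(epochs))) {
    x <- epochs$data[[i]]
    L <- ncol(x)
    if (L < window_len) {
      stop_frustbci(sprintf(
        "trial %s too short: %d samples < window length %d (not truncating)",
        epochs$trial_id[i], L, window_len), "range_error")
    }
    nw <- n_windows(L, window_len, step)
    for (w in seq_len(nw)) {
      off <- (w - 1L) * step
      seg <- x[, (off + 1):(off + window_len), drop = FALSE]
      windows[[length(windows) + 1L]] <- seg - rowMeans(seg)
      meta[[length(meta) + 1L]] <- tibble::tibble(
        subject_id = epochs$subject_id[i],
        trial_id = epochs$trial_id[i],
        mi_label = epochs$mi_label[i],
        state_label = epochs$state_label[i],
        stage = epochs$stage[i],
        offset = off)
    }
  }
  meta <- dplyr::bind_rows(meta)
  meta$window_id <- seq_len(nrow(meta))
  structure(list(windows = windows, meta = meta,
                 window_len = as.integer(window_len), step = as.integer(step),
                 rate = epochs$rate[1]),
            class = "window_set")
}

#' @export
print.window_set <- function(x, ...) {
  cat(sprintf("<window_set> %d windows of %d samples (step %d) @ %g Hz, %d trials\n",
              length(x$windows), x$window_len, x$step, x$rate,
              length(unique(x$meta$trial_id))))
  invisible(x)
}

#' Subset a window set
#' @param x A `window_set`.
#' @param i Integer or logical index over windows.
#' @param ... Unused.
#' @export
`[.window_set` <- function(x, i, ...) {
  i <- seq_along(x$windows)[i]
  structure(list(windows = x$windows[i], meta = x$meta[i, ],
                 window_len = x$window_len, step = x$step, rate = x$rate),
            class = "window_set")
}
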