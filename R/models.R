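#' Pipeline configuration
#'
#' One object carries every tunable of the decoding pipeline; unknown keys
#' are rejected. All stochastic steps (fold assignment, calibration splits,
#' subsampling) derive their streams from `seed`.
#'
#' @param seed Integer seed (required).
#' @param window_len,step Sliding-window length and step, samples.
#' @param epoch_offset_s Seconds discarded from the start of each stage-2
#'   epoch before windowing (analysis starts after ball-movement onset).
#' @param notch_hz,band Preprocessing notch frequency and bandpass edges, Hz.
#' @param bank Filter bank, a [filter_bank_spec()].
#' @param m CSP filter pairs per band and sub-problem.
#' @param k_select Features kept by mutual-information selection (before
#'   pair-completion).
#' @param backend `"auto"`, `"svm"` or `"lda"`.
#' @param svm_c SVM cost parameter.
#' @param k_folds Cross-validation folds.
#' @param pool_fraction Fraction of each state stratum sampled into the
#'   pooled (state-agnostic) training set.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed, window_len = 3000, step = 100,
                            epoch_offset_s = 0.5, notch_hz = 50,
                            band = c(1, 40), bank = filter_bank_spec(),
                            m = 2, k_select = 4,
                            backend = c("auto", "svm", "lda"), svm_c = 1,
                            k_folds = 5, pool_fraction = 1) {
  assert_that(!missing(seed) && is.numeric(seed) && length(seed) == 1,
              "seed is a required integer")
  backend <- match.arg(backend)
  assert_that(pool_fraction > 0 && pool_fraction <= 1,
              "pool_fraction must be in (0, 1]")
  structure(list(seed = as.integer(seed), window_len = window_len, step = step,
                 epoch_offset_s = epoch_offset_s, notch_hz = notch_hz,
                 band = band, bank = filter_bank_spec(bank), m = m,
                 k_select = k_select, backend = backend, svm_c = svm_c,
                 k_folds = k_folds, pool_fraction = pool_fraction),
            class = "pipeline_config")
}

state_levels <- c("low", "mid", "high")
mi_levels <- c("left", "right")

#' Train the frustration-state (passive BCI) classifier
#'
#' FBCSP features (one-vs-rest CSP per state) followed by the configured
#' backend; outputs are calibrated probabilities over low/mid/high.
#'
#' @param windows Stage-2 windows (`window_set`, list of matrices, or cached
#'   [fb_covariances()]).
#' @param state_labels Frustration label (`low`/`mid`/`high`) per window.
#' @param cfg A [pipeline_config()].
#' @param rate Sampling rate for bare matrix lists.
#' @return A fitted 3-class classifier.
#' @export
train_state_classifier <- function(windows, state_labels, cfg, rate = NULL) {
  missing_states <- setdiff(state_levels, unique(as.character(state_labels)))
  assert_that(length(missing_states) == 0,
              paste("missing frustration state(s):",
                    paste(missing_states, collapse = ", ")),
              class = "training_error")
  train_classifier(windows, factor(state_labels, levels = state_levels),
                   cfg, rate = rate)
}

#' Train the motor-imagery classifier bank
#'
#' Fits one MI classifier per frustration state on that state's windows only
#' (`M_low`, `M_mid`, `M_high`), a pooled state-agnostic classifier `M_all`
#' on the combined stage-2 windows (optionally a seeded stratified subsample
#' of each stratum, `cfg$pool_fraction`), and — when stage-1 calibration
#' windows are supplied — a non-frustration baseline classifier `M_stage1`.
#'
#' @param windows Stage-2 windows (or cached [fb_covariances()]).
#' @param mi_labels MI label (`left`/`right`) per stage-2 window.
#' @param state_labels Frustration label per stage-2 window.
#' @param stage1_windows Optional stage-1 windows for the `M_stage1` baseline.
#' @param stage1_mi_labels MI labels for the stage-1 windows.
#' @param cfg A [pipeline_config()].
#' @param state_clf Optional fitted state classifier to store in the bank.
#' @param rate Sampling rate for bare matrix lists.
#' @return A `classifier_bank`.
#' @export
train_mi_bank <- function(windows, mi_labels, state_labels,
                          stage1_windows = NULL, stage1_mi_labels = NULL,
                          cfg = pipeline_config(seed = 1), state_clf = NULL,
                          rate = NULL) {
  mi_labels <- as.character(mi_labels)
  state_labels <- as.character(state_labels)
  fc <- as_fb_covs(windows, cfg$bank, rate %||% attr_rate(windows))
  assert_that(length(mi_labels) == fc$n && length(state_labels) == fc$n,
              "labels must align with windows")
  members <- list()
  for (s in state_levels) {
    idx <- which(state_labels == s)
    present <- unique(mi_labels[idx])
    if (!all(mi_levels %in% present)) {
      stop_frustbci(sprintf(
        "state stratum '%s' lacks MI class(es): %s", s,
        paste(setdiff(mi_levels, present), collapse = ", ")), "training_error")
    }
    members[[s]] <- train_classifier(fc[idx],
                                     factor(mi_labels[idx], levels = mi_levels),
                                     cfg)
  }
  pool_idx <- seq_len(fc$n)
  if (cfg$pool_fraction < 1) {
    keep <- integer(0)
    with_seed(derive_seed(cfg$seed, "pool"), {
      for (s in state_levels) {
        idx <- which(state_labels == s)
        keep <- c(keep, sort(sample(idx, ceiling(length(idx) * cfg$pool_fraction))))
      }
    })
    pool_idx <- sort(keep)
  }
  m_all <- train_classifier(fc[pool_idx],
                            factor(mi_labels[pool_idx], levels = mi_levels), cfg)
  m_stage1 <- NULL
  if (!is.null(stage1_windows)) {
    assert_that(!is.null(stage1_mi_labels),
                "stage1_mi_labels required with stage1_windows")
    m_stage1 <- train_classifier(stage1_windows,
                                 factor(as.character(stage1_mi_labels),
                                        levels = mi_levels), cfg)
  }
  structure(list(state_clf = state_clf, members = members, m_all = m_all,
                 m_stage1 = m_stage1, pool_size = length(pool_idx),
                 strata_sizes = table(factor(state_labels, state_levels)),
                 cfg = cfg),
            class = "classifier_bank")
}

#' @export
print.classifier_bank <- function(x, ...) {
  cat(sprintf("<classifier_bank> M_low/M_mid/M_high (n = %s), M_all (n = %d)%s%s\n",
              paste(as.integer(x$strata_sizes), collapse = "/"), x$pool_size,
              if (!is.null(x$m_stage1)) ", M_stage1" else "",
              if (!is.null(x$state_clf)) ", state_clf" else ""))
  invisible(x)
}

bank_check_fitted <- function(bank, need_state = TRUE, need_stage1 = FALSE) {
  assert_that(inherits(bank, "classifier_bank"), "not a classifier bank",
              class = "state_error")
  if (need_state) {
    assert_that(!is.null(bank$state_clf),
                "bank has no fitted frustration-state classifier",
                class = "state_error")
  }
  if (need_stage1) {
    assert_that(!is.null(bank$m_stage1),
                "bank has no stage-1 (non-frustration) baseline classifier",
                class = "state_error")
  }
  invisible(TRUE)
}
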