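# Shared fixtures, all generated in code.

# windows of white noise with per-channel standard deviations
make_var_windows <- function(sds, n = 30, len = 400, seed = 1) {
  withr::with_seed(seed, lapply(seq_len(n), function(i) {
    t(vapply(sds, function(s) stats::rnorm(len, sd = s), numeric(len)))
  }))
}

# a window_set of independent noise windows, one window per trial
make_noise_window_set <- function(n_trials = 40, channels = 2, len = 300,
                                  rate = 100, labels = NULL, seed = 1) {
  withr::with_seed(seed, {
    epochs <- tibble::tibble(
      subject_id = "s1",
      trial_id = sprintf("t%03d", seq_len(n_trials)),
      mi_label = labels %||% sample(c("left", "right"), n_trials, replace = TRUE),
      state_label = NA_character_,
      stage = 2L,
      data = lapply(seq_len(n_trials),
                    function(i) matrix(stats::rnorm(channels * len), channels)),
      rate = rate)
    segment_windows(epochs, window_len = len, step = len)
  })
}

# tiny synthetic cohort used by several module tests
tiny_cohort <- function(n_subjects = 1, tpsc = 6, tps1 = 6, seed = 11, ...) {
  simulate_cohort(synth_config(
    n_subjects = n_subjects, trials_per_state_class = tpsc,
    trials_per_class_stage1 = tps1, trial_len_s = 4, seed = seed, ...))
}

fast_cfg <- function(seed = 1, ...) {
  pipeline_config(seed = seed, backend = "svm", ...)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
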