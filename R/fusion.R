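#' Fuse state and MI probabilities
#'
#' The pure decision arithmetic shared by the three strategies.
#'
#' * Method 1 (hard switching): `s_hat = argmax(p_f)`; the prediction is the
#'   selected state's MI output alone. Ties in `p_f` go to the lowest state
#'   index.
#' * Method 2 (probabilistic fusion): `p_final = sum_i p_i * p_i_mi`, the
#'   state-probability-weighted mixture of all three MI outputs.
#' * Methods 3-1 / 3-2 (state-agnostic): `p_final` is the pooled (or
#'   stage-1-trained) classifier's output; `p_f` is ignored.
#'
#' MI ties (`q_left == q_right`) resolve to `left`.
#'
#' @param p_f Numeric state probability vector `[p_low, p_mid, p_high]`.
#' @param mi_probs 3 x 2 matrix of per-state MI probabilities (rows =
#'   states low/mid/high, columns = left/right).
#' @param method One of `"1"`, `"2"`, `"3-1"`, `"3-2"`.
#' @param p_all MI probability pair from the state-agnostic classifier
#'   (required for method 3).
#' @return List with `p_final` (length-2), `s_hat` (0-based state index, or
#'   `NA` for method 3) and `y_hat` (`"left"`/`"right"`).
#' @export
fuse_probabilities <- function(p_f, mi_probs, method = c("1", "2", "3-1", "3-2"),
                               p_all = NULL) {
  method <- match.arg(method)
  if (method %in% c("3-1", "3-2")) {
    assert_that(!is.null(p_all), "method 3 requires the pooled classifier output")
    p_final <- as.numeric(p_all)
    s_hat <- NA_integer_
  } else {
    assert_that(length(p_f) == 3 && abs(sum(p_f) - 1) < 1e-6,
                "p_f must be a 3-state probability vector")
    assert_that(all(dim(mi_probs) == c(3, 2)), "mi_probs must be 3 x 2")
    if (method == "1") {
      s_hat <- which.max(p_f) - 1L           # ties -> lowest index
      p_final <- as.numeric(mi_probs[s_hat + 1L, ])
    } else {
      p_final <- as.numeric(colSums(p_f * mi_probs))
      s_hat <- NA_integer_
    }
  }
  y_hat <- mi_levels[which.max(p_final)]     # tie -> left
  list(p_final = p_final, s_hat = s_hat, y_hat = y_hat)
}

state_entropy <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

fuse_window_set <- function(bank, windows, method, rate = NULL,
                            entropy_fallback = NULL) {
  method <- as.character(method)
  assert_that(method %in% c("1", "2", "3-1", "3-2"),
              sprintf("unknown fusion method '%s'", method))
  bank_check_fitted(bank, need_state = method %in% c("1", "2"),
                    need_stage1 = method == "3-2")
  fc <- as_fb_covs(windows, bank$cfg$bank, rate %||% attr_rate(windows))
  meta <- if (inherits(windows, "window_set")) windows$meta else
    tibble::tibble(subject_id = NA_character_, trial_id = NA_character_,
                   window_id = seq_len(fc$n))
  p_f <- if (!is.null(bank$state_clf)) predict_proba(bank$state_clf, fc) else
    matrix(NA_real_, fc$n, 3)
  q <- lapply(state_levels, function(s) predict_proba(bank$members[[s]], fc))
  use_fallback <- method %in% c("1", "2") && !is.null(entropy_fallback)
  p_all <- if (method == "3-1" || use_fallback) predict_proba(bank$m_all, fc)
           else if (method == "3-2") predict_proba(bank$m_stage1, fc)
           else NULL
  rows <- lapply(seq_len(fc$n), function(i) {
    mi_probs <- rbind(q[[1]][i, ], q[[2]][i, ], q[[3]][i, ])
    method_i <- method
    if (use_fallback && state_entropy(p_f[i, ]) >= entropy_fallback) {
      method_i <- "3-1"     # too uncertain about the state: pooled decision
    }
    fd <- fuse_probabilities(p_f[i, ], mi_probs, method_i,
                             p_all = if (!is.null(p_all)) p_all[i, ] else NULL)
    tibble::tibble(
      subject = meta$subject_id[i], trial = meta$trial_id[i],
      window = meta$window_id[i],
      p0 = p_f[i, 1], p1 = p_f[i, 2], p2 = p_f[i, 3],
      q0L = mi_probs[1, 1], q0R = mi_probs[1, 2],
      q1L = mi_probs[2, 1], q1R = mi_probs[2, 2],
      q2L = mi_probs[3, 1], q2R = mi_probs[3, 2],
      pfL = fd$p_final[1], pfR = fd$p_final[2],
      s_hat = fd$s_hat, y_hat = fd$y_hat, method = method_i)
  })
  dplyr::bind_rows(rows)
}

#' Method 1: hard switching on the most probable frustration state
#'
#' The frustration classifier's most probable state selects one MI
#' classifier, whose output alone determines the prediction.
#'
#' @param x A single channels x samples window, a `window_set`, or cached
#'   [fb_covariances()].
#' @param bank A fitted `classifier_bank` (with state classifier).
#' @param rate Sampling rate for bare matrices.
#' @return A tibble of per-window fusion decisions (state probabilities,
#'   per-state MI probabilities, fused probabilities, `s_hat`, `y_hat`).
#' @export
method1_hard_switch <- function(x, bank, rate = NULL) {
  fuse_window_set(bank, as_window_input(x), "1", rate = rate)
}

#' Method 2: probabilistic fusion of all state-specific MI outputs
#'
#' All three MI classifier outputs are weighted by the full state
#' probability vector and summed; the fused probabilities always normalize.
#'
#' @inheritParams method1_hard_switch
#' @export
method2_soft_fusion <- function(x, bank, rate = NULL) {
  fuse_window_set(bank, as_window_input(x), "2", rate = rate)
}

#' Method 3: state-agnostic baselines
#'
#' Variant `3-1` uses the classifier trained on pooled stage-2 data from all
#' frustration levels; variant `3-2` uses the classifier trained on stage-1
#' (non-frustration) calibration data. The frustration classifier plays no
#' role.
#'
#' @inheritParams method1_hard_switch
#' @param variant `"3-1"` or `"3-2"`.
#' @export
method3_baseline <- function(x, bank, variant = c("3-1", "3-2"), rate = NULL) {
  if (length(variant) == 1 && !variant %in% c("3-1", "3-2")) {
    stop_frustbci(sprintf("unknown method-3 variant '%s'", variant),
                  "param_error")
  }
  variant <- match.arg(variant)
  fuse_window_set(bank, as_window_input(x), variant, rate = rate)
}

as_window_input <- function(x) {
  if (is.matrix(x)) list(x) else x
}

#' Run a fusion strategy over a window set
#'
#' @param bank A fitted `classifier_bank`.
#' @param windows A `window_set` (or cached [fb_covariances()]).
#' @param method `"1"`, `"2"`, `"3-1"` or `"3-2"`.
#' @param aggregate `"window"` (default; one decision per window, the unit
#'   in which accuracies are reported) or `"trial"` (majority vote over each
#'   trial's windows, ties to `left`).
#' @param rate Sampling rate for bare matrix lists.
#' @param entropy_fallback Optional entropy threshold in bits (`NULL` = off,
#'   the default behavior): under methods 1/2, windows whose state
#'   probability vector is at least this uncertain are decided by the
#'   pooled state-agnostic model instead (their `method` column reads
#'   `"3-1"`).
#' @return A tibble of fusion decisions.
#' @export
fuse <- function(bank, windows, method = "2", aggregate = c("window", "trial"),
                 rate = NULL, entropy_fallback = NULL) {
  aggregate <- match.arg(aggregate)
  dec <- fuse_window_set(bank, windows, method, rate = rate,
                         entropy_fallback = entropy_fallback)
  if (aggregate == "trial") {
    dec <- dec |>
      dplyr::group_by(.data$subject, .data$trial, .data$method) |>
      dplyr::summarise(
        n_windows = dplyr::n(),
        pfL = mean(.data$pfL), pfR = mean(.data$pfR),
        y_hat = ifelse(mean(.data$y_hat == "left") >= 0.5, "left", "right"),
        .groups = "drop")
  }
  dec
}
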