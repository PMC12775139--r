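# End-to-end per-subject evaluation: preprocessing, windowing, trial-level
# cross-validation of the state classifier, the state-specific MI bank and
# all four decision strategies.

# Band-filter whole epochs once, then slice window covariances out of the
# filtered signal. Statistically equivalent to filtering each window (the
# windows overlap by step/window_len) and much cheaper.
epoch_fb_covs <- function(epochs, cfg) {
  rate <- epochs$rate[1]
  flts <- lapply(cfg$bank, function(b) butter_bandpass(b[1], b[2], rate))
  covs <- lapply(seq_along(cfg$bank), function(b) list())
  meta <- list()
  wid <- 0L
  for (i in seq_len(nrow(epochs))) {
    x <- epochs$data[[i]]
    nw <- n_windows(ncol(x), cfg$window_len, cfg$step)
    filtered <- lapply(flts, function(f) filtfilt_mat(f, x))
    for (w in seq_len(nw)) {
      off <- (w - 1L) * cfg$step
      wid <- wid + 1L
      for (b in seq_along(cfg$bank)) {
        covs[[b]][[wid]] <- window_cov(
          filtered[[b]][, (off + 1):(off + cfg$window_len), drop = FALSE])
      }
      meta[[wid]] <- tibble::tibble(
        subject_id = epochs$subject_id[i], trial_id = epochs$trial_id[i],
        mi_label = epochs$mi_label[i], state_label = epochs$state_label[i],
        stage = epochs$stage[i], offset = off, window_id = wid)
    }
  }
  fc <- structure(list(covs = covs, n = wid, bank = cfg$bank, rate = rate,
                       n_channels = nrow(epochs$data[[1]])),
                  class = "fb_covs")
  list(fc = fc, meta = dplyr::bind_rows(meta))
}

prep_epochs <- function(epochs, cfg) {
  rate <- epochs$rate[1]
  off <- round(cfg$epoch_offset_s * rate)
  epochs$data <- lapply(seq_len(nrow(epochs)), function(i) {
    x <- preprocess_epoch(epochs$data[[i]], rate, cfg$notch_hz, cfg$band)
    if (epochs$stage[i] == 2L && off > 0) x[, -seq_len(off), drop = FALSE] else x
  })
  epochs
}

argmax_lab <- function(p) colnames(p)[max.col(p, ties.method = "first")]

#' Evaluate one subject end-to-end
#'
#' Preprocesses and windows the subject's epochs, then runs trial-stratified
#' k-fold cross-validation over the stage-2 trials. Per fold it trains the
#' frustration-state classifier and the MI classifier bank on training
#' windows only and scores, on test windows: the state classifier (pBCI),
#' the state-specific MI models on their own states versus the pooled model
#' (the specialization margin), and the four decision strategies (hard
#' switching, probabilistic fusion, pooled and stage-1 baselines). The
#' stage-1 baseline model is trained once on the subject's calibration data.
#'
#' @param epochs Epoch tibble for one subject (from a `synth_cohort` or
#'   [extract_trials()]): columns `trial_id`, `mi_label`, `state_label`,
#'   `stage`, `rate` and the `data` list-column.
#' @param cfg A [pipeline_config()].
#' @return One-row tibble of accuracies (percent) and margins.
#' @export
evaluate_subject <- function(epochs, cfg) {
  epochs <- prep_epochs(epochs, cfg)
  s2 <- epochs[epochs$stage == 2L, ]
  s1 <- epochs[epochs$stage == 1L, ]
  assert_that(nrow(s2) > 0, "no stage-2 epochs for this subject")
  e2 <- epoch_fb_covs(s2, cfg)
  m_stage1 <- NULL
  if (nrow(s1) > 0) {
    e1 <- epoch_fb_covs(s1, cfg)
    m_stage1 <- train_classifier(e1$fc, factor(e1$meta$mi_label, mi_levels), cfg)
  }

  trials <- dplyr::distinct(e2$meta[, c("trial_id", "mi_label", "state_label")])
  strat <- paste(trials$state_label, trials$mi_label)
  assert_that(all(table(strat) >= cfg$k_folds),
              sprintf("need at least %d trials per (state x MI) stratum",
                      cfg$k_folds))
  tf <- stratified_folds(strat, cfg$k_folds, derive_seed(cfg$seed, "cvfold"))
  fold <- tf[match(e2$meta$trial_id, trials$trial_id)]

  meta <- e2$meta
  tally <- list()
  for (f in sort(unique(fold))) {
    tr <- which(fold != f); te <- which(fold == f)
    state_clf <- train_state_classifier(e2$fc[tr], meta$state_label[tr], cfg)
    bank <- train_mi_bank(e2$fc[tr], meta$mi_label[tr], meta$state_label[tr],
                          cfg = cfg, state_clf = state_clf)
    bank$m_stage1 <- m_stage1

    p_f <- predict_proba(state_clf, e2$fc[te])
    q <- lapply(state_levels, function(s) predict_proba(bank$members[[s]], e2$fc[te]))
    p_all <- predict_proba(bank$m_all, e2$fc[te])
    p_s1 <- if (!is.null(m_stage1)) predict_proba(m_stage1, e2$fc[te]) else NULL

    true_mi <- meta$mi_label[te]
    true_state <- meta$state_label[te]
    y1 <- y2 <- character(length(te))
    for (i in seq_along(te)) {
      mi_probs <- rbind(q[[1]][i, ], q[[2]][i, ], q[[3]][i, ])
      y1[i] <- fuse_probabilities(p_f[i, ], mi_probs, "1")$y_hat
      y2[i] <- fuse_probabilities(p_f[i, ], mi_probs, "2")$y_hat
    }
    y31 <- argmax_lab(p_all)
    y32 <- if (!is.null(p_s1)) argmax_lab(p_s1) else rep(NA_character_, length(te))
    pred_state <- argmax_lab(p_f)

    rows <- tibble::tibble(
      state = true_state,
      pbci_ok = pred_state == true_state,
      m1_ok = y1 == true_mi, m2_ok = y2 == true_mi,
      m31_ok = y31 == true_mi, m32_ok = y32 == true_mi)
    for (si in seq_along(state_levels)) {
      sel <- true_state == state_levels[si]
      rows[[paste0("spec_ok_", state_levels[si])]] <-
        ifelse(sel, argmax_lab(q[[si]]) == true_mi, NA)
      rows[[paste0("pool_ok_", state_levels[si])]] <-
        ifelse(sel, y31 == true_mi, NA)
    }
    tally[[f]] <- rows
  }
  tally <- dplyr::bind_rows(tally)
  pct <- function(v) 100 * mean(v, na.rm = TRUE)
  out <- tibble::tibble(
    subject_id = s2$subject_id[1],
    n_trials = nrow(trials), n_windows = nrow(meta),
    pbci_acc = pct(tally$pbci_ok),
    mi_low_acc = pct(tally$spec_ok_low),
    mi_mid_acc = pct(tally$spec_ok_mid),
    mi_high_acc = pct(tally$spec_ok_high),
    pool_low_acc = pct(tally$pool_ok_low),
    pool_mid_acc = pct(tally$pool_ok_mid),
    pool_high_acc = pct(tally$pool_ok_high),
    method1_acc = pct(tally$m1_ok),
    method2_acc = pct(tally$m2_ok),
    method3_1_acc = pct(tally$m31_ok),
    method3_2_acc = if (is.null(m_stage1)) NA_real_ else pct(tally$m32_ok))
  out$own_state_margin <- mean(c(out$mi_low_acc - out$pool_low_acc,
                                 out$mi_mid_acc - out$pool_mid_acc,
                                 out$mi_high_acc - out$pool_high_acc))
  out
}

#' Evaluate a whole cohort
#'
#' Runs [evaluate_subject()] for every subject of a synthetic cohort (or an
#' epochs tibble covering several subjects) and binds the per-subject rows.
#'
#' @param cohort A `synth_cohort` or epochs tibble.
#' @param cfg A [pipeline_config()]; defaults to the cohort's rate-matched
#'   configuration with the cohort seed.
#' @param progress Print one line per subject.
#' @return A `cohort_report` tibble, one row per subject.
#' @export
evaluate_cohort <- function(cohort, cfg = NULL, progress = FALSE) {
  epochs <- if (inherits(cohort, "synth_cohort")) cohort$epochs else cohort
  cfg <- cfg %||% pipeline_config(
    seed = if (inherits(cohort, "synth_cohort")) cohort$config$seed else 1)
  out <- lapply(unique(epochs$subject_id), function(sid) {
    if (progress) message("subject ", sid)
    evaluate_subject(epochs[epochs$subject_id == sid, ], cfg)
  })
  res <- dplyr::bind_rows(out)
  class(res) <- c("cohort_report", class(res))
  attr(res, "cfg") <- cfg
  res
}

#' Summarize a cohort report
#'
#' Cohort mean and population standard deviation of every accuracy column
#' (via [aggregate_cohort()]), in the layout of a per-subject accuracy
#' table's closing rows.
#'
#' @param report A `cohort_report`.
#' @return Tibble with `metric`, `mean`, `sd`, `n`.
#' @export
summarize_cohort <- function(report) {
  cols <- setdiff(names(report), c("subject_id", "n_trials", "n_windows"))
  dplyr::bind_rows(lapply(cols, function(cl) {
    v <- report[[cl]]
    v <- v[is.finite(v)]
    if (length(v) == 0) return(NULL)
    dplyr::mutate(aggregate_cohort(v), metric = cl, .before = 1)
  }))
}
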