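#' Trial-stratified cross-validation with a leakage guard
#'
#' Folds partition *trials*, never windows: all windows cut from one trial
#' share a fold, so heavily overlapping windows can never straddle the
#' train/test split. Within each fold the full pipeline (FBCSP fit, feature
#' selection, backend training) is refitted on training windows only;
#' accuracy is counted over test windows.
#'
#' @param windows A `window_set` carrying labels in its metadata.
#' @param cfg A [pipeline_config()].
#' @param task `"mi"` or `"state"`: which label column to decode.
#' @param k Number of folds.
#' @param seed Fold-assignment seed (defaults to the pipeline seed).
#' @param guard `"trial"` (the leakage guard) or `"window"` (deliberately
#'   split windows at random, for demonstrating leakage in tests).
#' @param pipeline Optional custom pipeline: a list with `fit(windows,
#'   labels)` and `predict(fit, windows)` (returning labels); defaults to the
#'   package's FBCSP pipeline.
#' @return A `cv_report`: fold assignments, per-fold and mean accuracy,
#'   per-class precision/recall, the pooled confusion matrix and the seed.
#' @export
crossval <- function(windows, cfg = pipeline_config(seed = 1),
                     task = c("mi", "state"), k = cfg$k_folds,
                     seed = cfg$seed, guard = c("trial", "window"),
                     pipeline = NULL) {
  task <- match.arg(task)
  guard <- match.arg(guard)
  meta <- windows$meta
  labels <- as.character(if (task == "mi") meta$mi_label else meta$state_label)
  trial_tbl <- dplyr::distinct(
    tibble::tibble(trial_id = meta$trial_id, label = labels))
  per_class <- table(trial_tbl$label)
  assert_that(all(per_class >= k),
              sprintf("need at least %d trials per class, have %s", k,
                      paste(per_class, collapse = "/")))
  if (guard == "trial") {
    trial_fold <- stratified_folds(trial_tbl$label, k, derive_seed(seed, "cv"))
    fold <- trial_fold[match(meta$trial_id, trial_tbl$trial_id)]
  } else {
    fold <- stratified_folds(labels, k, derive_seed(seed, "cv"))
  }

  fc <- NULL
  if (is.null(pipeline)) {
    fc <- fb_covariances(windows, cfg$bank)
    pipeline <- list(
      fit = function(idx, y) train_classifier(fc[idx], y, cfg),
      predict = function(fit, idx) {
        p <- predict_proba(fit, fc[idx])
        colnames(p)[max.col(p, ties.method = "first")]
      })
  } else {
    user <- pipeline
    pipeline <- list(
      fit = function(idx, y) user$fit(windows[idx], y),
      predict = function(fit, idx) user$predict(fit, windows[idx]))
  }

  classes <- sort(unique(labels))
  cm <- matrix(0L, length(classes), length(classes),
               dimnames = list(true = classes, predicted = classes))
  per_fold <- list()
  for (f in sort(unique(fold))) {
    tr <- which(fold != f); te <- which(fold == f)
    fit <- pipeline$fit(tr, labels[tr])
    pred <- pipeline$predict(fit, te)
    for (i in seq_along(te)) cm[labels[te[i]], pred[i]] <- cm[labels[te[i]], pred[i]] + 1L
    per_fold[[f]] <- tibble::tibble(fold = f, n_test = length(te),
                                    accuracy = 100 * mean(pred == labels[te]))
  }
  per_fold <- dplyr::bind_rows(per_fold)
  structure(list(
    task = task, guard = guard, seed = seed, k = k,
    folds = tibble::tibble(trial_id = meta$trial_id, window_id = meta$window_id,
                           fold = fold),
    per_fold = per_fold,
    mean_accuracy = mean(per_fold$accuracy),
    sd_accuracy = pop_sd(per_fold$accuracy),
    confusion = cm,
    metrics = confusion_metrics(cm)),
    class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %s task, %d-fold (%s guard): %.2f%% +/- %.2f\n",
              x$task, x$k, x$guard, x$mean_accuracy, x$sd_accuracy))
  invisible(x)
}

#' Per-class precision and recall from a confusion matrix
#'
#' Accepts raw counts or row-normalized percentages (class order preserved).
#' Recall is the diagonal of the row-normalized matrix. Precision is the
#' diagonal share of each *column* after weighting rows by class priors —
#' with the default equal priors, each row of the row-normalized matrix
#' contributes equally, which is the convention for confusion matrices
#' reported as averaged row percentages. A class never predicted gets a
#' flagged, undefined precision rather than NaN.
#'
#' @param cm Square numeric matrix, rows = true classes.
#' @param priors `"equal"` or a numeric vector of class priors.
#' @return A tibble with `class`, `precision`, `recall` (percent) and
#'   `flagged`.
#' @export
confusion_metrics <- function(cm, priors = "equal") {
  cm <- as.matrix(cm)
  assert_that(nrow(cm) == ncol(cm) && all(cm >= 0),
              "confusion matrix must be square and non-negative")
  classes <- rownames(cm) %||% paste0("class", seq_len(nrow(cm)))
  rn <- cm / rowSums(cm)
  if (identical(priors, "equal")) {
    w <- rep(1 / nrow(cm), nrow(cm))
  } else {
    assert_that(length(priors) == nrow(cm) && all(priors >= 0),
                "priors must match the class count")
    w <- priors / sum(priors)
  }
  weighted <- rn * w
  colsum <- colSums(weighted)
  precision <- 100 * diag(weighted) / colsum
  flagged <- colsum <= 0
  precision[flagged] <- NA_real_
  tibble::tibble(class = classes, precision = unname(precision),
                 recall = unname(100 * diag(rn)), flagged = unname(flagged))
}

#' Band-wise PSD two-sample t-tests
#'
#' For each window, Welch PSD per channel is averaged into band powers over
#' the canonical bands; an independent two-sample pooled-variance t-test
#' compares groups A and B per band. The sign convention is
#' `t = (mean_A - mean_B) / se`, so A weaker than B gives a negative t.
#'
#' @param windows_a,windows_b `window_set`s or lists of window matrices.
#' @param bands Band table as from [eeg_bands()].
#' @param rate Sampling rate for bare matrix lists.
#' @return A `band_stats` tibble: band, edges, group means, t, p.
#' @export
band_psd_ttest <- function(windows_a, windows_b, bands = eeg_bands(),
                           rate = NULL) {
  get_w <- function(x) if (inherits(x, "window_set")) x$windows else x
  get_r <- function(x) if (inherits(x, "window_set")) x$rate else rate
  wa <- get_w(windows_a); wb <- get_w(windows_b)
  r <- get_r(windows_a) %||% get_r(windows_b)
  assert_that(!is.null(r), "rate is required")
  assert_that(length(wa) >= 2 && length(wb) >= 2,
              "need at least 2 windows per group")
  bp <- function(w) {
    vapply(seq_len(nrow(bands)), function(bi) {
      mean(vapply(seq_len(nrow(w)), function(ch) {
        band_power(welch_psd(w[ch, ], r), c(bands$low_hz[bi], bands$high_hz[bi]))
      }, 1))
    }, 1)
  }
  pa <- t(vapply(wa, bp, numeric(nrow(bands))))
  pb <- t(vapply(wb, bp, numeric(nrow(bands))))
  out <- lapply(seq_len(nrow(bands)), function(bi) {
    tt <- stats::t.test(pa[, bi], pb[, bi], var.equal = TRUE)
    tibble::tibble(band = bands$band[bi], low_hz = bands$low_hz[bi],
                   high_hz = bands$high_hz[bi],
                   mean_a = mean(pa[, bi]), mean_b = mean(pb[, bi]),
                   t = unname(tt$statistic), p = tt$p.value)
  })
  out <- dplyr::bind_rows(out)
  class(out) <- c("band_stats", class(out))
  out
}

#' Cohort-averaged evoked spectrum for one channel
#'
#' Welch spectrum of each record converted to decibels, with mean and
#' (population) standard deviation across records per frequency bin.
#'
#' @param records A list of [signal_record()]s.
#' @param channel Channel label (case-insensitive).
#' @return Tibble with `freq`, `mean_db`, `sd_db`.
#' @export
evoked_spectrum <- function(records, channel) {
  if (inherits(records, "signal_record")) records <- list(records)
  spectra <- lapply(records, function(rec) {
    idx <- channel_index(rec, channel)
    psd <- welch_psd(rec$data[idx, ], rec$rate)
    10 * log10(pmax(psd$psd, .Machine$double.xmin))
  })
  freq <- welch_psd(records[[1]]$data[1, ], records[[1]]$rate)$freq
  mat <- do.call(rbind, spectra)
  tibble::tibble(freq = freq,
                 mean_db = colMeans(mat),
                 sd_db = apply(mat, 2, pop_sd))
}

#' Cohort aggregation: mean and standard deviation
#'
#' Arithmetic mean and population (divide-by-n) standard deviation, reported
#' to two decimals — the summary used for per-subject accuracy tables.
#'
#' @param values Numeric vector of per-subject values.
#' @param sd_type `"population"` or `"sample"`.
#' @return One-row tibble with `mean`, `sd`, `n`.
#' @export
aggregate_cohort <- function(values, sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  assert_that(length(values) >= 1, "cannot aggregate an empty cohort")
  s <- if (length(values) == 1) 0
       else if (sd_type == "population") pop_sd(values) else stats::sd(values)
  tibble::tibble(mean = round(mean(values), 2), sd = round(s, 2),
                 n = length(values))
}

#' Paired t-test and Wilcoxon signed-rank test of two accuracy vectors
#'
#' Two-sided p-values, paired by subject. Degenerate cases are handled
#' explicitly: identical vectors give `t = 0, p = 1`; a constant nonzero
#' shift gives `|t| = Inf, p = 0`; the Wilcoxon test is flagged degenerate
#' when every difference is zero.
#'
#' @param acc_a,acc_b Equal-length (>= 5) numeric vectors.
#' @return One-row tibble: `t`, `p_t`, `v`, `p_wilcoxon`, `degenerate`.
#' @export
paired_tests <- function(acc_a, acc_b) {
  assert_that(length(acc_a) == length(acc_b) && length(acc_a) >= 5,
              "need equal-length vectors of at least 5 paired values")
  d <- acc_a - acc_b
  if (all(d == 0)) {
    return(tibble::tibble(t = 0, p_t = 1, v = NA_real_, p_wilcoxon = NA_real_,
                          degenerate = TRUE))
  }
  if (stats::sd(d) == 0) {
    return(tibble::tibble(t = sign(mean(d)) * Inf, p_t = 0, v = NA_real_,
                          p_wilcoxon = NA_real_, degenerate = TRUE))
  }
  tt <- stats::t.test(acc_a, acc_b, paired = TRUE)
  wt <- suppressWarnings(stats::wilcox.test(acc_a, acc_b, paired = TRUE))
  tibble::tibble(t = unname(tt$statistic), p_t = tt$p.value,
                 v = unname(wt$statistic), p_wilcoxon = wt$p.value,
                 degenerate = FALSE)
}

#' One-way repeated-measures ANOVA
#'
#' Subjects x conditions matrix (complete, no imputation); classical
#' within-subject F test with `(c - 1, (n - 1)(c - 1))` degrees of freedom.
#'
#' @param ratings Numeric matrix, rows = subjects, columns = conditions.
#' @return One-row tibble: `f`, `df1`, `df2`, `p`.
#' @export
rm_anova <- function(ratings) {
  ratings <- as.matrix(ratings)
  assert_that(nrow(ratings) >= 2 && ncol(ratings) >= 2,
              "need at least 2 subjects and 2 conditions")
  assert_that(all(is.finite(ratings)), "missing cells are not imputed")
  n <- nrow(ratings); c <- ncol(ratings)
  grand <- mean(ratings)
  ss_cond <- n * sum((colMeans(ratings) - grand)^2)
  ss_subj <- c * sum((rowMeans(ratings) - grand)^2)
  ss_tot <- sum((ratings - grand)^2)
  ss_err <- ss_tot - ss_cond - ss_subj
  df1 <- c - 1; df2 <- (n - 1) * (c - 1)
  ms_cond <- ss_cond / df1
  ms_err <- ss_err / df2
  f <- if (ms_err <= .Machine$double.eps) {
    if (ms_cond <= .Machine$double.eps) 0 else Inf
  } else ms_cond / ms_err
  p <- if (is.infinite(f)) 0 else stats::pf(f, df1, df2, lower.tail = FALSE)
  tibble::tibble(f = f, df1 = df1, df2 = df2, p = p)
}

#' Class-separability metrics on a 2-D embedding
#'
#' Pairwise Euclidean distances between class centroids, Fisher's
#' discriminant ratio (between-class to within-class variance, via traces of
#' the scatter matrices) and a cross-validated linear-probe accuracy
#' (shrinkage LDA, stratified folds).
#'
#' @param embedding Numeric matrix, points x 2 (or more) coordinates.
#' @param labels Class label per point (>= 2 classes, >= 2 points each).
#' @param k Probe cross-validation folds.
#' @param seed Probe fold seed.
#' @return List with `centroid_distances` (tibble), `fisher_ratio`,
#'   `separated` (TRUE when within-class spread is zero) and
#'   `probe_accuracy` (percent).
#' @export
separability_metrics <- function(embedding, labels, k = 5, seed = 1) {
  x <- as.matrix(embedding)
  y <- as.character(labels)
  classes <- sort(unique(y))
  assert_that(length(classes) >= 2, "need at least 2 classes",
              class = "training_error")
  assert_that(all(table(y) >= 2), "need at least 2 points per class")
  cent <- t(vapply(classes, function(cl) colMeans(x[y == cl, , drop = FALSE]),
                   numeric(ncol(x))))
  pairs <- utils::combn(classes, 2)
  cd <- tibble::tibble(
    class_a = pairs[1, ], class_b = pairs[2, ],
    distance = vapply(seq_len(ncol(pairs)), function(i) {
      sqrt(sum((cent[pairs[1, i], ] - cent[pairs[2, i], ])^2))
    }, 1))
  grand <- colMeans(x)
  sb <- sum(vapply(classes, function(cl) {
    sum(y == cl) * sum((cent[cl, ] - grand)^2)
  }, 1))
  sw <- sum(vapply(classes, function(cl) {
    sum((x[y == cl, , drop = FALSE] -
           matrix(cent[cl, ], sum(y == cl), ncol(x), byrow = TRUE))^2)
  }, 1))
  separated <- sw <= .Machine$double.eps
  fisher <- if (separated) Inf else sb / sw
  k_eff <- min(k, min(table(y)))
  folds <- stratified_folds(y, max(2, k_eff), derive_seed(seed, "probe"))
  correct <- 0
  for (f in sort(unique(folds))) {
    tr <- folds != f
    if (separated) {
      # zero within-class spread: nearest-centroid probe
      ctr <- t(vapply(classes, function(cl)
        colMeans(x[tr & y == cl, , drop = FALSE]), numeric(ncol(x))))
      d <- as.matrix(stats::dist(rbind(ctr, x[!tr, , drop = FALSE])))
      d <- d[-seq_len(nrow(ctr)), seq_len(nrow(ctr)), drop = FALSE]
      pred <- classes[max.col(-d, ties.method = "first")]
    } else {
      bk <- fit_backend_lda(x[tr, , drop = FALSE], factor(y[tr]), list())
      p <- predict_backend_lda(bk, x[!tr, , drop = FALSE])
      pred <- colnames(p)[max.col(p, ties.method = "first")]
    }
    correct <- correct + sum(pred == y[!tr])
  }
  list(centroid_distances = cd, fisher_ratio = fisher, separated = separated,
       probe_accuracy = 100 * correct / length(y))
}

#' Score a 25-item resilience questionnaire
#'
#' Items are rated 1-7; the score is their sum (25-175). Scores of 146-175
#' classify as high resilience, lower scores as general resilience.
#'
#' @param items Integer vector of exactly 25 ratings in 1..7.
#' @return List with `score` and `category` (`"high"`/`"general"`).
#' @export
score_resilience <- function(items) {
  assert_that(length(items) == 25, "exactly 25 items are required",
              class = "validation_error")
  assert_that(all(items == round(items) & items >= 1 & items <= 7),
              "items must be integer ratings in 1..7",
              class = "validation_error")
  score <- sum(items)
  list(score = score, category = if (score >= 146) "high" else "general")
}
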