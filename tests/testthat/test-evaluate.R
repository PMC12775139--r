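test_that("the leakage guard keeps same-trial windows co-assigned", {
  set.seed(130)
  # overlapping segmentation: each trial yields several windows
  epochs <- tibble::tibble(
    subject_id = "s1", trial_id = sprintf("t%02d", 1:10),
    mi_label = rep(c("left", "right"), 5), state_label = NA, stage = 2L,
    data = lapply(1:10, function(i) matrix(rnorm(2 * 500), 2)), rate = 100)
  ws <- segment_windows(epochs, window_len = 300, step = 50)
  cv <- crossval(ws, fast_cfg(seed = 1, m = 1, k_select = 2), task = "mi", k = 2)
  per_trial <- tapply(cv$folds$fold, cv$folds$trial_id, function(f) length(unique(f)))
  expect_true(all(per_trial == 1))
  # fold partition covers all trials disjointly, stratified within +/- 1
  tf <- dplyr::distinct(cv$folds[, c("trial_id", "fold")])
  expect_equal(sort(tf$trial_id), sort(unique(ws$meta$trial_id)))
  expect_lte(diff(range(table(tf$fold))), 2)
})

test_that("a memorizing pipeline is exposed by the guard and thrives without it", {
  set.seed(131)
  # each trial repeats a 100-sample pattern, so all of a trial's windows are
  # identical: exactly the within-trial redundancy the guard must contain
  epochs <- tibble::tibble(
    subject_id = "s1", trial_id = sprintf("t%02d", 1:20),
    mi_label = rep(c("left", "right"), 10), state_label = NA, stage = 2L,
    data = lapply(1:20, function(i) {
      matrix(rep(rnorm(2 * 100), 5), 2, 500)
    }), rate = 100)
  ws <- segment_windows(epochs, window_len = 300, step = 100)
  memorizer <- list(
    fit = function(w, labels) {
      keys <- vapply(w$windows, function(x) paste(signif(x[1, 1:5], 10),
                                                  collapse = ","), "")
      stats::setNames(labels, keys)
    },
    predict = function(fit, w) {
      keys <- vapply(w$windows, function(x) paste(signif(x[1, 1:5], 10),
                                                  collapse = ","), "")
      out <- unname(fit[keys])
      out[is.na(out)] <- "left"
      out
    })
  guarded <- crossval(ws, fast_cfg(seed = 2), task = "mi", k = 4,
                      pipeline = memorizer)
  unguarded <- crossval(ws, fast_cfg(seed = 2), task = "mi", k = 4,
                        guard = "window", pipeline = memorizer)
  expect_lt(guarded$mean_accuracy, 65)     # near chance under the guard
  expect_gt(unguarded$mean_accuracy, 95)   # leakage rewards memorization
})

test_that("random labels score inside the binomial chance band", {
  ws <- make_noise_window_set(n_trials = 40, len = 300, seed = 132)
  cv <- crossval(ws, fast_cfg(seed = 3, m = 1, k_select = 2), task = "mi", k = 4)
  half_width <- 100 * 1.96 * sqrt(0.25 / 40)
  expect_gt(cv$mean_accuracy, 50 - half_width)
  expect_lt(cv$mean_accuracy, 50 + half_width)
})

test_that("confusion metrics reproduce the reference low-class precision", {
  cm <- reference_cohort("confusion")
  m <- confusion_metrics(cm)
  expect_equal(m$precision[m$class == "low"], 86.7, tolerance = 0.05)
  expect_equal(m$recall, c(88.1, 80.3, 85.9), tolerance = 1e-9)
  # rows of a row-normalized matrix sum to 100 within rounding
  expect_true(all(abs(rowSums(cm) - 100) <= 0.2))
})

test_that("confusion metrics handle identity, uniform and empty-column cases", {
  m_id <- confusion_metrics(diag(3) * 10)
  expect_equal(m_id$precision, rep(100, 3))
  expect_equal(m_id$recall, rep(100, 3))
  m_u <- confusion_metrics(matrix(5, 3, 3))
  expect_equal(m_u$precision, rep(100 / 3, 3))
  expect_equal(m_u$recall, rep(100 / 3, 3))
  cm <- matrix(c(5, 5, 0, 0, 5, 5, 0, 0, 0), 3)  # third class never predicted
  m_e <- confusion_metrics(cm)
  expect_true(m_e$flagged[3])
  expect_true(is.na(m_e$precision[3]))
  expect_false(anyNA(m_e$precision[1:2]))
})

test_that("band t-tests find a planted gamma difference with the right sign", {
  rate <- 200
  mk <- function(n, gamma_scale, seed) {
    withr::with_seed(seed, lapply(seq_len(n), function(i) {
      x <- rnorm(600)
      g <- frustbci:::band_noise(600, rate, c(30, 45)) * gamma_scale
      matrix(x + g, 1)
    }))
  }
  wa <- mk(12, 1, 140); wb <- mk(12, 1.8, 141)
  bs <- band_psd_ttest(wa, wb, rate = rate)
  g <- bs[bs$band == "Gamma", ]
  expect_lt(g$t, 0)                       # A weaker than B
  # the t statistic matches the pooled-variance formula on the band powers
  bp <- function(w) band_power(welch_psd(w[1, ], rate), c(30, 45))
  a <- vapply(wa, bp, 1); b <- vapply(wb, bp, 1)
  s2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / (length(a) + length(b) - 2)
  t_hand <- (mean(a) - mean(b)) / sqrt(s2 * (1 / length(a) + 1 / length(b)))
  expect_equal(g$t, t_hand, tolerance = 1e-9)
  # |t| grows with group size
  wa2 <- c(wa, mk(12, 1, 142)); wb2 <- c(wb, mk(12, 1.8, 143))
  bs2 <- band_psd_ttest(wa2, wb2, rate = rate)
  expect_gt(abs(bs2$t[bs2$band == "Gamma"]), abs(g$t))
  expect_error(band_psd_ttest(wa[1], wb, rate = rate), "at least 2")
})

test_that("evoked spectra peak at the stimulus frequency and scale in dB", {
  t <- seq_len(2000) / 1000
  mk <- function(amp) signal_record(matrix(amp * sin(2 * pi * 10 * t), 1), 1000, "Oz")
  sp1 <- evoked_spectrum(list(mk(10)), "Oz")
  expect_equal(sp1$sd_db, rep(0, nrow(sp1)))                 # single record
  expect_equal(sp1$freq[which.max(sp1$mean_db)], 10)
  sp2 <- evoked_spectrum(list(mk(20)), "oz")                 # case-insensitive
  peak <- function(s) max(s$mean_db)
  expect_equal(peak(sp2) - peak(sp1), 20 * log10(2), tolerance = 0.05)
  expect_error(evoked_spectrum(list(mk(1)), "Pz"), class = "frustbci_lookup_error")
})

test_that("cohort aggregation is permutation-invariant with population sd", {
  v <- c(4.1, 7.3, 5.2, 9.9)
  a <- aggregate_cohort(v)
  b <- aggregate_cohort(rev(v))
  expect_identical(a, b)
  expect_equal(a$sd, round(sqrt(mean((v - mean(v))^2)), 2))
  single <- aggregate_cohort(42)
  expect_equal(single$mean, 42)
  expect_equal(single$sd, 0)
  expect_error(aggregate_cohort(numeric(0)))
})

test_that("paired tests handle degenerate and noise-free differences as documented", {
  a <- c(60, 65, 70, 75, 80)
  eq <- paired_tests(a, a)
  expect_equal(eq$t, 0); expect_equal(eq$p_t, 1); expect_true(eq$degenerate)
  shift <- paired_tests(a + 5, a)
  expect_lt(shift$p_t, 1e-6)
  set.seed(150)
  b <- a + rnorm(5, 2)
  fwd <- paired_tests(a, b); rev <- paired_tests(b, a)
  expect_equal(fwd$t, -rev$t)
  expect_equal(fwd$p_t, rev$p_t)
  expect_equal(fwd$p_wilcoxon, rev$p_wilcoxon)
  expect_error(paired_tests(a[1:4], a[1:4]), "at least 5")
})

test_that("repeated-measures ANOVA matches manual sum-of-squares arithmetic", {
  ident <- matrix(rep(c(3, 5, 4), each = 3), 3)  # identical columns
  expect_equal(rm_anova(t(ident))$f, 0)
  set.seed(151)
  strong <- cbind(rnorm(6, 0, 0.1), rnorm(6, 5, 0.1), rnorm(6, 10, 0.1))
  expect_lt(rm_anova(strong)$p, 0.01)
  # 3 subjects x 3 conditions integer table, manual oracle
  m <- matrix(c(2, 4, 6,
                3, 5, 7,
                4, 7, 9), 3, byrow = TRUE)
  res <- rm_anova(m)
  grand <- mean(m)
  ss_cond <- 3 * sum((colMeans(m) - grand)^2)
  ss_subj <- 3 * sum((rowMeans(m) - grand)^2)
  ss_err <- sum((m - grand)^2) - ss_cond - ss_subj
  f_hand <- (ss_cond / 2) / (ss_err / 4)
  expect_equal(res$f, f_hand, tolerance = 1e-12)
  expect_equal(res$df1, 2); expect_equal(res$df2, 4)
  m_na <- m; m_na[2, 2] <- NA
  expect_error(rm_anova(m_na))
})

test_that("separability metrics recover planted cluster geometry", {
  # two point-clusters with zero spread at distance 5
  x0 <- rbind(matrix(0, 10, 2), cbind(rep(3, 10), rep(4, 10)))
  y0 <- rep(c("a", "b"), each = 10)
  s0 <- separability_metrics(x0, y0)
  expect_equal(s0$centroid_distances$distance, 5)
  expect_true(is.infinite(s0$fisher_ratio) && s0$separated)
  # fully overlapping clusters: probe near chance
  set.seed(160)
  x1 <- matrix(rnorm(400), ncol = 2)
  y1 <- rep(c("a", "b"), each = 100)
  s1 <- separability_metrics(x1, y1, seed = 160)
  expect_lt(abs(s1$probe_accuracy - 50), 12)
  # three Gaussians with known means
  mus <- list(c(0, 0), c(6, 0), c(0, 8))
  x2 <- do.call(rbind, lapply(mus, function(m) {
    sweep(matrix(rnorm(120, sd = 0.5), ncol = 2), 2, m, "+")
  }))
  y2 <- rep(c("a", "b", "c"), each = 60)
  s2 <- separability_metrics(x2, y2, seed = 161)
  got <- s2$centroid_distances
  expect_equal(got$distance[got$class_a == "a" & got$class_b == "b"], 6,
               tolerance = 0.3)
  expect_equal(got$distance[got$class_a == "a" & got$class_b == "c"], 8,
               tolerance = 0.3)
  expect_equal(got$distance[got$class_a == "b" & got$class_b == "c"], 10,
               tolerance = 0.3)
  expect_gt(s2$probe_accuracy, 95)
  expect_error(separability_metrics(x1, rep("a", 200)),
               class = "frustbci_training_error")
})

test_that("resilience scoring applies the 146 threshold exactly", {
  expect_equal(score_resilience(rep(7, 25)),
               list(score = 175, category = "high"))
  expect_equal(score_resilience(rep(1, 25)),
               list(score = 25, category = "general"))
  base <- c(rep(6, 21), rep(5, 4))   # 126 + 20 = 146
  expect_equal(sum(base), 146)
  expect_identical(score_resilience(base)$category, "high")
  base145 <- c(rep(6, 20), rep(5, 5))
  expect_equal(sum(base145), 145)
  expect_identical(score_resilience(base145)$category, "general")
  expect_error(score_resilience(rep(7, 24)), class = "frustbci_validation_error")
  expect_error(score_resilience(c(rep(7, 24), 8)),
               class = "frustbci_validation_error")
})
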