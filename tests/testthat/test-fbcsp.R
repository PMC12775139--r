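test_that("CSP on identical class covariances gives near-0.5 eigenvalues", {
  w <- make_var_windows(c(1, 1), n = 120, len = 800, seed = 10)
  W <- fit_csp_pair(w[1:60], w[61:120], n_pairs = 1)
  expect_equal(attr(W, "eigenvalues"), c(0.5, 0.5), tolerance = 0.05)
})

test_that("CSP recovers the variance-ratio optimum found by brute-force search", {
  # class covariances diag(4, 1) vs diag(1, 4): best variance ratio is 4
  wa <- make_var_windows(c(2, 1), n = 50, len = 600, seed = 20)
  wb <- make_var_windows(c(1, 2), n = 50, len = 600, seed = 21)
  W <- fit_csp_pair(wa, wb, n_pairs = 1)
  ratio_of <- function(v) {
    va <- mean(vapply(wa, function(x) stats::var(drop(t(v) %*% x)), 1))
    vb <- mean(vapply(wb, function(x) stats::var(drop(t(v) %*% x)), 1))
    va / vb
  }
  csp_ratio <- ratio_of(W[, 1, drop = FALSE])
  expect_equal(csp_ratio, 4, tolerance = 0.4)   # planted ratio 4 within 10%
  set.seed(22)
  brute <- max(vapply(1:10000, function(i) {
    v <- stats::rnorm(2); ratio_of(matrix(v / sqrt(sum(v^2)), 2))
  }, 1))
  expect_equal(csp_ratio, brute, tolerance = 0.02 * brute)
})

test_that("CSP eigenvalues are ordered and mirror under label swap", {
  wa <- make_var_windows(c(3, 1, 0.5), n = 40, len = 500, seed = 30)
  wb <- make_var_windows(c(0.5, 1, 3), n = 40, len = 500, seed = 31)
  W <- fit_csp_pair(wa, wb, n_pairs = 1)
  ev <- attr(W, "eigenvalues")
  expect_gt(ev[1], ev[2])                      # top then bottom
  Wswap <- fit_csp_pair(wb, wa, n_pairs = 1)
  ev_swap <- attr(Wswap, "eigenvalues")
  expect_equal(sort(ev), sort(1 - ev_swap), tolerance = 1e-10)
  # the swap's top filter spans the original bottom filter (up to sign/scale)
  cossim <- abs(sum(W[, 2] * Wswap[, 1])) /
    sqrt(sum(W[, 2]^2) * sum(Wswap[, 1]^2))
  expect_gt(cossim, 0.999)
})

test_that("CSP errors on infeasible requests", {
  w <- make_var_windows(c(1, 1), n = 10, len = 100, seed = 1)
  expect_error(fit_csp_pair(w[1], w[2:10], 1), "at least 2")
  expect_error(fit_csp_pair(w[1:5], w[6:10], 2), "exceeds channel count")
})

test_that("log-variance features obey their normalization and invariances", {
  set.seed(40)
  X <- matrix(rnorm(2 * 4000), 2)
  f <- csp_log_variance(X, diag(2))
  expect_equal(sum(exp(f)), 1, tolerance = 1e-12)
  expect_equal(f, rep(log(0.5), 2), tolerance = 0.05)  # white noise, identity
  expect_equal(csp_log_variance(10 * X, diag(2)), f, tolerance = 1e-12)
  expect_error(csp_log_variance(matrix(0, 2, 100), diag(2)),
               class = "frustbci_numeric_error")
  expect_error(csp_log_variance(X, diag(3)), class = "frustbci_shape_error")
})

test_that("plug-in mutual information matches exhaustive counting and ranks noise last", {
  # hand-countable table: x bins perfectly aligned with labels
  x <- c(rep(0.1, 8), rep(0.9, 8)) + seq(0, 0.015, length.out = 16)
  y <- rep(c("a", "b"), each = 8)
  mi <- frustbci:::mi_quantile(x, y, n_bins = 4)
  # exhaustive counting oracle on the discretized table
  br <- unique(quantile(x, seq(0, 1, 0.25)))
  xb <- cut(x, br, include.lowest = TRUE, labels = FALSE)
  tab <- table(xb, y) / length(x)
  mi_hand <- 0
  for (i in seq_len(nrow(tab))) for (j in seq_len(ncol(tab))) {
    p <- tab[i, j]
    if (p > 0) mi_hand <- mi_hand + p * log2(p / (sum(tab[i, ]) * sum(tab[, j])))
  }
  expect_equal(mi, mi_hand, tolerance = 1e-12)
  expect_equal(mi, 1, tolerance = 1e-12)       # one bit: bins determine label

  set.seed(41)
  noise <- rnorm(16)
  expect_lt(frustbci:::mi_quantile(noise, y), mi)
})

test_that("FBCSP selects the discriminative features and separates a planted task", {
  bank <- filter_bank_spec(list(c(8, 12)))
  wa <- make_var_windows(c(2, 0.5), n = 24, len = 400, seed = 50)
  wb <- make_var_windows(c(0.5, 2), n = 24, len = 400, seed = 51)
  labels <- rep(c("left", "right"), each = 24)
  model <- fit_fbcsp(c(wa, wb), labels, bank = bank, m = 1, k_select = 2,
                     rate = 100)
  feats <- predict(model, c(wa, wb), rate = 100)
  expect_identical(dim(feats), c(48L, 2L))
  # the two selected features alone give perfect training separation
  thr_acc <- max(vapply(feats[, 1], function(th) {
    mean((feats[, 1] <= th) == (labels == "right"))
  }, 1))
  expect_equal(thr_acc, 1)
})

test_that("FBCSP selection is pair-complete and places flat-band features low", {
  bank <- filter_bank_spec(list(c(8, 12), c(20, 24)))
  # discriminative structure lives in broadband variance (both bands),
  # so instead plant it only in 8-12 by band-limited signals
  mk <- function(ch_amp, n, seed) {
    withr::with_seed(seed, lapply(seq_len(n), function(i) {
      t <- seq_len(500) / 250
      base <- rbind(rnorm(500, sd = 0.5), rnorm(500, sd = 0.5))
      base[1, ] <- base[1, ] + ch_amp * sin(2 * pi * 10 * t + runif(1, 0, 6))
      base
    }))
  }
  wa <- mk(2, 20, 60); wb <- mk(0.2, 20, 61)
  model <- fit_fbcsp(c(wa, wb), rep(c("A", "B"), each = 20), bank = bank,
                     m = 1, k_select = 2, rate = 250)
  meta <- tidy(model)
  # every selected feature has its CSP partner selected too
  sel <- meta[meta$selected, ]
  expect_true(all(sel$partner %in% sel$col))
  # the planted 8-12 band outranks the flat 20-24 band
  expect_true(all(sort(meta$mi[meta$band == 1], decreasing = TRUE)[1] >
                    max(meta$mi[meta$band == 2])))
})

test_that("the FBCSP transform is deterministic, order-equivariant and strict on shape", {
  bank <- filter_bank_spec(list(c(8, 12)))
  w <- make_var_windows(c(1, 2), n = 20, len = 300, seed = 70)
  labels <- rep(c("x", "y"), 10)
  model <- fit_fbcsp(w, labels, bank = bank, m = 1, k_select = 2, rate = 100)
  f1 <- predict(model, w, rate = 100)
  f2 <- predict(model, w, rate = 100)
  expect_identical(f1, f2)
  perm <- sample(20)
  expect_equal(predict(model, w[perm], rate = 100), f1[perm, ], tolerance = 1e-12)
  expect_error(predict(model, make_var_windows(c(1, 1, 1), 2, 300), rate = 100),
               class = "frustbci_shape_error")
})

test_that("CSP filters are invariant to a common invertible mixing (up to sign)", {
  wa <- make_var_windows(c(2, 0.6), n = 40, len = 2000, seed = 80)
  wb <- make_var_windows(c(0.6, 2), n = 40, len = 2000, seed = 81)
  A <- matrix(c(1.2, 0.4, -0.3, 0.9), 2)
  mix <- function(ws) lapply(ws, function(x) A %*% x)
  W0 <- fit_csp_pair(wa, wb, 1)
  W1 <- fit_csp_pair(mix(wa), mix(wb), 1)
  # the filters recover the same sources up to sign: w1' (A x) == +/- w0' x.
  # (eigenvalues are only near-invariant here because per-window trace
  # normalization and shrinkage weigh the two classes slightly differently
  # after mixing)
  x <- wa[[1]]
  for (j in 1:2) {
    p0 <- drop(t(W0[, j]) %*% x)
    p1 <- drop(t(W1[, j]) %*% (A %*% x))
    expect_equal(abs(cor(p0, p1)), 1, tolerance = 1e-3)
  }
  expect_equal(attr(W0, "eigenvalues"), attr(W1, "eigenvalues"),
               tolerance = 0.1)
})
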