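mi3 <- function(a, b, c) rbind(a, b, c)

test_that("hard switching commits to the most probable state's model", {
  mi <- mi3(c(0.2, 0.8), c(0.9, 0.1), c(0.3, 0.7))
  # the low state wins at [0.40, 0.38, 0.22]; only its model decides
  fd <- fuse_probabilities(c(0.40, 0.38, 0.22), mi, "1")
  expect_identical(fd$s_hat, 0L)
  expect_equal(fd$p_final, c(0.2, 0.8))
  expect_identical(fd$y_hat, "right")
  # degenerate state distribution: other models are irrelevant
  fd2 <- fuse_probabilities(c(1, 0, 0), mi3(c(0.9, 0.1), c(0, 1), c(0, 1)), "1")
  expect_identical(fd2$y_hat, "left")
  # state ties resolve to the lowest index (verified against both candidates)
  fd3 <- fuse_probabilities(c(0.5, 0.5, 0), mi, "1")
  expect_identical(fd3$s_hat, 0L)
  expect_equal(fd3$p_final, mi[1, ])
})

test_that("soft fusion computes the probability-weighted mixture", {
  mi <- mi3(c(0.9, 0.1), c(0.4, 0.6), c(0.2, 0.8))
  fd <- fuse_probabilities(c(0.5, 0.3, 0.2), mi, "2")
  expect_equal(fd$p_final, c(0.61, 0.39), tolerance = 1e-12)
  expect_identical(fd$y_hat, "left")
  # reduction: certainty about the state makes method 2 equal method 1
  for (s in 1:3) {
    p_f <- c(0, 0, 0); p_f[s] <- 1
    expect_equal(fuse_probabilities(p_f, mi, "2")$p_final,
                 fuse_probabilities(p_f, mi, "1")$p_final)
  }
  # MI tie goes left
  expect_identical(
    fuse_probabilities(c(1, 0, 0), mi3(c(0.5, 0.5), c(1, 0), c(1, 0)), "2")$y_hat,
    "left")
})

test_that("fused probabilities normalize for arbitrary valid inputs", {
  set.seed(110)
  for (i in 1:50) {
    p_f <- as.vector(stats::rgamma(3, 1)); p_f <- p_f / sum(p_f)
    q <- t(vapply(1:3, function(j) {
      v <- stats::runif(1); c(v, 1 - v)
    }, numeric(2)))
    for (m in c("1", "2")) {
      expect_equal(sum(fuse_probabilities(p_f, q, m)$p_final), 1,
                   tolerance = 1e-12)
    }
  }
})

test_that("method 3 ignores the state classifier entirely", {
  mi <- mi3(c(0.2, 0.8), c(0.9, 0.1), c(0.3, 0.7))
  fd <- fuse_probabilities(c(0.40, 0.38, 0.22), mi, "3-1", p_all = c(0.7, 0.3))
  expect_identical(fd$y_hat, "left")
  expect_true(is.na(fd$s_hat))
  # perturbing p_f never changes the decision
  fd2 <- fuse_probabilities(c(0.05, 0.05, 0.9), mi, "3-1", p_all = c(0.7, 0.3))
  expect_identical(fd$p_final, fd2$p_final)
  # the two variants share the decision rule; they differ only in training data
  fd3 <- fuse_probabilities(c(0.4, 0.4, 0.2), mi, "3-2", p_all = c(0.7, 0.3))
  expect_identical(fd3$p_final, fd$p_final)
  expect_error(fuse_probabilities(c(1, 0, 0), mi, "3-9", p_all = c(1, 0)))
})

test_that("identical per-state models make all methods agree", {
  q <- c(0.35, 0.65)
  mi <- mi3(q, q, q)
  set.seed(111)
  for (i in 1:20) {
    p_f <- as.vector(stats::rgamma(3, 1)); p_f <- p_f / sum(p_f)
    y1 <- fuse_probabilities(p_f, mi, "1")$y_hat
    y2 <- fuse_probabilities(p_f, mi, "2")$y_hat
    y3 <- fuse_probabilities(p_f, mi, "3-1", p_all = q)$y_hat
    expect_identical(y1, y2)
    expect_identical(y2, y3)
  }
})

test_that("soft fusion is 1-Lipschitz in the state probabilities", {
  set.seed(112)
  mi <- mi3(c(0.9, 0.1), c(0.4, 0.6), c(0.2, 0.8))
  p_f <- c(0.5, 0.3, 0.2)
  base <- fuse_probabilities(p_f, mi, "2")$p_final
  for (i in 1:20) {
    eps <- stats::runif(1, 0, 0.1)
    d <- stats::rnorm(3); d <- d - mean(d)
    d <- eps * d / max(abs(d))
    p2 <- p_f + d
    if (any(p2 < 0)) next
    pert <- fuse_probabilities(p2 / sum(p2), mi, "2")$p_final
    expect_lte(max(abs(pert - base)), eps + 1e-12)
  }
})

test_that("window-level fusion produces full decision traces and guards state", {
  cohort <- tiny_cohort(tpsc = 4, tps1 = 2, seed = 120)
  cfg <- fast_cfg(seed = 120)
  ep <- frustbci:::prep_epochs(cohort$epochs[cohort$epochs$stage == 2, ], cfg)
  e2 <- frustbci:::epoch_fb_covs(ep, cfg)
  state_clf <- train_state_classifier(e2$fc, e2$meta$state_label, cfg)
  bank <- train_mi_bank(e2$fc, e2$meta$mi_label, e2$meta$state_label,
                        cfg = cfg, state_clf = state_clf)
  dec <- fuse(bank, e2$fc, method = "2")
  expect_equal(nrow(dec), e2$fc$n)
  expect_equal(dec$pfL + dec$pfR, rep(1, nrow(dec)), tolerance = 1e-9)
  expect_true(all(dec$y_hat %in% c("left", "right")))
  # method 2 trace equals the hand-computed weighted sum
  i <- 5
  expect_equal(dec$pfL[i],
               unname(dec$p0[i] * dec$q0L[i] + dec$p1[i] * dec$q1L[i] +
                        dec$p2[i] * dec$q2L[i]),
               tolerance = 1e-9)
  # no state classifier -> methods 1/2 refuse, method 3-1 still works
  bank_nostate <- bank; bank_nostate$state_clf <- NULL
  expect_error(method1_hard_switch(e2$fc, bank_nostate),
               class = "frustbci_state_error")
  expect_error(method3_baseline(e2$fc, bank, variant = "9"),
               class = "frustbci_param_error")
  dec3 <- method3_baseline(e2$fc, bank_nostate, "3-1")
  expect_equal(nrow(dec3), e2$fc$n)
  expect_true(all(is.na(dec3$s_hat)))
})

test_that("the entropy gate reroutes only maximally uncertain windows", {
  cohort <- tiny_cohort(tpsc = 4, tps1 = 2, seed = 121)
  cfg <- fast_cfg(seed = 121)
  ep <- frustbci:::prep_epochs(cohort$epochs[cohort$epochs$stage == 2, ], cfg)
  e2 <- frustbci:::epoch_fb_covs(ep, cfg)
  state_clf <- train_state_classifier(e2$fc, e2$meta$state_label, cfg)
  bank <- train_mi_bank(e2$fc, e2$meta$mi_label, e2$meta$state_label,
                        cfg = cfg, state_clf = state_clf)
  off <- fuse(bank, e2$fc, method = "2")
  gate_all <- fuse(bank, e2$fc, method = "2", entropy_fallback = 0)
  gate_none <- fuse(bank, e2$fc, method = "2", entropy_fallback = log2(3) + 1)
  expect_true(all(gate_all$method == "3-1"))   # threshold 0 reroutes all
  expect_identical(gate_none[c("pfL", "pfR", "y_hat")],
                   off[c("pfL", "pfR", "y_hat")])
  ref <- method3_baseline(e2$fc, bank, "3-1")
  expect_identical(gate_all$y_hat, ref$y_hat)
})
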