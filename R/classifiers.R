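# Classifier backends over FBCSP features.
#
# SVM: e1071 (libsvm), RBF kernel. Probabilities come from an in-package
# Platt sigmoid fitted on stratified 3-fold cross-validated decision values
# (folds drawn from the pipeline seed, so fits are bit-reproducible), with
# Wu-Lin-Weng pairwise coupling for more than two classes.
#
# LDA: shrinkage-regularized linear discriminant analysis (Ledoit-Wolf
# shrinkage of the pooled covariance toward a scaled identity), with Gaussian
# posteriors as probabilities.

# Platt sigmoid fit (regularized ML, Newton iterations per Lin/Lin/Weng)
platt_fit <- function(deci, y01) {
  prior1 <- sum(y01 == 1); prior0 <- sum(y01 == 0)
  hi <- (prior1 + 1) / (prior1 + 2); lo <- 1 / (prior0 + 2)
  t <- ifelse(y01 == 1, hi, lo)
  A <- 0; B <- log((prior0 + 1) / (prior1 + 1))
  fval <- function(A, B) {
    f <- deci * A + B
    sum(ifelse(f >= 0, t * f + log1p(exp(-f)), (t - 1) * f + log1p(exp(f))))
  }
  Fv <- fval(A, B)
  for (it in 1:100) {
    f <- deci * A + B
    p <- ifelse(f >= 0, exp(-f) / (1 + exp(-f)), 1 / (1 + exp(f)))
    q <- 1 - p
    d1 <- t - p
    d2 <- p * q
    g1 <- sum(deci * d1); g2 <- sum(d1)
    if (abs(g1) < 1e-5 && abs(g2) < 1e-5) break
    h11 <- sum(deci^2 * d2) + 1e-12
    h22 <- sum(d2) + 1e-12
    h21 <- sum(deci * d2)
    det <- h11 * h22 - h21^2
    dA <- -(h22 * g1 - h21 * g2) / det
    dB <- -(-h21 * g1 + h11 * g2) / det
    gd <- g1 * dA + g2 * dB
    step <- 1
    repeat {
      An <- A + step * dA; Bn <- B + step * dB
      Fn <- fval(An, Bn)
      if (Fn < Fv + 1e-4 * step * gd || step < 1e-10) break
      step <- step / 2
    }
    A <- A + step * dA; B <- B + step * dB; Fv <- fval(A, B)
  }
  c(A = A, B = B)
}

platt_prob <- function(deci, ab) {
  f <- deci * ab[["A"]] + ab[["B"]]
  ifelse(f >= 0, exp(-f) / (1 + exp(-f)), 1 / (1 + exp(f)))
}

# Wu-Lin-Weng pairwise coupling (second method, as in libsvm):
# r[i, j] = P(class i | class i or j) for i != j -> class probabilities p
pairwise_couple <- function(r) {
  k <- nrow(r)
  if (k == 2) {
    p <- c(r[1, 2], r[2, 1])
    return(p / sum(p))
  }
  Q <- matrix(0, k, k)
  for (t in seq_len(k)) {
    for (j in seq_len(k)) {
      if (j == t) Q[t, t] <- sum(r[-t, t]^2)
      else Q[t, j] <- -r[j, t] * r[t, j]
    }
  }
  p <- rep(1 / k, k)
  for (it in 1:200) {
    Qp <- as.vector(Q %*% p)
    pQp <- sum(p * Qp)
    if (max(abs(Qp - pQp)) < 1e-10) break
    for (t in seq_len(k)) {
      diff <- (-Qp[t] + pQp) / Q[t, t]
      p[t] <- p[t] + diff
      pQp <- (pQp + diff * (diff * Q[t, t] + 2 * Qp[t])) / (1 + diff)^2
      Qp <- (Qp + diff * Q[t, ]) / (1 + diff)
      p <- p / (1 + diff)
    }
  }
  pmin(pmax(p, 0), 1) / sum(pmin(pmax(p, 0), 1))
}

# Decision values with libsvm's pair naming normalized to a canonical
# orientation: libsvm orders classes by first appearance in the training
# data, so the same pair can surface as "a/b" or "b/a" across refits.
svm_decision_matrix <- function(fit, x, pair_names = NULL) {
  dv <- attr(predict(fit, x, decision.values = TRUE), "decision.values")
  if (is.null(pair_names)) return(dv)
  out <- matrix(NA_real_, nrow(dv), length(pair_names),
                dimnames = list(NULL, pair_names))
  rev_name <- function(pn) paste(rev(strsplit(pn, "/", fixed = TRUE)[[1]]),
                                 collapse = "/")
  for (pn in pair_names) {
    if (pn %in% colnames(dv)) out[, pn] <- dv[, pn]
    else if (rev_name(pn) %in% colnames(dv)) out[, pn] <- -dv[, rev_name(pn)]
  }
  out
}

canonical_pairs <- function(classes) {
  cmb <- utils::combn(classes, 2)
  vapply(seq_len(ncol(cmb)), function(i) paste(cmb[, i], collapse = "/"), "")
}

fit_backend_svm <- function(x, y, cfg) {
  classes <- levels(y)
  cost <- cfg$svm_c %||% 1
  pooled_var <- mean(apply(x, 2, stats::var))
  gamma <- 1 / (ncol(x) * max(pooled_var, .Machine$double.eps))
  fit <- e1071::svm(x, y, kernel = "radial", cost = cost, gamma = gamma,
                    scale = FALSE)
  # cross-validated decision values for Platt calibration
  folds <- stratified_folds(y, k = 3, seed = derive_seed(cfg$seed %||% 1, "platt"))
  pair_names <- canonical_pairs(classes)
  cv_dv <- matrix(NA_real_, nrow(x), length(pair_names),
                  dimnames = list(NULL, pair_names))
  for (f in sort(unique(folds))) {
    tr <- folds != f
    if (length(unique(y[tr])) < length(classes)) { tr <- rep(TRUE, nrow(x)) }
    sub <- e1071::svm(x[tr, , drop = FALSE], droplevels(y[tr]),
                      kernel = "radial", cost = cost, gamma = gamma,
                      scale = FALSE)
    dv <- svm_decision_matrix(sub, x[folds == f, , drop = FALSE], pair_names)
    cv_dv[folds == f, ] <- dv
  }
  sigmoids <- lapply(pair_names, function(pn) {
    ab <- strsplit(pn, "/", fixed = TRUE)[[1]]
    rows <- y %in% ab & !is.na(cv_dv[, pn])
    platt_fit(cv_dv[rows, pn], as.integer(y[rows] == ab[1]))
  })
  names(sigmoids) <- pair_names
  list(kind = "svm", fit = fit, sigmoids = sigmoids, classes = classes,
       gamma = gamma, cost = cost)
}

predict_backend_svm <- function(bk, x) {
  classes <- bk$classes
  dv <- svm_decision_matrix(bk$fit, x, names(bk$sigmoids))
  out <- matrix(0, nrow(x), length(classes), dimnames = list(NULL, classes))
  for (i in seq_len(nrow(x))) {
    r <- matrix(0.5, length(classes), length(classes),
                dimnames = list(classes, classes))
    for (pn in colnames(dv)) {
      ab <- strsplit(pn, "/", fixed = TRUE)[[1]]
      pr <- platt_prob(dv[i, pn], bk$sigmoids[[pn]])
      pr <- min(max(pr, 1e-7), 1 - 1e-7)
      r[ab[1], ab[2]] <- pr
      r[ab[2], ab[1]] <- 1 - pr
    }
    out[i, ] <- pairwise_couple(r)
  }
  out
}

fit_backend_lda <- function(x, y, cfg) {
  classes <- levels(y)
  means <- t(vapply(classes, function(cl) colMeans(x[y == cl, , drop = FALSE]),
                    numeric(ncol(x))))
  centered <- x - means[as.integer(y), , drop = FALSE]
  lw <- ledoit_wolf_cov_pooled(centered)
  prec <- tryCatch(solve(lw$sigma), error = function(e) {
    solve(lw$sigma + diag(1e-8 * mean(diag(lw$sigma)), ncol(x)))
  })
  priors <- as.numeric(table(y)[classes]) / length(y)
  list(kind = "lda", means = means, prec = prec, priors = priors,
       classes = classes, lambda = lw$lambda)
}

# pooled within-class covariance with Ledoit-Wolf intensity (rows already
# centered on their class mean)
ledoit_wolf_cov_pooled <- function(xc) {
  n <- nrow(xc); p <- ncol(xc)
  s <- crossprod(xc) / n
  mu <- sum(diag(s)) / p
  d2 <- sum((s - diag(mu, p))^2)
  if (d2 < .Machine$double.eps) return(list(sigma = s + diag(1e-10, p), lambda = 0))
  b2 <- 0
  for (i in seq_len(n)) b2 <- b2 + sum((tcrossprod(xc[i, ]) - s)^2)
  b2 <- min(b2 / n^2, d2)
  lambda <- b2 / d2
  list(sigma = (1 - lambda) * s + lambda * diag(mu, p), lambda = lambda)
}

predict_backend_lda <- function(bk, x) {
  k <- length(bk$classes)
  disc <- matrix(0, nrow(x), k, dimnames = list(NULL, bk$classes))
  for (j in seq_len(k)) {
    mu <- bk$means[j, ]
    disc[, j] <- x %*% (bk$prec %*% mu) -
      0.5 * sum(mu * (bk$prec %*% mu)) + log(bk$priors[j])
  }
  disc <- disc - apply(disc, 1, max)
  p <- exp(disc)
  p / rowSums(p)
}

# ---------------------------------------------------------------------------

#' Choose a classifier backend by inner cross-validation
#'
#' Runs a stratified 5-fold comparison of the RBF-SVM and shrinkage-LDA
#' backends on the training features only, and returns the tag of the more
#' accurate one; ties go to the SVM.
#'
#' @param features Numeric feature matrix (rows = windows).
#' @param labels Class labels.
#' @param cfg A [pipeline_config()] (seed, SVM cost).
#' @return `"svm"` or `"lda"`.
#' @export
select_backend <- function(features, labels, cfg = pipeline_config(seed = 1)) {
  y <- factor(labels)
  assert_that(nlevels(y) >= 2, "need at least 2 classes to select a backend",
              class = "training_error")
  folds <- stratified_folds(y, k = 5, seed = derive_seed(cfg$seed, "backend"))
  acc <- c(svm = 0, lda = 0)
  n <- 0
  for (f in sort(unique(folds))) {
    tr <- folds != f
    xs <- scale(features[tr, , drop = FALSE])
    ctr <- attr(xs, "scaled:center"); sc <- attr(xs, "scaled:scale")
    sc[sc == 0 | !is.finite(sc)] <- 1
    xte <- sweep(sweep(features[!tr, , drop = FALSE], 2, ctr), 2, sc, "/")
    xs <- sweep(sweep(features[tr, , drop = FALSE], 2, ctr), 2, sc, "/")
    for (kind in c("svm", "lda")) {
      bk <- if (kind == "svm") fit_backend_svm(xs, droplevels(y[tr]), cfg)
            else fit_backend_lda(xs, droplevels(y[tr]), cfg)
      pr <- if (kind == "svm") predict_backend_svm(bk, xte)
            else predict_backend_lda(bk, xte)
      pred <- colnames(pr)[max.col(pr, ties.method = "first")]
      acc[kind] <- acc[kind] + sum(pred == as.character(y[!tr]))
    }
    n <- n + sum(!tr)
  }
  if (acc["lda"] > acc["svm"]) "lda" else "svm"
}

# ---------------------------------------------------------------------------
# FBCSP + backend classifier
# ---------------------------------------------------------------------------

# Fit a full FBCSP + backend classifier on windows (or cached covariances).
train_classifier <- function(windows, labels, cfg, rate = NULL) {
  fc <- as_fb_covs(windows, cfg$bank, rate %||% attr_rate(windows))
  # preserve supplied level order (low/mid/high, left/right); sort otherwise
  y <- if (is.factor(labels)) droplevels(labels) else factor(as.character(labels))
  fb <- fit_fbcsp(fc, as.character(labels), bank = cfg$bank, m = cfg$m,
                  k_select = cfg$k_select)
  feats <- predict(fb, fc)
  ctr <- colMeans(feats)
  sc <- apply(feats, 2, stats::sd)
  sc[sc == 0 | !is.finite(sc)] <- 1
  xs <- sweep(sweep(feats, 2, ctr), 2, sc, "/")
  backend <- cfg$backend
  if (backend == "auto") backend <- select_backend(xs, y, cfg)
  bk <- if (backend == "svm") fit_backend_svm(xs, y, cfg)
        else fit_backend_lda(xs, y, cfg)
  structure(list(fbcsp = fb, backend = backend, backend_fit = bk,
                 center = ctr, scale = sc, classes = levels(y), cfg = cfg),
            class = "frustbci_clf")
}

attr_rate <- function(x) {
  if (inherits(x, "window_set")) x$rate
  else if (inherits(x, "fb_covs")) x$rate
  else NULL
}

#' Predict class probabilities from a fitted FBCSP classifier
#'
#' @param clf A classifier fitted by the training functions of this package.
#' @param windows Windows (window set, list of matrices, or cached
#'   [fb_covariances()]).
#' @param rate Sampling rate for bare matrix lists.
#' @return Matrix of class probabilities, one row per window; rows sum to 1.
#' @export
predict_proba <- function(clf, windows, rate = NULL) {
  assert_that(inherits(clf, "frustbci_clf"), "not a fitted frustbci classifier",
              class = "state_error")
  feats <- predict(clf$fbcsp, windows, rate = rate)
  xs <- sweep(sweep(feats, 2, clf$center), 2, clf$scale, "/")
  p <- if (clf$backend == "svm") predict_backend_svm(clf$backend_fit, xs)
       else predict_backend_lda(clf$backend_fit, xs)
  p / rowSums(p)
}

#' @export
print.frustbci_clf <- function(x, ...) {
  cat(sprintf("<frustbci_clf> %s backend, classes: %s\n",
              x$backend, paste(x$classes, collapse = ", ")))
  invisible(x)
}
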