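#' Filter bank specification
#'
#' The canonical FBCSP layout is nine 4 Hz bands spanning 4-40 Hz
#' (4-8, 8-12, ..., 36-40).
#'
#' @param bands List (or 2-column matrix) of `c(low, high)` band edges in Hz.
#' @return A `filter_bank_spec`: list of band-edge pairs.
#' @export
filter_bank_spec <- function(bands = NULL) {
  if (is.null(bands)) {
    lo <- seq(4, 36, by = 4)
    bands <- lapply(lo, function(l) c(l, l + 4))
  }
  if (is.matrix(bands)) bands <- lapply(seq_len(nrow(bands)), function(i) bands[i, ])
  assert_that(length(bands) >= 1, "filter bank must contain at least one band")
  for (b in bands) {
    assert_that(length(b) == 2 && b[1] < b[2],
                "each band must be c(low, high) with low < high")
  }
  structure(bands, class = "filter_bank_spec")
}

# ---------------------------------------------------------------------------
# covariance machinery
# ---------------------------------------------------------------------------

# raw sample covariance of a (mean-removed) window, denominator T
window_cov <- function(x) {
  xc <- x - rowMeans(x)
  tcrossprod(xc) / ncol(x)
}

# Average of per-window covariances with analytic shrinkage toward nu*I
# (nu = mean variance). The intensity is estimated from the dispersion of
# the window covariances around their mean, so short windows with many
# channels are pulled toward a well-conditioned target.
shrink_average_cov <- function(covs) {
  K <- length(covs)
  C <- nrow(covs[[1]])
  sbar <- Reduce(`+`, covs) / K
  nu <- sum(diag(sbar)) / C
  target <- diag(nu, C)
  denom <- sum((sbar - target)^2)
  if (K < 2 || denom < .Machine$double.eps) {
    lambda <- if (denom < .Machine$double.eps) 1 else 0
  } else {
    disp <- mean(vapply(covs, function(s) sum((s - sbar)^2), 1)) / (K - 1)
    lambda <- max(0, min(1, disp / denom))
  }
  list(sigma = (1 - lambda) * sbar + lambda * target, lambda = lambda)
}

# ---------------------------------------------------------------------------
# CSP
# ---------------------------------------------------------------------------

#' Fit a common spatial pattern filter pair set for two classes
#'
#' Solves the generalized eigenproblem `Sigma_A w = lambda (Sigma_A +
#' Sigma_B) w` on trace-normalized, shrinkage-regularized average class
#' covariances (whitening + symmetric eigendecomposition). Returns the `m`
#' most extreme eigenvector pairs: columns `1..m` have the largest
#' eigenvalues (high class-A variance share, descending), columns
#' `m+1..2m` the smallest (ascending from the minimum). Column `j` is paired
#' with column `j + m`. Each filter satisfies
#' `w' (Sigma_A + Sigma_B) w = 1`.
#'
#' @param windows_a,windows_b Lists of channels x samples matrices (or of
#'   precomputed channel covariance matrices).
#' @param n_pairs Number of filter pairs `m`; `2 * n_pairs <= n_channels`.
#' @return A channels x `2 * n_pairs` filter matrix with attributes
#'   `eigenvalues` (the selected generalized eigenvalues) and `lambda`
#'   (shrinkage intensities for the two classes).
#' @export
fit_csp_pair <- function(windows_a, windows_b, n_pairs = 2) {
  assert_that(length(windows_a) >= 2 && length(windows_b) >= 2,
              "need at least 2 windows per class")
  as_cov <- function(w) if (ncol(w) == nrow(w) && isSymmetric(unname(w), tol = 1e-8))
    w else window_cov(w)
  covs_a <- lapply(windows_a, as_cov)
  covs_b <- lapply(windows_b, as_cov)
  C <- nrow(covs_a[[1]])
  assert_that(C >= 2, "need at least 2 channels")
  assert_that(2 * n_pairs <= C,
              sprintf("2 * n_pairs = %d exceeds channel count %d", 2 * n_pairs, C))
  tn <- function(s) s / sum(diag(s))
  sa <- shrink_average_cov(lapply(covs_a, tn))
  sb <- shrink_average_cov(lapply(covs_b, tn))
  comp <- sa$sigma + sb$sigma
  ec <- eigen((comp + t(comp)) / 2, symmetric = TRUE)
  tol <- max(ec$values) * C * .Machine$double.eps * 1e3
  if (any(ec$values <= tol)) {
    stop_frustbci(paste(
      "composite covariance is rank-deficient after regularization;",
      "increase shrinkage or supply more/longer windows"), "numeric_error")
  }
  P <- diag(1 / sqrt(ec$values)) %*% t(ec$vectors)          # whitener
  S <- P %*% sa$sigma %*% t(P)
  es <- eigen((S + t(S)) / 2, symmetric = TRUE)             # descending values
  W_full <- t(P) %*% es$vectors
  sel <- c(seq_len(n_pairs), C - seq_len(n_pairs) + 1L)     # top m, bottom m
  W <- W_full[, sel, drop = FALSE]
  # deterministic sign: largest-magnitude coefficient positive
  for (j in seq_len(ncol(W))) {
    k <- which.max(abs(W[, j]))
    if (W[k, j] < 0) W[, j] <- -W[, j]
  }
  attr(W, "eigenvalues") <- es$values[sel]
  attr(W, "lambda") <- c(a = sa$lambda, b = sb$lambda)
  W
}

#' Normalized log-variance CSP features for one window
#'
#' `f_j = log(var(w_j' X) / sum_k var(w_k' X))`, the standard CSP readout;
#' `sum_j exp(f_j) = 1` and the features are invariant to rescaling of `X`.
#'
#' @param x Channels x samples window matrix.
#' @param w Spatial filter matrix (channels x n_filters).
#' @return Numeric feature vector of length `ncol(w)`.
#' @export
csp_log_variance <- function(x, w) {
  assert_that(nrow(x) == nrow(w),
              sprintf("window has %d channels but filters expect %d",
                      nrow(x), nrow(w)), class = "shape_error")
  log_variance_from_cov(window_cov(x), w)
}

log_variance_from_cov <- function(sigma, w) {
  v <- colSums(w * (sigma %*% w))        # diag(w' Sigma w)
  if (any(v <= 0)) {
    stop_frustbci("zero-variance projection: degenerate window", "numeric_error")
  }
  log(v / sum(v))
}

# ---------------------------------------------------------------------------
# band-filtered covariance cache
# ---------------------------------------------------------------------------

#' Band-filtered window covariances for a filter bank
#'
#' Computes, for every window and every band of the bank, the channel
#' covariance of the zero-phase band-filtered window. All CSP fitting and
#' log-variance feature extraction run on these matrices, so they can be
#' computed once and shared across classifiers and cross-validation folds.
#'
#' @param windows A `window_set` or list of channels x samples matrices.
#' @param bank A [filter_bank_spec()].
#' @param rate Sampling rate (taken from the window set when present).
#' @return An `fb_covs` object: per-band lists of covariance matrices.
#' @export
fb_covariances <- function(windows, bank = filter_bank_spec(), rate = NULL) {
  if (inherits(windows, "window_set")) {
    rate <- windows$rate
    windows <- windows$windows
  }
  assert_that(!is.null(rate), "rate is required")
  flts <- lapply(bank, function(b) butter_bandpass(b[1], b[2], rate))
  covs <- lapply(seq_along(bank), function(bi) {
    lapply(windows, function(w) window_cov(filtfilt_mat(flts[[bi]], w)))
  })
  structure(list(covs = covs, n = length(windows), bank = bank, rate = rate,
                 n_channels = nrow(windows[[1]])),
            class = "fb_covs")
}

#' @export
`[.fb_covs` <- function(x, i, ...) {
  i <- seq_len(x$n)[i]
  structure(list(covs = lapply(x$covs, function(b) b[i]), n = length(i),
                 bank = x$bank, rate = x$rate, n_channels = x$n_channels),
            class = "fb_covs")
}

as_fb_covs <- function(x, bank, rate) {
  if (inherits(x, "fb_covs")) x else fb_covariances(x, bank, rate)
}

# ---------------------------------------------------------------------------
# mutual information feature selection (MIBIF)
# ---------------------------------------------------------------------------

# plug-in mutual information (bits) between a quantile-discretized feature
# and the class label
mi_quantile <- function(x, y, n_bins = 4) {
  br <- unique(stats::quantile(x, probs = seq(0, 1, length.out = n_bins + 1)))
  if (length(br) < 2) return(0)
  xb <- cut(x, breaks = br, include.lowest = TRUE, labels = FALSE)
  tab <- table(xb, y)
  p <- tab / sum(tab)
  px <- rowSums(p); py <- colSums(p)
  nz <- p > 0
  sum(p[nz] * log2(p[nz] / outer(px, py)[nz]))
}

# ---------------------------------------------------------------------------
# FBCSP model
# ---------------------------------------------------------------------------

#' Fit a filter-bank CSP feature extractor
#'
#' Band-filters each window with the bank, fits CSP per band (one-vs-rest per
#' class when more than two classes are present), computes normalized
#' log-variance features, ranks features by plug-in mutual information with
#' the label (quantile discretization, 4 bins; ties broken by lower feature
#' index) and retains the top `k_select` with CSP pair-completion: whenever a
#' feature is kept, its paired filter's feature is kept too.
#'
#' @param windows A `window_set`, list of window matrices, or a precomputed
#'   [fb_covariances()] object.
#' @param labels Class label per window (2 or more classes).
#' @param bank A [filter_bank_spec()].
#' @param m Number of CSP filter pairs per band and sub-problem.
#' @param k_select Number of features retained before pair-completion.
#' @param rate Sampling rate, required when `windows` is a bare list.
#' @return A fitted `csp_bank_model`.
#' @export
fit_fbcsp <- function(windows, labels, bank = filter_bank_spec(), m = 2,
                      k_select = 4, rate = NULL) {
  fc <- as_fb_covs(windows, bank, rate)
  labels <- as.character(labels)
  assert_that(length(labels) == fc$n, "one label per window is required")
  classes <- sort(unique(labels))
  assert_that(length(classes) >= 2, "need at least 2 classes",
              class = "training_error")
  problems <- if (length(classes) == 2) {
    list(list(name = paste(classes, collapse = "_vs_"),
              a = labels == classes[1]))
  } else {
    lapply(classes, function(cl) list(name = paste0(cl, "_vs_rest"),
                                      a = labels == cl))
  }
  n_bands <- length(fc$bank)
  filters <- vector("list", length(problems))
  meta <- list()
  col <- 0L
  for (pi in seq_along(problems)) {
    pr <- problems[[pi]]
    filters[[pi]] <- vector("list", n_bands)
    for (bi in seq_len(n_bands)) {
      filters[[pi]][[bi]] <- fit_csp_pair(fc$covs[[bi]][pr$a],
                                          fc$covs[[bi]][!pr$a], n_pairs = m)
      for (j in seq_len(2 * m)) {
        col <- col + 1L
        meta[[col]] <- tibble::tibble(
          col = col, problem = pr$name, band = bi,
          low_hz = fc$bank[[bi]][1], high_hz = fc$bank[[bi]][2],
          filter = j, partner = col + (if (j <= m) m else -m))
      }
    }
  }
  meta <- dplyr::bind_rows(meta)
  model <- structure(list(bank = fc$bank, m = m, k_select = k_select,
                          classes = classes, filters = filters,
                          feature_meta = meta, selected = seq_len(nrow(meta)),
                          rate = fc$rate, n_channels = fc$n_channels),
                     class = "csp_bank_model")
  feats <- fbcsp_features_all(model, fc)
  assert_that(k_select <= ncol(feats),
              sprintf("k_select = %d exceeds the %d available features",
                      k_select, ncol(feats)))
  mi <- vapply(seq_len(ncol(feats)), function(j) mi_quantile(feats[, j], labels), 1)
  ranked <- order(-mi, seq_along(mi))            # ties -> lower index
  top <- ranked[seq_len(k_select)]
  selected <- sort(unique(c(top, meta$partner[top])))
  model$selected <- selected
  model$mi_scores <- mi
  model
}

# all features (before selection), n x (problems * bands * 2m)
fbcsp_features_all <- function(model, fc) {
  n_bands <- length(model$bank)
  cols <- list()
  for (pi in seq_along(model$filters)) {
    for (bi in seq_len(n_bands)) {
      W <- model$filters[[pi]][[bi]]
      f <- t(vapply(fc$covs[[bi]],
                    function(s) log_variance_from_cov(s, W),
                    numeric(ncol(W))))
      cols[[length(cols) + 1]] <- f
    }
  }
  out <- do.call(cbind, cols)
  colnames(out) <- paste0("f", seq_len(ncol(out)))
  out
}

#' Apply a fitted FBCSP transform
#'
#' Deterministic: identical inputs give identical feature matrices.
#'
#' @param object A fitted `csp_bank_model`.
#' @param windows Windows (or [fb_covariances()]) to transform.
#' @param rate Sampling rate when `windows` is a bare list.
#' @param ... Unused.
#' @return Feature matrix, one row per window, columns = selected features.
#' @export
predict.csp_bank_model <- function(object, windows, rate = NULL, ...) {
  fc <- as_fb_covs(windows, object$bank, rate %||% object$rate)
  assert_that(fc$n_channels == object$n_channels,
              sprintf("windows have %d channels, model expects %d",
                      fc$n_channels, object$n_channels), class = "shape_error")
  feats <- fbcsp_features_all(object, fc)
  feats[, object$selected, drop = FALSE]
}

#' @export
print.csp_bank_model <- function(x, ...) {
  cat(sprintf("<csp_bank_model> %d-class, %d bands x %d pairs, %d/%d features selected\n",
              length(x$classes), length(x$bank), x$m,
              length(x$selected), nrow(x$feature_meta)))
  invisible(x)
}
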