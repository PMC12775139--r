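#' @importFrom rlang abort %||%
#' @importFrom stats var sd fft rnorm runif quantile predict
NULL

# classed conditions so callers/tests can distinguish failure modes
stop_frustbci <- function(msg, class) {
  rlang::abort(msg, class = c(paste0("frustbci_", class), "frustbci_error"))
}

assert_that <- function(ok, msg, class = "param_error") {
  if (!isTRUE(ok)) stop_frustbci(msg, class)
  invisible(TRUE)
}

# Deterministic 31-bit seed derivation so sub-streams (subjects, folds,
# calibration splits) never share a stream with the caller's seed.
derive_seed <- function(seed, ...) {
  parts <- c(seed, unlist(lapply(list(...), function(x) {
    if (is.character(x)) sum(utf8ToInt(x)) else as.numeric(x)
  })))
  s <- 0
  for (p in parts) s <- (s * 48271 + abs(p) + 11) %% 2147483629
  as.integer(s %% 2147483647)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# Stratified fold assignment: within each class, a seeded shuffle followed by
# round-robin allocation, so class balance per fold is within +/- 1.
stratified_folds <- function(labels, k, seed) {
  labels <- as.character(labels)
  assert_that(k >= 2, "number of folds must be >= 2")
  folds <- integer(length(labels))
  with_seed(seed, {
    for (cl in sort(unique(labels))) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

norm_channel <- function(x) toupper(gsub("\\s+", "", x))

# split a raw vector on a delimiter byte (no empty trailing pieces)
split_raw <- function(x, delim) {
  hits <- which(x == delim)
  starts <- c(1L, hits + 1L)
  ends <- c(hits - 1L, length(x))
  out <- list()
  for (i in seq_along(starts)) {
    if (starts[i] > ends[i]) out[[i]] <- raw(0)
    else out[[i]] <- x[starts[i]:ends[i]]
  }
  out
}

pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

chr_trim <- function(x) sub("\\s+$", "", sub("^\\s+", "", x))
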