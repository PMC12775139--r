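#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a cross-validation report
#'
#' @param x A `cv_report`.
#' @param ... Unused.
#' @return Per-fold accuracies as a tibble.
#' @export
tidy.cv_report <- function(x, ...) x$per_fold

#' @rdname tidy.cv_report
#' @export
glance.cv_report <- function(x, ...) {
  tibble::tibble(task = x$task, k = x$k, guard = x$guard,
                 mean_accuracy = x$mean_accuracy, sd_accuracy = x$sd_accuracy,
                 seed = x$seed)
}

#' Tidy a fitted FBCSP model
#'
#' One row per candidate feature: band edges, sub-problem, filter index,
#' mutual-information score and whether the feature was selected.
#'
#' @param x A `csp_bank_model`.
#' @param ... Unused.
#' @export
tidy.csp_bank_model <- function(x, ...) {
  dplyr::mutate(x$feature_meta,
                mi = x$mi_scores %||% NA_real_,
                selected = .data$col %in% x$selected)
}

#' @rdname tidy.csp_bank_model
#' @export
glance.csp_bank_model <- function(x, ...) {
  tibble::tibble(n_classes = length(x$classes), n_bands = length(x$bank),
                 m = x$m, k_select = x$k_select,
                 n_selected = length(x$selected),
                 n_channels = x$n_channels)
}

#' Tidy / summarize a classifier bank
#'
#' @param x A `classifier_bank`.
#' @param ... Unused.
#' @export
glance.classifier_bank <- function(x, ...) {
  tibble::tibble(
    backend_low = x$members$low$backend,
    backend_mid = x$members$mid$backend,
    backend_high = x$members$high$backend,
    backend_all = x$m_all$backend,
    has_state_clf = !is.null(x$state_clf),
    has_stage1 = !is.null(x$m_stage1),
    pool_size = x$pool_size)
}

#' Plot per-fold cross-validation accuracies
#'
#' @param object A `cv_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cv_report <- function(object, ...) {
  ggplot2::ggplot(object$per_fold,
                  ggplot2::aes(x = factor(.data$fold), y = .data$accuracy)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = object$mean_accuracy, linetype = 2) +
    ggplot2::labs(x = "fold", y = "accuracy (%)",
                  title = sprintf("%s decoding, %d-fold CV: %.1f%% +/- %.1f",
                                  object$task, object$k,
                                  object$mean_accuracy, object$sd_accuracy)) +
    ggplot2::theme_minimal()
}

#' Plot band-wise t statistics
#'
#' @param object A `band_stats` tibble from [band_psd_ttest()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.band_stats <- function(object, ...) {
  df <- dplyr::mutate(object, band = factor(.data$band, .data$band))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$band, y = .data$t,
                                   fill = .data$p < 0.05)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "firebrick",
                                          `FALSE` = "grey60"),
                               name = "p < 0.05") +
    ggplot2::labs(x = NULL, y = "t value (A - B)") +
    ggplot2::theme_minimal()
}

#' Plot per-subject accuracies of the four decision strategies
#'
#' @param object A `cohort_report` from [evaluate_cohort()].
#' @param ... Unused.
#' @return A ggplot (boxplots with per-subject points).
#' @export
autoplot.cohort_report <- function(object, ...) {
  df <- tidyr::pivot_longer(
    tibble::as_tibble(object)[, c("subject_id", "method1_acc", "method2_acc",
                                  "method3_1_acc", "method3_2_acc")],
    -"subject_id", names_to = "method", values_to = "accuracy")
  df$method <- factor(df$method,
                      levels = c("method1_acc", "method2_acc",
                                 "method3_1_acc", "method3_2_acc"),
                      labels = c("1 (hard switch)", "2 (soft fusion)",
                                 "3-1 (pooled)", "3-2 (stage 1)"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$method, y = .data$accuracy)) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey90") +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.7) +
    ggplot2::labs(x = NULL, y = "MI accuracy (%)") +
    ggplot2::theme_minimal()
}

#' Plot an evoked spectrum with a variability band
#'
#' @param spectrum Tibble from [evoked_spectrum()].
#' @param fmax Upper frequency limit to display, Hz.
#' @return A ggplot.
#' @export
plot_evoked_spectrum <- function(spectrum, fmax = 45) {
  df <- spectrum[spectrum$freq <= fmax, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$freq, y = .data$mean_db)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_db - .data$sd_db,
                                      ymax = .data$mean_db + .data$sd_db),
                         alpha = 0.3) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "frequency (Hz)", y = "power (dB)") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
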