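#' Reference cohort summary tables
#'
#' Per-subject decoding accuracies reported for a 12-participant
#' frustration-induction motor-imagery study, shipped as plain-text inputs
#' for the cohort-aggregation and confusion-metric utilities:
#'
#' * `"pbci"` — per-subject 3-class frustration (passive BCI) accuracy.
#' * `"mi"` — per-subject MI accuracy under each frustration-specific
#'   condition (low/mid/high) and the state-agnostic pooled condition.
#' * `"methods"` — per-subject MI accuracy of the four decision strategies
#'   (1, 2, 3-1, 3-2).
#' * `"confusion"` — the cohort-averaged row-normalized confusion matrix of
#'   the frustration classifier (percent).
#'
#' @param table Which table to load.
#' @return A tibble (for `"confusion"`, a 3x3 numeric matrix with state
#'   dimnames).
#' @export
reference_cohort <- function(table = c("pbci", "mi", "methods", "confusion")) {
  table <- match.arg(table)
  file <- system.file("extdata", switch(table,
    pbci = "reference_cohort_pbci.csv",
    mi = "reference_cohort_mi.csv",
    methods = "reference_cohort_methods.csv",
    confusion = "reference_confusion_pbci.csv"), package = "frustbci")
  df <- utils::read.csv(file, stringsAsFactors = FALSE, check.names = FALSE)
  if (table == "confusion") {
    m <- as.matrix(df[, -1])
    rownames(m) <- df$true
    return(m)
  }
  tibble::as_tibble(df)
}
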