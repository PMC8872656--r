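#' Write an APV feature table
#'
#' Comma-delimited with columns `subject_id`, `group`, `passage`,
#' `parameter`, `value` (28 rows per subject). An empty feature set
#' yields a header-only file.
#'
#' @param features a feature table from [extract_apv_features()] /
#'   [analyze_cohort()].
#' @param path output file path.
#' @export
write_features <- function(features, path) {
  cols <- c("subject_id", "group", "passage", "parameter", "value")
  df <- as.data.frame(features)[, cols, drop = FALSE]
  ok <- tryCatch({
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("I/O error: cannot write ", path)
  invisible(path)
}

#' Read an APV feature table
#'
#' @param path file written by [write_features()].
#' @return Data frame with columns `subject_id`, `group`, `passage`,
#'   `parameter`, `value`.
#' @export
read_features <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, colClasses = c(
    subject_id = "character", group = "character",
    passage = "character", parameter = "character", value = "numeric"))
  df
}

#' Write a group-comparison report
#'
#' Comma-delimited report with one row per (passage, parameter): group
#' means and SDs, the signed statistic of the test that ran, the
#' two-sided p, the test used, and the significance tier. Numeric
#' columns are rounded to 3 decimals in the conventional style of
#' clinical pulse-parameter tables.
#'
#' @param comparison output of [compare_groups()].
#' @param path output file path.
#' @export
write_comparison <- function(comparison, path) {
  df <- comparison
  for (col in c("mean_a", "sd_a", "mean_b", "sd_b", "statistic", "p_value"))
    df[[col]] <- round(df[[col]], 3)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
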