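#' Load the packaged per-subject classification results table
#'
#' Transcription of the published per-subject best-performing combinations:
#' selected channel, analysis interval, optimal feature set and
#' leave-one-out classification accuracy for 12 subjects.
#'
#' @return data.frame with columns `subject`, `channel`, `start_s`, `end_s`,
#'   `features` (semicolon-separated), `accuracy_pct`
#' @export
load_table2 <- function() {
  utils::read.csv(system.file("extdata", "table2_results.csv", package = "fnirsmi"),
                  stringsAsFactors = FALSE)
}

#' Load the packaged group-mean oxygenation table
#'
#' Group-level stimulation-minus-rest concentration changes (mean and
#' standard error, umol/l) and signal-to-noise ratios per channel and
#' condition, including the overall-channels column.
#'
#' @return data.frame with columns `condition`, `channel` (1--3 or
#'   `"overall"`), `chromophore`, `mean_umol_l`, `se_umol_l`, `snr`
#' @export
load_table1 <- function() {
  utils::read.csv(system.file("extdata", "table1_amplitudes.csv", package = "fnirsmi"),
                  stringsAsFactors = FALSE)
}

#' Convert a search result to a one-row record
#'
#' @param result a `search_result` from [exhaustive_search()]
#' @param subject subject identifier
#' @return one-row data.frame in the layout of [load_table2()]
#' @export
as_record <- function(result, subject = NA) {
  data.frame(subject = subject, channel = result$best$channel,
             start_s = result$best$start_s, end_s = result$best$end_s,
             features = result$best$features,
             accuracy_pct = 100 * result$accuracy,
             stringsAsFactors = FALSE)
}

#' Aggregate per-subject classification results to group level
#'
#' Mean, sample standard deviation (n - 1), minimum and maximum of the
#' accuracies; counts of subjects per selected channel and per feature
#' present in the optimal subset; and the per-subject interval lengths.
#' Displayed accuracies are rounded to one decimal in percent.
#'
#' @param records data.frame in the layout of [load_table2()] (or built
#'   with [as_record()])
#' @return object of class `group_report`
#' @export
aggregate_results <- function(records) {
  stopifnot(nrow(records) >= 2)
  acc <- records$accuracy_pct
  feats <- strsplit(records$features, ";", fixed = TRUE)
  feature_counts <- vapply(FEATURE_NAMES, function(f)
    sum(vapply(feats, function(x) f %in% x, logical(1))), integer(1))
  channel_counts <- c(table(factor(records$channel,
                                   levels = sort(unique(records$channel)))))
  structure(list(n_subjects = nrow(records),
                 accuracy_mean = mean(acc), accuracy_sd = stats::sd(acc),
                 accuracy_min = min(acc), accuracy_max = max(acc),
                 channel_counts = channel_counts,
                 feature_counts = feature_counts,
                 interval_lengths = records$end_s - records$start_s),
            class = "group_report")
}

#' @export
print.group_report <- function(x, ...) {
  cat("<group_report> ", x$n_subjects, " subjects: accuracy ",
      sprintf("%.1f +/- %.1f%% (range %.1f%% - %.1f%%)", x$accuracy_mean,
              x$accuracy_sd, x$accuracy_min, x$accuracy_max), "\n", sep = "")
  cat("  channels: ", paste(sprintf("ch%s = %d", names(x$channel_counts),
                                    as.integer(x$channel_counts)), collapse = ", "), "\n")
  cat("  features: ", paste(sprintf("%s = %d", names(x$feature_counts),
                                    x$feature_counts), collapse = ", "), "\n")
  invisible(x)
}

#' Pearson correlation between a mean feature value and accuracy
#'
#' Two-tailed Pearson correlation with the p-value from the t-transform
#' (`df = n - 2`). Intended for per-subject mean feature values against
#' per-subject classification accuracies, restricted by the caller to the
#' subjects whose optimal set includes the feature.
#'
#' @param feature_means per-subject mean feature values, length >= 3
#' @param accuracies per-subject accuracies, same length
#' @return list with `r`, `p`, `n`, `undefined` flag
#' @export
feature_accuracy_correlation <- function(feature_means, accuracies) {
  stopifnot(length(feature_means) == length(accuracies))
  n <- length(feature_means)
  if (n < 3) stop("correlation needs at least 3 subjects")
  if (stats::sd(feature_means) == 0 || stats::sd(accuracies) == 0)
    return(list(r = NA_real_, p = NA_real_, n = n, undefined = TRUE))
  r <- stats::cor(feature_means, accuracies)
  p <- if (abs(r) >= 1) 0 else {
    tval <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(tval), df = n - 2)
  }
  list(r = r, p = p, n = n, undefined = FALSE)
}

#' Keystroke error rate
#'
#' Total number of erroneous finger taps divided by the total number of
#' finger taps (control motor-execution runs).
#'
#' @param n_errors error count
#' @param n_taps total tap count, > 0
#' @return fraction in \code{[0, 1]}
#' @export
keystroke_error_rate <- function(n_errors, n_taps) {
  if (n_taps <= 0) stop("n_taps must be positive")
  if (n_errors < 0 || n_errors > n_taps) stop("n_errors must be in [0, n_taps]")
  n_errors / n_taps
}

#' Render per-subject records as a Markdown table
#'
#' @param records data.frame in the layout of [load_table2()]
#' @return character vector of Markdown lines
#' @export
format_results_md <- function(records) {
  hdr <- c("| Subject | Channel | Time interval | Optimal feature set | Accuracy |",
           "|---|---|---|---|---|")
  rows <- sprintf("| %s | %d | %d-%d s | %s | %.1f%% |", records$subject,
                  records$channel, records$start_s, records$end_s,
                  gsub(";", ", ", records$features, fixed = TRUE),
                  records$accuracy_pct)
  c(hdr, rows)
}
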