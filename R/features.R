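FEATURE_NAMES <- c("mean", "variance", "skewness", "kurtosis")

#' Enumerate candidate analysis windows
#'
#' All onset-relative time intervals with integer start times 1--11 s and
#' integer end times 5--15 s, `end > start`, ordered by start then end.
#' Windows are half-open `[start, end)` so a window contains exactly
#' `(end - start) * rate` samples.
#'
#' @param start_range allowed start times, seconds (default 1:11)
#' @param end_range allowed end times, seconds (default 5:15)
#' @return data.frame with columns `start`, `end` (93 rows with defaults)
#' @export
enumerate_windows <- function(start_range = 1:11, end_range = 5:15) {
  g <- expand.grid(end = end_range, start = start_range)[, c("start", "end")]
  g <- g[g$end > g$start, ]
  g <- g[order(g$start, g$end), ]
  rownames(g) <- NULL
  g
}

#' Extract statistical-moment features from a windowed signal segment
#'
#' Computes the subset of \{mean, variance, skewness, kurtosis\} on the
#' baseline-corrected stimulation samples falling in the half-open,
#' onset-relative window `[start, end)` seconds. Conventions: arithmetic
#' mean; unbiased (n - 1) sample variance; adjusted Fisher-Pearson sample
#' skewness; bias-adjusted sample excess kurtosis (normal distribution
#' gives 0). When the windowed samples have zero spread, skewness and
#' kurtosis are returned as NA (flagged undefined) while mean and variance
#' are still valid.
#'
#' @param x baseline-corrected stimulation trace, first sample at onset
#' @param rate sampling rate of `x`, Hz
#' @param window list or one-row data.frame with `start` and `end`, seconds
#' @param wanted feature names to compute (default all four)
#' @return named numeric vector over `wanted`, with attribute `undefined`
#'   naming any flagged features
#' @export
extract_features <- function(x, rate, window, wanted = FEATURE_NAMES) {
  stopifnot(all(wanted %in% FEATURE_NAMES))
  idx <- (window$start * rate + 1):(window$end * rate)
  if (max(idx) > length(x)) stop("window exceeds the stimulation segment")
  v <- x[idx]
  n <- length(v)
  if (n < 4) stop("window must contain at least 4 samples")
  m <- mean(v)
  s2 <- stats::var(v)
  undefined <- character(0)
  if (s2 == 0) {
    sk <- ku <- NA_real_
    undefined <- intersect(wanted, c("skewness", "kurtosis"))
  } else {
    cv <- v - m
    m2 <- mean(cv^2)
    g1 <- mean(cv^3) / m2^1.5
    g2 <- mean(cv^4) / m2^2 - 3
    sk <- g1 * sqrt(n * (n - 1)) / (n - 2)
    ku <- ((n + 1) * g2 + 6) * (n - 1) / ((n - 2) * (n - 3))
  }
  out <- c(mean = m, variance = s2, skewness = sk, kurtosis = ku)[wanted]
  attr(out, "undefined") <- undefined
  out
}

#' Feature matrix for one channel and window over all trials
#'
#' @param epochs a `trial_epochs` object
#' @param channel channel index
#' @param window list with `start`, `end` (seconds)
#' @param chromophore `"o2hb"` (default) or `"hhb"`
#' @return trials x 4 matrix of features (columns mean, variance, skewness,
#'   kurtosis), NA where undefined
#' @export
feature_matrix <- function(epochs, channel, window, chromophore = c("o2hb", "hhb")) {
  chromophore <- match.arg(chromophore)
  arr <- epochs[[paste0("corrected_stim_", chromophore)]]
  m <- t(vapply(seq_along(epochs$condition), function(i) {
    as.numeric(extract_features(arr[i, channel, ], epochs$sampling_rate, window))
  }, numeric(4)))
  colnames(m) <- FEATURE_NAMES
  m
}

#' Export a full feature table
#'
#' All four features for every (trial, channel, window) combination, in a
#' long data.frame suitable for CSV export or the exhaustive search.
#'
#' @param epochs a `trial_epochs` object
#' @param windows window grid (default [enumerate_windows()])
#' @param chromophore `"o2hb"` (default) or `"hhb"`
#' @return data.frame with columns `trial`, `condition`, `channel`,
#'   `start_s`, `end_s`, `mean`, `variance`, `skewness`, `kurtosis`
#' @export
feature_table <- function(epochs, windows = enumerate_windows(),
                          chromophore = "o2hb") {
  out <- list()
  for (ch in seq_len(epochs$n_channels)) {
    for (w in seq_len(nrow(windows))) {
      fm <- feature_matrix(epochs, ch, windows[w, ], chromophore)
      out[[length(out) + 1]] <- data.frame(
        trial = epochs$trial, condition = epochs$condition, channel = ch,
        start_s = windows$start[w], end_s = windows$end[w], fm,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
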