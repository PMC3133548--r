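#' Cut a concentration series into rest/stimulation trial epochs
#'
#' For every stimulation event, extracts the stimulation segment and the
#' rest segment immediately preceding it (the trial's baseline), per channel
#' and chromophore. Trials whose full rest or stimulation span falls outside
#' the recording are dropped with a warning.
#'
#' @param series a `hemo_series` (see [mbll()])
#' @param events event table; defaults to the one carried by `series`
#' @param rest_duration baseline length, seconds (default 20)
#' @param stim_duration stimulation length, seconds (default 15)
#' @return object of class `trial_epochs`: arrays `rest_o2hb`, `stim_o2hb`,
#'   `rest_hhb`, `stim_hhb` of dimension (trial, channel, sample),
#'   `condition` per trial, `baseline_o2hb`/`baseline_hhb` and
#'   `corrected_stim_o2hb`/`corrected_stim_hhb` derived per the baseline
#'   correction (stimulation minus mean of the preceding rest)
#' @export
epoch <- function(series, events = series$events, rest_duration = 20,
                  stim_duration = 15) {
  stopifnot(inherits(series, "hemo_series"))
  r <- series$sampling_rate
  nr <- round(rest_duration * r)
  ns <- round(stim_duration * r)
  n <- ncol(series$o2hb)
  nch <- nrow(series$o2hb)
  keep <- logical(nrow(events))
  for (i in seq_len(nrow(events))) {
    i0 <- round(events$onset_s[i] * r)
    keep[i] <- (i0 - nr >= 0) && (i0 + ns <= n)
  }
  if (any(!keep))
    warning(sum(!keep), " trial(s) dropped: rest or stimulation span truncated")
  ev <- events[keep, , drop = FALSE]
  nt <- nrow(ev)
  grab <- function(mat, from, len) {
    out <- array(NA_real_, c(nt, nch, len))
    for (i in seq_len(nt)) {
      i0 <- round(ev$onset_s[i] * r) + from
      out[i, , ] <- mat[, (i0 + 1):(i0 + len), drop = FALSE]
    }
    out
  }
  rest_o2 <- grab(series$o2hb, -nr, nr)
  stim_o2 <- grab(series$o2hb, 0, ns)
  rest_hb <- grab(series$hhb, -nr, nr)
  stim_hb <- grab(series$hhb, 0, ns)
  base_o2 <- apply(rest_o2, c(1, 2), mean)
  base_hb <- apply(rest_hb, c(1, 2), mean)
  corr_o2 <- stim_o2 - as.vector(base_o2)
  corr_hb <- stim_hb - as.vector(base_hb)
  structure(list(condition = ev$condition, trial = ev$trial,
                 sampling_rate = r, n_channels = nch,
                 rest_duration = rest_duration, stim_duration = stim_duration,
                 rest_o2hb = rest_o2, stim_o2hb = stim_o2,
                 rest_hhb = rest_hb, stim_hhb = stim_hb,
                 baseline_o2hb = base_o2, baseline_hhb = base_hb,
                 corrected_stim_o2hb = corr_o2, corrected_stim_hhb = corr_hb),
            class = "trial_epochs")
}

#' @export
print.trial_epochs <- function(x, ...) {
  cat("<trial_epochs> ", length(x$condition), " trials x ", x$n_channels,
      " channels (", length(x$condition) * x$n_channels, " epochs)\n", sep = "")
  invisible(x)
}

#' Number of (trial, channel) epochs
#' @param epochs a `trial_epochs` object
#' @return integer count
#' @export
n_epochs <- function(epochs) length(epochs$condition) * epochs$n_channels

#' Paired t-test on per-trial stimulation and rest means
#'
#' Classical paired t with `df = n - 1` and a two-sided p-value. When all
#' differences are identical (zero variance) the result is flagged
#' degenerate rather than returning an infinite statistic.
#'
#' @param stim_means per-trial stimulation means
#' @param rest_means per-trial rest means, same length
#' @return list with `t`, `p`, `df`, `mean_diff`, `degenerate`
#' @export
paired_ttest <- function(stim_means, rest_means) {
  stopifnot(length(stim_means) == length(rest_means))
  n <- length(stim_means)
  if (n < 2) stop("paired t-test needs at least 2 pairs (df = n - 1)")
  d <- stim_means - rest_means
  s <- stats::sd(d)
  if (s == 0)
    return(list(t = NA_real_, p = NA_real_, df = n - 1, mean_diff = mean(d),
                degenerate = TRUE))
  tval <- mean(d) / (s / sqrt(n))
  list(t = tval, p = 2 * stats::pt(-abs(tval), df = n - 1), df = n - 1,
       mean_diff = mean(d), degenerate = FALSE)
}

#' Signal-to-noise ratio of per-trial values
#'
#' The ratio of the mean to the sample standard deviation (n - 1
#' denominator) of the supplied per-trial values.
#'
#' @param per_trial_values numeric vector, length >= 2
#' @return list with `snr` (NA when undefined) and `undefined` flag
#' @export
snr <- function(per_trial_values) {
  stopifnot(length(per_trial_values) >= 2)
  s <- stats::sd(per_trial_values)
  if (s == 0) return(list(snr = NA_real_, undefined = TRUE))
  list(snr = mean(per_trial_values) / s, undefined = FALSE)
}

#' Per-channel, per-condition stimulation/rest statistics
#'
#' For every (channel, condition, chromophore) cell: per-trial stimulation
#' and rest means, their paired t-test, and the signal-to-noise ratio. The
#' SNR operand is configurable: `"trial_diffs"` (default) is the mean over
#' trials of the stimulation-minus-rest differences divided by their
#' across-trial standard deviation; `"within_epoch"` averages the
#' within-stimulation time-domain mean/SD ratio over trials.
#'
#' @param epochs a `trial_epochs` object
#' @param snr_mode `"trial_diffs"` (default) or `"within_epoch"`
#' @return data.frame with columns `channel`, `condition`, `chromophore`,
#'   `stim_mean`, `rest_mean`, `mean_diff`, `t`, `p`, `df`, `snr`,
#'   `degenerate`
#' @export
channel_stats <- function(epochs, snr_mode = c("trial_diffs", "within_epoch")) {
  stopifnot(inherits(epochs, "trial_epochs"))
  snr_mode <- match.arg(snr_mode)
  conds <- unique(epochs$condition)
  rows <- list()
  for (chromo in c("o2hb", "hhb")) {
    stim_arr <- epochs[[paste0("stim_", chromo)]]
    rest_arr <- epochs[[paste0("rest_", chromo)]]
    for (ch in seq_len(epochs$n_channels)) for (cc in conds) {
      tr <- which(epochs$condition == cc)
      sm <- apply(stim_arr[tr, ch, , drop = FALSE], 1, mean)
      rm_ <- apply(rest_arr[tr, ch, , drop = FALSE], 1, mean)
      tt <- paired_ttest(sm, rm_)
      sv <- if (snr_mode == "trial_diffs") {
        snr(sm - rm_)
      } else {
        per <- vapply(tr, function(i) {
          x <- stim_arr[i, ch, ] - mean(rest_arr[i, ch, ])
          s <- stats::sd(x)
          if (s == 0) NA_real_ else mean(x) / s
        }, numeric(1))
        list(snr = mean(per), undefined = anyNA(per))
      }
      rows[[length(rows) + 1]] <-
        data.frame(channel = ch, condition = cc, chromophore = chromo,
                   stim_mean = mean(sm), rest_mean = mean(rm_),
                   mean_diff = mean(sm - rm_),
                   t = tt$t, p = tt$p, df = tt$df, snr = sv$snr,
                   degenerate = tt$degenerate, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Apply channel and subject exclusion rules
#'
#' A channel is excluded when its oxygenation change (oxy-hemoglobin,
#' stimulation vs rest) is non-significant in every condition at
#' `alpha_channel`. A subject is excluded when all channels are
#' non-significant (p > `alpha_subject`) in both the task run and, when
#' supplied, the motor-execution control run.
#'
#' @param stats_task [channel_stats()] table for the task run
#' @param stats_control optional [channel_stats()] table for the control run
#' @param alpha_channel channel-level significance level (default 0.005)
#' @param alpha_subject subject-level significance level (default 0.05)
#' @return list with `channel_excluded` (logical per channel),
#'   `subject_excluded` (logical), and `reasons` (character)
#' @export
apply_exclusions <- function(stats_task, stats_control = NULL,
                             alpha_channel = 0.005, alpha_subject = 0.05) {
  sig_by_channel <- function(stats, alpha) {
    s <- stats[stats$chromophore == "o2hb", ]
    p <- ifelse(is.na(s$p), 1, s$p)
    tapply(p <= alpha, s$channel, any)
  }
  ch_sig <- sig_by_channel(stats_task, alpha_channel)
  channel_excluded <- !ch_sig
  reasons <- character(0)
  if (any(channel_excluded))
    reasons <- c(reasons, paste0("channel ", names(ch_sig)[channel_excluded],
                                 ": no significant oxygenation change at alpha = ",
                                 alpha_channel))
  task_all_null <- !any(sig_by_channel(stats_task, alpha_subject))
  ctrl_all_null <- if (is.null(stats_control)) TRUE else
    !any(sig_by_channel(stats_control, alpha_subject))
  subject_excluded <- task_all_null && ctrl_all_null
  if (subject_excluded)
    reasons <- c(reasons, paste0("subject: p > ", alpha_subject,
                                 " in all channels (task",
                                 if (!is.null(stats_control)) " and control", ")"))
  list(channel_excluded = as.vector(channel_excluded),
       subject_excluded = subject_excluded, reasons = reasons)
}
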