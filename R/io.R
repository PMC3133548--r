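#' Write a raw recording to the documented CSV pair
#'
#' Wide intensity CSV (`time_s`, `ch{i}_wl{lambda}_intensity` columns,
#' `ambient`) plus an events CSV (`onset_s`, `duration_s`, `condition`).
#'
#' @param raw a [raw_recording()]
#' @param dir output directory (created if missing)
#' @param prefix file name prefix (default `"recording"`)
#' @return invisibly, the two file paths
#' @export
write_raw_recording <- function(raw, dir, prefix = "recording") {
  stopifnot(inherits(raw, "raw_recording"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  nch <- dim(raw$intensity)[1]
  cols <- list(time_s = raw$time)
  for (ch in seq_len(nch)) for (w in 1:2)
    cols[[sprintf("ch%d_wl%d_intensity", ch, raw$wavelengths[w])]] <- raw$intensity[ch, w, ]
  cols$ambient <- raw$ambient
  data_path <- file.path(dir, paste0(prefix, "_intensity.csv"))
  events_path <- file.path(dir, paste0(prefix, "_events.csv"))
  utils::write.csv(as.data.frame(cols), data_path, row.names = FALSE)
  ev <- raw$events[, c("onset_s", "duration_s", "condition")]
  utils::write.csv(ev, events_path, row.names = FALSE)
  invisible(c(data = data_path, events = events_path))
}

#' Read a raw recording from the documented CSV pair
#'
#' @param data_path intensity CSV written by [write_raw_recording()]
#' @param events_path events CSV
#' @param distance_mm source-detector distance, mm (default 12.5; the CSV
#'   schema does not carry it)
#' @return a [raw_recording()]
#' @export
read_raw_recording <- function(data_path, events_path, distance_mm = 12.5) {
  d <- utils::read.csv(data_path)
  ev <- utils::read.csv(events_path, stringsAsFactors = FALSE)
  ev$trial <- seq_len(nrow(ev))
  icols <- grep("^ch[0-9]+_wl[0-9]+_intensity$", names(d), value = TRUE)
  chs <- sort(unique(as.integer(sub("^ch([0-9]+)_.*", "\\1", icols))))
  wls <- sort(unique(as.integer(sub("^ch[0-9]+_wl([0-9]+)_.*", "\\1", icols))))
  stopifnot(length(wls) == 2)
  n <- nrow(d)
  intensity <- array(NA_real_, c(length(chs), 2, n),
                     dimnames = list(NULL, paste0("wl", wls), NULL))
  for (ci in seq_along(chs)) for (wi in 1:2)
    intensity[ci, wi, ] <- d[[sprintf("ch%d_wl%d_intensity", chs[ci], wls[wi])]]
  rate <- round(1 / stats::median(diff(d$time_s)))
  raw_recording(sampling_rate = rate, time = d$time_s, intensity = intensity,
                ambient = d$ambient, events = ev, wavelengths = wls,
                distance_mm = distance_mm)
}

#' Write a concentration series as CSV
#'
#' Columns `time_s`, `ch{i}_o2hb`, `ch{i}_hhb` (umol/l).
#'
#' @param series a `hemo_series`
#' @param path output CSV path
#' @return invisibly, `path`
#' @export
write_hemo_series <- function(series, path) {
  stopifnot(inherits(series, "hemo_series"))
  cols <- list(time_s = series$time)
  for (ch in seq_len(nrow(series$o2hb))) {
    cols[[sprintf("ch%d_o2hb", ch)]] <- series$o2hb[ch, ]
    cols[[sprintf("ch%d_hhb", ch)]] <- series$hhb[ch, ]
  }
  utils::write.csv(as.data.frame(cols), path, row.names = FALSE)
  invisible(path)
}
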