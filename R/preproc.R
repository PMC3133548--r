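#' Subtract ambient light from raw intensities
#'
#' Samplewise subtraction of the recorded ambient light intensity from every
#' channel/wavelength intensity trace. Must precede low-pass filtering.
#'
#' @param raw a [raw_recording()]
#' @return a `raw_recording` with corrected intensities and the step logged
#' @export
subtract_ambient <- function(raw) {
  stopifnot(inherits(raw, "raw_recording"))
  out <- raw$intensity
  nch <- dim(out)[1]
  bad <- character(0)
  for (ch in seq_len(nch)) for (w in 1:2) {
    out[ch, w, ] <- raw$intensity[ch, w, ] - raw$ambient
    nbad <- sum(out[ch, w, ] <= 0)
    if (nbad > 0)
      bad <- c(bad, sprintf("channel %d, %d nm: %d samples", ch, raw$wavelengths[w], nbad))
  }
  if (length(bad))
    stop("ambient subtraction produced non-positive intensities (",
         paste(bad, collapse = "; "), ")")
  raw$intensity <- out
  raw$ambient <- rep(0, length(raw$ambient))
  raw$log <- log_step(raw$log, "subtract_ambient", list())
  raw
}

#' Design a Chebyshev low-pass filter
#'
#' Digital IIR low-pass via the bilinear transform of an analog Chebyshev
#' prototype. The default (and the one matching the acquisition chain
#' emulated here) is type II: monotone passband with `atten_db` of
#' attenuation from the stopband edge `edge_hz` onward. Type I (equiripple
#' passband with `atten_db` interpreted as passband ripple) is selectable.
#'
#' @param order filter order (default 7)
#' @param atten_db stopband attenuation (type II) or passband ripple
#'   (type I), dB (default 20)
#' @param edge_hz band edge frequency, Hz (default 5)
#' @param fs sampling rate, Hz
#' @param type `"II"` (default) or `"I"`
#' @return list with numerator `b`, denominator `a`, and the design
#'   parameters
#' @export
cheby_design <- function(order = 7, atten_db = 20, edge_hz = 5, fs = 100,
                         type = c("II", "I")) {
  type <- match.arg(type)
  stopifnot(order >= 1, atten_db > 0, edge_hz > 0, edge_hz < fs / 2)
  N <- as.integer(order)
  m <- seq(-N + 1, N - 1, by = 2)
  if (type == "II") {
    de <- 1 / sqrt(10^(0.1 * atten_db) - 1)
    mu <- asinh(1 / de) / N
    # analog prototype: zeros on the imaginary axis, poles = reciprocals of
    # the type-I poles; odd order drops the zero at infinity
    zm <- m[m != 0]
    z <- Conj(1i / sin(zm * pi / (2 * N)))
    p <- -exp(1i * pi * m / (2 * N))
    p <- complex(real = sinh(mu) * Re(p), imaginary = cosh(mu) * Im(p))
    p <- 1 / p
    k <- Re(prod(-p) / prod(-z))
  } else {
    eps <- sqrt(10^(0.1 * atten_db) - 1)
    mu <- asinh(1 / eps) / N
    z <- complex(0)
    theta <- pi * m / (2 * N)
    p <- -complex(real = sinh(mu) * cos(theta), imaginary = cosh(mu) * sin(theta))
    k <- Re(prod(-p))
    if (N %% 2 == 0) k <- k / sqrt(1 + eps^2)
  }
  # frequency pre-warp and low-pass scaling
  warped <- 2 * fs * tan(pi * edge_hz / fs)
  z <- z * warped
  p <- p * warped
  k <- k * warped^(length(p) - length(z))
  # bilinear transform
  fs2 <- 2 * fs
  zd <- (fs2 + z) / (fs2 - z)
  pd <- (fs2 + p) / (fs2 - p)
  kd <- k * Re(prod(fs2 - z) / prod(fs2 - p))
  zd <- c(zd, rep(-1 + 0i, length(pd) - length(zd)))
  b <- Re(poly_from_roots(zd)) * kd
  a <- Re(poly_from_roots(pd))
  list(b = b, a = a, order = N, atten_db = atten_db, edge_hz = edge_hz,
       fs = fs, type = type)
}

## Polynomial coefficients (descending powers, monic) from roots.
poly_from_roots <- function(r) {
  p <- 1 + 0i
  for (ri in r) p <- c(p, 0) - c(0, p * ri)
  p
}

#' Frequency response of a designed digital filter
#'
#' @param filt output of [cheby_design()]
#' @param f frequencies, Hz
#' @return complex response at each frequency
#' @export
filter_response <- function(filt, f) {
  w <- 2 * pi * f / filt$fs
  z1 <- exp(-1i * w)
  num <- outer(z1, seq_along(filt$b) - 1, `^`) %*% filt$b
  den <- outer(z1, seq_along(filt$a) - 1, `^`) %*% filt$a
  as.vector(num / den)
}

## Single-pass causal IIR filtering (direct form), via stats::filter for the
## MA and AR parts. `settle` prepends that many copies of x[1] before
## filtering (dropped afterwards) so the filter starts at its DC steady
## state instead of zero initial conditions; without it the startup
## transient corrupts the first rest phase.
iir_filter <- function(x, b, a, settle = 0) {
  xs <- if (settle > 0) c(rep(x[1], settle), x) else x
  nb <- length(b)
  xp <- c(rep(0, nb - 1), xs)
  v <- stats::filter(xp, b / a[1], method = "convolution", sides = 1)
  v <- as.numeric(v)[nb:(nb - 1 + length(xs))]
  if (length(a) > 1) {
    v <- as.numeric(stats::filter(v, -a[-1] / a[1], method = "recursive"))
  }
  if (settle > 0) v <- v[-seq_len(settle)]
  v
}

#' Low-pass filter and decimate a raw recording
#'
#' Filters every intensity trace (and the ambient trace) with a causal
#' 7th-order Chebyshev type-II low-pass (20 dB attenuation from 5 Hz) and
#' keeps every `sampling_rate / target_rate`-th sample, emulating the
#' instrument's acquisition chain. The specified filter is the anti-alias
#' stage; no further filtering is applied. A zero-phase variant (forward
#' and reverse application) is available via `zero_phase = TRUE`.
#'
#' @param raw a [raw_recording()]
#' @param order,atten_db,edge_hz see [cheby_design()]
#' @param target_rate output sampling rate, Hz (default 10); must divide
#'   `raw$sampling_rate`
#' @param type Chebyshev type, `"II"` (default) or `"I"`
#' @param zero_phase apply the filter forward and reverse (default FALSE)
#' @return a decimated `raw_recording` with the step logged
#' @export
lowpass_decimate <- function(raw, order = 7, atten_db = 20, edge_hz = 5,
                             target_rate = 10, type = "II", zero_phase = FALSE) {
  stopifnot(inherits(raw, "raw_recording"))
  fac <- raw$sampling_rate / target_rate
  if (abs(fac - round(fac)) > 1e-9)
    stop("target_rate must be a divisor of the sampling rate")
  fac <- round(fac)
  if (edge_hz > target_rate / 2)
    warning("filter edge above the decimated Nyquist frequency")
  filt <- cheby_design(order, atten_db, edge_hz, raw$sampling_rate, type)
  settle <- round(5 * raw$sampling_rate)
  apply_f <- function(x) {
    y <- iir_filter(x, filt$b, filt$a, settle = settle)
    if (zero_phase) y <- rev(iir_filter(rev(y), filt$b, filt$a, settle = settle))
    y
  }
  keep <- seq(1, length(raw$time), by = fac)
  n <- dim(raw$intensity)
  out <- array(NA_real_, dim = c(n[1], n[2], length(keep)),
               dimnames = dimnames(raw$intensity))
  for (ch in seq_len(n[1])) for (w in 1:2)
    out[ch, w, ] <- apply_f(raw$intensity[ch, w, ])[keep]
  raw$intensity <- out
  raw$ambient <- apply_f(raw$ambient)[keep]
  raw$time <- raw$time[keep]
  raw$sampling_rate <- target_rate
  raw$log <- log_step(raw$log, "lowpass_decimate",
                      list(order = order, atten_db = atten_db, edge_hz = edge_hz,
                           target_rate = target_rate, type = type,
                           zero_phase = zero_phase))
  raw
}

#' Modified Beer-Lambert law inversion
#'
#' Converts ambient-corrected light intensities to oxy- and deoxy-hemoglobin
#' concentration changes. Per channel and wavelength the absorbance change
#' is `dA(lambda, t) = log10(I_ref(lambda) / I(lambda, t))`; the 2x2 linear
#' system `dA = extinction %*% conc * distance_cm * DPF(lambda)` is solved
#' per sample, yielding concentration changes in umol/l relative to the
#' reference state.
#'
#' The reference intensity defaults to the per-channel/wavelength mean over
#' the first rest phase (everything before the first stimulation onset),
#' i.e. concentrations are changes relative to initial rest; `ref = "whole"`
#' uses the whole-recording mean instead.
#'
#' @param raw a [raw_recording()] (ambient-corrected)
#' @param dpf differential pathlength factors per wavelength
#'   (default 6.75 at 760 nm, 6.50 at 870 nm)
#' @param extinction 2 x 2 extinction matrix, rows = wavelengths, columns =
#'   (o2hb, hhb), 1/cm per (mol/l); default from the packaged table
#' @param distance_mm source-detector distance, mm (default from `raw`)
#' @param ref `"first_rest"` (default), `"whole"`, or a numeric
#'   channel x wavelength matrix of reference intensities (exact algebraic
#'   inversion against a known reference state)
#' @return a `hemo_series` object: `o2hb` and `hhb` matrices
#'   (channel x sample, umol/l), `time`, `sampling_rate`, `events`, `log`
#' @export
mbll <- function(raw, dpf = c(6.75, 6.50),
                 extinction = default_extinction(raw$wavelengths),
                 distance_mm = raw$distance_mm,
                 ref = c("first_rest", "whole")) {
  stopifnot(inherits(raw, "raw_recording"))
  ref_mat <- NULL
  if (is.numeric(ref)) {
    ref_mat <- matrix(ref, dim(raw$intensity)[1], 2)
    ref <- "numeric"
  } else {
    ref <- match.arg(ref)
  }
  extinction <- as.matrix(extinction)
  if (abs(det(extinction)) < 1e-12 * prod(abs(extinction[1, ]) + abs(extinction[2, ])))
    stop("extinction matrix is singular")
  if (any(raw$intensity <= 0))
    stop("non-positive intensities; run subtract_ambient first and check data")
  nch <- dim(raw$intensity)[1]
  n <- dim(raw$intensity)[3]
  ref_idx <- if (ref == "first_rest" && nrow(raw$events) > 0) {
    which(raw$time < raw$events$onset_s[1])
  } else {
    seq_len(n)
  }
  if (!length(ref_idx)) stop("no samples available for the reference intensity")
  d_cm <- distance_mm / 10
  # dA = M %*% conc_umol, with M in (absorbance per umol/l)
  M <- diag(dpf) %*% extinction * 1e-6 * d_cm
  Minv <- solve(M)
  o2hb <- matrix(NA_real_, nch, n)
  hhb <- matrix(NA_real_, nch, n)
  for (ch in seq_len(nch)) {
    iref <- if (!is.null(ref_mat)) ref_mat[ch, ] else
      c(mean(raw$intensity[ch, 1, ref_idx]), mean(raw$intensity[ch, 2, ref_idx]))
    dA <- rbind(log10(iref[1] / raw$intensity[ch, 1, ]),
                log10(iref[2] / raw$intensity[ch, 2, ]))
    conc <- Minv %*% dA
    o2hb[ch, ] <- conc[1, ]
    hhb[ch, ] <- conc[2, ]
  }
  structure(list(sampling_rate = raw$sampling_rate, time = raw$time,
                 o2hb = o2hb, hhb = hhb, events = raw$events,
                 log = log_step(raw$log, "mbll",
                                list(dpf = dpf, extinction = extinction,
                                     distance_mm = distance_mm,
                                     ref = if (!is.null(ref_mat)) ref_mat else ref))),
            class = "hemo_series")
}

#' @export
print.hemo_series <- function(x, ...) {
  cat("<hemo_series> ", nrow(x$o2hb), " channels x ", ncol(x$o2hb),
      " samples @ ", x$sampling_rate, " Hz (umol/l)\n", sep = "")
  invisible(x)
}

#' Remove the linear drift from a concentration series
#'
#' Subtracts the ordinary least-squares line fitted over the full recording
#' from each channel's oxy- and deoxy-hemoglobin trace. Idempotent; the
#' residual slope is zero to numerical precision.
#'
#' @param series a `hemo_series` from [mbll()]
#' @return the detrended `hemo_series` with the step logged
#' @export
detrend_linear <- function(series) {
  stopifnot(inherits(series, "hemo_series"), length(series$time) >= 2)
  tc <- series$time - mean(series$time)
  stt <- sum(tc^2)
  detrend1 <- function(x) {
    slope <- sum(tc * x) / stt
    x - mean(x) - slope * tc
  }
  series$o2hb <- t(apply(series$o2hb, 1, detrend1))
  series$hhb <- t(apply(series$hhb, 1, detrend1))
  series$log <- log_step(series$log, "detrend_linear", list())
  series
}

#' Run the full preprocessing chain
#'
#' [subtract_ambient()], [lowpass_decimate()], [mbll()], [detrend_linear()]
#' in the fixed order of the acquisition/analysis chain.
#'
#' @param raw a [raw_recording()]
#' @param ... passed on to [lowpass_decimate()] and [mbll()] (matched by
#'   name: `order`, `atten_db`, `edge_hz`, `target_rate`, `type`,
#'   `zero_phase`, `dpf`, `extinction`, `distance_mm`, `ref`)
#' @return a detrended `hemo_series`
#' @export
preprocess <- function(raw, ...) {
  dots <- list(...)
  pick <- function(names) dots[intersect(names(dots), names)]
  x <- subtract_ambient(raw)
  x <- do.call(lowpass_decimate,
               c(list(x), pick(c("order", "atten_db", "edge_hz", "target_rate",
                                 "type", "zero_phase"))))
  x <- do.call(mbll, c(list(x), pick(c("dpf", "extinction", "distance_mm", "ref"))))
  detrend_linear(x)
}

#' Replay a processing log
#'
#' Re-applies the steps recorded in a processing log, in order, to a raw
#' recording. Reproduces the logged output bit-identically (all steps are
#' deterministic).
#'
#' @param raw the original [raw_recording()]
#' @param log a processing log (the `log` field of a processed object)
#' @return the reprocessed object
#' @export
replay_processing <- function(raw, log) {
  x <- raw
  for (entry in log) {
    x <- switch(entry$step,
                subtract_ambient = subtract_ambient(x),
                lowpass_decimate = do.call(lowpass_decimate, c(list(x), entry$params)),
                mbll = do.call(mbll, c(list(x), entry$params)),
                detrend_linear = detrend_linear(x),
                stop("unknown processing step: ", entry$step))
  }
  x
}
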