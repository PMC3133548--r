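make_raw <- function(intensity_value = 100, ambient_value = 0, n = 1000,
                     rate = 100) {
  intensity <- array(intensity_value, c(1, 2, n))
  ev <- data.frame(trial = 1L, onset_s = 2, duration_s = 3,
                   condition = "MI-simple")
  raw_recording(sampling_rate = rate, time = (seq_len(n) - 1) / rate,
                intensity = intensity, ambient = rep(ambient_value, n),
                events = ev, wavelengths = c(760, 870), distance_mm = 12.5)
}

test_that("ambient subtraction is samplewise and guards against non-positive output", {
  raw <- make_raw(100, 10)
  out <- subtract_ambient(raw)
  expect_true(all(out$intensity == 90))

  raw0 <- make_raw(100, 0)
  out0 <- subtract_ambient(raw0)
  expect_identical(out0$intensity, raw0$intensity)

  bad <- make_raw(100, 100)
  expect_error(subtract_ambient(bad), "non-positive")
})

test_that("the designed filter honors its stopband and passband contract", {
  filt <- cheby_design(7, 20, 5, 100)
  # DC gain unity
  expect_equal(abs(filter_response(filt, 1e-9)), 1, tolerance = 1e-6)
  # >= 20 dB attenuation from the 5 Hz edge to Nyquist
  f_stop <- seq(5, 49.9, by = 0.1)
  expect_true(all(abs(filter_response(filt, f_stop)) <= 10^(-20 / 20) + 1e-9))

  # time-domain: 6 Hz sinusoid attenuated to <= 0.1 of its amplitude
  tt <- (0:9999) / 100
  y6 <- fnirsmi:::iir_filter(sin(2 * pi * 6 * tt), filt$b, filt$a)
  expect_lte(max(abs(y6[2000:10000])), 0.1)

  # passband: 0.05 Hz sinusoid passes with amplitude within [0.89, 1];
  # oracle is the designed filter's own frequency response
  h <- abs(filter_response(filt, 0.05))
  expect_gte(h, 0.89)
  expect_lte(h, 1)
  y_slow <- fnirsmi:::iir_filter(sin(2 * pi * 0.05 * tt), filt$b, filt$a)
  expect_equal(max(abs(y_slow[3000:10000])), h, tolerance = 1e-3)
})

test_that("lowpass_decimate keeps every k-th sample and preserves DC", {
  raw <- make_raw(250, 0, n = 1000)
  out <- lowpass_decimate(raw)
  expect_equal(dim(out$intensity)[3], 100)  # floor(1000 / 10)
  expect_equal(out$sampling_rate, 10)
  expect_equal(as.vector(out$intensity), rep(250, 200), tolerance = 1e-6 * 250)
  expect_error(lowpass_decimate(make_raw(), target_rate = 7), "divisor")
})

test_that("mbll inverts absorbance changes per its definition", {
  raw <- make_raw(500, 0, n = 500)
  h0 <- mbll(raw)
  expect_true(all(abs(h0$o2hb) < 1e-12))
  expect_true(all(abs(h0$hhb) < 1e-12))

  # halving the intensity at one wavelength => dA = log10(2) there
  raw2 <- raw
  post <- raw$time >= 2.5
  raw2$intensity[1, 1, post] <- 250
  ext <- default_extinction(c(760, 870))
  h <- mbll(raw2, extinction = ext)
  M <- diag(c(6.75, 6.50)) %*% ext * 1e-6 * 1.25
  expected <- solve(M, c(log10(2), 0))
  expect_equal(h$o2hb[1, which(post)[10]], unname(expected[1]), tolerance = 1e-9)
  expect_equal(h$hhb[1, which(post)[10]], unname(expected[2]), tolerance = 1e-9)

  expect_error(mbll(raw, extinction = matrix(1, 2, 2)), "singular")
})

test_that("linear detrending removes exactly the OLS line and is idempotent", {
  tt <- (0:999) / 10
  h <- make_hemo(3 + 0.01 * tt, rate = 10)
  out <- detrend_linear(h)
  expect_lt(max(abs(out$o2hb)), 1e-9)

  # a full-period sinusoid has zero mean but is NOT orthogonal to t over a
  # finite window (int t sin(wt) dt = -T/w over whole periods), so the OLS
  # line is small-but-nonzero; detrend must remove exactly that line
  s <- sin(2 * pi * 0.1 * tt[1:1000])
  hs <- make_hemo(s, rate = 10)
  outs <- detrend_linear(hs)
  line <- fitted(lm(s ~ tt[1:1000]))
  expect_equal(outs$o2hb[1, ], s - line, tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_lt(max(abs(line)), 0.1)  # ~= 12 / (w * T^2) * amplitude scale

  once <- detrend_linear(h)
  twice <- detrend_linear(once)
  expect_equal(twice$o2hb, once$o2hb, tolerance = 1e-9)
  # residual slope
  fit <- lm(out$o2hb[1, ] ~ tt)
  expect_lt(abs(coef(fit)[2]), 1e-12)
})

test_that("the full chain recovers noise-free responses within 2% of peak", {
  cfg <- quiet_config(seed = 61)
  sim <- simulate_subject(cfg, noise = FALSE)
  # zero-phase filtering isolates magnitude fidelity; the default causal
  # pass adds a ~0.06 s phase delay that alone contributes ~2% error on the
  # steepest response slopes (checked separately below at 3%)
  hemo <- preprocess(sim$raw, zero_phase = TRUE)
  truth10 <- sim$truth$o2hb[, seq(1, ncol(sim$truth$o2hb), by = 10)]
  # detrending removes the (zero-drift) mean; compare centered series,
  # excluding the first second of filter transient
  keep <- -(1:10)
  for (ch in 1:3) {
    rec <- hemo$o2hb[ch, keep]
    tr <- truth10[ch, keep]
    err <- (rec - mean(rec)) - (tr - mean(tr))
    expect_lt(max(abs(err)), 0.02 * max(tr))
  }
  # causal default: same bound plus the phase-delay contribution
  hemo_c <- preprocess(sim$raw)
  for (ch in 1:3) {
    rec <- hemo_c$o2hb[ch, keep]
    tr <- truth10[ch, keep]
    err <- (rec - mean(rec)) - (tr - mean(tr))
    expect_lt(max(abs(err)), 0.03 * max(tr))
  }
})

test_that("replaying the processing log reproduces the output bit-identically", {
  cfg <- generator_config(seed = 41, n_trials_per_condition = 2)
  sim <- simulate_subject(cfg)
  hemo <- preprocess(sim$raw)
  again <- replay_processing(sim$raw, hemo$log)
  expect_identical(again$o2hb, hemo$o2hb)
  expect_identical(again$hhb, hemo$hhb)
  expect_equal(length(hemo$log), 4)
})
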