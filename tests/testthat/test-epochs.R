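test_that("epoching counts trials, drops truncated ones, and is lossless", {
  cfg <- quiet_config(seed = 13)
  sim <- simulate_subject(cfg, noise = FALSE)
  hemo <- preprocess(sim$raw)
  ep <- epoch(hemo)
  expect_equal(n_epochs(ep), 72)  # 24 trials x 3 channels

  # a trial with no preceding rest is dropped
  ev_bad <- hemo$events
  ev_bad$onset_s[1] <- 0
  expect_warning(ep_bad <- epoch(hemo, ev_bad), "dropped")
  expect_equal(n_epochs(ep_bad), 69)

  # losslessness: concatenated rest+stim reproduces the series span exactly
  r <- hemo$sampling_rate
  i <- 5
  i0 <- round(hemo$events$onset_s[i] * r)
  span <- hemo$o2hb[2, (i0 - 200 + 1):(i0 + 150)]
  expect_identical(c(ep$rest_o2hb[i, 2, ], ep$stim_o2hb[i, 2, ]), span)

  # corrected stimulation trace identity
  expect_equal(mean(ep$corrected_stim_o2hb[i, 2, ]),
               mean(ep$stim_o2hb[i, 2, ]) - ep$baseline_o2hb[i, 2])
})

test_that("noiseless epochs carry the configured per-trial peak amplitudes", {
  cfg <- quiet_config(amp_mode = "peak", seed = 23)
  ev <- build_event_table(cfg)
  gt <- simulate_hemodynamics(cfg, ev)
  ep <- hemo_epochs(cfg)
  # trial 1 has a clean baseline (the opening rest), so its corrected peak
  # equals the configured amplitude up to the in-window fraction of the
  # unit-response peak (0.9992 here, the response peaks ~1 s after offset)
  expect_equal(max(ep$corrected_stim_o2hb[1, 1, ]),
               gt$trial_amps_o2hb[1, 1], tolerance = 0.01)
  # later trials: the previous trial's response tail elevates the rest
  # baseline (~25% of the preceding amplitude over a 20 s rest), so the
  # corrected peak is systematically below the configured amplitude
  for (i in c(9, 24)) {
    expect_lt(max(ep$corrected_stim_o2hb[i, 1, ]), gt$trial_amps_o2hb[i, 1])
    expect_equal(max(ep$corrected_stim_o2hb[i, 1, ]),
                 gt$trial_amps_o2hb[i, 1], tolerance = 0.4)
  }
})

test_that("paired t-test matches the closed form and flags degeneracy", {
  # differences 1, 2, 3: t = 2 / (1 / sqrt(3)), p from t distribution, df 2
  res <- paired_ttest(c(2, 4, 6), c(1, 2, 3))
  expect_equal(res$t, 3.4641016, tolerance = 1e-6)
  expect_equal(res$p, 0.0741799, tolerance = 1e-6)
  expect_equal(res$df, 2)
  # agreement with the standard library implementation on random data
  set.seed(42)
  for (i in 1:5) {
    a <- rnorm(12); b <- rnorm(12)
    ref <- t.test(a, b, paired = TRUE)
    res <- paired_ttest(a, b)
    expect_equal(res$t, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(res$p, ref$p.value, tolerance = 1e-12)
  }
  # zero-variance differences: degenerate, not infinite
  deg <- paired_ttest(c(1, 2, 3), c(1, 2, 3))
  expect_true(deg$degenerate)
  expect_true(is.na(deg$t))
  # zero mean with spread: t = 0, p = 1
  z <- paired_ttest(c(0, 0.001, -0.001), c(0, 0, 0))
  expect_equal(z$t, 0)
  expect_equal(z$p, 1)
  expect_error(paired_ttest(1, 2), "at least 2")
})

test_that("snr is mean over sample SD with an undefined flag", {
  expect_true(snr(c(1, 1, 1))$undefined)
  s <- snr(c(0, 2))
  expect_equal(s$snr, 1 / sqrt(2), tolerance = 1e-9)
  expect_false(s$undefined)
})

test_that("snr of trial differences approaches the configured ratio", {
  # additive per-trial amplitude SD 0.1 around mean 0.2 => SNR -> 2
  cfg <- quiet_config(amp_o2hb = c(0.2, 0.2), trial_amp_sd = 0.1,
                      n_trials_per_condition = 24)
  snrs <- vapply(1:12, function(s) {
    cfg$seed <- s * 101
    cs <- channel_stats(hemo_epochs(cfg))
    mean(cs$snr[cs$chromophore == "o2hb"])
  }, numeric(1))
  se <- sd(snrs) / sqrt(length(snrs))
  expect_lt(abs(mean(snrs) - 2), 2 * se + 0.25)
})

test_that("exclusion rules drop null channels and null subjects", {
  stats_tab <- function(p_by_channel) {
    do.call(rbind, lapply(seq_along(p_by_channel), function(ch) {
      data.frame(channel = ch, condition = c("MI-simple", "MI-complex"),
                 chromophore = "o2hb", p = p_by_channel[[ch]])
    }))
  }
  # all channels strongly significant
  ex <- apply_exclusions(stats_tab(list(c(1e-5, 1e-5), c(1e-5, 1e-5), c(1e-5, 1e-5))))
  expect_false(any(ex$channel_excluded))
  expect_false(ex$subject_excluded)
  # one null channel
  ex1 <- apply_exclusions(stats_tab(list(c(0.5, 0.8), c(1e-5, 1e-5), c(1e-5, 1e-4))))
  expect_equal(ex1$channel_excluded, c(TRUE, FALSE, FALSE))
  expect_false(ex1$subject_excluded)
  # everything null in task and control
  null_tab <- stats_tab(list(c(0.4, 0.6), c(0.2, 0.9), c(0.35, 0.7)))
  ex2 <- apply_exclusions(null_tab, stats_control = null_tab)
  expect_true(ex2$subject_excluded)
  # null task but significant control: subject kept
  sig_tab <- stats_tab(list(c(1e-4, 1e-4), c(1e-4, 1e-4), c(1e-4, 1e-4)))
  ex3 <- apply_exclusions(null_tab, stats_control = sig_tab)
  expect_false(ex3$subject_excluded)
})

test_that("simulated null subjects are excluded, active ones kept", {
  # a null subject is kept only when at least one of the 6 (channel,
  # condition) tests is falsely significant at 0.05: exclusion probability
  # is 0.95^6 ~ 0.735 per subject
  n_excluded <- 0
  for (s in 1:12) {
    cfg <- quiet_config(amp_o2hb = c(0, 0), amp_hhb = c(0, 0),
                        trial_amp_sd = 0.05, seed = 7000 + s)
    ex <- apply_exclusions(channel_stats(hemo_epochs(cfg)))
    if (ex$subject_excluded) n_excluded <- n_excluded + 1
  }
  expect_gte(n_excluded, 6)

  # single active channel with a strong effect: that channel is kept
  cfg <- quiet_config(amp_o2hb = rbind(c(0.02, 0.5, 0.02), c(0.02, 1.0, 0.02)),
                      amp_hhb = matrix(0, 2, 3), trial_amp_sd = 0.05, seed = 3)
  ex <- apply_exclusions(channel_stats(hemo_epochs(cfg)))
  expect_false(ex$channel_excluded[2])
})
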