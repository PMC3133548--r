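test_that("event table implements the randomized block design", {
  cfg <- generator_config(seed = 5)
  ev <- build_event_table(cfg)
  expect_equal(nrow(ev), 24)
  expect_equal(attr(ev, "total_duration_s"), 840)  # 14 min
  expect_equal(as.vector(table(ev$condition)), c(12, 12))
  expect_equal(ev$onset_s, 20 + (0:23) * 35)
  expect_equal(ev$duration_s, rep(15, 24))

  tiny <- generator_config(n_trials_per_condition = 1)
  ev1 <- build_event_table(tiny)
  expect_equal(nrow(ev1), 2)
  expect_equal(attr(ev1, "total_duration_s"), 70)

  expect_identical(build_event_table(cfg)$condition,
                   build_event_table(cfg)$condition)
  expect_false(identical(build_event_table(generator_config(seed = 5))$condition,
                         build_event_table(generator_config(seed = 6))$condition))
})

test_that("zero-amplitude hemodynamics reduce to drift plus oscillations", {
  cfg <- quiet_config(amp_o2hb = c(0, 0), amp_hhb = c(0, 0),
                      drift_slope = 0.12, seed = 9)
  gt <- simulate_hemodynamics(cfg, build_event_table(cfg))
  drift <- 0.12 * gt$time / 60
  for (ch in 1:3) expect_equal(gt$o2hb[ch, ], drift, tolerance = 1e-12)

  # with oscillations: rest phases outside response tails are drift + osc only
  cfg2 <- generator_config(trial_amp_sd = 0, trial_amp_sd_hhb = 0,
                           white_noise_sd = 0, seed = 9)
  gt2 <- simulate_hemodynamics(cfg2, build_event_table(cfg2))
  cfg2z <- cfg2
  cfg2z$amp_o2hb[] <- 0
  gt2z <- simulate_hemodynamics(cfg2z, build_event_table(cfg2z))
  # last 2 s of each rest phase are >18 s after the previous offset:
  # response tail is < 1e-3 of peak there by kernel construction
  idx <- unlist(lapply(gt2$events$onset_s, function(on) {
    (round((on - 2) * 100) + 1):round(on * 100)
  }))
  expect_lt(max(abs(gt2$o2hb[1, idx] - gt2z$o2hb[1, idx])), 2e-3 * max(cfg2$amp_o2hb))
})

test_that("peak amplitude mode yields unit-peak responses", {
  cfg <- quiet_config(n_trials_per_condition = 1, amp_mode = "peak",
                      amp_o2hb = c(0.25, 0), amp_hhb = c(0, 0), seed = 2)
  ev <- build_event_table(cfg)
  gt <- simulate_hemodynamics(cfg, ev)
  expect_equal(max(gt$o2hb[1, ]), 0.25, tolerance = 1e-9)
})

test_that("kernels wider than a trial cycle are rejected unless allowed", {
  cfg <- quiet_config(hrf_peak = 25, hrf_fwhm = 30)
  ev <- build_event_table(cfg)
  expect_error(simulate_hemodynamics(cfg, ev), "allow_overlap")
  cfg$allow_overlap <- TRUE
  expect_s3_class(simulate_hemodynamics(cfg, ev), "ground_truth")
})

test_that("forward optics is the exact algebraic inverse of mbll", {
  cfg <- quiet_config(seed = 31)
  sim <- simulate_subject(cfg, noise = FALSE)
  # zero ground truth: constant intensities
  cfg0 <- quiet_config(amp_o2hb = c(0, 0), amp_hhb = c(0, 0), seed = 31)
  sim0 <- simulate_subject(cfg0, noise = FALSE)
  expect_equal(as.vector(sim0$raw$intensity),
               rep(cfg$baseline_intensity + cfg$ambient_level,
                   length(sim0$raw$intensity)),
               tolerance = 1e-12)
  # roundtrip, no filtering
  h <- mbll(subtract_ambient(sim$raw))
  expect_lt(max(abs(h$o2hb - sim$truth$o2hb)), 1e-9)
  expect_lt(max(abs(h$hhb - sim$truth$hhb)), 1e-9)
})

test_that("inverting with a stale distance rescales concentrations accordingly", {
  cfg <- quiet_config(distance_mm = 25, seed = 12)
  sim <- simulate_subject(cfg, noise = FALSE)
  h_right <- mbll(subtract_ambient(sim$raw), distance_mm = 25)
  h_wrong <- mbll(subtract_ambient(sim$raw), distance_mm = 12.5)
  expect_equal(h_wrong$o2hb, 2 * h_right$o2hb, tolerance = 1e-9)
})

test_that("mbll is linear in the underlying concentrations", {
  cfg <- quiet_config(seed = 17)
  sim <- simulate_subject(cfg, noise = FALSE)
  cfg3 <- quiet_config(seed = 17, amp_o2hb = 3 * cfg$amp_o2hb,
                       amp_hhb = 3 * cfg$amp_hhb)
  sim3 <- simulate_subject(cfg3, noise = FALSE)
  h1 <- mbll(subtract_ambient(sim$raw))
  h3 <- mbll(subtract_ambient(sim3$raw))
  expect_equal(h3$o2hb, 3 * h1$o2hb, tolerance = 1e-9)
})

test_that("identical config and seed give bit-identical recordings", {
  cfg <- generator_config(seed = 77)
  s1 <- simulate_subject(cfg)
  s2 <- simulate_subject(cfg)
  expect_identical(s1$raw$intensity, s2$raw$intensity)
  expect_identical(s1$truth$o2hb, s2$truth$o2hb)
})

test_that("stronger amplitudes strictly increase downstream effect sizes", {
  diffs <- vapply(c(0.05, 0.1, 0.2), function(a) {
    cfg <- quiet_config(amp_o2hb = c(a, a), amp_hhb = c(0, 0), seed = 4)
    sim <- simulate_subject(cfg, noise = FALSE)
    cs <- channel_stats(epoch(preprocess(sim$raw)))
    mean(cs$mean_diff[cs$chromophore == "o2hb"])
  }, numeric(1))
  expect_true(all(diff(diffs) > 0))
})

test_that("multi-subject studies are reproducible and positively scaled", {
  cfg <- generator_config(seed = 21)
  st1 <- simulate_study(cfg, n_subjects = 3, seed = 99)
  st2 <- simulate_study(cfg, n_subjects = 3, seed = 99)
  expect_identical(st1[[2]]$raw$intensity, st2[[2]]$raw$intensity)
  expect_length(st1, 3)
  for (su in st1) expect_true(all(su$config$amp_o2hb > 0))
})

test_that("raw recordings survive the CSV roundtrip", {
  cfg <- quiet_config(n_trials_per_condition = 2, seed = 8)
  sim <- simulate_subject(cfg)
  dir <- withr::local_tempdir()
  paths <- write_raw_recording(sim$raw, dir)
  back <- read_raw_recording(paths["data"], paths["events"])
  expect_equal(back$intensity, sim$raw$intensity, tolerance = 1e-9)
  expect_equal(back$events$condition, sim$raw$events$condition)
  expect_equal(back$sampling_rate, 100)
})
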