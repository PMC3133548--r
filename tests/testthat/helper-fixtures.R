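# Shared fixtures and independent oracles, all built in code.

# Small, fast generator config: clean signal unless noise is asked for.
quiet_config <- function(...) {
  args <- utils::modifyList(
    list(drift_slope = 0, osc_components = list(), white_noise_sd = 0,
         trial_amp_sd = 0, trial_amp_sd_hhb = 0),
    list(...))
  do.call(generator_config, args)
}

# Wrap matrices into a hemo_series (for tests that bypass the optics).
make_hemo <- function(o2hb, hhb = o2hb * 0, rate = 10, events = NULL) {
  o2hb <- rbind(o2hb)
  hhb <- rbind(hhb)
  structure(list(sampling_rate = rate,
                 time = (seq_len(ncol(o2hb)) - 1) / rate,
                 o2hb = o2hb, hhb = hhb,
                 events = events, log = list()),
            class = "hemo_series")
}

# Epochs for a synthetic subject simulated directly in concentration space
# (no optics/filtering): ground-truth hemodynamics plus optional white
# noise at the analysis rate. Fast path for classifier calibration tests.
hemo_epochs <- function(cfg, noise_sd = 0) {
  ev <- build_event_table(cfg)
  gt <- simulate_hemodynamics(cfg, ev)
  o2 <- gt$o2hb
  if (noise_sd > 0)
    o2 <- o2 + matrix(rnorm(length(o2), 0, noise_sd), nrow(o2))
  h <- structure(list(sampling_rate = cfg$sampling_rate, time = gt$time,
                      o2hb = o2, hhb = gt$hhb, events = ev, log = list()),
                 class = "hemo_series")
  epoch(h, rest_duration = cfg$rest_duration, stim_duration = cfg$stim_duration)
}

# Independent textbook-formula oracles for the sample moments (standard
# SAS/adjusted formulations, algebraically distinct code path from the
# package's central-moment route).
oracle_skewness <- function(x) {
  n <- length(x)
  s <- sd(x)
  (n / ((n - 1) * (n - 2))) * sum(((x - mean(x)) / s)^3)
}
oracle_kurtosis <- function(x) {
  n <- length(x)
  s <- sd(x)
  (n * (n + 1) / ((n - 1) * (n - 2) * (n - 3))) * sum(((x - mean(x)) / s)^4) -
    3 * (n - 1)^2 / ((n - 2) * (n - 3))
}
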