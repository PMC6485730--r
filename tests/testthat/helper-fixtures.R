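# Shared fixture builders. Everything is generated in code at test time.

# Noiseless nerve-twitch parameter set used by several metric tests.
nerve_like_params <- function(target_peak = NULL, latency = 5) {
  twitch_params(A_max = 10, d50 = 0.5, h = 4, tau_rise = 5,
                tau_fatigue = 1e5, tau_decay = 15, plateau_fraction = 1,
                latency_ms = latency, noise_sd = 0,
                target_peak_deg = target_peak)
}

# Small two-subject session written to a CSV; returns the path.
write_toy_traces <- function(path, n_subjects = 2, noise_sd = 0.1,
                             seed = 11) {
  spec <- cohort_spec(n_subjects = n_subjects, days = 0L,
                      twitch_by_day = twitch_params(noise_sd = noise_sd),
                      durations_ms = c(5, 1000), replicates = 1L,
                      cv = 0.2, trial_length_ms = 400, stim_onset_ms = 200)
  # trial_length shorter than the long stimulus is invalid; use 1500
  spec$trial_length_ms <- 1500
  ss <- simulate_session(spec, seed = seed)
  write_traces(ss, path)
  ss
}

# Direct (oracle) evaluation of the twitch closed form, independent of the
# package internals.
oracle_twitch <- function(tt, A, tau_rise, tau_fatigue, p, tau_decay,
                          d, onset, latency) {
  u <- tt - onset - latency
  r <- numeric(length(tt))
  on <- u >= 0 & u <= d
  r[on] <- A * (1 - exp(-u[on] / tau_rise)) *
    (p + (1 - p) * exp(-u[on] / tau_fatigue))
  off <- u > d
  rend <- A * (1 - exp(-d / tau_rise)) * (p + (1 - p) * exp(-d / tau_fatigue))
  r[off] <- rend * exp(-(u[off] - d) / tau_decay)
  r
}

# Piecewise-linear trace through (time, value) anchor points on a 2-ms grid.
piecewise_trace <- function(anchors_t, anchors_v, trial_length = 3000,
                            onset = 200, stim_duration = 1000) {
  tt <- seq(0, trial_length, by = 2)
  angle_trace(approx(anchors_t, anchors_v, xout = tt, rule = 2)$y,
              stim_duration_ms = stim_duration, stim_onset_ms = onset)
}

expect_trace_equal <- function(a, b, tol = 1e-12) {
  expect_equal(a$angle_deg, b$angle_deg, tolerance = tol)
  expect_identical(a$mask, b$mask)
  expect_equal(a$stim_onset_ms, b$stim_onset_ms)
  expect_equal(a$sample_period_ms, b$sample_period_ms)
}
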