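test_that("baseline is the pre-stimulus mean", {
  const <- angle_trace(rep(5, 500), stim_onset_ms = 400)
  expect_equal(baseline_angle(const), 5)
  tt <- seq(0, 998, by = 2)
  ramp <- angle_trace(ifelse(tt < 400, 0, (tt - 400) / 50),
                      stim_onset_ms = 400)
  expect_equal(baseline_angle(ramp), 0)
  set.seed(9)
  noisy_vals <- rnorm(500)
  noisy <- angle_trace(noisy_vals, stim_onset_ms = 400)
  sel <- tt >= 200 & tt < 400
  expect_equal(baseline_angle(noisy, 200), mean(noisy_vals[sel]))
  expect_error(baseline_angle(angle_trace(c(1, 2), stim_onset_ms = 0)),
               "window")
})

test_that("smoothed derivative is exact on polynomials and accurate on tones", {
  tt <- seq(0, 2000, by = 2)
  ramp <- tt / 2  # 1 deg per frame at 2 ms/frame -> 500 deg/s
  v <- smooth_and_differentiate(ramp, sample_period_ms = 2)
  interior <- 10:(length(v) - 10)
  expect_equal(v[interior], rep(500, length(interior)), tolerance = 1e-9)
  sine <- 5 * sin(2 * pi * 5 * tt / 1000)
  vs <- smooth_and_differentiate(sine, sample_period_ms = 2)
  expect_equal(max(vs), 2 * pi * 5 * 5, tolerance = 0.01)
  expect_lt(max(abs(smooth_and_differentiate(rep(3, 500),
                                             sample_period_ms = 2))), 1e-9)
  expect_error(smooth_and_differentiate(1:5, sample_period_ms = 2),
               "shorter")
  expect_error(smooth_and_differentiate(1:50, window_samples = 10,
                                        sample_period_ms = 2), "odd")
})

test_that("metrics on the calibrated exponential rise match closed forms", {
  tr <- exp_rise_trace(asymptote_deg = 10, tau_ms = 100,
                       stim_duration_ms = 1000)
  m <- extract_metrics(tr)
  expect_equal(m$peak_amplitude_deg, 10 * (1 - exp(-1000 / 100)),
               tolerance = 0.001)
  expect_equal(m$persistence_index, 1, tolerance = 0.001)
  # peak velocity A/tau = 100 deg/s, resolvable at tau = 100 ms
  expect_equal(m$peak_velocity_deg_per_s, 10 / 100 * 1000, tolerance = 0.02)
})

test_that("persistence index reproduces a constructed settling response", {
  # rises to 10 deg, settles to 3.012 deg by stimulus offset
  tr <- piecewise_trace(c(0, 200, 250, 700, 1200, 1500, 3000),
                        c(0, 0, 10, 3.012, 3.012, 0, 0))
  m <- extract_metrics(tr)
  expect_equal(m$peak_amplitude_deg, 10)
  expect_equal(m$persistence_index, 0.3012, tolerance = 1e-9)
})

test_that("zero traces are flagged no-response with null time metrics", {
  z <- angle_trace(rep(0, 1501), stim_duration_ms = 1000,
                   stim_onset_ms = 200)
  m <- extract_metrics(z)
  expect_true(m$no_response)
  expect_equal(m$peak_amplitude_deg, 0)
  expect_true(is.na(m$time_to_peak_ms))
  expect_true(is.na(m$half_width_ms))
})

test_that("half-width is the interpolated FWHM", {
  # symmetric triangular bump: base 40 ms, peak 10 deg -> FWHM 20 ms
  tr <- piecewise_trace(c(0, 200, 220, 240, 3000), c(0, 0, 10, 0, 0),
                        stim_duration = 5)
  m <- extract_metrics(tr)
  expect_equal(m$half_width_ms, 20, tolerance = 1e-9)
  expect_false(m$censored_half_width)
  # Gaussian bump with analytic FWHM
  g <- gaussian_bump_trace(peak_deg = 10, fwhm_ms = 100)
  expect_equal(extract_metrics(g)$half_width_ms, 100, tolerance = 2)
  # response still above half max at trace end -> censored
  never_down <- piecewise_trace(c(0, 200, 400, 3000), c(0, 0, 10, 9),
                                stim_duration = 1000)
  expect_true(extract_metrics(never_down)$censored_half_width)
})

test_that("averaging is the pointwise mean and respects masks", {
  a <- angle_trace(rep(1, 300), stim_onset_ms = 100)
  b <- angle_trace(rep(3, 300), stim_onset_ms = 100)
  avg <- average_traces(list(a, b))
  expect_true(all(avg$angle_deg == 2))
  expect_equal(attr(avg, "n_averaged"), 2)
  same <- average_traces(list(a, a, a))
  expect_true(all(same$angle_deg == 1))
  # a frame masked in one trial falls back to the remaining trials
  am <- a
  am$mask[50] <- TRUE
  avg2 <- average_traces(list(am, b))
  expect_equal(avg2$angle_deg[50], 3)
  expect_equal(avg2$angle_deg[51], 2)
  short <- angle_trace(rep(1, 200), stim_onset_ms = 100)
  expect_error(average_traces(list(a, short)), "shape")
})

test_that("duration families recover the Hill amplitude curve", {
  # sub-ms rise so the realized peak equals the Hill drive A(d)
  p <- twitch_params(A_max = 10, d50 = 10, h = 2, tau_rise = 0.2,
                     tau_fatigue = 1e6, tau_decay = 100,
                     plateau_fraction = 1, latency_ms = 0, noise_sd = 0)
  spec <- cohort_spec(n_subjects = 1, days = 0L, twitch_by_day = p,
                      replicates = 1L, cv = 0)
  ss <- simulate_session(spec, seed = 1)
  fam <- duration_family(ss)
  hill <- function(d) 10 * d^2 / (d^2 + 100)
  for (i in seq_len(nrow(fam)))
    expect_equal(fam$peak_amplitude_deg[i], hill(fam$stim_duration_ms[i]),
                 tolerance = 0.02)
  # single-duration family
  one <- duration_family(subset_session(ss, stim_duration_ms = 1000))
  expect_equal(nrow(one), 1)
})

test_that("sensitivity threshold matches criterion crossing and inversion", {
  fam <- data.frame(subject = "s", day = 0, absent = FALSE,
                    stim_duration_ms = c(1, 3, 5, 10),
                    peak_amplitude_deg = c(0.1, 0.5, 2, 8))
  expect_equal(sensitivity_threshold(fam, 1), 5)
  fam$peak_amplitude_deg <- fam$peak_amplitude_deg / 100
  expect_true(is.na(sensitivity_threshold(fam, 1)))
  # noiseless Hill family: threshold equals the analytic inversion
  # d* = d50 * (c / (A_max - c))^(1/h), rounded up to the protocol ladder
  p <- twitch_params(A_max = 10, d50 = 10, h = 2, tau_rise = 0.2,
                     tau_fatigue = 1e6, tau_decay = 100,
                     plateau_fraction = 1, latency_ms = 0, noise_sd = 0)
  ss <- simulate_session(cohort_spec(1, 0L, p, replicates = 1L, cv = 0),
                         seed = 1)
  famh <- duration_family(ss)
  d_star <- 10 * (1 / (10 - 1))^(1 / 2)
  ladder <- famh$stim_duration_ms
  expect_equal(sensitivity_threshold(famh, 1),
               min(ladder[ladder >= d_star]))
})

test_that("percent of baseline reproduces the worked arithmetic", {
  expect_equal(percent_of_baseline(0.7655, 0.3012), 254)
  expect_equal(percent_of_baseline(13.90, 2.75), 505)
  expect_equal(percent_of_baseline(4.2, 4.2), 100)
  expect_error(percent_of_baseline(1, 0), "baseline")
})

test_that("group summaries average within then between subjects", {
  df <- data.frame(subject = rep(c("a", "b", "c"), 2),
                   day = rep(c(0, 7), each = 3),
                   amp = c(1, 2, 3, 2, 4, 9))
  gs <- group_summary(df, "amp")
  st <- gs$stats
  expect_equal(st$mean[st$day == 0], mean(1:3))
  expect_equal(st$se[st$day == 7], sd(c(2, 4, 9)) / sqrt(3))
  expect_equal(gs$direction$n_increased, 3)
  expect_equal(gs$direction$n_total, 3)
  # 8 of 9 subjects increasing is reported as such
  df9 <- data.frame(subject = rep(sprintf("s%d", 1:9), 2),
                    day = rep(c(0, 7), each = 9),
                    amp = c(rep(1, 9), c(rep(2, 8), 0.5)))
  gs9 <- group_summary(df9, "amp")
  expect_equal(gs9$direction$n_increased, 8)
  expect_equal(gs9$direction$n_total, 9)
  expect_warning(
    group_summary(df[df$subject == "a" & df$day == 0, ], "amp"), "n = 1")
})

test_that("metrics are homogeneous in amplitude and shift invariant", {
  p <- twitch_params(A_max = 10, d50 = 5, h = 2, tau_rise = 15,
                     tau_fatigue = 300, tau_decay = 50,
                     plateau_fraction = 0.4, latency_ms = 5, noise_sd = 0)
  base <- simulate_twitch(p, 1000, 200)
  m0 <- extract_metrics(base)
  for (k in c(0.5, 2, 3)) {
    scaled <- base
    scaled$angle_deg <- k * base$angle_deg
    mk <- extract_metrics(scaled)
    expect_equal(mk$peak_amplitude_deg, k * m0$peak_amplitude_deg,
                 tolerance = 1e-12)
    expect_equal(mk$peak_velocity_deg_per_s, k * m0$peak_velocity_deg_per_s,
                 tolerance = 1e-12)
    expect_equal(mk$time_to_peak_ms, m0$time_to_peak_ms)
    expect_equal(mk$half_width_ms, m0$half_width_ms, tolerance = 1e-12)
    expect_equal(mk$persistence_index, m0$persistence_index,
                 tolerance = 1e-12)
  }
  for (shift in c(100, 400)) {
    moved <- simulate_twitch(p, 1000, 200 + shift,
                             trial_length_ms = 3000 + shift)
    ms <- extract_metrics(moved)
    expect_equal(ms$peak_amplitude_deg, m0$peak_amplitude_deg,
                 tolerance = 1e-12)
    expect_equal(ms$time_to_peak_ms, m0$time_to_peak_ms)
    expect_equal(ms$half_width_ms, m0$half_width_ms, tolerance = 1e-9)
    expect_equal(ms$persistence_index, m0$persistence_index,
                 tolerance = 1e-12)
  }
})

test_that("persistence index stays in [0,1] and tracks the plateau fraction", {
  # fast rise, fatigue converged within the stimulus
  for (pl in c(0.2, 0.5, 0.8)) {
    p <- twitch_params(A_max = 10, d50 = 0, tau_rise = 5, tau_fatigue = 200,
                       tau_decay = 50, plateau_fraction = pl,
                       latency_ms = 5, noise_sd = 0.2)
    tr <- simulate_twitch(p, 1000, 200, seed = round(1000 * pl))
    m <- extract_metrics(tr)
    expect_gte(m$persistence_index, 0)
    expect_lte(m$persistence_index, 1)
    expect_lte(abs(m$persistence_index - pl), 0.05)
  }
})

test_that("day-7 preset amplifies short stimuli more than long ones", {
  pr <- demo_presets()$muscle$twitch_by_day
  noiseless <- function(q) { q$noise_sd <- 0; q }
  amp <- function(q, d) max(simulate_twitch(noiseless(q), d, 200)$angle_deg)
  gain5 <- amp(pr[["7"]], 5) / amp(pr[["-1"]], 5)
  gain1000 <- amp(pr[["7"]], 1000) / amp(pr[["-1"]], 1000)
  expect_gt(gain5, gain1000)
  expect_gt(gain1000, 1)
})
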