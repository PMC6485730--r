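test_that("noise-free twitch matches its closed form on the sample grid", {
  p <- twitch_params(A_max = 8, d50 = 12, h = 2, tau_rise = 15,
                     tau_fatigue = 300, tau_decay = 50,
                     plateau_fraction = 0.4, latency_ms = 7, noise_sd = 0)
  tr <- simulate_twitch(p, stim_duration_ms = 100, stim_onset_ms = 200)
  A <- 8 * 100^2 / (100^2 + 12^2)
  expected <- oracle_twitch(trace_time(tr), A, 15, 300, 0.4, 50,
                            100, 200, 7)
  expect_equal(tr$angle_deg, expected, tolerance = 1e-12)
})

test_that("zero-amplitude and degenerate stimuli behave as stated", {
  p0 <- twitch_params(A_max = 0, noise_sd = 0)
  tr <- simulate_twitch(p0, 100, 200)
  expect_true(all(tr$angle_deg == 0))
  expect_error(simulate_twitch(p0, 5000, 200, trial_length_ms = 3000),
               "past")
  expect_error(simulate_twitch(p0, -1, 200), "negative")
})

test_that("saturating amplitude follows the Hill curve and rise velocity A/tau", {
  # asymptote scaled to 10 deg for a long stimulus, no fatigue
  p <- twitch_params(A_max = 10, d50 = 0, tau_rise = 20, tau_fatigue = 1e6,
                     tau_decay = 20, plateau_fraction = 1, latency_ms = 0,
                     noise_sd = 0)
  tr <- simulate_twitch(p, 1000, 200, sample_period_ms = 0.1)
  expect_equal(max(tr$angle_deg), 10, tolerance = 1e-3)
  # dense-grid max derivative approximates A/tau = 500 deg/s
  v <- diff(tr$angle_deg) / 0.1 * 1000
  expect_equal(max(v), 500, tolerance = 5e-3)
  # amplitude ratio at d = d50 vs d >> d50 is 1/2
  ph <- twitch_params(A_max = 10, d50 = 10, h = 2, tau_rise = 0.5,
                      tau_fatigue = 1e6, tau_decay = 50,
                      plateau_fraction = 1, latency_ms = 0, noise_sd = 0)
  a_d50 <- max(simulate_twitch(ph, 10, 200)$angle_deg)
  a_sat <- max(simulate_twitch(ph, 1000, 200)$angle_deg)
  # A(1000)/A_max = 1000^2/(1000^2+10^2) ~ 1, so the ratio is ~ A(d50)/A_max
  expect_equal(a_d50 / a_sat, 0.5, tolerance = 0.01)
})

test_that("target_peak_deg calibrates the realized maximum exactly", {
  p <- nerve_like_params(target_peak = 8.77)
  tr <- simulate_twitch(p, 5, stim_onset_ms = 100)
  expect_equal(max(tr$angle_deg), 8.77, tolerance = 1e-6)
})

test_that("pure-tone fasciculation has exact peak-to-peak amplitude", {
  fp <- fasciculation_params(f0 = 6.5, p2p_deg = 2.45, mode = "pure",
                             noise_sd = 0)
  tr <- simulate_fasciculation(fp)
  expect_equal(max(tr$angle_deg) - min(tr$angle_deg), 2.45,
               tolerance = 1e-9)
  flat <- simulate_fasciculation(fasciculation_params(p2p_deg = 0,
                                                      noise_sd = 0))
  expect_true(all(flat$angle_deg == 0))
  expect_error(simulate_fasciculation(fasciculation_params(f0 = 300)),
               "Nyquist")
})

test_that("narrowband fasciculation concentrates power in 5-8 Hz", {
  fp <- fasciculation_params(p2p_deg = 2, mode = "narrowband", noise_sd = 0)
  tr <- simulate_fasciculation(fp, seed = 21)
  sp <- power_spectrum(tr)
  in_band <- sum(sp$power[sp$freq_hz >= 5 & sp$freq_hz <= 8])
  expect_gte(in_band / sum(sp$power), 0.9)
})

test_that("session simulation counts, determinism and CV = 0 collapse", {
  spec <- cohort_spec(n_subjects = 2, days = 0L,
                      twitch_by_day = twitch_params(noise_sd = 0.1),
                      replicates = 8L, cv = 0.2)
  ss <- simulate_session(spec, seed = 4)
  expect_equal(nrow(ss$index), 2 * 8 * 8)
  ss2 <- simulate_session(spec, seed = 4)
  for (i in seq_along(ss$traces))
    expect_identical(ss$traces[[i]]$angle_deg, ss2$traces[[i]]$angle_deg)
  # CV = 0, noiseless: all subjects share identical waveforms
  spec0 <- cohort_spec(n_subjects = 3, days = 0L,
                       twitch_by_day = twitch_params(noise_sd = 0),
                       durations_ms = c(10, 1000), replicates = 1L, cv = 0)
  s0 <- simulate_session(spec0, seed = 4)
  for (dur in c(10, 1000)) {
    sel <- which(s0$index$stim_duration_ms == dur)
    ref <- s0$traces[[sel[1]]]$angle_deg
    for (i in sel[-1]) expect_equal(s0$traces[[i]]$angle_deg, ref)
  }
})

test_that("planted DE structure is recovered exactly downstream", {
  sim <- simulate_de_tables(de_sim_spec(), seed = 2)
  sa <- filter_de(sim$a, day = 3)
  sb <- filter_de(sim$b, day = 3)
  expect_setequal(sa$transcript_id, sim$truth$planted_a)
  vn <- venn_sets(sa, sb)
  expect_equal(unname(vn$counts["common"]), 63)
  expect_equal(unname(vn$counts["union"]), 692)
  expect_equal(unname(vn$counts["unique_a"] + vn$counts["unique_b"]), 629)
  # same seed reproduces the tables bit for bit
  sim2 <- simulate_de_tables(de_sim_spec(), seed = 2)
  expect_identical(as.data.frame(sim$a), as.data.frame(sim2$a))
  expect_identical(sim$truth, sim2$truth)
  # infeasible overlap is rejected
  expect_error(de_sim_spec(n_sig_a = 10, n_sig_b = 10, n_common = 20),
               "infeasible")
})

test_that("null simulation yields at most alpha-bounded false positives", {
  for (seed in 1:20) {
    sim <- simulate_de_tables(
      de_sim_spec(n_transcripts = 500, fraction_de = 0), seed = seed)
    sa <- filter_de(sim$a, day = 3)
    expect_lte(nrow(sa), ceiling(0.05 * 500))
  }
})

test_that("kinematics recovers generator truths at low noise", {
  cfg <- default_config()
  # target peak within 2 % at noise 0.2 deg (averaged over 8 replicates)
  p <- twitch_params(A_max = 10, d50 = 0, tau_rise = 30, tau_fatigue = 400,
                     tau_decay = 60, plateau_fraction = 0.5,
                     latency_ms = 5, noise_sd = 0.2, target_peak_deg = 10)
  reps <- lapply(1:8, function(r)
    simulate_twitch(p, 1000, 200, seed = 100 + r, trial_index = r))
  m <- extract_metrics(average_traces(reps), cfg)
  expect_equal(m$peak_amplitude_deg, 10, tolerance = 0.02)
  # dominant frequency within one bin of the generator f0
  fp <- fasciculation_params(f0 = 6.5, p2p_deg = 2, mode = "pure",
                             noise_sd = 0.2)
  sp <- power_spectrum(simulate_fasciculation(fp, seed = 8))
  f_est <- sp$freq_hz[which.max(sp$power)]
  expect_lte(abs(f_est - 6.5), sp$freq_hz[2])
})
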