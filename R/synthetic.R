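#' @title Synthetic whisker-movement and transcriptome generators
#' @description Generators that emulate the statistical structure the
#'   analysis assumes: evoked protraction transients with duration-dependent
#'   amplitude saturation, adaptation/fatigue, latency, subject variability
#'   and frame noise; 5-8 Hz fasciculation oscillations; and transcript-level
#'   DE tables with planted overlap structure. Every generator is
#'   deterministic given its seed.
#' @name synthetic
NULL

# Run expr with a local RNG state; NULL seed consumes the global stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Twitch generator parameters
#'
#' Parameters of the evoked-response waveform model. During the stimulus
#' (time `u` since onset + latency) the noise-free response is
#' `A(d) * (1 - exp(-u/tau_rise)) * (p + (1-p) * exp(-u/tau_fatigue))`,
#' i.e. an exponential rise multiplied by exponential adaptation towards a
#' plateau fraction `p`; after stimulus offset it decays with `tau_decay`.
#' The drive amplitude saturates with stimulus duration `d` along a Hill
#' curve `A(d) = A_max * d^h / (d^h + d50^h)` (with `d50 = 0` meaning no
#' saturation). The four axes of the movement phenotype are thus
#' independently controlled: sensitivity by `d50`, amplitude by `A_max`,
#' velocity by `tau_rise`, fatigability by `p`.
#'
#' @param A_max saturating drive amplitude (deg).
#' @param d50 stimulus duration of half-maximal drive (ms); 0 disables
#'   saturation.
#' @param h Hill steepness (dimensionless, > 0).
#' @param tau_rise,tau_fatigue,tau_decay time constants (ms, > 0).
#' @param plateau_fraction plateau fraction `p` in [0, 1]; 1 = no fatigue.
#' @param latency_ms delay from light onset to movement onset (ms).
#' @param noise_sd per-frame Gaussian measurement noise SD (deg).
#' @param target_peak_deg optional calibration: rescale the waveform so its
#'   noise-free maximum (on a 0.1-ms grid) equals this value exactly.
#' @return a `twitch_params` list.
#' @export
twitch_params <- function(A_max = 10, d50 = 10, h = 1.5, tau_rise = 20,
                          tau_fatigue = 500, tau_decay = 40,
                          plateau_fraction = 0.5, latency_ms = 5,
                          noise_sd = 0.15, target_peak_deg = NULL) {
  stopifnot(A_max >= 0, d50 >= 0, h > 0, tau_rise > 0, tau_fatigue > 0,
            tau_decay > 0, plateau_fraction >= 0, plateau_fraction <= 1,
            latency_ms >= 0, noise_sd >= 0)
  structure(list(A_max = A_max, d50 = d50, h = h, tau_rise = tau_rise,
                 tau_fatigue = tau_fatigue, tau_decay = tau_decay,
                 plateau_fraction = plateau_fraction, latency_ms = latency_ms,
                 noise_sd = noise_sd, target_peak_deg = target_peak_deg),
            class = "twitch_params")
}

hill_amplitude <- function(params, d) {
  if (d <= 0) return(0)
  if (params$d50 == 0) return(params$A_max)
  params$A_max * d^params$h / (d^params$h + params$d50^params$h)
}

# Noise-free waveform at times tt (ms from trial start).
twitch_waveform <- function(tt, params, stim_duration_ms, stim_onset_ms) {
  A <- hill_amplitude(params, stim_duration_ms)
  p <- params$plateau_fraction
  u <- tt - stim_onset_ms - params$latency_ms
  r <- numeric(length(tt))
  on <- u >= 0 & u <= stim_duration_ms
  r[on] <- A * (1 - exp(-u[on] / params$tau_rise)) *
    (p + (1 - p) * exp(-u[on] / params$tau_fatigue))
  off <- u > stim_duration_ms
  if (any(off)) {
    r_end <- A * (1 - exp(-stim_duration_ms / params$tau_rise)) *
      (p + (1 - p) * exp(-stim_duration_ms / params$tau_fatigue))
    r[off] <- r_end * exp(-(u[off] - stim_duration_ms) / params$tau_decay)
  }
  r
}

# Noise-free maximum on a dense 0.1-ms grid (used for calibration).
twitch_dense_peak <- function(params, stim_duration_ms, stim_onset_ms,
                              trial_length_ms) {
  tt <- seq(stim_onset_ms, trial_length_ms, by = 0.1)
  w <- twitch_waveform(tt, params, stim_duration_ms, stim_onset_ms)
  list(peak = max(w), t_peak = tt[which.max(w)])
}

#' Simulate one evoked-twitch trial
#'
#' Evaluates the [twitch_params()] waveform model on the sample grid and
#' adds per-frame Gaussian noise. If `target_peak_deg` is set in the
#' parameters, the waveform is first rescaled so its noise-free maximum on
#' a 0.1-ms grid equals the target (the calibrated-primitive mechanism
#' used when a metric's ground truth must be set directly).
#'
#' @param params a [twitch_params()] object.
#' @param stim_duration_ms stimulus duration (ms, >= 0).
#' @param stim_onset_ms stimulus onset (ms from trial start).
#' @param trial_length_ms recorded trial length (ms).
#' @param sample_period_ms sample period (ms; default 2 = 500 frames/s).
#' @param time_start_ms time of the first sample.
#' @param seed RNG seed for the noise (`NULL` uses the global stream).
#' @param subject_id,day,trial_index trace annotation.
#' @return an [angle_trace()].
#' @export
simulate_twitch <- function(params, stim_duration_ms, stim_onset_ms = 200,
                            trial_length_ms = 3000, sample_period_ms = 2,
                            time_start_ms = 0, seed = NULL,
                            subject_id = "sim", day = 0L, trial_index = 1L) {
  if (stim_duration_ms < 0) stop("simulate_twitch: negative stimulus duration")
  if (stim_onset_ms + stim_duration_ms > trial_length_ms)
    stop("simulate_twitch: stimulus extends past the end of the trial")
  tt <- seq(time_start_ms, trial_length_ms, by = sample_period_ms)
  w <- twitch_waveform(tt, params, stim_duration_ms, stim_onset_ms)
  if (!is.null(params$target_peak_deg)) {
    dense <- twitch_dense_peak(params, stim_duration_ms, stim_onset_ms,
                               trial_length_ms)
    if (dense$peak > 0) w <- w * (params$target_peak_deg / dense$peak)
  }
  if (params$noise_sd > 0)
    w <- w + with_seed(seed, stats::rnorm(length(w), 0, params$noise_sd))
  angle_trace(w, subject_id = subject_id, day = day,
              trial_index = trial_index,
              stim_duration_ms = stim_duration_ms,
              stim_onset_ms = stim_onset_ms,
              sample_period_ms = sample_period_ms,
              time_start_ms = time_start_ms)
}

#' Calibrated exponential-rise primitive
#'
#' A saturation-free, fatigue-free twitch whose noise-free asymptote is
#' `asymptote_deg` and whose analytic peak velocity is
#' `asymptote_deg / tau_ms` deg/ms (i.e. `1000 * asymptote/tau` deg/s) at
#' movement onset. Used where a velocity or plateau ground truth must be
#' known in closed form. Velocity recovery from sampled data requires
#' `tau_ms` to be resolved by the smoothing window (see the methods
#' vignette); the default 100 ms is comfortably resolvable at 500 frames/s.
#'
#' @param asymptote_deg rise asymptote (deg).
#' @param tau_ms rise time constant (ms).
#' @param stim_duration_ms,stim_onset_ms,trial_length_ms,sample_period_ms,seed,noise_sd
#'   as in [simulate_twitch()].
#' @return an [angle_trace()].
#' @export
exp_rise_trace <- function(asymptote_deg = 10, tau_ms = 100,
                           stim_duration_ms = 1000, stim_onset_ms = 200,
                           trial_length_ms = 3000, sample_period_ms = 2,
                           noise_sd = 0, seed = NULL) {
  p <- twitch_params(A_max = asymptote_deg, d50 = 0, tau_rise = tau_ms,
                     tau_fatigue = 1e6, tau_decay = tau_ms,
                     plateau_fraction = 1, latency_ms = 0,
                     noise_sd = noise_sd)
  simulate_twitch(p, stim_duration_ms, stim_onset_ms, trial_length_ms,
                  sample_period_ms, seed = seed)
}

#' Calibrated Gaussian-bump primitive
#'
#' A Gaussian transient with exact analytic full width at half maximum,
#' used where a half-width ground truth must be set directly.
#'
#' @param peak_deg bump height (deg).
#' @param fwhm_ms full width at half maximum (ms).
#' @param center_ms bump center (ms from trial start).
#' @param stim_onset_ms nominal stimulus onset stored in the annotation
#'   (the bump itself is analytic, not driven by the stimulus).
#' @param stim_duration_ms annotation stimulus duration.
#' @param trial_length_ms,sample_period_ms,noise_sd,seed as in
#'   [simulate_twitch()].
#' @return an [angle_trace()].
#' @export
gaussian_bump_trace <- function(peak_deg = 10, fwhm_ms = 100,
                                center_ms = 1200, stim_onset_ms = 200,
                                stim_duration_ms = 1000,
                                trial_length_ms = 3000, sample_period_ms = 2,
                                noise_sd = 0, seed = NULL) {
  stopifnot(fwhm_ms > 0)
  tt <- seq(0, trial_length_ms, by = sample_period_ms)
  w <- peak_deg * exp(-4 * log(2) * (tt - center_ms)^2 / fwhm_ms^2)
  if (noise_sd > 0)
    w <- w + with_seed(seed, stats::rnorm(length(w), 0, noise_sd))
  angle_trace(w, subject_id = "sim", stim_duration_ms = stim_duration_ms,
              stim_onset_ms = stim_onset_ms,
              sample_period_ms = sample_period_ms)
}

#' Fasciculation generator parameters
#'
#' Spontaneous ~5-8 Hz whisker oscillation model. `pure` mode is a single
#' tone of exact peak-to-peak amplitude; `narrowband` mode is Gaussian
#' noise band-limited to `band` and rescaled so its 1st-99th percentile
#' range equals `p2p_deg`.
#'
#' @param f0 center frequency (Hz); must be below Nyquist.
#' @param p2p_deg peak-to-peak amplitude (deg, >= 0).
#' @param mode `"pure"` or `"narrowband"`.
#' @param phase initial phase (rad) of the pure tone. The default `pi/2`
#'   places samples on the tone's extremes for records with a
#'   half-integer number of cycles per second, making max - min exact.
#' @param phase_jitter_sd random-walk phase jitter SD (rad per sqrt(s));
#'   0 = coherent tone.
#' @param noise_sd additive white measurement noise SD (deg).
#' @param duration_s record length (s).
#' @param sample_period_ms sample period (ms).
#' @param band band edges (Hz) for narrowband mode.
#' @return a `fasciculation_params` list.
#' @export
fasciculation_params <- function(f0 = 6.5, p2p_deg = 2.45,
                                 mode = c("pure", "narrowband"),
                                 phase = pi / 2, phase_jitter_sd = 0,
                                 noise_sd = 0, duration_s = 3,
                                 sample_period_ms = 2, band = c(5, 8)) {
  mode <- match.arg(mode)
  stopifnot(p2p_deg >= 0, f0 > 0, duration_s > 0, noise_sd >= 0)
  structure(list(f0 = f0, p2p_deg = p2p_deg, mode = mode, phase = phase,
                 phase_jitter_sd = phase_jitter_sd, noise_sd = noise_sd,
                 duration_s = duration_s, sample_period_ms = sample_period_ms,
                 band = band),
            class = "fasciculation_params")
}

#' Simulate a spontaneous fasciculation record
#'
#' @param params a [fasciculation_params()] object.
#' @param seed RNG seed (`NULL` uses the global stream).
#' @param subject_id,day,trial_index trace annotation.
#' @return an [angle_trace()] with `stim_duration_ms = 0`.
#' @export
simulate_fasciculation <- function(params, seed = NULL, subject_id = "sim",
                                   day = 0L, trial_index = 1L) {
  fs <- 1000 / params$sample_period_ms
  if (params$f0 >= fs / 2)
    stop("simulate_fasciculation: f0 must be below the Nyquist frequency")
  n <- round(params$duration_s * fs) + 1L
  tt <- (seq_len(n) - 1) / fs
  x <- with_seed(seed, {
    if (params$mode == "pure") {
      ph <- 2 * pi * params$f0 * tt + params$phase
      if (params$phase_jitter_sd > 0)
        ph <- ph + cumsum(stats::rnorm(n, 0, params$phase_jitter_sd / sqrt(fs)))
      x <- (params$p2p_deg / 2) * sin(ph)
    } else {
      z <- stats::rnorm(n)
      xf <- stats::fft(z)
      freq <- (seq_len(n) - 1) * fs / n
      freq <- pmin(freq, fs - freq)  # two-sided
      keep <- freq >= params$band[1] & freq <= params$band[2]
      xf[!keep] <- 0
      x <- Re(stats::fft(xf, inverse = TRUE)) / n
      rng <- diff(stats::quantile(x, c(0.01, 0.99), names = FALSE))
      x <- if (rng > 0) x * (params$p2p_deg / rng) else x * 0
    }
    if (params$noise_sd > 0) x <- x + stats::rnorm(n, 0, params$noise_sd)
    x
  })
  angle_trace(x, subject_id = subject_id, day = day,
              trial_index = trial_index, stim_duration_ms = 0,
              stim_onset_ms = 0, sample_period_ms = params$sample_period_ms)
}

#' Cohort specification for session simulation
#'
#' Defines a longitudinal stimulation study: subjects, days, the stimulus
#' duration ladder, replicates per duration, per-day twitch (and optional
#' fasciculation) parameter means, and the between-subject coefficient of
#' variation. Subject-level parameters are drawn once per subject and
#' applied to every day's means, so subjects are consistent across the time
#' course: log-normal multiplicative factors on amplitude-like parameters
#' (`A_max`, `d50`), truncated-normal factors on time constants and
#' latency, and a log-odds jitter with SD `cv/2` on the bounded plateau
#' fraction.
#'
#' @param n_subjects number of subjects (>= 1).
#' @param days integer vector of study days (negative = prelesion).
#' @param twitch_by_day named list (names = days) of [twitch_params()]
#'   day means, or a single `twitch_params` recycled to all days.
#' @param fasc_by_day optional named list of [fasciculation_params()].
#' @param durations_ms stimulus duration ladder (ms); default the 8-step
#'   protocol 1, 3, 5, 10, 20, 50, 100, 1000.
#' @param replicates replicates per duration (default 8).
#' @param cv between-subject coefficient of variation (default 0.3).
#' @param trial_length_ms,stim_onset_ms,sample_period_ms trial geometry.
#' @return a `cohort_spec` list.
#' @export
cohort_spec <- function(n_subjects, days, twitch_by_day,
                        fasc_by_day = NULL,
                        durations_ms = c(1, 3, 5, 10, 20, 50, 100, 1000),
                        replicates = 8L, cv = 0.3, trial_length_ms = 3000,
                        stim_onset_ms = 200, sample_period_ms = 2) {
  stopifnot(n_subjects >= 1, replicates >= 1, all(durations_ms > 0))
  if (inherits(twitch_by_day, "twitch_params"))
    twitch_by_day <- stats::setNames(
      rep(list(twitch_by_day), length(days)), as.character(days))
  if (!all(as.character(days) %in% names(twitch_by_day)))
    stop("cohort_spec: twitch_by_day must name every day")
  if (!is.null(fasc_by_day) && inherits(fasc_by_day, "fasciculation_params"))
    fasc_by_day <- stats::setNames(
      rep(list(fasc_by_day), length(days)), as.character(days))
  structure(list(n_subjects = as.integer(n_subjects), days = as.integer(days),
                 twitch_by_day = twitch_by_day, fasc_by_day = fasc_by_day,
                 durations_ms = durations_ms, replicates = as.integer(replicates),
                 cv = cv, trial_length_ms = trial_length_ms,
                 stim_onset_ms = stim_onset_ms,
                 sample_period_ms = sample_period_ms),
            class = "cohort_spec")
}

# Per-subject multiplicative/additive effects, drawn once per subject.
draw_subject_effects <- function(n_subjects, cv) {
  sdlog <- sqrt(log(1 + cv^2))
  trunc_factor <- function(n) {
    f <- stats::rnorm(n, 1, cv)
    pmax(f, 0.05)
  }
  data.frame(
    amp = stats::rlnorm(n_subjects, -sdlog^2 / 2, sdlog),
    d50 = stats::rlnorm(n_subjects, -sdlog^2 / 2, sdlog),
    tau = trunc_factor(n_subjects),
    lat = trunc_factor(n_subjects),
    logit_p = stats::rnorm(n_subjects, 0, cv / 2)
  )
}

apply_subject_effects <- function(params, eff) {
  q <- params
  q$A_max <- params$A_max * eff$amp
  if (!is.null(params$target_peak_deg))
    q$target_peak_deg <- params$target_peak_deg * eff$amp
  q$d50 <- params$d50 * eff$d50
  q$tau_rise <- params$tau_rise * eff$tau
  q$tau_fatigue <- params$tau_fatigue * eff$tau
  q$tau_decay <- params$tau_decay * eff$tau
  q$latency_ms <- params$latency_ms * eff$lat
  p0 <- min(max(params$plateau_fraction, 1e-6), 1 - 1e-6)
  q$plateau_fraction <- stats::plogis(stats::qlogis(p0) + eff$logit_p)
  q
}

#' Simulate an evoked-response session set for a cohort
#'
#' Generates `n_subjects x days x durations x replicates` trial traces.
#' Fully reproducible: the master seed drives one subject-effect draw plus
#' a deterministic per-trace seed table.
#'
#' @param spec a [cohort_spec()].
#' @param seed master seed.
#' @return a [session_set()]; the per-subject realized parameters are
#'   attached as attribute `"subject_params"`.
#' @export
simulate_session <- function(spec, seed = 1L) {
  out <- with_seed(seed, {
    eff <- draw_subject_effects(spec$n_subjects, spec$cv)
    n_traces <- spec$n_subjects * length(spec$days) *
      length(spec$durations_ms) * spec$replicates
    trace_seeds <- sample.int(.Machine$integer.max - 1L, n_traces,
                              replace = TRUE)
    traces <- vector("list", n_traces)
    subj_params <- list()
    k <- 0L
    for (s in seq_len(spec$n_subjects)) {
      sid <- sprintf("m%02d", s)
      for (d in spec$days) {
        pars <- apply_subject_effects(spec$twitch_by_day[[as.character(d)]],
                                      eff[s, ])
        subj_params[[paste(sid, d, sep = "/")]] <- pars
        for (dur in spec$durations_ms) {
          for (r in seq_len(spec$replicates)) {
            k <- k + 1L
            traces[[k]] <- simulate_twitch(
              pars, stim_duration_ms = dur,
              stim_onset_ms = spec$stim_onset_ms,
              trial_length_ms = spec$trial_length_ms,
              sample_period_ms = spec$sample_period_ms,
              seed = trace_seeds[k], subject_id = sid, day = d,
              trial_index = r)
          }
        }
      }
    }
    list(traces = traces, subj_params = subj_params)
  })
  ss <- session_set(out$traces,
                    protocol = list(durations_ms = spec$durations_ms,
                                    replicates = spec$replicates,
                                    trial_length_ms = spec$trial_length_ms))
  attr(ss, "subject_params") <- out$subj_params
  ss
}

#' Simulate stimulus-free fasciculation recordings for a cohort
#'
#' One spontaneous record per subject, day and replicate, using the
#' cohort's per-day fasciculation parameter means with log-normal
#' between-subject variation (CV `spec$cv`) on the peak-to-peak amplitude.
#'
#' @param spec a [cohort_spec()] with `fasc_by_day` set.
#' @param seed master seed.
#' @param replicates spontaneous records per subject/day (default 3).
#' @return a [session_set()] of `stim_duration_ms = 0` traces.
#' @export
simulate_fasciculation_session <- function(spec, seed = 1L, replicates = 3L) {
  if (is.null(spec$fasc_by_day))
    stop("simulate_fasciculation_session: spec has no fasc_by_day")
  with_seed(seed, {
    sdlog <- sqrt(log(1 + spec$cv^2))
    amp_f <- stats::rlnorm(spec$n_subjects, -sdlog^2 / 2, sdlog)
    n_traces <- spec$n_subjects * length(spec$days) * replicates
    trace_seeds <- sample.int(.Machine$integer.max - 1L, n_traces,
                              replace = TRUE)
    traces <- vector("list", n_traces)
    k <- 0L
    for (s in seq_len(spec$n_subjects)) {
      sid <- sprintf("m%02d", s)
      for (d in spec$days) {
        fp <- spec$fasc_by_day[[as.character(d)]]
        fp$p2p_deg <- fp$p2p_deg * amp_f[s]
        for (r in seq_len(replicates)) {
          k <- k + 1L
          traces[[k]] <- simulate_fasciculation(fp, seed = trace_seeds[k],
                                                subject_id = sid, day = d,
                                                trial_index = r)
        }
      }
    }
    session_set(traces,
                protocol = list(durations_ms = 0, replicates = replicates,
                                trial_length_ms = spec$fasc_by_day[[1]]$duration_s * 1000))
  })
}

#' Specification of simulated DE tables
#'
#' Plants a known differential-expression structure across two tissues so
#' downstream overlap arithmetic has exact ground truth. Planted transcripts
#' receive Wald q-values drawn below `alpha/2`, LRT flags set, and |log2FC|
#' drawn in `lfc_range` (>= 1, so the fold-change-2 filter keeps them);
#' null transcripts receive uniform q-values, N(0, `null_lfc_sd`) log2FC,
#' and LRT flags set at a small false rate. Overlap transcripts are
#' concordant in sign unless `n_discordant` > 0. Default set sizes make
#' the planted day-3 overlap 63 of a 692-transcript union.
#'
#' @param n_transcripts transcript universe size.
#' @param n_sig_a,n_sig_b planted significant set sizes per tissue.
#' @param n_common planted overlap size (<= min of the set sizes).
#' @param n_discordant overlap transcripts with opposite signs (default 0).
#' @param fraction_de if non-`NULL`, overrides the set sizes: both tissues
#'   get `round(fraction_de * n_transcripts)` planted transcripts with a
#'   10% overlap.
#' @param days_a,days_b assay days per tissue.
#' @param alpha nominal q-value threshold the q-noise model respects.
#' @param lfc_range range of |log2FC| for planted transcripts (>= 1).
#' @param null_lfc_sd SD of null log2FC.
#' @param lrt_false_rate LRT flag false-positive rate among nulls.
#' @param tpm_meanlog,tpm_sdlog log-normal baseline TPM parameters.
#' @return a `de_sim_spec` list.
#' @export
de_sim_spec <- function(n_transcripts = 5000, n_sig_a = 389, n_sig_b = 366,
                        n_common = 63, n_discordant = 0, fraction_de = NULL,
                        days_a = c(1, 3, 7), days_b = 3, alpha = 0.05,
                        lfc_range = c(1.2, 4), null_lfc_sd = 0.3,
                        lrt_false_rate = 0.01, tpm_meanlog = 3,
                        tpm_sdlog = 1.5) {
  if (!is.null(fraction_de)) {
    stopifnot(fraction_de >= 0, fraction_de <= 1)
    n_sig_a <- n_sig_b <- round(fraction_de * n_transcripts)
    n_common <- round(0.1 * n_sig_a)
  }
  if (n_common > min(n_sig_a, n_sig_b))
    stop("de_sim_spec: infeasible overlap: n_common exceeds a set size")
  if (n_sig_a + n_sig_b - n_common > n_transcripts)
    stop("de_sim_spec: union exceeds the transcript universe")
  stopifnot(n_transcripts >= 1, lfc_range[1] >= 1, n_discordant <= n_common)
  structure(list(n_transcripts = n_transcripts, n_sig_a = n_sig_a,
                 n_sig_b = n_sig_b, n_common = n_common,
                 n_discordant = n_discordant, days_a = days_a,
                 days_b = days_b, alpha = alpha, lfc_range = lfc_range,
                 null_lfc_sd = null_lfc_sd, lrt_false_rate = lrt_false_rate,
                 tpm_meanlog = tpm_meanlog, tpm_sdlog = tpm_sdlog),
            class = "de_sim_spec")
}

build_de_table <- function(spec, tissue, days, planted, signs, baseline_tpm,
                           ids, genes) {
  n <- spec$n_transcripts
  is_de <- ids %in% planted
  sign_vec <- rep(0, n)
  sign_vec[match(planted, ids)] <- signs
  df <- data.frame(transcript_id = ids, gene_id = genes,
                   stringsAsFactors = FALSE)
  df$lrt_flag <- is_de | (!is_de & stats::runif(n) < spec$lrt_false_rate)
  for (d in days) {
    lfc <- stats::rnorm(n, 0, spec$null_lfc_sd)
    lfc[is_de] <- sign_vec[is_de] *
      stats::runif(sum(is_de), spec$lfc_range[1], spec$lfc_range[2])
    q <- stats::runif(n)
    q[is_de] <- stats::runif(sum(is_de), 0, spec$alpha / 2)
    df[[sprintf("log2_fc_d%d", d)]] <- lfc
    df[[sprintf("qval_wt_d%d", d)]] <- q
    inj <- baseline_tpm * 2^lfc * stats::rlnorm(n, 0, 0.1)
    sham <- baseline_tpm * stats::rlnorm(n, 0, 0.1)
    df[[sprintf("tpm_%s_%d_inj", tissue, d)]] <- inj
    df[[sprintf("tpm_%s_%d_sham", tissue, d)]] <- sham
  }
  de_table(df, tissue = tissue)
}

#' Simulate a pair of cross-tissue DE tables with planted truth
#'
#' @param spec a [de_sim_spec()].
#' @param seed RNG seed.
#' @param tissues character vector of two tissue labels.
#' @return list with elements `a` and `b` ([de_table()]s) and `truth`
#'   (planted id sets and signs).
#' @export
simulate_de_tables <- function(spec, seed = 1L,
                               tissues = c("whisker", "soleus")) {
  with_seed(seed, {
    n <- spec$n_transcripts
    ids <- sprintf("TX%06d", seq_len(n))
    genes <- sprintf("GENE%05d", ((seq_len(n) - 1L) %/% 2L) + 1L)
    baseline <- stats::rlnorm(n, spec$tpm_meanlog, spec$tpm_sdlog)
    pool <- sample(ids, spec$n_sig_a + spec$n_sig_b - spec$n_common)
    common <- pool[seq_len(spec$n_common)]
    only_a <- pool[spec$n_common + seq_len(spec$n_sig_a - spec$n_common)]
    only_b <- pool[spec$n_sig_a + seq_len(spec$n_sig_b - spec$n_common)]
    planted_a <- c(common, only_a)
    planted_b <- c(common, only_b)
    sign_common <- sample(c(-1, 1), spec$n_common, replace = TRUE)
    sign_common_b <- sign_common
    if (spec$n_discordant > 0) {
      flip <- seq_len(spec$n_discordant)
      sign_common_b[flip] <- -sign_common_b[flip]
    }
    signs_a <- c(sign_common,
                 sample(c(-1, 1), length(only_a), replace = TRUE))
    signs_b <- c(sign_common_b,
                 sample(c(-1, 1), length(only_b), replace = TRUE))
    ta <- build_de_table(spec, tissues[1], spec$days_a, planted_a, signs_a,
                         baseline, ids, genes)
    tb <- build_de_table(spec, tissues[2], spec$days_b, planted_b, signs_b,
                         baseline, ids, genes)
    list(a = ta, b = tb,
         truth = list(planted_a = sort(planted_a),
                      planted_b = sort(planted_b),
                      common = sort(common),
                      signs_a = signs_a[order(planted_a)],
                      signs_b = signs_b[order(planted_b)]))
  })
}
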