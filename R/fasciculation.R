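#' Extract the stimulus-free portion of a trace
#'
#' Fasciculation analysis must not include evoked movements. For a trace
#' recorded with a stimulus, this returns the pre-stimulus epoch as a new
#' stimulus-free trace; stimulus-free traces are returned unchanged.
#'
#' @param trace an [angle_trace()].
#' @return an [angle_trace()] with `stim_duration_ms = 0`.
#' @export
stimulus_free_segment <- function(trace) {
  if (trace$stim_duration_ms == 0) return(trace)
  tt <- trace_time(trace)
  sel <- tt < trace$stim_onset_ms
  if (sum(sel) < 2)
    stop("stimulus_free_segment: no pre-stimulus samples")
  angle_trace(trace$angle_deg[sel], subject_id = trace$subject_id,
              day = trace$day, trial_index = trace$trial_index,
              stim_duration_ms = 0, stim_onset_ms = trace$time_start_ms,
              sample_period_ms = trace$sample_period_ms,
              time_start_ms = trace$time_start_ms,
              mask = trace$mask[sel])
}

#' Variance-normalized periodogram of a stimulus-free record
#'
#' Linearly detrends the signal and computes a one-sided FFT periodogram
#' normalized so that the sum of power over all bins equals the variance of
#' the detrended signal (Parseval identity, exact up to floating point).
#' Rectangular window, no padding, deterministic.
#'
#' @param trace an [angle_trace()] (must be stimulus-free; use
#'   [stimulus_free_segment()] first for evoked trials), or a numeric
#'   vector with `sample_period_ms` supplied.
#' @param sample_period_ms sample period for numeric input (ms).
#' @param detrend detrending method; only `"linear"` is implemented.
#' @param max_mask_run masked-run interpolation limit.
#' @return an object of class `power_spectrum` with fields `freq_hz`,
#'   `power` (deg^2 per bin), `record_s`, `normalization`, `detrend`.
#' @export
power_spectrum <- function(trace, sample_period_ms = NULL,
                           detrend = "linear", max_mask_run = 5L) {
  if (inherits(trace, "angle_trace")) {
    if (trace$stim_duration_ms > 0)
      stop("power_spectrum: trace contains a stimulus; use stimulus_free_segment()")
    trace <- interpolate_masked(trace, max_mask_run)
    x <- trace$angle_deg
    dt <- trace$sample_period_ms
  } else {
    x <- as.numeric(trace)
    if (is.null(sample_period_ms))
      stop("power_spectrum: sample_period_ms required for numeric input")
    dt <- sample_period_ms
  }
  n <- length(x)
  record_s <- n * dt / 1000
  if (record_s < 1) stop("power_spectrum: record shorter than 1 s")
  if (detrend != "linear") stop("power_spectrum: only linear detrend implemented")
  idx <- seq_len(n)
  x <- stats::lm.fit(cbind(1, idx), x)$residuals
  fs <- 1000 / dt
  xf <- stats::fft(x)
  nfreq <- floor(n / 2) + 1L
  freq <- (seq_len(nfreq) - 1) * fs / n
  p <- Mod(xf[seq_len(nfreq)])^2 / n^2
  dbl <- rep(2, nfreq)
  dbl[1] <- 1
  if (n %% 2 == 0) dbl[nfreq] <- 1
  p <- p * dbl
  structure(list(freq_hz = freq, power = p, record_s = record_s,
                 normalization = "bin-sum equals variance of detrended signal",
                 detrend = detrend),
            class = "power_spectrum")
}

#' @export
print.power_spectrum <- function(x, ...) {
  cat(sprintf(
    "<power_spectrum> %d bins, 0-%.4g Hz (resolution %.4g Hz), %.3g s record\n",
    length(x$freq_hz), max(x$freq_hz), x$freq_hz[2], x$record_s))
  cat(sprintf("  total power %.6g deg^2 (%s)\n", sum(x$power),
              x$normalization))
  invisible(x)
}

#' @export
plot.power_spectrum <- function(x, xlim = c(0, 20), ...) {
  graphics::plot(x$freq_hz, x$power, type = "h", xlim = xlim,
                 xlab = "frequency (Hz)", ylab = "power (deg^2)", ...)
  invisible(x)
}

#' Mean power in a frequency band
#'
#' Mean of the periodogram over bins with `lo <= f <= hi` (closed band).
#' The 5-8 Hz default is the fasciculation band.
#'
#' @param spectrum a [power_spectrum()].
#' @param lo,hi band edges in Hz.
#' @return mean per-bin power in deg^2.
#' @export
band_power <- function(spectrum, lo = 5, hi = 8) {
  if (lo >= hi) stop("band_power: lo must be < hi")
  sel <- spectrum$freq_hz >= lo & spectrum$freq_hz <= hi
  if (!any(sel)) stop("band_power: no bins inside the band")
  mean(spectrum$power[sel])
}

#' Peak-to-peak amplitude of a trace
#'
#' Plain mode is max - min; robust mode is the 99th minus 1st percentile,
#' which resists isolated tracking spikes in noisy records.
#'
#' @param trace an [angle_trace()] or numeric vector.
#' @param robust use the percentile range (default `FALSE`: plain
#'   max - min).
#' @return amplitude in degrees.
#' @export
p2p_amplitude <- function(trace, robust = FALSE) {
  x <- if (inherits(trace, "angle_trace"))
    trace$angle_deg[!trace$mask] else as.numeric(trace)
  if (!length(x)) stop("p2p_amplitude: empty trace")
  if (robust)
    diff(stats::quantile(x, c(0.01, 0.99), names = FALSE))
  else
    max(x) - min(x)
}

#' Fasciculation band-power time course
#'
#' Per-trial 5-8 Hz band powers from stimulus-free records, averaged first
#' within and then between subjects, per day (and per treatment condition
#' when `condition_by_subject` is given, mirroring a vehicle-vs-antagonist
#' layout).
#'
#' @param sessions a [session_set()] of stimulus-free traces (evoked traces
#'   are reduced to their pre-stimulus epoch automatically).
#' @param band band edges in Hz.
#' @param condition_by_subject optional named character vector mapping
#'   subject id to a condition label; every subject present must be
#'   labelled.
#' @param config analysis parameters (used for the mask-run limit).
#' @return a data.frame of class `band_power_table` with columns `day`,
#'   (`condition`,) `mean_power`, `se`, `n_subjects`; per-trial values are
#'   attached as attribute `"trials"` (including `total_power` and
#'   `signal_var`, whose equality is the Parseval check).
#' @export
fasciculation_time_course <- function(sessions, band = c(5, 8),
                                      condition_by_subject = NULL,
                                      config = default_config()) {
  trials <- lapply(sessions$traces, function(tr) {
    seg <- stimulus_free_segment(tr)
    seg <- interpolate_masked(seg, config$max_mask_run)
    sp <- power_spectrum(seg)
    x <- seg$angle_deg
    detr <- stats::lm.fit(cbind(1, seq_along(x)), x)$residuals
    data.frame(subject = tr$subject_id, day = tr$day,
               trial = tr$trial_index,
               band_power = band_power(sp, band[1], band[2]),
               p2p_deg = p2p_amplitude(seg, robust = TRUE),
               total_power = sum(sp$power),
               signal_var = mean(detr^2),
               stringsAsFactors = FALSE)
  })
  trials <- do.call(rbind, trials)
  if (!is.null(condition_by_subject)) {
    missing <- setdiff(unique(trials$subject), names(condition_by_subject))
    if (length(missing))
      stop("fasciculation_time_course: missing condition label for subject(s): ",
           paste(missing, collapse = ", "))
    trials$condition <- unname(condition_by_subject[trials$subject])
    grp_cols <- c("day", "condition")
  } else {
    grp_cols <- "day"
  }
  # within-subject means first
  per_subj <- stats::aggregate(
    trials[, c("band_power", "p2p_deg")],
    trials[, c("subject", grp_cols), drop = FALSE], mean)
  agg <- function(v) {
    n <- length(v)
    c(mean = mean(v), se = if (n >= 2) stats::sd(v) / sqrt(n) else NA_real_,
      n = n)
  }
  out <- do.call(rbind, lapply(
    split(per_subj, per_subj[, grp_cols, drop = FALSE], drop = TRUE),
    function(g) {
      s <- agg(g$band_power)
      p <- agg(g$p2p_deg)
      r <- g[1, grp_cols, drop = FALSE]
      r$mean_power <- s["mean"]; r$se <- s["se"]
      r$mean_p2p <- p["mean"]; r$n_subjects <- as.integer(s["n"])
      r
    }))
  out <- out[order(out$day), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "trials") <- trials
  attr(out, "band") <- band
  attr(out, "band_statistic") <- "mean power per bin over the closed band"
  class(out) <- c("band_power_table", "data.frame")
  out
}
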