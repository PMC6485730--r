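#' Resting (baseline) whisker angle
#'
#' Mean angle over the pre-stimulus window `[onset - pre_window_ms, onset)`,
#' ignoring masked samples. All response metrics are measured relative
#' to this resting angle.
#'
#' @param trace an [angle_trace()].
#' @param pre_window_ms window length before stimulus onset (ms).
#' @return baseline angle in degrees.
#' @export
baseline_angle <- function(trace, pre_window_ms = 200) {
  tt <- trace_time(trace)
  sel <- tt >= trace$stim_onset_ms - pre_window_ms & tt < trace$stim_onset_ms &
    !trace$mask
  if (!any(sel)) stop("baseline_angle: no usable samples in the pre-stimulus window")
  mean(trace$angle_deg[sel])
}

baseline_sd <- function(trace, pre_window_ms = 200) {
  tt <- trace_time(trace)
  sel <- tt >= trace$stim_onset_ms - pre_window_ms & tt < trace$stim_onset_ms &
    !trace$mask
  if (sum(sel) < 2) return(0)
  stats::sd(trace$angle_deg[sel])
}

#' Savitzky-Golay smoothed angular velocity
#'
#' Smooths the angle series with a least-squares local polynomial
#' (Savitzky-Golay) filter and differentiates it by central differences
#' scaled by the sample period (one-sided differences at the edges). This
#' is the estimator behind the "peak velocity" metric.
#'
#' @param trace an [angle_trace()], or a bare numeric vector (then
#'   `sample_period_ms` must be given).
#' @param window_samples filter window length in samples (odd, >=
#'   `polyorder + 2`); default 11 (22 ms at 500 frames/s).
#' @param polyorder polynomial order (default 3).
#' @param sample_period_ms sample period for numeric input.
#' @param max_mask_run masked-run interpolation limit for trace input.
#' @return numeric vector of velocities in deg/s, same length as the input.
#' @export
smooth_and_differentiate <- function(trace, window_samples = 11L,
                                     polyorder = 3L, sample_period_ms = NULL,
                                     max_mask_run = 5L) {
  if (inherits(trace, "angle_trace")) {
    trace <- interpolate_masked(trace, max_mask_run)
    x <- trace$angle_deg
    dt <- trace$sample_period_ms
  } else {
    x <- as.numeric(trace)
    if (is.null(sample_period_ms))
      stop("smooth_and_differentiate: sample_period_ms required for numeric input")
    dt <- sample_period_ms
  }
  window_samples <- as.integer(window_samples)
  polyorder <- as.integer(polyorder)
  if (window_samples %% 2L == 0L)
    stop("smooth_and_differentiate: window_samples must be odd")
  if (window_samples < polyorder + 2L)
    stop("smooth_and_differentiate: window_samples must be >= polyorder + 2")
  n <- length(x)
  if (n <= window_samples)
    stop("smooth_and_differentiate: trace shorter than the smoothing window")
  s <- signal::sgolayfilt(x, p = polyorder, n = window_samples)
  v <- c(s[2] - s[1],
         (s[3:n] - s[1:(n - 2)]) / 2,
         s[n] - s[n - 1]) / dt
  v * 1000  # deg/ms -> deg/s
}

# Linear-interpolated crossing times of rel = level, flanking index ipk.
half_crossings <- function(tt, rel, ipk, level) {
  left <- NA_real_
  for (i in seq(ipk, 2)) {
    if (rel[i - 1] < level && rel[i] >= level) {
      left <- tt[i - 1] + (level - rel[i - 1]) / (rel[i] - rel[i - 1]) *
        (tt[i] - tt[i - 1])
      break
    }
  }
  right <- NA_real_
  n <- length(rel)
  if (ipk < n) {
    for (i in seq(ipk, n - 1)) {
      if (rel[i] >= level && rel[i + 1] < level) {
        right <- tt[i] + (rel[i] - level) / (rel[i] - rel[i + 1]) *
          (tt[i + 1] - tt[i])
        break
      }
    }
  }
  c(left = left, right = right)
}

#' Extract per-response kinematic metrics
#'
#' Computes the five response statistics from a (typically
#' replicate-averaged) trial trace, relative to the pre-stimulus baseline:
#'
#' * `peak_amplitude_deg`: maximum baseline-subtracted angle in the
#'   response window (stimulus onset to onset + `response_window_ms`).
#' * `time_to_peak_ms`: time of that maximum minus stimulus onset.
#' * `peak_velocity_deg_per_s`: maximum of the Savitzky-Golay smoothed
#'   derivative in the same window.
#' * `half_width_ms`: full width at half of the peak amplitude, from
#'   linearly interpolated crossings flanking the peak; `censored_half_width`
#'   is set when the response has not decayed below half maximum by the end
#'   of the record.
#' * `persistence_index`: for the long (1000-ms) stimulus only, the
#'   amplitude at stimulus offset (mean over the final
#'   `persistence_tail_ms`) divided by the peak amplitude, clamped to
#'   [0, 1]. Higher values mean less fatigable responses.
#'
#' A response is flagged `no_response` when the peak does not exceed
#' `noise_criterion_k` times the baseline SD; time metrics are then `NA`.
#' With `response_sign = -1` the trace is negated first, so retractions can
#' be analysed with the same machinery.
#'
#' @param trace an [angle_trace()], usually from [average_traces()].
#' @param config parameter list from [default_config()]/[load_config()].
#' @return a one-row data.frame of class `kinematic_metrics`.
#' @export
extract_metrics <- function(trace, config = default_config()) {
  trace <- interpolate_masked(trace, config$max_mask_run)
  if (config$response_sign == -1) trace$angle_deg <- -trace$angle_deg
  tt <- trace_time(trace)
  base <- baseline_angle(trace, config$baseline_window_ms)
  bsd <- baseline_sd(trace, config$baseline_window_ms)
  onset <- trace$stim_onset_ms
  win <- tt >= onset & tt <= onset + config$response_window_ms
  if (!any(win)) stop("extract_metrics: empty response window")
  rel <- trace$angle_deg - base
  iw <- which(win)
  ipk <- iw[which.max(rel[iw])]
  peak <- rel[ipk]
  peak <- max(peak, 0)
  responded <- peak > config$noise_criterion_k * bsd && peak > 0
  vel <- smooth_and_differentiate(trace, config$sg_window, config$sg_polyorder)
  peak_vel <- max(vel[iw])
  half_width <- NA_real_
  censored <- NA
  t_peak <- NA_real_
  pi_val <- NA_real_
  if (responded) {
    t_peak <- tt[ipk] - onset
    cr <- half_crossings(tt, rel, ipk, peak / 2)
    censored <- is.na(cr["right"])
    if (!censored && !is.na(cr["left"]))
      half_width <- unname(cr["right"] - cr["left"])
    if (trace$stim_duration_ms == config$long_stim_ms) {
      t_off <- onset + trace$stim_duration_ms
      tail_sel <- tt >= t_off - config$persistence_tail_ms & tt <= t_off
      if (any(tail_sel)) {
        pi_val <- mean(rel[tail_sel]) / peak
        pi_val <- min(max(pi_val, 0), 1)
      }
    }
  }
  out <- data.frame(
    subject = trace$subject_id, day = trace$day,
    stim_duration_ms = trace$stim_duration_ms,
    baseline_deg = base,
    peak_amplitude_deg = peak,
    peak_velocity_deg_per_s = peak_vel,
    time_to_peak_ms = t_peak,
    half_width_ms = half_width,
    censored_half_width = censored,
    persistence_index = pi_val,
    no_response = !responded,
    n_trials_averaged = if (!is.null(attr(trace, "n_averaged")))
      attr(trace, "n_averaged") else 1L,
    stringsAsFactors = FALSE)
  class(out) <- c("kinematic_metrics", "data.frame")
  out
}

#' Pointwise average of replicate traces
#'
#' Averages trial traces within a (subject, day, duration) group frame by
#' frame, ignoring masked samples; a frame is masked in the result only if
#' it is masked in every trial. Traces must share length, sample period and
#' stimulus annotation.
#'
#' @param traces list of [angle_trace()] objects (or a `session_set`, in
#'   which case all of its traces are averaged).
#' @return an [angle_trace()] with attribute `n_averaged`.
#' @export
average_traces <- function(traces) {
  if (inherits(traces, "session_set")) traces <- traces$traces
  if (inherits(traces, "angle_trace")) traces <- list(traces)
  if (!length(traces)) stop("average_traces: no traces")
  n <- length(traces[[1]]$angle_deg)
  per <- traces[[1]]$sample_period_ms
  onset <- traces[[1]]$stim_onset_ms
  dur <- traces[[1]]$stim_duration_ms
  t0 <- traces[[1]]$time_start_ms
  for (tr in traces) {
    if (length(tr$angle_deg) != n || tr$sample_period_ms != per ||
        tr$stim_onset_ms != onset || tr$stim_duration_ms != dur ||
        tr$time_start_ms != t0)
      stop("average_traces: traces differ in shape or stimulus annotation")
  }
  mat <- vapply(traces, function(tr) ifelse(tr$mask, NA_real_, tr$angle_deg),
                numeric(n))
  mat <- matrix(mat, nrow = n)
  mean_v <- rowMeans(mat, na.rm = TRUE)
  all_masked <- rowSums(!is.na(mat)) == 0
  mean_v[all_masked] <- NA_real_
  out <- angle_trace(mean_v, subject_id = traces[[1]]$subject_id,
                     day = traces[[1]]$day, trial_index = 0L,
                     stim_duration_ms = dur, stim_onset_ms = onset,
                     sample_period_ms = per, time_start_ms = t0,
                     mask = all_masked)
  attr(out, "n_averaged") <- length(traces)
  out
}

#' Duration-response family for one subject and day
#'
#' For every stimulus duration in the protocol: averages the replicate
#' traces, extracts metrics from the averaged trace (the primary values),
#' and reports the across-replicate standard error of each metric from
#' per-trial extraction. Durations absent from the data yield a row with
#' `absent = TRUE`.
#'
#' @param sessions a [session_set()] (may contain several subjects/days).
#' @param subject,day which subject/day to summarize.
#' @param config analysis parameters.
#' @return a data.frame of class `duration_family`, one row per protocol
#'   duration.
#' @export
duration_family <- function(sessions, subject = NULL, day = NULL,
                            config = default_config()) {
  idx <- sessions$index
  if (is.null(subject)) subject <- idx$subject[1]
  if (is.null(day)) day <- idx$day[1]
  keep <- idx$subject == subject & idx$day == day
  if (!any(keep)) stop("duration_family: no traces for that subject/day")
  durations <- sessions$protocol$durations_ms
  metric_cols <- c("peak_amplitude_deg", "peak_velocity_deg_per_s",
                   "time_to_peak_ms", "half_width_ms", "persistence_index")
  rows <- lapply(durations, function(dur) {
    sel <- which(keep & idx$stim_duration_ms == dur)
    if (!length(sel)) {
      r <- data.frame(subject = subject, day = day, stim_duration_ms = dur,
                      absent = TRUE, n_replicates = 0L,
                      stringsAsFactors = FALSE)
      for (mc in metric_cols) {
        r[[mc]] <- NA_real_
        r[[paste0("se_", mc)]] <- NA_real_
      }
      return(r)
    }
    avg <- average_traces(sessions$traces[sel])
    m <- extract_metrics(avg, config)
    per_rep <- do.call(rbind, lapply(sessions$traces[sel], function(tr)
      as.data.frame(extract_metrics(tr, config))))
    r <- data.frame(subject = subject, day = day, stim_duration_ms = dur,
                    absent = FALSE, n_replicates = length(sel),
                    stringsAsFactors = FALSE)
    for (mc in metric_cols) {
      r[[mc]] <- m[[mc]]
      vals <- per_rep[[mc]]
      vals <- vals[is.finite(vals)]
      r[[paste0("se_", mc)]] <- if (length(vals) >= 2)
        stats::sd(vals) / sqrt(length(vals)) else NA_real_
    }
    r$no_response <- m$no_response
    r
  })
  out <- do.call(rbind, lapply(rows, function(r) {
    if (is.null(r$no_response)) r$no_response <- NA
    r
  }))
  rownames(out) <- NULL
  class(out) <- c("duration_family", "data.frame")
  out
}

#' Stimulus-duration threshold of a response family
#'
#' The smallest protocol duration whose mean peak amplitude reaches the
#' criterion. A leftward shift of this threshold across days indicates
#' increased sensitivity.
#'
#' @param family a [duration_family()].
#' @param criterion_deg amplitude criterion in degrees (default 1).
#' @return threshold duration in ms, or `NA` (censored) if no duration
#'   reaches the criterion.
#' @export
sensitivity_threshold <- function(family, criterion_deg = 1.0) {
  f <- family[!family$absent, , drop = FALSE]
  if (nrow(f) < 2) stop("sensitivity_threshold: need >= 2 durations")
  f <- f[order(f$stim_duration_ms), , drop = FALSE]
  hit <- which(f$peak_amplitude_deg >= criterion_deg)
  if (!length(hit)) return(NA_real_)
  f$stim_duration_ms[hit[1]]
}

#' Express a follow-up value as percent of baseline
#'
#' @param post_value value at the follow-up time point.
#' @param baseline_value baseline value (> 0).
#' @return `100 * post / baseline`, rounded to 3 significant figures.
#' @export
percent_of_baseline <- function(post_value, baseline_value) {
  if (any(baseline_value <= 0))
    stop("percent_of_baseline: baseline must be > 0")
  signif(100 * post_value / baseline_value, 3)
}

#' Group summary of per-subject metrics across days
#'
#' Averages within and then between subjects: takes a long table of
#' per-subject, per-day metric values (one row per subject x day) and
#' returns per-day group means with SE = sd/sqrt(n), plus counts of
#' subjects whose value increased relative to the baseline day (the
#' "8/9 mice" style of statement).
#'
#' @param metrics data.frame with columns `subject`, `day`, and metric
#'   columns.
#' @param metric_cols which columns to summarize (default: all numeric
#'   besides subject/day bookkeeping).
#' @param baseline_day day used as reference for direction counts
#'   (default: the smallest day).
#' @return a list of class `group_summary` with elements `stats` (day x
#'   metric means/SE/n) and `direction` (per day/metric: `n_increased`,
#'   `n_total`).
#' @export
group_summary <- function(metrics, metric_cols = NULL, baseline_day = NULL) {
  stopifnot(all(c("subject", "day") %in% names(metrics)))
  if (is.null(metric_cols)) {
    metric_cols <- setdiff(names(metrics)[vapply(metrics, is.numeric,
                                                 logical(1))],
                           c("day", "stim_duration_ms", "n_replicates",
                             "n_trials_averaged"))
  }
  if (is.null(baseline_day)) baseline_day <- min(metrics$day)
  days <- sort(unique(metrics$day))
  stats_rows <- list()
  dir_rows <- list()
  for (d in days) {
    sub <- metrics[metrics$day == d, , drop = FALSE]
    for (mc in metric_cols) {
      vals <- sub[[mc]][is.finite(sub[[mc]])]
      n <- length(vals)
      se <- if (n >= 2) stats::sd(vals) / sqrt(n) else {
        if (n == 1) warning("group_summary: SE undefined for n = 1 (reported as 0)")
        0
      }
      stats_rows[[length(stats_rows) + 1L]] <- data.frame(
        day = d, metric = mc, mean = if (n) mean(vals) else NA_real_,
        se = se, n = n, stringsAsFactors = FALSE)
      if (d != baseline_day) {
        base <- metrics[metrics$day == baseline_day,
                        c("subject", mc), drop = FALSE]
        cur <- sub[, c("subject", mc), drop = FALSE]
        mg <- merge(base, cur, by = "subject", suffixes = c("_base", "_cur"))
        ok <- is.finite(mg[[2]]) & is.finite(mg[[3]])
        dir_rows[[length(dir_rows) + 1L]] <- data.frame(
          day = d, metric = mc,
          n_increased = sum(mg[[3]][ok] > mg[[2]][ok]),
          n_total = sum(ok), stringsAsFactors = FALSE)
      }
    }
  }
  structure(list(stats = do.call(rbind, stats_rows),
                 direction = if (length(dir_rows)) do.call(rbind, dir_rows)
                             else NULL,
                 baseline_day = baseline_day),
            class = "group_summary")
}

#' @export
print.group_summary <- function(x, ...) {
  cat("<group_summary> per-day means +/- SE (sd/sqrt(n)):\n")
  print(x$stats, row.names = FALSE)
  if (!is.null(x$direction)) {
    cat(sprintf("direction counts vs baseline day %s:\n", x$baseline_day))
    d <- x$direction
    d$count <- sprintf("%d/%d", d$n_increased, d$n_total)
    print(d[, c("day", "metric", "count")], row.names = FALSE)
  }
  invisible(x)
}

#' @export
plot.duration_family <- function(x, metric = "peak_amplitude_deg", ...) {
  f <- x[!x$absent, , drop = FALSE]
  graphics::plot(f$stim_duration_ms, f[[metric]], log = "x", type = "b",
                 xlab = "stimulus duration (ms)", ylab = metric,
                 main = sprintf("%s day %d", f$subject[1], f$day[1]), ...)
  se <- f[[paste0("se_", metric)]]
  ok <- is.finite(se)
  if (any(ok))
    graphics::arrows(f$stim_duration_ms[ok], f[[metric]][ok] - se[ok],
                     f$stim_duration_ms[ok], f[[metric]][ok] + se[ok],
                     angle = 90, code = 3, length = 0.03)
  invisible(x)
}
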