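#' Construct a single-trial whisker angle trace
#'
#' An `angle_trace` is the atomic input of the kinematics pipeline: one
#' trial's whisker angle sampled at a fixed frame rate (500 frames/s, i.e.
#' a 2-ms sample period, by default), annotated with the stimulus it was
#' recorded under. Protraction is the positive direction. Missing frames
#' (e.g. tracking artifacts) are represented by a logical mask, not dropped,
#' so trial alignment is preserved.
#'
#' @param angle_deg numeric vector of whisker angles in degrees, one per
#'   frame. `NA` entries are treated as masked samples.
#' @param subject_id character scalar identifying the animal.
#' @param day integer day relative to lesion (negative = prelesion).
#' @param trial_index integer trial number within the session.
#' @param stim_duration_ms stimulus (light) duration in ms; 0 for
#'   stimulus-free (spontaneous) recordings.
#' @param stim_onset_ms stimulus onset time in ms from trial start. Must lie
#'   within the recorded span. Need not fall on the sample grid.
#' @param sample_period_ms sample period in ms (default 2, i.e. 500 frames/s).
#' @param time_start_ms time of the first sample, ms from trial start.
#' @param mask optional logical vector, `TRUE` where a sample is missing;
#'   merged with `is.na(angle_deg)`.
#' @return an object of class `angle_trace`.
#' @export
angle_trace <- function(angle_deg, subject_id = "s1", day = 0L,
                        trial_index = 1L, stim_duration_ms = 0,
                        stim_onset_ms = 0, sample_period_ms = 2,
                        time_start_ms = 0, mask = NULL) {
  angle_deg <- as.numeric(angle_deg)
  n <- length(angle_deg)
  if (n < 2L) stop("angle_trace: angle sequence must have length >= 2")
  if (!is.numeric(sample_period_ms) || sample_period_ms <= 0)
    stop("angle_trace: sample_period_ms must be > 0")
  if (is.null(mask)) mask <- rep(FALSE, n)
  mask <- as.logical(mask) | is.na(angle_deg)
  if (length(mask) != n) stop("angle_trace: mask length must match angle length")
  if (stim_duration_ms < 0) stop("angle_trace: stim_duration_ms must be >= 0")
  t_end <- time_start_ms + (n - 1) * sample_period_ms
  if (stim_onset_ms < time_start_ms || stim_onset_ms > t_end)
    stop("angle_trace: stim_onset_ms must lie within the recorded span")
  if (any(!is.finite(angle_deg[!mask])))
    stop("angle_trace: non-masked samples must be finite")
  structure(list(
    subject_id = as.character(subject_id), day = as.integer(day),
    trial_index = as.integer(trial_index),
    stim_duration_ms = as.numeric(stim_duration_ms),
    stim_onset_ms = as.numeric(stim_onset_ms),
    sample_period_ms = as.numeric(sample_period_ms),
    time_start_ms = as.numeric(time_start_ms),
    angle_deg = angle_deg, mask = mask
  ), class = "angle_trace")
}

#' Sample times of a trace
#' @param trace an `angle_trace`.
#' @return numeric vector of sample times in ms from trial start.
#' @export
trace_time <- function(trace) {
  trace$time_start_ms +
    (seq_along(trace$angle_deg) - 1) * trace$sample_period_ms
}

#' @export
print.angle_trace <- function(x, ...) {
  cat(sprintf(
    "<angle_trace> subject %s, day %d, trial %d: %d frames @ %g ms (%g s)\n",
    x$subject_id, x$day, x$trial_index, length(x$angle_deg),
    x$sample_period_ms,
    (length(x$angle_deg) - 1) * x$sample_period_ms / 1000))
  cat(sprintf("  stimulus: %g ms at t = %g ms; masked samples: %d\n",
              x$stim_duration_ms, x$stim_onset_ms, sum(x$mask)))
  invisible(x)
}

#' Fill short masked runs by linear interpolation
#'
#' Downstream operations require gapless signals. Masked runs of at most
#' `max_run` samples are filled by linear interpolation between their
#' flanking good samples (constant extension at trace edges); a longer run
#' means the trial is unusable and is rejected.
#'
#' @param trace an `angle_trace`.
#' @param max_run longest interpolatable run of masked samples (default 5).
#' @return the trace with `angle_deg` gapless and `mask` cleared.
#' @export
interpolate_masked <- function(trace, max_run = 5L) {
  m <- trace$mask
  if (!any(m)) return(trace)
  r <- rle(m)
  if (any(r$values & r$lengths > max_run))
    stop(sprintf("trace %s/d%d/t%d: masked run longer than %d samples",
                 trace$subject_id, trace$day, trace$trial_index, max_run))
  if (all(m)) stop("interpolate_masked: all samples masked")
  idx <- seq_along(m)
  trace$angle_deg <- stats::approx(idx[!m], trace$angle_deg[!m], xout = idx,
                                   rule = 2)$y
  trace$mask <- rep(FALSE, length(m))
  trace
}

#' Build a session set from a list of traces
#'
#' A `session_set` groups trial traces by (subject, day, stimulus duration)
#' and carries the stimulation protocol (duration list, replicates per
#' duration). Within a group all traces must share sample period and length
#' so that pointwise averaging is defined.
#'
#' @param traces list of `angle_trace` objects.
#' @param protocol optional list with elements `durations_ms`,
#'   `replicates`, `trial_length_ms`; inferred from the traces if omitted.
#' @return an object of class `session_set`.
#' @export
session_set <- function(traces, protocol = NULL) {
  if (!length(traces)) stop("session_set: no traces")
  ok <- vapply(traces, inherits, logical(1), "angle_trace")
  if (!all(ok)) stop("session_set: all elements must be angle_trace objects")
  index <- data.frame(
    subject = vapply(traces, `[[`, character(1), "subject_id"),
    day = vapply(traces, `[[`, integer(1), "day"),
    stim_duration_ms = vapply(traces, `[[`, numeric(1), "stim_duration_ms"),
    trial = vapply(traces, `[[`, integer(1), "trial_index"),
    n_samples = vapply(traces, function(x) length(x$angle_deg), integer(1)),
    n_masked = vapply(traces, function(x) sum(x$mask), integer(1)),
    stringsAsFactors = FALSE)
  ord <- order(index$subject, index$day, index$stim_duration_ms, index$trial)
  traces <- traces[ord]
  index <- index[ord, , drop = FALSE]
  rownames(index) <- NULL
  key <- paste(index$subject, index$day, index$stim_duration_ms, sep = "\r")
  for (k in unique(key)) {
    sel <- which(key == k)
    per <- vapply(traces[sel], `[[`, numeric(1), "sample_period_ms")
    len <- index$n_samples[sel]
    if (length(unique(per)) > 1L)
      stop("session_set: mixed sample periods within group ", gsub("\r", "/", k))
    if (length(unique(len)) > 1L)
      stop("session_set: mixed trace lengths within group ", gsub("\r", "/", k))
  }
  if (is.null(protocol)) {
    protocol <- list(
      durations_ms = sort(unique(index$stim_duration_ms)),
      replicates = max(table(key)),
      trial_length_ms = max((index$n_samples - 1) *
        vapply(traces, `[[`, numeric(1), "sample_period_ms")))
  }
  structure(list(traces = traces, index = index, protocol = protocol),
            class = "session_set")
}

#' @export
print.session_set <- function(x, ...) {
  cat(sprintf(
    "<session_set> %d traces: %d subject(s), %d day(s), %d duration(s)\n",
    nrow(x$index), length(unique(x$index$subject)),
    length(unique(x$index$day)),
    length(unique(x$index$stim_duration_ms))))
  cat(sprintf("  protocol: durations %s ms, up to %d replicates\n",
              paste(x$protocol$durations_ms, collapse = ", "),
              x$protocol$replicates))
  invisible(x)
}

#' Subset a session set
#' @param sessions a `session_set`.
#' @param subject,day,stim_duration_ms optional filters; `NULL` keeps all.
#' @return a `session_set` with the matching traces.
#' @export
subset_session <- function(sessions, subject = NULL, day = NULL,
                           stim_duration_ms = NULL) {
  keep <- rep(TRUE, nrow(sessions$index))
  if (!is.null(subject)) keep <- keep & sessions$index$subject %in% subject
  if (!is.null(day)) keep <- keep & sessions$index$day %in% day
  if (!is.null(stim_duration_ms))
    keep <- keep & sessions$index$stim_duration_ms %in% stim_duration_ms
  if (!any(keep)) stop("subset_session: no traces match the filter")
  protocol <- sessions$protocol
  if (!is.null(stim_duration_ms))
    protocol$durations_ms <- intersect(protocol$durations_ms,
                                       stim_duration_ms)
  session_set(sessions$traces[keep], protocol)
}

trace_columns <- c("subject", "day", "trial", "stim_duration_ms",
                   "time_ms", "angle_deg")

#' Read whisker-angle traces from a long-format CSV
#'
#' The canonical on-disk trace format is one row per frame with columns
#' `subject, day, trial, stim_duration_ms, time_ms, angle_deg` plus an
#' optional `stim_onset_ms` column (constant within trial; defaults to the
#' `stim_onset_ms` argument). `NA` angles become masked samples. Rows may
#' appear in any order; grouping and within-trial ordering are
#' reconstructed deterministically.
#'
#' @param path CSV file path.
#' @param stim_onset_ms fallback stimulus onset when the file carries no
#'   `stim_onset_ms` column.
#' @return a `session_set`.
#' @export
read_traces <- function(path, stim_onset_ms = 0) {
  if (!file.exists(path)) stop("read_traces: file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(trace_columns, names(df))
  if (length(missing))
    stop("read_traces: missing column(s): ", paste(missing, collapse = ", "))
  has_onset <- "stim_onset_ms" %in% names(df)
  df <- df[order(df$subject, df$day, df$stim_duration_ms, df$trial,
                 df$time_ms), , drop = FALSE]
  key <- paste(df$subject, df$day, df$stim_duration_ms, df$trial, sep = "\r")
  traces <- lapply(split(seq_len(nrow(df)), factor(key, unique(key))),
                   function(rows) {
    d <- df[rows, , drop = FALSE]
    tt <- d$time_ms
    if (any(diff(tt) <= 0))
      stop("read_traces: non-monotonic time in trial ",
           d$subject[1], "/d", d$day[1], "/t", d$trial[1])
    per <- diff(tt)
    if (length(per) && max(abs(per - per[1])) > 1e-9 * max(per[1], 1))
      stop("read_traces: mixed sample periods in trial ",
           d$subject[1], "/d", d$day[1], "/t", d$trial[1])
    angle_trace(d$angle_deg, subject_id = d$subject[1], day = d$day[1],
                trial_index = d$trial[1],
                stim_duration_ms = d$stim_duration_ms[1],
                stim_onset_ms = if (has_onset) d$stim_onset_ms[1] else stim_onset_ms,
                sample_period_ms = per[1], time_start_ms = tt[1])
  })
  session_set(unname(traces))
}

#' Write a session set to the canonical long-format CSV
#'
#' Values are written in a 6-significant-digit dialect so that a write/read
#' round trip reproduces the numbers to that precision.
#'
#' @param sessions a `session_set`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_traces <- function(sessions, path) {
  rows <- lapply(sessions$traces, function(tr) {
    data.frame(subject = tr$subject_id, day = tr$day, trial = tr$trial_index,
               stim_duration_ms = tr$stim_duration_ms,
               stim_onset_ms = tr$stim_onset_ms,
               time_ms = trace_time(tr),
               angle_deg = ifelse(tr$mask, NA_real_, tr$angle_deg),
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) formatC(x, format = "g", digits = 6))
  df[num] <- lapply(df[num], function(x) ifelse(x == "NA", "", x))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Construct a differential-expression table
#'
#' A `de_table` holds downstream (post-quantification) transcript-level DE
#' results: per-day Wald-test q-values and log2 fold changes (injured vs.
#' control), a likelihood-ratio-test significance flag, and normalized TPM
#' columns labelled `tpm_<tissue>_<day>_<arm>`. Transcript ids must be
#' unique; q-values must lie in [0, 1]; TPM must be non-negative.
#'
#' @param df data.frame with columns `transcript_id`, `gene_id`,
#'   `lrt_flag`, and per-day `log2_fc_d<day>` / `qval_wt_d<day>` pairs
#'   (single-day tables may use plain `log2_fc` / `qval_wt`), plus TPM
#'   columns.
#' @param tissue optional tissue label stored as an attribute.
#' @return the validated data.frame with class `de_table`.
#' @export
de_table <- function(df, tissue = NULL) {
  req <- c("transcript_id", "lrt_flag")
  missing <- setdiff(req, names(df))
  if (length(missing))
    stop("de_table: missing column(s): ", paste(missing, collapse = ", "))
  dup <- unique(df$transcript_id[duplicated(df$transcript_id)])
  if (length(dup))
    stop("de_table: duplicated transcript id(s): ",
         paste(utils::head(dup, 10), collapse = ", "))
  qcols <- grep("^qval_wt(_d[0-9]+)?$", names(df), value = TRUE)
  fcols <- grep("^log2_fc(_d[0-9]+)?$", names(df), value = TRUE)
  if (!length(qcols) || !length(fcols))
    stop("de_table: needs at least one qval_wt and one log2_fc column")
  for (qc in qcols) {
    bad <- !is.na(df[[qc]]) & (df[[qc]] < 0 | df[[qc]] > 1)
    if (any(bad)) stop("de_table: q-values outside [0,1] in column ", qc)
  }
  tcols <- grep("^tpm_", names(df), value = TRUE)
  if (!length(tcols)) stop("de_table: needs at least one tpm_ column")
  for (tc in tcols)
    if (any(df[[tc]] < 0, na.rm = TRUE))
      stop("de_table: negative TPM in column ", tc)
  days <- sort(as.integer(sub("^qval_wt_d", "", qcols[grepl("_d", qcols)])))
  df$lrt_flag <- as.logical(df$lrt_flag)
  structure(df, class = c("de_table", "data.frame"),
            days = days, tissue = tissue)
}

#' Read a differential-expression table from TSV
#' @param path TSV file path.
#' @param tissue optional tissue label.
#' @return a `de_table`.
#' @export
read_de_table <- function(path, tissue = NULL) {
  if (!file.exists(path)) stop("read_de_table: file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  de_table(df, tissue = tissue)
}

#' Write a differential-expression table to TSV
#' @param table a `de_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_de_table <- function(table, path) {
  utils::write.table(as.data.frame(table), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Significance days recorded in a DE table
#' @param table a `de_table`.
#' @return integer vector of days with per-day Wald columns (may be empty
#'   for single-day tables with unsuffixed columns).
#' @export
de_days <- function(table) attr(table, "days")
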