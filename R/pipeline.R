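#' Realized persistence index of the noise-free waveform
#'
#' Closed-form (dense-grid) persistence index of a [twitch_params()]
#' waveform for the long stimulus: mean response over the final
#' `tail_ms` of the stimulus divided by the waveform maximum. Because the
#' peak of the rise-times-fatigue product is below the drive amplitude,
#' the realized index slightly exceeds the plateau fraction `p`; this
#' function and [calibrate_plateau()] close that gap when an exact index
#' is required.
#'
#' @param params a [twitch_params()].
#' @param stim_duration_ms long-stimulus duration (default 1000).
#' @param tail_ms averaging window at the stimulus end (default 10).
#' @return persistence index in [0, 1].
#' @export
realized_persistence <- function(params, stim_duration_ms = 1000,
                                 tail_ms = 10) {
  onset <- 0
  tt <- seq(0, stim_duration_ms, by = 0.1)
  p0 <- params
  p0$latency_ms <- 0
  w <- twitch_waveform(tt, p0, stim_duration_ms, onset)
  tail_mean <- mean(w[tt >= stim_duration_ms - tail_ms])
  pk <- max(w)
  if (pk <= 0) return(NA_real_)
  min(max(tail_mean / pk, 0), 1)
}

#' Calibrate the plateau fraction to a target persistence index
#'
#' Solves for the plateau fraction `p` such that the noise-free waveform's
#' realized persistence index ([realized_persistence()]) equals `target_pi`.
#'
#' @param params a [twitch_params()] whose `plateau_fraction` is replaced.
#' @param target_pi desired persistence index in (0, 1).
#' @param stim_duration_ms long-stimulus duration.
#' @return the params with calibrated `plateau_fraction`.
#' @export
calibrate_plateau <- function(params, target_pi, stim_duration_ms = 1000) {
  stopifnot(target_pi > 0, target_pi < 1)
  f <- function(p) {
    q <- params
    q$plateau_fraction <- p
    realized_persistence(q, stim_duration_ms) - target_pi
  }
  sol <- stats::uniroot(f, c(1e-4, 1 - 1e-6), tol = 1e-8)
  params$plateau_fraction <- sol$root
  params
}

#' Calibrate the drive amplitude to a target realized peak
#'
#' Scales `A_max` so that the noise-free dense-grid maximum of the
#' response to `stim_duration_ms` equals `target_peak_deg`.
#'
#' @param params a [twitch_params()].
#' @param target_peak_deg desired realized peak (deg).
#' @param stim_duration_ms stimulus duration the target refers to.
#' @param stim_onset_ms,trial_length_ms trial geometry for the dense scan.
#' @return the params with scaled `A_max`.
#' @export
calibrate_amplitude <- function(params, target_peak_deg,
                                stim_duration_ms = 1000,
                                stim_onset_ms = 200,
                                trial_length_ms = 3000) {
  pk <- twitch_dense_peak(params, stim_duration_ms, stim_onset_ms,
                          trial_length_ms)$peak
  if (pk <= 0) stop("calibrate_amplitude: waveform peak is zero")
  params$A_max <- params$A_max * target_peak_deg / pk
  params
}

#' Calibrate the plateau fraction to a target group-mean persistence index
#'
#' The printed reference values are group means across subjects, and the
#' realized persistence index is a nonlinear function of the
#' between-subject time-constant and plateau variation, so matching the
#' median subject to a group mean leaves a bias. This variant solves for
#' the plateau fraction such that the expected realized index over the
#' subject-effect distribution (truncated-normal factor on the time
#' constants, log-odds jitter with SD `cv/2` on the plateau) equals the
#' target, using deterministic Gauss-Hermite quadrature.
#'
#' @param params a [twitch_params()].
#' @param target_pi desired group-mean persistence index in (0, 1).
#' @param cv between-subject coefficient of variation (as in
#'   [cohort_spec()]).
#' @param stim_duration_ms long-stimulus duration.
#' @return the params with calibrated `plateau_fraction`.
#' @export
calibrate_plateau_group <- function(params, target_pi, cv = 0.3,
                                    stim_duration_ms = 1000) {
  stopifnot(target_pi > 0, target_pi < 1)
  # 5-node Gauss-Hermite rule (probabilists' scaling)
  gh_x <- c(-2.0201828704560856, -0.9585724646138185, 0,
            0.9585724646138185, 2.0201828704560856) * sqrt(2)
  gh_w <- c(0.019953242059045913, 0.39361932315224116, 0.9453087204829419,
            0.39361932315224116, 0.019953242059045913) / sqrt(pi)
  mean_pi <- function(p) {
    tot <- 0
    for (i in seq_along(gh_x)) {
      f <- max(1 + cv * gh_x[i], 0.05)
      for (j in seq_along(gh_x)) {
        q <- params
        q$tau_rise <- params$tau_rise * f
        q$tau_fatigue <- params$tau_fatigue * f
        q$tau_decay <- params$tau_decay * f
        p0 <- min(max(p, 1e-6), 1 - 1e-6)
        q$plateau_fraction <- stats::plogis(stats::qlogis(p0) +
                                              (cv / 2) * gh_x[j])
        tot <- tot + gh_w[i] * gh_w[j] *
          realized_persistence(q, stim_duration_ms)
      }
    }
    tot
  }
  sol <- stats::uniroot(function(p) mean_pi(p) - target_pi,
                        c(1e-4, 1 - 1e-6), tol = 1e-7)
  params$plateau_fraction <- sol$root
  params
}

#' Demonstration study presets
#'
#' Per-day generator parameters for the two reference cohorts:
#'
#' * `muscle`: a 9-subject direct muscle-stimulation cohort (baseline day
#'   -1, then days 1-10). Baseline parameters are calibrated so the
#'   noise-free 1000-ms response peaks at 13.88 deg with persistence index
#'   0.3012; day-7-and-later parameters peak at 20.32 deg with persistence
#'   index 0.7655, with a faster rise and a smaller half-maximal duration
#'   (increased sensitivity). Days 2-6 interpolate between the two states;
#'   day 1 equals baseline.
#' * `nerve`: a 6-subject nerve-stimulation cohort (baseline day -1, an
#'   acute post-lesion day 0 with reduced amplitude, and day 1 with
#'   responses abolished), brief-twitch kinetics with an 8.77-deg peak and
#'   a 16.2-ms time-to-peak at baseline.
#' * `fasc`: per-day fasciculation parameters ramping the peak-to-peak
#'   amplitude from a noise floor up to 2.45 deg by day 7.
#'
#' @return list with elements `muscle`, `nerve` ([cohort_spec()]s) and
#'   `treatment` (a 10-subject vehicle/antagonist fasciculation cohort
#'   with its `condition_by_subject` map).
#' @export
demo_presets <- function() {
  muscle_state <- function(frac) {
    pk <- 13.88 + frac * (20.32 - 13.88)
    pi_t <- 0.3012 + frac * (0.7655 - 0.3012)
    p <- twitch_params(A_max = 15, d50 = 12.7 + frac * (3 - 12.7), h = 1.5,
                       tau_rise = 33.5 + frac * (20.5 - 33.5),
                       tau_fatigue = 350, tau_decay = 80,
                       plateau_fraction = 0.5, latency_ms = 10,
                       noise_sd = 0.15)
    p <- calibrate_plateau_group(p, pi_t, cv = 0.3)
    calibrate_amplitude(p, pk, stim_duration_ms = 1000)
  }
  ramp <- c("-1" = 0, "1" = 0, "2" = 0.5, "3" = 0.7, "4" = 0.8,
            "5" = 0.9, "6" = 0.95, "7" = 1, "8" = 1, "9" = 1, "10" = 1)
  muscle_days <- as.integer(names(ramp))
  twitch_by_day <- lapply(ramp, muscle_state)
  names(twitch_by_day) <- names(ramp)
  fasc_p2p <- c("-1" = 0.1, "1" = 0.5, "2" = 1.2, "3" = 1.8, "4" = 2.0,
                "5" = 2.1, "6" = 2.3, "7" = 2.45, "8" = 2.45, "9" = 2.45,
                "10" = 2.45)
  fasc_by_day <- lapply(fasc_p2p, function(a)
    fasciculation_params(p2p_deg = a, mode = "narrowband", noise_sd = 0.1))
  names(fasc_by_day) <- names(fasc_p2p)
  muscle <- cohort_spec(n_subjects = 9, days = muscle_days,
                        twitch_by_day = twitch_by_day,
                        fasc_by_day = fasc_by_day)
  nerve_state <- function(peak) {
    twitch_params(A_max = 10, d50 = 0.5, h = 4, tau_rise = 5,
                  tau_fatigue = 1e5, tau_decay = 15,
                  plateau_fraction = 1, latency_ms = 11.2, noise_sd = 0.15,
                  target_peak_deg = if (peak > 0) peak else NULL)
  }
  nerve_by_day <- list("-1" = nerve_state(8.77), "0" = nerve_state(6.5),
                       "1" = {
                         p <- nerve_state(0)
                         p$A_max <- 0
                         p
                       })
  nerve <- cohort_spec(n_subjects = 6, days = c(-1L, 0L, 1L),
                       twitch_by_day = nerve_by_day,
                       durations_ms = c(5, 1000))
  treat_fasc <- list(
    vehicle = lapply(c("-1" = 0.1, "7" = 2.45), function(a)
      fasciculation_params(p2p_deg = a, mode = "narrowband", noise_sd = 0.1)),
    antagonist = lapply(c("-1" = 0.1, "7" = 0), function(a)
      fasciculation_params(p2p_deg = a, mode = "narrowband", noise_sd = 0.1)))
  treatment <- list(
    vehicle = cohort_spec(n_subjects = 5, days = c(-1L, 7L),
                          twitch_by_day = twitch_params(),
                          fasc_by_day = treat_fasc$vehicle),
    antagonist = cohort_spec(n_subjects = 5, days = c(-1L, 7L),
                             twitch_by_day = twitch_params(),
                             fasc_by_day = treat_fasc$antagonist))
  list(muscle = muscle, nerve = nerve, treatment = treatment)
}

fnv1a <- function(s) {
  h <- 5381
  for (b in utf8ToInt(s)) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", h)
}

config_hash <- function(config) {
  attr(config, "provenance") <- NULL
  fnv1a(paste(deparse(config), collapse = ""))
}

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Run the reproducible demonstration study
#'
#' End-to-end pipeline on synthetic data: simulates the muscle- and
#' nerve-stimulation cohorts and the treatment fasciculation cohort
#' ([demo_presets()]), extracts kinematic metrics and duration-response
#' families, computes percent-of-baseline changes, sensitivity thresholds
#' and responder counts, the fasciculation band-power time course, and the
#' cross-tissue DE comparison, writing all tables plus a JSON report to
#' `out_dir`. Fully reproducible for a given seed.
#'
#' @param seed master seed; every stage's seed derives from it.
#' @param out_dir output directory (created if needed).
#' @param presets cohort/preset list as from [demo_presets()]; override to
#'   run a scaled-down study.
#' @param de_spec a [de_sim_spec()] for the transcriptome stage.
#' @param config analysis parameters.
#' @param fasc_replicates spontaneous records per subject/day.
#' @return a `study_report` list (also written as `report.json`),
#'   invisibly.
#' @export
run_demo <- function(seed = 1L, out_dir = tempfile("whiskerkin_demo"),
                     presets = demo_presets(), de_spec = de_sim_spec(),
                     config = default_config(), fasc_replicates = 3L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("run_demo: cannot create output directory")
  manifest <- character(0)
  emit <- function(name, writer) {
    path <- file.path(out_dir, name)
    writer(path)
    manifest <<- c(manifest, name)
    path
  }
  metric_cols <- c("peak_amplitude_deg", "peak_velocity_deg_per_s",
                   "time_to_peak_ms", "half_width_ms", "persistence_index")

  ## --- muscle-stimulation cohort -------------------------------------
  muscle <- simulate_session(presets$muscle, seed = seed)
  fam <- list()
  for (s in unique(muscle$index$subject))
    for (d in unique(muscle$index$day[muscle$index$subject == s]))
      fam[[paste(s, d)]] <- duration_family(muscle, s, d, config)
  muscle_metrics <- do.call(rbind, fam)
  rownames(muscle_metrics) <- NULL
  emit("muscle_metrics.csv", function(p)
    utils::write.csv(muscle_metrics, p, row.names = FALSE))

  long_m <- muscle_metrics[muscle_metrics$stim_duration_ms ==
                             config$long_stim_ms, ]
  gs_long <- group_summary(long_m, metric_cols)
  short_m <- muscle_metrics[muscle_metrics$stim_duration_ms == 5, ]
  gs_short <- group_summary(short_m, c("peak_amplitude_deg",
                                       "peak_velocity_deg_per_s"))
  baseline_day <- min(muscle_metrics$day)
  final_day <- 7L
  pct <- function(gs, metric, day) {
    st <- gs$stats
    b <- st$mean[st$metric == metric & st$day == baseline_day]
    v <- st$mean[st$metric == metric & st$day == day]
    percent_of_baseline(v, b)
  }
  pct_table <- data.frame(
    metric = c("peak_amplitude_1000ms", "peak_velocity_1000ms",
               "persistence_index_1000ms", "peak_amplitude_5ms"),
    day = final_day,
    percent_of_baseline = c(
      pct(gs_long, "peak_amplitude_deg", final_day),
      pct(gs_long, "peak_velocity_deg_per_s", final_day),
      pct(gs_long, "persistence_index", final_day),
      pct(gs_short, "peak_amplitude_deg", final_day)),
    stringsAsFactors = FALSE)
  emit("percent_of_baseline.csv", function(p)
    utils::write.csv(pct_table, p, row.names = FALSE))

  sens <- do.call(rbind, lapply(fam, function(f) data.frame(
    subject = f$subject[1], day = f$day[1],
    threshold_ms = sensitivity_threshold(f, config$sensitivity_criterion_deg),
    stringsAsFactors = FALSE)))
  rownames(sens) <- NULL
  emit("sensitivity_thresholds.csv", function(p)
    utils::write.csv(sens, p, row.names = FALSE))

  ## --- nerve-stimulation cohort --------------------------------------
  nerve <- simulate_session(presets$nerve, seed = seed + 1L)
  nerve_metrics <- do.call(rbind, lapply(
    unique(nerve$index$subject), function(s) do.call(rbind, lapply(
      unique(nerve$index$day), function(d)
        duration_family(nerve, s, d, config)))))
  rownames(nerve_metrics) <- NULL
  emit("nerve_metrics.csv", function(p)
    utils::write.csv(nerve_metrics, p, row.names = FALSE))
  nm5 <- nerve_metrics[nerve_metrics$stim_duration_ms == 5, ]
  responders <- do.call(rbind, lapply(split(nm5, nm5$day), function(g)
    data.frame(day = g$day[1],
               n_responders = sum(g$peak_amplitude_deg >=
                                    config$sensitivity_criterion_deg),
               n_subjects = nrow(g))))
  rownames(responders) <- NULL
  emit("nerve_responders.csv", function(p)
    utils::write.csv(responders, p, row.names = FALSE))

  ## --- fasciculation time course -------------------------------------
  fasc <- simulate_fasciculation_session(presets$muscle, seed = seed + 2L,
                                         replicates = fasc_replicates)
  tc <- fasciculation_time_course(fasc, band = c(config$band_lo,
                                                 config$band_hi),
                                  config = config)
  emit("bandpower.csv", function(p)
    utils::write.csv(as.data.frame(tc), p, row.names = FALSE))
  emit("bandpower_trials.csv", function(p)
    utils::write.csv(attr(tc, "trials"), p, row.names = FALSE))

  veh <- simulate_fasciculation_session(presets$treatment$vehicle,
                                        seed = seed + 3L,
                                        replicates = fasc_replicates)
  ant <- simulate_fasciculation_session(presets$treatment$antagonist,
                                        seed = seed + 4L,
                                        replicates = fasc_replicates)
  relabel <- function(ss, prefix) {
    ss$traces <- lapply(ss$traces, function(tr) {
      tr$subject_id <- paste0(prefix, tr$subject_id)
      tr
    })
    ss
  }
  veh <- relabel(veh, "veh_"); ant <- relabel(ant, "ant_")
  both <- session_set(c(veh$traces, ant$traces), veh$protocol)
  cond <- c(stats::setNames(rep("vehicle", 5),
                            unique(vapply(veh$traces, `[[`, character(1),
                                          "subject_id"))),
            stats::setNames(rep("antagonist", 5),
                            unique(vapply(ant$traces, `[[`, character(1),
                                          "subject_id"))))
  treat <- fasciculation_time_course(both, band = c(config$band_lo,
                                                    config$band_hi),
                                     condition_by_subject = cond,
                                     config = config)
  emit("treatment_bandpower.csv", function(p)
    utils::write.csv(as.data.frame(treat), p, row.names = FALSE))

  ## --- DE comparison ---------------------------------------------------
  de <- simulate_de_tables(de_spec, seed = seed + 5L)
  emit("de_whisker.tsv", function(p) write_de_table(de$a, p))
  emit("de_soleus.tsv", function(p) write_de_table(de$b, p))
  cmp <- compare_de(de$a, de$b, day = 3,
                    spec = filter_spec(config$alpha, config$fc_min,
                                       config$require_lrt))
  emit("venn.json", function(p)
    write_json_file(list(common = unname(cmp$venn$counts["common"]),
                         unique_a = unname(cmp$venn$counts["unique_a"]),
                         unique_b = unname(cmp$venn$counts["unique_b"]),
                         union = unname(cmp$venn$counts["union"]),
                         opposite_direction = cmp$opposite_count), p))
  emit("zmatrix.tsv", function(p) {
    zdf <- data.frame(transcript_id = rownames(cmp$z), cmp$z,
                      check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(zdf, p, sep = "\t", row.names = FALSE, quote = FALSE)
  })
  emit("polar.txt", function(p) writeLines(cmp$polar_ids, p))
  emit("heatmap_table.tsv", function(p) {
    keep <- rownames(cmp$z) %in% cmp$polar_ids
    ht <- heatmap_table(cmp$z[keep, , drop = FALSE])
    utils::write.table(ht, p, sep = "\t", row.names = FALSE, quote = FALSE)
  })

  ## --- report ----------------------------------------------------------
  report <- list(
    seed = seed,
    config_hash = config_hash(config),
    package_version = as.character(utils::packageVersion("whiskerkin")),
    cohorts = list(
      muscle = list(n_subjects = presets$muscle$n_subjects,
                    days = presets$muscle$days,
                    durations_ms = presets$muscle$durations_ms,
                    replicates = presets$muscle$replicates),
      nerve = list(n_subjects = presets$nerve$n_subjects,
                   days = presets$nerve$days,
                   durations_ms = presets$nerve$durations_ms)),
    percent_of_baseline = pct_table,
    nerve_responders = responders,
    sensitivity_threshold_medians = stats::aggregate(
      threshold_ms ~ day, sens, stats::median),
    fasciculation = as.data.frame(tc),
    de = list(common = unname(cmp$venn$counts["common"]),
              union = unname(cmp$venn$counts["union"]),
              opposite_direction = cmp$opposite_count,
              n_polar = length(cmp$polar_ids)),
    manifest = manifest)
  emit("report.json", function(p) write_json_file(report, p))
  report$out_dir <- out_dir
  class(report) <- "study_report"
  invisible(report)
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("<study_report> seed %d, config %s -> %s\n", x$seed,
              x$config_hash, x$out_dir))
  cat("percent of baseline at day 7 (muscle cohort):\n")
  print(x$percent_of_baseline, row.names = FALSE)
  cat("nerve responders by day:\n")
  print(x$nerve_responders, row.names = FALSE)
  cat(sprintf("DE overlap: %d of %d common, %d opposite-direction, %d polar\n",
              x$de$common, x$de$union, x$de$opposite_direction, x$de$n_polar))
  invisible(x)
}

#' Validate the outputs of a demo run
#'
#' Machine-readable checklist of pipeline invariants over a completed
#' [run_demo()] output directory: output manifest completeness, the
#' persistence-index range, the Venn identity, the Parseval identity of
#' every stored spectrum summary, z-matrix row normalization, and filter
#' monotonicity on the stored DE tables.
#'
#' @param out_dir directory written by [run_demo()].
#' @return data.frame of class `validation_checklist` with columns
#'   `check`, `pass`, `detail`; attribute `"pass"` is the conjunction.
#' @export
validate_run <- function(out_dir) {
  checks <- list()
  add <- function(name, pass, detail = "") {
    checks[[length(checks) + 1L]] <<- data.frame(
      check = name, pass = pass, detail = detail, stringsAsFactors = FALSE)
  }
  rpt_path <- file.path(out_dir, "report.json")
  if (!file.exists(rpt_path)) {
    add("report_exists", FALSE, "report.json missing")
  } else {
    rpt <- jsonlite::read_json(rpt_path, simplifyVector = TRUE)
    missing <- rpt$manifest[!file.exists(file.path(out_dir, rpt$manifest))]
    add("manifest_complete", length(missing) == 0,
        if (length(missing)) paste("missing:", paste(missing, collapse = ", "))
        else "")
    mm <- suppressWarnings(try(
      utils::read.csv(file.path(out_dir, "muscle_metrics.csv")),
      silent = TRUE))
    if (inherits(mm, "try-error")) {
      add("persistence_in_range", FALSE, "muscle_metrics.csv unreadable")
    } else {
      pi_v <- mm$persistence_index[is.finite(mm$persistence_index)]
      add("persistence_in_range", all(pi_v >= 0 & pi_v <= 1),
          sprintf("%d values", length(pi_v)))
    }
    vn <- suppressWarnings(try(jsonlite::read_json(
      file.path(out_dir, "venn.json"), simplifyVector = TRUE),
      silent = TRUE))
    if (inherits(vn, "try-error")) {
      add("venn_identity", FALSE, "venn.json unreadable")
    } else {
      add("venn_identity",
          vn$common + vn$unique_a + vn$unique_b == vn$union,
          sprintf("%d + %d + %d vs union %d", vn$common, vn$unique_a,
                  vn$unique_b, vn$union))
    }
    bt <- suppressWarnings(try(
      utils::read.csv(file.path(out_dir, "bandpower_trials.csv")),
      silent = TRUE))
    if (inherits(bt, "try-error")) {
      add("parseval_identity", FALSE, "bandpower_trials.csv unreadable")
    } else {
      rel <- abs(bt$total_power - bt$signal_var) /
        pmax(bt$signal_var, .Machine$double.eps)
      add("parseval_identity", all(rel <= 1e-6),
          sprintf("max rel dev %.3g over %d spectra", max(rel), nrow(bt)))
    }
    zm <- suppressWarnings(try(utils::read.delim(
      file.path(out_dir, "zmatrix.tsv"), check.names = FALSE),
      silent = TRUE))
    if (inherits(zm, "try-error") || !"transcript_id" %in% names(zm)) {
      add("zmatrix_normalized", FALSE, "zmatrix.tsv unreadable")
    } else {
      z <- as.matrix(zm[, setdiff(names(zm), "transcript_id"), drop = FALSE])
      suppressWarnings(storage.mode(z) <- "double")
      if (anyNA(z) || ncol(z) < 2) {
        add("zmatrix_normalized", FALSE, "non-numeric or degenerate matrix")
      } else {
        rm_ <- rowMeans(z)
        nonconst <- apply(z, 1, function(r) any(r != 0))
        add("zmatrix_normalized", all(abs(rm_[nonconst]) < 1e-6),
            sprintf("%d rows", nrow(z)))
      }
    }
    dw <- suppressWarnings(try(
      read_de_table(file.path(out_dir, "de_whisker.tsv")),
      silent = TRUE))
    if (inherits(dw, "try-error")) {
      add("filter_monotonicity", FALSE, "de_whisker.tsv unreadable")
    } else {
      day <- de_days(dw)[1]
      loose <- filter_de(dw, day, filter_spec(alpha = 0.05))
      tight <- filter_de(dw, day, filter_spec(alpha = 0.01))
      tighter_fc <- filter_de(dw, day, filter_spec(fc_min = 4))
      add("filter_monotonicity",
          all(tight$transcript_id %in% loose$transcript_id) &&
            all(tighter_fc$transcript_id %in% loose$transcript_id),
          sprintf("|q<=.05| = %d, |q<=.01| = %d, |FC>=4| = %d",
                  nrow(loose), nrow(tight), nrow(tighter_fc)))
    }
  }
  out <- do.call(rbind, checks)
  attr(out, "pass") <- all(out$pass)
  class(out) <- c("validation_checklist", "data.frame")
  out
}

#' @export
print.validation_checklist <- function(x, ...) {
  cat(sprintf("<validation_checklist> %s\n",
              if (attr(x, "pass")) "ALL CHECKS PASS" else "FAILURES PRESENT"))
  df <- as.data.frame(x)
  df$pass <- ifelse(df$pass, "ok", "FAIL")
  print(df, row.names = FALSE)
  invisible(x)
}
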