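#' Default analysis parameters
#'
#' Central parameter set consumed by the kinematics, fasciculation and DE
#' comparison stages. All values are configurable through [load_config()].
#'
#' * `sg_window`, `sg_polyorder`: Savitzky-Golay smoothing window (samples,
#'   odd) and polynomial order used before differentiation. Defaults 11 and
#'   3: a 22-ms window at 500 frames/s, short enough to preserve ~16-ms
#'   nerve-twitch rises while suppressing frame noise.
#' * `baseline_window_ms`: pre-stimulus window for the resting angle (200).
#' * `response_window_ms`: search window after stimulus onset for peak
#'   metrics (2000; covers post-offset peaks of short stimuli).
#' * `long_stim_ms`: stimulus duration for which the persistence index is
#'   defined (1000).
#' * `persistence_tail_ms`: averaging window at the end of the long
#'   stimulus for the persistence numerator (10).
#' * `band_lo`, `band_hi`: fasciculation band edges in Hz (5, 8).
#' * `alpha`, `fc_min`, `require_lrt`: DE filter chain (Wald q <= 0.05,
#'   fold change >= 2, LRT membership required).
#' * `sensitivity_criterion_deg`: absolute amplitude criterion for the
#'   duration threshold and responder counts (1 degree).
#' * `noise_criterion_k`: multiple of the baseline SD below which a peak is
#'   flagged "no response" and time metrics are withheld (3).
#' * `max_mask_run`: longest run of missing frames repaired by linear
#'   interpolation before a trial is rejected (5).
#' * `response_sign`: +1 analyses protractions (positive deflections), -1
#'   retractions.
#'
#' @return named list of defaults.
#' @export
default_config <- function() {
  list(
    sg_window = 11L,
    sg_polyorder = 3L,
    baseline_window_ms = 200,
    response_window_ms = 2000,
    long_stim_ms = 1000,
    persistence_tail_ms = 10,
    band_lo = 5,
    band_hi = 8,
    alpha = 0.05,
    fc_min = 2,
    require_lrt = TRUE,
    sensitivity_criterion_deg = 1.0,
    noise_criterion_k = 3,
    max_mask_run = 5L,
    response_sign = 1
  )
}

validate_config <- function(cfg) {
  if (cfg$sg_window %% 2L == 0L)
    stop("config: sg_window must be odd")
  if (cfg$sg_window < cfg$sg_polyorder + 2L)
    stop("config: sg_window must be at least sg_polyorder + 2")
  if (cfg$band_lo >= cfg$band_hi)
    stop("config: band_lo must be < band_hi")
  if (cfg$alpha <= 0 || cfg$alpha >= 1)
    stop("config: alpha must be in (0,1)")
  if (cfg$fc_min < 1) stop("config: fc_min must be >= 1")
  if (!cfg$response_sign %in% c(-1, 1))
    stop("config: response_sign must be +1 or -1")
  if (cfg$baseline_window_ms <= 0)
    stop("config: baseline_window_ms must be > 0")
  cfg
}

#' Load analysis parameters from a YAML file
#'
#' Reads a flat key/value YAML file, fills every unset key from
#' [default_config()], warns on unknown keys, and errors on type
#' mismatches. An empty or absent file yields the full default set. The
#' convenience key `band: [lo, hi]` expands to `band_lo`/`band_hi`.
#' Overrides applied are recorded in the `"provenance"` attribute.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @param overrides named list applied on top of the file.
#' @return validated configuration list.
#' @export
load_config <- function(path = NULL, overrides = list()) {
  cfg <- default_config()
  user <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("load_config: file not found: ", path)
    user <- yaml::read_yaml(path)
    if (is.null(user)) user <- list()
  }
  user <- utils::modifyList(user, overrides)
  if (!is.null(user$band)) {
    if (length(user$band) != 2)
      stop("load_config: key 'band' must be [lo, hi]")
    user$band_lo <- user$band[[1]]
    user$band_hi <- user$band[[2]]
    user$band <- NULL
  }
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown))
    warning("load_config: unknown key(s) ignored: ",
            paste(unknown, collapse = ", "))
  prov <- character(0)
  for (k in intersect(names(user), names(cfg))) {
    v <- user[[k]]
    if (is.logical(cfg[[k]])) {
      if (!is.logical(v))
        stop("load_config: key '", k, "' must be logical")
    } else if (is.numeric(cfg[[k]])) {
      if (!is.numeric(v))
        stop("load_config: key '", k, "' must be numeric")
    }
    if (is.integer(cfg[[k]])) v <- as.integer(v)
    cfg[[k]] <- v
    prov <- c(prov, sprintf("%s = %s", k, paste(format(v), collapse = ", ")))
  }
  cfg <- validate_config(cfg)
  attr(cfg, "provenance") <- prov
  cfg
}
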