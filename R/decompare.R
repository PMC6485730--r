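#' Differential-expression filter specification
#'
#' The significance chain applied to each tissue/day: Wald-test q-value at
#' most `alpha`, membership in the experiment-wide LRT-significant set
#' (when `require_lrt`), and absolute fold change of at least `fc_min`
#' (i.e. `|log2FC| >= log2(fc_min)`, boundary included, either direction).
#'
#' @param alpha Wald q-value threshold, in (0, 1).
#' @param fc_min minimum fold change (>= 1; default 2).
#' @param require_lrt require the LRT flag (default `TRUE`).
#' @return a `filter_spec` list.
#' @export
filter_spec <- function(alpha = 0.05, fc_min = 2, require_lrt = TRUE) {
  stopifnot(alpha > 0, alpha < 1, fc_min >= 1)
  structure(list(alpha = alpha, fc_min = fc_min, require_lrt = require_lrt),
            class = "filter_spec")
}

de_cols <- function(table, day) {
  if (is.null(day)) {
    qc <- "qval_wt"; fc <- "log2_fc"
  } else {
    qc <- sprintf("qval_wt_d%d", day)
    fc <- sprintf("log2_fc_d%d", day)
    if (!qc %in% names(table) && "qval_wt" %in% names(table) &&
        length(attr(table, "days")) == 0) {
      qc <- "qval_wt"; fc <- "log2_fc"
    }
  }
  if (!qc %in% names(table))
    stop("filter_de: table has no Wald q-values for day ",
         if (is.null(day)) "(unsuffixed)" else day)
  list(q = qc, fc = fc)
}

#' Apply the significance filter chain to a DE table
#'
#' @param table a [de_table()].
#' @param day which day's Wald columns to use (`NULL` for single-day
#'   tables with unsuffixed columns).
#' @param spec a [filter_spec()].
#' @return data.frame of class `de_sig_set` with columns `transcript_id`,
#'   `log2_fc`, `sign`, sorted by id.
#' @export
filter_de <- function(table, day = NULL, spec = filter_spec()) {
  cl <- de_cols(table, day)
  q <- table[[cl$q]]
  lfc <- table[[cl$fc]]
  keep <- !is.na(q) & q <= spec$alpha & abs(lfc) >= log2(spec$fc_min)
  if (spec$require_lrt) keep <- keep & table$lrt_flag
  out <- data.frame(transcript_id = table$transcript_id[keep],
                    log2_fc = lfc[keep],
                    sign = sign(lfc[keep]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$transcript_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("de_sig_set", "data.frame")
  out
}

#' Overlap (Venn) decomposition of two transcript sets
#'
#' @param set_a,set_b character vectors of transcript ids (or
#'   `de_sig_set`s, whose ids are used).
#' @return list of class `venn` with sorted membership vectors `common`,
#'   `unique_a`, `unique_b` and a `counts` vector satisfying
#'   `common + unique_a + unique_b = union`.
#' @export
venn_sets <- function(set_a, set_b) {
  ids <- function(x) if (is.data.frame(x)) x$transcript_id else as.character(x)
  a <- unique(ids(set_a)); b <- unique(ids(set_b))
  common <- sort(intersect(a, b))
  ua <- sort(setdiff(a, b))
  ub <- sort(setdiff(b, a))
  structure(list(common = common, unique_a = ua, unique_b = ub,
                 counts = c(common = length(common), unique_a = length(ua),
                            unique_b = length(ub),
                            union = length(common) + length(ua) + length(ub))),
            class = "venn")
}

#' @export
print.venn <- function(x, ...) {
  cat(sprintf("<venn> union %d: common %d, unique A %d, unique B %d\n",
              x$counts["union"], x$counts["common"], x$counts["unique_a"],
              x$counts["unique_b"]))
  invisible(x)
}

#' Count transcripts regulated in opposite directions
#'
#' Among shared transcript ids, counts those whose log2 fold changes have
#' opposite signs in the two tables while both exceed the fold-change
#' threshold.
#'
#' @param table_a,table_b [de_table()]s.
#' @param ids transcript ids to examine (typically the Venn `common` set).
#' @param day_a,day_b which day's fold changes to compare.
#' @param fc_min fold-change threshold (default 2).
#' @return integer count.
#' @export
opposite_direction_count <- function(table_a, table_b, ids, day_a = 3,
                                     day_b = 3, fc_min = 2) {
  if (!length(ids)) return(0L)
  ca <- de_cols(table_a, day_a); cb <- de_cols(table_b, day_b)
  ia <- match(ids, table_a$transcript_id)
  ib <- match(ids, table_b$transcript_id)
  if (anyNA(ia) || anyNA(ib))
    stop("opposite_direction_count: id(s) missing from a table: ",
         paste(utils::head(ids[is.na(ia) | is.na(ib)], 5), collapse = ", "))
  fa <- table_a[[ca$fc]][ia]
  fb <- table_b[[cb$fc]][ib]
  thr <- log2(fc_min)
  sum(sign(fa) != sign(fb) & abs(fa) >= thr & abs(fb) >= thr)
}

#' Row-wise z-scores of a TPM submatrix
#'
#' For each transcript (row), `z = (x - mean) / sd` across the included
#' condition columns, using the sample (n-1) standard deviation.
#' Constant rows get z = 0 and are flagged degenerate. With `groups`,
#' columns are standardized within each group separately (the "each day
#' separately" mode); every group then needs at least two columns.
#'
#' @param tpm numeric matrix, transcripts x conditions (rownames = ids).
#' @param groups optional factor/character of length `ncol(tpm)` defining
#'   column groups to standardize within.
#' @return z matrix of the same shape, with logical attribute
#'   `"degenerate"` marking all-constant rows (per group, any).
#' @export
zscore_matrix <- function(tpm, groups = NULL) {
  tpm <- as.matrix(tpm)
  if (ncol(tpm) < 2) stop("zscore_matrix: need at least 2 condition columns")
  zs <- function(m) {
    mu <- rowMeans(m)
    sdv <- apply(m, 1, stats::sd)
    z <- (m - mu) / ifelse(sdv == 0, 1, sdv)
    z[sdv == 0, ] <- 0
    attr(z, "deg") <- sdv == 0
    z
  }
  if (is.null(groups)) {
    z <- zs(tpm)
    degenerate <- attr(z, "deg")
  } else {
    if (length(groups) != ncol(tpm))
      stop("zscore_matrix: groups must label every column")
    z <- tpm
    degenerate <- rep(FALSE, nrow(tpm))
    for (g in unique(groups)) {
      sel <- groups == g
      if (sum(sel) < 2)
        stop("zscore_matrix: group '", g, "' has fewer than 2 columns")
      zg <- zs(tpm[, sel, drop = FALSE])
      z[, sel] <- zg
      degenerate <- degenerate | attr(zg, "deg")
    }
  }
  attr(z, "deg") <- NULL
  attr(z, "degenerate") <- unname(degenerate)
  attr(z, "sd_convention") <- "sample (n-1)"
  z
}

#' Polar-expression filter
#'
#' Keeps transcripts that are significant in at least one dataset and whose
#' signed day-3 values (z-scores by default) have strictly opposite signs
#' between the two tissues; a zero on either side is not polar.
#'
#' @param values_a,values_b named numeric vectors (names = transcript ids)
#'   of signed day-3 values per tissue.
#' @param significant character vector of ids significant in >= 1 dataset.
#' @return sorted character vector of polar transcript ids.
#' @export
polar_filter <- function(values_a, values_b, significant) {
  ids <- intersect(names(values_a), names(values_b))
  ids <- intersect(ids, significant)
  va <- values_a[ids]; vb <- values_b[ids]
  polar <- !is.na(va) & !is.na(vb) & sign(va) * sign(vb) < 0
  sort(ids[polar])
}

#' Long-format heatmap table of z-scores by gene group
#'
#' Flattens a z matrix into a (transcript, group, condition, z) table with
#' a deterministic row order: by group, then by descending |z| at the
#' reference (first) condition, then by id. Transcripts with no group
#' label get group "other" with a warning.
#'
#' @param z z-score matrix (rownames = transcript ids, colnames =
#'   condition labels, e.g. `W1, W3, W7, S3`).
#' @param groups named character vector mapping transcript id to a gene
#'   group label.
#' @param reference_condition condition used for within-group ordering
#'   (default: first column).
#' @return long-format data.frame with `nrow(z) * ncol(z)` rows.
#' @export
heatmap_table <- function(z, groups = NULL, reference_condition = NULL) {
  z <- as.matrix(z)
  ids <- rownames(z)
  if (is.null(ids)) stop("heatmap_table: z must have transcript rownames")
  conds <- colnames(z)
  if (is.null(conds)) conds <- paste0("C", seq_len(ncol(z)))
  if (is.null(reference_condition)) reference_condition <- conds[1]
  if (is.null(groups)) groups <- stats::setNames(rep("other", length(ids)), ids)
  lab <- unname(groups[ids])
  if (anyNA(lab)) {
    warning("heatmap_table: unlabelled transcript(s) assigned to group 'other'")
    lab[is.na(lab)] <- "other"
  }
  refz <- z[, reference_condition]
  ord <- order(lab, -abs(refz), ids)
  rows <- expand.grid(condition = conds, transcript_id = ids[ord],
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  rows <- rows[, c("transcript_id", "condition")]
  rows$group <- lab[ord][match(rows$transcript_id, ids[ord])]
  rows$z <- z[cbind(match(rows$transcript_id, ids),
                    match(rows$condition, conds))]
  rows <- rows[, c("transcript_id", "group", "condition", "z")]
  rownames(rows) <- NULL
  rows
}

#' Cross-tissue DE comparison
#'
#' Orchestrates the post-DE comparison between two tissues at a matched
#' day: applies the filter chain to both tables, computes the overlap
#' decomposition and the opposite-direction count, builds the z-score
#' matrix of injured TPM across the included conditions, and applies the
#' polar-expression filter to the day-matched z columns.
#'
#' @param table_a,table_b [de_table()]s (e.g. whisker pad and soleus).
#' @param day comparison day (default 3).
#' @param spec a [filter_spec()].
#' @param z_groups `NULL` (z across all included injured conditions, the
#'   default) or `"within_day"` (standardize each day's columns
#'   separately; requires >= 2 columns per day).
#' @return list of class `de_comparison` with fields `sig_a`, `sig_b`,
#'   `venn`, `opposite_count`, `z` (matrix with conditions like
#'   `W1, W3, W7, S3`), `polar_ids`, `day`.
#' @export
compare_de <- function(table_a, table_b, day = 3, spec = filter_spec(),
                       z_groups = NULL) {
  sig_a <- filter_de(table_a, day, spec)
  sig_b <- filter_de(table_b, day, spec)
  vn <- venn_sets(sig_a, sig_b)
  opp <- opposite_direction_count(table_a, table_b, vn$common,
                                  day_a = day, day_b = day,
                                  fc_min = spec$fc_min)
  union_ids <- sort(unique(c(sig_a$transcript_id, sig_b$transcript_id)))
  inj_cols <- function(tb) {
    cols <- grep("^tpm_.*_inj$", names(tb), value = TRUE)
    if (!length(cols)) stop("compare_de: no tpm_*_inj columns in a table")
    cols
  }
  ca <- inj_cols(table_a); cb <- inj_cols(table_b)
  shared <- intersect(union_ids,
                      intersect(table_a$transcript_id, table_b$transcript_id))
  ma <- as.matrix(table_a[match(shared, table_a$transcript_id), ca,
                          drop = FALSE])
  mb <- as.matrix(table_b[match(shared, table_b$transcript_id), cb,
                          drop = FALSE])
  lab <- function(cols) {
    parts <- strsplit(sub("^tpm_", "", cols), "_")
    vapply(parts, function(p)
      paste0(toupper(substr(p[1], 1, 1)), p[2]), character(1))
  }
  tpm <- cbind(ma, mb)
  rownames(tpm) <- shared
  colnames(tpm) <- c(lab(ca), lab(cb))
  groups <- NULL
  if (identical(z_groups, "within_day"))
    groups <- sub("^[A-Z]", "", colnames(tpm))
  z <- zscore_matrix(tpm, groups = groups)
  day_cols <- grep(paste0("^[A-Z]", day, "$"), colnames(z), value = TRUE)
  polar <- if (length(day_cols) == 2) {
    polar_filter(stats::setNames(z[, day_cols[1]], rownames(z)),
                 stats::setNames(z[, day_cols[2]], rownames(z)),
                 union_ids)
  } else character(0)
  structure(list(sig_a = sig_a, sig_b = sig_b, venn = vn,
                 opposite_count = opp, z = z, polar_ids = polar, day = day,
                 filter = spec),
            class = "de_comparison")
}

#' @export
print.de_comparison <- function(x, ...) {
  cat(sprintf("<de_comparison> day %d: |A| = %d, |B| = %d\n", x$day,
              nrow(x$sig_a), nrow(x$sig_b)))
  print(x$venn)
  cat(sprintf("  opposite-direction (both >= FC %g): %d\n",
              x$filter$fc_min, x$opposite_count))
  cat(sprintf("  polar transcripts at day %d: %d\n", x$day,
              length(x$polar_ids)))
  invisible(x)
}
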