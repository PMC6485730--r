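make_de_df <- function(n, seed = 1, day = 3) {
  set.seed(seed)
  df <- data.frame(transcript_id = sprintf("t%04d", 1:n),
                   gene_id = sprintf("g%04d", 1:n),
                   lrt_flag = runif(n) < 0.5,
                   stringsAsFactors = FALSE)
  df[[sprintf("log2_fc_d%d", day)]] <- rnorm(n, 0, 1.5)
  df[[sprintf("qval_wt_d%d", day)]] <- runif(n)
  df[[sprintf("tpm_x_%d_inj", day)]] <- rlnorm(n)
  df[[sprintf("tpm_x_%d_sham", day)]] <- rlnorm(n)
  de_table(df)
}

test_that("filter chain applies boundary-inclusive thresholds", {
  df <- data.frame(transcript_id = c("a", "b", "c", "d"),
                   gene_id = "g", lrt_flag = c(TRUE, TRUE, FALSE, TRUE),
                   log2_fc_d3 = c(1.0, 0.9, 2.0, -1.5),
                   qval_wt_d3 = c(0.01, 0.01, 0.01, 0.05),
                   tpm_x_3_inj = 1, tpm_x_3_sham = 1)
  tb <- de_table(df)
  sig <- filter_de(tb, 3)
  # exactly FC 2 (log2 = 1) is included; |log2FC| 0.9 excluded; no-LRT excluded;
  # q exactly at alpha included
  expect_setequal(sig$transcript_id, c("a", "d"))
  expect_equal(sig$sign[sig$transcript_id == "d"], -1)
  no_lrt <- filter_de(tb, 3, filter_spec(require_lrt = FALSE))
  expect_setequal(no_lrt$transcript_id, c("a", "c", "d"))
  expect_error(filter_de(tb, 5), "day 5")
})

test_that("filter matches a brute-force row scan on random tables", {
  tb <- make_de_df(500, seed = 42)
  spec <- filter_spec(alpha = 0.05, fc_min = 2, require_lrt = TRUE)
  sig <- filter_de(tb, 3, spec)
  expected <- character(0)
  for (i in seq_len(nrow(tb))) {
    if (tb$qval_wt_d3[i] <= 0.05 && tb$lrt_flag[i] &&
        abs(tb$log2_fc_d3[i]) >= 1)
      expected <- c(expected, tb$transcript_id[i])
  }
  expect_setequal(sig$transcript_id, expected)
})

test_that("filter output shrinks monotonically as thresholds tighten", {
  tb <- make_de_df(500, seed = 7)
  base <- filter_de(tb, 3, filter_spec(alpha = 0.2, fc_min = 1.5))
  for (a in c(0.1, 0.05, 0.01)) {
    tighter <- filter_de(tb, 3, filter_spec(alpha = a, fc_min = 1.5))
    expect_true(all(tighter$transcript_id %in% base$transcript_id))
  }
  for (fc in c(2, 3, 6)) {
    tighter <- filter_de(tb, 3, filter_spec(alpha = 0.2, fc_min = fc))
    expect_true(all(tighter$transcript_id %in% base$transcript_id))
  }
  # output is a subset of the WT-significant and LRT sets
  sig <- filter_de(tb, 3)
  expect_true(all(tb$qval_wt_d3[match(sig$transcript_id,
                                      tb$transcript_id)] <= 0.05))
  expect_true(all(tb$lrt_flag[match(sig$transcript_id, tb$transcript_id)]))
})

test_that("venn counts satisfy the partition identity", {
  vn <- venn_sets(c("a", "b", "c"), c("b", "c", "d", "e"))
  expect_equal(unname(vn$counts["common"]), 2)
  expect_equal(unname(vn$counts["union"]), 5)
  expect_equal(sum(vn$counts[c("common", "unique_a", "unique_b")]),
               unname(vn$counts["union"]))
  expect_equal(venn_sets("a", "b")$counts[["common"]], 0)
  expect_equal(venn_sets(c("x", "y"), c("y", "x"))$counts[["unique_a"]], 0)
  # permutation invariance
  set.seed(5)
  a <- sample(letters, 10); b <- sample(letters, 12)
  v1 <- venn_sets(a, b)
  v2 <- venn_sets(sample(a), sample(b))
  expect_identical(v1, v2)
})

test_that("opposite-direction counting matches a brute-force scan", {
  ta <- make_de_df(200, seed = 3)
  tb <- make_de_df(200, seed = 4)
  ids <- ta$transcript_id[1:100]
  got <- opposite_direction_count(ta, tb, ids, fc_min = 2)
  manual <- 0
  for (id in ids) {
    fa <- ta$log2_fc_d3[ta$transcript_id == id]
    fb <- tb$log2_fc_d3[tb$transcript_id == id]
    if (sign(fa) != sign(fb) && abs(fa) >= 1 && abs(fb) >= 1)
      manual <- manual + 1
  }
  expect_equal(got, manual)
  one <- data.frame(transcript_id = "t0001", gene_id = "g", lrt_flag = TRUE,
                    log2_fc_d3 = 1.5, qval_wt_d3 = 0.01,
                    tpm_x_3_inj = 1, tpm_x_3_sham = 1)
  two <- one
  two$log2_fc_d3 <- -1.2
  expect_equal(opposite_direction_count(de_table(one), de_table(two),
                                        "t0001"), 1)
  expect_error(opposite_direction_count(ta, tb, "nope"), "missing")
})

test_that("z-scores use the sample-sd convention and flag constant rows", {
  z <- zscore_matrix(matrix(c(1, 2, 3), nrow = 1))
  expect_equal(as.numeric(z), c(-1, 0, 1))
  zc <- zscore_matrix(matrix(c(5, 5, 5, 1, 2, 3), nrow = 2, byrow = TRUE))
  expect_equal(as.numeric(zc[1, ]), c(0, 0, 0))
  expect_identical(attr(zc, "degenerate"), c(TRUE, FALSE))
  expect_error(zscore_matrix(matrix(1:5, ncol = 1)), "2 condition")
  set.seed(8)
  m <- matrix(rlnorm(200), nrow = 50)
  zm <- zscore_matrix(m)
  for (i in seq_len(nrow(m)))
    expect_equal(zm[i, ], (m[i, ] - mean(m[i, ])) / sd(m[i, ]),
                 tolerance = 1e-12)
  # within-day grouping standardizes each group separately
  zg <- zscore_matrix(m, groups = c("d1", "d1", "d3", "d3"))
  expect_equal(zg[1, 1:2],
               (m[1, 1:2] - mean(m[1, 1:2])) / sd(m[1, 1:2]),
               tolerance = 1e-12)
  expect_error(zscore_matrix(m, groups = c("a", "b", "b", "b")), "fewer")
})

test_that("polar filter keeps strictly opposite-signed significant transcripts", {
  za <- c(t1 = 1.3, t2 = 1.3, t3 = 0, t4 = -2)
  zb <- c(t1 = -0.8, t2 = 0.2, t3 = -1, t4 = 3)
  expect_equal(polar_filter(za, zb, names(za)), c("t1", "t4"))
  # zero is not polar
  expect_false("t3" %in% polar_filter(za, zb, names(za)))
  # significance gate
  expect_equal(polar_filter(za, zb, "t4"), "t4")
})

test_that("heatmap table is long-format with deterministic ordering", {
  z <- matrix(c(0.5, -2, 1.5, 1, 0.2, -1, -0.3, 2, 0.1, 0.7, -1.2, 0.4),
              nrow = 3, dimnames = list(c("t1", "t2", "t3"),
                                        c("W1", "W3", "W7", "S3")))
  groups <- c(t1 = "channel", t2 = "channel", t3 = "junction")
  ht <- heatmap_table(z, groups)
  expect_equal(nrow(ht), 12)
  # within group, descending |z| at the reference condition W1
  ch <- unique(ht$transcript_id[ht$group == "channel"])
  expect_equal(ch, c("t2", "t1"))
  expect_identical(ht, heatmap_table(z, groups))
  expect_warning(heatmap_table(z, groups[1:2]), "other")
})

test_that("planted DE truth is recovered across seeds", {
  for (seed in 1:20) {
    sim <- simulate_de_tables(
      de_sim_spec(n_transcripts = 400, n_sig_a = 30, n_sig_b = 25,
                  n_common = 8), seed = seed)
    sa <- filter_de(sim$a, 3)
    sb <- filter_de(sim$b, 3)
    # no planted transcript is omitted
    expect_true(all(sim$truth$planted_a %in% sa$transcript_id))
    expect_true(all(sim$truth$planted_b %in% sb$transcript_id))
    # false discoveries are bounded by the q-noise model
    expect_lte(sum(!sa$transcript_id %in% sim$truth$planted_a),
               ceiling(0.05 * 400))
  }
})

test_that("compare_de assembles a consistent comparison object", {
  sim <- simulate_de_tables(
    de_sim_spec(n_transcripts = 600, n_sig_a = 50, n_sig_b = 40,
                n_common = 12), seed = 9)
  cmp <- compare_de(sim$a, sim$b, day = 3)
  expect_equal(unname(cmp$venn$counts["common"]), 12)
  expect_equal(sum(cmp$venn$counts[c("common", "unique_a", "unique_b")]),
               unname(cmp$venn$counts["union"]))
  expect_equal(cmp$opposite_count, 0)
  expect_equal(colnames(cmp$z), c("W1", "W3", "W7", "S3"))
  # every polar transcript is significant in at least one dataset
  union_ids <- union(cmp$sig_a$transcript_id, cmp$sig_b$transcript_id)
  expect_true(all(cmp$polar_ids %in% union_ids))
  # discordant plants are counted
  simd <- simulate_de_tables(
    de_sim_spec(n_transcripts = 600, n_sig_a = 50, n_sig_b = 40,
                n_common = 12, n_discordant = 3), seed = 9)
  cmpd <- compare_de(simd$a, simd$b, day = 3)
  expect_equal(cmpd$opposite_count, 3)
})
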