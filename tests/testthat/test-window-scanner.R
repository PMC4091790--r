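manifest_df <- function(pos, chrom = "chr1") {
  data.frame(probe_id = sprintf("p%03d", seq_along(pos)),
             chrom = rep_len(chrom, length(pos)),
             pos = as.integer(pos), stringsAsFactors = FALSE)
}

test_that("window enumeration anchors, filters and collapses candidates", {
  w <- enumerate_windows(manifest_df(c(10L, 500L, 900L)))
  expect_equal(nrow(w), 1L)
  expect_equal(w$start, 9L)
  expect_equal(w$end, 1009L)
  expect_equal(w$n_probes, 3L)

  expect_equal(nrow(enumerate_windows(manifest_df(c(10L, 5000L)))), 0L)

  # five probes within 100 bp collapse onto one maximal candidate
  w5 <- enumerate_windows(manifest_df(c(100L, 120L, 150L, 170L, 199L)))
  expect_equal(nrow(w5), 1L)
  expect_equal(w5$n_probes, 5L)

  # empty manifest -> empty output
  expect_equal(nrow(enumerate_windows(manifest_df(integer()))), 0L)

  # staggered probes keep distinct maximal windows
  ws <- enumerate_windows(manifest_df(c(10L, 400L, 800L, 1200L, 1600L)))
  expect_true(all(ws$n_probes >= 3L))
  expect_gt(nrow(ws), 1L)
  expect_error(enumerate_windows(manifest_df(c(500L, 10L))), "sorted")
})

test_that("the regression filter keeps age-linear windows and drops flat ones", {
  ages <- c(25, 30, 35, 40, 45, 50, 55, 60)
  exact <- regression_filter(0.6 - 0.003 * ages, ages)
  expect_equal(exact$slope, -0.003, tolerance = 1e-12)
  expect_true(exact$keep)

  flat <- regression_filter(rep(0.4, 8), ages)
  expect_equal(flat$slope, 0)
  expect_false(flat$keep)

  # slope is also reported in percent per year
  conv <- regression_filter(0.55 - 0.00281 * ages + stats::rnorm(8, 0, 1e-9),
                            ages)
  expect_equal(conv$slope_pct_per_year, -0.281, tolerance = 1e-4)

  expect_warning(out <- regression_filter(stats::runif(4), rep(40, 4)),
                 "zero age variance")
  expect_false(out$keep)
})

test_that("the confirmatory paired t-test matches its closed form", {
  d <- c(-0.05, -0.04, -0.06)
  ct <- confirm_ttest(rep(0, 3), d)
  tstat <- mean(d) / (stats::sd(d) / sqrt(3))
  expect_equal(ct$p, 2 * stats::pt(abs(tstat), df = 2, lower.tail = FALSE),
               tolerance = 1e-12)
  # equal nonzero differences: zero variance, undefined, flagged
  deg <- confirm_ttest(c(0.5, 0.6, 0.7), c(0.45, 0.55, 0.65))
  expect_false(deg$defined)
  expect_true(is.na(deg$p))
  expect_equal(deg$mean_difference, -0.05)
  same <- confirm_ttest(c(0.5, 0.6), c(0.5, 0.6))
  expect_equal(same$mean_difference, 0)
})

test_that("calling and merging honours thresholds, unions and direction", {
  base <- data.frame(window_id = sprintf("w%d", 1:4), chrom = "chr1",
                     start = c(100L, 600L, 5000L, 9000L),
                     end = c(1100L, 1600L, 6000L, 10000L),
                     q_bh = c(5e-5, 5e-5, 5e-5, 0.5),
                     log2_ratio = c(-0.3, -0.25, 0.4, -0.5),
                     slope_pct_per_year = c(-0.3, -0.3, 0.4, -0.5),
                     direction = c("hypo", "hypo", "hyper", "none"),
                     stringsAsFactors = FALSE)
  reg <- call_and_merge(base)
  expect_equal(nrow(reg), 2L)
  hypo <- reg[reg$direction == "hypo", ]
  expect_equal(hypo$start, 100L)  # overlapping windows union to [100, 1600)
  expect_equal(hypo$end, 1600L)
  expect_equal(hypo$n_windows, 2L)
  expect_equal(reg$best_q, c(5e-5, 5e-5))

  # book-ended same-direction windows merge; opposite directions never do
  bk <- base
  bk$start <- c(100L, 1100L, 2100L, 9000L)
  bk$end <- c(1100L, 2100L, 3100L, 10000L)
  bk$direction <- c("hypo", "hypo", "hyper", "none")
  bk$log2_ratio <- c(-0.3, -0.25, 0.4, -0.5)
  reg2 <- call_and_merge(bk)
  expect_equal(nrow(reg2), 2L)
  expect_equal(reg2[reg2$direction == "hypo", ]$end, 2100L)
  expect_equal(reg2[reg2$direction == "hyper", ]$start, 2100L)
})

test_that("scored windows satisfy their internal consistency invariants", {
  cfg <- synthetic_config(seed = 2, n_candidate_windows = 60L,
                          planted_hypo = 6L, planted_hyper = 2L)
  m <- generate_manifest(cfg)
  bb <- generate_paired_betas(cfg, m)
  scan <- scan_methylome(m, bb$betas, bb$samples)
  sw <- scan$windows
  expect_true(all(sw$n_probes >= 3L))
  expect_equal(sw$fdr_transformed,
               -10 * log10(pmax(sw$q_bh, 1e-30)), tolerance = 1e-9)
  expect_equal(sw$slope_pct_per_year, 100 * sw$slope)
  hypo <- sw$direction == "hypo"
  hyper <- sw$direction == "hyper"
  expect_true(all(sw$log2_ratio[hypo] <= -0.2 & sw$q_bh[hypo] <= 1e-4))
  expect_true(all(sw$log2_ratio[hyper] >= 0.2 & sw$q_bh[hyper] <= 1e-4))
  expect_true(all(sw$baseline_class %in% c("low", "intermediate", "high")))
  # windows over planted baselines (0.2-0.6) are never high at baseline
  expect_true(all(sw$baseline_class[hypo | hyper] != "high"))
})

test_that("the scanner recovers exactly the planted regions on a small cohort", {
  cfg <- synthetic_config(seed = 19, n_candidate_windows = 300L,
                          planted_hypo = 12L, planted_hyper = 3L)
  m <- generate_manifest(cfg)
  bb <- generate_paired_betas(cfg, m)
  scan <- scan_methylome(m, bb$betas, bb$samples)
  expect_equal(sum(scan$regions$direction == "hypo"), 12L)
  expect_equal(sum(scan$regions$direction == "hyper"), 3L)
  rg <- GenomicRanges::GRanges(scan$regions$chrom,
                               IRanges::IRanges(scan$regions$start + 1,
                                                scan$regions$end))
  tg <- GenomicRanges::GRanges(m$truth$chrom,
                               IRanges::IRanges(m$truth$start + 1,
                                                m$truth$end))
  ov <- GenomicRanges::findOverlaps(rg, tg)
  match_dir <- scan$regions$direction[S4Vectors::queryHits(ov)] ==
    m$truth$direction[S4Vectors::subjectHits(ov)]
  expect_equal(length(unique(S4Vectors::queryHits(ov)[match_dir])),
               nrow(scan$regions))
})
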