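small_cfg <- function(seed = 1, ...) {
  synthetic_config(seed = seed, n_candidate_windows = 40L,
                   planted_hypo = 4L, planted_hyper = 2L, ...)
}

test_that("configuration invariants are enforced", {
  expect_error(synthetic_config(n_candidate_windows = 10L, planted_hypo = 9L,
                                planted_hyper = 2L),
               "planted windows exceed")
  expect_error(synthetic_config(probes_per_planted_window = 2L),
               "must be >= 3")
  expect_error(synthetic_config(n_candidate_windows = 100L, n_probes = 500L,
                                planted_hypo = 10L, planted_hyper = 2L),
               "n_probes")
})

test_that("manifest placement honours the planted-truth contract", {
  cfg <- small_cfg()
  m <- generate_manifest(cfg)
  expect_equal(nrow(m$truth), 6L)
  expect_equal(sum(m$truth$direction == "hypo"), 4L)
  expect_equal(sum(m$truth$direction == "hyper"), 2L)
  # probes sorted within each chromosome block
  for (ch in unique(m$probes$chrom))
    expect_false(is.unsorted(m$probes$pos[m$probes$chrom == ch]))
  # every truth region contains at least 3 (here exactly 5) manifest probes
  for (i in seq_len(nrow(m$truth))) {
    inside <- m$probes$chrom == m$truth$chrom[i] &
      m$probes$pos > m$truth$start[i] & m$probes$pos <= m$truth$end[i]
    expect_gte(sum(inside), 3L)
  }
  # truth regions pairwise disjoint
  tg <- GenomicRanges::GRanges(m$truth$chrom,
                               IRanges::IRanges(m$truth$start + 1, m$truth$end))
  expect_equal(sum(GenomicRanges::countOverlaps(tg, tg) > 1), 0L)
  # drifts signed by direction
  expect_true(all(m$truth$drift[m$truth$direction == "hypo"] < 0))
  expect_true(all(m$truth$drift[m$truth$direction == "hyper"] > 0))
})

test_that("the full-design truth set has 147 disjoint regions", {
  cfg <- synthetic_config(seed = 3, n_candidate_windows = 200L)
  m <- generate_manifest(cfg)
  expect_equal(nrow(m$truth), 147L)
  tg <- GenomicRanges::GRanges(m$truth$chrom,
                               IRanges::IRanges(m$truth$start + 1, m$truth$end))
  expect_equal(sum(GenomicRanges::countOverlaps(tg, tg) > 1), 0L)
})

test_that("generation is deterministic under a fixed seed", {
  cfg <- small_cfg(seed = 99)
  m1 <- generate_manifest(cfg)
  m2 <- generate_manifest(cfg)
  expect_identical(m1, m2)
  b1 <- generate_paired_betas(cfg, m1)
  b2 <- generate_paired_betas(cfg, m2)
  expect_identical(b1$betas, b2$betas)
  r1 <- generate_read_table(cfg)
  r2 <- generate_read_table(cfg)
  expect_identical(r1$reads, r2$reads)
  # a different seed changes the draw
  m3 <- generate_manifest(small_cfg(seed = 100))
  expect_false(identical(m1$probes$pos, m3$probes$pos))
})

test_that("noise-free paired differences equal drift times interval", {
  cfg <- small_cfg(seed = 5, interval_range = c(10, 10),
                   drift_per_year = c(0.005, 0.005),
                   planted_log2_min = NULL, noise_sd = 0,
                   probe_jitter_sd = 0, donor_sd = 0)
  m <- generate_manifest(cfg)
  bb <- generate_paired_betas(cfg, m)
  young <- bb$betas[, bb$samples$group == "young"]
  aged <- bb$betas[, bb$samples$group == "aged"]
  d <- aged - young
  truth_probe <- rep(FALSE, nrow(m$probes))
  for (i in seq_len(nrow(m$truth))) {
    truth_probe <- truth_probe | (m$probes$chrom == m$truth$chrom[i] &
                                    m$probes$pos > m$truth$start[i] &
                                    m$probes$pos <= m$truth$end[i])
  }
  hypo_probe <- m$probes$cluster %in%
    m$truth$cluster[m$truth$direction == "hypo"]
  hyper_probe <- m$probes$cluster %in%
    m$truth$cluster[m$truth$direction == "hyper"]
  expect_equal(max(abs(d[hypo_probe, ] + 0.05)), 0, tolerance = 1e-12)
  expect_equal(max(abs(d[hyper_probe, ] - 0.05)), 0, tolerance = 1e-12)
  expect_equal(max(abs(d[!truth_probe, ])), 0, tolerance = 1e-12)
})

test_that("betas stay in [0, 1] and planted drift is recovered on average", {
  cfg <- small_cfg(seed = 8)
  m <- generate_manifest(cfg)
  bb <- generate_paired_betas(cfg, m)
  expect_true(all(bb$betas >= 0 & bb$betas <= 1))
  # per-region mean paired difference ~ drift * mean interval
  intervals <- unlist(with(bb$samples,
                           tapply(age, donor_id, function(a) diff(sort(a)))))
  d <- bb$betas[, bb$samples$group == "aged"] -
    bb$betas[, bb$samples$group == "young"]
  for (i in seq_len(nrow(m$truth))) {
    pi <- which(m$probes$cluster == m$truth$cluster[i])
    expected <- m$truth$drift[i] * mean(intervals)
    got <- mean(d[pi, ])
    se <- cfg$noise_sd * sqrt(2) / sqrt(length(pi) * cfg$n_donors)
    expect_lt(abs(got - expected), 6 * se)
  }
})

test_that("cohort demographics follow the configured envelopes", {
  cfg <- synthetic_config(seed = 21, n_candidate_windows = 40L,
                          planted_hypo = 0L, planted_hyper = 0L)
  s <- sample_cohort(cfg)
  expect_equal(nrow(s), 34L)
  expect_equal(length(unique(s$donor_id)), 17L)
  young <- s$age[s$group == "young"]
  aged <- s$age[s$group == "aged"]
  expect_true(all(young >= 23 & young <= 56))
  expect_true(all(aged - young >= 9 & aged - young <= 19))
})

test_that("read tables exercise mixture shapes and the minority-length rule", {
  cfg <- small_cfg(seed = 13)
  rt <- generate_read_table(cfg)
  expect_true(all(c("AMP_low", "AMP_shift", "AMP_bimodal") %in%
                    rt$reads$amplicon_id))
  nc <- nchar(rt$reads$call_string)
  amp <- rt$reads$amplicon_id == "AMP_low"
  expect_setequal(unique(nc[amp]), c(5L, 6L))
  expect_lt(mean(nc[amp] == 5L), 0.10)  # minority lengths stay a minority

  # single zero-mean component yields all-unmethylated calls
  spec0 <- list(list(amplicon_id = "A0", n_cpg = 4L, concentration = 10,
                     young = list(means = 0, weights = 1),
                     aged = list(means = 0, weights = 1)))
  rt0 <- generate_read_table(cfg, amplicons = spec0, reads_per_sample = 20L,
                             minority_fraction = 0)
  expect_true(all(grepl("^U+$", rt0$reads$call_string)))

  # balanced extreme components produce a bimodal methylated-count histogram
  spec2 <- list(list(amplicon_id = "A2", n_cpg = 6L, concentration = 50,
                     young = list(means = c(0.1, 0.9), weights = c(0.5, 0.5)),
                     aged = list(means = c(0.1, 0.9), weights = c(0.5, 0.5))))
  rt2 <- generate_read_table(cfg, amplicons = spec2, reads_per_sample = 200L,
                             minority_fraction = 0)
  mcount <- vapply(strsplit(rt2$reads$call_string, ""),
                   function(s) sum(s == "M"), integer(1))
  h <- tabulate(mcount + 1L, nbins = 7L)
  expect_gt(h[1] + h[2], h[4])  # low mode outweighs the trough
  expect_gt(h[6] + h[7], h[4])  # high mode outweighs the trough
})

test_that("disease tables carry the universe and planted enrichment", {
  cfg <- small_cfg(seed = 17)
  genes <- sprintf("G%03d", 1:200)
  hits <- genes[1:40]
  tab <- generate_disease_table(cfg, genes, hit_genes = hits)
  expect_true(all(tab$associations$gene_id %in% tab$universe))
  # a universe gene without associations is still only in the universe
  lonely <- setdiff(genes, tab$associations$gene_id)
  expect_gt(length(lonely), 0L)
  expect_true(all(lonely %in% tab$universe))

  tab10 <- generate_disease_table(cfg, genes, hit_genes = hits,
                                  enrichment_factor = 10)
  en <- disease_enrichment(hits, tab10)
  expect_lt(en$p_bonferroni[en$disease == "disease_01"], 0.05)
})
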