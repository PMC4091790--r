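reg_df <- function(start, end, direction = "hypo", chrom = "chr1") {
  data.frame(chrom = chrom, start = as.integer(start), end = as.integer(end),
             direction = direction, stringsAsFactors = FALSE)
}

test_that("island-context classification partitions island/shore/other", {
  islands <- data.frame(chrom = "chr1", start = 10000L, end = 11000L)
  regions <- reg_df(start = c(10200L, 11500L, 21000L, 8200L),
                    end = c(10400L, 11700L, 21200L, 8400L))
  ctx <- classify_island_context(regions, islands)
  expect_equal(ctx, c("island", "shore", "other", "shore"))
  # every region gets exactly one label
  expect_equal(length(ctx), nrow(regions))
  # empty island track -> everything "other"
  expect_equal(classify_island_context(regions, islands[0, ]),
               rep("other", 4L))
})

test_that("gene annotation assigns promoter precedence and allows misses", {
  genes <- data.frame(gene_id = c("G1", "G2"), chrom = "chr1",
                      strand = c("+", "-"), tss = c(5000L, 40000L),
                      start = c(5000L, 30000L), end = c(15000L, 40000L),
                      stringsAsFactors = FALSE)
  regions <- reg_df(start = c(4500L, 8000L, 100000L, 39500L),
                    end = c(5200L, 9000L, 100500L, 39900L))
  ann <- annotate_genes(regions, genes)
  expect_equal(ann$feature[ann$region_idx == 1L], "promoter")  # spans TSS
  expect_equal(ann$feature[ann$region_idx == 2L], "body")
  expect_false(3L %in% ann$region_idx)  # 50 kb away from everything
  # minus-strand promoter lies downstream of the stored tss coordinate
  g2 <- ann[ann$region_idx == 4L, ]
  expect_equal(g2$gene_id, "G2")
  expect_equal(g2$feature, "body")
})

test_that("Fisher exact matches the hypergeometric enumeration oracle", {
  expect_equal(fisher_exact_2x2(rbind(c(10, 0), c(0, 10))),
               2 / choose(20, 10), tolerance = 1e-9)
  expect_equal(fisher_exact_2x2(rbind(c(1, 1), c(1, 1))), 1)
  expect_equal(fisher_exact_2x2(rbind(c(5, 5), c(5, 5))), 1)
  expect_equal(fisher_exact_2x2(rbind(c(0, 0), c(3, 4))), 1)  # degenerate
  set.seed(23)
  for (rep in 1:20) {
    tab <- matrix(stats::rpois(4, 5), 2, 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(fisher_exact_2x2(tab), fisher_enum_oracle(tab),
                 tolerance = 1e-9)
  }
})

test_that("co-localization flags use edge-to-edge distance within margin", {
  track <- data.frame(chrom = "chr1", start = 600L, end = 700L)
  regions <- reg_df(start = c(0L, 650L, 6000L),
                    end = c(100L, 680L, 6100L),
                    direction = c("hypo", "hypo", "hyper"))
  co <- colocalize(regions, track)
  expect_identical(co$flags, c(TRUE, TRUE, FALSE))  # 500 bp away; overlap; 5.3 kb
  expect_equal(unname(co$table["hypo", "colocalized"]), 2L)
  # identical proportions -> Fisher p = 1
  regions2 <- reg_df(start = c(0L, 10000L, 0L, 10000L),
                     end = c(100L, 10100L, 100L, 10100L),
                     direction = c("hypo", "hypo", "hyper", "hyper"))
  co2 <- colocalize(regions2, track)
  expect_equal(co2$fisher_p, 1)
  # empty track: all flags false, no test
  co3 <- colocalize(regions, track[0, ])
  expect_identical(co3$flags, rep(FALSE, 3L))
  expect_true(is.na(co3$fisher_p))
})

test_that("100-kb cluster calling counts midpoints and calibrates by permutation", {
  lens <- c(chr1 = 2e8)
  two <- reg_df(start = c(1000000L, 1050000L), end = c(1000200L, 1050200L))
  cl <- chromosomal_clusters(two, lens, n_permutations = 200L, seed = 5)
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$n_marks, 2L)
  expect_true(cl$perm_p >= 1 / 201 && cl$perm_p <= 1)

  one <- reg_df(start = 1000000L, end = 1000200L)
  expect_equal(nrow(chromosomal_clusters(one, lens)), 0L)

  far <- reg_df(start = c(1000000L, 2000000L), end = c(1000200L, 2000200L))
  expect_equal(nrow(chromosomal_clusters(far, lens)), 0L)

  # 147 regions scattered uniformly over a 3-Gb genome: any called pair is
  # unremarkable against the permutation background
  glens <- stats::setNames(rep(136363636, 22), paste0("chr", 1:22))
  set.seed(77)
  chrom <- sample(names(glens), 147, replace = TRUE)
  pos <- floor(stats::runif(147, 0, glens[chrom] - 300))
  scatter <- data.frame(chrom = chrom, start = as.integer(pos),
                        end = as.integer(pos + 200), stringsAsFactors = FALSE)
  cls <- chromosomal_clusters(scatter, glens, n_permutations = 300L, seed = 9)
  if (nrow(cls) > 0L) expect_gt(min(cls$perm_p), 0.05)
})
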