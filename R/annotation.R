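# Genomic annotation of called regions: CpG-island context, gene features,
# co-localization with chromatin tracks (Fisher tests), and 100-kb
# chromosomal cluster calling against a permutation background.

regions_to_granges <- function(regions) {
  GenomicRanges::GRanges(regions$chrom,
                         IRanges::IRanges(regions$start + 1L,
                                          pmax(regions$start + 1L, regions$end)))
}

#' Classify regions by CpG-island context
#'
#' A region overlapping an island is `island`; otherwise, within
#' `shore_flank` bp of an island it is `shore`; otherwise `other`. Every
#' region receives exactly one label.
#'
#' @param regions Region data frame (`chrom`, `start`, `end`, BED 0-based
#'   half-open).
#' @param island_track BED-style data frame of CpG islands.
#' @param shore_flank Shore width in bp around islands (default 2000).
#' @return Character vector of labels, one per region.
#' @export
classify_island_context <- function(regions, island_track, shore_flank = 2000) {
  n <- nrow(regions)
  if (n == 0L) return(character())
  if (is.null(island_track) || nrow(island_track) == 0L)
    return(rep("other", n))
  rg <- regions_to_granges(regions)
  ig <- bed_to_granges(island_track)
  out <- rep("other", n)
  hit <- suppressWarnings(GenomicRanges::distanceToNearest(rg, ig))
  qh <- S4Vectors::queryHits(hit)
  dd <- S4Vectors::mcols(hit)$distance
  out[qh[dd == 0]] <- "island"
  out[qh[dd > 0 & dd <= shore_flank]] <- "shore"
  out
}

#' Annotate regions with gene features
#'
#' A region within `promoter_window` bp upstream of (or overlapping) a
#' gene's TSS is a `promoter` hit; a region overlapping the gene extent is
#' otherwise a `body` hit. Promoter takes precedence per gene, and a region
#' may hit several genes.
#'
#' @param regions Region data frame (BED 0-based half-open).
#' @param gene_models Data frame with `gene_id`, `chrom`, `strand`, `tss`,
#'   `start`, `end` (0-based half-open extent, `tss` a 1-based-style
#'   coordinate treated as a point).
#' @param promoter_window Promoter span upstream of the TSS (default 1000).
#' @return Data frame with `region_idx`, `gene_id`, `feature`.
#' @export
annotate_genes <- function(regions, gene_models, promoter_window = 1000) {
  empty <- data.frame(region_idx = integer(), gene_id = character(),
                      feature = character(), stringsAsFactors = FALSE)
  if (nrow(regions) == 0L || is.null(gene_models) || nrow(gene_models) == 0L)
    return(empty)
  rg <- regions_to_granges(regions)
  minus <- gene_models$strand == "-"
  pstart <- ifelse(minus, gene_models$tss, gene_models$tss - promoter_window)
  pend <- ifelse(minus, gene_models$tss + promoter_window, gene_models$tss)
  prom <- GenomicRanges::GRanges(
    gene_models$chrom, IRanges::IRanges(pmax(1, pstart), pmax(1, pend)))
  body <- GenomicRanges::GRanges(
    gene_models$chrom,
    IRanges::IRanges(gene_models$start + 1L, pmax(gene_models$start + 1L,
                                                  gene_models$end)))
  ph <- suppressWarnings(GenomicRanges::findOverlaps(rg, prom))
  bh <- suppressWarnings(GenomicRanges::findOverlaps(rg, body))
  res <- rbind(
    data.frame(region_idx = S4Vectors::queryHits(ph),
               gene_id = gene_models$gene_id[S4Vectors::subjectHits(ph)],
               feature = "promoter", stringsAsFactors = FALSE),
    data.frame(region_idx = S4Vectors::queryHits(bh),
               gene_id = gene_models$gene_id[S4Vectors::subjectHits(bh)],
               feature = "body", stringsAsFactors = FALSE))
  if (nrow(res) == 0L) return(empty)
  # promoter precedence within (region, gene)
  res <- res[order(res$region_idx, res$gene_id,
                   match(res$feature, c("promoter", "body"))), ]
  res <- res[!duplicated(res[, c("region_idx", "gene_id")]), ]
  rownames(res) <- NULL
  res
}

#' Two-sided Fisher exact test on a 2x2 table
#'
#' Sums the hypergeometric probabilities of all tables (at fixed margins)
#' no more probable than the observed one.
#'
#' @param tab 2x2 matrix of nonnegative integer counts.
#' @return Two-sided p-value; 1 when a margin is degenerate.
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == c(2L, 2L)), all(tab >= 0), all(tab == round(tab)))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) return(1)
  stats::fisher.test(tab)$p.value
}

#' Co-localization of regions with a genomic track
#'
#' Flags each region as co-localized when the edge-to-edge distance to the
#' nearest track interval is at most `margin` bp (overlap counts as distance
#' 0), then compares hypo vs hyper co-localization rates with a two-sided
#' Fisher exact test.
#'
#' @param regions Region data frame with a `direction` column.
#' @param track BED-style data frame of intervals.
#' @param margin Maximum distance in bp (default 1000).
#' @param track_name Label for reporting.
#' @return A list with `flags` (logical per region), `table` (2x2 counts:
#'   direction x co-localized), and `fisher_p` (`NA` when the track is empty
#'   or a direction is absent).
#' @export
colocalize <- function(regions, track, margin = 1000, track_name = "track") {
  n <- nrow(regions)
  if (is.null(track) || nrow(track) == 0L) {
    return(list(track = track_name, flags = rep(FALSE, n), table = NULL,
                fisher_p = NA_real_))
  }
  rg <- regions_to_granges(regions)
  tg <- bed_to_granges(track)
  flags <- rep(FALSE, n)
  hit <- suppressWarnings(GenomicRanges::distanceToNearest(rg, tg))
  flags[S4Vectors::queryHits(hit)] <- S4Vectors::mcols(hit)$distance <= margin
  tab <- NULL; p <- NA_real_
  if (all(c("hypo", "hyper") %in% regions$direction)) {
    tab <- rbind(hypo = c(sum(flags & regions$direction == "hypo"),
                          sum(!flags & regions$direction == "hypo")),
                 hyper = c(sum(flags & regions$direction == "hyper"),
                           sum(!flags & regions$direction == "hyper")))
    colnames(tab) <- c("colocalized", "not")
    p <- fisher_exact_2x2(tab)
  }
  list(track = track_name, flags = flags, table = tab, fisher_p = p)
}

#' Call 100-kb chromosomal clusters with a permutation background
#'
#' Reports every 100-kb span (anchored at a region midpoint) containing at
#' least `min_marks` region midpoints; overlapping called spans merge into
#' one cluster. The background places the same number of midpoints per
#' chromosome uniformly at random and records the genome-wide maximum span
#' occupancy; each cluster's empirical enrichment p-value is the fraction of
#' permutations whose maximum occupancy reaches that cluster's count
#' (with the add-one correction, so p is in `[1/(n+1), 1]`).
#'
#' @param regions Region data frame (BED 0-based half-open).
#' @param chrom_lengths Named vector of chromosome lengths (bp).
#' @param window Span size in bp (default 1e5).
#' @param min_marks Minimum midpoints per called span (default 2).
#' @param n_permutations Number of permutations (default 1000).
#' @param seed RNG seed for the permutations.
#' @return Data frame of clusters: `chrom`, `start`, `end`, `n_marks`,
#'   `perm_p`; zero rows when no span reaches `min_marks`.
#' @export
chromosomal_clusters <- function(regions, chrom_lengths, window = 1e5,
                                 min_marks = 2L, n_permutations = 1000L,
                                 seed = 1L) {
  empty <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                      n_marks = integer(), perm_p = numeric(),
                      stringsAsFactors = FALSE)
  if (nrow(regions) == 0L) return(empty)
  mids <- floor((regions$start + regions$end) / 2)
  chroms <- regions$chrom

  max_occupancy <- function(m) {
    # max number of points within any half-open span of `window` starting
    # at a point (sorted single-chromosome positions)
    m <- sort(m)
    hi <- findInterval(m + window - 1, m)
    max(hi - seq_along(m) + 1L)
  }

  clusters <- list()
  for (ch in unique(chroms)) {
    m <- sort(mids[chroms == ch])
    hi <- findInterval(m + window - 1, m)
    cnt <- hi - seq_along(m) + 1L
    called <- which(cnt >= min_marks)
    if (!length(called)) next
    ir <- IRanges::reduce(IRanges::IRanges(m[called] + 1, m[called] + window))
    for (j in seq_along(ir)) {
      s <- IRanges::start(ir)[j] - 1; e <- IRanges::end(ir)[j]
      clusters[[length(clusters) + 1L]] <- data.frame(
        chrom = ch, start = s, end = e,
        n_marks = sum(m >= s & m < e), stringsAsFactors = FALSE)
    }
  }
  if (!length(clusters)) return(empty)
  clusters <- do.call(rbind, clusters)

  per_chrom_n <- table(chroms)
  perm_max <- with_seed(seed, {
    vapply(seq_len(n_permutations), function(p) {
      mx <- 0L
      for (ch in names(per_chrom_n)) {
        len <- chrom_lengths[[ch]]
        pts <- floor(stats::runif(per_chrom_n[[ch]], 0, len))
        mx <- max(mx, max_occupancy(pts))
      }
      mx
    }, integer(1))
  })
  clusters$perm_p <- vapply(clusters$n_marks, function(k)
    (sum(perm_max >= k) + 1) / (n_permutations + 1), numeric(1))
  rownames(clusters) <- NULL
  clusters
}
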