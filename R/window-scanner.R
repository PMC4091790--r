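# Sliding-window paired differential-methylation scanner: enumerate
# probe-anchored 1000-bp windows, score each with pseudo-medians, a pooled
# paired Wilcoxon signed-rank test and a log2 ratio, correct with
# Benjamini-Hochberg, apply the age-regression filter, and merge the
# surviving windows into regions.

#' Enumerate candidate windows over a probe manifest
#'
#' One candidate window is anchored at each probe and spans
#' `[pos, pos + window_size)`. Candidates covering fewer than `min_probes`
#' probes are discarded and candidates with identical probe sets are
#' collapsed to the first anchor.
#'
#' @param probes Manifest data frame (`probe_id`, `chrom`, `pos` 1-based),
#'   sorted by chromosome and position (a `synthetic_manifest` may be passed
#'   directly).
#' @param window_size Window span in bp (default 1000).
#' @param min_probes Minimum probes per emitted window (default 3).
#' @return Data frame with `window_id`, `chrom`, `start`, `end` (BED
#'   0-based half-open), `n_probes`, and a list-column `probe_idx` of row
#'   indices into `probes`.
#' @export
enumerate_windows <- function(probes, window_size = 1000L, min_probes = 3L) {
  if (inherits(probes, "synthetic_manifest")) probes <- probes$probes
  empty <- data.frame(window_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      n_probes = integer(), stringsAsFactors = FALSE)
  empty$probe_idx <- list()
  if (is.null(probes) || nrow(probes) == 0L) return(empty)

  # each chromosome must form one contiguous block with nondecreasing pos
  runs <- rle(probes$chrom)$values
  if (anyDuplicated(runs) ||
      any(vapply(unique(probes$chrom), function(ch)
        is.unsorted(probes$pos[probes$chrom == ch]), TRUE)))
    stop("manifest must be sorted by (chrom, pos)")

  out <- vector("list", length(unique(probes$chrom)))
  oi <- 0L
  for (ch in unique(probes$chrom)) {
    idx <- which(probes$chrom == ch)
    pos <- probes$pos[idx]
    # rightmost probe inside [pos_i, pos_i + window_size)
    last <- findInterval(pos + window_size - 1L, pos)
    n_in <- last - seq_along(pos) + 1L
    # a candidate whose probe set repeats or nests inside an earlier
    # candidate's set collapses onto it; with sorted anchors that leaves
    # exactly the candidates contributing a new rightmost probe
    maximal <- c(TRUE, diff(last) > 0L)
    keep <- which(n_in >= min_probes & maximal)
    if (!length(keep)) next
    sets <- lapply(keep, function(i) idx[seq.int(i, last[i])])
    df <- data.frame(chrom = ch, start = pos[keep] - 1L,
                     end = pos[keep] - 1L + as.integer(window_size),
                     n_probes = n_in[keep], stringsAsFactors = FALSE)
    df$probe_idx <- sets
    oi <- oi + 1L
    out[[oi]] <- df
  }
  if (oi == 0L) return(empty)
  res <- do.call(rbind, out[seq_len(oi)])
  res <- cbind(window_id = sprintf("win%06d", seq_len(nrow(res))), res,
               stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

# Closed-form simple OLS of y on x; returns slope, intercept and the
# two-sided t-test p-value for the slope.
ols_slope_p <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L || stats::var(x) == 0)
    return(list(slope = NA_real_, intercept = NA_real_, p = NA_real_, n = n))
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(x)
  res <- y - intercept - slope * x
  s2 <- sum(res^2) / (n - 2L)
  if (s2 == 0) {
    p <- if (slope == 0) 1 else 0
  } else {
    tstat <- slope / sqrt(s2 / sxx)
    p <- 2 * stats::pt(abs(tstat), df = n - 2L, lower.tail = FALSE)
  }
  list(slope = slope, intercept = intercept, p = p, n = n)
}

#' Age-regression filter for a window
#'
#' Ordinary least-squares regression of the per-sample window mean beta on
#' age at collection across all samples. A window is kept only when the
#' regression p-value is at most `alpha`; windows with zero age variance are
#' inapplicable and dropped with a warning.
#'
#' @param window_means Numeric vector of per-sample window mean betas.
#' @param ages Ages at collection, aligned with `window_means`.
#' @param alpha Significance level for retention (default 0.05).
#' @return A list with `slope` (fraction/year), `slope_pct_per_year`
#'   (`100 * slope`), `p`, and `keep`.
#' @export
regression_filter <- function(window_means, ages, alpha = 0.05) {
  if (length(unique(ages[!is.na(ages)])) < 2L) {
    warning("zero age variance: regression filter inapplicable, window dropped")
    return(list(slope = NA_real_, slope_pct_per_year = NA_real_,
                p = NA_real_, keep = FALSE))
  }
  fit <- ols_slope_p(ages, window_means)
  keep <- !is.na(fit$p) && fit$p <= alpha
  list(slope = fit$slope, slope_pct_per_year = 100 * fit$slope,
       p = fit$p, keep = keep)
}

#' Confirmatory paired t-test on per-donor window means
#'
#' Two-sided paired t-test of each donor's aged vs young window mean;
#' reported alongside the Wilcoxon result, not used as a filter.
#'
#' @param young_means,aged_means Per-donor window means, aligned by donor.
#' @return A list with `p`, `mean_difference`, and `defined` (`FALSE` with
#'   `p = NA` when the differences have zero variance).
#' @export
confirm_ttest <- function(young_means, aged_means) {
  stopifnot(length(young_means) == length(aged_means))
  d <- aged_means - young_means
  d <- d[!is.na(d)]
  if (length(d) < 2L)
    return(list(p = NA_real_, mean_difference = mean(d), defined = FALSE))
  # zero (or numerically zero) variance of the differences
  if (stats::sd(d) / sqrt(length(d)) <=
      10 * .Machine$double.eps * max(abs(mean(d)), 1e-12))
    return(list(p = NA_real_, mean_difference = mean(d), defined = FALSE))
  list(p = stats::t.test(d)$p.value, mean_difference = mean(d), defined = TRUE)
}

#' Score candidate windows on a paired beta matrix
#'
#' For each candidate window computes group pseudo-medians of per-sample
#' window means, the pseudo-median of pooled probe-level paired differences,
#' the log2 ratio of group pseudo-medians, the pooled paired Wilcoxon
#' signed-rank p-value, BH q-values across all candidates, the transformed
#' FDR, the confirmatory paired t-test, and the age-regression filter.
#'
#' @param windows Candidate windows from [enumerate_windows()].
#' @param betas Probes x samples beta matrix (rownames = probe ids matching
#'   the manifest used for enumeration, in the same row order).
#' @param samples Sample table with `sample_id`, `donor_id`, `age`, `group`
#'   (`young`/`aged`); column order of `betas` must match `sample_id`.
#' @param q_max,min_abs_log2,regression_alpha Significance thresholds
#'   (defaults 1e-4, 0.2, 0.05).
#' @param eps Epsilon guard for the log2 ratio.
#' @return The `windows` data frame augmented with `pm_young`, `pm_aged`,
#'   `pm_diff`, `log2_ratio`, `p_raw`, `q_bh`, `fdr_transformed`,
#'   `t_paired_p`, `slope`, `slope_pct_per_year`, `regression_p`,
#'   `regression_keep`, `direction` and `baseline_class`.
#' @export
score_windows <- function(windows, betas, samples, q_max = 1e-4,
                          min_abs_log2 = 0.2, regression_alpha = 0.05,
                          eps = 1e-6) {
  stopifnot(identical(colnames(betas), samples$sample_id))
  nw <- nrow(windows)
  if (nw == 0L) return(windows)

  donors <- unique(samples$donor_id)
  young_col <- vapply(donors, function(d)
    which(samples$donor_id == d & samples$group == "young")[1L], 1L)
  aged_col <- vapply(donors, function(d)
    which(samples$donor_id == d & samples$group == "aged")[1L], 1L)
  if (anyNA(young_col) || anyNA(aged_col))
    stop("every donor needs one young and one aged sample")

  # probe-level paired differences, computed once
  diff_mat <- betas[, aged_col, drop = FALSE] - betas[, young_col, drop = FALSE]
  ages <- samples$age
  is_young <- samples$group == "young"

  pm_young <- pm_aged <- pm_diff <- p_raw <- t_p <- slope <- reg_p <-
    numeric(nw)
  keep <- logical(nw)
  for (i in seq_len(nw)) {
    pi <- windows$probe_idx[[i]]
    wm <- colMeans(betas[pi, , drop = FALSE], na.rm = TRUE)
    pm_young[i] <- pseudo_median(wm[is_young])
    pm_aged[i] <- pseudo_median(wm[!is_young])
    d <- as.vector(diff_mat[pi, , drop = FALSE])
    pm_diff[i] <- pseudo_median(d)
    p_raw[i] <- paired_wilcoxon(d)$p
    t_p[i] <- confirm_ttest(wm[young_col], wm[aged_col])$p
    rf <- regression_filter(wm, ages, alpha = regression_alpha)
    slope[i] <- rf$slope; reg_p[i] <- rf$p; keep[i] <- rf$keep
  }

  q <- bh_fdr(p_raw)
  l2 <- window_log2_ratio(pm_aged, pm_young, eps = eps)
  direction <- rep("none", nw)
  sig <- !is.na(q) & q <= q_max & keep
  direction[sig & l2 <= -min_abs_log2] <- "hypo"
  direction[sig & l2 >= min_abs_log2] <- "hyper"
  baseline_class <- cut(pm_young, c(-Inf, 0.2, 0.8, Inf),
                        labels = c("low", "intermediate", "high"),
                        right = FALSE)
  baseline_class[pm_young == 0.8] <- "intermediate"

  windows$pm_young <- pm_young
  windows$pm_aged <- pm_aged
  windows$pm_diff <- pm_diff
  windows$log2_ratio <- l2
  windows$p_raw <- p_raw
  windows$q_bh <- q
  windows$fdr_transformed <- as.numeric(transform_fdr(q))
  windows$t_paired_p <- t_p
  windows$slope <- slope
  windows$slope_pct_per_year <- 100 * slope
  windows$regression_p <- reg_p
  windows$regression_keep <- keep
  windows$direction <- direction
  windows$baseline_class <- as.character(baseline_class)
  windows
}

#' Call significant windows and merge them into regions
#'
#' A window is significant when its BH q-value is at most `q_max`, its
#' |log2 ratio| at least `min_abs_log2` and it passed the regression filter
#' (i.e. `direction != "none"` after [score_windows()]). Overlapping or
#' book-ended significant windows of the same direction merge into one
#' region.
#'
#' @param scored Scored windows from [score_windows()].
#' @param q_max,min_abs_log2 Thresholds re-applied defensively (defaults
#'   1e-4, 0.2).
#' @return Data frame of regions: `chrom`, `start`, `end` (BED 0-based
#'   half-open), `direction`, `n_windows`, `window_ids`, `best_q`,
#'   `mean_log2_ratio`, `mean_slope_pct_per_year`.
#' @export
call_and_merge <- function(scored, q_max = 1e-4, min_abs_log2 = 0.2) {
  sig <- scored[scored$direction %in% c("hypo", "hyper") &
                  scored$q_bh <= q_max &
                  abs(scored$log2_ratio) >= min_abs_log2, , drop = FALSE]
  empty <- data.frame(chrom = character(), start = integer(), end = integer(),
                      direction = character(), n_windows = integer(),
                      window_ids = character(), best_q = numeric(),
                      mean_log2_ratio = numeric(),
                      mean_slope_pct_per_year = numeric(),
                      stringsAsFactors = FALSE)
  if (nrow(sig) == 0L) return(empty)
  out <- list()
  for (dir in c("hypo", "hyper")) {
    ss <- sig[sig$direction == dir, , drop = FALSE]
    if (nrow(ss) == 0L) next
    gr <- GenomicRanges::GRanges(ss$chrom,
                                 IRanges::IRanges(ss$start + 1L, ss$end))
    red <- GenomicRanges::reduce(gr)  # merges overlapping and book-ended
    ov <- GenomicRanges::findOverlaps(gr, red)
    grp <- S4Vectors::subjectHits(ov)[order(S4Vectors::queryHits(ov))]
    agg <- lapply(seq_along(red), function(j) {
      wi <- which(grp == j)
      data.frame(
        chrom = as.character(GenomicRanges::seqnames(red))[j],
        start = GenomicRanges::start(red)[j] - 1L,
        end = GenomicRanges::end(red)[j],
        direction = dir, n_windows = length(wi),
        window_ids = paste(ss$window_id[wi], collapse = ","),
        best_q = min(ss$q_bh[wi]),
        mean_log2_ratio = mean(ss$log2_ratio[wi]),
        mean_slope_pct_per_year = mean(ss$slope_pct_per_year[wi]),
        stringsAsFactors = FALSE)
    })
    out[[dir]] <- do.call(rbind, agg)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(match(res$chrom, unique(scored$chrom)), res$start), , drop = FALSE]
}

#' Run the full sliding-window scan
#'
#' Convenience wrapper: [enumerate_windows()] over the manifest,
#' [score_windows()] against the paired beta matrix, then [call_and_merge()].
#'
#' @param manifest Probe manifest data frame or `synthetic_manifest`.
#' @param betas Probes x samples beta matrix (row order matching the
#'   manifest).
#' @param samples Sample table (`sample_id`, `donor_id`, `age`, `group`).
#' @param window_size,min_probes,q_max,min_abs_log2,regression_alpha
#'   Scanner settings (defaults 1000, 3, 1e-4, 0.2, 0.05).
#' @return A list with `windows` (scored candidates), `regions` (merged
#'   calls) and `log` (named counts at each filter stage).
#' @export
scan_methylome <- function(manifest, betas, samples, window_size = 1000L,
                           min_probes = 3L, q_max = 1e-4,
                           min_abs_log2 = 0.2, regression_alpha = 0.05) {
  probes <- if (inherits(manifest, "synthetic_manifest")) manifest$probes
            else manifest
  stopifnot(identical(rownames(betas), probes$probe_id))
  windows <- enumerate_windows(probes, window_size = window_size,
                               min_probes = min_probes)
  scored <- score_windows(windows, betas, samples, q_max = q_max,
                          min_abs_log2 = min_abs_log2,
                          regression_alpha = regression_alpha)
  regions <- call_and_merge(scored, q_max = q_max,
                            min_abs_log2 = min_abs_log2)
  log <- c(n_probes = nrow(probes),
           n_candidate_windows = nrow(windows),
           n_q_pass = if (nrow(windows)) sum(scored$q_bh <= q_max) else 0L,
           n_q_log2_pass = if (nrow(windows))
             sum(scored$q_bh <= q_max &
                   abs(scored$log2_ratio) >= min_abs_log2) else 0L,
           n_significant = if (nrow(windows))
             sum(scored$direction != "none") else 0L,
           n_regions = nrow(regions),
           n_regions_hypo = sum(regions$direction == "hypo"),
           n_regions_hyper = sum(regions$direction == "hyper"))
  list(windows = scored, regions = regions, log = log)
}
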