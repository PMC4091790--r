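# Single-molecule (epiallele) analysis of targeted bisulfite reads:
# consensus CpG count with the 10% rule, per-read binning by methylated-CpG
# count, age-group pooling, and normalization to 100 reads.

read_cpg_counts <- function(call_strings) nchar(call_strings)
read_meth_counts <- function(call_strings) {
  vapply(strsplit(call_strings, ""), function(s) sum(s == "M"), integer(1))
}

#' Consensus CpG count for an amplicon
#'
#' The largest CpG count carried by at least `min_fraction` of all aligned
#' reads of the amplicon. With `rule = "at_least"` the fraction is instead
#' computed over reads carrying at least that many CpGs. If no count reaches
#' the threshold the modal count is returned and flagged.
#'
#' @param call_strings Character vector of per-read call strings (`M`/`U`),
#'   one CpG per character.
#' @param min_fraction Minimum fraction of reads supporting the count
#'   (default 0.10).
#' @param rule `"exact"` (default; reads with exactly that CpG count) or
#'   `"at_least"`.
#' @return Integer consensus count with a logical `"fallback"` attribute.
#' @examples
#' # 80 reads of 5 CpGs, 15 of 6, 5 of 7: 6 is the largest count with >= 10%
#' consensus_cpg_count(c(rep("UUUUU", 80), rep("UUUUUU", 15), rep("UUUUUUU", 5)))
#' @export
consensus_cpg_count <- function(call_strings, min_fraction = 0.10,
                                rule = c("exact", "at_least")) {
  rule <- match.arg(rule)
  stopifnot(length(call_strings) >= 1L)
  nc <- read_cpg_counts(call_strings)
  n <- length(nc)
  counts <- sort(unique(nc))
  frac <- if (rule == "exact") {
    vapply(counts, function(c) sum(nc == c) / n, numeric(1))
  } else {
    vapply(counts, function(c) sum(nc >= c) / n, numeric(1))
  }
  ok <- counts[frac >= min_fraction]
  if (length(ok)) {
    out <- max(ok)
    attr(out, "fallback") <- FALSE
  } else {
    tab <- table(nc)
    out <- as.integer(names(tab)[which.max(tab)])
    attr(out, "fallback") <- TRUE
  }
  out
}

#' Bin reads by methylated-CpG count
#'
#' Retains only reads carrying exactly `consensus_c` CpGs and counts them
#' into bins `0..consensus_c` by their number of methylated calls.
#'
#' @param call_strings Character vector of per-read call strings.
#' @param consensus_c Consensus CpG count (>= 1).
#' @return Integer vector of length `consensus_c + 1` (names are methylated
#'   counts); a `"n_retained"` attribute gives the retained read count, and
#'   an `"empty"` flag is set when no read matches.
#' @export
bin_reads <- function(call_strings, consensus_c) {
  stopifnot(consensus_c >= 1L)
  keep <- read_cpg_counts(call_strings) == consensus_c
  bins <- integer(consensus_c + 1L)
  names(bins) <- 0:consensus_c
  if (any(keep)) {
    m <- read_meth_counts(call_strings[keep])
    tb <- table(factor(m, levels = 0:consensus_c))
    bins[] <- as.integer(tb)
  } else {
    warning("no reads match the consensus CpG count; empty profile")
  }
  attr(bins, "n_retained") <- sum(keep)
  attr(bins, "empty") <- !any(keep)
  bins
}

#' Pool binned reads by age group and normalize to 100 reads
#'
#' Samples donated at `age_cutoff` years or older form the aged group,
#' younger samples the young group. Bin counts are summed within each group
#' and scaled so each group's profile totals exactly 100 reads.
#'
#' @param reads Read table (`amplicon_id`, `sample_id`, `call_string`).
#' @param samples Sample table (`sample_id`, `age`).
#' @param age_cutoff Age boundary in years; the boundary itself is aged
#'   (default 45).
#' @param min_fraction Consensus-rule fraction passed to
#'   [consensus_cpg_count()].
#' @param rule Consensus rule variant.
#' @return Data frame with one row per (amplicon, age group, bin):
#'   `amplicon_id`, `age_group`, `consensus_c`, `bin` (methylated count),
#'   `count` (raw pooled reads), `normalized` (sums to 100 within each
#'   profile). Empty groups are omitted with a warning.
#' @export
pool_and_normalize <- function(reads, samples, age_cutoff = 45,
                               min_fraction = 0.10,
                               rule = c("exact", "at_least")) {
  rule <- match.arg(rule)
  age <- samples$age[match(reads$sample_id, samples$sample_id)]
  if (anyNA(age)) stop("every read's sample needs an age")
  group <- ifelse(age >= age_cutoff, "aged", "young")
  out <- list()
  for (amp in unique(reads$amplicon_id)) {
    ai <- reads$amplicon_id == amp
    cc <- consensus_cpg_count(reads$call_string[ai],
                              min_fraction = min_fraction, rule = rule)
    for (grp in c("young", "aged")) {
      gi <- ai & group == grp
      if (!any(gi)) {
        warning(sprintf("amplicon %s: no reads in %s group; profile omitted",
                        amp, grp))
        next
      }
      bins <- suppressWarnings(bin_reads(reads$call_string[gi], cc))
      tot <- sum(bins)
      if (tot == 0L) {
        warning(sprintf(
          "amplicon %s, %s group: no reads at consensus CpG count; omitted",
          amp, grp))
        next
      }
      out[[length(out) + 1L]] <- data.frame(
        amplicon_id = amp, age_group = grp,
        consensus_c = as.integer(cc), bin = 0:as.integer(cc),
        count = as.integer(bins), normalized = 100 * as.numeric(bins) / tot,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(amplicon_id = character(), age_group = character(),
                      consensus_c = integer(), bin = integer(),
                      count = integer(), normalized = numeric(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Fractional difference between aged and young values
#'
#' `(aged / young) - 1`; the cross-platform comparison statistic for paired
#' methylation summaries.
#'
#' @param aged_value,young_value Fractions; `young_value` must be positive.
#' @return Numeric fractional difference.
#' @export
fractional_difference <- function(aged_value, young_value) {
  if (any(young_value <= 0))
    stop("fractional difference undefined: young value must be > 0")
  aged_value / young_value - 1
}

#' Plot normalized read-population profiles
#'
#' Spline-smoothed display of the young vs aged normalized bin profiles of
#' one amplicon. Smoothing is cosmetic; all statistics operate on the raw
#' bins.
#'
#' @param profile Output of [pool_and_normalize()] restricted to one
#'   amplicon (or containing an `amplicon_id` to select via `amplicon`).
#' @param amplicon Optional amplicon id to select.
#' @return Invisibly, the profile used.
#' @export
plot_population_profile <- function(profile, amplicon = NULL) {
  if (!is.null(amplicon))
    profile <- profile[profile$amplicon_id == amplicon, , drop = FALSE]
  stopifnot(length(unique(profile$amplicon_id)) == 1L)
  cols <- c(young = "#2166ac", aged = "#b2182b")
  graphics::plot(NULL, xlim = range(profile$bin),
                 ylim = c(0, max(profile$normalized) * 1.1),
                 xlab = "methylated CpGs per read",
                 ylab = "reads (normalized to 100)",
                 main = profile$amplicon_id[1L])
  for (grp in unique(profile$age_group)) {
    pp <- profile[profile$age_group == grp, ]
    sp <- stats::spline(pp$bin, pp$normalized, n = 10 * nrow(pp))
    graphics::lines(sp, col = cols[[grp]], lwd = 2)
    graphics::points(pp$bin, pp$normalized, col = cols[[grp]], pch = 19)
  }
  graphics::legend("topright", legend = unique(profile$age_group),
                   col = cols[unique(profile$age_group)], lwd = 2, bty = "n")
  invisible(profile)
}
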