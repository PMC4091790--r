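# Beta-value computation, probe QC filtering, and the global
# (LINE-1-style) methylation trend analysis.

#' Compute a beta value from channel intensities
#'
#' `beta = M / (M + U)`, the fraction-methylation summary of an array probe.
#' When both intensities are zero the value is missing and flagged.
#'
#' @param methylated,unmethylated Nonnegative intensity vectors.
#' @return Numeric vector in `[0, 1]`, `NA` where both intensities are zero;
#'   carries a logical `"missing"` attribute marking those entries.
#' @examples
#' compute_beta(800, 200)  # 0.8
#' @export
compute_beta <- function(methylated, unmethylated) {
  stopifnot(all(methylated >= 0, na.rm = TRUE),
            all(unmethylated >= 0, na.rm = TRUE))
  tot <- methylated + unmethylated
  missing <- !is.na(tot) & tot == 0
  out <- ifelse(missing, NA_real_, methylated / tot)
  attr(out, "missing") <- missing
  out
}

#' Filter poorly performing probes on their QC p-value
#'
#' Removes probes whose QC p-value falls on the failing side of `threshold`.
#' The rule as printed for this analysis removes probes with `qc_p <
#' threshold`; because detection-p conventions in array processing usually
#' flag the opposite tail, the polarity is exposed as a flag.
#'
#' @param records Data frame with columns `probe_id` and `qc_p`.
#' @param threshold QC p-value threshold (default 0.05).
#' @param polarity `"below"` (as printed: remove `qc_p < threshold`) or
#'   `"above"` (detection-p convention: remove `qc_p > threshold`).
#' @return Character vector of kept probe ids, with attributes `n_removed`
#'   and `removed` (the dropped ids).
#' @export
qc_filter <- function(records, threshold = 0.05,
                      polarity = c("below", "above")) {
  polarity <- match.arg(polarity)
  stopifnot(nrow(records) > 0L, all(records$qc_p >= 0 & records$qc_p <= 1))
  fail <- if (polarity == "below") records$qc_p < threshold
          else records$qc_p > threshold
  kept <- unique(records$probe_id[!fail])
  kept <- setdiff(kept, unique(records$probe_id[fail]))
  out <- kept
  attr(out, "removed") <- setdiff(unique(records$probe_id), kept)
  attr(out, "n_removed") <- length(attr(out, "removed"))
  out
}

#' Global methylation trend with age
#'
#' Tests per-sample mean global methylation (e.g. a LINE-1 repetitive-element
#' assay averaged over its CpGs) for an age trend two ways: a paired t-test
#' of per-donor (aged - young) means, and ordinary least-squares regression
#' of mean methylation on age at collection across all samples.
#'
#' @param records Data frame with columns `sample_id`, `donor_id`, `age`,
#'   `mean_fraction_methylation`, two rows (young and aged) per donor for
#'   the paired test.
#' @return A list with `paired_p`, `mean_difference` (aged - young),
#'   `slope` (fraction/year), `intercept`, `regression_p`, `n_pairs`,
#'   `n_samples`, and `paired_defined` (`FALSE` when the paired differences
#'   have zero variance, in which case `paired_p` is `NA`).
#' @export
global_trend <- function(records) {
  stopifnot(all(c("sample_id", "donor_id", "age",
                  "mean_fraction_methylation") %in% names(records)))
  sp <- split(records, records$donor_id)
  diffs <- vapply(sp, function(d) {
    if (nrow(d) != 2L) return(NA_real_)
    d <- d[order(d$age), ]
    d$mean_fraction_methylation[2L] - d$mean_fraction_methylation[1L]
  }, numeric(1))
  diffs <- diffs[!is.na(diffs)]
  if (length(diffs) < 2L)
    stop("need >= 2 donors with both young and aged values for the paired test")
  paired_defined <- stats::sd(diffs) / sqrt(length(diffs)) >
    10 * .Machine$double.eps * max(abs(mean(diffs)), 1e-12)
  paired_p <- if (paired_defined)
    stats::t.test(diffs)$p.value else NA_real_

  if (nrow(records) < 3L) stop("need >= 3 samples for regression")
  fit <- stats::lm(mean_fraction_methylation ~ age, data = records)
  sm <- summary(fit)
  list(paired_p = paired_p,
       mean_difference = mean(diffs),
       slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       regression_p = unname(sm$coefficients["age", "Pr(>|t|)"]),
       n_pairs = length(diffs), n_samples = nrow(records),
       paired_defined = paired_defined)
}
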