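#' Hodges-Lehmann pseudo-median
#'
#' Robust one-sample location estimate used to summarise methylation within a
#' window: the median of all Walsh averages \eqn{(x_i + x_j)/2} over pairs
#' \eqn{i \le j} (pairs include each value with itself).
#'
#' @param x Numeric vector; `NA`s are dropped.
#' @return The pseudo-median as a single numeric value; `NA` if no finite
#'   values remain.
#' @examples
#' pseudo_median(c(1, 2, 6))  # median of 1, 1.5, 2, 3.5, 4, 6 -> 2.75
#' @export
pseudo_median <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n == 0L) return(NA_real_)
  if (n == 1L) return(x)
  w <- outer(x, x, "+") / 2
  stats::median(w[upper.tri(w, diag = TRUE)])
}

#' Paired Wilcoxon signed-rank test on pooled differences
#'
#' Two-sided signed-rank test of the paired differences pooled over all
#' (probe, donor) pairs of a window. Zero differences are dropped before
#' ranking; ties receive average ranks. The null distribution is exact
#' (computed by convolution over the rank weights, valid with ties) when the
#' number of nonzero differences is at most `exact_max`, and a normal
#' approximation with tie correction and continuity correction otherwise.
#'
#' @param d Numeric vector of paired differences (aged - young).
#' @param exact_max Largest nonzero-difference count for which the exact null
#'   distribution is used (default 25).
#' @return A list with `p` (two-sided p-value), `n_nonzero`, `statistic`
#'   (the positive-rank sum V), `method` ("exact", "normal", or
#'   "degenerate"), and `all_zero` (logical flag; when `TRUE` the p-value is
#'   1 by convention).
#' @export
paired_wilcoxon <- function(d, exact_max = 25L) {
  d <- d[!is.na(d)]
  nz <- d[d != 0]
  n <- length(nz)
  if (n == 0L) {
    return(list(p = 1, n_nonzero = 0L, statistic = NA_real_,
                method = "degenerate", all_zero = TRUE))
  }
  r <- rank(abs(nz))
  v <- sum(r[nz > 0])
  if (n <= exact_max) {
    p <- signed_rank_exact_p(r, v)
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- v - mu
    z <- (z - sign(z) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * min(stats::pnorm(z), stats::pnorm(z, lower.tail = FALSE)))
    method <- "normal"
  }
  list(p = p, n_nonzero = n, statistic = v, method = method, all_zero = FALSE)
}

# Exact two-sided p for the signed-rank statistic given the rank vector.
# Doubling the (possibly half-integer, tie-averaged) ranks gives integer
# weights; the null distribution of the doubled statistic is then built by
# dynamic-programming convolution over the 2^n equiprobable sign assignments.
signed_rank_exact_p <- function(r, v) {
  w <- as.integer(round(2 * r))
  total <- sum(w)
  f <- numeric(total + 1L)
  f[1L] <- 1
  for (wi in w) {
    shifted <- c(numeric(wi), f[seq_len(total + 1L - wi)])
    f <- f + shifted
  }
  f <- f / 2^length(w)
  v2 <- as.integer(round(2 * v))
  p_le <- sum(f[seq_len(v2 + 1L)])
  p_ge <- sum(f[seq.int(v2 + 1L, total + 1L)])
  min(1, 2 * min(p_le, p_ge))
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false discovery rate adjustment,
#' \eqn{q_{(i)} = \min_{j \ge i} p_{(j)} m / j}, capped at 1.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Vector of q-values, same order as `p`.
#' @export
bh_fdr <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  stats::p.adjust(p, method = "BH")
}

#' Transformed FDR
#'
#' Maps a BH q-value onto the display scale `-10 * log10(q)` used to report
#' window significance (40 corresponds to q = 0.0001, 20 to q = 0.01, 13 to
#' q = 0.05). q-values below `floor` (or exactly zero) are reported at the
#' floor and flagged via the `"floored"` attribute.
#'
#' @param q Numeric vector of q-values in `[0, 1]`.
#' @param floor Smallest q-value honoured before flooring (default 1e-30).
#' @return Numeric vector of transformed values (>= 0 for q <= 1), with a
#'   logical `"floored"` attribute marking entries at or below the floor.
#' @export
transform_fdr <- function(q, floor = 1e-30) {
  stopifnot(all(q >= 0 & q <= 1, na.rm = TRUE), floor > 0)
  floored <- !is.na(q) & q < floor
  qf <- pmax(q, floor)
  out <- -10 * log10(qf)
  attr(out, "floored") <- floored
  out
}

#' Window log2 ratio of group pseudo-medians
#'
#' `log2((pm_aged + eps) / (pm_young + eps))`; negative values indicate
#' hypomethylation with age. The epsilon guard keeps the ratio finite when a
#' pseudo-median is zero.
#'
#' @param pm_aged,pm_young Group pseudo-medians in `[0, 1]`.
#' @param eps Additive guard (default 1e-6).
#' @return Numeric log2 ratio.
#' @export
window_log2_ratio <- function(pm_aged, pm_young, eps = 1e-6) {
  log2((pm_aged + eps) / (pm_young + eps))
}
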