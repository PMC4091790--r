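# Independent brute-force oracles used to check the analytic code paths.

# Exact two-sided signed-rank p by enumerating all 2^n sign assignments.
wilcoxon_enum_oracle <- function(d) {
  nz <- d[d != 0]
  n <- length(nz)
  if (n == 0L) return(1)
  r <- rank(abs(nz))
  signs <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
  w_all <- apply(signs, 1L, function(s) sum(r[s]))
  w_obs <- sum(r[nz > 0])
  p_le <- mean(w_all <= w_obs + 1e-9)
  p_ge <- mean(w_all >= w_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# Pseudo-median by explicit pairwise enumeration (combn), including i == j.
walsh_enum_oracle <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 1L) return(x)
  pairs <- utils::combn(length(x), 2L)
  walsh <- c((x[pairs[1L, ]] + x[pairs[2L, ]]) / 2, x)
  stats::median(walsh)
}

# Two-sided Fisher p by full enumeration of tables at fixed margins.
fisher_enum_oracle <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  r1 <- a + b; c1 <- a + c_; n <- a + b + c_ + d
  lo <- max(0L, c1 - (n - r1)); hi <- min(r1, c1)
  xs <- lo:hi
  pr <- choose(r1, xs) * choose(n - r1, c1 - xs) / choose(n, c1)
  p_obs <- choose(r1, a) * choose(n - r1, c1 - a) / choose(n, c1)
  sum(pr[pr <= p_obs * (1 + 1e-7)])
}

# BH step-up by the hand rule for a length-3 input.
bh_oracle3 <- function(p) {
  stopifnot(length(p) == 3L)
  o <- order(p)
  ps <- p[o]
  q <- numeric(3L)
  for (i in 3:1) {
    q[i] <- min(1, ps[i] * 3 / i, if (i < 3L) q[i + 1L] else Inf)
  }
  out <- numeric(3L)
  out[o] <- q
  out
}

# Count substantial local maxima of a spline-smoothed bin profile
# (modality check); peaks below 10% of the tallest are spline wiggle.
count_modes <- function(bins, values) {
  sp <- stats::spline(bins, values, n = 200)$y
  peaks <- which(diff(sign(diff(sp))) < 0) + 1L
  if (sp[1] > sp[2]) peaks <- c(1L, peaks)
  n <- length(sp)
  if (sp[n] > sp[n - 1L]) peaks <- c(peaks, n)
  sum(sp[peaks] >= 0.1 * max(sp))
}
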