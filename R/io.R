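# Tab-delimited readers and writers for the pipeline's interchange formats:
# probe manifest, beta matrix, sample table, BED-style tracks, gene models,
# per-read call tables and gene-disease association tables.

#' @name pipeline-io
#' @title Read and write pipeline interchange files
#' @description All files are plain tab-delimited text with a header row
#'   (except BED tracks, which are headerless `chrom`, `start`, `end`
#'   0-based half-open, plus optional extra columns such as the truth file's
#'   `direction`). The beta matrix is probes x samples with probe ids in the
#'   first column.
#' @param path File path.
#' @param x Object to write (data frame, or matrix for the beta matrix).
#' @return Readers return data frames (the beta-matrix reader a numeric
#'   matrix with probe-id rownames); writers return `path` invisibly.
NULL

#' @rdname pipeline-io
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname pipeline-io
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname pipeline-io
#' @export
write_beta_matrix <- function(x, path) {
  df <- data.frame(probe_id = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname pipeline-io
#' @export
read_beta_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- df[[1L]]
  m
}

#' @rdname pipeline-io
#' @export
write_bed <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname pipeline-io
#' @param extra_cols Names for columns beyond `chrom`, `start`, `end`.
#' @export
read_bed <- function(path, extra_cols = character()) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  names(df) <- c("chrom", "start", "end", extra_cols)[seq_len(ncol(df))]
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  df
}

#' Write scored windows and merged regions as BED6+
#'
#' Emits the scanner's outputs in BED-style tab-delimited form: name and
#' score columns followed by the window statistics (`pm_young`, `pm_aged`,
#' `log2_ratio`, `q_bh`, `fdr_transformed`, `slope_pct_per_year`,
#' `t_paired_p`, `direction`).
#'
#' @param scored Scored windows from [score_windows()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_windows_bed <- function(scored, path) {
  strand_of <- function(dir) ifelse(dir == "hypo", "-",
                                    ifelse(dir == "hyper", "+", "."))
  bed <- data.frame(
    chrom = scored$chrom, start = scored$start, end = scored$end,
    name = scored$window_id,
    score = round(pmin(1000, pmax(0, scored$fdr_transformed * 10))),
    strand = strand_of(scored$direction),
    pm_young = signif(scored$pm_young, 6),
    pm_aged = signif(scored$pm_aged, 6),
    log2_ratio = signif(scored$log2_ratio, 6),
    q_bh = signif(scored$q_bh, 6),
    fdr_transformed = signif(scored$fdr_transformed, 6),
    slope_pct_per_year = signif(scored$slope_pct_per_year, 6),
    t_paired_p = signif(scored$t_paired_p, 6),
    direction = scored$direction,
    stringsAsFactors = FALSE)
  write_bed(bed, path)
}
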