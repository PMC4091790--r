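# Disease-association enrichment: compare the frequency of disease-linked
# genes in a study hit set against the background of all genes carrying at
# least one disease association, chi-squared with Bonferroni correction.

#' Select diseases to test
#'
#' Diseases associated with at least `min_genes` of the study's hit genes.
#'
#' @param hit_genes Character vector of study-hit gene ids.
#' @param table A disease-association table: list with `associations`
#'   (data frame `gene_id`, `disease`) and `universe` (character vector of
#'   background genes).
#' @param min_genes Minimum hit genes per disease (default 2).
#' @return Character vector of disease labels.
#' @export
select_diseases <- function(hit_genes, table, min_genes = 2L) {
  if (!length(hit_genes)) return(character())
  a <- table$associations
  a <- a[a$gene_id %in% hit_genes, , drop = FALSE]
  if (!nrow(a)) return(character())
  counts <- base::table(a$disease)
  sort(names(counts)[counts >= min_genes])
}

#' Test one disease for enrichment among hit genes
#'
#' 2x2 comparison (hit genes vs rest of the universe x associated with the
#' disease vs not) by Pearson chi-squared, with a Fisher exact fallback when
#' any expected cell is below 5. The Bonferroni-corrected p multiplies by
#' `n_tested`.
#'
#' @param disease Disease label.
#' @param hit_genes Character vector of hit gene ids (intersected with the
#'   universe).
#' @param table Disease-association table (see [select_diseases()]).
#' @param n_tested Number of diseases in the Bonferroni family (default 1).
#' @param correct Apply Yates continuity correction (default `FALSE`).
#' @return A list of class `enrichment_result`: `disease`, `hits_with`,
#'   `hits_total`, `background_with`, `background_total`, `chi2`, `p`,
#'   `p_bonferroni`, `method` (`"chisq"`, `"fisher"`, or `"skipped"`).
#' @export
enrichment_test <- function(disease, hit_genes, table, n_tested = 1L,
                            correct = FALSE) {
  universe <- unique(table$universe)
  hits <- intersect(unique(hit_genes), universe)
  bg <- setdiff(universe, hits)
  with_dis <- unique(table$associations$gene_id[
    table$associations$disease == disease])
  hw <- sum(hits %in% with_dis)
  bw <- sum(bg %in% with_dis)
  res <- list(disease = disease, hits_with = hw, hits_total = length(hits),
              background_with = bw, background_total = length(bg),
              chi2 = NA_real_, p = NA_real_, p_bonferroni = NA_real_,
              method = "skipped")
  class(res) <- "enrichment_result"
  tab <- rbind(hits = c(hw, length(hits) - hw),
               background = c(bw, length(bg) - bw))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    res$reason <- "degenerate margin"
    return(res)
  }
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 5)) {
    res$p <- stats::fisher.test(tab)$p.value
    res$method <- "fisher"
  } else {
    ct <- suppressWarnings(stats::chisq.test(tab, correct = correct))
    res$chi2 <- unname(ct$statistic)
    res$p <- ct$p.value
    res$method <- "chisq"
  }
  res$p_bonferroni <- min(1, res$p * n_tested)
  res
}

#' Disease-association enrichment over all eligible diseases
#'
#' Runs [select_diseases()] then [enrichment_test()] for each selected
#' disease with Bonferroni correction across the tested family.
#'
#' @inheritParams select_diseases
#' @param correct Yates continuity correction flag (default `FALSE`).
#' @return Data frame with one row per tested disease: `disease`,
#'   `hits_with`, `hits_total`, `background_with`, `background_total`,
#'   `chi2`, `p`, `p_bonferroni`, `method`.
#' @export
disease_enrichment <- function(hit_genes, table, min_genes = 2L,
                               correct = FALSE) {
  diseases <- select_diseases(hit_genes, table, min_genes = min_genes)
  empty <- data.frame(disease = character(), hits_with = integer(),
                      hits_total = integer(), background_with = integer(),
                      background_total = integer(), chi2 = numeric(),
                      p = numeric(), p_bonferroni = numeric(),
                      method = character(), stringsAsFactors = FALSE)
  if (!length(diseases)) return(empty)
  rows <- lapply(diseases, function(d) {
    r <- enrichment_test(d, hit_genes, table, n_tested = length(diseases),
                         correct = correct)
    data.frame(disease = r$disease, hits_with = r$hits_with,
               hits_total = r$hits_total, background_with = r$background_with,
               background_total = r$background_total, chi2 = r$chi2,
               p = r$p, p_bonferroni = r$p_bonferroni, method = r$method,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
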