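# End-to-end orchestration: validated configuration, staged execution
# (simulate -> preprocess -> scan -> annotate -> reads -> enrichment) with
# per-stage logging, and a one-call seeded demo on synthetic fixtures.

pipeline_defaults <- function() {
  list(seed = 1L,
       out_dir = NULL,
       window_size = 1000L, min_probes = 3L, q_max = 1e-4,
       min_abs_log2 = 0.2, regression_alpha = 0.05,
       colocalization_margin = 1000, shore_flank = 2000,
       promoter_window = 1000,
       age_cutoff = 45, min_fraction = 0.10,
       cluster_window = 1e5, cluster_min_marks = 2L,
       cluster_permutations = 1000L,
       enrichment_min_genes = 2L)
}

#' Pipeline configuration
#'
#' Validated key-value settings for [run_pipeline()]. Unknown keys are
#' rejected; all thresholds must be positive.
#'
#' @param ... Named overrides of the defaults: `seed`, `out_dir`,
#'   `window_size` (1000 bp), `min_probes` (3), `q_max` (1e-4),
#'   `min_abs_log2` (0.2), `regression_alpha` (0.05),
#'   `colocalization_margin` (1000 bp), `shore_flank` (2000 bp),
#'   `promoter_window` (1000 bp), `age_cutoff` (45 y), `min_fraction`
#'   (0.10), `cluster_window` (1e5 bp), `cluster_min_marks` (2),
#'   `cluster_permutations` (1000), `enrichment_min_genes` (2).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- pipeline_defaults()
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown pipeline config keys: ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  num <- c("window_size", "min_probes", "q_max", "min_abs_log2",
           "regression_alpha", "colocalization_margin", "shore_flank",
           "promoter_window", "age_cutoff", "min_fraction", "cluster_window",
           "cluster_min_marks", "cluster_permutations",
           "enrichment_min_genes")
  bad <- num[vapply(cfg[num], function(v)
    !is.numeric(v) || length(v) != 1L || v <= 0, TRUE)]
  if (length(bad))
    stop("pipeline config thresholds must be positive scalars: ",
         paste(bad, collapse = ", "))
  class(cfg) <- "pipeline_config"
  cfg
}

stage_msg <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order on supplied inputs (or on synthetic fixtures
#' generated from `sim_config`): window scan on the paired beta matrix,
#' region annotation (island context, gene features, track co-localization,
#' 100-kb clusters), single-molecule read profiling, disease enrichment of
#' region-associated genes, and the global methylation trend. Any stage
#' failure aborts with a stage-tagged error; results of completed stages are
#' preserved in the error's `partial` attribute. When `config$out_dir` is
#' set, windows/regions (BED and TSV), profiles, enrichment and the run
#' report are written there.
#'
#' @param config A [pipeline_config()].
#' @param sim_config A [synthetic_config()]; when supplied, all inputs are
#'   generated from it and the explicit input arguments are ignored.
#' @param manifest,betas,samples,reads,disease_table,global_table Explicit
#'   inputs (see the module functions for their shapes). `manifest` must be
#'   a `synthetic_manifest`-shaped list (probes, tracks, genes,
#'   chrom_lengths) when annotation stages are wanted.
#' @return A list of class `pipeline_result` with `scan`, `annotation`,
#'   `profiles`, `enrichment`, `global_trend`, `report` (parameters, seed,
#'   per-stage counts) and the inputs used.
#' @export
run_pipeline <- function(config = pipeline_config(), sim_config = NULL,
                         manifest = NULL, betas = NULL, samples = NULL,
                         reads = NULL, disease_table = NULL,
                         global_table = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  partial <- list()
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      err <- simpleError(sprintf("stage '%s' failed: %s", stage,
                                 conditionMessage(e)))
      attr(err, "partial") <- partial
      stop(err)
    })
  }

  if (!is.null(sim_config)) {
    run_stage("simulate", {
      manifest <- generate_manifest(sim_config)
      bb <- generate_paired_betas(sim_config, manifest)
      betas <- bb$betas; samples <- bb$samples
      rt <- generate_read_table(sim_config)
      reads <- rt$reads
      global_table <- generate_global_table(sim_config)
      stage_msg("simulate", "%d probes, %d samples, %d truth regions",
                nrow(manifest$probes), nrow(samples), nrow(manifest$truth))
    })
  }
  if (is.null(manifest) || is.null(betas) || is.null(samples))
    stop("stage 'input' failed: manifest, betas and samples are required")

  scan <- run_stage("scan", {
    s <- scan_methylome(manifest, betas, samples,
                        window_size = config$window_size,
                        min_probes = config$min_probes,
                        q_max = config$q_max,
                        min_abs_log2 = config$min_abs_log2,
                        regression_alpha = config$regression_alpha)
    stage_msg("scan", "%d candidates -> %d significant windows -> %d regions",
              s$log[["n_candidate_windows"]], s$log[["n_significant"]],
              s$log[["n_regions"]])
    s
  })
  partial$scan <- scan

  annotation <- run_stage("annotate", {
    regions <- scan$regions
    ann <- list()
    if (nrow(regions) > 0L && is.list(manifest) && !is.null(manifest$islands)) {
      ann$island_context <- classify_island_context(
        regions, manifest$islands, shore_flank = config$shore_flank)
      ann$genes <- annotate_genes(regions, manifest$genes,
                                  promoter_window = config$promoter_window)
      ann$colocalization <- lapply(
        c(nucleosomes = "nucleosomes", h3k4me = "h3k4me",
          h3k27me = "h3k27me"),
        function(tr) colocalize(regions, manifest[[tr]],
                                margin = config$colocalization_margin,
                                track_name = tr))
      ann$clusters <- chromosomal_clusters(
        regions, manifest$chrom_lengths, window = config$cluster_window,
        min_marks = config$cluster_min_marks,
        n_permutations = config$cluster_permutations, seed = config$seed)
      stage_msg("annotate", "%d regions annotated; %d 100-kb clusters",
                nrow(regions), nrow(ann$clusters))
    }
    ann
  })
  partial$annotation <- annotation

  profiles <- run_stage("reads", {
    if (is.null(reads)) NULL else {
      pr <- pool_and_normalize(reads, samples, age_cutoff = config$age_cutoff,
                               min_fraction = config$min_fraction)
      stage_msg("reads", "%d amplicon profiles",
                nrow(unique(pr[, c("amplicon_id", "age_group")])))
      pr
    }
  })
  partial$profiles <- profiles

  enrichment <- run_stage("enrich", {
    hit_genes <- unique(annotation$genes$gene_id)
    if (is.null(disease_table) && !is.null(sim_config) &&
        !is.null(manifest$genes) && nrow(manifest$genes) > 0L) {
      disease_table <- generate_disease_table(
        sim_config, gene_universe = unique(manifest$genes$gene_id),
        hit_genes = hit_genes)
    }
    if (is.null(disease_table) || !length(hit_genes)) NULL else {
      en <- disease_enrichment(hit_genes, disease_table,
                               min_genes = config$enrichment_min_genes)
      stage_msg("enrich", "%d diseases tested", nrow(en))
      en
    }
  })
  partial$enrichment <- enrichment

  gtrend <- run_stage("global", {
    if (is.null(global_table)) NULL else global_trend(global_table)
  })

  report <- list(
    seed = config$seed,
    parameters = unclass(config),
    package_version = as.character(utils::packageVersion("methagescan")),
    counts = scan$log,
    n_hit_genes = length(unique(annotation$genes$gene_id)),
    n_diseases_tested = if (is.null(enrichment)) 0L else nrow(enrichment))

  res <- list(scan = scan, annotation = annotation, profiles = profiles,
              enrichment = enrichment, global_trend = gtrend,
              report = report, manifest = manifest, samples = samples)
  class(res) <- "pipeline_result"

  if (!is.null(config$out_dir)) {
    run_stage("write", {
      dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
      out <- function(f) file.path(config$out_dir, f)
      write_windows_bed(scan$windows, out("windows.bed"))
      write_tsv(scan$windows[, setdiff(names(scan$windows), "probe_idx")],
                out("windows.tsv"))
      write_tsv(scan$regions, out("regions.tsv"))
      reg_bed <- scan$regions
      if (nrow(reg_bed) > 0L)
        write_bed(reg_bed[, c("chrom", "start", "end", "direction")],
                  out("regions.bed"))
      if (!is.null(profiles)) write_tsv(profiles, out("read_profiles.tsv"))
      if (!is.null(enrichment)) write_tsv(enrichment, out("enrichment.tsv"))
      writeLines(c(
        sprintf("seed\t%s", report$seed),
        sprintf("package_version\t%s", report$package_version),
        sprintf("%s\t%s", names(report$counts), report$counts)),
        out("run_report.tsv"))
    })
  }
  res
}

#' One-command synthetic demo
#'
#' Generates a small synthetic cohort and runs every pipeline stage on it.
#'
#' @param seed Master seed.
#' @param n_candidate_windows Number of probe clusters (default 400, with 12
#'   hypo and 3 hyper planted, to keep the demo fast).
#' @param out_dir Optional output directory.
#' @return The [run_pipeline()] result.
#' @export
demo_pipeline <- function(seed = 7L, n_candidate_windows = 400L,
                          out_dir = NULL) {
  sim <- synthetic_config(seed = seed,
                          n_candidate_windows = n_candidate_windows,
                          planted_hypo = 12L, planted_hyper = 3L)
  run_pipeline(pipeline_config(seed = seed, out_dir = out_dir),
               sim_config = sim)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("methagescan pipeline result\n")
  cat(sprintf("  candidate windows : %d\n",
              x$report$counts[["n_candidate_windows"]]))
  cat(sprintf("  significant windows: %d\n",
              x$report$counts[["n_significant"]]))
  cat(sprintf("  regions           : %d (%d hypo, %d hyper)\n",
              x$report$counts[["n_regions"]],
              x$report$counts[["n_regions_hypo"]],
              x$report$counts[["n_regions_hyper"]]))
  if (!is.null(x$enrichment) && nrow(x$enrichment))
    cat(sprintf("  diseases tested   : %d (min p_bonferroni = %.3g)\n",
                nrow(x$enrichment), min(x$enrichment$p_bonferroni)))
  invisible(x)
}
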