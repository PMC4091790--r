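# Seeded synthetic-data generator emulating a paired-donor sperm methylome
# study: an array-style probe manifest with annotation tracks, paired
# beta-value matrices with planted linear age drift, targeted-bisulfite read
# populations, disease-association tables and global methylation values.

#' Synthetic cohort and fixture configuration
#'
#' Bundles every parameter of the synthetic-data generator. The defaults
#' emulate the paired-donor study design the scanner is built for: 17 donors
#' each sampled twice 9-19 years apart, first collection at 23-56 years of
#' age, 139 planted hypomethylation and 8 planted hypermethylation windows of
#' 5 probes each among ~10,000 candidate probe clusters, per-year drift at
#' planted windows of 0.0008-0.0095 fraction methylation (raised where needed
#' so the log2 ratio at the aged timepoint reaches `planted_log2_min` for
#' every donor), probe noise SD 0.02, and initial fraction methylation below
#' 0.6 at altered regions.
#'
#' @param seed Integer master seed; all artifact sub-seeds derive from it.
#' @param n_donors Number of paired donors (two samples each).
#' @param age_young_range Age range (years) at first collection.
#' @param interval_range Range (years) between the two collections.
#' @param n_candidate_windows Number of probe clusters laid down; each cluster
#'   yields one candidate window neighbourhood.
#' @param n_probes Total probes on the manifest; must be at least
#'   `10 * n_candidate_windows`. Probes not used by clusters are placed as
#'   isolated singletons that can never form a window.
#' @param planted_hypo,planted_hyper Number of clusters carrying negative /
#'   positive age drift.
#' @param probes_per_planted_window Probes per cluster (>= 3).
#' @param drift_per_year Range of absolute drift (fraction methylation per
#'   year) sampled for planted clusters.
#' @param planted_log2_min If non-`NULL`, each planted cluster's drift is
#'   raised so that even the donor with the shortest possible interval shows
#'   at least this |log2 ratio| at the aged timepoint. Set to `NULL` to use
#'   the sampled drift unchanged.
#' @param noise_sd SD of independent Gaussian probe noise (fraction).
#' @param baseline_range Baseline (initial) fraction methylation range for
#'   hypomethylated and null clusters.
#' @param baseline_range_hyper Baseline range for hypermethylated clusters;
#'   kept low so gains stay modest, as aged-gain regions start from
#'   low-methylation island contexts.
#' @param donor_sd SD of the per-donor global offset (fraction).
#' @param probe_jitter_sd SD of per-probe baseline jitter within a cluster.
#' @param nucleosome_frac Fraction of planted hypo clusters placed within
#'   1 kb of a nucleosome-retention interval.
#' @param cluster_span Width (bp) over which a cluster's probes scatter.
#' @param n_chrom Number of chromosomes the manifest spans.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L,
                             n_donors = 17L,
                             age_young_range = c(23, 56),
                             interval_range = c(9, 19),
                             n_candidate_windows = 10000L,
                             n_probes = 10L * n_candidate_windows,
                             planted_hypo = 139L,
                             planted_hyper = 8L,
                             probes_per_planted_window = 5L,
                             drift_per_year = c(0.0008, 0.0095),
                             planted_log2_min = 0.3,
                             noise_sd = 0.02,
                             baseline_range = c(0.2, 0.6),
                             baseline_range_hyper = c(0.2, 0.35),
                             donor_sd = 0.01,
                             probe_jitter_sd = 0.01,
                             nucleosome_frac = 0.88,
                             cluster_span = 400L,
                             n_chrom = 22L) {
  cfg <- list(seed = as.integer(seed), n_donors = as.integer(n_donors),
              age_young_range = age_young_range,
              interval_range = interval_range,
              n_candidate_windows = as.integer(n_candidate_windows),
              n_probes = as.integer(n_probes),
              planted_hypo = as.integer(planted_hypo),
              planted_hyper = as.integer(planted_hyper),
              probes_per_planted_window = as.integer(probes_per_planted_window),
              drift_per_year = drift_per_year,
              planted_log2_min = planted_log2_min,
              noise_sd = noise_sd,
              baseline_range = baseline_range,
              baseline_range_hyper = baseline_range_hyper,
              donor_sd = donor_sd, probe_jitter_sd = probe_jitter_sd,
              nucleosome_frac = nucleosome_frac,
              cluster_span = as.integer(cluster_span),
              n_chrom = as.integer(n_chrom))
  if (cfg$planted_hypo + cfg$planted_hyper > cfg$n_candidate_windows)
    stop("configuration error: planted windows exceed candidate windows")
  if (cfg$probes_per_planted_window < 3L)
    stop("configuration error: probes_per_planted_window must be >= 3")
  if (cfg$n_probes < 10L * cfg$n_candidate_windows)
    stop("configuration error: n_probes must be >= 10 * n_candidate_windows")
  class(cfg) <- "synthetic_config"
  cfg
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Deterministic sub-seed per artifact, kept inside 32-bit integer range.
sub_seed <- function(seed, k) {
  as.integer((as.numeric(seed) %% 10000019) * 131 + k)
}

#' Sample the paired-donor cohort
#'
#' Draws each donor's age at first collection uniformly from
#' `age_young_range` and the between-collection interval uniformly from
#' `interval_range`, yielding two samples per donor.
#'
#' @param config A [synthetic_config()].
#' @return Data frame with columns `sample_id`, `donor_id`, `age`, `group`
#'   (`young`/`aged`).
#' @export
sample_cohort <- function(config) {
  with_seed(sub_seed(config$seed, 1L), {
    n <- config$n_donors
    young <- stats::runif(n, config$age_young_range[1], config$age_young_range[2])
    interval <- stats::runif(n, config$interval_range[1], config$interval_range[2])
    donor <- sprintf("D%02d", seq_len(n))
    data.frame(
      sample_id = c(paste0(donor, "_young"), paste0(donor, "_aged")),
      donor_id = rep(donor, 2L),
      age = c(young, young + interval),
      group = rep(c("young", "aged"), each = n),
      stringsAsFactors = FALSE
    )
  })
}

#' Generate a probe manifest, annotation tracks and planted truth
#'
#' Lays `n_candidate_windows` probe clusters (each a candidate 1000-bp
#' window) across `n_chrom` chromosomes with inter-cluster gaps large enough
#' that windows from different clusters can never merge, plants
#' `planted_hypo` + `planted_hyper` disjoint truth regions each covering
#' `probes_per_planted_window` probes, scatters the remaining probes as
#' isolated singletons, and emits CpG-island, nucleosome-retention and
#' histone-mark tracks plus gene models positioned consistently with the
#' planted regions (e.g. a configurable fraction of hypo clusters within
#' 1 kb of a nucleosome interval).
#'
#' @param config A [synthetic_config()].
#' @return A list of class `synthetic_manifest` with elements `probes`
#'   (manifest data frame: `probe_id`, `chrom`, `pos` 1-based,
#'   `island_context`, `gene_id`, `gene_feature`), `truth` (BED-style truth
#'   regions with `direction`, `drift`, `baseline`), `islands`,
#'   `nucleosomes`, `h3k4me`, `h3k27me` (BED-style data frames), `genes`
#'   (gene models) and `chrom_lengths`.
#' @export
generate_manifest <- function(config) {
  cfg <- config
  k <- cfg$probes_per_planted_window
  n_clust <- cfg$n_candidate_windows
  n_single <- cfg$n_probes - n_clust * k
  if (n_single < 0L)
    stop("configuration error: too few probes to place requested clusters")

  with_seed(sub_seed(cfg$seed, 2L), {
    # planted cluster assignment
    direction <- rep("none", n_clust)
    planted <- sample.int(n_clust, cfg$planted_hypo + cfg$planted_hyper)
    direction[planted[seq_len(cfg$planted_hypo)]] <- "hypo"
    if (cfg$planted_hyper > 0L)
      direction[planted[cfg$planted_hypo + seq_len(cfg$planted_hyper)]] <- "hyper"

    baseline <- stats::runif(n_clust, cfg$baseline_range[1], cfg$baseline_range[2])
    hyperi <- direction == "hyper"
    baseline[hyperi] <- stats::runif(sum(hyperi), cfg$baseline_range_hyper[1],
                                     cfg$baseline_range_hyper[2])

    drift <- numeric(n_clust)
    isp <- direction != "none"
    drift[isp] <- stats::runif(sum(isp), cfg$drift_per_year[1], cfg$drift_per_year[2])
    if (!is.null(cfg$planted_log2_min)) {
      L <- cfg$planted_log2_min
      imin <- cfg$interval_range[1]
      need <- ifelse(direction == "hypo",
                     baseline * (1 - 2^(-L)) / imin,
                     baseline * (2^L - 1) / imin)
      drift[isp] <- pmax(drift[isp], need[isp])
    }
    drift[direction == "hypo"] <- -drift[direction == "hypo"]

    # island / nucleosome / histone / gene co-placement probabilities by
    # cluster class, shaped after the genomic context of aged-sperm
    # methylation change (hypo at shores near retained nucleosomes, hyper at
    # low-methylation islands)
    ctx_prob <- function(dir) {
      switch(dir,
             hypo = c(island = 0.09, shore = 0.55, other = 0.36),
             hyper = c(island = 0.60, shore = 0.15, other = 0.25),
             none = c(island = 0.30, shore = 0.30, other = 0.40))
    }
    nuc_prob <- c(hypo = cfg$nucleosome_frac, hyper = 0.375, none = 0.30)
    k4_prob <- c(hypo = 0.23, hyper = 0.05, none = 0.15)
    k27_prob <- c(hypo = 0.453, hyper = 0.05, none = 0.15)
    gene_prob <- c(hypo = 112 / 139, hyper = 7 / 8, none = 0.30)

    context <- vapply(direction, function(d)
      sample(c("island", "shore", "other"), 1L, prob = ctx_prob(d)), "")
    has_nuc <- stats::runif(n_clust) < nuc_prob[direction]
    has_k4 <- stats::runif(n_clust) < k4_prob[direction]
    has_k27 <- stats::runif(n_clust) < k27_prob[direction]
    has_gene <- stats::runif(n_clust) < gene_prob[direction]
    gene_feature <- ifelse(stats::runif(n_clust) < 0.5, "promoter", "body")

    # spatial layout: clusters in order along chromosomes, gaps >= 6 kb so
    # windows, shores (2 kb) and co-localization margins (1 kb) of different
    # clusters stay independent; singletons trail each chromosome 1.5 kb
    # apart so they can never assemble a 3-probe window
    chrom_of <- rep(seq_len(cfg$n_chrom), length.out = n_clust)
    chrom_of <- sort(chrom_of)
    single_chrom <- rep(seq_len(cfg$n_chrom), length.out = max(n_single, 0L))

    probes <- vector("list", cfg$n_chrom)
    truth <- vector("list", cfg$n_chrom)
    islands <- vector("list", cfg$n_chrom)
    nucs <- vector("list", cfg$n_chrom)
    k4s <- vector("list", cfg$n_chrom)
    k27s <- vector("list", cfg$n_chrom)
    genes <- vector("list", cfg$n_chrom)
    chrom_lengths <- integer(cfg$n_chrom)
    cluster_id <- 0L

    for (ch in seq_len(cfg$n_chrom)) {
      chrom <- paste0("chr", ch)
      idx <- which(chrom_of == ch)
      cursor <- 10000
      pb_pos <- integer(0); pb_clust <- integer(0)
      isl <- list(); nu <- list(); h4 <- list(); h27 <- list(); gn <- list()
      tr <- list()
      for (ci in idx) {
        cluster_id <- cluster_id + 1L
        pos <- cursor + sort(sample.int(cfg$cluster_span, k))
        cstart <- pos[1]; cend <- pos[k]
        pb_pos <- c(pb_pos, pos); pb_clust <- c(pb_clust, rep(ci, k))
        if (direction[ci] != "none")
          tr[[length(tr) + 1L]] <- data.frame(
            chrom = chrom, start = cstart - 1L, end = cend,
            direction = direction[ci], drift = drift[ci],
            baseline = baseline[ci], cluster = ci,
            stringsAsFactors = FALSE)
        if (context[ci] == "island") {
          isl[[length(isl) + 1L]] <- c(cstart - 201, cend + 200)
        } else if (context[ci] == "shore") {
          d <- stats::runif(1, 200, 1500)
          isl[[length(isl) + 1L]] <- c(cstart - d - 500, cstart - d)
        }
        if (has_nuc[ci]) {
          d <- stats::runif(1, 0, 700)
          nu[[length(nu) + 1L]] <- c(cend + d, cend + d + 500)
        }
        if (has_k4[ci]) {
          d <- stats::runif(1, 0, 700)
          h4[[length(h4) + 1L]] <- c(cend + d, cend + d + 300)
        }
        if (has_k27[ci]) {
          d <- stats::runif(1, 0, 700)
          h27[[length(h27) + 1L]] <- c(cend + d, cend + d + 300)
        }
        if (has_gene[ci]) {
          gid <- sprintf("GENE%05d", ci)
          if (gene_feature[ci] == "promoter") {
            tss <- cend + round(stats::runif(1, 200, 800))
            gn[[length(gn) + 1L]] <- data.frame(
              gene_id = gid, chrom = chrom, strand = "+", tss = tss,
              start = tss, end = tss + 5000L, stringsAsFactors = FALSE)
          } else {
            gstart <- max(0L, cstart - 2000L)
            gn[[length(gn) + 1L]] <- data.frame(
              gene_id = gid, chrom = chrom, strand = "+", tss = gstart,
              start = gstart, end = cend + 3000L, stringsAsFactors = FALSE)
          }
        }
        cursor <- cend + round(stats::runif(1, 6000, 12000))
      }
      ns <- sum(single_chrom == ch)
      if (ns > 0L) {
        spos <- cursor + 1500L * seq_len(ns)
        pb_pos <- c(pb_pos, spos); pb_clust <- c(pb_clust, rep(NA_integer_, ns))
        cursor <- spos[ns]
      }
      chrom_lengths[ch] <- as.integer(cursor + 10000)
      probes[[ch]] <- data.frame(chrom = chrom, pos = pb_pos,
                                 cluster = pb_clust, stringsAsFactors = FALSE)
      bind_bed <- function(lst) {
        if (!length(lst)) return(NULL)
        m <- do.call(rbind, lst)
        data.frame(chrom = chrom, start = as.integer(round(m[, 1])),
                   end = as.integer(round(m[, 2])), stringsAsFactors = FALSE)
      }
      islands[[ch]] <- bind_bed(isl); nucs[[ch]] <- bind_bed(nu)
      k4s[[ch]] <- bind_bed(h4); k27s[[ch]] <- bind_bed(h27)
      genes[[ch]] <- if (length(gn)) do.call(rbind, gn) else NULL
      truth[[ch]] <- if (length(tr)) do.call(rbind, tr) else NULL
    }

    probes <- do.call(rbind, probes)
    probes <- probes[order(match(probes$chrom, paste0("chr", seq_len(cfg$n_chrom))),
                           probes$pos), ]
    probes$probe_id <- sprintf("cg%07d", seq_len(nrow(probes)))
    rownames(probes) <- NULL
    names(chrom_lengths) <- paste0("chr", seq_len(cfg$n_chrom))

    cat_bed <- function(lst) {
      lst <- Filter(Negate(is.null), lst)
      if (!length(lst))
        return(data.frame(chrom = character(), start = integer(),
                          end = integer(), stringsAsFactors = FALSE))
      out <- do.call(rbind, lst); rownames(out) <- NULL; out
    }
    islands <- cat_bed(islands); nucs <- cat_bed(nucs)
    k4s <- cat_bed(k4s); k27s <- cat_bed(k27s)
    genes <- cat_bed(genes)
    truth <- cat_bed(truth)

    # per-probe annotation columns mirroring array-style manifests
    probes$island_context <- annotate_probe_context(probes, islands)
    pg <- annotate_probe_genes(probes, genes)
    probes$gene_id <- pg$gene_id
    probes$gene_feature <- pg$gene_feature

    out <- list(probes = probes[, c("probe_id", "chrom", "pos",
                                    "island_context", "gene_id",
                                    "gene_feature", "cluster")],
                truth = truth, islands = islands, nucleosomes = nucs,
                h3k4me = k4s, h3k27me = k27s, genes = genes,
                chrom_lengths = chrom_lengths, config = cfg)
    class(out) <- "synthetic_manifest"
    out
  })
}

# Island / shore / other context per probe (1-based positions, BED islands).
annotate_probe_context <- function(probes, islands, shore_flank = 2000) {
  if (nrow(islands) == 0L) return(rep("other", nrow(probes)))
  pr <- GenomicRanges::GRanges(probes$chrom,
                               IRanges::IRanges(probes$pos, probes$pos))
  is <- bed_to_granges(islands)
  ctx <- rep("other", nrow(probes))
  hit <- suppressWarnings(GenomicRanges::distanceToNearest(pr, is))
  qh <- S4Vectors::queryHits(hit)
  dd <- S4Vectors::mcols(hit)$distance
  ctx[qh[dd == 0]] <- "island"
  ctx[qh[dd > 0 & dd <= shore_flank]] <- "shore"
  ctx
}

annotate_probe_genes <- function(probes, genes, promoter_window = 1000) {
  gene_id <- rep("", nrow(probes))
  gene_feature <- rep("", nrow(probes))
  if (is.null(genes) || nrow(genes) == 0L)
    return(data.frame(gene_id = gene_id, gene_feature = gene_feature,
                      stringsAsFactors = FALSE))
  pr <- GenomicRanges::GRanges(probes$chrom,
                               IRanges::IRanges(probes$pos, probes$pos))
  prom <- GenomicRanges::GRanges(
    genes$chrom,
    IRanges::IRanges(pmax(1L, genes$tss - promoter_window), genes$tss + 1L))
  body <- GenomicRanges::GRanges(genes$chrom,
                                 IRanges::IRanges(genes$start + 1L, genes$end))
  hb <- suppressWarnings(GenomicRanges::findOverlaps(pr, body, select = "first"))
  hit <- !is.na(hb)
  gene_id[hit] <- genes$gene_id[hb[hit]]
  gene_feature[hit] <- "body"
  hp <- suppressWarnings(GenomicRanges::findOverlaps(pr, prom, select = "first"))
  hit <- !is.na(hp)
  gene_id[hit] <- genes$gene_id[hp[hit]]
  gene_feature[hit] <- "promoter"
  data.frame(gene_id = gene_id, gene_feature = gene_feature,
             stringsAsFactors = FALSE)
}

#' Generate paired beta-value matrices for the synthetic cohort
#'
#' Each beta value is
#' `clamp(base_probe + donor_offset + drift * age * [probe in truth] + noise)`
#' with independent Gaussian noise of SD `noise_sd`. For planted probes the
#' per-probe base is shifted by `-drift * mean(young ages)` so that the level
#' at first collection matches the cluster's sampled baseline; the planted
#' signal is thus a linear-in-age drift whose paired (aged - young)
#' difference per donor is `drift * interval`.
#'
#' @param config A [synthetic_config()].
#' @param manifest A [generate_manifest()] result (same seed lineage).
#' @param truth Truth-region table; defaults to `manifest$truth`.
#' @return A list of class `synthetic_betas` with elements `betas` (numeric
#'   matrix, probes x samples, rownames probe ids), `samples` (cohort table
#'   from [sample_cohort()]) and `truth`.
#' @export
generate_paired_betas <- function(config, manifest, truth = manifest$truth) {
  cfg <- config
  samples <- sample_cohort(cfg)
  probes <- manifest$probes
  n_p <- nrow(probes)
  n_s <- nrow(samples)

  with_seed(sub_seed(cfg$seed, 3L), {
    # per-cluster baseline for clustered probes; scattered singletons take a
    # broad genome-like baseline
    clustered <- !is.na(probes$cluster)
    base <- stats::runif(n_p, 0.05, 0.95)
    # cluster baselines; planted clusters take the baseline fixed in truth
    cl_ids <- sort(unique(probes$cluster[clustered]))
    cl_baseline <- stats::runif(length(cl_ids), cfg$baseline_range[1],
                                cfg$baseline_range[2])
    names(cl_baseline) <- as.character(cl_ids)
    if (nrow(truth) > 0L) {
      cl_baseline[as.character(truth$cluster)] <- truth$baseline
    }
    base[clustered] <- cl_baseline[as.character(probes$cluster[clustered])]
    base <- base + stats::rnorm(n_p, 0, cfg$probe_jitter_sd)

    drift <- numeric(n_p)
    if (nrow(truth) > 0L) {
      cl_drift <- numeric(length(cl_ids))
      names(cl_drift) <- as.character(cl_ids)
      cl_drift[as.character(truth$cluster)] <- truth$drift
      drift[clustered] <- cl_drift[as.character(probes$cluster[clustered])]
    }

    age_ref <- mean(samples$age[samples$group == "young"])
    base <- base - drift * age_ref

    donor_offset <- stats::rnorm(cfg$n_donors, 0, cfg$donor_sd)
    names(donor_offset) <- unique(samples$donor_id)
    off_s <- donor_offset[samples$donor_id]

    betas <- matrix(base, n_p, n_s) +
      outer(drift, samples$age) +
      matrix(off_s, n_p, n_s, byrow = TRUE) +
      matrix(stats::rnorm(n_p * n_s, 0, cfg$noise_sd), n_p, n_s)
    betas[betas < 0] <- 0
    betas[betas > 1] <- 1
    dimnames(betas) <- list(probes$probe_id, samples$sample_id)

    out <- list(betas = betas, samples = samples, truth = truth)
    class(out) <- "synthetic_betas"
    out
  })
}

#' Default amplicon mixture specifications
#'
#' Three amplicons reproducing the three population-shift patterns seen in
#' aged-sperm epiallele profiles: (A) strongly unmethylated young profile
#' that deepens slightly with age, (B) a unimodal profile shifted toward
#' hypomethylation with age, and (C) a bimodal young profile collapsing to a
#' single hypomethylated mode with age.
#'
#' @return A list of amplicon specifications, each with `amplicon_id`,
#'   `n_cpg`, and per-age-group mixture `means`/`weights` plus a
#'   beta-binomial `concentration`.
#' @export
default_amplicon_specs <- function() {
  list(
    list(amplicon_id = "AMP_low", n_cpg = 6L, concentration = 30,
         young = list(means = 0.10, weights = 1),
         aged = list(means = 0.04, weights = 1)),
    list(amplicon_id = "AMP_shift", n_cpg = 7L, concentration = 30,
         young = list(means = 0.45, weights = 1),
         aged = list(means = 0.25, weights = 1)),
    list(amplicon_id = "AMP_bimodal", n_cpg = 8L, concentration = 40,
         young = list(means = c(0.15, 0.75), weights = c(0.5, 0.5)),
         aged = list(means = 0.15, weights = 1))
  )
}

#' Generate a per-read CpG methylation call table
#'
#' Draws reads from per-amplicon beta-binomial mixtures whose components
#' differ between the young (< 45 y) and aged (>= 45 y) groups. A minority of
#' reads carries one fewer CpG than the amplicon consensus, exercising the
#' 10% consensus rule downstream.
#'
#' @param config A [synthetic_config()] (provides seed and cohort).
#' @param samples Sample table with `sample_id` and `age`; defaults to the
#'   config's cohort.
#' @param amplicons Amplicon specifications; see [default_amplicon_specs()].
#' @param reads_per_sample Reads per amplicon per sample (default 150).
#' @param minority_fraction Fraction of reads emitted with one fewer CpG
#'   (default 0.05).
#' @param age_cutoff Age (years) separating young from aged mixtures.
#' @return A list with `reads` (data frame: `amplicon_id`, `sample_id`,
#'   `read_id`, `call_string` of `M`/`U`) and `samples`.
#' @export
generate_read_table <- function(config, samples = NULL,
                                amplicons = default_amplicon_specs(),
                                reads_per_sample = 150L,
                                minority_fraction = 0.05,
                                age_cutoff = 45) {
  if (is.null(samples)) samples <- sample_cohort(config)
  stopifnot(reads_per_sample >= 1L)
  with_seed(sub_seed(config$seed, 4L), {
    out <- list()
    for (amp in amplicons) {
      stopifnot(amp$n_cpg >= 3L)
      for (si in seq_len(nrow(samples))) {
        grp <- if (samples$age[si] >= age_cutoff) "aged" else "young"
        mix <- amp[[grp]]
        comp <- sample.int(length(mix$means), reads_per_sample,
                           replace = TRUE, prob = mix$weights)
        conc <- amp$concentration
        mu <- mix$means[comp]
        pr <- ifelse(mu <= 0, 0, ifelse(mu >= 1, 1,
                     stats::rbeta(reads_per_sample, mu * conc,
                                  (1 - mu) * conc)))
        short <- stats::runif(reads_per_sample) < minority_fraction
        ncpg <- ifelse(short, amp$n_cpg - 1L, amp$n_cpg)
        calls <- vapply(seq_len(reads_per_sample), function(ri) {
          m <- stats::rbinom(ncpg[ri], 1L, pr[ri])
          paste(ifelse(m == 1L, "M", "U"), collapse = "")
        }, "")
        out[[length(out) + 1L]] <- data.frame(
          amplicon_id = amp$amplicon_id,
          sample_id = samples$sample_id[si],
          read_id = sprintf("%s_%s_r%04d", amp$amplicon_id,
                            samples$sample_id[si], seq_len(reads_per_sample)),
          call_string = calls, stringsAsFactors = FALSE)
      }
    }
    list(reads = do.call(rbind, out), samples = samples)
  })
}

#' Generate a gene-disease association table with one planted enrichment
#'
#' Associates genes with diseases at a uniform background rate, except that
#' one disease's rate among a designated hit-gene set is multiplied by
#' `enrichment_factor`.
#'
#' @param config A [synthetic_config()] (seed source).
#' @param gene_universe Character vector of background genes.
#' @param hit_genes Character vector of study-hit genes (subset of the
#'   universe) receiving the planted enrichment.
#' @param n_diseases Number of disease labels.
#' @param base_rate Background association probability per gene-disease pair.
#' @param enriched_disease Label index (1-based) of the planted disease.
#' @param enrichment_factor Rate multiplier among hit genes (1 = null).
#' @return A list of class `disease_table` with `associations` (data frame
#'   `gene_id`, `disease`) and `universe`.
#' @export
generate_disease_table <- function(config, gene_universe, hit_genes = character(),
                                   n_diseases = 8L, base_rate = 0.08,
                                   enriched_disease = 1L,
                                   enrichment_factor = 1) {
  stopifnot(length(gene_universe) > 0L)
  diseases <- sprintf("disease_%02d", seq_len(n_diseases))
  with_seed(sub_seed(config$seed, 5L), {
    rows <- list()
    hit <- gene_universe %in% hit_genes
    for (di in seq_len(n_diseases)) {
      rate <- rep(base_rate, length(gene_universe))
      if (di == enriched_disease)
        rate[hit] <- pmin(1, base_rate * enrichment_factor)
      assoc <- stats::runif(length(gene_universe)) < rate
      if (any(assoc))
        rows[[length(rows) + 1L]] <- data.frame(
          gene_id = gene_universe[assoc], disease = diseases[di],
          stringsAsFactors = FALSE)
    }
    associations <- if (length(rows)) do.call(rbind, rows) else
      data.frame(gene_id = character(), disease = character(),
                 stringsAsFactors = FALSE)
    out <- list(associations = associations, universe = gene_universe)
    class(out) <- "disease_table"
    out
  })
}

#' Generate global (LINE-1-style) methylation values with a planted trend
#'
#' @param config A [synthetic_config()] (seed source).
#' @param samples Sample table (`sample_id`, `donor_id`, `age`); defaults to
#'   the config's cohort.
#' @param base Intercept fraction methylation at age 0.
#' @param drift_per_year Planted linear trend (fraction/year).
#' @param noise_sd Gaussian noise SD.
#' @return Data frame with `sample_id`, `donor_id`, `age`,
#'   `mean_fraction_methylation`.
#' @export
generate_global_table <- function(config, samples = NULL, base = 0.70,
                                  drift_per_year = 0.002, noise_sd = 0.01) {
  if (is.null(samples)) samples <- sample_cohort(config)
  with_seed(sub_seed(config$seed, 6L), {
    v <- base + drift_per_year * samples$age +
      stats::rnorm(nrow(samples), 0, noise_sd)
    data.frame(sample_id = samples$sample_id, donor_id = samples$donor_id,
               age = samples$age,
               mean_fraction_methylation = pmin(1, pmax(0, v)),
               stringsAsFactors = FALSE)
  })
}

# BED-style data frame (0-based half-open) -> GRanges (1-based closed).
bed_to_granges <- function(bed) {
  GenomicRanges::GRanges(
    bed$chrom, IRanges::IRanges(bed$start + 1L, pmax(bed$start + 1L, bed$end)))
}
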