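# fixed per-stage sub-seed derivation, so stages can be rerun
# independently yet reproducibly from one top-level seed
sub_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) + 77003 * stage) %% 2147483647)
}

#' Simulate a complete synthetic ChIP-seq study
#'
#' Generates the coupled inputs of one experiment: a random genome,
#' gene models with TSS, planted binding sites placed in promoter
#' regions, an enriched IP read sample and a non-enriched control, a
#' wild-type vs mutant expression table, and functional-category
#' annotations. `n_regulatory` sites go upstream (within the promoter
#' window) of genes made regulator-dependent in the expression table;
#' `n_decoy` sites go upstream of genes that are not dependent, so each
#' decoy fails exactly the misregulation filter during curation. Any
#' remaining sites (`cfg$n_sites - n_regulatory - n_decoy`) are placed
#' uniformly away from genes.
#'
#' @param cfg A [sim_config()].
#' @param n_regulatory,n_decoy Site-role design (see above); their sum
#'   must not exceed `cfg$n_sites`.
#' @param effect,noise_cv Expression-simulation parameters.
#' @param target_category Category assigned to regulator-dependent
#'   genes (drives a detectable enrichment signal).
#' @return List: `genome` (named vector), `truth` (site tibble with
#'   `role` and `target_gene`), `genes`, `tss`, `expression`,
#'   `annotations`, `reads_ip`, `reads_ctrl`, `cfg`.
#' @export
simulate_chipseq_study <- function(cfg, n_regulatory = 10, n_decoy = 5,
                                   effect = 8, noise_cv = 0.1,
                                   target_category = "heterocyst differentiation") {
  if (n_regulatory + n_decoy > cfg$n_sites) {
    abort("n_regulatory + n_decoy cannot exceed cfg$n_sites.")
  }
  w <- cfg$site_pwm$width
  genome_str <- simulate_genome(cfg$genome_length, cfg$gc_fraction,
                                seed = sub_seed(cfg$seed, 1))
  gm <- simulate_genes(cfg$genome_length, cfg$n_genes,
                       seed = sub_seed(cfg$seed, 2))
  genes <- gm$genes
  tss <- gm$tss

  set.seed(sub_seed(cfg$seed, 3))
  n_targeted <- n_regulatory + n_decoy
  # promoter placement: site centered ~150 bp upstream of the ORF start
  # on the coding strand; gene layout guarantees the gap is intergenic
  pick <- sample(which(seq_len(nrow(genes)) %% 2 == 1), n_targeted)
  target <- genes[pick, ]
  offset <- 150
  centers <- ifelse(target$strand == "+",
                    target$start - offset,
                    target$end - 1L + offset)
  positions <- as.integer(round(centers - w / 2))
  roles <- c(rep("regulatory", n_regulatory), rep("decoy", n_decoy))
  n_free <- cfg$n_sites - n_targeted
  if (n_free > 0) {
    # background sites in gene-free territory near the end of each
    # intergenic stretch, far (> 2 kb) from any ORF start
    occupied <- sort(c(positions, genes$start))
    cand <- setdiff(
      as.integer(round(seq(5000, cfg$genome_length - 5000,
                           length.out = 4 * n_free))),
      occupied
    )
    far <- vapply(cand, function(p) {
      min(abs(p - genes$start), abs(p - genes$end)) > 2000 &&
        min(abs(p - positions)) > 1000
    }, logical(1))
    free_pos <- sample(cand[far], n_free)
    positions <- c(positions, free_pos)
    roles <- c(roles, rep("intergenic", n_free))
  }
  # planted sites are genuine motif instances: a real binding site
  # identified by scanning passes the scan threshold by construction
  planted <- plant_sites(genome_str, cfg$site_pwm, cfg$n_sites,
                         seed = sub_seed(cfg$seed, 4),
                         positions = positions,
                         min_score = score_threshold(cfg$site_pwm, 1e-4))
  truth <- planted$truth
  truth$role <- roles
  truth$target_gene <- c(target$gene_id, rep(NA_character_,
                                             cfg$n_sites - n_targeted))

  dependent <- target$gene_id[roles[seq_len(n_targeted)] == "regulatory"]
  expression <- simulate_expression(genes, hetr_dependent = dependent,
                                    effect = effect, noise_cv = noise_cv,
                                    seed = sub_seed(cfg$seed, 5))

  set.seed(sub_seed(cfg$seed, 6))
  pool <- c("unknown", "metabolism", "transport", "transcription",
            "transposon related functions")
  cat_bg <- sample(pool, nrow(genes), replace = TRUE,
                   prob = c(0.45, 0.25, 0.15, 0.1, 0.05))
  is_dep <- genes$gene_id %in% dependent
  cat_bg[is_dep] <- ifelse(runif(sum(is_dep)) < 0.8, target_category,
                           cat_bg[is_dep])
  # the target category also exists at low genome-wide frequency
  rare <- runif(nrow(genes)) < 0.01 & !is_dep
  annotations <- tibble::tibble(
    gene_id = c(genes$gene_id, genes$gene_id[rare]),
    category = c(cat_bg, rep(target_category, sum(rare)))
  ) |> dplyr::distinct()

  reads_ip <- simulate_reads(planted$genome, truth, cfg, enriched = TRUE,
                             seed = sub_seed(cfg$seed, 7))
  reads_ctrl <- simulate_reads(planted$genome, truth, cfg, enriched = FALSE,
                               seed = sub_seed(cfg$seed, 8))
  list(
    genome = c(chr = planted$genome),
    truth = truth,
    genes = genes,
    tss = tss,
    expression = expression,
    annotations = annotations,
    reads_ip = reads_ip,
    reads_ctrl = reads_ctrl,
    cfg = cfg
  )
}

#' Default end-to-end run configuration
#'
#' The desk-scale demo study: 1-Mb genome, 200k reads per sample, 15
#' planted sites (10 regulatory + 5 decoy) at 10x local enrichment,
#' default caller/curation/motif/enrichment parameters.
#'
#' @param seed Integer seed.
#' @return A nested configuration list consumable by [run_pipeline()].
#' @export
default_run_config <- function(seed) {
  list(
    seed = as.integer(seed),
    sim = list(genome_length = 1e6, gc_fraction = 0.41, n_sites = 15,
               n_reads_ip = 2e5, n_reads_control = 2e5, read_length = 40,
               fragment_mean = 250, fragment_sd = 40, enrichment_ratio = 10,
               n_genes = 200),
    study = list(n_regulatory = 10, n_decoy = 5, effect = 8, noise_cv = 0.1),
    caller = list(window = 100, fdr_q = 0.05, pseudocount = 0.5,
                  merge_gap = 1, min_ip_reads = 1,
                  n_splits = 3, min_support = 2),
    curation = list(min_fold_enrichment = 3, min_misregulation_fold = 1.5,
                    smooth_bp = 25, min_shift = 20, max_shift = 500,
                    min_correlation = 0.5, min_reads_per_strand = 10,
                    upstream_limit = 500),
    motif = list(seed_string = "GGGTCTAgCCCagCA", strong_weight = 0.91,
                 weak_weight = 0.55, p_threshold = 1e-4),
    enrichment = list(min_fold = 3)
  )
}

#' Read / write a run configuration as YAML
#'
#' @param path YAML file path.
#' @return Configuration list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$seed)) {
    abort("run configuration must set a seed.")
  }
  defaults <- default_run_config(cfg$seed)
  for (section in names(defaults)) {
    if (is.list(defaults[[section]])) {
      cfg[[section]] <- utils::modifyList(defaults[[section]],
                                          cfg[[section]] %||% list())
    }
  }
  cfg
}

#' @rdname read_run_config
#' @param config Configuration list.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Run the whole pipeline: simulate, call, curate, scan, enrich
#'
#' Executes every stage on a synthetic study and returns a run manifest
#' with the funnel counts (peaks called, peaks after
#' replicate-consistency, regions after curation, regions with at least
#' one motif hit, total hits, consensus width) plus all intermediate
#' results. With `outdir` set, stage outputs are written to standard
#' formats (FASTA, BED, GFF3, TSV, MEME motif text, YAML manifest).
#'
#' @param config Configuration list (see [default_run_config()]), or a
#'   path to a YAML file.
#' @param outdir Optional output directory.
#' @return A `run_manifest` list: `config`, `seed`, `counts`, `results`,
#'   `paths`, `version`.
#' @export
run_pipeline <- function(config, outdir = NULL) {
  if (is.character(config)) {
    config <- read_run_config(config)
  }
  seed <- config$seed
  seed_pwm <- seed_to_pwm(config$motif$seed_string,
                          config$motif$strong_weight,
                          config$motif$weak_weight)
  cfg <- sim_config(
    genome_length = config$sim$genome_length,
    gc_fraction = config$sim$gc_fraction,
    n_sites = config$sim$n_sites,
    site_pwm = seed_pwm,
    n_reads_ip = config$sim$n_reads_ip,
    n_reads_control = config$sim$n_reads_control,
    read_length = config$sim$read_length,
    fragment_mean = config$sim$fragment_mean,
    fragment_sd = config$sim$fragment_sd,
    enrichment_ratio = config$sim$enrichment_ratio,
    n_genes = config$sim$n_genes,
    seed = seed
  )
  stage <- "simulate"
  manifest_so_far <- list(config = config, seed = seed)
  result <- tryCatch({
    study <- simulate_chipseq_study(
      cfg,
      n_regulatory = config$study$n_regulatory,
      n_decoy = config$study$n_decoy,
      effect = config$study$effect,
      noise_cv = config$study$noise_cv
    )

    stage <- "callpeaks"
    cp <- config$caller
    called <- call_peaks_replicated(
      study$reads_ip, study$reads_ctrl,
      caller_params(cp$window, cp$fdr_q, cp$pseudocount, cp$merge_gap,
                    cp$min_ip_reads),
      replicon_length = cfg$genome_length,
      n_splits = cp$n_splits, min_support = cp$min_support,
      seed = sub_seed(seed, 11)
    )

    stage <- "curate"
    cu <- config$curation
    curated <- curate_regions(
      called$peaks, study$reads_ip, study$genes, study$tss,
      study$expression,
      curation_params(cu$min_fold_enrichment, cu$min_misregulation_fold,
                      cu$smooth_bp, cu$min_shift, cu$max_shift,
                      cu$min_correlation, cu$min_reads_per_strand,
                      cu$upstream_limit),
      replicon_length = cfg$genome_length
    )
    regions <- curated[curated$retained, , drop = FALSE]

    stage <- "motif"
    scan_input <- if (nrow(regions)) {
      tibble::tibble(region_id = regions$name, replicon = regions$replicon,
                     start = regions$start, end = regions$end)
    } else {
      tibble::tibble(region_id = character(), replicon = character(),
                     start = integer(), end = integer())
    }
    hits <- scan_regions(scan_input, study$genome, seed_pwm,
                         config$motif$p_threshold)
    consensus <- if (nrow(hits) > 0) build_consensus(hits) else NULL

    stage <- "enrich"
    hit_genes <- unique(stats::na.omit(c(regions$gene_left,
                                         regions$gene_right)))
    enrichment <- if (length(hit_genes)) {
      category_fold_enrichment(hit_genes, study$annotations,
                               study$genes$gene_id)
    } else {
      tibble::tibble()
    }
    list(study = study, called = called, curated = curated,
         regions = regions, hits = hits, consensus = consensus,
         enrichment = enrichment)
  }, error = function(e) {
    abort(paste0("pipeline stage '", stage, "' failed: ",
                 conditionMessage(e)))
  })

  counts <- list(
    sites_planted = nrow(result$study$truth),
    peaks_raw = nrow(result$called$peaks_raw),
    peaks_consensus = nrow(result$called$peaks),
    regions_curated = nrow(result$regions),
    regions_with_hit = length(unique(result$hits$region_id)),
    motif_hits = nrow(result$hits),
    consensus_width = if (is.null(result$consensus)) 0L else
      result$consensus$pwm$width,
    enriched_categories = if (nrow(result$enrichment)) {
      nrow(flag_enriched(result$enrichment, config$enrichment$min_fold))
    } else {
      0L
    }
  )
  paths <- list()
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(outdir, f)
    write_genome_fasta(result$study$genome, p("genome.fasta"))
    write_bed(result$study$truth, p("truth_sites.bed"))
    write_bed(result$study$reads_ip, p("reads_ip.bed"))
    write_bed(result$study$reads_ctrl, p("reads_wt.bed"))
    write_gene_models(result$study$genes, p("genes.gff3"))
    write_tss(result$study$tss, p("tss.tsv"))
    write_expression_table(result$study$expression, p("expression.tsv"))
    readr::write_tsv(result$study$annotations, p("categories.tsv"))
    write_peaks_bed(result$called$peaks, p("peaks.bed"))
    readr::write_tsv(curated_region_table(result$curated,
                                          result$study$expression),
                     p("regions.tsv"))
    readr::write_tsv(result$hits, p("motif_hits.tsv"))
    if (!is.null(result$consensus)) {
      write_meme(result$consensus$pwm, p("consensus.meme"),
                 name = "consensus", nsites = result$consensus$n_sites)
    }
    if (nrow(result$enrichment)) {
      readr::write_tsv(result$enrichment, p("enrichment.tsv"))
    }
    paths <- list(outdir = outdir)
  }
  manifest <- structure(
    list(config = config, seed = seed, counts = counts,
         results = result, paths = paths,
         version = as.character(packageVersion("hetrseq"))),
    class = "run_manifest"
  )
  if (!is.null(outdir)) {
    yaml::write_yaml(list(seed = seed, counts = counts,
                          version = manifest$version,
                          config = config),
                     file.path(outdir, "manifest.yaml"))
  }
  manifest
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("<run_manifest> seed", x$seed, "version", x$version, "\n")
  cat("  funnel:\n")
  for (nm in names(x$counts)) {
    cat(sprintf("    %-20s %s\n", nm, x$counts[[nm]]))
  }
  invisible(x)
}
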