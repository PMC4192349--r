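#' Simulation configuration for a synthetic ChIP-seq study
#'
#' Bundles and validates the parameters of the synthetic-data generator.
#' Defaults emulate the sequencing design the pipeline was built for,
#' scaled down to desk size: a 1-Mb bacterial-style genome at the
#' organism's ~41% GC, 40-bp single-end reads, sonication fragments of a
#' few hundred bp, an IP sample enriched at planted motif instances and
#' a non-enriched control.
#'
#' `enrichment_ratio` is the target local fold enrichment at a site: it
#' maps to the per-fragment probability of being site-derived as
#' `p_site = min(1, ratio * n_sites * fragment_mean / genome_length)`,
#' which makes the site-conditioned read-start density approximately
#' `ratio` times the background density. `Inf` forces `p_site = 1`
#' (every IP fragment comes from a site).
#'
#' @param genome_length Genome size in bp.
#' @param gc_fraction GC content in `[0, 1]`.
#' @param n_sites Number of planted binding sites.
#' @param site_pwm PWM the planted sites are sampled from.
#' @param n_reads_ip,n_reads_control Reads per sample.
#' @param read_length Read length in bp (default 40).
#' @param fragment_mean,fragment_sd Sonication fragment-length model
#'   (Gaussian, truncated at `read_length`); `fragment_sd` also sets the
#'   Gaussian jitter of site-derived fragment centers around the site.
#' @param enrichment_ratio Target local fold enrichment at sites (>= 1,
#'   may be `Inf`).
#' @param n_genes Number of simulated gene models.
#' @param seed Mandatory integer seed.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(genome_length = 1e6,
                       gc_fraction = 0.41,
                       n_sites = 30,
                       site_pwm = default_seed_pwm(),
                       n_reads_ip = 2e5,
                       n_reads_control = 2e5,
                       read_length = 40,
                       fragment_mean = 250,
                       fragment_sd = 40,
                       enrichment_ratio = 10,
                       n_genes = 200,
                       seed) {
  if (missing(seed) || is.null(seed)) {
    abort("sim_config requires an explicit seed.")
  }
  if (genome_length <= 0) abort("genome_length must be positive.")
  if (gc_fraction < 0 || gc_fraction > 1) abort("gc_fraction must be in [0, 1].")
  if (read_length > fragment_mean) {
    abort("read_length must not exceed fragment_mean.")
  }
  if (enrichment_ratio < 1) abort("enrichment_ratio must be >= 1.")
  counts <- c(n_sites = n_sites, n_reads_ip = n_reads_ip,
              n_reads_control = n_reads_control, n_genes = n_genes)
  if (any(counts < 0)) abort("counts must be >= 0.")
  cfg <- list(
    genome_length = as.integer(genome_length),
    gc_fraction = gc_fraction,
    n_sites = as.integer(n_sites),
    site_pwm = site_pwm,
    n_reads_ip = as.integer(n_reads_ip),
    n_reads_control = as.integer(n_reads_control),
    read_length = as.integer(read_length),
    fragment_mean = fragment_mean,
    fragment_sd = fragment_sd,
    enrichment_ratio = enrichment_ratio,
    n_genes = as.integer(n_genes),
    seed = as.integer(seed)
  )
  p <- site_fragment_prob(cfg)
  if (cfg$n_sites > 0 && (p <= 0 || p > 1)) {
    abort("site-fragment probability must fall in (0, 1].")
  }
  structure(cfg, class = "sim_config")
}

#' Per-fragment probability of a site-derived IP fragment
#'
#' @param cfg A [sim_config()].
#' @return Probability in `[0, 1]`.
#' @export
site_fragment_prob <- function(cfg) {
  if (cfg$n_sites == 0) {
    return(0)
  }
  if (is.infinite(cfg$enrichment_ratio)) {
    return(1)
  }
  min(1, cfg$enrichment_ratio * cfg$n_sites * cfg$fragment_mean /
        cfg$genome_length)
}

#' Simulate an i.i.d. random genome sequence
#'
#' Bases are drawn independently with `P(G) = P(C) = gc/2` and
#' `P(A) = P(T) = (1 - gc)/2`. Deterministic for a fixed seed.
#'
#' @param length Genome length in bp (> 0).
#' @param gc GC fraction in `[0, 1]`.
#' @param seed Integer seed.
#' @return A single DNA string.
#' @export
simulate_genome <- function(length, gc = 0.41, seed) {
  if (length <= 0) abort("genome length must be positive.")
  if (gc < 0 || gc > 1) abort("gc must be in [0, 1].")
  set.seed(seed)
  bases <- sample(DNA_BASES, length, replace = TRUE,
                  prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
  paste(bases, collapse = "")
}

# sample one site sequence column-wise from a PWM
sample_site_sequence <- function(pwm) {
  paste(vapply(seq_len(pwm$width), function(j) {
    sample(DNA_BASES, 1, prob = pwm$probs[, j])
  }, character(1)), collapse = "")
}

#' Plant motif instances into a genome
#'
#' Sites are sampled column-wise from the PWM, placed at non-overlapping
#' positions (uniformly at random unless `positions` is given) on a
#' uniformly chosen strand, and written into the sequence
#' (reverse-complemented for minus-strand sites). The returned truth
#' table records, for each site, its interval, strand, planted (plus
#' orientation) sequence and the PWM log-odds of the planted string.
#'
#' @param genome DNA string.
#' @param pwm Site model ([pwm()]).
#' @param n_sites Number of sites to plant.
#' @param min_spacing Minimum gap between planted sites in bp.
#' @param seed Integer seed.
#' @param positions Optional integer vector of site start positions
#'   (overrides random placement; length `n_sites`).
#' @param strands Optional strand vector (`"+"`/`"-"`) per site.
#' @param replicon Replicon name recorded in the truth table.
#' @param min_score Optional log-odds floor in bits: each site sequence
#'   is resampled until it scores at least this (e.g.
#'   [score_threshold()] of the scan cutoff, making every planted site
#'   a genuine motif instance). `NULL` keeps pure column-wise PWM
#'   sampling.
#' @return List with `genome` (modified string) and `truth` (tibble:
#'   `replicon`, `start`, `end`, `name`, `score`, `strand`,
#'   `site_sequence`).
#' @export
plant_sites <- function(genome, pwm, n_sites, min_spacing = 500, seed,
                        positions = NULL, strands = NULL,
                        replicon = "chr", min_score = NULL) {
  L <- nchar(genome)
  w <- pwm$width
  if (n_sites == 0) {
    return(list(genome = genome,
                truth = genome_intervals(character(), integer(), integer())))
  }
  if (n_sites * (w + min_spacing) > L) {
    abort("infeasible site packing: n_sites * (width + min_spacing) exceeds genome length.")
  }
  set.seed(seed)
  if (is.null(positions)) {
    # rejection-sample sorted starts until all gaps respect the spacing
    for (attempt in 1:1000) {
      cand <- sort(sample.int(L - w + 1L, n_sites))
      if (n_sites == 1 || all(diff(cand) >= w + min_spacing)) {
        positions <- cand
        break
      }
    }
    if (is.null(positions)) {
      abort("failed to place sites after 1000 attempts; lower n_sites or min_spacing.")
    }
  } else {
    positions <- as.integer(positions)
    if (length(positions) != n_sites) {
      abort("positions must have length n_sites.")
    }
    if (any(positions < 1 | positions + w - 1L > L)) {
      abort("explicit site positions fall outside the genome.")
    }
    if (n_sites > 1 && any(diff(sort(positions)) < w)) {
      abort("explicit site positions overlap.")
    }
  }
  if (is.null(strands)) {
    strands <- sample(c("+", "-"), n_sites, replace = TRUE)
  }
  seqs <- vapply(seq_len(n_sites), function(i) {
    for (try in 1:1000) {
      s <- sample_site_sequence(pwm)
      if (is.null(min_score) || log_odds_score(pwm, s) >= min_score) {
        return(s)
      }
    }
    abort("could not sample a site reaching min_score; lower it.")
  }, character(1))
  planted <- ifelse(strands == "-", reverse_complement(seqs), seqs)
  for (i in seq_len(n_sites)) {
    substr(genome, positions[i], positions[i] + w - 1L) <- planted[i]
  }
  scores <- vapply(seqs, function(s) log_odds_score(pwm, s), numeric(1))
  truth <- genome_intervals(
    replicon = replicon,
    start = positions,
    end = positions + w,
    name = sprintf("site_%03d", seq_len(n_sites)),
    score = scores,
    strand = strands
  )
  truth$site_sequence <- unname(seqs)
  list(genome = genome, truth = truth)
}

#' Simulate aligned ChIP-seq reads
#'
#' Fragment centers are drawn uniformly over the genome (background) or,
#' with probability [site_fragment_prob()] when `enriched = TRUE`, at a
#' uniformly chosen planted-site center plus Gaussian jitter
#' (`sd = fragment_sd`). Fragment lengths are Gaussian
#' (`fragment_mean`, `fragment_sd`), truncated below at `read_length`.
#' Each fragment is sequenced from its 5' end on a uniformly chosen
#' strand: a plus-strand read starts at the fragment's left end, a
#' minus-strand read ends at its right end -- the geometry that produces
#' the strand-offset twin peak at a binding site. Reads overhanging the
#' genome are re-drawn, so every read lies within bounds and exactly the
#' requested number is returned, sorted by start.
#'
#' @param genome DNA string or genome length in bp.
#' @param truth Truth tibble from [plant_sites()] (ignored when
#'   `enriched = FALSE` or empty).
#' @param cfg A [sim_config()].
#' @param enriched `TRUE` for the IP sample, `FALSE` for the control.
#' @param seed Integer seed (defaults to `cfg$seed`).
#' @param replicon Replicon name.
#' @return Interval tibble of aligned reads (BED-ready).
#' @export
simulate_reads <- function(genome, truth = NULL, cfg, enriched = TRUE,
                           seed = cfg$seed, replicon = "chr") {
  L <- if (is.character(genome)) nchar(genome) else as.integer(genome)
  n <- if (enriched) cfg$n_reads_ip else cfg$n_reads_control
  if (n == 0) {
    return(genome_intervals(character(), integer(), integer()))
  }
  rl <- cfg$read_length
  p_site <- if (enriched && !is.null(truth) && nrow(truth) > 0) {
    site_fragment_prob(cfg)
  } else {
    0
  }
  centers_sites <- if (p_site > 0) (truth$start + truth$end - 1) / 2 else numeric(0)
  set.seed(seed)

  draw <- function(m) {
    from_site <- if (p_site > 0) runif(m) < p_site else rep(FALSE, m)
    center <- numeric(m)
    n_site <- sum(from_site)
    if (n_site > 0) {
      center[from_site] <- centers_sites[sample.int(length(centers_sites),
                                                    n_site, replace = TRUE)] +
        rnorm(n_site, 0, cfg$fragment_sd)
    }
    center[!from_site] <- runif(m - n_site, 1, L)
    fraglen <- pmax(rl, round(rnorm(m, cfg$fragment_mean, cfg$fragment_sd)))
    left <- round(center - fraglen / 2)
    right <- left + fraglen          # end-exclusive fragment bound
    strand <- sample(c("+", "-"), m, replace = TRUE)
    start <- ifelse(strand == "+", left, right - rl)
    tibble::tibble(start = start, end = start + rl, strand = strand)
  }

  out <- draw(n)
  bad <- out$start < 1 | out$end > L + 1
  while (any(bad)) {
    out[bad, ] <- draw(sum(bad))
    bad <- out$start < 1 | out$end > L + 1
  }
  reads <- genome_intervals(
    replicon = replicon,
    start = out$start,
    end = out$end,
    name = sprintf("read_%07d", seq_len(n)),
    score = 0,
    strand = out$strand
  )
  dplyr::arrange(reads, .data$start, .data$end, .data$strand)
}

#' Simulate non-overlapping gene models with TSS
#'
#' Genes of Gamma-distributed length are laid head-to-tail with
#' intergenic gaps wide enough to host planted promoter sites, on
#' random strands. Each gene gets a TSS 20-100 bp upstream of its start
#' codon on the coding strand, with the leader recorded as a 5' UTR.
#'
#' @param genome_length Genome size in bp.
#' @param n_genes Number of genes (trimmed if the genome is too small).
#' @param seed Integer seed.
#' @param mean_gene_length,min_gap Layout parameters in bp.
#' @param replicon Replicon name.
#' @return List with `genes` (gene-model tibble) and `tss` (TSS tibble).
#' @export
simulate_genes <- function(genome_length, n_genes, seed,
                           mean_gene_length = 900, min_gap = 1200,
                           replicon = "chr") {
  set.seed(seed)
  lens <- pmax(150L, as.integer(round(
    stats::rgamma(n_genes, shape = 4, scale = mean_gene_length / 4)
  )))
  gaps <- as.integer(round(runif(n_genes, min_gap, min_gap * 2)))
  starts <- cumsum(c(gaps[1], head(lens, -1) + gaps[-1])) + 1L
  keep <- starts + lens - 1L <= genome_length - min_gap
  starts <- starts[keep]
  lens <- lens[keep]
  n <- length(starts)
  strand <- sample(c("+", "-"), n, replace = TRUE)
  leader <- as.integer(round(runif(n, 20, 100)))
  tss_pos <- ifelse(strand == "+", starts - leader, starts + lens - 1L + leader)
  genes <- tibble::tibble(
    gene_id = sprintf("gene_%04d", seq_len(n)),
    replicon = replicon,
    start = starts,
    end = starts + lens,
    strand = strand,
    utr5_start = as.integer(ifelse(strand == "+", tss_pos, starts + lens)),
    utr5_end = as.integer(ifelse(strand == "+", starts, tss_pos + 1L))
  )
  tss <- tibble::tibble(
    replicon = replicon,
    position = as.integer(tss_pos),
    strand = strand,
    gene_id = genes$gene_id
  )
  list(genes = genes, tss = tss)
}

#' Reads per kilobase of gene model per million mapped reads
#'
#' The standard RPKM definition:
#' `count / ((gene_length/1000) * (total_mapped/1e6))`.
#'
#' @param read_count Reads mapped to the gene (vectorised).
#' @param gene_length Gene length in bp (> 0).
#' @param total_mapped Library size in reads (> 0).
#' @return RPKM values.
#' @export
#' @examples
#' rpkm(100, 1000, 1e6)  # 100
rpkm <- function(read_count, gene_length, total_mapped) {
  if (any(gene_length <= 0)) abort("gene_length must be positive.")
  if (any(total_mapped <= 0)) abort("total_mapped must be positive.")
  read_count / ((gene_length / 1000) * (total_mapped / 1e6))
}

#' Simulate a wild-type vs mutant expression table
#'
#' Per-gene expected read counts are log-normal across genes; the
#' regulator-dependent subset has its mutant expectation divided by
#' `effect`. Multiplicative log-normal noise with coefficient of
#' variation `noise_cv` is applied per measurement and counts are
#' rounded, so strongly dependent, weakly expressed genes can drop to
#' zero mutant reads -- serialized with the `"n / 0"` sentinel
#' convention. RPKM values and signed fold changes are derived per
#' timepoint (0 h and 6 h after nitrogen step-down).
#'
#' @param genes Gene-model tibble.
#' @param hetr_dependent Character vector of dependent `gene_id`s.
#' @param effect Fold reduction of mutant expression (>= 1).
#' @param noise_cv Coefficient of variation of measurement noise.
#' @param seed Integer seed.
#' @param mean_count Median expected read count per gene.
#' @return Tibble with per-timepoint WT/mutant counts and RPKM, numeric
#'   signed fold changes (`fc_0h`, `fc_6h`) and serialized fields
#'   (`fc_wt0_mut0`, `fc_wt6_mut6`).
#' @export
simulate_expression <- function(genes, hetr_dependent = character(),
                                effect = 8, noise_cv = 0.1, seed,
                                mean_count = 200) {
  if (effect < 1) abort("effect must be >= 1.")
  set.seed(seed)
  n <- nrow(genes)
  dep <- genes$gene_id %in% hetr_dependent
  base <- exp(rnorm(n, log(mean_count), 1))
  sdlog <- sqrt(log(1 + noise_cv^2))
  noisy <- function(mu) {
    if (noise_cv == 0) round(mu) else round(mu * exp(rnorm(n, 0, sdlog)))
  }
  wt0 <- noisy(base)
  wt6 <- noisy(base)
  mut0 <- noisy(ifelse(dep, base / effect, base))
  mut6 <- noisy(ifelse(dep, base / effect, base))
  lib <- 1e6
  glen <- interval_length(genes)
  signed <- function(wt, mut) {
    ifelse(wt == 0 & mut == 0, NA_real_,
           ifelse(mut == 0, -Inf,
                  ifelse(wt == 0, Inf,
                         ifelse(mut <= wt,
                                ifelse(wt == mut, 1, -wt / mut),
                                mut / wt))))
  }
  tibble::tibble(
    gene_id = genes$gene_id,
    hetr_dependent = dep,
    wt_count_0h = wt0, mut_count_0h = mut0,
    wt_count_6h = wt6, mut_count_6h = mut6,
    wt_rpkm_0h = rpkm(wt0, glen, lib),
    mut_rpkm_0h = rpkm(mut0, glen, lib),
    wt_rpkm_6h = rpkm(wt6, glen, lib),
    mut_rpkm_6h = rpkm(mut6, glen, lib),
    fc_0h = signed(wt0, mut0),
    fc_6h = signed(wt6, mut6),
    fc_wt0_mut0 = format_signed_fc(wt0, mut0),
    fc_wt6_mut6 = format_signed_fc(wt6, mut6)
  )
}
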