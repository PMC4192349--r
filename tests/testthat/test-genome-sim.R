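test_that("simulate_genome validates inputs and hits its composition", {
  expect_error(simulate_genome(0, 0.4, seed = 1), "positive")
  expect_error(simulate_genome(100, 1.2, seed = 1), "gc")

  at_only <- simulate_genome(5000, gc = 0, seed = 3)
  expect_false(grepl("[GC]", at_only))

  g <- simulate_genome(1e6, gc = 0.412, seed = 11)
  expect_equal(nchar(g), 1e6)
  gc_obs <- nchar(gsub("[AT]", "", g)) / 1e6
  se <- sqrt(0.412 * (1 - 0.412) / 1e6)
  expect_lt(abs(gc_obs - 0.412), 3 * se)

  expect_identical(simulate_genome(2000, 0.4, seed = 5),
                   simulate_genome(2000, 0.4, seed = 5))
})

test_that("plant_sites plants what it promises", {
  g <- simulate_genome(2e4, 0.4, seed = 21)

  none <- plant_sites(g, default_seed_pwm(), 0, seed = 1)
  expect_identical(none$genome, g)
  expect_equal(nrow(none$truth), 0)

  # deterministic PWM: every planted substring is the consensus
  det <- seed_to_pwm("GGGTCTAGCCCAGCA", strong_weight = 1)
  pl <- plant_sites(g, det, 5, min_spacing = 100, seed = 22)
  for (i in 1:5) {
    sub <- substr(pl$genome, pl$truth$start[i], pl$truth$end[i] - 1L)
    if (pl$truth$strand[i] == "-") sub <- reverse_complement(sub)
    expect_identical(sub, "GGGTCTAGCCCAGCA")
    expect_identical(pl$truth$site_sequence[i], "GGGTCTAGCCCAGCA")
  }

  expect_error(plant_sites(g, det, 1000, min_spacing = 100, seed = 1),
               "packing")
})

test_that("planted site sequences follow the PWM column-wise", {
  g <- simulate_genome(3e5, 0.4, seed = 31)
  pw <- default_seed_pwm()
  pl <- plant_sites(g, pw, 60, min_spacing = 200, seed = 32)
  mat <- do.call(rbind, strsplit(pl$truth$site_sequence, ""))
  # chi-square goodness of fit per column against the PWM probabilities
  pvals <- vapply(seq_len(pw$width), function(j) {
    obs <- tabulate(match(mat[, j], c("A", "C", "G", "T")), nbins = 4)
    keep <- pw$probs[, j] > 0
    suppressWarnings(
      stats::chisq.test(obs[keep], p = pw$probs[keep, j])$p.value
    )
  }, numeric(1))
  expect_gt(min(pvals), 1e-4)
})

test_that("read simulation has the deterministic twin geometry", {
  expect_equal(nrow(simulate_reads(1e4, NULL,
                                   sim_config(n_sites = 0, n_reads_ip = 0,
                                              seed = 1),
                                   enriched = TRUE)), 0)

  # single site, enrichment probability 1, fragment_sd = 0:
  # plus-strand starts at center - mean/2, minus-strand ends at
  # center + mean/2 (end-exclusive)
  pw <- seed_to_pwm("GGGTCTAGCCCAGCA", strong_weight = 1)
  cfg <- sim_config(genome_length = 1e4, n_sites = 1, site_pwm = pw,
                    n_reads_ip = 500, n_reads_control = 0,
                    fragment_mean = 200, fragment_sd = 0,
                    enrichment_ratio = Inf, seed = 7)
  g <- simulate_genome(cfg$genome_length, 0.4, seed = 71)
  pl <- plant_sites(g, pw, 1, seed = 72, positions = 5000)
  center <- (pl$truth$start + pl$truth$end - 1) / 2  # 5007
  reads <- simulate_reads(pl$genome, pl$truth, cfg, enriched = TRUE,
                          seed = 73)
  expect_equal(nrow(reads), 500)
  plus <- reads[reads$strand == "+", ]
  minus <- reads[reads$strand == "-", ]
  expect_true(all(plus$start == center - 100))
  expect_true(all(minus$end == center + 100))
})

test_that("IP twin peaks are separated by about the fragment length", {
  pw <- default_seed_pwm()
  cfg <- sim_config(genome_length = 5e4, n_sites = 1, site_pwm = pw,
                    n_reads_ip = 2e4, n_reads_control = 0,
                    fragment_mean = 250, fragment_sd = 30,
                    enrichment_ratio = Inf, seed = 8)
  g <- simulate_genome(cfg$genome_length, 0.4, seed = 81)
  pl <- plant_sites(g, pw, 1, seed = 82, positions = 25000)
  reads <- simulate_reads(pl$genome, pl$truth, cfg, enriched = TRUE,
                          seed = 83)
  # independent histogram of 5' ends per strand
  p5 <- reads$start[reads$strand == "+"]
  m5 <- reads$end[reads$strand == "-"] - 1L
  hp <- tabulate(p5, nbins = cfg$genome_length)
  hm <- tabulate(m5, nbins = cfg$genome_length)
  k <- rep(1 / 25, 25)
  sp <- stats::filter(hp, k)
  sm <- stats::filter(hm, k)
  sep <- which.max(sm) - which.max(sp)
  expect_lt(abs(sep - cfg$fragment_mean), 50)
})

test_that("read counts and bounds are conserved; control is Poisson-flat", {
  cfg <- sim_config(genome_length = 2e5, n_sites = 0, n_reads_ip = 3e4,
                    n_reads_control = 3e4, seed = 9)
  ctrl <- simulate_reads(2e5, NULL, cfg, enriched = FALSE, seed = 91)
  expect_equal(nrow(ctrl), 3e4)
  expect_true(all(ctrl$start >= 1 & ctrl$end <= 2e5 + 1))
  expect_true(all(interval_length(ctrl) == cfg$read_length))
  expect_false(is.unsorted(ctrl$start))

  # dispersion of read starts over 1000 windows consistent with Poisson
  track <- build_coverage(ctrl, 2e5, mode = "read_start")
  wc <- window_counts(track, 200)[1:1000, ]
  disp <- (1000 - 1) * stats::var(wc$count) / mean(wc$count)
  p <- stats::pchisq(disp, df = 999)
  expect_gt(min(p, 1 - p), 0.001)
})

test_that("identical config and seed give byte-identical reads", {
  cfg <- sim_config(genome_length = 5e4, n_sites = 2, n_reads_ip = 5000,
                    n_reads_control = 5000, seed = 10)
  g <- simulate_genome(5e4, 0.4, seed = 101)
  pl <- plant_sites(g, cfg$site_pwm, 2, seed = 102)
  r1 <- simulate_reads(pl$genome, pl$truth, cfg, TRUE, seed = 103)
  r2 <- simulate_reads(pl$genome, pl$truth, cfg, TRUE, seed = 103)
  expect_identical(r1, r2)
})

test_that("rpkm matches direct arithmetic and guards degenerate input", {
  expect_equal(rpkm(100, 1000, 1e6), 100)
  expect_equal(rpkm(0, 1000, 1e6), 0)
  expect_equal(rpkm(37, 1234, 3.5e6), 37 / (1.234 * 3.5))
  expect_error(rpkm(10, 0, 1e6), "gene_length")
  expect_error(rpkm(10, 100, 0), "total_mapped")
})

test_that("expression simulation recovers its effect size and sentinels", {
  genes <- tibble::tibble(
    gene_id = sprintf("g%03d", 1:200),
    replicon = "chr",
    start = seq(1, by = 2000, length.out = 200),
    end = seq(1, by = 2000, length.out = 200) + 999,
    strand = "+",
    utr5_start = NA_integer_, utr5_end = NA_integer_
  )

  flat <- simulate_expression(genes, character(), effect = 1, noise_cv = 0,
                              seed = 1)
  expect_true(all(flat$fc_0h == 1) && all(flat$fc_6h == 1))

  dep <- genes$gene_id[1:80]
  ex <- simulate_expression(genes, dep, effect = 8, noise_cv = 0.1, seed = 2)
  rec <- abs(ex$fc_6h[ex$hetr_dependent])
  rec <- rec[is.finite(rec)]
  expect_lt(abs(mean(rec) - 8) / 8, 0.10)

  # the zero-mutant serialization convention
  expect_identical(format_signed_fc(11, 0), "11 / 0")
  expect_identical(parse_signed_fc("11 / 0")$sentinel, "zero_mutant")
})
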