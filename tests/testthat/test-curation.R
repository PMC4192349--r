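test_that("the fold filter is boundary-inclusive at 3", {
  pk <- tibble::tibble(fold_enrichment = c(3.0, 2.99, 10))
  expect_identical(fold_filter(pk), c(TRUE, FALSE, TRUE))
})

test_that("twin-peak scoring detects strand-offset pileups", {
  # synthetic tracks: plus starts centered at 1000, minus 5' ends at 1200
  mk_track <- function(centers, strand, n_each = 80, sd = 20, L = 3000) {
    set.seed(42)
    pos <- as.integer(round(rnorm(n_each * length(centers),
                                  rep(centers, each = n_each), sd)))
    # place the read so its 5' end (strand-dependent) is at `pos`
    start <- if (strand == "+") pos else pos - 39L
    reads <- genome_intervals("chr", start, start + 40L, strand = strand)
    build_coverage(reads, L, strand_filter = strand, mode = "read_start")
  }
  peak <- tibble::tibble(replicon = "chr", start = 900L, end = 1300L,
                         name = "p1", fold_enrichment = 10)
  params <- curation_params(max_shift = 400)

  tw <- twin_peak_score(peak, mk_track(1000, "+"), mk_track(1200, "-"),
                        params)
  expect_true(tw$is_twin)
  expect_lt(abs(tw$shift - 200), 50)
  expect_gte(tw$correlation_score, 0.5)

  # all reads on one strand: degenerate, not a twin peak
  empty_minus <- build_coverage(genome_intervals(character(), integer(),
                                                 integer())[0, ],
                                3000, strand_filter = "-",
                                mode = "read_start")
  tw2 <- twin_peak_score(peak, mk_track(1000, "+"), empty_minus, params)
  expect_false(tw2$is_twin)
  expect_true(is.na(tw2$correlation_score))

  # coincident summits: shift 0 must not count as a twin peak
  tw3 <- twin_peak_score(peak, mk_track(1100, "+"), mk_track(1100, "-"),
                         params)
  expect_equal(tw3$shift, 0)
  expect_false(tw3$is_twin)
})

test_that("proximity categories follow the footnote definitions", {
  genes <- tibble::tibble(
    gene_id = c("gA", "gB"), replicon = "chr",
    start = c(5000L, 9000L), end = c(6000L, 9900L),
    strand = c("+", "+"),
    utr5_start = NA_integer_, utr5_end = NA_integer_
  )
  tss <- tibble::tibble(replicon = "chr", position = integer(),
                        strand = character(), gene_id = character())
  peak <- function(s, e) tibble::tibble(replicon = "chr", start = s, end = e,
                                        name = "p", fold_enrichment = 5)

  # 100 bp upstream of a plus-strand start: promoter window
  a <- annotate_region(peak(4800L, 4900L), genes, tss)
  expect_identical(a$proximity_right, "within_500bp_upstream")
  # 600 bp upstream, no TSS between: beyond the window
  b <- annotate_region(peak(4300L, 4400L), genes, tss)
  expect_identical(b$proximity_right, "beyond_500bp_upstream")
  # between an assigned TSS and the start codon: leader region
  tss2 <- tibble::tibble(replicon = "chr", position = 4700L, strand = "+",
                         gene_id = "gA")
  d <- annotate_region(peak(4750L, 4850L), genes, tss2)
  expect_identical(d$proximity_right, "downstream_of_TSS")
  # entirely 3' of a gene on its coding strand: cannot regulate it
  expect_identical(a$proximity_left, NA_character_)
  e <- annotate_region(peak(6200L, 6300L), genes, tss)
  expect_identical(e$proximity_left, "not_applicable")

  # mirrored construction on the minus strand
  genes_m <- tibble::tibble(
    gene_id = "gM", replicon = "chr", start = 5000L, end = 6000L,
    strand = "-", utr5_start = NA_integer_, utr5_end = NA_integer_
  )
  f <- annotate_region(peak(6100L, 6200L), genes_m, tss)
  expect_identical(f$proximity_left, "within_500bp_upstream")
  g <- annotate_region(peak(4300L, 4400L), genes_m, tss)
  expect_identical(g$proximity_right, "not_applicable")

  expect_error(annotate_region(peak(1L, 10L), genes[0, ], tss), "gene")
})

test_that("misregulation uses either timepoint and spares sentinels", {
  expr <- read_expression_table()
  expect_true(misregulation_flag("all0521", expr, 1.5))  # -13 / -8.0
  expect_true(misregulation_flag("patA (all0521)", expr, 1.5))
  expect_true(misregulation_flag("alr3758", expr, 1.5))  # "11 / 0"
  expect_true(is.na(misregulation_flag("not_a_gene", expr, 1.5)))

  flat <- tibble::tibble(gene_id = c("g1", "g2"),
                         fc_0h = c(1.0, NA), fc_6h = c(-1.1, NA),
                         fc_0h_sentinel = c("none", "low_coverage"),
                         fc_6h_sentinel = c("none", "low_coverage"))
  expect_false(misregulation_flag("g1", flat, 1.5))
  expect_true(is.na(misregulation_flag("g2", flat, 1.5)))
})

test_that("curation retains regulatory sites and drops decoys", {
  study <- small_study()
  called <- small_called(study)
  cur <- curate_regions(called$peaks, study$reads_ip, study$genes,
                        study$tss, study$expression,
                        replicon_length = study$cfg$genome_length)
  kept <- cur[cur$retained, ]
  tr <- study$truth
  reg <- tr[tr$role == "regulatory", ]
  dec <- tr[tr$role == "decoy", ]
  expect_equal(sum(count_overlaps(reg, kept) > 0), nrow(reg))
  expect_equal(sum(count_overlaps(dec, kept) > 0), 0)
  # the audit trail shows decoys failing exactly the misregulation filter
  decoy_rows <- cur[count_overlaps(cur, dec) > 0, ]
  expect_true(all(!decoy_rows$pass_misregulation))
  expect_true(all(decoy_rows$pass_fold & decoy_rows$pass_twin &
                    decoy_rows$pass_proximity))

  # zero peaks in, zero records out
  expect_equal(nrow(curate_regions(called$peaks[0, ], study$reads_ip,
                                   study$genes, study$tss,
                                   study$expression)), 0)

  # disabling every filter passes everything through
  open_params <- curation_params(enable_fold = FALSE, enable_twin = FALSE,
                                 enable_misregulation = FALSE,
                                 enable_proximity = FALSE)
  all_in <- curate_regions(called$peaks, study$reads_ip, study$genes,
                           study$tss, study$expression, open_params,
                           replicon_length = study$cfg$genome_length)
  expect_equal(sum(all_in$retained), nrow(called$peaks))

  # relaxing a single threshold never decreases the retained count
  relaxed <- curate_regions(called$peaks, study$reads_ip, study$genes,
                            study$tss, study$expression,
                            curation_params(min_fold_enrichment = 1),
                            replicon_length = study$cfg$genome_length)
  expect_gte(sum(relaxed$retained), sum(cur$retained))

  # the published-schema formatter carries coordinates and lengths
  tab <- curated_region_table(cur, study$expression)
  expect_equal(nrow(tab), sum(cur$retained))
  expect_equal(tab$length_bp, tab$end - tab$start)
})

test_that("annotation is invariant under genome reflection", {
  study <- small_study()
  called <- small_called(study)
  L <- study$cfg$genome_length
  cur <- curate_regions(called$peaks, study$reads_ip, study$genes,
                        study$tss, study$expression,
                        replicon_length = L)
  r_peaks <- reflect_intervals(called$peaks, L)
  r_peaks$summit <- L - called$peaks$summit + 1L
  r_cur <- curate_regions(r_peaks, reflect_intervals(study$reads_ip, L),
                          reflect_genes(study$genes, L),
                          reflect_tss(study$tss, L),
                          study$expression,
                          replicon_length = L)
  kept_genes <- function(cc) {
    sort(unique(stats::na.omit(c(cc$gene_left[cc$retained],
                                 cc$gene_right[cc$retained]))))
  }
  expect_identical(kept_genes(r_cur), kept_genes(cur))
})
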