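test_that("reverse complement is an involution matching the oracle", {
  expect_identical(reverse_complement("ACGT"), "ACGT")
  expect_identical(reverse_complement(""), "")
  s <- "GAGGGGTCTAACCCCTC"
  expect_identical(reverse_complement(s), oracle_revcomp(s))
  set.seed(5)
  for (i in 1:10) {
    r <- paste(sample(c("A", "C", "G", "T"), 30, replace = TRUE),
               collapse = "")
    expect_identical(reverse_complement(r), oracle_revcomp(r))
    expect_identical(reverse_complement(reverse_complement(r)), r)
  }
})

test_that("seed strings map to PWMs by conservation case", {
  one <- seed_to_pwm("G")
  expect_equal(unname(one$probs[, 1]), c(0.03, 0.03, 0.91, 0.03))
  expect_equal(seed_to_pwm("GGGTCTAgCCCagCA")$width, 15)
  expect_equal(unname(seed_to_pwm("N")$probs[, 1]), rep(0.25, 4))
  low <- seed_to_pwm("g")
  expect_equal(unname(low$probs["G", 1]), 0.55)
  expect_error(seed_to_pwm("GQX"), "invalid")
})

test_that("log-odds scoring matches closed forms and a second scorer", {
  det3 <- seed_to_pwm("GGG", strong_weight = 1)
  expect_equal(log_odds_score(det3, "GGG"), 3 * log2(4))
  unif <- pwm(matrix(0.25, 4, 4))
  expect_equal(log_odds_score(unif, "ACGT"), 0)
  expect_error(log_odds_score(unif, "ACGN"), "non-ACGT")
  expect_error(log_odds_score(unif, "ACG"), "width")
  set.seed(6)
  for (i in 1:15) {
    w <- sample(3:10, 1)
    pw <- random_pwm(w, seed = 600 + i)
    kmer <- paste(sample(c("A", "C", "G", "T"), w, replace = TRUE),
                  collapse = "")
    expect_equal(log_odds_score(pw, kmer), oracle_log_odds(pw, kmer),
                 tolerance = 1e-10)
  }
})

test_that("score p-values bracket the exhaustive enumeration", {
  pw <- random_pwm(6, seed = 61)
  enum <- oracle_all_scores(pw)
  g <- 1e-3
  for (s in stats::quantile(enum$scores, c(0.01, 0.25, 0.5, 0.9, 0.999))) {
    p_dp <- score_pvalue(pw, s, granularity = g)
    lo <- oracle_exact_pvalue(enum, s + pw$width * g)
    hi <- oracle_exact_pvalue(enum, s - pw$width * g)
    expect_gte(p_dp, lo)
    expect_lte(p_dp, hi)
  }
  expect_equal(score_pvalue(pw, min(enum$scores) - 1), 1)
  expect_equal(score_pvalue(pw, max(enum$scores) + 1), 0)
  # non-increasing in score
  ss <- sort(stats::runif(20, min(enum$scores), max(enum$scores)))
  expect_true(all(diff(score_pvalue(pw, ss)) <= 1e-15))
})

test_that("score_threshold is consistent with score_pvalue", {
  pw <- default_seed_pwm()
  thr <- score_threshold(pw, 1e-4)
  expect_lte(score_pvalue(pw, thr), 1e-4)
  expect_gt(score_pvalue(pw, thr - 0.01), 1e-4)
})

test_that("scanning recovers a planted consensus on both strands", {
  pw <- default_seed_pwm()
  set.seed(7)
  bg <- paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE),
              collapse = "")
  site <- "GGGTCTAGCCCAGCA"
  seq <- paste0(substr(bg, 1, 100), site, substr(bg, 101, 200))
  hits <- scan_sequence(seq, pw)
  expect_gte(nrow(hits), 1)
  expect_true(site %in% hits$matched_sequence)
  best <- hits[which.max(hits$score), ]
  expect_equal(best$start, 101L)
  expect_equal(best$end, 116L)

  # mirrored coordinates on the reverse-complemented sequence
  rc_hits <- scan_sequence(reverse_complement(seq), pw)
  L <- nchar(seq)
  expect_true(any(rc_hits$start == L - best$end + 2L &
                    rc_hits$matched_sequence == site))

  expect_equal(nrow(scan_sequence(strrep("A", 300), pw)), 0)
  expect_equal(nrow(scan_sequence("ACGT", pw)), 0)
})

test_that("strand symmetry: hit sets mirror exactly", {
  pw <- default_seed_pwm()
  set.seed(8)
  g <- simulate_genome(3000, 0.4, seed = 88)
  pl <- plant_sites(g, pw, 4, min_spacing = 300, seed = 89)
  fwd <- scan_sequence(pl$genome, pw)
  rev <- scan_sequence(reverse_complement(pl$genome), pw)
  L <- nchar(pl$genome)
  mirrored <- tibble::tibble(
    start = L - rev$end + 2L,
    score = rev$score,
    matched_sequence = rev$matched_sequence
  )
  key <- function(d) dplyr::arrange(d[c("start", "score",
                                        "matched_sequence")],
                                    .data$start, .data$matched_sequence)
  expect_equal(key(mirrored), key(fwd[c("start", "score",
                                        "matched_sequence")]),
               tolerance = 1e-12)
})

test_that("region scans find planted sites and count per region", {
  pw <- default_seed_pwm()
  g <- simulate_genome(2e4, 0.4, seed = 9)
  thr <- score_threshold(pw, 1e-4)
  pl <- plant_sites(g, pw, 5, seed = 91,
                    positions = c(2000, 5000, 8000, 11000, 14000),
                    min_score = thr)
  regions <- tibble::tibble(
    region_id = paste0("R", 1:5), replicon = "chr",
    start = pl$truth$start - 150L, end = pl$truth$end + 150L
  )
  hits <- scan_regions(regions, c(chr = pl$genome), pw)
  summ <- scan_summary(hits, regions)
  expect_equal(summ$n_regions_with_hit, 5)
  expect_gte(summ$n_hits, 5)
  # hit coordinates are genomic: each region's own site is inside it
  expect_true(all(hits$start >= regions$start[match(hits$region_id,
                                                    regions$region_id)]))

  # a region holding two planted sites yields two hits
  two <- tibble::tibble(region_id = "R12", replicon = "chr",
                        start = pl$truth$start[1] - 100L,
                        end = pl$truth$end[2] + 100L)
  h2 <- scan_regions(two, c(chr = pl$genome), pw)
  expect_gte(nrow(h2), 2)

  none <- scan_regions(regions[0, ], c(chr = pl$genome), pw)
  expect_equal(nrow(none), 0)
  expect_true("region_id" %in% names(none))
})

test_that("consensus construction reports IC and IUPAC calls", {
  ident <- build_consensus(rep("GGGTCTAGCCCAGCA", 30))
  expect_identical(ident$iupac, "GGGTCTAGCCCAGCA")
  expect_equal(ident$per_column_ic, rep(2, 15))
  expect_equal(ident$n_sites, 30)

  half <- build_consensus(c(rep("A", 15), rep("G", 15)))
  expect_identical(half$iupac, "R")
  expect_equal(half$per_column_ic, 1)

  expect_error(build_consensus(character()), "zero")
  expect_error(build_consensus(c("ACGT", "ACG")), "equal length")
})

test_that("consensus recovers the generating PWM from sampled sites", {
  pw <- default_seed_pwm()
  set.seed(10)
  sites <- vapply(1:59, function(i) {
    paste(vapply(seq_len(pw$width), function(j) {
      sample(c("A", "C", "G", "T"), 1, prob = pw$probs[, j])
    }, character(1)), collapse = "")
  }, character(1))
  cons <- build_consensus(sites)
  expect_gte(cor(as.vector(cons$pwm$probs), as.vector(pw$probs)), 0.9)
  # the strongly conserved core renders GGG ... CCC
  expect_identical(substr(cons$iupac, 1, 3), "GGG")
  expect_identical(substr(cons$iupac, 9, 11), "CCC")
})

test_that("kmers passing the scan threshold keep the GGG core", {
  sub <- seed_to_pwm("GGGTCT")  # first half of the seed
  enum <- oracle_all_scores(sub)
  thr <- score_threshold(sub, 1e-3)
  passing <- enum$scores >= thr
  expect_gt(sum(passing), 0)
  idx <- as.matrix(expand.grid(rep(list(1:4), 6)))[passing, , drop = FALSE]
  n_g <- rowSums(idx[, 1:3, drop = FALSE] == 3)  # base 3 is G
  expect_true(all(n_g >= 2))
})

test_that("MEME minimal format round-trips", {
  pw <- default_seed_pwm()
  f <- withr::local_tempfile(fileext = ".meme")
  write_meme(pw, f, name = "seed", nsites = 59)
  back <- read_meme(f)
  expect_equal(back$width, pw$width)
  expect_equal(back$probs, pw$probs, tolerance = 1e-5)
  expect_equal(back$background, pw$background, tolerance = 1e-5)
})

test_that("tidiers expose motif objects as tibbles", {
  cons <- build_consensus(rep("GGGTCTAGCCCAGCA", 10))
  td <- tidy(cons)
  expect_equal(nrow(td), 15 * 4)
  expect_true(all(c("position", "base", "prob", "ic", "iupac") %in%
                    names(td)))
  gl <- glance(cons)
  expect_equal(gl$width, 15)
  expect_equal(gl$n_sites, 10)
  p <- autoplot(cons)
  expect_s3_class(p, "ggplot")
})
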