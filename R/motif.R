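DNA_BASES <- c("A", "C", "G", "T")

# IUPAC letter -> base set (used both for seed construction and for
# consensus IUPAC calls)
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  M = c("A", "C"), R = c("A", "G"), W = c("A", "T"),
  S = c("C", "G"), Y = c("C", "T"), K = c("G", "T"),
  V = c("A", "C", "G"), H = c("A", "C", "T"),
  D = c("A", "G", "T"), B = c("C", "G", "T"),
  N = c("A", "C", "G", "T")
)

set_to_iupac <- function(bases) {
  key <- paste(sort(unique(bases)), collapse = "")
  codes <- vapply(IUPAC_SETS, function(b) paste(sort(b), collapse = ""),
                  character(1))
  names(codes)[match(key, codes)]
}

#' Construct a position weight matrix
#'
#' A PWM is a per-position base-probability model of a binding motif,
#' scored against sequence as background-relative log-odds (bits).
#'
#' @param probs 4 x width numeric matrix, rows A/C/G/T, columns summing
#'   to 1.
#' @param background Named base probabilities (default uniform).
#' @param pseudocount Pseudocount weight already folded into `probs`
#'   (recorded for provenance only).
#' @return A `pwm` object.
#' @export
pwm <- function(probs, background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                pseudocount = 0) {
  probs <- as.matrix(probs)
  if (nrow(probs) != 4) {
    abort("probs must have 4 rows (A, C, G, T).")
  }
  rownames(probs) <- DNA_BASES
  if (any(abs(colSums(probs) - 1) > 1e-9)) {
    abort("each PWM column must sum to 1.")
  }
  background <- background[DNA_BASES]
  if (abs(sum(background) - 1) > 1e-9) {
    abort("background must sum to 1.")
  }
  structure(
    list(probs = probs, background = background,
         width = ncol(probs), pseudocount = pseudocount),
    class = "pwm"
  )
}

#' @export
print.pwm <- function(x, ...) {
  cat("<pwm> width", x$width, "\n")
  print(round(x$probs, 3))
  invisible(x)
}

#' Reverse complement of DNA sequences
#'
#' @param seq Character vector of DNA sequences (IUPAC letters allowed).
#' @return Character vector of reverse complements.
#' @export
#' @examples
#' reverse_complement("GAGGGGTCTAACCCCTC")
reverse_complement <- function(seq) {
  out <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAStringSet(seq))
  )
  unname(out)
}

#' Build a PWM from a case-annotated IUPAC seed string
#'
#' The previously characterised binding site is printed as a
#' case-annotated string (e.g. `"GGGTCTAgCCCagCA"`): uppercase positions
#' are strongly conserved, lowercase weakly conserved. An uppercase base
#' receives probability `strong_weight` (split across the code's bases
#' for degenerate letters), a lowercase base `weak_weight`, with the
#' remainder spread uniformly over the other bases; `N` positions take
#' the background.
#'
#' @param iupac_seed Case-sensitive IUPAC string.
#' @param strong_weight,weak_weight Probabilities for upper/lowercase
#'   positions.
#' @param background Named base probabilities.
#' @return A [pwm()].
#' @export
#' @examples
#' seed_to_pwm("GGGTCTAgCCCagCA")$width  # 15
seed_to_pwm <- function(iupac_seed, strong_weight = 0.91, weak_weight = 0.55,
                        background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  letters_vec <- strsplit(iupac_seed, "")[[1]]
  if (length(letters_vec) == 0) {
    abort("empty seed string.")
  }
  cols <- lapply(letters_vec, function(ch) {
    up <- toupper(ch)
    if (!up %in% names(IUPAC_SETS)) {
      abort(paste0("invalid IUPAC letter in seed: '", ch, "'"))
    }
    if (up == "N") {
      return(background[DNA_BASES])
    }
    bases <- IUPAC_SETS[[up]]
    w <- if (ch == up) strong_weight else weak_weight
    col <- setNames(rep((1 - w) / (4 - length(bases)), 4), DNA_BASES)
    col[bases] <- w / length(bases)
    col
  })
  pwm(do.call(cbind, cols), background = background)
}

#' The default seed motif for binding-site scans
#'
#' PWM derived from the imperfect palindrome `GGGTCTAgCCCagCA`
#' characterised upstream of known regulon members, via [seed_to_pwm()]
#' with the default strong/weak weights.
#'
#' @param ... Passed to [seed_to_pwm()].
#' @return A [pwm()] of width 15.
#' @export
default_seed_pwm <- function(...) {
  seed_to_pwm("GGGTCTAgCCCagCA", ...)
}

# log2 odds matrix (4 x width)
log_odds_matrix <- function(pwm) {
  log2(pwm$probs / pwm$background)
}

#' Log-odds score of a k-mer against a PWM
#'
#' `sum_i log2(p_i(base_i) / background(base_i))`, in bits. Ambiguity
#' codes are not scored.
#'
#' @param pwm A [pwm()].
#' @param kmer String of length `pwm$width` over A/C/G/T.
#' @return Score in bits.
#' @export
log_odds_score <- function(pwm, kmer) {
  b <- strsplit(toupper(kmer), "")[[1]]
  if (length(b) != pwm$width) {
    abort("kmer length must equal PWM width.")
  }
  idx <- match(b, DNA_BASES)
  if (anyNA(idx)) {
    abort(paste0("non-ACGT character in kmer: ", kmer))
  }
  lod <- log_odds_matrix(pwm)
  sum(lod[cbind(idx, seq_along(idx))])
}

# Discretized exact null distribution of PWM scores.
# Column log-odds are rounded to an integer grid of `granularity` bits
# and the per-column score distributions under the background are
# convolved; the absolute error of any tail probability's score
# threshold is at most width * granularity.
pwm_score_distribution <- function(pwm, granularity = 1e-3) {
  lod <- log_odds_matrix(pwm)
  si <- round(lod / granularity)
  if (any(!is.finite(si))) {
    abort("PWM has zero-probability cells; add a pseudocount before scoring.")
  }
  bg <- pwm$background
  mins <- apply(si, 2, min)
  dist <- 1
  offset <- 0
  for (j in seq_len(pwm$width)) {
    shifts <- si[, j] - mins[j]
    newlen <- length(dist) + max(shifts)
    nd <- numeric(newlen)
    for (b in 1:4) {
      idx <- seq_along(dist) + shifts[b]
      nd[idx] <- nd[idx] + bg[b] * dist
    }
    dist <- nd
    offset <- offset + mins[j]
  }
  scores_int <- offset + seq_along(dist) - 1
  tail_p <- rev(cumsum(rev(dist)))
  list(
    granularity = granularity,
    scores_int = scores_int,
    density = dist,
    tail_p = tail_p
  )
}

# p-value lookup against a precomputed distribution
tail_p_lookup <- function(dist, score_bits) {
  q <- round(score_bits / dist$granularity)
  vapply(q, function(qi) {
    if (qi <= dist$scores_int[1]) {
      return(1)
    }
    if (qi > dist$scores_int[length(dist$scores_int)]) {
      return(0)
    }
    dist$tail_p[qi - dist$scores_int[1] + 1]
  }, numeric(1))
}

#' Minimal score passing a scan p-value threshold
#'
#' The smallest log-odds score (in bits, on the discretization grid)
#' whose exact p-value under the background model is at most
#' `p_threshold` -- the effective cutoff of a [scan_sequence()] run.
#'
#' @param pwm A [pwm()].
#' @param p_threshold Scan p-value threshold.
#' @param granularity Grid step in bits.
#' @return Score in bits (`Inf` if no score passes).
#' @export
score_threshold <- function(pwm, p_threshold = 1e-4, granularity = 1e-3) {
  dist <- pwm_score_distribution(pwm, granularity)
  pass <- dist$tail_p <= p_threshold
  if (!any(pass)) {
    return(Inf)
  }
  dist$scores_int[which(pass)[1]] * granularity
}

#' Exact p-value of a PWM score under the background model
#'
#' `P(score(K) >= score)` for a random k-mer drawn column-i.i.d. from
#' the background, computed by discretizing column log-odds to a
#' `granularity`-bit grid and convolving the column score
#' distributions. The score-threshold error is bounded by
#' `width * granularity`.
#'
#' @param pwm A [pwm()].
#' @param score Score in bits (vectorised).
#' @param granularity Grid step in bits.
#' @return Probabilities in `[0, 1]`, non-increasing in `score`.
#' @export
score_pvalue <- function(pwm, score, granularity = 1e-3) {
  dist <- pwm_score_distribution(pwm, granularity)
  tail_p_lookup(dist, score)
}

# integer-encode a DNA string; non-ACGT -> NA
encode_dna <- function(seq) {
  lut <- rep(NA_integer_, 256)
  lut[utf8ToInt("A")] <- 1L
  lut[utf8ToInt("C")] <- 2L
  lut[utf8ToInt("G")] <- 3L
  lut[utf8ToInt("T")] <- 4L
  lut[utf8ToInt(seq)]
}

# score every offset of an encoded sequence; windows containing
# non-ACGT letters score NA
scan_scores <- function(code, lod) {
  w <- ncol(lod)
  n <- length(code)
  if (n < w) {
    return(numeric(0))
  }
  npos <- n - w + 1L
  sc <- numeric(npos)
  for (j in seq_len(w)) {
    sc <- sc + lod[cbind(code[j:(j + npos - 1L)], j)]
  }
  sc
}

#' Scan a sequence with a PWM at a p-value threshold
#'
#' FiMO-style scan: every offset on both strands is scored; matches
#' whose exact score p-value (see [score_pvalue()]) is at or below
#' `p_threshold` are reported. Minus-strand hit coordinates refer to the
#' forward strand; `matched_sequence` is strand-corrected (the sequence
#' actually matching the motif). Palindromic hits found identically on
#' both strands are reported once, on the plus strand.
#'
#' @param seq DNA string.
#' @param pwm A [pwm()].
#' @param p_threshold Report hits with `p_value <= p_threshold`.
#' @param granularity Grid step for the score null distribution.
#' @return Tibble of hits (`start`, `end`, `strand`, `score`, `p_value`,
#'   `matched_sequence`) sorted by position; zero rows if the sequence
#'   is shorter than the motif.
#' @export
scan_sequence <- function(seq, pwm, p_threshold = 1e-4, granularity = 1e-3) {
  empty <- tibble::tibble(
    start = integer(), end = integer(), strand = character(),
    score = numeric(), p_value = numeric(), matched_sequence = character()
  )
  seq <- toupper(seq)
  L <- nchar(seq)
  w <- pwm$width
  if (L < w) {
    return(empty)
  }
  dist <- pwm_score_distribution(pwm, granularity)
  lod <- log_odds_matrix(pwm)
  # minimal grid score passing the threshold
  pass <- dist$tail_p <= p_threshold
  if (!any(pass)) {
    return(empty)
  }
  min_int <- dist$scores_int[which(pass)[1]]

  hits_for <- function(sequence, strand_label) {
    sc <- scan_scores(encode_dna(sequence), lod)
    qi <- round(sc / dist$granularity)
    keep <- which(!is.na(sc) & qi >= min_int)
    if (length(keep) == 0) {
      return(empty)
    }
    if (strand_label == "+") {
      start <- keep
    } else {
      start <- L - (keep + w - 1L) + 1L
    }
    tibble::tibble(
      start = as.integer(start),
      end = as.integer(start + w),
      strand = strand_label,
      score = sc[keep],
      p_value = tail_p_lookup(dist, sc[keep]),
      matched_sequence = substring(sequence, keep, keep + w - 1L)
    )
  }

  out <- dplyr::bind_rows(
    hits_for(seq, "+"),
    hits_for(reverse_complement(seq), "-")
  )
  out <- dplyr::arrange(out, .data$start, .data$strand)
  # palindrome-orientation tie: identical interval and score on both
  # strands -> keep the plus-strand record
  out |>
    dplyr::group_by(.data$start, .data$end, .data$score) |>
    dplyr::filter(dplyr::n() == 1 | .data$strand == "+") |>
    dplyr::ungroup()
}

#' Scan curated regions for motif hits
#'
#' Extracts each region's sequence from the genome, scans it with
#' [scan_sequence()], and reports hits in genome coordinates tagged by
#' region. Regions may contain several sites.
#'
#' @param regions Tibble with `region_id`, `replicon`, `start`, `end`.
#' @param genome Named character vector of replicon sequences.
#' @param pwm A [pwm()].
#' @param p_threshold Hit threshold (default `1e-4`).
#' @param granularity Score-grid step.
#' @return Tibble of hits with `region_id` and genome coordinates.
#' @export
scan_regions <- function(regions, genome, pwm, p_threshold = 1e-4,
                         granularity = 1e-3) {
  empty <- tibble::tibble(
    region_id = character(), replicon = character(),
    start = integer(), end = integer(), strand = character(),
    score = numeric(), p_value = numeric(), matched_sequence = character()
  )
  if (nrow(regions) == 0) {
    return(empty)
  }
  out <- purrr::map_dfr(seq_len(nrow(regions)), function(i) {
    r <- regions[i, ]
    if (!r$replicon %in% names(genome)) {
      abort(paste0("replicon not in genome: ", r$replicon))
    }
    s <- substr(genome[[r$replicon]], r$start, r$end - 1L)
    h <- scan_sequence(s, pwm, p_threshold, granularity)
    if (nrow(h) == 0) {
      return(h[0, ])
    }
    dplyr::mutate(h,
                  region_id = r$region_id,
                  replicon = r$replicon,
                  start = .data$start + r$start - 1L,
                  end = .data$end + r$start - 1L) |>
      dplyr::select("region_id", "replicon", dplyr::everything())
  })
  if (nrow(out) == 0) empty else out
}

#' Summarise a region scan
#'
#' @param hits Hit tibble from [scan_regions()].
#' @param regions The scanned regions.
#' @return One-row tibble: `n_regions`, `n_regions_with_hit`, `n_hits`.
#' @export
scan_summary <- function(hits, regions) {
  tibble::tibble(
    n_regions = nrow(regions),
    n_regions_with_hit = length(unique(hits$region_id)),
    n_hits = nrow(hits)
  )
}

#' Build a consensus motif from aligned hits
#'
#' Stacks the strand-corrected matched sequences of a motif scan (all of
#' one width, so the alignment is an ungapped stack in the scanning
#' PWM's register), forms a position frequency matrix with an optional
#' pseudocount, and reports per-column information content and an IUPAC
#' consensus: per column, the minimal IUPAC code covering all bases at
#' frequency >= 0.25, uppercase where the information content reaches
#' 1 bit.
#'
#' @param hits Hit tibble (uses `matched_sequence`) or a character
#'   vector of equal-length sites.
#' @param background Named base probabilities.
#' @param pseudocount Total pseudocount weight distributed by the
#'   background (0 keeps pure observed frequencies).
#' @return A `consensus_motif`: list with `pwm`, `iupac`,
#'   `per_column_ic` (bits), `n_sites`, `sites`.
#' @export
build_consensus <- function(hits,
                            background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                            pseudocount = 0) {
  sites <- if (is.data.frame(hits)) hits$matched_sequence else hits
  if (length(sites) == 0) {
    abort("cannot build a consensus from zero sites.")
  }
  sites <- toupper(sites)
  w <- unique(nchar(sites))
  if (length(w) != 1) {
    abort("all sites must have equal length.")
  }
  mat <- do.call(rbind, strsplit(sites, ""))
  counts <- apply(mat, 2, function(col) {
    tabulate(match(col, DNA_BASES), nbins = 4)
  })
  rownames(counts) <- DNA_BASES
  n <- length(sites)
  probs <- sweep(counts + pseudocount * background[DNA_BASES],
                 2, n + pseudocount, "/")
  # information content: relative entropy vs background
  # (for a uniform background this is 2 + sum p log2 p per column)
  ic <- apply(probs, 2, function(p) {
    nz <- p > 0
    sum(p[nz] * log2(p[nz] / background[DNA_BASES][nz]))
  })
  iupac <- vapply(seq_len(w), function(j) {
    bases <- DNA_BASES[probs[, j] >= 0.25]
    if (length(bases) == 0) bases <- DNA_BASES[which.max(probs[, j])]
    code <- set_to_iupac(bases)
    if (ic[j] >= 1) toupper(code) else tolower(code)
  }, character(1))
  structure(
    list(
      pwm = pwm(probs, background = background, pseudocount = pseudocount),
      iupac = paste(iupac, collapse = ""),
      per_column_ic = unname(ic),
      n_sites = n,
      sites = sites
    ),
    class = "consensus_motif"
  )
}

#' @export
print.consensus_motif <- function(x, ...) {
  cat("<consensus_motif> width", x$pwm$width, "from", x$n_sites, "sites\n")
  cat("  IUPAC:", x$iupac, "\n")
  cat("  IC (bits):", paste(round(x$per_column_ic, 2), collapse = " "), "\n")
  invisible(x)
}

#' Write / read a PWM in MEME minimal text format
#'
#' The minimal motif text format (version line, alphabet, background
#' frequencies, one `MOTIF` block with a letter-probability matrix),
#' interoperable with standard motif-scanning suites.
#'
#' @param pwm A [pwm()].
#' @param path Output path.
#' @param name Motif name.
#' @param nsites Number of sites the motif was built from.
#' @return `path`, invisibly.
#' @export
write_meme <- function(pwm, path, name = "motif_1", nsites = 20) {
  bg <- pwm$background
  lines <- c(
    "MEME version 4",
    "",
    "ALPHABET= ACGT",
    "",
    "strands: + -",
    "",
    "Background letter frequencies",
    sprintf("A %.5f C %.5f G %.5f T %.5f", bg["A"], bg["C"], bg["G"], bg["T"]),
    "",
    paste("MOTIF", name),
    sprintf("letter-probability matrix: alength= 4 w= %d nsites= %d E= 0",
            pwm$width, nsites),
    apply(pwm$probs, 2, function(col) {
      sprintf(" %.6f %.6f %.6f %.6f", col[1], col[2], col[3], col[4])
    })
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_meme
#' @export
read_meme <- function(path) {
  lines <- readLines(path)
  bg <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  bg_at <- grep("^Background letter frequencies", lines)
  if (length(bg_at)) {
    tok <- strsplit(trimws(lines[bg_at[1] + 1]), "\\s+")[[1]]
    vals <- as.numeric(tok[seq(2, length(tok), by = 2)])
    names(vals) <- tok[seq(1, length(tok), by = 2)]
    bg <- vals[DNA_BASES]
  }
  mat_at <- grep("^letter-probability matrix", lines)
  if (length(mat_at) == 0) {
    abort(paste0("no letter-probability matrix in ", path))
  }
  w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[mat_at[1]]))
  rows <- lines[(mat_at[1] + 1):(mat_at[1] + w)]
  probs <- t(vapply(rows, function(r) {
    as.numeric(strsplit(trimws(r), "\\s+")[[1]])
  }, numeric(4), USE.NAMES = FALSE))
  pwm(t(probs), background = bg)
}
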