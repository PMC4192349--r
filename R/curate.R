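#' Curation parameters
#'
#' Operationalises the biological peak-curation criteria: minimum fold
#' enrichment over the control, the strand-offset twin-peak morphology
#' of point-source binding, proximity of the peak to a gene's promoter
#' or 5' UTR, and misregulation of a flanking gene in the
#' regulator-deletion mutant. Every filter can be switched off to audit
#' the funnel.
#'
#' @param min_fold_enrichment Minimum peak fold enrichment (default 3).
#' @param min_misregulation_fold Minimum |signed fold change| at either
#'   timepoint for a gene to count as misregulated (default 1.5; the
#'   published tables contain |FC| values near 1, so the default is
#'   permissive).
#' @param smooth_bp Moving-average width for twin-peak summit detection.
#' @param min_shift,max_shift Acceptable plus-to-minus summit offsets in
#'   bp (`max_shift` defaults to 2x the expected fragment length).
#' @param min_correlation Minimum shifted strand cross-correlation.
#' @param min_reads_per_strand Peaks with fewer read starts on either
#'   strand fail the twin-peak test with a sentinel score.
#' @param upstream_limit Promoter window upstream of the ORF start (bp).
#' @param enable_fold,enable_twin,enable_misregulation,enable_proximity
#'   Toggles for the four filters.
#' @return A `curation_params` list.
#' @export
curation_params <- function(min_fold_enrichment = 3,
                            min_misregulation_fold = 1.5,
                            smooth_bp = 25,
                            min_shift = 20,
                            max_shift = 500,
                            min_correlation = 0.5,
                            min_reads_per_strand = 10,
                            upstream_limit = 500,
                            enable_fold = TRUE,
                            enable_twin = TRUE,
                            enable_misregulation = TRUE,
                            enable_proximity = TRUE) {
  structure(
    list(min_fold_enrichment = min_fold_enrichment,
         min_misregulation_fold = min_misregulation_fold,
         smooth_bp = as.integer(smooth_bp),
         min_shift = as.integer(min_shift),
         max_shift = as.integer(max_shift),
         min_correlation = min_correlation,
         min_reads_per_strand = as.integer(min_reads_per_strand),
         upstream_limit = as.integer(upstream_limit),
         enable_fold = enable_fold,
         enable_twin = enable_twin,
         enable_misregulation = enable_misregulation,
         enable_proximity = enable_proximity),
    class = "curation_params"
  )
}

#' Fold-enrichment filter
#'
#' `TRUE` iff the peak's fold enrichment reaches the threshold
#' (boundary inclusive: a peak at exactly 3-fold passes the default).
#'
#' @param peaks Peak tibble with `fold_enrichment`.
#' @param threshold Minimum fold (default 3).
#' @return Logical vector.
#' @export
fold_filter <- function(peaks, threshold = 3) {
  peaks$fold_enrichment >= threshold
}

#' Score the twin-peak morphology of a peak
#'
#' A transcription factor bound at a point source produces read-start
#' pileups offset between strands by roughly the fragment length: the
#' plus-strand summit upstream, the minus-strand summit downstream.
#' Summits are the argmax of the smoothed per-strand read-start density
#' within the peak; the correlation score is the maximum Pearson
#' correlation between the plus profile and the minus profile shifted
#' back by `d` over `d` in `[min_shift, max_shift]`. The peak is a twin
#' peak iff the summit shift is positive, at most `max_shift`, the
#' correlation reaches `min_correlation`, and both strands carry at
#' least `min_reads_per_strand` read starts (otherwise the score is the
#' sentinel `NA`).
#'
#' @param peak One-row peak tibble.
#' @param plus_track,minus_track Per-strand `read_start` coverage
#'   tracks covering the peak and its `max_shift` flanks.
#' @param params A [curation_params()].
#' @return One-row tibble: `plus_summit`, `minus_summit`, `shift`,
#'   `correlation_score`, `is_twin`.
#' @export
twin_peak_score <- function(peak, plus_track, minus_track,
                            params = curation_params()) {
  L <- length(plus_track)
  lo <- max(1L, peak$start - params$max_shift)
  hi <- min(L, peak$end - 1L + params$max_shift)
  plus <- as.numeric(unclass(plus_track)[lo:hi])
  minus <- as.numeric(unclass(minus_track)[lo:hi])
  in_peak <- (peak$start:(peak$end - 1L)) - lo + 1L
  n_plus <- sum(plus[in_peak])
  n_minus <- sum(minus[in_peak])
  fail <- function(score = NA_real_, p_s = NA_integer_, m_s = NA_integer_,
                   shift = NA_integer_) {
    tibble::tibble(plus_summit = p_s, minus_summit = m_s, shift = shift,
                   correlation_score = score, is_twin = FALSE)
  }
  if (n_plus < params$min_reads_per_strand ||
      n_minus < params$min_reads_per_strand) {
    return(fail())
  }
  sp <- smooth_track(plus, params$smooth_bp)
  sm <- smooth_track(minus, params$smooth_bp)
  plus_summit <- lo + in_peak[which.max(sp[in_peak])] - 1L
  minus_summit <- lo + in_peak[which.max(sm[in_peak])] - 1L
  shift <- minus_summit - plus_summit
  shifts <- params$min_shift:params$max_shift
  n <- length(sp)
  cors <- vapply(shifts, function(d) {
    if (d >= n - 2) {
      return(NA_real_)
    }
    a <- sp[1:(n - d)]
    b <- sm[(1 + d):n]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) {
      return(NA_real_)
    }
    cor(a, b)
  }, numeric(1))
  score <- if (all(is.na(cors))) NA_real_ else max(cors, na.rm = TRUE)
  is_twin <- !is.na(score) &&
    shift > 0 && shift <= params$max_shift &&
    score >= params$min_correlation
  tibble::tibble(
    plus_summit = as.integer(plus_summit),
    minus_summit = as.integer(minus_summit),
    shift = as.integer(shift),
    correlation_score = score,
    is_twin = is_twin
  )
}

# proximity of one peak to one gene, on the gene's coding strand
classify_proximity <- function(peak_start, peak_end, gene, tss_positions,
                               upstream_limit = 500) {
  if (is.null(gene) || is.na(gene$gene_id)) {
    return(NA_character_)
  }
  overlaps <- function(a1, a2, b1, b2) a1 < b2 && b1 < a2
  if (gene$strand == "+") {
    orf_start <- gene$start
    entirely_3prime <- peak_start >= gene$end
    upstream_win <- c(orf_start - upstream_limit, orf_start)
    leader <- function(t) t < orf_start && overlaps(peak_start, peak_end,
                                                    t, orf_start)
  } else {
    orf_start <- gene$end - 1L   # 5' start of a minus-strand gene
    entirely_3prime <- peak_end <= gene$start
    upstream_win <- c(orf_start + 1L, orf_start + 1L + upstream_limit)
    leader <- function(t) t > orf_start && overlaps(peak_start, peak_end,
                                                    orf_start + 1L, t + 1L)
  }
  if (entirely_3prime) {
    return("not_applicable")
  }
  # a peak between an assigned TSS and the start codon sits in the
  # transcribed leader (5' UTR): the TSS-based call takes precedence
  # over the bare distance rule
  if (length(tss_positions) && any(vapply(tss_positions, leader, logical(1)))) {
    return("downstream_of_TSS")
  }
  if (overlaps(peak_start, peak_end, upstream_win[1], upstream_win[2])) {
    return("within_500bp_upstream")
  }
  "beyond_500bp_upstream"
}

#' Annotate peaks with flanking genes and proximity categories
#'
#' For each peak, finds the nearest gene entirely to its left and right,
#' and classifies the peak's position relative to each on that gene's
#' coding strand: `within_500bp_upstream` (the peak overlaps the
#' `upstream_limit`-bp window before the ORF start),
#' `downstream_of_TSS` (the peak lies between an assigned TSS and the
#' start codon, i.e. in the 5' UTR/leader), `beyond_500bp_upstream`, or
#' `not_applicable` (the peak is entirely 3' of the gene and unlikely
#' to regulate it).
#'
#' @param peaks Peak tibble.
#' @param genes Gene-model tibble (sorted by coordinate).
#' @param tss TSS tibble (`position`, `gene_id`).
#' @param upstream_limit Promoter window size in bp (default 500).
#' @return `peaks` with `gene_left`, `proximity_left`, `gene_right`,
#'   `proximity_right` columns added.
#' @export
annotate_region <- function(peaks, genes, tss, upstream_limit = 500) {
  if (nrow(genes) == 0) {
    abort("annotate_region requires a non-empty gene list.")
  }
  genes <- dplyr::arrange(genes, .data$start)
  one <- function(i) {
    p <- peaks[i, ]
    # flanking genes include genes the peak partially overlaps (a peak
    # over a gene's 5' end flanks that gene); left = rightmost gene
    # starting before the peak, right = leftmost gene ending after it
    left_idx <- which(genes$replicon == p$replicon & genes$start < p$start)
    right_idx <- which(genes$replicon == p$replicon & genes$end > p$end)
    gl <- if (length(left_idx)) genes[max(left_idx), ] else NULL
    gr <- if (length(right_idx)) genes[min(right_idx), ] else NULL
    tss_for <- function(g) {
      if (is.null(g)) integer(0) else tss$position[tss$gene_id == g$gene_id]
    }
    tibble::tibble(
      gene_left = if (is.null(gl)) NA_character_ else gl$gene_id,
      proximity_left = if (is.null(gl)) NA_character_ else
        classify_proximity(p$start, p$end, gl, tss_for(gl), upstream_limit),
      gene_right = if (is.null(gr)) NA_character_ else gr$gene_id,
      proximity_right = if (is.null(gr)) NA_character_ else
        classify_proximity(p$start, p$end, gr, tss_for(gr), upstream_limit)
    )
  }
  dplyr::bind_cols(peaks, purrr::map_dfr(seq_len(nrow(peaks)), one))
}

#' Is a gene misregulated in the mutant?
#'
#' `TRUE` iff the absolute signed fold change reaches `min_fold` at
#' either timepoint. Sentinel fields propagate as `NA` (indeterminate):
#' a peak is never excluded because its neighbour's expression could
#' not be measured. The `"n / 0"` convention (expressed in the wild
#' type, zero mutant reads) has infinite magnitude and is always
#' misregulated.
#'
#' @param gene_id Gene identifiers (vectorised); matched against the
#'   expression table's `gene_id` and, when present, `locus_tag`.
#' @param expr Expression tibble with `fc_0h`, `fc_6h` and their
#'   sentinel columns (see [read_expression_table()]).
#' @param min_fold Magnitude threshold (default 1.5).
#' @return Logical vector (`NA` = indeterminate or gene absent).
#' @export
misregulation_flag <- function(gene_id, expr, min_fold = 1.5) {
  idx <- match(gene_id, expr$gene_id)
  if ("locus_tag" %in% names(expr)) {
    idx2 <- match(gene_id, expr$locus_tag)
    idx[is.na(idx)] <- idx2[is.na(idx)]
  }
  vapply(idx, function(i) {
    if (is.na(i)) {
      return(NA)
    }
    vals <- c(expr$fc_0h[i], expr$fc_6h[i])
    hit <- abs(vals) >= min_fold
    if (any(hit, na.rm = TRUE)) {
      return(TRUE)
    }
    if (any(is.na(vals))) {
      return(NA)
    }
    FALSE
  }, logical(1))
}

#' Curate called peaks into a final region set
#'
#' Applies the four biological filters to a peak set and emits curated
#' regions in the published table schema, carrying a per-filter audit
#' trail (`pass_fold`, `pass_twin`, `pass_misregulation`,
#' `pass_proximity`, `retained`) so the peak-funnel reduction can be
#' reconstructed exactly. A peak is retained iff every enabled filter
#' passes; the misregulation filter fails only when all flanking genes
#' are measurably not misregulated, and the proximity filter passes
#' when at least one flank is in the promoter window or downstream of a
#' TSS (equivalently, the peak overlaps an annotated 5' UTR).
#'
#' @param peaks Peak tibble (from [call_peaks()] or
#'   [call_peaks_replicated()]).
#' @param ip_reads Read tibble used to build per-strand tracks for the
#'   twin-peak score.
#' @param genes,tss,expr Gene models, TSS list and expression table.
#' @param params A [curation_params()].
#' @param replicon_length Replicon length in bp.
#' @return Tibble of all input peaks with annotation, audit columns and
#'   `retained`; filter retained rows for the final region set.
#' @export
curate_regions <- function(peaks, ip_reads, genes, tss, expr,
                           params = curation_params(),
                           replicon_length = NULL) {
  if (nrow(peaks) == 0) {
    return(dplyr::mutate(peaks, retained = logical(0)))
  }
  if (is.null(replicon_length)) {
    replicon_length <- max(ip_reads$end) - 1L
  }
  plus <- build_coverage(ip_reads, replicon_length, strand_filter = "+",
                         mode = "read_start")
  minus <- build_coverage(ip_reads, replicon_length, strand_filter = "-",
                          mode = "read_start")
  twin <- purrr::map_dfr(seq_len(nrow(peaks)), function(i) {
    twin_peak_score(peaks[i, ], plus, minus, params)
  })
  ann <- annotate_region(peaks, genes, tss, params$upstream_limit)
  mis_left <- misregulation_flag(ann$gene_left, expr,
                                 params$min_misregulation_fold)
  mis_right <- misregulation_flag(ann$gene_right, expr,
                                  params$min_misregulation_fold)
  pass_mis <- purrr::map_lgl(seq_len(nrow(ann)), function(i) {
    flags <- c(mis_left[i], mis_right[i])
    # exclusion needs positive evidence: all neighbours known-unmoved
    if (any(flags, na.rm = TRUE) || any(is.na(flags))) TRUE else FALSE
  })
  qualifying <- c("within_500bp_upstream", "downstream_of_TSS")
  pass_prox <- (ann$proximity_left %in% qualifying) |
    (ann$proximity_right %in% qualifying)
  out <- dplyr::bind_cols(ann, twin)
  out$misregulated_left <- mis_left
  out$misregulated_right <- mis_right
  out$pass_fold <- fold_filter(out, params$min_fold_enrichment)
  out$pass_twin <- twin$is_twin
  out$pass_misregulation <- pass_mis
  out$pass_proximity <- pass_prox
  checks <- cbind(
    if (params$enable_fold) out$pass_fold else TRUE,
    if (params$enable_twin) out$pass_twin else TRUE,
    if (params$enable_misregulation) out$pass_misregulation else TRUE,
    if (params$enable_proximity) out$pass_proximity else TRUE
  )
  out$retained <- apply(checks, 1, all)
  out
}

#' Format curated regions in the published table schema
#'
#' @param curated Output of [curate_regions()] (retained rows are
#'   selected here).
#' @param expr Expression table used to print flanking fold changes.
#' @return Tibble with the curated-region columns (coordinates, length,
#'   flanking genes with 6-h fold change, proximity categories,
#'   binding-site flag placeholder).
#' @export
curated_region_table <- function(curated, expr) {
  kept <- curated[curated$retained, , drop = FALSE]
  sent <- if ("fc_6h_sentinel" %in% names(expr)) {
    expr$fc_6h_sentinel
  } else {
    ifelse(is.na(expr$fc_6h), "na",
           ifelse(is.infinite(expr$fc_6h), "zero_mutant", "none"))
  }
  fc6 <- function(gene_id) {
    idx <- match(gene_id, expr$gene_id)
    ifelse(is.na(idx), NA_character_,
           ifelse(sent[idx] != "none",
                  c(na = "NA", low_coverage = "Low coverage",
                    zero_mutant = "n / 0")[sent[idx]],
                  as.character(signif(expr$fc_6h[idx], 3))))
  }
  tibble::tibble(
    region_id = kept$name,
    replicon = kept$replicon,
    start = kept$start,
    end = kept$end,
    length_bp = interval_length(kept),
    gene_left = kept$gene_left,
    fc_left = fc6(kept$gene_left),
    proximity_left = kept$proximity_left,
    gene_right = kept$gene_right,
    fc_right = fc6(kept$gene_right),
    proximity_right = kept$proximity_right
  )
}
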