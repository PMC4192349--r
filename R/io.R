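#' Read a genome FASTA file
#'
#' Sequences are uppercased on input. Letters outside A/C/G/T are
#' preserved but reported with a warning, so degenerate or masked bases
#' are never silently dropped.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector, one element per replicon.
#' @export
read_genome_fasta <- function(path) {
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0) {
    abort(paste0("empty FASTA file: ", path))
  }
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids)) {
    abort(paste0("duplicate replicon ids in ", path, ": ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  out <- toupper(as.character(seqs))
  names(out) <- ids
  n_bad <- sum(vapply(out, function(s) {
    nchar(gsub("[ACGT]", "", s))
  }, integer(1)))
  if (n_bad > 0) {
    warn(paste0(n_bad, " non-ACGT letters present in ", path,
                " (preserved as-is)."))
  }
  out
}

#' Write a genome FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(seqs, path) {
  x <- Biostrings::BStringSet(seqs)
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

# strand conversion between internal (".") and GRanges ("*") vocabularies
strand_to_gr <- function(s) ifelse(s == ".", "*", s)
strand_from_gr <- function(s) {
  s <- as.character(s)
  ifelse(s == "*", ".", s)
}

intervals_to_granges <- function(x) {
  GenomicRanges::GRanges(
    seqnames = x$replicon,
    ranges = IRanges::IRanges(start = x$start, end = x$end - 1L),
    strand = strand_to_gr(x$strand)
  )
}

#' Read aligned reads (or any features) from a BED6 file
#'
#' BED is 0-based half-open; internally the package is 1-based
#' end-exclusive, so a BED line `chr 0 40` becomes `start = 1, end = 41`
#' (length 40 either way).
#'
#' @param path Path to a BED file.
#' @param require_strand Alignments must carry a strand; set `FALSE` for
#'   strand-less feature files.
#' @return Interval tibble (`replicon`, `start`, `end`, `name`, `score`,
#'   `strand`).
#' @export
read_alignments_bed <- function(path, require_strand = TRUE) {
  gr <- rtracklayer::import(path, format = "BED")
  strand <- strand_from_gr(GenomicRanges::strand(gr))
  if (require_strand && any(strand == ".")) {
    abort(paste0("alignment BED records without strand in ", path))
  }
  nm <- S4Vectors::mcols(gr)$name %||% rep(NA_character_, length(gr))
  sc <- S4Vectors::mcols(gr)$score %||% rep(0, length(gr))
  sc[is.na(sc)] <- 0
  genome_intervals(
    replicon = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr) + 1L,
    strand = strand,
    name = as.character(nm),
    score = as.numeric(sc)
  )
}

#' Write intervals to a BED6 file
#'
#' Inverse of [read_alignments_bed()]; coordinates are converted back to
#' BED's 0-based half-open convention.
#'
#' @param records Interval tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(records, path) {
  gr <- intervals_to_granges(records)
  nm <- records$name
  nm[is.na(nm)] <- "."
  S4Vectors::mcols(gr)$name <- nm
  S4Vectors::mcols(gr)$score <- records$score
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Write called peaks as BED6+ (extra columns appended)
#'
#' Standard BED6 columns followed by `fold_enrichment`, `min_p`,
#' `support` and `summit` (1-based). The file remains readable by BED
#' tools that ignore trailing columns; [read_peaks_bed()] restores the
#' full peak tibble.
#'
#' @param peaks Peak tibble from [call_peaks()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peaks_bed <- function(peaks, path) {
  out <- tibble::tibble(
    chrom = peaks$replicon,
    chromStart = peaks$start - 1L,
    chromEnd = peaks$end - 1L,
    name = peaks$name,
    score = round(pmin(1000, peaks$fold_enrichment * 100)),
    strand = ".",
    fold_enrichment = peaks$fold_enrichment,
    min_p = peaks$min_p,
    support = peaks$support,
    summit = peaks$summit
  )
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

#' @rdname write_peaks_bed
#' @export
read_peaks_bed <- function(path) {
  x <- readr::read_tsv(
    path,
    col_names = c("chrom", "chromStart", "chromEnd", "name", "score",
                  "strand", "fold_enrichment", "min_p", "support", "summit"),
    col_types = "ciicdcddii",
    progress = FALSE
  )
  tibble::tibble(
    replicon = x$chrom,
    start = x$chromStart + 1L,
    end = x$chromEnd + 1L,
    name = x$name,
    fold_enrichment = x$fold_enrichment,
    min_p = x$min_p,
    support = x$support,
    summit = x$summit,
    strand = "."
  )
}

#' Read gene models from GFF3
#'
#' Expects `gene` features with `ID` attributes (locus tags) and
#' optional `five_prime_UTR` children. Returns one row per gene with the
#' UTR, when present, folded into `utr5_start`/`utr5_end`.
#'
#' @param path Path to a GFF3 file.
#' @return Tibble with `gene_id`, `replicon`, `start`, `end`, `strand`,
#'   `utr5_start`, `utr5_end` (internal 1-based end-exclusive).
#' @export
read_gene_models <- function(path) {
  g <- rtracklayer::readGFF(path)
  genes <- g[g$type == "gene", , drop = FALSE]
  if (nrow(genes) == 0) {
    abort(paste0("no gene features in ", path))
  }
  utrs <- g[g$type == "five_prime_UTR", , drop = FALSE]
  out <- tibble::tibble(
    gene_id = as.character(genes$ID),
    replicon = as.character(genes$seqid),
    start = as.integer(genes$start),
    end = as.integer(genes$end) + 1L,
    strand = strand_from_gr(genes$strand),
    utr5_start = NA_integer_,
    utr5_end = NA_integer_
  )
  if (nrow(utrs) > 0) {
    parent <- vapply(utrs$Parent, function(p) as.character(p)[1], character(1))
    idx <- match(parent, out$gene_id)
    out$utr5_start[idx] <- as.integer(utrs$start)
    out$utr5_end[idx] <- as.integer(utrs$end) + 1L
  }
  dplyr::arrange(out, .data$replicon, .data$start)
}

#' Write gene models to GFF3
#'
#' @param genes Gene-model tibble (see [read_gene_models()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(genes, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = genes$replicon,
    ranges = IRanges::IRanges(start = genes$start, end = genes$end - 1L),
    strand = strand_to_gr(genes$strand),
    type = "gene",
    ID = genes$gene_id
  )
  has_utr <- !is.na(genes$utr5_start)
  if (any(has_utr)) {
    u <- genes[has_utr, ]
    ugr <- GenomicRanges::GRanges(
      seqnames = u$replicon,
      ranges = IRanges::IRanges(start = u$utr5_start, end = u$utr5_end - 1L),
      strand = strand_to_gr(u$strand),
      type = "five_prime_UTR",
      ID = paste0(u$gene_id, ".utr5")
    )
    S4Vectors::mcols(ugr)$Parent <- u$gene_id
    S4Vectors::mcols(gr)$Parent <- NA_character_
    gr <- c(gr, ugr)
  }
  rtracklayer::export(gr, path, format = "GFF3")
  invisible(path)
}

#' Read / write transcription start sites
#'
#' TSS lists are an input to the pipeline (mapped experimentally, e.g. by
#' differential RNA-seq), never computed here. Plain TSV with columns
#' `replicon`, `position`, `strand`, `gene_id`.
#'
#' @param path TSV path.
#' @return Tibble of TSS records.
#' @export
read_tss <- function(path) {
  x <- readr::read_tsv(path, col_types = "cicc", progress = FALSE)
  need <- c("replicon", "position", "strand", "gene_id")
  if (!all(need %in% names(x))) {
    abort(paste0("TSS table must have columns: ", paste(need, collapse = ", ")))
  }
  x
}

#' @rdname read_tss
#' @param tss TSS tibble.
#' @export
write_tss <- function(tss, path) {
  readr::write_tsv(tss, path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Signed fold changes and their sentinel domain
# ---------------------------------------------------------------------------

#' Parse signed fold-change fields with sentinels
#'
#' Expression tables use signed fold changes whose magnitude is the ratio
#' of the larger to the smaller value and whose sign marks the direction
#' of change in the mutant (negative = lower in the mutant). Three
#' sentinels occur and form a closed domain: `"NA"` (not
#' applicable/not measured), `"Low coverage"` (too few reads to call), and
#' `"n / 0"` (n reads in the wild type dropped to zero in the mutant --
#' an infinite-magnitude decrease). Anything else that fails numeric
#' parsing is an error, never a silent `NA`.
#'
#' @param x Character vector of fold-change fields.
#' @return Tibble with `value` (numeric; `-Inf` for `"n / 0"`, `NA` for
#'   the other sentinels) and `sentinel` (one of `"none"`, `"na"`,
#'   `"low_coverage"`, `"zero_mutant"`).
#' @export
#' @examples
#' parse_signed_fc(c("-8.0", "11 / 0", "Low coverage", "NA"))
parse_signed_fc <- function(x) {
  x <- as.character(x)
  value <- rep(NA_real_, length(x))
  sentinel <- rep("none", length(x))
  trimmed <- trimws(x)
  is_na <- is.na(trimmed) | trimmed == "NA"
  is_low <- !is_na & tolower(trimmed) == "low coverage"
  is_zero <- !is_na & grepl("^[0-9]+(\\.[0-9]+)?\\s*/\\s*0$", trimmed)
  sentinel[is_na] <- "na"
  sentinel[is_low] <- "low_coverage"
  sentinel[is_zero] <- "zero_mutant"
  value[is_zero] <- -Inf
  plain <- !(is_na | is_low | is_zero)
  parsed <- suppressWarnings(as.numeric(trimmed[plain]))
  if (any(is.na(parsed))) {
    bad <- trimmed[plain][is.na(parsed)]
    abort(paste0("unknown fold-change token(s): ",
                 paste(unique(bad), collapse = ", ")))
  }
  value[plain] <- parsed
  tibble::tibble(value = value, sentinel = sentinel)
}

#' Serialize a wild-type/mutant pair as a signed fold-change field
#'
#' Inverse convention of [parse_signed_fc()]: when the mutant count is
#' zero but the wild type is expressed, the field is the string
#' `"<wt> / 0"`; when both are below `low_cutoff` the field is
#' `"Low coverage"`; otherwise the signed ratio (negative when the
#' mutant is lower).
#'
#' @param wt,mut Non-negative counts (or abundances) per gene.
#' @param low_cutoff Both values below this serialize as low coverage.
#' @param digits Significant digits for the printed ratio.
#' @return Character vector.
#' @export
format_signed_fc <- function(wt, mut, low_cutoff = 5, digits = 3) {
  stopifnot(length(wt) == length(mut))
  out <- character(length(wt))
  low <- wt < low_cutoff & mut < low_cutoff
  zero_mut <- !low & mut == 0 & wt > 0
  zero_wt <- !low & wt == 0 & mut > 0
  plain <- !(low | zero_mut | zero_wt)
  out[low] <- "Low coverage"
  out[zero_mut] <- paste0(format(wt[zero_mut], trim = TRUE), " / 0")
  out[zero_wt] <- paste0("0 / ", format(mut[zero_wt], trim = TRUE))
  ratio <- ifelse(mut[plain] <= wt[plain],
                  -wt[plain] / pmax(mut[plain], .Machine$double.xmin),
                  mut[plain] / wt[plain])
  # a tie (no change) prints +1, not -1
  ratio[wt[plain] == mut[plain]] <- 1
  out[plain] <- as.character(signif(ratio, digits))
  out
}

# footnote letters of the curated-region table <-> proximity categories
footnote_to_proximity <- c(
  none = "within_500bp_upstream",
  c = "downstream_of_TSS",
  d = "beyond_500bp_upstream",
  b = "not_applicable"
)

#' Read a curated-region table (published Table-1 schema)
#'
#' Parses the packaged transcription of the study's curated ChIP-region
#' table (or any file in the same schema): coordinates, printed length,
#' flanking genes with footnote-coded proximity categories, signed
#' fold-change fields with sentinels, and the binding-site Yes/No flag.
#' One row whose printed end coordinate is inconsistent with its printed
#' length carries `end_unreliable = TRUE` and is excluded from
#' length-arithmetic checks.
#'
#' @param path TSV path; defaults to the packaged fixture.
#' @return Tibble of curated regions with parsed fold changes
#'   (`fc_left`, `fc_left_sentinel`, ...), proximity categories and a
#'   logical `has_binding_site`.
#' @export
#' @examples
#' regions <- read_region_table()
#' nrow(regions)            # 26
#' sum(regions$has_binding_site)  # 20
read_region_table <- function(path = system.file("extdata",
                                                 "table1_regions.tsv",
                                                 package = "hetrseq")) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  need <- c("region_id", "replicon", "start", "end", "printed_length",
            "end_unreliable", "gene_left", "fc_left", "footnote_left",
            "gene_right", "fc_right", "footnote_right", "binding_site")
  if (!all(need %in% names(raw))) {
    abort(paste0("region table ", path, " must have columns: ",
                 paste(setdiff(need, names(raw)), collapse = ", ")))
  }
  if (nrow(raw) == 0) {
    return(tibble::tibble())
  }
  check_row <- function(ok, what) {
    if (any(!ok)) {
      abort(paste0("malformed region table row(s) ",
                   paste(which(!ok) + 1L, collapse = ", "),
                   " in ", path, ": ", what))
    }
  }
  start <- suppressWarnings(as.integer(raw$start))
  end <- suppressWarnings(as.integer(raw$end))
  plen <- suppressWarnings(as.integer(raw$printed_length))
  check_row(!is.na(start) & !is.na(end) & !is.na(plen), "non-integer coordinates")
  check_row(raw$footnote_left %in% names(footnote_to_proximity) &
              raw$footnote_right %in% names(footnote_to_proximity),
            "unknown footnote code")
  check_row(raw$binding_site %in% c("Yes", "No"), "binding_site must be Yes/No")
  fl <- parse_signed_fc(raw$fc_left)
  fr <- parse_signed_fc(raw$fc_right)
  tibble::tibble(
    region_id = raw$region_id,
    replicon = raw$replicon,
    start = start,
    end = end,
    printed_length = plen,
    end_unreliable = toupper(raw$end_unreliable) == "TRUE",
    gene_left = raw$gene_left,
    fc_left = fl$value,
    fc_left_sentinel = fl$sentinel,
    proximity_left = unname(footnote_to_proximity[raw$footnote_left]),
    gene_right = raw$gene_right,
    fc_right = fr$value,
    fc_right_sentinel = fr$sentinel,
    proximity_right = unname(footnote_to_proximity[raw$footnote_right]),
    has_binding_site = raw$binding_site == "Yes"
  )
}

#' Read an expression fold-change table (published Table-2 schema)
#'
#' Columns are the signed RPKM fold changes between wild type and the
#' regulator-deletion mutant at 0 h and 6 h after nitrogen step-down,
#' plus optional wild-type time-course ratios. Sentinels are parsed via
#' [parse_signed_fc()]; the `"n / 0"` convention (reads present in the
#' wild type, none in the mutant) parses as an infinite-magnitude
#' decrease.
#'
#' @param path TSV path; defaults to the packaged fixture.
#' @return Tibble with `gene_id`, `locus_tag`, parsed `fc_0h`/`fc_6h`
#'   (+ sentinel columns) and any remaining columns as character.
#' @export
#' @examples
#' expr <- read_expression_table()
#' expr[expr$locus_tag == "all0521", c("fc_0h", "fc_6h")]  # -13, -8
read_expression_table <- function(path = system.file("extdata",
                                                     "table2_expression.tsv",
                                                     package = "hetrseq")) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  need <- c("gene_id", "fc_wt0_mut0", "fc_wt6_mut6")
  if (!all(need %in% names(raw))) {
    abort(paste0("expression table must have columns: ",
                 paste(need, collapse = ", ")))
  }
  f0 <- parse_signed_fc(raw$fc_wt0_mut0)
  f6 <- parse_signed_fc(raw$fc_wt6_mut6)
  # "name (locus_tag)" rows are addressable by either identifier
  locus <- ifelse(grepl("\\(([^)]+)\\)", raw$gene_id),
                  sub(".*\\(([^)]+)\\).*", "\\1", raw$gene_id),
                  raw$gene_id)
  extra <- raw[setdiff(names(raw), need)]
  dplyr::bind_cols(
    tibble::tibble(
      gene_id = raw$gene_id,
      locus_tag = locus,
      fc_0h = f0$value,
      fc_0h_sentinel = f0$sentinel,
      fc_6h = f6$value,
      fc_6h_sentinel = f6$sentinel
    ),
    extra
  )
}

#' Write an expression table in the serialized Table-2 schema
#'
#' @param expr Tibble with character fold-change columns `fc_wt0_mut0`,
#'   `fc_wt6_mut6` (already serialized, e.g. by [simulate_expression()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(expr, path) {
  readr::write_tsv(expr, path)
  invisible(path)
}

#' Read a gene-to-category annotation table
#'
#' Two-column TSV (`gene_id`, `category`); genes may carry several
#' categories on separate rows.
#'
#' @param path TSV path.
#' @return Tibble with `gene_id` and `category`.
#' @export
read_category_annotations <- function(path) {
  x <- readr::read_tsv(path, col_types = "cc", progress = FALSE)
  if (!all(c("gene_id", "category") %in% names(x))) {
    abort("annotation table must have columns gene_id, category")
  }
  x
}
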