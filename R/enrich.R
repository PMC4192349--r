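#' Genome-relative category fold enrichment of target genes
#'
#' For each functional category, the fold enrichment is the fraction of
#' distinct hit genes annotated to the category divided by the fraction
#' of genome genes annotated to it:
#' `fold(c) = (|hits in c| / |hit genes|) / (|genome in c| / |genome|)`.
#' Genes may carry several categories (counted once per category);
#' categories absent from the hits are reported with fold 0. A
#' hypergeometric upper-tail p-value annotates each category's
#' significance.
#'
#' @param hit_genes Character vector of target gene ids (must be a
#'   subset of `genome_genes`).
#' @param annotations Tibble with `gene_id`, `category`.
#' @param genome_genes Character vector of all gene ids in the genome.
#' @return Tibble per category: `n_hits`, `n_genome`, `hit_fraction`,
#'   `genome_fraction`, `fold`, `p_value`.
#' @export
category_fold_enrichment <- function(hit_genes, annotations, genome_genes) {
  hit_genes <- unique(hit_genes)
  genome_genes <- unique(genome_genes)
  if (length(hit_genes) == 0) abort("empty hit gene set.")
  if (length(genome_genes) == 0) abort("empty genome gene set.")
  if (!all(hit_genes %in% genome_genes)) {
    abort("hit_genes must be a subset of genome_genes.")
  }
  ann <- dplyr::distinct(annotations[annotations$gene_id %in% genome_genes, ])
  cats <- sort(unique(ann$category))
  purrr::map_dfr(cats, function(cc) {
    in_cat <- unique(ann$gene_id[ann$category == cc])
    n_genome <- length(in_cat)
    n_hits <- sum(hit_genes %in% in_cat)
    hit_fraction <- n_hits / length(hit_genes)
    genome_fraction <- n_genome / length(genome_genes)
    tibble::tibble(
      category = cc,
      n_hits = as.integer(n_hits),
      n_genome = as.integer(n_genome),
      hit_fraction = hit_fraction,
      genome_fraction = genome_fraction,
      fold = hit_fraction / genome_fraction,
      p_value = hypergeometric_tail(length(genome_genes), n_genome,
                                    length(hit_genes), n_hits)
    )
  })
}

#' Hypergeometric upper-tail probability
#'
#' `P(X >= k)` where `X` counts category members among `n_hits` draws
#' without replacement from a population of `n_genome` genes of which
#' `n_category` are in the category. Computed via the stable survival
#' function of the hypergeometric distribution.
#'
#' @param n_genome Population size.
#' @param n_category Category size within the population.
#' @param n_hits Number of draws.
#' @param k_observed Observed category members among the draws.
#' @return Probability in `[0, 1]`.
#' @export
hypergeometric_tail <- function(n_genome, n_category, n_hits, k_observed) {
  if (k_observed > min(n_category, n_hits) || n_category > n_genome ||
      n_hits > n_genome || any(c(n_genome, n_category, n_hits, k_observed) < 0)) {
    abort("inconsistent hypergeometric counts.")
  }
  phyper(k_observed - 1, n_category, n_genome - n_category, n_hits,
         lower.tail = FALSE)
}

#' Flag categories enriched at least `min_fold`-fold
#'
#' Boundary inclusive ("at least 3-fold" keeps a category at exactly
#' 3.0).
#'
#' @param table Category table from [category_fold_enrichment()].
#' @param min_fold Fold threshold (default 3).
#' @return The enriched subset of `table`.
#' @export
flag_enriched <- function(table, min_fold = 3) {
  table[table$fold >= min_fold, , drop = FALSE]
}
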