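#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble

#' Tidy a PWM into a long tibble
#'
#' @param x A [pwm()].
#' @param ... Unused.
#' @return Tibble with `position`, `base`, `prob`, `background`.
#' @export
tidy.pwm <- function(x, ...) {
  tidyr::expand_grid(position = seq_len(x$width), base = DNA_BASES) |>
    dplyr::mutate(
      prob = purrr::map2_dbl(.data$position, .data$base,
                             ~ x$probs[.y, .x]),
      background = x$background[.data$base]
    )
}

#' @rdname tidy.pwm
#' @export
glance.pwm <- function(x, ...) {
  lod <- log_odds_matrix(x)
  tibble::tibble(
    width = x$width,
    max_score = sum(apply(lod, 2, max)),
    min_score = sum(apply(lod, 2, min)),
    pseudocount = x$pseudocount
  )
}

#' Tidy a consensus motif
#'
#' One row per position and base, with per-column information content
#' and the IUPAC call attached.
#'
#' @param x A `consensus_motif` from [build_consensus()].
#' @param ... Unused.
#' @return Long tibble (`position`, `base`, `prob`, `ic`, `iupac`).
#' @export
tidy.consensus_motif <- function(x, ...) {
  iupac <- strsplit(x$iupac, "")[[1]]
  tidy.pwm(x$pwm) |>
    dplyr::mutate(
      ic = x$per_column_ic[.data$position],
      iupac = iupac[.data$position]
    )
}

#' @rdname tidy.consensus_motif
#' @export
glance.consensus_motif <- function(x, ...) {
  tibble::tibble(
    width = x$pwm$width,
    n_sites = x$n_sites,
    total_ic = sum(x$per_column_ic),
    mean_ic = mean(x$per_column_ic),
    iupac = x$iupac
  )
}

#' One-row summary of a pipeline run
#'
#' @param x A `run_manifest` from [run_pipeline()].
#' @param ... Unused.
#' @return Tibble of the funnel counts.
#' @export
glance.run_manifest <- function(x, ...) {
  tibble::as_tibble(x$counts)
}
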