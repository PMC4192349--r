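#' Plot per-column composition and information content of a motif
#'
#' A stacked per-position base-probability chart with the per-column
#' information content (bits) overlaid as a line, plus the IUPAC
#' consensus along the axis -- a plain-ggplot2 rendering of the usual
#' sequence-logo content.
#'
#' @param object A `consensus_motif` (or [pwm()], for which IC is
#'   computed against its background).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.consensus_motif <- function(object, ...) {
  td <- tidy.consensus_motif(object)
  ic <- tibble::tibble(position = seq_along(object$per_column_ic),
                       ic = object$per_column_ic)
  labels <- strsplit(object$iupac, "")[[1]]
  ggplot2::ggplot(td, ggplot2::aes(x = .data$position, y = .data$prob,
                                   fill = .data$base)) +
    ggplot2::geom_col(width = 0.85) +
    ggplot2::geom_line(data = ic,
                       ggplot2::aes(x = .data$position, y = .data$ic / 2),
                       inherit.aes = FALSE, linewidth = 0.6) +
    ggplot2::geom_point(data = ic,
                        ggplot2::aes(x = .data$position, y = .data$ic / 2),
                        inherit.aes = FALSE, size = 1) +
    ggplot2::scale_x_continuous(breaks = seq_along(labels), labels = labels) +
    ggplot2::scale_y_continuous(
      name = "base probability",
      sec.axis = ggplot2::sec_axis(~ . * 2, name = "information (bits)")
    ) +
    ggplot2::labs(x = "consensus position",
                  title = paste0("Consensus motif (", object$n_sites,
                                 " sites)")) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.consensus_motif
#' @export
plot_motif <- function(object, ...) {
  autoplot.consensus_motif(object, ...)
}

#' Plot the strand-resolved read-start profile around a peak
#'
#' Shows the smoothed plus- and minus-strand 5'-end densities across a
#' peak and its flanks: a genuine binding site shows the twin-peak
#' morphology (plus summit left of minus summit, offset by roughly the
#' fragment length).
#'
#' @param peak One-row peak tibble.
#' @param plus_track,minus_track Per-strand `read_start` coverage
#'   tracks.
#' @param flank Flank width in bp to display (default 500).
#' @param smooth_bp Moving-average width (default 25).
#' @return A ggplot object.
#' @export
plot_peak_profile <- function(peak, plus_track, minus_track, flank = 500,
                              smooth_bp = 25) {
  L <- length(plus_track)
  lo <- max(1L, peak$start - flank)
  hi <- min(L, peak$end - 1L + flank)
  pos <- lo:hi
  df <- dplyr::bind_rows(
    tibble::tibble(position = pos, strand = "+",
                   density = smooth_track(unclass(plus_track)[pos], smooth_bp)),
    tibble::tibble(position = pos, strand = "-",
                   density = smooth_track(unclass(minus_track)[pos], smooth_bp))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$density,
                                   colour = .data$strand)) +
    ggplot2::geom_line() +
    ggplot2::annotate("rect", xmin = peak$start, xmax = peak$end - 1L,
                      ymin = -Inf, ymax = Inf, alpha = 0.08) +
    ggplot2::labs(y = "smoothed read-start density",
                  title = paste0("Peak ", peak$name, " (fold ",
                                 signif(peak$fold_enrichment, 3), ")")) +
    ggplot2::theme_minimal()
}

#' Plot category fold enrichment
#'
#' Horizontal bars of genome-relative fold enrichment per functional
#' category, with the `min_fold` rule-in threshold marked.
#'
#' @param table Category table from [category_fold_enrichment()].
#' @param min_fold Threshold line (default 3).
#' @return A ggplot object.
#' @export
plot_enrichment <- function(table, min_fold = 3) {
  tab <- dplyr::arrange(table, .data$fold)
  tab$category <- factor(tab$category, levels = tab$category)
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$fold, y = .data$category)) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = min_fold, linetype = "dashed") +
    ggplot2::labs(x = "fold enrichment over genome", y = NULL) +
    ggplot2::theme_minimal()
}
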