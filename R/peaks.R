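#' Peak-caller parameters
#'
#' Defaults reproduce the published settings of the workflow: a 100-bp
#' non-overlapping window for the Poisson enrichment test and a 5%
#' false discovery rate against the non-enriched control, with the
#' remaining knobs (pseudocount, merge gap, minimum IP reads per tested
#' window) made explicit and configurable.
#'
#' @param window Window size in bp (default 100).
#' @param fdr_q FDR level for Benjamini-Hochberg selection (default 0.05).
#' @param pseudocount Floor for the Poisson rate from the scaled control.
#' @param merge_gap Maximum number of non-significant windows bridged
#'   when merging runs of significant windows into peaks (default 1;
#'   0 merges adjacent windows only).
#' @param min_ip_reads Windows with fewer IP reads are not tested (they
#'   cannot be significant; excluding them changes the BH denominator).
#' @param test Window test form. `"binomial"` (default) is the exact
#'   conditional test for comparing two Poisson counts: under the null
#'   of equal (library-scaled) rates,
#'   `k_ip | k_ip + k_ctrl ~ Binomial(k_ip + k_ctrl, s/(1+s))`, which
#'   accounts for control sampling noise and keeps the false discovery
#'   rate at its nominal level. `"poisson"` treats the scaled control
#'   count as a known rate (`lambda = max(pseudocount, s * k_ctrl)`),
#'   which is anti-conservative when control counts are noisy and is
#'   provided for comparison only.
#' @return A `caller_params` list.
#' @export
caller_params <- function(window = 100, fdr_q = 0.05, pseudocount = 0.5,
                          merge_gap = 1, min_ip_reads = 1,
                          test = c("binomial", "poisson")) {
  if (window <= 0) abort("window must be positive.")
  if (fdr_q <= 0 || fdr_q >= 1) abort("fdr_q must be in (0, 1).")
  if (pseudocount <= 0) abort("pseudocount must be positive.")
  structure(
    list(window = as.integer(window), fdr_q = fdr_q,
         pseudocount = pseudocount, merge_gap = as.integer(merge_gap),
         min_ip_reads = as.integer(min_ip_reads),
         test = match.arg(test)),
    class = "caller_params"
  )
}

#' Tile a read-start coverage track into fixed windows
#'
#' Consecutive non-overlapping windows tile the replicon (last window
#' truncated); counts sum to the number of reads on the track.
#'
#' @param track A `coverage_track` in `read_start` mode (or any
#'   per-position integer vector).
#' @param window Window size in bp.
#' @return Tibble with `window_idx`, `start`, `end` (end-exclusive,
#'   truncated at the replicon end) and `count`.
#' @export
window_counts <- function(track, window) {
  if (window <= 0) abort("window must be positive.")
  L <- length(track)
  n_win <- ceiling(L / window)
  starts <- (seq_len(n_win) - 1L) * as.integer(window) + 1L
  ends <- pmin(starts + as.integer(window), L + 1L)
  cs <- c(0, cumsum(as.numeric(track)))
  counts <- cs[ends] - cs[starts]
  tibble::tibble(
    window_idx = seq_len(n_win),
    start = starts,
    end = ends,
    count = as.integer(counts)
  )
}

#' Library-size normalization factor
#'
#' Scales control window counts to the IP library depth:
#' `s = n_ip / n_ctrl`.
#'
#' @param n_ip,n_ctrl Total mapped reads per library.
#' @return The ratio `n_ip / n_ctrl`.
#' @export
normalization_factor <- function(n_ip, n_ctrl) {
  if (n_ctrl <= 0) abort("control library size must be positive.")
  n_ip / n_ctrl
}

#' Upper-tail Poisson probability
#'
#' `P(X >= k)` for `X ~ Poisson(lambda)`, computed with the survival
#' function (no `1 - CDF` subtraction), so extreme tails do not
#' underflow to zero prematurely.
#'
#' @param k Observed count (vectorised, >= 0).
#' @param lambda Expected count under the null (> 0).
#' @return Probabilities in `[0, 1]`.
#' @export
#' @examples
#' poisson_upper_tail(3, 1)  # 1 - exp(-1) * (1 + 1 + 1/2)
poisson_upper_tail <- function(k, lambda) {
  if (any(k < 0)) abort("k must be >= 0.")
  if (any(lambda <= 0)) abort("lambda must be positive.")
  ppois(k - 1, lambda, lower.tail = FALSE)
}

#' Benjamini-Hochberg selection at FDR level q
#'
#' Standard step-up: with sorted p-values `p_(1) <= ... <= p_(m)`,
#' reject all `p <= p_(i*)` where `i*` is the largest `i` with
#' `p_(i) <= i q / m`.
#'
#' @param p_values Numeric vector in `[0, 1]`.
#' @param q FDR level in `(0, 1)`.
#' @return Logical vector of selections, same order as the input.
#' @export
bh_select <- function(p_values, q = 0.05) {
  if (q <= 0 || q >= 1) abort("q must be in (0, 1).")
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    abort("p-values must lie in [0, 1].")
  }
  if (length(p_values) == 0) {
    return(logical(0))
  }
  p.adjust(p_values, method = "BH") <= q
}

#' Split reads into technical replicates
#'
#' Each read is independently assigned to one of `n_splits` files with
#' equal probability (a multinomial partition), mirroring the published
#' random three-way split used to assess peak reproducibility.
#'
#' @param reads Interval tibble of reads.
#' @param n_splits Number of replicates (default 3).
#' @param seed Integer seed.
#' @return List of `n_splits` read tibbles partitioning the input.
#' @export
split_replicates <- function(reads, n_splits = 3, seed) {
  set.seed(seed)
  assignment <- sample.int(n_splits, nrow(reads), replace = TRUE)
  lapply(seq_len(n_splits), function(i) reads[assignment == i, , drop = FALSE])
}

# merge significant window indices into runs, bridging up to
# merge_gap intervening non-significant windows (the twin-peak
# morphology leaves a dip at the site center that must not split the
# peak in two)
merge_windows <- function(idx, merge_gap) {
  if (length(idx) == 0) {
    return(list())
  }
  idx <- sort(idx)
  brk <- c(0, cumsum(diff(idx) - 1 > merge_gap))
  split(idx, brk)
}

#' Call enriched peaks with a windowed Poisson test
#'
#' The genome is tiled into non-overlapping windows; per window the IP
#' read-start count is tested for enrichment over the library-scaled
#' control (`s = n_ip / n_ctrl`) with the exact conditional binomial
#' test for two Poisson counts by default, or an upper-tail Poisson
#' test against `lambda = max(pseudocount, s * k_ctrl)` (see
#' [caller_params()]). Windows with at least
#' `min_ip_reads` IP reads enter Benjamini-Hochberg selection at
#' `fdr_q`; runs of significant windows (index gap <= `merge_gap`)
#' merge into peaks. Each peak reports its pooled counts, fold
#' enrichment over the scaled control, minimum window p-value, and the
#' summit (position of maximal IP read-body coverage).
#'
#' @param ip_reads,ctrl_reads Read tibbles (single replicon).
#' @param params A [caller_params()].
#' @param replicon_length Replicon length in bp (default: rightmost
#'   read end).
#' @return Peak tibble (`replicon`, `start`, `end`, `name`, `k_ip`,
#'   `k_ctrl`, `k_ctrl_norm`, `fold_enrichment`, `min_p`, `summit`,
#'   `n_windows`, `support`, `strand`). Empty IP input yields zero rows.
#' @export
call_peaks <- function(ip_reads, ctrl_reads, params = caller_params(),
                       replicon_length = NULL) {
  empty <- tibble::tibble(
    replicon = character(), start = integer(), end = integer(),
    name = character(), k_ip = integer(), k_ctrl = integer(),
    k_ctrl_norm = numeric(), fold_enrichment = numeric(),
    min_p = numeric(), summit = integer(), n_windows = integer(),
    support = integer(), strand = character()
  )
  if (nrow(ip_reads) == 0) {
    return(empty)
  }
  replicon <- unique(c(ip_reads$replicon, ctrl_reads$replicon))
  if (length(replicon) > 1) {
    abort("call_peaks expects a single shared replicon.")
  }
  if (is.null(replicon_length)) {
    replicon_length <- max(ip_reads$end, ctrl_reads$end) - 1L
  }
  ip_start <- build_coverage(ip_reads, replicon_length, mode = "read_start")
  ct_start <- build_coverage(ctrl_reads, replicon_length, mode = "read_start")
  win_ip <- window_counts(ip_start, params$window)
  win_ct <- window_counts(ct_start, params$window)
  s <- normalization_factor(nrow(ip_reads), max(1, nrow(ctrl_reads)))
  lambda <- pmax(params$pseudocount, s * win_ct$count)
  p <- if (params$test == "binomial") {
    # exact conditional two-Poisson comparison: P(X >= k_ip) for
    # X ~ Binom(k_ip + k_ctrl, s / (1 + s))
    stats::pbinom(win_ip$count - 1L, win_ip$count + win_ct$count,
                  s / (1 + s), lower.tail = FALSE)
  } else {
    poisson_upper_tail(win_ip$count, lambda)
  }
  testable <- win_ip$count >= params$min_ip_reads
  sig <- logical(nrow(win_ip))
  sig[testable] <- bh_select(p[testable], params$fdr_q)
  if (!any(sig)) {
    return(empty)
  }
  runs <- merge_windows(win_ip$window_idx[sig], params$merge_gap)
  body <- build_coverage(ip_reads, replicon_length, mode = "read_body")
  peaks <- purrr::map_dfr(seq_along(runs), function(i) {
    idx <- runs[[i]]
    start <- win_ip$start[idx[1]]
    end <- win_ip$end[idx[length(idx)]]
    k_ip <- sum(win_ip$count[idx])
    k_ctrl <- sum(win_ct$count[idx])
    span <- start:(end - 1L)
    tibble::tibble(
      replicon = replicon,
      start = start,
      end = end,
      name = sprintf("peak_%03d", i),
      k_ip = as.integer(k_ip),
      k_ctrl = as.integer(k_ctrl),
      k_ctrl_norm = s * k_ctrl,
      fold_enrichment = k_ip / max(params$pseudocount, s * k_ctrl),
      min_p = min(p[idx]),
      summit = as.integer(span[which.max(unclass(body)[span])]),
      n_windows = length(idx),
      support = NA_integer_,
      strand = "."
    )
  })
  dplyr::arrange(peaks, .data$start)
}

#' Retain peaks supported by technical replicates
#'
#' Peaks from the full-data call are kept iff they overlap (by at least
#' one bp) a peak in at least `min_support` of the replicate peak sets;
#' the achieved support count is recorded.
#'
#' @param peaks Full-data peak tibble.
#' @param replicate_peak_sets List of peak tibbles, one per replicate.
#' @param min_support Minimum number of supporting replicates (default 2).
#' @return Filtered peak tibble with `support` filled in.
#' @export
consensus_peaks <- function(peaks, replicate_peak_sets, min_support = 2) {
  if (min_support > length(replicate_peak_sets)) {
    abort("min_support cannot exceed the number of replicate peak sets.")
  }
  if (nrow(peaks) == 0) {
    return(peaks)
  }
  support <- Reduce(`+`, lapply(replicate_peak_sets, function(rp) {
    as.integer(count_overlaps(peaks, rp) > 0)
  }))
  peaks$support <- as.integer(support)
  peaks[peaks$support >= min_support, , drop = FALSE]
}

#' Full-data peak call with replicate-consistency filtering
#'
#' Runs [call_peaks()] on the full IP sample, splits the IP reads into
#' `n_splits` technical replicates, re-calls peaks on each with
#' identical parameters, and retains full-data peaks supported by at
#' least `min_support` replicates.
#'
#' @inheritParams call_peaks
#' @param n_splits,min_support Replicate design (default 3, 2).
#' @param seed Integer seed for the read split.
#' @return List with `peaks` (retained), `peaks_raw` (full-data call)
#'   and `replicate_peaks` (list of per-replicate calls).
#' @export
call_peaks_replicated <- function(ip_reads, ctrl_reads,
                                  params = caller_params(),
                                  replicon_length = NULL,
                                  n_splits = 3, min_support = 2, seed) {
  full <- call_peaks(ip_reads, ctrl_reads, params, replicon_length)
  splits <- split_replicates(ip_reads, n_splits, seed)
  rep_calls <- lapply(splits, function(r) {
    call_peaks(r, ctrl_reads, params, replicon_length)
  })
  list(
    peaks = consensus_peaks(full, rep_calls, min_support),
    peaks_raw = full,
    replicate_peaks = rep_calls
  )
}
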