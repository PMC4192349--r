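# Independent oracles and small scenario builders used across the suite.
# Each oracle is deliberately written with a different algorithm than the
# package implementation it checks.

# character-wise complement-and-reverse (no Biostrings)
oracle_revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A",
            a = "t", c = "g", g = "c", t = "a", N = "N", n = "n")
  chars <- strsplit(s, "")[[1]]
  paste(rev(unname(comp[chars])), collapse = "")
}

# log-space series for P(Poisson(lambda) >= k): sum_{i>=k} exp(i log l - l - log i!)
oracle_poisson_tail <- function(k, lambda, terms = 400) {
  i <- k:(k + terms)
  logs <- i * log(lambda) - lambda - lgamma(i + 1)
  m <- max(logs)
  exp(m) * sum(exp(logs - m))
}

# O(m^2) brute-force BH step-up
oracle_bh <- function(p, q) {
  m <- length(p)
  ord <- order(p)
  istar <- 0
  for (i in seq_len(m)) {
    if (p[ord[i]] <= i * q / m) istar <- i
  }
  if (istar == 0) {
    return(rep(FALSE, m))
  }
  p <= p[ord[istar]]
}

# hypergeometric upper tail by enumeration over all C(N, n) draws
oracle_hyper_tail <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  in_cat <- draws <= K  # label genes 1..K as the category
  mean(colSums(in_cat) >= k)
}

# exact score distribution by exhaustive enumeration of all 4^w kmers
# (returns the sorted vector of scores; each kmer has prob prod(bg))
oracle_all_scores <- function(pwm) {
  w <- pwm$width
  lod <- log2(pwm$probs / pwm$background)
  idx <- as.matrix(expand.grid(rep(list(1:4), w)))
  sc <- numeric(nrow(idx))
  for (j in seq_len(w)) {
    sc <- sc + lod[cbind(idx[, j], j)]
  }
  pr <- apply(idx, 1, function(r) prod(pwm$background[r]))
  list(scores = sc, probs = pr)
}

oracle_exact_pvalue <- function(enum, s) {
  sum(enum$probs[enum$scores >= s])
}

# independent per-character log-odds scorer (no matrix indexing)
oracle_log_odds <- function(pwm, kmer) {
  total <- 0
  for (j in seq_len(nchar(kmer))) {
    b <- substr(kmer, j, j)
    total <- total + log2(pwm$probs[b, j]) - log2(pwm$background[[b]])
  }
  unname(total)
}

# random PWM with no zero cells
random_pwm <- function(w, seed) {
  set.seed(seed)
  probs <- matrix(stats::rgamma(4 * w, shape = 1) + 0.05, nrow = 4)
  probs <- sweep(probs, 2, colSums(probs), "/")
  pwm(probs)
}

# O(n * m) interval-overlap counting (loop form, no vectorised trickery)
oracle_count_overlaps <- function(x, y) {
  out <- integer(nrow(x))
  for (i in seq_len(nrow(x))) {
    n <- 0L
    for (j in seq_len(nrow(y))) {
      if (x$replicon[i] == y$replicon[j] &&
          x$start[i] < y$end[j] && y$start[j] < x$end[i]) {
        n <- n + 1L
      }
    }
    out[i] <- n
  }
  out
}

# mirror a set of intervals through the midpoint of a length-L genome
reflect_intervals <- function(df, L) {
  out <- df
  out$start <- L - df$end + 2L
  out$end <- L - df$start + 2L
  out$strand <- chartr("+-", "-+", df$strand)
  out
}

reflect_genes <- function(genes, L) {
  out <- reflect_intervals(genes, L)
  u1 <- L - genes$utr5_end + 2L
  u2 <- L - genes$utr5_start + 2L
  out$utr5_start <- u1
  out$utr5_end <- u2
  out
}

reflect_tss <- function(tss, L) {
  out <- tss
  out$position <- L - tss$position + 1L
  out$strand <- chartr("+-", "-+", tss$strand)
  out
}

reflect_genome_seq <- function(seq) reverse_complement(seq)

# small coupled study used by curation/pipeline unit tests (a few
# seconds, not the full acceptance-scale run)
small_study <- function(seed = 404) {
  cfg <- sim_config(genome_length = 3e5, n_sites = 6, n_reads_ip = 6e4,
                    n_reads_control = 6e4, n_genes = 60, seed = seed)
  simulate_chipseq_study(cfg, n_regulatory = 4, n_decoy = 2)
}

small_called <- function(study, seed = 505) {
  call_peaks_replicated(study$reads_ip, study$reads_ctrl, caller_params(),
                        replicon_length = study$cfg$genome_length,
                        seed = seed)
}
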