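---
title: "Methods: peak calling, curation and binding-site discovery in hetrseq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: peak calling, curation and binding-site discovery in hetrseq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hetrseq)
```

hetrseq implements a complete bacterial ChIP-seq analysis chain of the
kind used to map the regulon of HetR, the master regulator of heterocyst
differentiation in filamentous cyanobacteria: windowed enrichment peak
calling of an immunoprecipitated (IP) sample against a non-enriched
wild-type control, technical-replicate consistency filtering, biological
peak curation, position-weight-matrix (PWM) binding-site discovery in the
curated regions, consensus-motif construction, and functional-category
fold enrichment of the target genes. Because the original sequencing data
are not required for any of this logic, the package ships a
synthetic-data generator that reproduces the statistical structure of the
experiment; every stage is exercised and tested against it.

## Coordinate conventions

Intervals are 1-based, start-inclusive and end-exclusive, so that an
interval's length is exactly `end - start`. This is the convention under
which the published curated-region table's printed lengths (431, 955, ...)
equal the difference of its printed coordinates, and it converts to BED's
0-based half-open coordinates by subtracting one from both ends. One
fixture row prints a length inconsistent with its coordinates; it is
flagged `end_unreliable` and excluded from length arithmetic rather than
silently corrected.

Signed expression fold changes use the published convention: magnitude is
the ratio of the larger to the smaller value, the sign marks the
direction of change in the deletion mutant (negative = lower in the
mutant), and three sentinels form a closed domain — `NA`,
`"Low coverage"`, and `"n / 0"` (reads in the wild type, none in the
mutant), the last parsing as an infinite-magnitude decrease. Sentinels
are never silently coerced to numbers.

## The synthetic study

`simulate_genome()` draws an i.i.d. sequence at a specified GC content
(default 0.41, matching the AT-rich chromosome of the organism the
workflow was built for). `simulate_genes()` lays non-overlapping genes
(Gamma-distributed lengths, mean 900 bp) with intergenic gaps of
1.2–2.4 kb, a transcription start site (TSS) 20–100 bp upstream of each
start codon on the coding strand, and the leader recorded as a 5′ UTR.

`plant_sites()` writes motif instances sampled column-wise from a PWM
into the genome on uniformly chosen strands. The scenario builder
`simulate_chipseq_study()` additionally conditions each planted sequence
on scoring at or above the scan threshold (`score_threshold(pwm, 1e-4)`):
a site identified by motif scanning passes the threshold by construction,
whereas an unconditioned PWM sample misses it a few percent of the time,
which would make "every planted region contains a discoverable site"
false by accident rather than by biology. `plant_sites()` itself defaults
to unconditioned sampling, so the per-column base frequencies of planted
sites remain an unbiased draw from the PWM (and are tested as such).

`simulate_reads()` models the sequencing geometry that produces the
twin-peak morphology diagnostic of point-source binding. A fragment
center is drawn uniformly (background) or, with probability
`p_site = min(1, enrichment_ratio * n_sites * fragment_mean /
genome_length)`, at a planted-site center plus Gaussian jitter. Fragment
length is Gaussian (`fragment_mean = 250` bp, `fragment_sd = 40` bp,
clipped below at the 40-bp read length); the read is the fragment's
5′-most 40 bp on a uniformly chosen strand. Under this mapping the local
read-start density at a site is approximately `enrichment_ratio` times
the background density, which is what "10× enrichment" means throughout
the package. The jitter standard deviation is tied to `fragment_sd` so a
zero-variance fragment model yields exactly deterministic read
placement — plus-strand starts at `center - fragment_mean/2`, minus-strand
ends at `center + fragment_mean/2` — the geometry the twin-peak score
relies on. Reads overhanging the genome are re-drawn. There is no
sequencing-error, quality, or duplicate model: reads arrive as aligned
intervals, since alignment is outside the package's scope.

`simulate_expression()` gives each gene a log-normal expected count
(median 200 reads), divides the mutant expectation by `effect` (default
8) for regulator-dependent genes, applies log-normal measurement noise
(`noise_cv = 0.1`, an ordinary biological coefficient of variation for
RNA-seq), and rounds; weakly expressed, strongly dependent genes can
therefore hit zero mutant reads and exercise the `"n / 0"` serialization.
RPKM is computed with the standard reads-per-kilobase-per-million
definition, `count / ((len/1000) * (lib/1e6))`.

What the generator does *not* emulate: mappability and copy-number
structure, GC bias, sonication-site preference, operon structure,
overdispersed (non-Poisson) background, or a control harvested under a
slightly different condition than the IP (the real control was collected
two hours later than the IP sample; the simulator treats both as
same-condition, so any time-offset background shift is not modeled).
Passing tests therefore demonstrate correctness of the statistical
machinery under a clean Poisson background, not robustness to every
artifact of real libraries.

## Peak calling

The replicon is tiled with non-overlapping 100-bp windows (the published
window size; overlapping tiling buys little at 250-bp fragments and
complicates the multiple-testing accounting). Per window the IP
read-start count `k_ip` is compared with the control count `k_ctrl`,
scaled by the library-size ratio `s = n_ip / n_ctrl`.

The test form deserves a note. Treating the scaled control count as a
*known* Poisson rate (`p = P(Pois(max(eps, s*k_ctrl)) >= k_ip)`) ignores
the sampling noise of the control itself and is anti-conservative:
windows where the control happens to fluctuate low receive spuriously
small p-values, and at realistic depths (a few reads per window) this
produces large numbers of false windows regardless of the
Benjamini–Hochberg (BH) step that follows — false discovery rate (FDR)
control is then impossible. hetrseq therefore defaults to the exact
conditional test for comparing two Poisson rates: under the null of
equal scaled rates,

$$ k_{ip} \mid (k_{ip} + k_{ctrl} = t) \;\sim\; \mathrm{Binomial}\!\left(t, \frac{s}{1+s}\right), $$

and the window p-value is the upper tail of that binomial. This is the
uniformly most powerful unbiased test for the two-Poisson comparison,
reduces to the naive form as the control depth grows, and empirically
keeps null peak calls at their nominal level (the acceptance suite
measures the null false-discovery proportion directly). The known-rate
Poisson form remains available as `caller_params(test = "poisson")`, and
`poisson_upper_tail()` is exported in its own right; `lambda =
max(pseudocount, s * k_ctrl)` (pseudocount 0.5) still defines per-peak
fold enrichment.

Windows with fewer than `min_ip_reads` (default 1) IP reads cannot be
significant and are excluded before BH selection, which changes the BH
denominator `m`; both the floor and the exclusion are configurable. BH
selection is the standard step-up at `q = 0.05`. Runs of significant
windows are merged into peaks, bridging up to `merge_gap = 1`
intervening non-significant window: the twin-peak geometry concentrates
read *starts* half a fragment to either side of the site, leaving a dip
at the site center that must not split one binding event into two peaks.
Each peak reports pooled counts, fold enrichment over the scaled
control, the minimum window p-value, and the summit (argmax of IP
read-body coverage; with 40-bp reads of 250-bp fragments this profile is
itself bimodal, so the summit sits on one of the two modes rather than
the geometric center).

Replicate consistency follows the published design: the IP reads are
randomly split into three technical replicates, the identical analysis
runs on each, and a full-data peak is retained only if it overlaps (by
at least 1 bp) peaks in at least two of the three replicate calls; the
achieved support count is recorded.

## Curation

Four biological filters, each with an audit column so the funnel can be
reconstructed exactly, and each individually switchable:

* **Fold enrichment** — at least 3-fold over the scaled control,
  boundary inclusive.
* **Twin-peak morphology** — the published workflow assessed this by
  eye; hetrseq operationalises it. Per-strand read-start densities are
  smoothed with a 25-bp moving average; the summits within the peak must
  be offset by a positive shift of at most `max_shift` (default 500 bp,
  i.e. twice the expected fragment length), and the maximum Pearson
  correlation between the plus profile and the back-shifted minus
  profile over shifts in `[20, max_shift]` must reach 0.5. Peaks with
  fewer than 10 read starts on either strand fail with a sentinel score.
* **Misregulation** — a flanking gene must change at least 1.5-fold (at
  either 0 h or 6 h) in the deletion mutant. The published tables
  contain |FC| values near 1, so the default is permissive and
  configurable. Sentinel expression values are indeterminate: a peak is
  excluded only when *every* flanking gene is measurably unmoved —
  missing data never removes a peak. One qualifying side suffices.
* **Proximity** — the peak must sit in a regulatory position for at
  least one flanking gene: overlapping the 500-bp window upstream of the
  start codon on that gene's coding strand, or between an assigned TSS
  and the start codon (the 5′ UTR/leader). Flanking genes include genes
  the peak partially overlaps, since peaks routinely cover their target
  gene's 5′ end. Category priority is: entirely 3′ of the gene →
  `not_applicable`; in the TSS–start leader → `downstream_of_TSS`;
  overlapping the upstream window → `within_500bp_upstream`; otherwise
  `beyond_500bp_upstream`. The TSS-based call outranks the bare distance
  rule because a peak inside an annotated leader is in transcribed
  regulatory sequence regardless of its distance to the start codon.

## Motif scanning and the consensus

Scanning is FiMO-style: every offset on both strands is scored as
background-relative log-odds in bits, and matches are reported at an
exact score p-value threshold of 1e-4 with no correction across
positions (the conventional behaviour of a fixed-threshold scan;
q-values are out of scope). The null score distribution is computed
exactly by discretizing each column's log-odds to a 0.001-bit grid and
convolving the per-column distributions under the background; the score
error of any quoted tail probability is bounded by `width × grid` (0.015
bits for the width-15 seed), and the tests bracket the dynamic-programming
p-values between exhaustive-enumeration values at ±that slack. The
default background is the uniform 0-order composition (configurable);
whole-genome composition is preferable to per-region composition because
curated regions are short.

The seed motif is built from the case-annotated string
`GGGTCTAgCCCagCA` characterised upstream of known regulon members:
uppercase (strongly conserved) positions take probability 0.91 on their
base, lowercase 0.55, the remainder uniform on the other bases. The
original numeric matrix behind that string is not available; the
weights were chosen once so that the strong core is nearly deterministic
while lowercase positions remain clearly informative, and both are
arguments of `seed_to_pwm()`.

Minus-strand hits are reported in forward coordinates with the
strand-corrected matched sequence; a palindromic hit that scores
identically on both strands is reported once, on the plus strand.

`build_consensus()` stacks the strand-corrected matched sequences — an
ungapped alignment, justified because all hits share the scanning PWM's
width and register (a deliberate simplification of a full motif
aligner's shift/width search) — into a position frequency matrix, with
an optional background-weighted pseudocount (default 0, keeping observed
frequencies and making a stack of identical sites exactly 2 bits per
column). Information content is relative entropy against the background;
the IUPAC call per column is the minimal code covering all bases at
frequency ≥ 0.25, uppercase where the column reaches 1 bit. PWMs
round-trip through the minimal MEME text format for interoperability.

## Category enrichment

For curated target genes, per-category fold enrichment is the fraction
of distinct hit genes in the category divided by the fraction of genome
genes in it; genes with several categories count once per category, and
the hit denominator is the number of distinct hit genes. Categories are
flagged at ≥ 3-fold (inclusive). A hypergeometric upper-tail p-value is
attached for rigor (the original analysis reported folds only); no
correction across categories is applied, and no ontology-graph
propagation is attempted — annotations are a flat input table.

## Pipeline, seeds and problem sizes

`run_pipeline()` chains simulate → callpeaks → curate → motif → enrich
under one configuration (R list or YAML) and one seed; per-stage
sub-seeds are derived by a fixed affine map so stages can be re-run
independently yet reproducibly, and the returned manifest carries the
funnel counts (peaks called, after replicate consistency, after
curation, regions with hits, total hits, consensus width). Two runs with
the same configuration and seed are identical.

The shipped problem sizes are chosen so the full test suite runs in
about two minutes on one core: the default study uses a 1-Mb genome
with 200 000 reads per sample (the original experiment sequenced ~40
million 40-bp reads per sample on a ~7-Mb genome — the per-window read
depth is comparable after scaling); FDR control is measured on one
hundred 1-Mb null genomes at 50 000 reads per sample; recovery uses 30
planted sites at 10× enrichment; the end-to-end demo plants 10
regulatory sites (upstream of mutant-misregulated genes) and 5 decoys
(upstream of unaffected genes), so the decoys fail exactly the
misregulation filter and the curation funnel is fully auditable.

## Known limitations

* The background model is Poisson; real bacterial ChIP input shows
  overdispersion that would require a local-rate or negative-binomial
  extension (no MACS-style local lambda is attempted).
* The twin-peak score assumes point-source binding; broad or composite
  binding modes (e.g. multiple adjacent sites bound by higher-order
  oligomers) produce wide peaks whose strand correlation may pass at an
  uninformative shift.
* The consensus stack cannot discover a motif wider than, offset from,
  or gapped relative to the scanning seed; it refines, not discovers.
* Curated-region fixtures transcribed from the published tables carry
  that table's one internally inconsistent coordinate row, preserved and
  flagged rather than repaired.
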