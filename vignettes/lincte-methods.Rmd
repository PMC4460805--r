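---
title: "Quantifying transposable-element content in lincRNA gene architecture"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying transposable-element content in lincRNA gene architecture}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lincte)
```

## The problem

Transposable elements (TEs) make up roughly half of mammalian genomes, and
most long intergenic non-coding RNA (lincRNA) genes carry recognisable
TE-derived sequence (TES). `lincte` quantifies that contribution at
nucleotide resolution across the three compartments of a gene — the core
promoter (here the 100 bp immediately upstream of the TSS), the exons and
the introns — and asks three follow-up questions:

1. Are TES densities different between compartments, and between lincRNA
   and protein-coding genes? (Fisher exact tests on nucleotide counts.)
2. Are TE insertions in promoters/exons older — i.e. shared across a
   species split — than intronic ones? (Ancient vs lineage-specific
   classification from cross-species pairwise alignments.)
3. Does TES content co-vary with the evolutionary rate and the expression
   level of the host gene? (Kimura 2-parameter distances; Pearson
   correlations.)

Everything runs end to end on a synthetic genome with planted truth, so
every stage of the pipeline is testable without any external download.

## Coordinate conventions and inputs

All internal coordinates are 0-based half-open (BED convention); format
converters live exclusively at the I/O boundary:

* RepeatMasker `.out` (1-based inclusive, strand `C` for minus) via
  `read_repeatmasker_out()`. The class/family string maps to one of
  `LINE`, `SINE`, `LTR`, `DNA`, `OTHER`, `NON_TE`; simple repeats,
  low-complexity and structural-RNA records are `NON_TE` and excluded from
  TES totals by default. Whether such records should count as TES is
  genuinely ambiguous in the underlying protocol, so the exclusion is a
  switch (`analysis_params(include_nonte = TRUE)`).
* BED12 gene models via `read_bed12()`; mature length is the sum of exon
  lengths, not the genomic span, because the 200 nt lincRNA length filter
  applies to transcripts.
* MAF pairwise alignments via `read_maf()`, using only the first two `s`
  rows of each block (the analysis is strictly pairwise); minus-strand
  query coordinates are normalised to the + strand at parse time.

## Region partitioning

`build_region_sets()` unions per-gene promoters, exons and introns across
genes and then makes the three sets disjoint with the precedence
EXON > INTRON > PROMOTER, so every base lands in exactly one Fisher
denominator. The precedence is a design choice (the alternative — counting
a base twice when genes overlap — would break the contingency-table
margins); it only matters where gene models overlap. Intergenicity of a
lincRNA candidate is tested against protein-coding *spans* (first exon
start to last exon end), mirroring the idea of a transcript lying between
two adjacent protein-coding genes; one base of span overlap disqualifies.

## TES coverage and tests

`te_coverage()` computes union coverage: overlapping TE records never
double count, and records spanning a compartment boundary contribute only
their overlapping bases. Per-TE-class accounting (`te_class_coverage()`)
must attribute bases where records of *different* classes overlap; the
higher Smith–Waterman score wins the shared bases (ties: earlier record),
which mirrors RepeatMasker's own preference for higher-scoring matches and
keeps per-class counts summing to the union. A `record_sum` mode that
skips de-duplication is available for comparison.

The two-group comparison uses the exact two-sided Fisher test on
`[[TES_A, TE-free_A], [TES_B, TE-free_B]]`, implemented by full
hypergeometric enumeration with the probability-mass definition of
two-sidedness and a relative tie tolerance of 1e-7 (the definition used by
standard statistical suites, so results are reproducible across float
regimes). A zero row or column margin returns p = 1 by convention, with a
message. Raw p-values are reported to match the presentation style of the
analysis; the pipeline adds a clearly-marked Bonferroni column as an
extension.

## Ancient vs lineage-specific TEs

A TE interval is projected through the alignment blocks:
all columns whose reference coordinate falls inside the TE, plus
query-insertion (reference-gap) columns strictly between the first and
last selected reference column of a block. TEs spanning several blocks
concatenate their projections; unaligned stretches contribute nothing. A
TE with no overlapping block is lineage-specific.

The classification reads "insertions/deletions" as the *gap-column
fraction* of the projected alignment — pairwise alignment files expose gap
columns directly, whereas indel *events* would require arbitrary gap
merging. "Longer than 100 bp" is read strictly (`columns > 100`; the
boundary is tested explicitly). Thresholds: stringent `< 5%`, relaxed
`<= 25%`, so the stringent set is provably a subset of the relaxed set.

For element-level counts each TE is attributed to the region class with
maximal base overlap (ties: PROMOTER > EXON > INTRON — promoters are the
smallest compartment and would otherwise be swallowed by their
neighbours).

## Evolutionary distances

`kimura_k2p()` implements the closed form
`d = -1/2 ln[(1 - 2P - Q) sqrt(1 - 2Q)]`
on transition/transversion proportions counted from the projected,
gap-and-ambiguity-filtered columns (ambiguity codes are excluded entirely
rather than partially weighted; on synthetic data the difference
vanishes). When `1 - 2P - Q <= 0` or `1 - 2Q <= 0` the distance is
saturated: the result is flagged undefined rather than returned as an
infinity. Per-gene rates pool site-pattern counts over all exon
projections before a single K2P estimate; genes with fewer than 50
comparable sites (a configurable artifact choice) are flagged
low-confidence.

## Expression and association

Microarray-style expression is summarised as the median of log2 tissue
intensities ("median-of-log2"; ranking is identical to log2-of-median and
values differ only for even tissue counts). Non-positive intensities are
an error — no silent pseudo-count. RNA-seq counts become
`RPKM = 1e9 * C / (N * L)`; correlations use `log2(RPKM)`. Pearson r with
the t-based two-sided p is computed per pairing with pairwise-complete
deletion (listwise deletion would needlessly discard genes whose rate is
missing but whose expression is not).

## TATA scanning

Promoter sequences are extracted 5'→3' on the gene's sense strand, so the
base immediately upstream of the TSS is offset −1. The detector is an
IUPAC consensus, default `TATAWAW`; the underlying protocol never defines
its TATA model, so the motif is a parameter and the profiling machinery is
motif-agnostic. `N` never matches. Match offsets refer to the 5'-most base
of the window (the window interpretation of "−25 to −35" is ambiguous;
start-offset is used and switchable via the window parameter). The
positional profile reports, per offset, the share of promoters with a
match starting there; the headline fraction counts promoters with a match
starting inside −35..−25.

## The synthetic genome

`simulate_genome()` is first-class, tested code, not a fixture. Its
defaults are the package's reference study conditions:

* 3 chromosomes × 2.4 Mb; 1000 lincRNA and 200 protein-coding genes with
  2–5 exons of 150–600 nt, introns of 400–1500 nt and intergenic gaps of
  1000–2500 nt — about 1.3 Mb of exon, 2.3 Mb of intron and exactly
  100 kb of promoter sequence, enough for the tightest recovery tests
  while a full run stays in the one-minute range on one CPU.
* Planted TES densities per compartment: intron 0.35 > exon 0.20 >
  promoter 0.10 (intergenic 0.40 plus 2% simple repeats), with SINEs
  enriched and LINEs depleted in exons/promoters relative to introns,
  reproducing the qualitative density structure the analysis is designed
  to detect. TEs are 120–350 nt, planted non-overlapping; the final TE of
  each class is clamped to the remaining deficit so realised coverage
  matches the target to within one minimum TE length.
* Promoter TEs cover 30–70 bases of the promoter's upstream end and
  extend into intergenic sequence, never across the TSS — this keeps exon
  truth clean while letting promoter TEs exceed the 100-column ancient
  threshold.
* Each TE is ancient with a compartment-specific probability (promoter
  0.5 > exon 0.35 > intron 0.15). The simulated ortholog substitutes
  per site with transition probability `ortho_P = 0.10` and transversion
  probability `ortho_Q = 0.05` (so the planted K2P distance is
  `-0.5 ln(0.75 sqrt(0.9)) ≈ 0.1702`), plants gap columns inside ancient
  TEs at 2% per site, and omits lineage-specific TEs from the alignment
  entirely.
* Expression is built so the *population* correlation between the
  per-gene TES fraction and latent log2 expression is exactly
  `expr_rho = -0.25` (noise-scaled construction); tissue intensities and
  Poisson read counts add realistic measurement noise on top. The
  TES–rate correlation is induced by modulating each gene's substitution
  rate (target 0.3); because it passes through the K2P estimator it is
  only approximately the target, which is why exact-rho recovery tests
  use the direct table generator `simulate_feature_table()`.
* A literal `TATAAAA` is written at offset −30 into 25% of promoters.

What the generator does *not* emulate: real repeat-family sequence (TE
bodies are random sequence tagged by class), nested/fragmented
RepeatMasker annotations (the quantifier handles overlap, tested with
hand-built fixtures, but truth bookkeeping assumes non-overlap), indel
*events* (gaps are independent per site), GC heterogeneity and isochore
structure, and any phylogenetic realism beyond a single pairwise split.
Passing recovery tests therefore demonstrate the correctness of the
accounting and statistics, not robustness to annotation noise in real
genomes.

All generators are pure functions of the configuration (including its
seed): the same `sim_config()` yields byte-identical files.

## Numerical and degenerate-input choices

* Fisher ties: probabilities within a relative 1e-7 of the observed
  table's probability count as "as extreme".
* `total_nt = 0` yields fraction `NA` (undefined), distinct from a true
  zero; empty region classes are excluded from tests.
* Saturated K2P distances are `NA` with `defined = FALSE`, never `Inf`.
* Promoters clipped at chromosome ends are dropped from TATA profiling
  (to keep the profile length-uniform) and flagged.
* Report TSVs round numerics to 6 significant digits so outputs are
  byte-stable across platforms; `manifest.json` records wall-clock
  runtimes and is therefore the one report file not expected to be
  byte-identical across reruns.

## A small run

```{r example, eval = FALSE}
cfg <- sim_config(seed = 1, n_chroms = 1, chrom_len = 500000,
                  n_linc_genes = 60, n_pc_genes = 15)
run <- run_full(run_config(sim = cfg), outdir = tempfile("lincte-"))
tidy(run)       # region-class TES fractions + Fisher p-values
glance(run)     # one-row run summary
autoplot(run)   # region-fraction panel
```

## Known limitations

* The ancient/lineage split ignores whether the orthologous sequence is
  itself annotated as the same repeat family in the second species; a
  stricter reciprocal mode would need the second species' annotation.
* Probe-to-gene aggregation for real microarray data is out of scope; the
  expression table carries one record per gene.
* Overlapping lincRNA candidates are kept (and logged), not collapsed.
* The Fisher test treats nucleotides as independent observations, as in
  the original analysis style it reproduces; spatial autocorrelation of
  TE insertions makes these p-values anti-conservative on real data.
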