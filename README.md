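# lincte

Nucleotide-level quantification of transposable-element-derived sequence
(TES) in the architecture of long intergenic non-coding RNA (lincRNA)
genes.

Transposable elements make up about half of mammalian genomes, and most
lincRNAs carry recognisable TE-derived sequence. Where that sequence sits
— core promoter, exon or intron — and how old it is says a lot about how
lincRNA genes arise and acquire function. `lincte` is an R package for
researchers in regulatory genomics who want to measure that signal and
test it, end to end, with a fully synthetic, truth-carrying genome:

* **Region partitioning** — strand-aware core promoters (100 bp upstream
  of the TSS), exons and introns from BED12 gene models, made disjoint
  with the precedence EXON > INTRON > PROMOTER; lincRNA selection filters
  (intergenicity against protein-coding spans, mature length ≥ 200 nt).
* **TES coverage** — union coverage of RepeatMasker `.out` annotations
  per region class and per TE class (LINE/SINE/LTR/DNA), per-gene TES
  fractions and their histogram.
* **Fisher exact tests** on 2×2 nucleotide contingency tables
  `[[TES, TE-free], [TES, TE-free]]`, computed by full hypergeometric
  enumeration with the two-sided probability-mass definition:

      p = Σ { P(X = x) : P(X = x) ≤ P(X = a) (1 + 1e-7) }

* **Ancient-TE classification** — TE intervals projected through MAF
  pairwise alignments; an insertion is *ancient* when its orthologous
  alignment exceeds 100 columns with a gap-column fraction < 5 %
  (stringent) or ≤ 25 % (relaxed), otherwise *lineage-specific*; per-region
  ancient fractions with pairwise Fisher tests.
* **Evolutionary rates** — Kimura 2-parameter distances
  `d = -½ ln[(1 − 2P − Q) √(1 − 2Q)]` from pooled exon alignments
  (P = transition, Q = transversion proportion).
* **Association** — median log2 microarray expression, RPKM
  (`10⁹·C/(N·L)`), and Pearson correlations (t-based two-sided p) between
  TES fraction, rate and expression.
* **TATA scanning** — IUPAC consensus (default `TATAWAW`) positional
  profiles over promoters and the fraction with a match in −35..−25.
* **Synthetic data** — a seeded generator planting all of the above with
  known truth: per-compartment TES densities, ancient probabilities,
  substitution/gap rates, expression correlation, TATA placement.

Everything is tibble-in/tibble-out and pipe-friendly; results ship with
`tidy()`, `glance()`, `autoplot()` and `plot_*()` helpers.

## Worked example

```r
library(lincte)

cfg <- sim_config(seed = 7, n_chroms = 1, chrom_len = 500000,
                  n_linc_genes = 60, n_pc_genes = 15)
run <- run_full(run_config(sim = cfg), outdir = "demo-run")
run
#> <lincte_run>
#>   report directory: demo-run
#>   lincRNAs analysed: 60
#>   region TES fractions (lincRNA):
#>     EXON      0.2022
#>     INTRON    0.3513
#>     PROMOTER  0.1045

tidy(run)
#> # A tibble: 6 × 7
#>   gene_set       region_class total_nt te_nt fraction fisher_p_vs_intron
#> 1 lincRNA        EXON            77668 15707    0.202          0
#> 2 lincRNA        INTRON         143619 50458    0.351         NA
#> 3 lincRNA        PROMOTER         6000   627    0.104          0
#> 4 protein_coding EXON            19202  3944    0.205          5.99e-299
#> 5 protein_coding INTRON          35874 12709    0.354         NA
#> 6 protein_coding PROMOTER         1500   180    0.12           1.28e- 91
```

The configuration planted TES densities of 0.35 in introns, 0.20 in exons
and 0.10 in promoters; the recovered fractions (0.351, 0.202, 0.104) match
the plant, and the Fisher tests confirm that both promoter and exon
densities differ from the intronic background far beyond p < 10⁻⁵ — the
qualitative ordering intron > exon > promoter that the analysis is built
to detect. `glance(run)` adds one-row summary statistics (share of genes
with < 20 % TES, TATA-containing promoter fraction, TES–rate correlation),
and the report directory holds one TSV per figure-style table
(`fig1_fractions.tsv`, `fig34_classes.tsv`, `fig2_correlation.tsv`,
`figS2_expression.tsv`, `fig5_ancient.tsv`, `figS1_histogram.tsv`,
`figS3_tata.tsv`) plus `manifest.json` with input/output digests and
stage runtimes.

A thin command-line wrapper is included for shell use:

```sh
Rscript inst/scripts/lincte.R simulate --seed 42 --outdir sim-out
Rscript inst/scripts/lincte.R run --seed 42 --outdir report
```

See `vignettes/lincte-methods.Rmd` for the model assumptions, parameter
defaults and the design decisions behind them.

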