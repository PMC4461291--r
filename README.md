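# codonusage

Tidy tools for analysing **synonymous codon usage bias (CUB)** in sets of
coding sequences — the kind of comparative survey used to ask whether a
genome's codon choices are driven by nucleotide composition, directed
mutational pressure, or translational selection, e.g. when contrasting
highly reduced parasite genomes with their larger relatives.

The package is aimed at comparative genomicists and molecular
evolutionists who have CDS FASTA files (or want fully synthetic,
seeded test genomes) and need the standard CUB battery end to end:

* **RSCU** — relative synonymous codon usage: for codon *j* in a family of
  size *k* with family total *N*, RSCU<sub>j</sub> = x<sub>j</sub>/(N/k);
  1 = no bias, family values sum to *k*.
* **CAI** — codon adaptation index: the count-weighted geometric mean of
  relative adaptiveness w<sub>j</sub> = RSCU<sub>j</sub>/max(family RSCU)
  taken from a high-expression reference (packaged default: the classic
  *S. cerevisiae* weights; any reference CDS set may be supplied).
* **ENc** — Wright's effective number of codons, ENc = 2 + 9/F̄₂ + 1/F̄₃ +
  5/F̄₄ + 3/F̄₆ with per-family homozygosity F = (nΣp² − 1)/(n − 1),
  clipped to [20, 61], plus the composition-only expectation
  ENc = 2 + s + 29/(s² + (1 − s)²) for the ENc-plot.
* **Positional composition** — GC<sub>cds</sub>, P1, P2, P3, P12, GC3s and
  the PR2 coordinates A3/(A3+U3) vs G3/(G3+C3), with the exclusion rules
  (Met/Trp out of P1–P3; stops and Ile additionally out of P3) that make
  neutrality and parity analyses well defined.
* **Neutrality fit** — OLS of P12 on P3 with Spearman correlation; slope
  ×100 = relative neutrality.
* **Optimal / rare codons** — 5% CAI tails, per-codon family-conditional
  2×2 chi-squared between tails (optimal: p < 0.05 and higher RSCU in the
  high tail; rare: genome RSCU < 0.1), with third-base summaries.
* **Correspondence analysis** of the genes × 59 informative-codon RSCU
  table (≤ 41 informative axes), plus axis–index correlations.
* **Inter-genome clustering** of RSCU profiles (Euclidean, average
  linkage, Newick export) and cross-species ANOVA / Welch tests.
* A **seeded synthetic CDS generator** with planted third-base
  preference, GC3 gradients, calibrated mutational-pressure coupling
  (expected neutrality slope = *m*) and an expression tier — so the whole
  pipeline is testable without downloading anything.

Everything takes and returns tibbles; fitted objects have
`tidy()`/`glance()`/`autoplot()` methods; `plot_enc_gc3s()`, `plot_pr2()`
and `autoplot()` give the standard diagnostic figures.

## Worked example

Simulate one genome with mutational pressure (`m = 0.3`), an A/U-leaning
composition (GC3 target 0.4) and a 5% high-expression tier, then run the
core analyses:

```r
library(codonusage)

spec <- synthetic_spec(n_genes = 500, len_mean_bp = 900, m = 0.3,
                       gc3_target = 0.4, tier_fraction = 0.05, seed = 42)
genome <- generate_genome(spec)
counts <- count_codons(filter_cds(genome$cds))

# the planted tier serves as the known high-expression reference set
ref     <- counts[counts$id %in% genome$truth$id[genome$truth$tier], ]
indices <- cub_indices(counts, cai_weights(ref))
head(indices, 3)
#> # A tibble: 3 × 4
#>   id       cai   enc  gc3s
#>   <chr>  <dbl> <dbl> <dbl>
#> 1 g00001 0.489  55.5 0.388
#> 2 g00002 0.404  61   0.505
#> 3 g00003 0.577  54.4 0.299

neutrality_fit(codon_composition(counts))
#> Neutrality-plot fit (P12 ~ P3), n = 500 genes
#>   slope 0.2610 (relative neutrality 26.10%), intercept 0.3884
#>   Spearman rho 0.755, p = 3.25e-93

glance(correspondence_analysis(counts))
#> # A tibble: 1 × 7
#>   n_genes n_codons total_inertia axis1_fraction axis2_fraction first4_fraction
#>     <int>    <int>         <dbl>          <dbl>          <dbl>           <dbl>
#> 1     500       59         0.303          0.267         0.0399           0.379
```

Reading the output: per-gene ENc values near 61 (like `g00002`) are
essentially unbiased genes, lower values are more biased; the fitted
neutrality slope 0.261 recovers the generator's planted coupling
`m = 0.3` up to sampling error at 500 genes (the recovery tests use
2,000), indicating directed mutational pressure rather than neutral
drift; CA axis 1 carries 26.7% of the inertia, an order of magnitude more
than axis 2, and tracks the planted GC3 variation.

Optimal-codon calling from the CAI tails recovers the planted tier
preference — every codon called optimal is A/U-ending:

```r
tails <- select_expression_tails(indices, 0.05)
opt <- call_optimal_codons(
  counts[counts$id %in% tails$id[tails$tail == "high"], ],
  counts[counts$id %in% tails$id[tails$tail == "low"], ],
  counts)
dplyr::filter(optimal_codon_summary(opt), category == "optimal")
#> # A tibble: 7 × 3
#>   category third n_codons
#>   <chr>    <chr>    <int>
#> 1 optimal  A           14
#> 2 optimal  U           16
#> 3 optimal  G            0
#> 4 optimal  C            0
#> 5 optimal  A/U         30
#> 6 optimal  G/C          0
#> 7 optimal  total       30
```

Multi-genome comparisons go through `run_cub_pipeline()`, which emits
per-genome TSV tables, a Newick dendrogram of RSCU profiles and a JSON
manifest of every statistic.

## Package layout

* `R/genetic-code.R`, `R/cds-io.R` — code table, FASTA I/O, filtering,
  codon counting
* `R/composition.R` — positional GC, GC3s, PR2 quantities
* `R/indices.R` — RSCU, CAI (+ reference weights), ENc, expected ENc
* `R/optimal.R`, `R/neutrality.R`, `R/correlations.R` — tails and
  optimal/rare calling; neutrality and PR2; correlation matrices, group
  tests, clustering
* `R/coa.R` — correspondence analysis and axis diagnostics
* `R/synthetic.R` — the seeded generator
* `R/pipeline.R` — `run_cub_pipeline()` and report/manifest output
* `vignettes/codon-usage-methods.Rmd` — full methods description,
  conventions and generator calibration
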