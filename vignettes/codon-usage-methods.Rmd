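---
title: "Methods: quantifying synonymous codon usage bias"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying synonymous codon usage bias}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codonusage)
```

# Scope and data model

`codonusage` quantifies synonymous codon usage bias (CUB) in sets of coding
sequences, as is routinely done when comparing compact parasite genomes,
organelles or newly annotated microbial genomes. Everything operates on
tidy tables: a CDS set is a tibble of `id`/`sequence` rows, codon counts
are one wide tibble (genes × 64 codons), and every analysis returns a
tibble (or a small S3 object with `tidy()`/`glance()`/`autoplot()`
methods), so stages chain with the pipe.

The substrate is the standard genetic code only. Its census matters for
several formulas: 61 sense codons; two single-codon amino acids (Met, Trp);
9 two-fold, 1 three-fold (Ile), 5 four-fold and 3 six-fold degenerate
families, i.e. 18 families covering the 59 *informative* codons on which
synonymous choice is observable.

## Filtering

`filter_cds()` keeps sequences that are (i) at least 300 bp — the
conventional floor that avoids index estimates dominated by small-sample
noise — (ii) a whole number of codons, and (iii) free of in-frame internal
stop codons (terminal stop allowed). Rules (ii) and (iii) are this
package's own hygiene decisions: public annotations occasionally contain
frame-shifted or pseudogenised CDS, and dropping them with a per-reason
report keeps the downstream arithmetic well defined. Codons containing
ambiguity codes are skipped and tallied, never imputed, since imputation
would bias composition. Terminal stop codons are counted by default (so
stop-codon RSCU can be reported); a flag excludes them for annotation
styles that strip stops.

# Composition quantities and their exclusion sets

For each gene we report the GC fraction of the whole CDS (`gc_cds`) and of
each codon position (`p1`, `p2`, `p3`), plus `p12 = (p1 + p2)/2`. The
exclusions follow the conventions of neutrality-plot analysis: Met and Trp
codons are excluded from `p1`, `p2`, `p3` (their positions carry no
synonymous signal), and `p3` additionally excludes the three stop codons
and the three Ile codons, whose third position is not a symmetric
two/four-way choice — transition/transversion rate inequality makes their
inclusion misleading. `gc3s`, the quantity used in the ENc-plot, is
different by construction: third-position GC over *degenerate sense*
codons, so Ile is included while Met/Trp/stops are not. The two values
agree exactly on genes without Ile codons and differ otherwise; both are
reported.

The parity-rule-2 (PR2) coordinates are the third-position base fractions
`a3`, `u3`, `g3`, `c3` and the biases `au_bias = a3/(a3 + u3)`,
`gc_bias = g3/(g3 + c3)`. A genome shaped by composition alone sits at
(0.5, 0.5). The base fractions use the same universe as `p3` by default so
that one plot has one third-position universe; the classic variant
restricted to four-fold degenerate families is available via
`pr2_universe = "fourfold"` (the default is a deliberate choice the
literature leaves open).

Any ratio whose denominator is empty propagates as `NA`, never 0, so
correlations and regressions downstream automatically use complete pairs.
Genome-level summaries are computed both as means of per-gene values (the
reported convention) and on pooled counts, side by side.

# Indices

**RSCU.** For codon $j$ in a family of size $k$ with family total $N$,
$\mathrm{RSCU}_j = x_j / (N/k)$: 1 means no bias, values sum to $k$ within
each observed family. Unobserved families are missing, not 0; Met and Trp
print as 1 by convention.

**CAI.** Relative adaptiveness $w_j = \mathrm{RSCU}_j / \max_{j' \in
\text{fam}} \mathrm{RSCU}_{j'}$ is computed on a pooled high-expression
reference set; codons unseen in the reference get a 0.5 pseudocount so
every weight is positive. CAI of a gene is the count-weighted geometric
mean of $w$ over its codons, with Met, Trp and stops excluded (they carry
no synonymous information). The packaged default reference is the classic
*S. cerevisiae* high-expression weight table (Sharp & Li's values as
distributed in `seqinr::caitab`); any reference CDS set can be supplied to
`cai_weights()` instead, and the provenance travels with the table.

**ENc.** Wright's effective number of codons. Per family with total $n >
1$ the codon homozygosity is $F = (n\sum_i p_i^2 - 1)/(n-1)$; then

$$\mathrm{ENc} = 2 + \frac{9}{\bar F_2} + \frac{1}{\bar F_3} +
\frac{5}{\bar F_4} + \frac{3}{\bar F_6}.$$

Conventions, chosen to match how the widely used CodonW implementation
behaves on short genes: families with $n \le 1$ or $F = 0$ are dropped
from their class mean; if the single three-fold family (Ile) is absent,
$\bar F_3$ is substituted by the class-weighted mean $(9\bar F_2 + 5\bar
F_4)/14$; if any other size class has no usable family the gene's ENc is
`NA`. Finite-sample $F$ can stray outside the theoretical range, so the
result is clipped to $[20, 61]$ — the cap is why unbiased genes read
exactly 61. The composition-only expectation $\mathrm{ENc} = 2 + s +
29/(s^2 + (1-s)^2)$, $s = \mathrm{GC3s}$, is exposed as `expected_enc()`
for the ENc-plot.

# Genome-level inference

**Optimal and rare codons.** The putative high- and low-expression sets
are the upper and lower 5% CAI tails (`ceiling` sizes, ties broken by gene
id for reproducibility). For each informative codon we form the 2×2 table
of its pooled count against the *rest of its family* in the two tails and
apply Pearson's chi-squared without continuity correction. The
family-conditional construction is deliberate: it is the only 2×2 layout
under which "used more frequently" is the same statement RSCU makes. A
codon is optimal when $p < 0.05$ *and* its RSCU is higher in the high
tail (`"*"` below 0.01, `"@"` between 0.01 and 0.05); genome RSCU > 1
marks preferred codons and genome RSCU < 0.1 rare ones. Raw thresholds
are the field's convention here; a Benjamini–Hochberg option exists but is
off by default, and a whole-family chi-squared variant is kept behind
`test = "family"`.

**Neutrality fit.** OLS of `p12` on `p3` across genes plus a Spearman
rank correlation. Slope near 1 = the three positions drift together
(neutrality); slope near 0 = directed mutational pressure on third
positions or selective constraint on the first two. The slope × 100 is
reported as `relative_neutrality` (unrounded).

**Correlation matrix, group tests, clustering.** Spearman with two-sided
p-values on pairwise-complete gene values for {`gc_cds`, `p1`, `p2`,
`p12`, `p3`, `enc`}; one-way ANOVA across species on per-gene CAI and ENc
(per-gene observations, not genome means — F statistics in the thousands
are only reachable with thousands of observations); Welch's t-test between
two species groups, since variances differ markedly between genomes.
Genome RSCU vectors over the 59 informative codons are clustered with
average linkage on Euclidean distances, rows pre-sorted by label so ties
break deterministically; the dendrogram exports as Newick.

# Correspondence analysis

CA is run on the genes × 59 RSCU matrix (not raw counts — RSCU removes
amino-acid composition so axes reflect synonymous choice; the count
variant is available behind `input = "counts"`). Missing family entries
are imputed at the family-neutral value 1 and flagged. The matrix is
scaled to a correspondence table, standardized residuals are decomposed by
SVD, and genes/codons are reported in principal coordinates with per-axis
inertia fractions; four axes are retained by default. Because RSCU sums
to $k$ within each family, the residual has at most $59 - 18 = 41$
informative axes — a property verified numerically in the tests. CA axis
signs are arbitrary, so axis 1 is oriented to correlate non-negatively
with GC3s and later axes so their largest codon loading is positive,
making outputs stable across SVD implementations.

# The synthetic generator

`generate_genome()` draws seeded CDS sets carrying exactly the structure
the analyses are meant to detect, so every stage can be validated against
planted truth without any downloads. Genes are built codon by codon: an
amino acid from a frequency vector (default: average protein composition),
then a codon from its family's conditional distribution. Genes start with
ATG and end with a stop, so they pass `filter_cds()` unchanged.

Three planted layers:

* **Third-base preference.** Each degenerate family uses a G/C-ending
  codon with probability $\theta$, split equally within the G/C and A/U
  subsets. A genome-wide odds multiplier (`au_odds`) tilts every family
  towards A/U or G/C ends — emulating the contrast between an A/U-loving
  clade and a G/C-loving one; expression-tier genes (a planted
  `tier_fraction`, default tier odds 4:1 towards A/U) get an extra tilt,
  giving them a recoverable optimal-codon signature. In tier recovery
  tests the tier plays the role of the externally known high-expression
  reference set, exactly as a curated reference organism does on real
  data.
* **GC3 gradient.** Optionally each gene's baseline $\theta$ is drawn
  uniformly from a range, planting the GC3 gradient that CA axis 1 and
  the ENc-plot should pick up.
* **Mutational pressure $m$.** A latent per-gene drift $\delta \sim
  N(0, \tau^2)$ (default $\tau = 0.12$) is added to $\theta$, and the
  amino-acid distribution is shifted along a one-parameter family mixing
  an A/T-rich-at-positions-1-2 tilt with a G/C-rich tilt, with mixing
  weight $w_g = 1/2 + c\,\delta_g/(\mu_{GC} - \mu_{AU})$. Since the
  expected `p12` is linear in $w_g$, this makes
  $E[p_{12}\mid\delta] = \text{const} + c\,\delta$ while
  $E[p_3\mid\delta] = \text{const} + \delta$. The OLS slope of `p12` on
  `p3` is then $c\,\tau^2 / (\tau^2 + \sigma^2_{\text{grad}} +
  \sigma^2_{\text{samp}})$, where $\sigma^2_{\text{samp}} =
  \bar\theta(1-\bar\theta)/\bar n_3$ is the analytic binomial sampling
  variance of a gene's `p3` ($\bar n_3$ = expected codons in the `p3`
  universe per gene) and $\sigma^2_{\text{grad}}$ the gradient variance.
  Setting $c = m(\tau^2 + \sigma^2_{\text{grad}} +
  \sigma^2_{\text{samp}})/\tau^2$ gives the regression slope expectation
  $m$ exactly, without post-hoc tuning. The recovery tests confirm the
  calibration at $m \in \{0, 0.2, 0.4\}$ to within ±0.05 on 2,000 genes.

Default study conditions: 2,000 genes, mean CDS length 900 bp
(gamma-distributed interior length, shape 6, floored at 300 bp),
$\theta_0 = 0.5$, tier fraction 5% matching the CAI tail fraction. These
mirror the scale of compact microbial genomes (a few thousand CDS of
median ~1 kb); unit tests use smaller slices of the same generator (tens
to hundreds of genes) to stay fast, and the figures quoted in the README
come from the sizes shown there.

What the generator does *not* emulate: real length–bias covariation,
amino-acid composition differences between expression tiers, dinucleotide
constraints, strand asymmetry, or evolution along a phylogeny. Passing
the planted-truth tests therefore demonstrates correctness of the
estimators and the detectability of each signal at realistic sizes — not
that any particular real genome will show these signals.

# Numerical choices, in one place

* Ratios with empty denominators → `NA`, never 0.
* ENc clipped to [20, 61]; class-mean substitution for missing Ile only.
* CAI reference pseudocount 0.5; weights clamped to $(10^{-4}, 1]$ when
  an external table supplies them.
* Chi-squared: no Yates correction, no multiplicity adjustment by
  default.
* Tails: `ceiling(fraction × N)`, ties by id order.
* CA: missing RSCU imputed at 1.0; axis-sign normalisation as above;
  rank-0 residuals return all-zero coordinates.
* Clustering: labels sorted before `hclust`, average linkage, Euclidean.
* All generator randomness flows from one integer seed; the generator
  restores the caller's RNG state.

# Limitations

The CAI default weights assume the yeast reference is meaningful for the
query organism; for distant taxa supply a native reference set. The
optimal-codon test inherits the classic design's selection-vs-expression
confound: CAI tails computed against a biased reference can enrich for
composition rather than expression. CA percentages are sensitive to the
imputation choice for genes missing whole families (short genes); with
the default 300 bp floor this is rare. The ENc missing-class conventions
match one established implementation; other tools differ in the third
decimal on short genes.
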