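# Positional nucleotide composition with the exclusion rules used in
# neutrality and parity-rule-2 analysis.
#
# Exclusion sets:
#   * GC_cds  — no exclusions: GC over all counted codon positions.
#   * P1, P2  — exclude the single-codon amino acids Met (AUG) and Trp (UGG),
#               whose first/second positions carry no synonymous signal.
#   * P3      — additionally exclude the three stop codons and the three Ile
#               codons (the one family whose third position is not a clean
#               two- or four-way choice).
#   * GC3s    — third-position GC over degenerate sense codons (Ile INCLUDED,
#               Met/Trp/stops excluded); deliberately distinct from P3.
# A3/U3/G3/C3 (the PR2 quantities) use the P3 exclusion set by default; the
# classic fourfold-degenerate-only variant is available via `pr2_universe`.

#' Per-gene nucleotide composition profile
#'
#' Computes, for each gene in a codon-count table, the GC content of the
#' whole CDS (`gc_cds`), the positional GC contents `p1`, `p2`, `p3` (with
#' the exclusions described below), their mean `p12 = (p1 + p2)/2`, the
#' third-position GC over synonymous codons (`gc3s`), the third-position
#' base fractions `a3`, `u3`, `g3`, `c3`, and the parity-rule-2 coordinates
#' `au_bias = a3/(a3 + u3)` and `gc_bias = g3/(g3 + c3)`.
#'
#' Met (AUG) and Trp (UGG) are excluded from `p1`, `p2` and `p3`; the stop
#' codons and the isoleucine family are additionally excluded from `p3` and
#' from the third-position base fractions. `gc_cds` uses every counted codon.
#' `gc3s` is computed over degenerate sense codons only (Ile included,
#' Met/Trp/stops excluded), so `p3` and `gc3s` agree exactly on genes with
#' no Ile codons and differ otherwise. Ratios whose denominator is empty
#' are returned as `NA`, never 0, so downstream correlations use complete
#' pairs only.
#'
#' @param counts A counts tibble from [count_codons()] (one or many genes).
#' @param pr2_universe Third-position universe for `a3`..`c3` and the PR2
#'   biases: `"p3"` (default; same exclusions as `p3`) or `"fourfold"`
#'   (four-fold degenerate families only, the classic PR2 convention).
#' @return A tibble with one row per gene: `id`, `gc_cds`, `p1`, `p2`, `p3`,
#'   `p12`, `gc3s`, `a3`, `u3`, `g3`, `c3`, `au_bias`, `gc_bias`.
#' @examples
#' cds <- tibble::tibble(id = "g", sequence = "ATGATTGAATAA")
#' codon_composition(count_codons(cds))
#' @export
codon_composition <- function(counts, pr2_universe = c("p3", "fourfold")) {
  pr2_universe <- match.arg(pr2_universe)
  code <- genetic_code()
  m <- counts_matrix(counts)
  tot <- rowSums(m)

  frac <- function(universe, weights) {
    keep <- code$codon %in% universe
    den <- unname(rowSums(m[, keep, drop = FALSE]))
    num <- as.vector(m[, keep, drop = FALSE] %*% weights[keep])
    ifelse(den > 0, num / den, NA_real_)
  }

  tot <- unname(tot)
  gc_cds <- ifelse(tot > 0,
                   as.vector(m %*% (code$gc1 + code$gc2 + code$gc3)) / (3 * tot),
                   NA_real_)
  u12 <- codon_universe("p12")
  u3 <- codon_universe("p3")
  p1 <- frac(u12, code$gc1)
  p2 <- frac(u12, code$gc2)
  p3 <- frac(u3, code$gc3)
  gc3s <- frac(codon_universe("gc3s"), code$gc3)

  upr2 <- if (pr2_universe == "p3") u3 else codon_universe("fourfold")
  base3 <- function(base) frac(upr2, as.numeric(code$third_base == base))
  a3 <- base3("A"); u3f <- base3("T"); g3 <- base3("G"); c3 <- base3("C")

  tibble::tibble(
    id = counts$id,
    gc_cds = gc_cds, p1 = p1, p2 = p2, p3 = p3, p12 = (p1 + p2) / 2,
    gc3s = gc3s,
    a3 = a3, u3 = u3f, g3 = g3, c3 = c3,
    au_bias = ifelse(!is.na(a3) & (a3 + u3f) > 0, a3 / (a3 + u3f), NA_real_),
    gc_bias = ifelse(!is.na(g3) & (g3 + c3) > 0, g3 / (g3 + c3), NA_real_)
  )
}

#' Genome-level composition summary
#'
#' Averages per-gene composition over a genome (the reported convention),
#' and also recomputes each quantity on the pooled codon counts for
#' comparison. Per-gene `NA`s are dropped from the means.
#'
#' @param counts A counts tibble from [count_codons()].
#' @param label Genome label for the output.
#' @inheritParams codon_composition
#' @return A tibble with one row per quantity: `genome`, `statistic`,
#'   `mean_of_genes`, `pooled`.
#' @export
genome_composition <- function(counts, label = "genome",
                               pr2_universe = c("p3", "fourfold")) {
  pr2_universe <- match.arg(pr2_universe)
  prof <- codon_composition(counts, pr2_universe)
  pooled <- codon_composition(pool_codon_counts(counts), pr2_universe)
  vars <- setdiff(names(prof), "id")
  tibble::tibble(
    genome = label,
    statistic = vars,
    mean_of_genes = vapply(vars, function(v) mean(prof[[v]], na.rm = TRUE),
                           numeric(1)),
    pooled = vapply(vars, function(v) pooled[[v]], numeric(1))
  )
}
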