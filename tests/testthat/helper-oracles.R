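# Shared fixtures and independent oracles. The oracles re-derive the target
# quantities directly from their defining formulas (Wright's per-family
# homozygosity; the chi-squared expected-count formula) so that the package
# implementation is checked against an independent computation path.

# build a CDS tibble from a vector of codons
make_cds <- function(codons, id = "g1") {
  tibble::tibble(id = id, sequence = paste(codons, collapse = ""))
}

# counts tibble straight from a named codon-count vector
counts_tbl <- function(x, id = "g1") {
  code <- genetic_code()
  full <- stats::setNames(numeric(64), code$codon)
  full[names(x)] <- x
  dplyr::bind_cols(tibble::tibble(id = id, n_skipped = 0L),
                   tibble::as_tibble(as.list(full)))
}

# random multinomial "gene": n_codons codons drawn uniformly over the 61
# sense codons (as a counts tibble)
random_gene_counts <- function(n_codons, id = "g1") {
  code <- genetic_code()
  sense <- code$codon[code$sense]
  cnt <- table(factor(sample(sense, n_codons, replace = TRUE),
                      levels = sense))
  counts_tbl(stats::setNames(as.numeric(cnt), names(cnt)), id = id)
}

# Independent ENc oracle: Wright's equations applied family by family from
# the genetic-code map, with the same missing-class conventions the package
# documents (size-3 substitute (9*F2 + 5*F4)/14; clip to [20, 61]).
oracle_enc <- function(cnt) {
  gcmap <- Biostrings::GENETIC_CODE
  names(gcmap) <- chartr("U", "T", names(gcmap))
  fvals <- numeric(0)
  fsizes <- integer(0)
  for (a in setdiff(unique(gcmap), "*")) {
    codons <- names(gcmap)[gcmap == a]
    k <- length(codons)
    if (k < 2L) next
    n <- sum(cnt[codons], na.rm = TRUE)
    if (n <= 1) next
    p <- cnt[codons] / n
    p[is.na(p)] <- 0
    fa <- (n * sum(p^2) - 1) / (n - 1)
    if (fa <= 0) next
    fvals <- c(fvals, fa)
    fsizes <- c(fsizes, k)
  }
  fbar <- function(k) if (any(fsizes == k)) mean(fvals[fsizes == k]) else NA
  f2 <- fbar(2L); f3 <- fbar(3L); f4 <- fbar(4L); f6 <- fbar(6L)
  if (is.na(f2) || is.na(f4) || is.na(f6)) return(NA_real_)
  if (is.na(f3)) f3 <- (9 * f2 + 5 * f4) / 14
  min(max(2 + 9 / f2 + 1 / f3 + 5 / f4 + 3 / f6, 20), 61)
}

# Independent Pearson chi-squared oracle for a 2x2 table
oracle_chisq <- function(tab) {
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - e)^2 / e)
}
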