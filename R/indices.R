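# Core codon-usage indices: RSCU, CAI and Wright's effective number of
# codons, plus the expected ENc ~ GC3s curve.

#' Relative synonymous codon usage
#'
#' RSCU is the observed count of a codon divided by the count expected if
#' all synonyms of its amino acid were used equally: for codon j in a family
#' of size k with family total N, `RSCU_j = count_j / (N / k)`. Values near 1
#' indicate no bias; within each observed family the values sum to k.
#' Families with no observed codons yield `NA` (missing, not zero). The
#' single-codon amino acids Met and Trp are reported as exactly 1 when
#' observed. Stop codons are treated as a three-codon family and included by
#' default; set `include_stops = FALSE` for annotation styles that strip
#' terminal stops.
#'
#' @param counts A counts tibble from [count_codons()]; pool first with
#'   [pool_codon_counts()] for a genome-level table.
#' @param include_stops Include the stop-codon family?
#' @return A long tibble: `id`, `aa`, `codon`, `count`, `rscu`.
#' @examples
#' cds <- tibble::tibble(id = "g", sequence = "ATGTTTTTTTTTTTCTAA")
#' rscu(count_codons(cds))
#' @export
rscu <- function(counts, include_stops = TRUE) {
  code <- genetic_code()
  keep <- if (include_stops) rep(TRUE, nrow(code)) else !code$stop
  m <- counts_matrix(counts)[, keep, drop = FALSE]
  sub <- code[keep, ]
  fam <- split(seq_len(nrow(sub)), sub$aa)
  r <- matrix(NA_real_, nrow(m), ncol(m), dimnames = dimnames(m))
  for (cols in fam) {
    k <- length(cols)
    n <- rowSums(m[, cols, drop = FALSE])
    expd <- n / k
    r[, cols] <- sweep(m[, cols, drop = FALSE], 1, expd, "/")
    r[n == 0, cols] <- NA_real_
  }
  # single-codon amino acids print as 1.00 when observed
  single <- which(sub$family_size == 1L)
  for (j in single) r[, j] <- ifelse(m[, j] > 0, 1, NA_real_)
  out <- tibble::as_tibble(r)
  out$id <- counts$id
  out <- tidyr::pivot_longer(out, -"id", names_to = "codon",
                             values_to = "rscu")
  out$aa <- sub$aa[match(out$codon, sub$codon)]
  out$count <- as.vector(t(m))
  out[, c("id", "aa", "codon", "count", "rscu")]
}

#' Relative-adaptiveness weights for the codon adaptation index
#'
#' Computes per-codon weights `w = RSCU / max(family RSCU)` from a pooled
#' reference set of (typically highly expressed) genes. Codons unobserved in
#' the reference receive a 0.5 pseudocount before RSCU so that every weight
#' is strictly positive. Single-codon amino acids (Met, Trp) and stop codons
#' carry no information about synonymous choice and are excluded from the
#' weight set.
#'
#' @param reference_counts A counts tibble for the reference gene set
#'   (pooled internally if it has several rows).
#' @param pseudocount Count added to unobserved codons (default 0.5).
#' @return A tibble `codon`, `aa`, `w` covering the 59 degenerate sense
#'   codons, with `max(w) == 1` within every family.
#' @seealso [cai_reference_weights()] for the packaged yeast default.
#' @export
cai_weights <- function(reference_counts, pseudocount = 0.5) {
  code <- genetic_code()
  if (nrow(reference_counts) > 1L) {
    reference_counts <- pool_codon_counts(reference_counts)
  }
  m <- counts_matrix(reference_counts)[1, ]
  sub <- code[code$degenerate, ]
  x <- m[sub$codon]
  fam_tot <- tapply(x, sub$aa, sum)
  absent <- names(fam_tot)[fam_tot == 0]
  if (length(absent)) {
    stop("amino-acid families absent from the reference set: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  x[x == 0] <- pseudocount
  fam <- split(seq_along(x), sub$aa)
  w <- numeric(length(x))
  for (cols in fam) {
    k <- length(cols)
    r <- x[cols] / (sum(x[cols]) / k)
    w[cols] <- r / max(r)
  }
  tibble::tibble(codon = sub$codon, aa = sub$aa, w = w)
}

#' Packaged reference weights for CAI
#'
#' Returns a ready-made relative-adaptiveness table. `"yeast"` uses the
#' classic *Saccharomyces cerevisiae* high-expression weights of Sharp & Li
#' as distributed in \pkg{seqinr}'s `caitab` (the same lineage of reference
#' values used by CodonW); the weight set is restricted to the 59 degenerate
#' sense codons. Supply your own reference gene set to [cai_weights()] to
#' use a different organism.
#'
#' @param reference `"yeast"`.
#' @return A tibble `codon`, `aa`, `w`.
#' @export
cai_reference_weights <- function(reference = c("yeast")) {
  reference <- match.arg(reference)
  caitab <- NULL
  utils::data("caitab", package = "seqinr", envir = environment())
  w <- caitab[["sc"]]
  names(w) <- toupper(rownames(caitab))
  code <- genetic_code()
  sub <- code[code$degenerate, ]
  out <- tibble::tibble(codon = sub$codon, aa = sub$aa,
                        w = unname(w[sub$codon]))
  # guard against degenerate external values; weights must lie in (0, 1]
  out$w <- pmin(pmax(out$w, 1e-4), 1)
  out
}

#' Codon adaptation index
#'
#' CAI is the geometric mean of the relative adaptiveness of a gene's
#' codons: `CAI = exp(sum(count_j * log(w_j)) / sum(count_j))` over the
#' codons that carry weights (Met, Trp and stops excluded). Values range in
#' (0, 1]; higher values indicate codon usage closer to the high-expression
#' reference and, by proxy, potentially higher expression.
#'
#' @param counts A counts tibble from [count_codons()].
#' @param weights A weight table from [cai_weights()] or
#'   [cai_reference_weights()].
#' @return A tibble `id`, `cai` (`NA` when a gene has no weighted codons).
#' @export
cai <- function(counts, weights = cai_reference_weights("yeast")) {
  stopifnot(all(weights$w > 0), all(weights$w <= 1))
  m <- counts_matrix(counts)[, weights$codon, drop = FALSE]
  n <- unname(rowSums(m))
  lw <- log(weights$w)
  val <- exp(as.vector(m %*% lw) / n)
  tibble::tibble(id = counts$id, cai = ifelse(n > 0, val, NA_real_))
}

#' Effective number of codons (Wright's ENc)
#'
#' Measures overall synonymous codon usage bias irrespective of which codons
#' are preferred, ranging from 20 (one codon used per amino acid) to 61 (all
#' sense codons used uniformly). For each synonymous family with total count
#' n > 1 the codon homozygosity is `F = (n * sum(p_i^2) - 1) / (n - 1)` with
#' `p_i` the within-family codon frequencies; `ENc = 2 + 9/F2 + 1/F3 + 5/F4 +
#' 3/F6`, where `Fk` is the mean F over observed families of size k.
#'
#' Families with n <= 1 or F = 0 are dropped from their class mean. If no
#' three-fold family is observed (Ile absent), `F3` is substituted with the
#' class-weighted mean `(9*F2 + 5*F4)/14`; if any other class has no usable
#' family the gene's ENc is undefined (`NA`). Finite-sample noise can push
#' the raw value outside the theoretical range, so the result is clipped to
#' [20, 61] — genes reported at exactly 61 use the sense codons with no
#' detectable bias.
#'
#' @param counts A counts tibble from [count_codons()].
#' @return A tibble `id`, `enc`.
#' @examples
#' # one codon per amino acid -> maximal bias, ENc = 20
#' cds <- tibble::tibble(id = "g", sequence = paste0(
#'   "ATG", strrep("AAATTTGAA", 40), "TAA"))
#' @export
enc <- function(counts) {
  code <- genetic_code()
  m <- counts_matrix(counts)
  sub <- code[code$degenerate, ]
  fams <- split(sub$codon, sub$aa)
  fam_size <- vapply(fams, length, integer(1))

  # F per family, vectorised over genes; NA where the family is unusable
  fmat <- vapply(fams, function(cols) {
    x <- m[, cols, drop = FALSE]
    n <- rowSums(x)
    f <- (n * rowSums((x / n)^2) - 1) / (n - 1)
    f[n <= 1] <- NA_real_
    f[!is.na(f) & f <= 0] <- NA_real_
    f
  }, numeric(nrow(m)))
  if (nrow(m) == 1L) fmat <- matrix(fmat, nrow = 1,
                                    dimnames = list(NULL, names(fams)))

  class_mean <- function(k) {
    cols <- which(fam_size == k)
    f <- fmat[, cols, drop = FALSE]
    cnt <- rowSums(!is.na(f))
    ifelse(cnt > 0, rowMeans(f, na.rm = TRUE), NA_real_)
  }
  f2 <- class_mean(2L); f3 <- class_mean(3L)
  f4 <- class_mean(4L); f6 <- class_mean(6L)
  f3 <- ifelse(is.na(f3) & !is.na(f2) & !is.na(f4),
               (9 * f2 + 5 * f4) / 14, f3)
  val <- 2 + 9 / f2 + 1 / f3 + 5 / f4 + 3 / f6
  tibble::tibble(id = counts$id, enc = pmin(pmax(val, 20), 61))
}

#' Expected ENc under composition alone
#'
#' The reference curve for the ENc-plot: the ENc a gene would have if its
#' codon usage were shaped only by its third-position composition,
#' `ENc = 2 + s + 29 / (s^2 + (1 - s)^2)` with `s = GC3s`. Genes far below
#' the curve are biased beyond what composition explains.
#'
#' @param gc3s GC3s value(s) in `[0, 1]`.
#' @return Numeric vector of expected ENc values.
#' @examples
#' expected_enc(0.5) # 60.5
#' @export
expected_enc <- function(gc3s) {
  stopifnot(all(gc3s >= 0 & gc3s <= 1, na.rm = TRUE))
  2 + gc3s + 29 / (gc3s^2 + (1 - gc3s)^2)
}

#' Per-gene codon-usage indices
#'
#' Convenience wrapper assembling the CodonW-equivalent per-gene columns:
#' CAI, ENc and GC3s.
#'
#' @inheritParams cai
#' @return A tibble `id`, `cai`, `enc`, `gc3s`.
#' @export
cub_indices <- function(counts, weights = cai_reference_weights("yeast")) {
  dplyr::left_join(
    dplyr::left_join(cai(counts, weights), enc(counts), by = "id"),
    codon_composition(counts)[, c("id", "gc3s")],
    by = "id"
  )
}
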