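# Optimal and rare codon identification from CAI expression tails.

#' Select high- and low-expression gene tails by CAI
#'
#' The putative high- and low-expression datasets are the genes in the upper
#' and lower `fraction` of CAI values. Tail sizes use `ceiling(fraction * N)`
#' and ties at the boundary are broken by gene id order, so the selection is
#' reproducible.
#'
#' @param indices A per-gene index table with columns `id` and `cai`
#'   ([cub_indices()] output works directly).
#' @param fraction Tail fraction (default 0.05).
#' @return A tibble `id`, `cai`, `tail` (`"high"` or `"low"`).
#' @export
select_expression_tails <- function(indices, fraction = 0.05) {
  idx <- indices[!is.na(indices$cai), ]
  n <- nrow(idx)
  if (n < 40L) {
    stop("need at least 40 genes with CAI values to take ", fraction,
         " tails; got ", n, call. = FALSE)
  }
  k <- ceiling(fraction * n)
  high <- idx[order(-idx$cai, idx$id), ][seq_len(k), ]
  low <- idx[order(idx$cai, idx$id), ][seq_len(k), ]
  dplyr::bind_rows(
    tibble::tibble(id = high$id, cai = high$cai, tail = "high"),
    tibble::tibble(id = low$id, cai = low$cai, tail = "low")
  )
}

#' Call optimal and rare codons from expression-tail counts
#'
#' For each of the 59 degenerate sense codons, compares its usage between a
#' pooled high-expression and a pooled low-expression gene set with a 2x2
#' Pearson chi-squared test (no continuity correction) of the codon against
#' the rest of its synonymous family — the family-conditional construction
#' under which "used more frequently" aligns with RSCU. A codon is *optimal*
#' when its usage is significantly higher in the high-expression pool
#' (p < 0.05 and `rscu_high > rscu_low`), annotated `"*"` for p < 0.01 and
#' `"@"` for 0.01 <= p < 0.05. Codons with genome-wide RSCU > 1 are
#' *preferred*; genome-wide RSCU < 0.1 marks *rare* codons. No
#' multiple-testing adjustment is applied (raw 0.05/0.01 thresholds);
#' set `adjust` for a Benjamini-Hochberg variant.
#'
#' @param high_counts,low_counts Counts tibbles for the two tails (pooled
#'   internally).
#' @param genome_counts Counts tibble for the whole genome (pooled
#'   internally), used for the preferred/rare classification.
#' @param alpha,alpha_strict Significance thresholds (defaults 0.05, 0.01).
#' @param adjust P-value adjustment method passed to [stats::p.adjust()]
#'   (default `"none"`).
#' @param test `"codon"` (default): each codon against the rest of its
#'   family; `"family"`: one chi-squared over the whole family's
#'   high-vs-low contingency table, assigning the family-level p to each
#'   codon.
#' @return A tibble with one row per degenerate sense codon: `codon`, `aa`,
#'   `third_base`, `count_high`, `count_low`, `rscu_high`, `rscu_low`,
#'   `rscu_genome`, `chisq`, `p_value`, `preferred`, `optimal` (`"*"`,
#'   `"@"` or `NA`), `rare`, `testable`.
#' @export
call_optimal_codons <- function(high_counts, low_counts, genome_counts,
                                alpha = 0.05, alpha_strict = 0.01,
                                adjust = "none",
                                test = c("codon", "family")) {
  test <- match.arg(test)
  code <- genetic_code()
  sub <- code[code$degenerate, ]
  hi <- counts_matrix(pool_codon_counts(high_counts))[1, sub$codon]
  lo <- counts_matrix(pool_codon_counts(low_counts))[1, sub$codon]

  rscu_of <- function(counts) {
    r <- rscu(pool_codon_counts(counts), include_stops = TRUE)
    r$rscu[match(sub$codon, r$codon)]
  }
  rscu_high <- rscu_of(high_counts)
  rscu_low <- rscu_of(low_counts)
  rscu_genome <- rscu_of(genome_counts)

  fam <- split(seq_len(nrow(sub)), sub$aa)
  chisq <- rep(NA_real_, nrow(sub))
  pval <- rep(NA_real_, nrow(sub))
  testable <- rep(FALSE, nrow(sub))
  for (cols in fam) {
    nh <- sum(hi[cols]); nl <- sum(lo[cols])
    if (nh == 0 || nl == 0) next
    if (test == "family") {
      tab <- rbind(hi[cols], lo[cols])
      keep <- colSums(tab) > 0
      if (sum(keep) < 2) next
      ct <- suppressWarnings(stats::chisq.test(tab[, keep], correct = FALSE))
      chisq[cols] <- unname(ct$statistic)
      pval[cols] <- ct$p.value
      testable[cols] <- TRUE
    } else {
      for (j in cols) {
        tab <- matrix(c(hi[j], nh - hi[j], lo[j], nl - lo[j]),
                      nrow = 2, byrow = TRUE)
        if (any(colSums(tab) == 0)) next
        ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
        chisq[j] <- unname(ct$statistic)
        pval[j] <- ct$p.value
        testable[j] <- TRUE
      }
    }
  }
  pval <- stats::p.adjust(pval, method = adjust)

  higher <- !is.na(rscu_high) & !is.na(rscu_low) & rscu_high > rscu_low
  optimal <- rep(NA_character_, nrow(sub))
  sig <- testable & !is.na(pval) & pval < alpha & higher
  optimal[sig] <- ifelse(pval[sig] < alpha_strict, "*", "@")

  tibble::tibble(
    codon = sub$codon, aa = sub$aa, third_base = sub$third_base,
    count_high = unname(hi), count_low = unname(lo),
    rscu_high = rscu_high, rscu_low = rscu_low, rscu_genome = rscu_genome,
    chisq = chisq, p_value = pval,
    preferred = !is.na(rscu_genome) & rscu_genome > 1,
    optimal = optimal,
    rare = !is.na(rscu_genome) & rscu_genome < 0.1,
    testable = testable
  )
}

#' Third-base summary of preferred, optimal and rare codons
#'
#' Tallies the codon classes of [call_optimal_codons()] by their third base
#' (A/U/G/C and the A/U vs G/C split) — the summary under which genome-wide
#' third-position preference becomes visible.
#'
#' @param optimal_table Output of [call_optimal_codons()].
#' @return A tibble `category` (`"preferred"`, `"optimal"`, `"rare"`),
#'   `third` (`"A"`, `"U"`, `"G"`, `"C"`, `"A/U"`, `"G/C"`, `"total"`),
#'   `n_codons`.
#' @export
optimal_codon_summary <- function(optimal_table) {
  classes <- list(
    preferred = optimal_table$preferred,
    optimal = !is.na(optimal_table$optimal),
    rare = optimal_table$rare
  )
  third <- ifelse(optimal_table$third_base == "T", "U",
                  optimal_table$third_base)
  purrr::map_dfr(names(classes), function(cl) {
    keep <- classes[[cl]]
    tb <- third[keep]
    tibble::tibble(
      category = cl,
      third = c("A", "U", "G", "C", "A/U", "G/C", "total"),
      n_codons = c(sum(tb == "A"), sum(tb == "U"), sum(tb == "G"),
                   sum(tb == "C"), sum(tb %in% c("A", "U")),
                   sum(tb %in% c("G", "C")), length(tb))
    )
  })
}
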