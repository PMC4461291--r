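# Standard genetic code as a tidy lookup table, derived once from
# Biostrings::GENETIC_CODE and cached for the session.

.codonusage_env <- new.env(parent = emptyenv())

#' The standard genetic code as a tidy table
#'
#' Returns one row per codon (DNA alphabet, alphabetical order AAA..TTT) with
#' the amino acid it encodes, its synonymous family and the family size.
#' Synonymous "families" group codons by amino acid; the three stop codons
#' form the family `"*"`. Under the standard code there are 2 single-codon
#' families (Met, Trp), 9 two-fold, 1 three-fold (Ile), 5 four-fold and 3
#' six-fold families, so the 18 degenerate sense families cover 59 codons --
#' the informative codons of codon-usage analysis.
#'
#' @return A tibble with columns:
#' \describe{
#'   \item{codon}{codon, DNA alphabet (e.g. `"ATG"`).}
#'   \item{aa}{one-letter amino acid code, `"*"` for stop.}
#'   \item{family_size}{number of synonymous codons for this amino acid
#'     (3 for stops).}
#'   \item{third_base}{base at codon position 3.}
#'   \item{third_at}{`TRUE` if the third base is A or T (U).}
#'   \item{stop}{stop codon flag.}
#'   \item{sense}{sense codon flag (61 codons).}
#'   \item{degenerate}{sense codon in a family of size >= 2 (59 codons).}
#'   \item{gc1, gc2, gc3}{0/1 indicators: G or C at positions 1, 2, 3.}
#' }
#' @examples
#' code <- genetic_code()
#' dplyr::count(code[code$sense, ], family_size)
#' @export
genetic_code <- function() {
  if (!is.null(.codonusage_env$code)) {
    return(.codonusage_env$code)
  }
  gc_map <- Biostrings::GENETIC_CODE
  codon <- sort(names(gc_map))
  aa <- unname(gc_map[codon])
  is_gc <- function(b) as.integer(b %in% c("G", "C"))
  b1 <- substr(codon, 1, 1)
  b2 <- substr(codon, 2, 2)
  b3 <- substr(codon, 3, 3)
  tbl <- tibble::tibble(
    codon = codon,
    aa = aa,
    third_base = b3,
    third_at = b3 %in% c("A", "T"),
    stop = aa == "*",
    gc1 = is_gc(b1),
    gc2 = is_gc(b2),
    gc3 = is_gc(b3)
  )
  fam_size <- table(tbl$aa)
  tbl$family_size <- as.integer(fam_size[tbl$aa])
  tbl$sense <- !tbl$stop
  tbl$degenerate <- tbl$sense & tbl$family_size >= 2L
  tbl <- tbl[, c("codon", "aa", "family_size", "third_base", "third_at",
                 "stop", "sense", "degenerate", "gc1", "gc2", "gc3")]
  .codonusage_env$code <- tbl
  tbl
}

# Codon universe helpers. `single` = AUG + UGG; `p12` excludes Met/Trp;
# `p3` additionally excludes stops and the Ile family; `gc3s` = degenerate
# sense codons (Ile in, Met/Trp/stops out); `fourfold` = four-fold families
# only (classic PR2 universe).
codon_universe <- function(which = c("all", "p12", "p3", "gc3s", "fourfold",
                                     "sense", "degenerate")) {
  which <- match.arg(which)
  code <- genetic_code()
  keep <- switch(which,
    all = rep(TRUE, nrow(code)),
    sense = code$sense,
    p12 = !(code$codon %in% c("ATG", "TGG")),
    p3 = !(code$codon %in% c("ATG", "TGG")) & !code$stop & code$aa != "I",
    gc3s = code$degenerate,
    degenerate = code$degenerate,
    fourfold = code$sense & code$family_size == 4L
  )
  code$codon[keep]
}
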