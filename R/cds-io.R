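# CDS FASTA ingestion, filtering and codon counting.

#' Read coding sequences from a FASTA file
#'
#' Reads a multi-record nucleotide FASTA into a tidy table of coding
#' sequences. Sequences are upper-cased and RNA `U` is normalised to `T`;
#' FASTA headers are kept verbatim as gene ids.
#'
#' @param path Path to a nucleotide FASTA file.
#' @return A tibble with columns `id`, `sequence`, `length` (bases).
#'   An empty file yields an empty tibble with a warning.
#' @seealso [filter_cds()], [count_codons()]
#' @export
read_cds_fasta <- function(path) {
  stopifnot(file.exists(path))
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("malformed FASTA in ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  if (length(set) == 0L) {
    warning("no records in ", path)
    return(tibble::tibble(id = character(), sequence = character(),
                          length = integer()))
  }
  seqs <- toupper(as.character(set))
  seqs <- gsub("U", "T", seqs, fixed = TRUE)
  bad <- grepl("[^ACGTRYSWKMBDHVN]", seqs)
  if (any(bad)) {
    stop("record(s) with illegal characters: ",
         paste(names(set)[bad], collapse = ", "), call. = FALSE)
  }
  tibble::tibble(id = names(set), sequence = unname(seqs),
                 length = nchar(seqs))
}

#' Write coding sequences to FASTA
#'
#' @param cds A tibble with columns `id` and `sequence`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cds_fasta <- function(cds, path) {
  set <- Biostrings::BStringSet(cds$sequence)
  names(set) <- cds$id
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

#' Filter coding sequences for codon-usage analysis
#'
#' Keeps sequences that are at least `min_len` bases long (the conventional
#' 300 bp floor that avoids small-size outliers), a whole number of codons,
#' and free of in-frame internal stop codons (a terminal stop is allowed).
#' The per-reason drop tally is attached as the `"filter_report"` attribute
#' and can be retrieved with [filter_report()].
#'
#' @param cds A tibble as returned by [read_cds_fasta()].
#' @param min_len Minimum CDS length in bases (default 300).
#' @return The kept rows of `cds`, with a `filter_report` attribute: a tibble
#'   of `id`, `length`, `kept`, `reason` (`NA` for kept records; otherwise
#'   `"short"`, `"frame"` or `"internal_stop"`, assessed in that order).
#' @examples
#' cds <- tibble::tibble(
#'   id = c("a", "b"),
#'   sequence = c(strrep("ATGAAAGGG", 40), strrep("ATGAAAGGG", 30)),
#'   length = c(360L, 270L)
#' )
#' kept <- filter_cds(cds)
#' filter_report(kept)
#' @export
filter_cds <- function(cds, min_len = 300) {
  stopifnot(min_len > 0)
  n <- nrow(cds)
  reason <- rep(NA_character_, n)
  len <- nchar(cds$sequence)
  reason[is.na(reason) & len < min_len] <- "short"
  reason[is.na(reason) & len %% 3L != 0L] <- "frame"
  todo <- which(is.na(reason))
  if (length(todo)) {
    stops <- c("TAA", "TAG", "TGA")
    has_internal_stop <- vapply(todo, function(i) {
      s <- cds$sequence[i]
      nc <- nchar(s) %/% 3L
      if (nc <= 1L) return(FALSE)
      starts <- seq.int(1L, by = 3L, length.out = nc - 1L)
      any(substring(s, starts, starts + 2L) %in% stops)
    }, logical(1))
    reason[todo[has_internal_stop]] <- "internal_stop"
  }
  kept <- cds[is.na(reason), , drop = FALSE]
  report <- tibble::tibble(id = cds$id, length = len,
                           kept = is.na(reason), reason = reason)
  attr(kept, "filter_report") <- report
  kept
}

#' @rdname filter_cds
#' @param x An object returned by [filter_cds()].
#' @export
filter_report <- function(x) {
  rep <- attr(x, "filter_report")
  if (is.null(rep)) {
    stop("no filter report attached; was this object returned by filter_cds()?",
         call. = FALSE)
  }
  rep
}

#' Write a CDS filter report as TSV
#'
#' @param x An object returned by [filter_cds()], or a report tibble.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_filter_report <- function(x, path) {
  rep <- if (is.data.frame(x) && all(c("kept", "reason") %in% names(x))) {
    x
  } else {
    filter_report(x)
  }
  utils::write.table(rep, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Count in-frame codons per coding sequence
#'
#' Counts non-overlapping in-frame triplets for each sequence. Triplets
#' containing any non-ACGT symbol (ambiguity codes) are skipped, not imputed,
#' and tallied in `n_skipped`. The terminal stop codon is counted by default
#' so that stop-codon usage can be reported alongside sense codons; set
#' `include_terminal_stop = FALSE` to drop it.
#'
#' @param cds A tibble with columns `id` and `sequence` (in-frame CDS).
#' @param include_terminal_stop Count the final codon when it is a stop?
#' @return A wide tibble: `id`, `n_skipped`, then one integer column per
#'   codon (AAA..TTT). For every row,
#'   `3 * (rowSums(counts) + n_skipped)` equals the (truncated) CDS length
#'   when the terminal stop is included.
#' @examples
#' cds <- tibble::tibble(id = "g1", sequence = "ATGAAATAA")
#' counts <- count_codons(cds)
#' counts$ATG + counts$AAA + counts$TAA
#' @export
count_codons <- function(cds, include_terminal_stop = TRUE) {
  code <- genetic_code()
  dna <- Biostrings::DNAStringSet(
    substr(cds$sequence, 1L, (nchar(cds$sequence) %/% 3L) * 3L)
  )
  m <- Biostrings::trinucleotideFrequency(dna, step = 3)
  m <- m[, code$codon, drop = FALSE]
  n_codons <- nchar(cds$sequence) %/% 3L
  if (!include_terminal_stop) {
    last <- substring(cds$sequence, (n_codons - 1L) * 3L + 1L, n_codons * 3L)
    is_stop <- last %in% c("TAA", "TAG", "TGA")
    if (any(is_stop)) {
      idx <- cbind(which(is_stop), match(last[is_stop], colnames(m)))
      m[idx] <- m[idx] - 1L
      n_codons[is_stop] <- n_codons[is_stop] - 1L
    }
  }
  out <- tibble::tibble(id = cds$id,
                        n_skipped = as.integer(n_codons - rowSums(m)))
  dplyr::bind_cols(out, tibble::as_tibble(m))
}

# Internal: codon count columns of a counts tibble as a plain matrix with
# genes as rows.
counts_matrix <- function(counts) {
  code <- genetic_code()
  m <- as.matrix(counts[, code$codon, drop = FALSE])
  rownames(m) <- counts$id
  storage.mode(m) <- "double"
  m
}

#' Pool per-gene codon counts into one genome-level row
#'
#' @param counts A counts tibble from [count_codons()].
#' @param id Label for the pooled row.
#' @return A one-row counts tibble.
#' @export
pool_codon_counts <- function(counts, id = "pooled") {
  code <- genetic_code()
  m <- counts_matrix(counts)
  out <- tibble::tibble(id = id, n_skipped = sum(counts$n_skipped))
  dplyr::bind_cols(out, tibble::as_tibble(t(colSums(m))))[
    , c("id", "n_skipped", code$codon)]
}
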