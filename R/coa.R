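# Correspondence analysis of the gene x codon RSCU table.

# Internal: genes x 59 RSCU matrix over the degenerate sense codons.
# Families unobserved in a gene give NA.
rscu_matrix <- function(counts) {
  code <- genetic_code()
  sub <- code[code$degenerate, ]
  m <- counts_matrix(counts)[, sub$codon, drop = FALSE]
  fam <- split(seq_len(nrow(sub)), sub$aa)
  r <- matrix(NA_real_, nrow(m), ncol(m), dimnames = dimnames(m))
  for (cols in fam) {
    n <- rowSums(m[, cols, drop = FALSE])
    r[, cols] <- sweep(m[, cols, drop = FALSE], 1, n / length(cols), "/")
    r[n == 0, cols] <- NA_real_
  }
  r
}

#' Correspondence analysis of codon usage
#'
#' Classic correspondence analysis of the genes-by-codons table of RSCU
#' values over the 59 informative codons (degenerate sense codons): the
#' table is scaled to a correspondence matrix, row and column masses are
#' computed, and the standardized residuals are decomposed by SVD. Genes and
#' codons are returned in principal coordinates and each axis carries an
#' inertia (variance) fraction. Because each gene's RSCU values sum to a
#' constant within every synonymous family, the residual table has at most
#' 41 axes of nonzero inertia (59 codons minus 18 family constraints).
#'
#' RSCU entries for families unobserved in a gene are imputed with the
#' family-neutral value 1 (flagged in `n_imputed`); the raw-count variant is
#' available via `input = "counts"`. The sign of each axis is arbitrary in
#' CA, so axis 1 is oriented to correlate non-negatively with gene GC3s and
#' the remaining axes so that their strongest codon loading is positive,
#' making outputs reproducible across SVD implementations.
#'
#' @param counts A counts tibble from [count_codons()] (>= 3 genes).
#' @param n_axes Number of axes to retain in the coordinate tables
#'   (default 4).
#' @param input `"rscu"` (default) or `"counts"`.
#' @return An object of class `"cub_coa"` with elements `gene_coords`
#'   (tibble: `id`, `axis1`..), `codon_coords` (tibble: `codon`, `axis1`..),
#'   `inertia` (tibble over all axes: `axis`, `inertia`, `fraction`),
#'   `n_axes`, `n_imputed`.
#' @export
correspondence_analysis <- function(counts, n_axes = 4,
                                    input = c("rscu", "counts")) {
  input <- match.arg(input)
  if (nrow(counts) < 3L) stop("need at least 3 genes", call. = FALSE)
  code <- genetic_code()
  sub <- code[code$degenerate, ]
  if (input == "rscu") {
    x <- rscu_matrix(counts)
    n_imputed <- sum(is.na(x))
    x[is.na(x)] <- 1
  } else {
    x <- counts_matrix(counts)[, sub$codon, drop = FALSE]
    n_imputed <- 0L
    keep <- rowSums(x) > 0
    x <- x[keep, , drop = FALSE]
  }
  p <- x / sum(x)
  r <- rowSums(p)
  cm <- colSums(p)
  s <- (p - r %o% cm) / sqrt(r %o% cm)
  sv <- svd(s)
  d <- sv$d
  tol <- max(dim(x)) * max(d) * .Machine$double.eps
  rank <- sum(d > tol)
  # rank 0 (all rows proportional): keep one axis of all-zero coordinates
  k <- min(n_axes, max(rank, 1L))
  inertia <- d^2

  row_coords <- sweep(sv$u[, seq_len(k), drop = FALSE] %*%
                        diag(d[seq_len(k)], k), 1, sqrt(r), "/")
  col_coords <- sweep(sv$v[, seq_len(k), drop = FALSE] %*%
                        diag(d[seq_len(k)], k), 1, sqrt(cm), "/")

  # orient axes deterministically
  gc3s_vals <- codon_composition(counts)$gc3s
  flip <- rep(1, k)
  if (k >= 1) {
    rho <- suppressWarnings(
      stats::cor(row_coords[, 1], gc3s_vals, method = "spearman",
                 use = "complete.obs")
    )
    if (!is.na(rho) && rho < 0) flip[1] <- -1
  }
  if (k >= 2) {
    for (a in 2:k) {
      j <- which.max(abs(col_coords[, a]))
      if (col_coords[j, a] < 0) flip[a] <- -1
    }
  }
  row_coords <- sweep(row_coords, 2, flip, "*")
  col_coords <- sweep(col_coords, 2, flip, "*")

  axis_names <- paste0("axis", seq_len(k))
  gene_coords <- tibble::as_tibble(row_coords, .name_repair = ~axis_names)
  gene_coords <- dplyr::bind_cols(tibble::tibble(id = rownames(x)),
                                  gene_coords)
  codon_coords <- tibble::as_tibble(col_coords, .name_repair = ~axis_names)
  codon_coords <- dplyr::bind_cols(tibble::tibble(codon = sub$codon),
                                   codon_coords)
  structure(
    list(
      gene_coords = gene_coords,
      codon_coords = codon_coords,
      inertia = tibble::tibble(
        axis = seq_along(inertia), inertia = inertia,
        fraction = if (sum(inertia) > 0) inertia / sum(inertia) else
          rep(0, length(inertia))),
      n_axes = k,
      n_imputed = n_imputed
    ),
    class = "cub_coa"
  )
}

#' @export
print.cub_coa <- function(x, ...) {
  cat("Correspondence analysis of codon usage:",
      nrow(x$gene_coords), "genes x", nrow(x$codon_coords), "codons\n")
  fr <- x$inertia$fraction[seq_len(min(4, nrow(x$inertia)))]
  cat("  inertia fractions (first axes):",
      paste(sprintf("%.1f%%", 100 * fr), collapse = ", "), "\n")
  if (x$n_imputed > 0) {
    cat("  ", x$n_imputed, "missing RSCU entries imputed at 1.0\n")
  }
  invisible(x)
}

#' Tidy the per-axis inertia of a correspondence analysis
#'
#' @param x A `"cub_coa"` object.
#' @param ... Unused.
#' @return The per-axis inertia tibble (`axis`, `inertia`, `fraction`).
#' @method tidy cub_coa
#' @export
tidy.cub_coa <- function(x, ...) {
  x$inertia
}

#' One-row summary of a correspondence analysis
#'
#' @param x A `"cub_coa"` object.
#' @param ... Unused.
#' @return A one-row tibble: `n_genes`, `n_codons`, `total_inertia`,
#'   `axis1_fraction`, `axis2_fraction`, `first4_fraction`, `n_axes`.
#' @method glance cub_coa
#' @export
glance.cub_coa <- function(x, ...) {
  fr <- x$inertia$fraction
  tibble::tibble(
    n_genes = nrow(x$gene_coords),
    n_codons = nrow(x$codon_coords),
    total_inertia = sum(x$inertia$inertia),
    axis1_fraction = fr[1],
    axis2_fraction = if (length(fr) >= 2) fr[2] else NA_real_,
    first4_fraction = sum(fr[seq_len(min(4, length(fr)))]),
    n_axes = x$n_axes
  )
}

#' Plot genes on the first two CA axes
#'
#' @param object A `"cub_coa"` object.
#' @param ... Unused.
#' @return A ggplot of gene coordinates on axes 1 and 2, axis labels
#'   annotated with inertia fractions.
#' @method autoplot cub_coa
#' @export
autoplot.cub_coa <- function(object, ...) {
  fr <- object$inertia$fraction
  ggplot2::ggplot(object$gene_coords,
                  ggplot2::aes(x = .data$axis1, y = .data$axis2)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::labs(
      x = sprintf("Axis 1 (%.1f%%)", 100 * fr[1]),
      y = sprintf("Axis 2 (%.1f%%)", 100 * fr[2])
    ) +
    ggplot2::theme_minimal()
}

#' Correlate CA axes with codon-usage indices
#'
#' Spearman correlations between gene coordinates on the leading CA axes and
#' per-gene CAI, ENc and GC3s — the diagnostic that identifies which
#' biological gradients the axes capture.
#'
#' @param coa A `"cub_coa"` object.
#' @param indices A per-gene table with `id` plus the columns in `vars`
#'   ([cub_indices()] output).
#' @param vars Index columns to correlate (default `cai`, `enc`, `gc3s`).
#' @return A tibble `axis`, `index`, `rho`, `p_value`.
#' @export
axis_correlations <- function(coa, indices, vars = c("cai", "enc", "gc3s")) {
  vars <- intersect(vars, names(indices))
  d <- dplyr::inner_join(coa$gene_coords, indices, by = "id")
  axes <- grep("^axis", names(coa$gene_coords), value = TRUE)
  tidyr::expand_grid(axis = axes, index = vars) |>
    purrr::pmap_dfr(function(axis, index) {
      x <- d[[axis]]; y <- d[[index]]
      ok <- stats::complete.cases(x, y)
      ct <- suppressWarnings(
        stats::cor.test(x[ok], y[ok], method = "spearman", exact = FALSE)
      )
      tibble::tibble(axis = axis, index = index,
                     rho = unname(ct$estimate), p_value = ct$p.value)
    })
}
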