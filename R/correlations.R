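# Correlation matrices, group comparisons and inter-genome clustering.

#' Spearman correlation matrix of composition and bias indices
#'
#' Pairwise Spearman rank correlations (two-sided p-values, pairwise-complete
#' observations) among the per-gene quantities that drive codon usage:
#' `gc_cds`, `p1`, `p2`, `p12`, `p3` and `enc` by default.
#'
#' @param data A per-gene table containing the columns in `vars` (join
#'   [codon_composition()] and [cub_indices()] output by `id`).
#' @param vars Character vector of columns to correlate.
#' @return A long tibble `var1`, `var2`, `rho`, `p_value`, `n` covering each
#'   unordered pair once (lower triangle); constant columns give `NA` rho.
#' @export
correlation_matrix <- function(data,
                               vars = c("gc_cds", "p1", "p2", "p12", "p3",
                                        "enc")) {
  stopifnot(all(vars %in% names(data)))
  if (nrow(data) < 3L) stop("need at least 3 genes", call. = FALSE)
  pairs <- utils::combn(vars, 2, simplify = FALSE)
  purrr::map_dfr(pairs, function(pr) {
    x <- data[[pr[1]]]; y <- data[[pr[2]]]
    ok <- stats::complete.cases(x, y)
    if (sum(ok) < 3 || stats::var(x[ok]) == 0 || stats::var(y[ok]) == 0) {
      return(tibble::tibble(var1 = pr[1], var2 = pr[2], rho = NA_real_,
                            p_value = NA_real_, n = sum(ok)))
    }
    ct <- suppressWarnings(
      stats::cor.test(x[ok], y[ok], method = "spearman", exact = FALSE)
    )
    tibble::tibble(var1 = pr[1], var2 = pr[2], rho = unname(ct$estimate),
                   p_value = ct$p.value, n = sum(ok))
  })
}

#' Wide view of a correlation matrix with significance stars
#'
#' @param cor_tbl Output of [correlation_matrix()].
#' @param star_alpha Significance threshold for the star annotation
#'   (default 0.01).
#' @return A wide tibble of formatted `rho` values, starred at
#'   `p < star_alpha`.
#' @export
correlation_matrix_wide <- function(cor_tbl, star_alpha = 0.01) {
  cor_tbl$label <- ifelse(
    is.na(cor_tbl$rho), "NA",
    paste0(sprintf("%.3f", cor_tbl$rho),
           ifelse(!is.na(cor_tbl$p_value) & cor_tbl$p_value < star_alpha,
                  "*", ""))
  )
  tidyr::pivot_wider(cor_tbl[, c("var1", "var2", "label")],
                     names_from = "var2", values_from = "label")
}

#' Compare codon-usage indices across species and between groups
#'
#' One-way ANOVA of a per-gene index across species, plus a Welch two-sample
#' t-test between two groups of species (e.g. a compact-genome lineage versus
#' the rest). Observations are per-gene values pooled by species.
#'
#' @param data A table with one row per gene: a `species` column, the index
#'   columns, and (for the t-test) group membership via `grouping`.
#' @param indices Character vector of index columns (default CAI and ENc).
#' @param grouping Optional named character vector mapping species to one of
#'   two group labels; when omitted only the ANOVA is run.
#' @return A tibble with one row per index: `index`, `anova_f`, `anova_p`,
#'   and (when `grouping` is given) `t_statistic`, `t_p`.
#' @export
group_comparison <- function(data, indices = c("cai", "enc"),
                             grouping = NULL) {
  stopifnot("species" %in% names(data), all(indices %in% names(data)))
  counts <- table(data$species)
  if (length(counts) < 2L || any(counts < 2L)) {
    stop("need >= 2 species with >= 2 genes each", call. = FALSE)
  }
  if (!is.null(grouping)) {
    miss <- setdiff(unique(data$species), names(grouping))
    if (length(miss)) {
      stop("species missing from grouping: ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
    grp <- factor(unname(grouping[data$species]))
    if (nlevels(grp) != 2L) stop("grouping must define exactly 2 groups",
                                 call. = FALSE)
  }
  purrr::map_dfr(indices, function(v) {
    d <- data[!is.na(data[[v]]), ]
    fit <- stats::aov(d[[v]] ~ factor(d$species))
    s <- summary(fit)[[1]]
    out <- tibble::tibble(index = v, anova_f = s[1, "F value"],
                          anova_p = s[1, "Pr(>F)"])
    if (!is.null(grouping)) {
      g <- factor(unname(grouping[d$species]))
      tt <- stats::t.test(d[[v]] ~ g)  # Welch by default
      out$t_statistic <- unname(tt$statistic)
      out$t_p <- tt$p.value
    }
    out
  })
}

#' Cluster genomes by their RSCU profiles
#'
#' Agglomerative average-linkage clustering of genome-level RSCU vectors
#' (the 59 informative codons) under Euclidean distance. Genomes are ordered
#' by label before clustering so tie-breaking is deterministic.
#'
#' @param genome_rscu A long tibble of genome-level RSCU with columns
#'   `genome` (or `id`), `codon`, `rscu` — e.g. bind the [rscu()] output of
#'   several pooled genomes.
#' @return An `hclust` object with genome labels.
#' @export
cluster_species <- function(genome_rscu) {
  lab <- if ("genome" %in% names(genome_rscu)) "genome" else "id"
  sub <- genome_rscu[genome_rscu$codon %in% codon_universe("degenerate"), ]
  wide <- tidyr::pivot_wider(sub[, c(lab, "codon", "rscu")],
                             names_from = "codon", values_from = "rscu")
  wide <- wide[order(wide[[lab]]), ]
  m <- as.matrix(wide[, -1])
  rownames(m) <- wide[[lab]]
  if (nrow(m) < 2L) stop("need at least 2 genomes", call. = FALSE)
  if (anyNA(m)) {
    warning("missing RSCU entries; using pairwise-complete distances")
    d <- stats::as.dist(outer(seq_len(nrow(m)), seq_len(nrow(m)),
      Vectorize(function(i, j) {
        ok <- stats::complete.cases(m[i, ], m[j, ])
        sqrt(sum((m[i, ok] - m[j, ok])^2))
      })))
    attr(d, "Labels") <- rownames(m)
  } else {
    d <- stats::dist(m, method = "euclidean")
  }
  stats::hclust(d, method = "average")
}

#' Write a species dendrogram as Newick
#'
#' @param hc An `hclust` object from [cluster_species()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(hc, path) {
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}
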