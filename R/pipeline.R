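# End-to-end pipeline: per-genome analyses, cross-genome comparisons and a
# machine-readable manifest.

#' Run the complete codon-usage-bias pipeline
#'
#' Orchestrates every analysis stage for one or more genomes: CDS filtering,
#' codon counting, per-gene composition and indices, genome RSCU, optimal
#' and rare codon calling from CAI tails, the composition/ENc correlation
#' matrix, the neutrality fit, the PR2 summary, ENc-plot data and
#' correspondence analysis; across genomes it clusters RSCU profiles and,
#' when a grouping is supplied, compares CAI and ENc between groups. All
#' numeric results are collected in a nested manifest that can be written as
#' JSON; the tables are pure views of the manifest.
#'
#' @param genomes A named list of CDS tibbles (`id`, `sequence`) or of FASTA
#'   paths; names are the genome labels and must be unique.
#' @param min_len Minimum CDS length in bases (default 300).
#' @param weights CAI reference weights (default packaged yeast).
#' @param tail_fraction CAI tail fraction for optimal-codon calling
#'   (default 0.05).
#' @param pr2_universe Third-position universe for PR2 quantities
#'   (`"p3"` or `"fourfold"`).
#' @param grouping Optional named character vector mapping genome labels to
#'   two group labels for the cross-genome comparison.
#' @param n_axes CA axes to retain (default 4).
#' @param output_dir Optional directory; when given, per-genome TSVs, the
#'   Newick dendrogram and `manifest.json` are written there.
#' @return A list of class `"cub_pipeline"`: `genomes` (per-genome result
#'   lists), `cross` (clustering, group comparison), `manifest` (nested list
#'   of every statistic).
#' @export
run_cub_pipeline <- function(genomes, min_len = 300,
                             weights = cai_reference_weights("yeast"),
                             tail_fraction = 0.05,
                             pr2_universe = c("p3", "fourfold"),
                             grouping = NULL, n_axes = 4,
                             output_dir = NULL) {
  pr2_universe <- match.arg(pr2_universe)
  labels <- names(genomes)
  if (is.null(labels) || any(labels == "") || anyDuplicated(labels)) {
    stop("genomes must be a named list with unique, non-empty labels",
         call. = FALSE)
  }
  if (!is.null(grouping)) {
    miss <- setdiff(labels, names(grouping))
    if (length(miss)) stop("grouping missing labels: ",
                           paste(miss, collapse = ", "), call. = FALSE)
  }

  per_genome <- purrr::map(labels, function(lab) {
    cds <- genomes[[lab]]
    if (is.character(cds)) cds <- read_cds_fasta(cds)
    kept <- filter_cds(cds, min_len = min_len)
    if (nrow(kept) < 40L) {
      stop("pipeline stage 'filter' failed for genome '", lab,
           "': fewer than 40 CDS retained", call. = FALSE)
    }
    counts <- count_codons(kept)
    profiles <- codon_composition(counts, pr2_universe = pr2_universe)
    indices <- cub_indices(counts, weights)
    genome_rscu <- rscu(pool_codon_counts(counts, id = lab))
    tails <- select_expression_tails(indices, fraction = tail_fraction)
    hi <- counts[counts$id %in% tails$id[tails$tail == "high"], ]
    lo <- counts[counts$id %in% tails$id[tails$tail == "low"], ]
    optimal <- call_optimal_codons(hi, lo, counts)
    list(
      label = lab,
      filter_report = filter_report(kept),
      counts = counts,
      profiles = profiles,
      indices = indices,
      genome_rscu = genome_rscu,
      genome_summary = genome_composition(counts, label = lab,
                                          pr2_universe = pr2_universe),
      tails = tails,
      optimal = optimal,
      optimal_summary = optimal_codon_summary(optimal),
      correlations = correlation_matrix(
        dplyr::inner_join(profiles, indices[, c("id", "enc")], by = "id")),
      neutrality = neutrality_fit(profiles),
      pr2 = pr2_summary(profiles, label = lab),
      coa = correspondence_analysis(counts, n_axes = n_axes)
    )
  })
  names(per_genome) <- labels

  cross <- list()
  if (length(labels) >= 2L) {
    all_rscu <- purrr::map_dfr(per_genome, function(g) {
      out <- g$genome_rscu
      out$genome <- g$label
      out
    })
    cross$cluster <- cluster_species(all_rscu)
    if (!is.null(grouping)) {
      idx <- purrr::map_dfr(per_genome, function(g) {
        out <- g$indices
        out$species <- g$label
        out
      })
      cross$group_comparison <- group_comparison(idx, grouping = grouping)
    }
  }

  manifest <- list(
    parameters = list(min_len = min_len, tail_fraction = tail_fraction,
                      pr2_universe = pr2_universe, n_axes = n_axes),
    genomes = purrr::map(per_genome, function(g) {
      coa_gl <- glance(g$coa)
      list(
        n_input = nrow(g$filter_report),
        n_kept = sum(g$filter_report$kept),
        composition_means = stats::setNames(
          as.list(g$genome_summary$mean_of_genes),
          g$genome_summary$statistic),
        mean_cai = mean(g$indices$cai, na.rm = TRUE),
        mean_enc = mean(g$indices$enc, na.rm = TRUE),
        neutrality = as.list(glance(g$neutrality)),
        pr2 = list(mean_au_bias = g$pr2$mean_au_bias,
                   mean_gc_bias = g$pr2$mean_gc_bias),
        n_optimal = sum(!is.na(g$optimal$optimal)),
        n_optimal_au = sum(!is.na(g$optimal$optimal) &
                             g$optimal$third_base %in% c("A", "T")),
        n_preferred = sum(g$optimal$preferred),
        n_rare = sum(g$optimal$rare),
        coa_axis_fractions = g$coa$inertia$fraction[
          seq_len(min(4, nrow(g$coa$inertia)))]
      )
    })
  )
  if (!is.null(cross$group_comparison)) {
    manifest$cross$group_comparison <- purrr::transpose(
      as.list(cross$group_comparison))
  }

  result <- structure(list(genomes = per_genome, cross = cross,
                           manifest = manifest),
                      class = "cub_pipeline")
  if (!is.null(output_dir)) write_pipeline_outputs(result, output_dir)
  result
}

#' @export
print.cub_pipeline <- function(x, ...) {
  cat("Codon-usage pipeline:", length(x$genomes), "genome(s)\n")
  for (g in x$genomes) {
    cat(sprintf(
      "  %s: %d genes, mean CAI %.3f, mean ENc %.2f, %d optimal codons\n",
      g$label, nrow(g$indices), mean(g$indices$cai, na.rm = TRUE),
      mean(g$indices$enc, na.rm = TRUE), sum(!is.na(g$optimal$optimal))))
  }
  invisible(x)
}

#' Write pipeline outputs to disk
#'
#' Emits, per genome, the filter report, per-gene indices, composition
#' profiles, genome RSCU table, optimal-codon table and its third-base
#' summary, plus the cross-genome Newick dendrogram and a JSON manifest.
#' All files are plain text (TSV / Newick / JSON).
#'
#' @param pipeline A `"cub_pipeline"` object.
#' @param output_dir Output directory (created if needed).
#' @return `output_dir`, invisibly.
#' @export
write_pipeline_outputs <- function(pipeline, output_dir) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(d, file) utils::write.table(
    d, file.path(output_dir, file), sep = "\t", quote = FALSE,
    row.names = FALSE)
  for (g in pipeline$genomes) {
    tsv(g$filter_report, paste0(g$label, "_filter.tsv"))
    tsv(g$indices, paste0(g$label, "_indices.tsv"))
    tsv(g$profiles, paste0(g$label, "_composition.tsv"))
    tsv(g$genome_rscu, paste0(g$label, "_rscu.tsv"))
    tsv(g$optimal, paste0(g$label, "_optimal.tsv"))
    tsv(g$optimal_summary, paste0(g$label, "_optimal_summary.tsv"))
    tsv(correlation_matrix_wide(g$correlations),
        paste0(g$label, "_correlations.tsv"))
  }
  if (!is.null(pipeline$cross$cluster)) {
    write_newick(pipeline$cross$cluster,
                 file.path(output_dir, "species_cluster.nwk"))
  }
  jsonlite::write_json(pipeline$manifest,
                       file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(output_dir)
}
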