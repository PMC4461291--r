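# Neutrality-plot regression and PR2 summary.

#' Neutrality-plot fit of P12 on P3
#'
#' Regresses the mean GC content of codon positions 1 and 2 (`p12`) on the
#' third-position GC content (`p3`) across the genes of a genome. Under
#' neutral mutational drift all three positions respond alike and genes fall
#' near the identity line (slope 1); directed mutational pressure on the
#' third position, or selection constraining positions 1-2, flattens the
#' regression towards slope 0. The slope expressed as a percentage is the
#' genome's *relative neutrality*. A Spearman rank correlation between
#' `p12` and `p3` accompanies the fit. Only genes with both values defined
#' are used.
#'
#' @param profiles A per-gene composition table from [codon_composition()]
#'   (needs columns `p12` and `p3`).
#' @return An object of class `"neutrality_fit"`; see [glance.neutrality_fit()]
#'   for the one-row summary and [autoplot.neutrality_fit()] for the plot.
#' @export
neutrality_fit <- function(profiles) {
  d <- profiles[stats::complete.cases(profiles[, c("p12", "p3")]),
                c("id", "p12", "p3")]
  if (nrow(d) < 3L) {
    stop("need at least 3 genes with complete (p12, p3) pairs", call. = FALSE)
  }
  if (stats::var(d$p3) == 0) {
    fit <- NULL
    slope <- NA_real_
    intercept <- NA_real_
  } else {
    fit <- stats::lm(p12 ~ p3, data = d)
    slope <- unname(stats::coef(fit)[2])
    intercept <- unname(stats::coef(fit)[1])
  }
  ct <- suppressWarnings(
    stats::cor.test(d$p12, d$p3, method = "spearman", exact = FALSE)
  )
  structure(
    list(
      data = d, fit = fit,
      slope = slope, intercept = intercept,
      spearman_rho = unname(ct$estimate), spearman_p = ct$p.value,
      n_genes = nrow(d),
      relative_neutrality = 100 * slope
    ),
    class = "neutrality_fit"
  )
}

#' @export
print.neutrality_fit <- function(x, ...) {
  cat("Neutrality-plot fit (P12 ~ P3), n =", x$n_genes, "genes\n")
  cat(sprintf("  slope %.4f (relative neutrality %.2f%%), intercept %.4f\n",
              x$slope, x$relative_neutrality, x$intercept))
  cat(sprintf("  Spearman rho %.3f, p = %.3g\n", x$spearman_rho,
              x$spearman_p))
  invisible(x)
}

#' Tidy a neutrality fit
#'
#' @param x A `"neutrality_fit"` object.
#' @param ... Unused.
#' @return A tibble of regression terms (`term`, `estimate`, `std.error`,
#'   `statistic`, `p.value`).
#' @method tidy neutrality_fit
#' @export
tidy.neutrality_fit <- function(x, ...) {
  if (is.null(x$fit)) {
    return(tibble::tibble(term = c("(Intercept)", "p3"),
                          estimate = NA_real_, std.error = NA_real_,
                          statistic = NA_real_, p.value = NA_real_))
  }
  s <- summary(x$fit)$coefficients
  tibble::tibble(term = rownames(s), estimate = unname(s[, 1]),
                 std.error = unname(s[, 2]), statistic = unname(s[, 3]),
                 p.value = unname(s[, 4]))
}

#' One-row summary of a neutrality fit
#'
#' @param x A `"neutrality_fit"` object.
#' @param ... Unused.
#' @return A one-row tibble: `slope`, `intercept`, `relative_neutrality`
#'   (slope as a percentage), `spearman_rho`, `spearman_p`, `n_genes`.
#' @method glance neutrality_fit
#' @export
glance.neutrality_fit <- function(x, ...) {
  tibble::tibble(
    slope = x$slope, intercept = x$intercept,
    relative_neutrality = x$relative_neutrality,
    spearman_rho = x$spearman_rho, spearman_p = x$spearman_p,
    n_genes = x$n_genes
  )
}

#' Neutrality plot
#'
#' @param object A `"neutrality_fit"` object.
#' @param ... Unused.
#' @return A ggplot: genes as points, fitted regression line (solid) and the
#'   identity line (dashed).
#' @method autoplot neutrality_fit
#' @export
autoplot.neutrality_fit <- function(object, ...) {
  d <- object$data
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$p3, y = .data$p12)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::labs(
      x = expression(P[3]), y = expression(P[12]),
      subtitle = sprintf("slope = %.3f, Spearman rho = %.3f",
                         object$slope, object$spearman_rho)
    ) +
    ggplot2::theme_minimal()
  if (!is.null(object$fit)) {
    p <- p + ggplot2::geom_abline(slope = object$slope,
                                  intercept = object$intercept)
  }
  p
}

#' Parity-rule-2 summary
#'
#' Mean AU-bias (`a3/(a3+u3)`) and GC-bias (`g3/(g3+c3)`) across genes.
#' Under composition alone both center on 0.5; departures reveal
#' strand- or selection-driven asymmetry between complementary bases at the
#' third position.
#'
#' @param profiles A per-gene composition table from [codon_composition()].
#' @param label Genome label.
#' @return A one-row tibble: `genome`, `mean_au_bias`, `mean_gc_bias`,
#'   `n_genes`.
#' @export
pr2_summary <- function(profiles, label = "genome") {
  tibble::tibble(
    genome = label,
    mean_au_bias = mean(profiles$au_bias, na.rm = TRUE),
    mean_gc_bias = mean(profiles$gc_bias, na.rm = TRUE),
    n_genes = sum(stats::complete.cases(profiles[, c("au_bias", "gc_bias")]))
  )
}

#' PR2 plot
#'
#' @param profiles A per-gene composition table from [codon_composition()].
#' @return A ggplot of GC-bias (x) vs AU-bias (y) with the (0.5, 0.5)
#'   parity point marked.
#' @export
plot_pr2 <- function(profiles) {
  d <- profiles[stats::complete.cases(profiles[, c("au_bias", "gc_bias")]), ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$gc_bias, y = .data$au_bias)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed") +
    ggplot2::geom_vline(xintercept = 0.5, linetype = "dashed") +
    ggplot2::labs(x = expression(G[3] / (G[3] + C[3])),
                  y = expression(A[3] / (A[3] + U[3]))) +
    ggplot2::theme_minimal()
}

#' ENc versus GC3s plot with the expected curve
#'
#' @param indices A per-gene index table from [cub_indices()] (columns
#'   `enc`, `gc3s`).
#' @return A ggplot of per-gene ENc against GC3s with the composition-only
#'   expectation [expected_enc()] overlaid.
#' @export
plot_enc_gc3s <- function(indices) {
  d <- indices[stats::complete.cases(indices[, c("enc", "gc3s")]), ]
  curve <- tibble::tibble(gc3s = seq(0.001, 0.999, length.out = 200))
  curve$enc <- pmin(expected_enc(curve$gc3s), 61)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$gc3s, y = .data$enc)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_line(data = curve, colour = "red") +
    ggplot2::coord_cartesian(ylim = c(20, 61)) +
    ggplot2::labs(x = expression(GC[3 * s]), y = "ENc") +
    ggplot2::theme_minimal()
}
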