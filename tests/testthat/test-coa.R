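test_that("homogeneous RSCU tables carry no inertia", {
  # identical codon usage in every gene: total inertia ~ 0
  code <- genetic_code()
  sense <- code$codon[code$sense]
  g <- purrr::map_dfr(1:5, ~counts_tbl(stats::setNames(rep(10, 61), sense),
                                       id = paste0("g", .x)))
  coa <- correspondence_analysis(g)
  expect_lt(sum(coa$inertia$inertia), 1e-20)
})

test_that("the residual rank never exceeds the 41 degrees of freedom", {
  set.seed(51)
  genes <- purrr::map_dfr(1:80, ~random_gene_counts(sample(100:250, 1),
                                                    id = paste0("g", .x)))
  coa <- correspondence_analysis(genes)
  expect_lte(sum(coa$inertia$inertia > 1e-10), 41L)
  # inertia fractions are a proper distribution
  expect_true(all(coa$inertia$fraction >= 0))
  expect_equal(sum(coa$inertia$fraction), 1)
})

test_that("CA reconstitutes the analysed table from its axes", {
  set.seed(52)
  genes <- purrr::map_dfr(1:10, ~random_gene_counts(150,
                                                    id = paste0("g", .x)))
  coa <- correspondence_analysis(genes, n_axes = 59)
  x <- codonusage:::rscu_matrix(genes)
  x[is.na(x)] <- 1
  p <- x / sum(x)
  r <- rowSums(p)
  cm <- colSums(p)
  f <- as.matrix(coa$gene_coords[, -1])
  g <- as.matrix(coa$codon_coords[, -1])
  d <- sqrt(coa$inertia$inertia[seq_len(ncol(f))])
  keep <- d > 1e-12
  recon <- (r %o% cm) *
    (1 + f[, keep] %*% diag(1 / d[keep]) %*% t(g[, keep]))
  expect_equal(unname(recon), unname(p), tolerance = 1e-9)
})

test_that("eigenvalues match an independent CA implementation", {
  skip_if_not_installed("vegan")
  set.seed(53)
  genes <- purrr::map_dfr(1:40, ~random_gene_counts(sample(100:200, 1),
                                                    id = paste0("g", .x)))
  coa <- correspondence_analysis(genes)
  x <- codonusage:::rscu_matrix(genes)
  x[is.na(x)] <- 1
  ev <- vegan::cca(x)$CA$eig
  expect_equal(unname(coa$inertia$inertia[1:10]), unname(ev[1:10]),
               tolerance = 1e-8)
})

test_that("axis 1 separates planted codon-preference populations", {
  a <- generate_genome(synthetic_spec(n_genes = 120, len_mean_bp = 600,
                                      au_odds = 4, seed = 54), prefix = "a")
  b <- generate_genome(synthetic_spec(n_genes = 120, len_mean_bp = 600,
                                      au_odds = 0.25, seed = 55),
                       prefix = "b")
  counts <- count_codons(dplyr::bind_rows(a$cds, b$cds))
  coa <- correspondence_analysis(counts)
  gc <- coa$gene_coords
  pop <- substr(gc$id, 1, 1)
  gap <- abs(mean(gc$axis1[pop == "a"]) - mean(gc$axis1[pop == "b"]))
  spread <- sqrt(stats::var(gc$axis1[pop == "a"]) +
                   stats::var(gc$axis1[pop == "b"]))
  expect_gt(gap / spread, 3)
  fr <- coa$inertia$fraction
  expect_gt(fr[1] / fr[2], 5)
})

test_that("gene coordinates are stable when one gene's counts double", {
  set.seed(56)
  genes <- purrr::map_dfr(1:50, ~random_gene_counts(200,
                                                    id = paste0("g", .x)))
  coa1 <- correspondence_analysis(genes)
  code <- genetic_code()
  genes2 <- genes
  genes2[1, code$codon] <- genes2[1, code$codon] * 2
  coa2 <- correspondence_analysis(genes2)
  # doubling counts leaves the gene's RSCU profile unchanged; only its mass
  # shifts, so its principal coordinate moves negligibly
  expect_equal(coa1$gene_coords$axis1[1], coa2$gene_coords$axis1[1],
               tolerance = 0.05)
})

test_that("inertia is invariant to gene and codon order", {
  set.seed(57)
  genes <- purrr::map_dfr(1:30, ~random_gene_counts(150,
                                                    id = paste0("g", .x)))
  coa1 <- correspondence_analysis(genes)
  coa2 <- correspondence_analysis(genes[sample(nrow(genes)), ])
  expect_equal(coa1$inertia$inertia, coa2$inertia$inertia, tolerance = 1e-9)
})

test_that("axis 1 tracks a planted GC3 gradient and sign is normalised", {
  g <- generate_genome(synthetic_spec(n_genes = 150, len_mean_bp = 600,
                                      gc3_range = c(0.2, 0.8), seed = 58))
  counts <- count_codons(g$cds)
  coa <- correspondence_analysis(counts)
  idx <- cub_indices(counts)
  ac <- axis_correlations(coa, idx)
  rho1 <- ac$rho[ac$axis == "axis1" & ac$index == "gc3s"]
  expect_gt(abs(rho1), 0.9)
  expect_gte(rho1, 0)  # orientation rule: non-negative with GC3s

  # flipping an axis by hand leaves |rho| unchanged
  coa_flipped <- coa
  coa_flipped$gene_coords$axis1 <- -coa_flipped$gene_coords$axis1
  ac2 <- axis_correlations(coa_flipped, idx)
  expect_equal(abs(ac2$rho[ac2$axis == "axis1" & ac2$index == "gc3s"]),
               abs(rho1))
})

test_that("glance and tidy summarise the decomposition", {
  set.seed(59)
  genes <- purrr::map_dfr(1:20, ~random_gene_counts(150,
                                                    id = paste0("g", .x)))
  coa <- correspondence_analysis(genes)
  gl <- glance(coa)
  expect_equal(gl$n_genes, 20L)
  expect_equal(gl$n_codons, 59L)
  expect_equal(gl$axis1_fraction, tidy(coa)$fraction[1])
  expect_equal(gl$first4_fraction, sum(tidy(coa)$fraction[1:4]))
})
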