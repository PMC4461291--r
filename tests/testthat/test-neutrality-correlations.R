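test_that("neutrality fit recovers exact linear relationships", {
  on_line <- tibble::tibble(id = as.character(1:5),
                            p3 = c(0.1, 0.3, 0.5, 0.7, 0.9))
  on_line$p12 <- on_line$p3
  fit <- neutrality_fit(on_line)
  expect_equal(fit$slope, 1)
  expect_equal(fit$spearman_rho, 1)
  expect_equal(fit$relative_neutrality, 100)

  flat <- tibble::tibble(id = as.character(1:5),
                         p3 = c(0.1, 0.3, 0.5, 0.7, 0.9), p12 = 0.4)
  expect_equal(neutrality_fit(flat)$slope, 0)

  # closed-form OLS on four points
  four <- tibble::tibble(id = as.character(1:4),
                         p3 = c(0.1, 0.2, 0.3, 0.4),
                         p12 = c(0.2, 0.25, 0.3, 0.35))
  fit <- neutrality_fit(four)
  expect_equal(fit$slope, 0.5, tolerance = 1e-12)
  expect_equal(fit$n_genes, 4L)
  expect_equal(glance(fit)$relative_neutrality, 50, tolerance = 1e-9)
})

test_that("neutrality fit handles degenerate and incomplete input", {
  const <- tibble::tibble(id = as.character(1:4), p3 = 0.5,
                          p12 = c(0.1, 0.2, 0.3, 0.4))
  fit <- neutrality_fit(const)
  expect_true(is.na(fit$slope))

  with_na <- tibble::tibble(id = as.character(1:5),
                            p3 = c(0.1, 0.2, NA, 0.3, 0.4),
                            p12 = c(0.2, 0.25, 0.5, 0.3, NA))
  expect_equal(neutrality_fit(with_na)$n_genes, 3L)
  expect_error(neutrality_fit(with_na[1:2, ]), "at least 3")
})

test_that("tidy and glance expose the regression consistently", {
  set.seed(21)
  d <- tibble::tibble(id = as.character(1:50), p3 = runif(50, 0.2, 0.8))
  d$p12 <- 0.3 + 0.4 * d$p3 + rnorm(50, 0, 0.01)
  fit <- neutrality_fit(d)
  td <- tidy(fit)
  gl <- glance(fit)
  expect_equal(td$estimate[td$term == "p3"], gl$slope)
  expect_equal(td$estimate[td$term == "(Intercept)"], gl$intercept)
  expect_equal(gl$slope, 0.4, tolerance = 0.05)
})

test_that("the correlation matrix is complete-pair Spearman with sane signs", {
  set.seed(22)
  g <- generate_genome(synthetic_spec(n_genes = 60, len_mean_bp = 600,
                                      gc3_range = c(0.2, 0.8), seed = 23))
  counts <- count_codons(g$cds)
  d <- dplyr::inner_join(codon_composition(counts),
                         enc(counts), by = "id")
  cm <- correlation_matrix(d)
  expect_equal(nrow(cm), choose(6, 2))
  expect_true(all(abs(cm$rho) <= 1, na.rm = TRUE))
  # p12 is built from p1 and p2, so it must correlate positively with both
  expect_gt(cm$rho[cm$var1 == "p1" & cm$var2 == "p12"], 0)
  expect_gt(cm$rho[cm$var1 == "p2" & cm$var2 == "p12"], 0)

  # anti-monotone transforms flip the sign exactly
  d2 <- tibble::tibble(id = as.character(1:30), gc_cds = runif(30),
                       p1 = runif(30), p2 = runif(30), p12 = runif(30))
  d2$p3 <- -d2$p12
  d2$enc <- runif(30)
  cm2 <- correlation_matrix(d2)
  expect_equal(cm2$rho[cm2$var1 == "p12" & cm2$var2 == "p3"], -1)

  # a constant column yields NA, not a number
  d2$p1 <- 0.5
  cm3 <- correlation_matrix(d2)
  expect_true(is.na(cm3$rho[cm3$var1 == "p1" & cm3$var2 == "p2"]))
})

test_that("group comparison separates planted differences and not nulls", {
  # identical value sets in both species: F = 0, p = 1
  d0 <- tibble::tibble(species = rep(c("s1", "s2"), each = 4),
                       cai = rep(c(0.1, 0.2, 0.3, 0.4), 2),
                       enc = rep(c(40, 45, 50, 55), 2))
  res0 <- group_comparison(d0)
  expect_equal(res0$anova_f, c(0, 0))
  expect_equal(res0$anova_p, c(1, 1))

  # two groups with means 0 and 10, sd 1, n = 50: decisively significant
  set.seed(31)
  d1 <- tibble::tibble(species = rep(c("s1", "s2"), each = 50),
                       cai = c(rnorm(50, 0), rnorm(50, 10)),
                       enc = c(rnorm(50, 0), rnorm(50, 10)))
  res1 <- group_comparison(d1, grouping = c(s1 = "a", s2 = "b"))
  expect_true(all(res1$anova_p < 0.01))
  expect_true(all(res1$t_p < 0.01))

  # permuting species labels destroys the planted significance
  d_perm <- d1
  set.seed(32)
  d_perm$species <- sample(d_perm$species)
  res_perm <- group_comparison(d_perm, grouping = c(s1 = "a", s2 = "b"))
  expect_true(all(res_perm$anova_p > 0.05))

  expect_error(group_comparison(d1[1:51, ]), ">= 2")
  expect_error(group_comparison(d1, grouping = c(s1 = "a")), "missing")
})

test_that("species clustering reproduces hand-run average linkage", {
  # two identical RSCU vectors merge at height 0
  codons <- codon_universe("degenerate")
  base <- tibble::tibble(codon = codons, rscu = 1)
  two <- dplyr::bind_rows(dplyr::mutate(base, genome = "A"),
                          dplyr::mutate(base, genome = "B"))
  hc <- cluster_species(two)
  expect_equal(hc$height, 0)

  # d(A,B) = 1, d(A,C) = d(B,C) = 10: {A,B} first, then C at height 10
  v <- function(x1, x2) {
    out <- base
    out$rscu <- 0
    out$rscu[1] <- x1
    out$rscu[2] <- x2
    out
  }
  three <- dplyr::bind_rows(
    dplyr::mutate(v(0, 0), genome = "A"),
    dplyr::mutate(v(1, 0), genome = "B"),
    dplyr::mutate(v(0.5, sqrt(100 - 0.25)), genome = "C")
  )
  hc <- cluster_species(three)
  expect_equal(hc$height, c(1, 10), tolerance = 1e-12)
  first_pair <- hc$labels[-hc$merge[1, ]]
  expect_setequal(first_pair, c("A", "B"))
})

test_that("opposite third-base preferences split genomes at the first cut", {
  pair <- generate_biased_pair("AU", 4, synthetic_spec(n_genes = 120,
                                                       len_mean_bp = 600,
                                                       seed = 41))
  one_rscu <- function(g, lab) {
    r <- rscu(pool_codon_counts(count_codons(g$cds), id = lab))
    r$genome <- lab
    r
  }
  # two AU-biased replicates and one GC-biased genome: the AU pair clusters
  rep2 <- generate_genome(synthetic_spec(n_genes = 120, len_mean_bp = 600,
                                         au_odds = 4, seed = 42),
                          prefix = "r")
  all_rscu <- dplyr::bind_rows(one_rscu(pair$biased, "au1"),
                               one_rscu(rep2, "au2"),
                               one_rscu(pair$opposite, "gc1"))
  hc <- cluster_species(all_rscu)
  expect_setequal(hc$labels[-hc$merge[1, ]], c("au1", "au2"))

  # strength 1: the two genomes are near-indistinguishable
  null_pair <- generate_biased_pair("AU", 1, synthetic_spec(
    n_genes = 120, len_mean_bp = 600, seed = 43))
  hc0 <- cluster_species(dplyr::bind_rows(one_rscu(null_pair$biased, "A"),
                                          one_rscu(null_pair$opposite, "B")))
  expect_lt(hc0$height, 1)

  # and a Table-2-style summary: preferred codons are overwhelmingly A/U
  counts <- count_codons(pair$biased$cds)
  opt <- call_optimal_codons(counts, counts, counts)
  s <- optimal_codon_summary(opt)
  au <- s$n_codons[s$category == "preferred" & s$third == "A/U"]
  tot <- s$n_codons[s$category == "preferred" & s$third == "total"]
  expect_gte(au / tot, 0.9)
})
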