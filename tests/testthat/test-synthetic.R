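test_that("generation is byte-identical under a fixed seed", {
  spec <- synthetic_spec(n_genes = 40, len_mean_bp = 500, m = 0.3,
                         tier_fraction = 0.1, seed = 99)
  g1 <- generate_genome(spec)
  g2 <- generate_genome(spec)
  expect_identical(g1$cds, g2$cds)
  expect_identical(g1$truth, g2$truth)
  # and a FASTA round trip of the same genome is byte-identical too
  p1 <- withr::local_tempfile(fileext = ".fasta")
  p2 <- withr::local_tempfile(fileext = ".fasta")
  write_cds_fasta(g1$cds, p1)
  write_cds_fasta(g2$cds, p2)
  expect_identical(readLines(p1), readLines(p2))
  # a different seed changes the sequences
  g3 <- generate_genome(spec, seed = 100)
  expect_false(identical(g1$cds$sequence, g3$cds$sequence))
})

test_that("the generator does not disturb the caller's RNG stream", {
  set.seed(1234)
  before <- runif(1)
  set.seed(1234)
  invisible(generate_genome(synthetic_spec(n_genes = 5, seed = 7)))
  after <- runif(1)
  expect_identical(before, after)
})

test_that("synthetic genomes pass the CDS filter unchanged", {
  g <- generate_genome(synthetic_spec(n_genes = 60, len_mean_bp = 450,
                                      seed = 61))
  kept <- filter_cds(g$cds)
  expect_equal(nrow(kept), 60L)
  expect_true(all(g$cds$length >= 300))
  expect_true(all(g$cds$length %% 3 == 0))
  expect_true(all(substr(g$cds$sequence, 1, 3) == "ATG"))
  last <- substring(g$cds$sequence, g$cds$length - 2, g$cds$length)
  expect_true(all(last %in% c("TAA", "TAG", "TGA")))
})

test_that("empirical codon frequencies converge to the spec distribution", {
  # ~1e5 codons; within-family frequencies should approach the model's
  # conditional distribution (equal within third-base subsets at theta)
  spec <- synthetic_spec(n_genes = 350, len_mean_bp = 900, gc3_target = 0.3,
                         seed = 62)
  g <- generate_genome(spec)
  counts <- pool_codon_counts(count_codons(g$cds))
  code <- genetic_code()
  m <- as.matrix(counts[, code$codon])[1, ]
  model_l1 <- 0
  n_fam <- 0
  for (a in unique(code$aa[code$degenerate])) {
    codons <- code$codon[code$aa == a]
    gc_end <- code$gc3[code$aa == a] == 1
    expected <- ifelse(gc_end, 0.3 / sum(gc_end), 0.7 / sum(!gc_end))
    observed <- m[codons] / sum(m[codons])
    model_l1 <- model_l1 + sum(abs(observed - expected))
    n_fam <- n_fam + 1
  }
  expect_lt(model_l1 / n_fam, 0.02)
  expect_gt(sum(m), 9e4)
})

test_that("the planted expression tier is recovered end to end", {
  spec <- synthetic_spec(n_genes = 1000, len_mean_bp = 750,
                         tier_fraction = 0.05, tier_au_odds = 4, seed = 63)
  g <- generate_genome(spec)
  counts <- count_codons(filter_cds(g$cds))
  tier_ids <- g$truth$id[g$truth$tier]
  # the tier plays the role of the known high-expression reference set
  w <- cai_weights(counts[counts$id %in% tier_ids, ])
  idx <- cub_indices(counts, w)
  tails <- select_expression_tails(idx, fraction = 0.05)
  hi <- tails$id[tails$tail == "high"]
  expect_gte(mean(hi %in% tier_ids), 0.9)

  opt <- call_optimal_codons(counts[counts$id %in% hi, ],
                             counts[counts$id %in%
                                      tails$id[tails$tail == "low"], ],
                             counts)
  fav <- g$params$tier_favored_codons
  expect_gte(mean(!is.na(opt$optimal[opt$codon %in% fav])), 0.9)
  # and nearly all called optimal codons are A/U-ending
  called <- opt$codon[!is.na(opt$optimal)]
  expect_gte(mean(called %in% fav), 0.9)
})

test_that("neutrality slope recovery tracks the coupling parameter", {
  for (m in c(0, 0.4)) {
    g <- generate_genome(synthetic_spec(n_genes = 800, len_mean_bp = 900,
                                        m = m, seed = 64 + round(10 * m)))
    prof <- codon_composition(count_codons(g$cds))
    fit <- neutrality_fit(prof)
    expect_lt(abs(fit$slope - m), 0.07)
  }
})

test_that("biased pairs point their third-base preferences apart", {
  spec <- synthetic_spec(n_genes = 60, len_mean_bp = 450, seed = 65)
  pr <- generate_biased_pair("AU", 4, spec)
  gc3s_of <- function(g) {
    codon_composition(pool_codon_counts(count_codons(g$cds)))$gc3s
  }
  expect_lt(gc3s_of(pr$biased), 0.35)
  expect_gt(gc3s_of(pr$opposite), 0.65)
  expect_error(generate_biased_pair("AU", 0.5), "strength")
})

test_that("infeasible specifications fail before generation", {
  expect_error(synthetic_spec(gc3_target = 1.5))
  expect_error(synthetic_spec(n_genes = 0))
  expect_error(synthetic_spec(len_mean_bp = 150))
  expect_error(synthetic_spec(gc3_range = c(0.8, 0.2)))
  expect_error(synthetic_spec(tier_fraction = 1))
})

test_that("the truth table writes as TSV", {
  g <- generate_genome(synthetic_spec(n_genes = 10, seed = 66))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_truth_tsv(g, path)
  back <- utils::read.delim(path)
  expect_equal(nrow(back), 10L)
  expect_true(all(c("id", "tier", "delta", "gc3_base") %in% names(back)))
})
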