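# Seeded synthetic CDS generator with planted codon-usage structure.
#
# Genes are generated codon by codon: an amino acid is drawn from a
# frequency vector, then a codon from its family's preference distribution.
# Three layers of planted structure mirror what the analyses are designed to
# detect:
#   * a genome-wide third-base preference (`au_odds`) that biases every
#     degenerate family towards A/U- or G/C-ending codons;
#   * a latent per-gene GC drift delta that couples third-position GC with
#     first/second-position GC so that the neutrality regression of P12 on
#     P3 has expected slope m (see the methods vignette for the
#     calibration);
#   * an expression tier: a subset of genes drawn from a distinct,
#     A/U-boosted codon distribution, giving them a planted high-CAI /
#     optimal-codon signature.
# Every gene starts with ATG and ends with a stop codon, so synthetic
# genomes pass filter_cds() unchanged.

# average protein amino-acid frequencies (Swiss-Prot-style), used as the
# default amino-acid sampling distribution
.default_aa_freq <- c(
  A = 8.25, R = 5.53, N = 4.06, D = 5.45, C = 1.38, Q = 3.93, E = 6.75,
  G = 7.07, H = 2.27, I = 5.96, L = 9.66, K = 5.84, M = 2.42, F = 3.86,
  P = 4.70, S = 6.56, T = 5.34, W = 1.08, Y = 2.92, V = 6.87
)

#' Specification for a synthetic CDS set
#'
#' Collects the generator parameters: number of genes, length distribution
#' (gamma-distributed interior codon count, floored so every CDS is at
#' least 300 bp), amino-acid frequencies, third-base composition target and
#' optional per-gene gradient, the mutational-pressure coupling `m`, a
#' genome-wide third-base odds multiplier, and the expression-tier
#' structure.
#'
#' @param n_genes Number of genes (default 2000).
#' @param len_mean_bp Mean CDS length in bases (default 900).
#' @param len_shape Gamma shape for the length distribution (default 6;
#'   larger = less dispersed).
#' @param aa_freq Named amino-acid frequency vector (one-letter codes;
#'   normalised internally). Default: average protein composition.
#' @param gc3_target Baseline probability that a degenerate family uses a
#'   G/C-ending codon (default 0.5).
#' @param gc3_range Optional length-2 range; when given, each gene's
#'   baseline third-base GC target is drawn uniformly from it (a GC3
#'   gradient across genes).
#' @param m Mutational-pressure coupling in `[0, 1]`: the expected OLS slope
#'   of P12 on P3 across genes (default 0 = no coupling).
#' @param delta_sd Standard deviation of the latent per-gene GC drift
#'   (default 0.12).
#' @param au_odds Genome-wide odds multiplier favouring A/U-ending codons
#'   (> 1 favours A/U, < 1 favours G/C, 1 = neutral).
#' @param tier_fraction Fraction of genes in the planted high-expression
#'   tier (default 0 = no tier).
#' @param tier_au_odds Extra A/U odds applied to tier genes (default 4).
#' @param seed Integer seed; the same spec and seed give byte-identical
#'   output.
#' @return A list of class `"synthetic_spec"`.
#' @export
synthetic_spec <- function(n_genes = 2000, len_mean_bp = 900, len_shape = 6,
                           aa_freq = NULL, gc3_target = 0.5,
                           gc3_range = NULL, m = 0, delta_sd = 0.12,
                           au_odds = 1, tier_fraction = 0, tier_au_odds = 4,
                           seed = 1) {
  if (is.null(aa_freq)) aa_freq <- .default_aa_freq
  stopifnot(
    n_genes >= 1, len_mean_bp >= 300, m >= 0, m <= 1, delta_sd > 0,
    au_odds > 0, tier_fraction >= 0, tier_fraction < 1, tier_au_odds > 0,
    all(names(.default_aa_freq) %in% names(aa_freq))
  )
  if (!is.null(gc3_range)) {
    stopifnot(length(gc3_range) == 2, gc3_range[1] <= gc3_range[2],
              gc3_range[1] >= 0.02, gc3_range[2] <= 0.98)
  } else {
    stopifnot(gc3_target >= 0.02, gc3_target <= 0.98)
  }
  aa_freq <- aa_freq[names(.default_aa_freq)] / sum(aa_freq[names(.default_aa_freq)])
  structure(
    list(n_genes = as.integer(n_genes), len_mean_bp = len_mean_bp,
         len_shape = len_shape, aa_freq = aa_freq, gc3_target = gc3_target,
         gc3_range = gc3_range, m = m, delta_sd = delta_sd,
         au_odds = au_odds, tier_fraction = tier_fraction,
         tier_au_odds = tier_au_odds, seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

# Internal: static codon model shared by the generator: for each sense
# codon, its amino acid, whether its third base is G/C, its within-subset
# share (equal weights within the GC-ending and A/U-ending subsets of each
# family), and its GC count at positions 1+2.
.codon_model <- function() {
  if (!is.null(.codonusage_env$codon_model)) return(.codonusage_env$codon_model)
  code <- genetic_code()
  sub <- code[code$sense, ]
  share <- numeric(nrow(sub))
  for (cols in split(seq_len(nrow(sub)), sub$aa)) {
    gc <- sub$gc3[cols] == 1
    share[cols[gc]] <- if (any(gc)) 1 / sum(gc) else 0
    share[cols[!gc]] <- if (any(!gc)) 1 / sum(!gc) else 0
  }
  model <- list(codon = sub$codon, aa = sub$aa, gc3 = sub$gc3 == 1,
                third_at = sub$third_at, share = share,
                gc12 = sub$gc1 + sub$gc2, single = sub$family_size == 1L,
                degenerate = sub$degenerate)
  .codonusage_env$codon_model <- model
  model
}

# Internal: expected GC fraction at positions 1+2 (P12 numerator per
# included codon) under amino-acid distribution f and GC-ending probability
# theta; excludes Met/Trp as the composition module does.
.expected_p12 <- function(f, theta, model) {
  p_aa <- f[model$aa]
  cond <- ifelse(model$single, 1,
                 model$share * ifelse(model$gc3, theta, 1 - theta))
  p <- p_aa * cond
  incl <- !(model$codon %in% c("ATG", "TGG"))
  sum(p[incl] * model$gc12[incl]) / (2 * sum(p[incl]))
}

# Internal: tilt the amino-acid frequencies of the degenerate families
# towards (dir = +1) or away from (dir = -1) GC-rich first/second positions,
# holding Met and Trp fixed so the P12 universe mass is constant.
.tilt_aa <- function(f, dir, model, strength = 1.6) {
  g12 <- vapply(split(model$gc12, model$aa), mean, numeric(1))
  w <- exp(dir * strength * (g12[names(f)] / 2 - 0.5))
  w[c("M", "W")] <- 1
  out <- f * w
  mass <- 1 - f["M"] - f["W"]
  deg <- setdiff(names(f), c("M", "W"))
  out[deg] <- out[deg] / sum(out[deg]) * mass
  out
}

#' Generate a synthetic CDS set
#'
#' Draws a seeded multi-gene CDS set from a [synthetic_spec()], returning
#' the sequences together with the per-gene generative truth (tier
#' membership, GC drift, third-base target) needed for planted-truth
#' recovery tests.
#'
#' @param spec A [synthetic_spec()].
#' @param seed Seed override (defaults to `spec$seed`).
#' @param prefix Gene id prefix.
#' @return A list with elements `cds` (tibble `id`, `sequence`, `length`),
#'   `truth` (tibble `id`, `tier`, `delta`, `gc3_base`, `theta`,
#'   `n_codons`), and `params` (calibration constants, including the P12
#'   coupling coefficient and the tier's favoured codon set).
#' @export
generate_genome <- function(spec, seed = spec$seed, prefix = "g") {
  stopifnot(inherits(spec, "synthetic_spec"))
  model <- .codon_model()
  old_seed <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  }, add = TRUE)
  set.seed(seed)

  n <- spec$n_genes
  f0 <- spec$aa_freq

  # lengths: interior codons, gamma with floor so total length >= 300 bp
  mean_codons <- spec$len_mean_bp / 3 - 2
  len <- pmax(98L, as.integer(round(
    stats::rgamma(n, shape = spec$len_shape,
                  scale = mean_codons / spec$len_shape))))

  # per-gene third-base baseline and latent drift
  gc3_base <- if (is.null(spec$gc3_range)) rep(spec$gc3_target, n) else
    stats::runif(n, spec$gc3_range[1], spec$gc3_range[2])
  delta <- if (spec$m > 0) stats::rnorm(n, 0, spec$delta_sd) else numeric(n)
  theta <- pmin(pmax(gc3_base + delta, 0.02), 0.98)

  # tier membership
  n_tier <- ceiling(spec$tier_fraction * n)
  tier <- rep(FALSE, n)
  if (n_tier > 0) tier[sample.int(n, n_tier)] <- TRUE

  # P12 coupling calibration: choose the coupling coefficient so that the
  # OLS slope of P12 on P3 across genes has expectation m (sampling noise
  # in P3 and any GC3 gradient attenuate the slope and are compensated)
  params <- list(m = spec$m)
  if (spec$m > 0) {
    f_au <- .tilt_aa(f0, -1, model)
    f_gc <- .tilt_aa(f0, +1, model)
    theta0 <- mean(gc3_base)
    mu_au <- .expected_p12(f_au, theta0, model)
    mu_gc <- .expected_p12(f_gc, theta0, model)
    p3_universe <- 1 - f0["I"] - f0["M"] - f0["W"]
    n3_bar <- mean(len) * p3_universe
    samp_var <- theta0 * (1 - theta0) / n3_bar
    grad_var <- if (is.null(spec$gc3_range)) 0 else
      diff(spec$gc3_range)^2 / 12
    tau2 <- spec$delta_sd^2
    coupling <- spec$m * (tau2 + grad_var + samp_var) / tau2
    w12 <- pmin(pmax(0.5 + coupling * delta / (mu_gc - mu_au), 0), 1)
    params <- c(params, list(coupling = unname(coupling),
                             mu_au = unname(mu_au), mu_gc = unname(mu_gc),
                             samp_var = unname(samp_var)))
  } else {
    w12 <- rep(0.5, n)
    f_au <- f_gc <- f0
  }

  favored <- model$codon[model$degenerate & model$third_at]
  params$tier_favored_codons <- if (spec$tier_fraction > 0) favored else
    character(0)

  stops <- c("TAA", "TAG", "TGA")
  p_aa_codon <- function(f, th) {
    cond <- ifelse(model$single, 1,
                   model$share * ifelse(model$gc3, th, 1 - th))
    f[model$aa] * cond
  }
  seqs <- character(n)
  n_codon <- length(model$codon)
  for (g in seq_len(n)) {
    f_g <- if (spec$m > 0)
      (1 - w12[g]) * f_au + w12[g] * f_gc else f0
    odds <- spec$au_odds * if (tier[g]) spec$tier_au_odds else 1
    th_g <- theta[g] / (theta[g] + odds * (1 - theta[g]))
    p <- p_aa_codon(f_g, th_g)
    idx <- sample.int(n_codon, len[g], replace = TRUE, prob = p)
    seqs[g] <- paste0("ATG", paste(model$codon[idx], collapse = ""),
                      sample(stops, 1))
  }
  ids <- sprintf("%s%05d", prefix, seq_len(n))
  list(
    cds = tibble::tibble(id = ids, sequence = seqs, length = nchar(seqs)),
    truth = tibble::tibble(id = ids, tier = tier, delta = delta,
                           gc3_base = gc3_base, theta = theta,
                           n_codons = len),
    params = params
  )
}

#' Generate a pair of genomes with opposite third-base preferences
#'
#' Two synthetic genomes identical in every respect except the direction of
#' their genome-wide third-base preference: one favours the `bias` direction
#' at the given odds `strength`, the other the opposite direction. At
#' `strength = 1` the two genomes are statistically indistinguishable.
#' Useful for testing third-base summaries and inter-genome clustering.
#'
#' @param bias `"AU"` or `"GC"` — the direction favoured by the first
#'   genome.
#' @param strength Odds ratio >= 1.
#' @param base_spec A [synthetic_spec()] providing all other parameters.
#' @return A named list of two [generate_genome()] results, `biased` and
#'   `opposite`.
#' @export
generate_biased_pair <- function(bias = c("AU", "GC"), strength = 4,
                                 base_spec = synthetic_spec()) {
  bias <- match.arg(bias)
  stopifnot(strength >= 1)
  odds <- if (bias == "AU") strength else 1 / strength
  spec1 <- base_spec; spec1$au_odds <- odds
  spec2 <- base_spec; spec2$au_odds <- 1 / odds
  list(
    biased = generate_genome(spec1, seed = base_spec$seed, prefix = "a"),
    opposite = generate_genome(spec2, seed = base_spec$seed + 1L,
                               prefix = "b")
  )
}

#' Write the generator truth table as TSV
#'
#' @param genome A [generate_genome()] result.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_truth_tsv <- function(genome, path) {
  utils::write.table(genome$truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
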