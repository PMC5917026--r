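#' Exon-level association layout for the ELL2 locus
#'
#' Per-exon effect sizes and hg38 coordinates for the ELL2 gene as used by the
#' default simulation scenario: twelve exon features on chr5 with standardized
#' effect sizes (SD units per risk-allele copy) ranging from -0.04 to -0.20.
#' These values parameterize the synthetic exon-expression generator; they are
#' inputs, not outputs, of the package.
#'
#' @return data.frame with columns `exon`, `chrom`, `start`, `end`, `beta`.
#' @export
ell2_exon_table <- function() {
  data.frame(
    exon = 1:12,
    chrom = "chr5",
    start = c(95885097L, 95889085L, 95891102L, 95895627L, 95898239L, 95900692L,
              95900955L, 95906522L, 95913770L, 95919423L, 95913001L, 95911574L),
    end = c(95888987L, 95889130L, 95891274L, 95895691L, 95898810L, 95900780L,
            95901080L, 95906782L, 95913934L, 95919545L, 95913049L, 95912071L),
    beta = c(-0.15, -0.16, -0.17, -0.16, -0.15, -0.14,
             -0.04, -0.11, -0.20, -0.20, -0.19, -0.12)
  )
}

#' Allele-distinguishing key sequences at the coding variant
#'
#' The 27-base subsequences that distinguish the two alleles of the exonic
#' genotyping variant in raw mRNA-seq reads (first base C = risk allele,
#' T = protective allele). Used by the allele-specific read counter and the
#' read simulator.
#'
#' @return named character vector with elements `ref` (C allele) and
#'   `alt` (T allele).
#' @export
ase_keys <- function() {
  c(ref = "CAGCATTCTGAGACGGATTTAGTTTTC",
    alt = "TAGCATTCTGAGACGGATTTAGTTTTC")
}

#' Define one linkage-disequilibrium block for the haplotype simulator
#'
#' @param n_variants number of variants in the block.
#' @param n_founders number of founder haplotypes the block mosaics over.
#' @param founder_freqs frequencies at which founders are drawn; must sum to 1.
#' @return list describing the block.
#' @export
ld_block <- function(n_variants, n_founders,
                     founder_freqs = rep(1 / n_founders, n_founders)) {
  list(n_variants = as.integer(n_variants), n_founders = as.integer(n_founders),
       founder_freqs = founder_freqs)
}

#' Simulation configuration
#'
#' Bundles every generator parameter. Defaults encode the study conditions the
#' pipeline emulates: a per-allele expression effect of -0.24 SD at the gene
#' level with the twelve per-exon effects of [ell2_exon_table()], an allelic
#' expression ratio of 0.545, four cohorts of 185/658/183/604 samples, and a
#' tight 72-variant LD block around the risk variant.
#'
#' @param n_samples samples in the discovery (mRNA-seq) cohort.
#' @param ld_block_spec list of [ld_block()] descriptions; haplotypes are
#'   independent across blocks.
#' @param risk_variant_index column index of the risk variant in the panel.
#' @param beta_per_exon standardized effect sizes, one per exon feature.
#' @param gene_beta standardized gene-level effect used for the validation
#'   cohorts and the co-expression anchor.
#' @param noise_sd expression noise SD; `NULL` (default) sets, per feature,
#'   `sqrt(1 - beta^2)` so the latent trait has unit variance and the planted
#'   standardized effect equals the expected Pearson correlation.
#' @param allelic_ratio expected fraction of alternate-allele reads among
#'   allele-informative reads of a heterozygote.
#' @param n_reads reads simulated per allele-counting experiment.
#' @param read_length read length in bases; must fit the allele keys.
#' @param n_genes genes (including the anchor) in the co-expression matrix.
#' @param planted_sets list of planted gene sets; each element a list with
#'   `name`, `size`, `shift` (correlation-score shift with the anchor in units
#'   of the null score SD, 1/sqrt(n)), and optional `dosage_shift` (direct
#'   genotype effect on the set, same units) and `members` (explicit indices).
#' @param cohort_n sample sizes of the cohorts entering the meta-analysis.
#' @param flip_noise per-site allele flip probability when copying founders.
#' @param fpkm_baseline_log2 baseline of the latent-to-FPKM mapping
#'   `fpkm = 2^(latent + baseline) - 1`.
#' @param seed run seed; all stage seeds derive from it.
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(n_samples = 185,
                              ld_block_spec = list(ld_block(24, 4),
                                                   ld_block(72, 2),
                                                   ld_block(24, 4)),
                              risk_variant_index = 60,
                              beta_per_exon = ell2_exon_table()$beta,
                              gene_beta = -0.24,
                              noise_sd = NULL,
                              allelic_ratio = 0.545,
                              n_reads = 2000,
                              read_length = 75,
                              n_genes = 5000,
                              planted_sets = list(
                                list(name = "RPG", size = 80, shift = 1, dosage_shift = 1),
                                list(name = "SEC", size = 7, shift = 1, dosage_shift = 1)
                              ),
                              cohort_n = c(185, 658, 183, 604),
                              flip_noise = 0.01,
                              fpkm_baseline_log2 = 5,
                              seed = 1L) {
  cfg <- list(
    n_samples = as.integer(n_samples), ld_block_spec = ld_block_spec,
    risk_variant_index = as.integer(risk_variant_index),
    beta_per_exon = beta_per_exon, gene_beta = gene_beta, noise_sd = noise_sd,
    allelic_ratio = allelic_ratio, n_reads = as.integer(n_reads),
    read_length = as.integer(read_length), n_genes = as.integer(n_genes),
    planted_sets = planted_sets, cohort_n = as.integer(cohort_n),
    flip_noise = flip_noise, fpkm_baseline_log2 = fpkm_baseline_log2,
    seed = as.integer(seed)
  )
  cfg$n_variants <- sum(vapply(ld_block_spec, function(b) b$n_variants, 1L))
  class(cfg) <- "simulation_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  counts <- c(cfg$n_samples, cfg$n_variants, cfg$n_reads, cfg$read_length,
              cfg$n_genes, cfg$cohort_n)
  if (any(counts <= 0)) abort_config("all counts must be positive")
  if (cfg$allelic_ratio < 0 || cfg$allelic_ratio > 1)
    abort_config("allelic_ratio must lie in [0, 1]")
  if (cfg$flip_noise < 0 || cfg$flip_noise > 0.5)
    abort_config("flip_noise must lie in [0, 0.5]")
  for (b in cfg$ld_block_spec) {
    if (b$n_variants <= 0 || b$n_founders <= 0)
      abort_config("block lengths and founder counts must be positive")
    if (length(b$founder_freqs) != b$n_founders)
      abort_config("founder_freqs length must equal n_founders")
    if (abs(sum(b$founder_freqs) - 1) > 1e-8)
      abort_config("founder frequencies must sum to 1")
    if (any(b$founder_freqs < 0)) abort_config("founder frequencies must be nonnegative")
  }
  if (cfg$risk_variant_index < 1 || cfg$risk_variant_index > cfg$n_variants)
    abort_config("risk_variant_index out of range")
  sizes <- vapply(cfg$planted_sets, function(s) s$size, 1)
  if (length(sizes) && sum(sizes) > cfg$n_genes - 1)
    abort_config("planted set sizes must sum to at most n_genes - 1")
  members <- lapply(cfg$planted_sets, function(s) s$members)
  members <- members[!vapply(members, is.null, TRUE)]
  if (length(members) > 1 && anyDuplicated(unlist(members)))
    abort_config("planted sets must not overlap")
  if (!is.null(cfg$noise_sd) && any(cfg$noise_sd < 0))
    abort_config("noise_sd must be nonnegative")
  invisible(cfg)
}

#' Simulate a phased haplotype panel with block LD structure
#'
#' Within each block, the 2 * n_samples haplotypes are copies of founder
#' haplotypes drawn at the founder frequencies, with independent per-site
#' allele flips at probability `flip_noise`; blocks are independent. This
#' founder-mosaic construction yields tunable r-squared neighborhoods without
#' a demographic model.
#'
#' @param config a [simulation_config()].
#' @return object of class `haplotype_panel`: list with `haplotypes`
#'   (2n x m binary matrix, two consecutive rows per sample), `variants`
#'   (a variant table with 1-based positions) and `expected_freq`
#'   (founder-implied post-flip alternate-allele frequency per variant).
#' @export
simulate_haplotype_panel <- function(config) {
  validate_config(config)
  n_hap <- 2L * config$n_samples
  with_seed(derive_seed(config$seed, "panel"), {
    cols <- list(); efreq <- numeric(0); block_id <- integer(0)
    for (bi in seq_along(config$ld_block_spec)) {
      b <- config$ld_block_spec[[bi]]
      founders <- matrix(rbinom(b$n_founders * b$n_variants, 1, 0.5),
                         nrow = b$n_founders)
      if (b$n_founders >= 2) {
        ## guarantee every site segregates among founders
        for (j in which(apply(founders, 2, function(x) length(unique(x)) == 1)))
          founders[sample.int(b$n_founders, 1), j] <- 1 - founders[1, j]
      }
      pick <- sample.int(b$n_founders, n_hap, replace = TRUE,
                         prob = b$founder_freqs)
      h <- founders[pick, , drop = FALSE]
      if (config$flip_noise > 0) {
        flips <- matrix(rbinom(length(h), 1, config$flip_noise), nrow = n_hap)
        h <- abs(h - flips)
      }
      f0 <- as.vector(b$founder_freqs %*% founders)
      efreq <- c(efreq, f0 * (1 - 2 * config$flip_noise) + config$flip_noise)
      cols[[bi]] <- h
      block_id <- c(block_id, rep(bi, b$n_variants))
    }
    haplotypes <- do.call(cbind, cols)
  })
  storage.mode(haplotypes) <- "integer"
  m <- ncol(haplotypes)
  samples <- sprintf("S%03d", seq_len(config$n_samples))
  rownames(haplotypes) <- paste0(rep(samples, each = 2), c("_h1", "_h2"))
  variants <- data.frame(
    id = sprintf("var%03d", seq_len(m)),
    chrom = "chr5",
    pos = 95880000L + seq_len(m) * 500L,
    ref = "T", alt = "C", risk_is_alt = TRUE,
    block = block_id
  )
  variants$id[config$risk_variant_index] <- "rs_causal"
  colnames(haplotypes) <- variants$id
  structure(list(haplotypes = haplotypes, variants = variants,
                 expected_freq = efreq, samples = samples),
            class = "haplotype_panel")
}

#' Collapse a phased panel to per-sample risk-allele dosages
#'
#' @param panel a `haplotype_panel`.
#' @return object of class `genotype_data`: list with `dosage`
#'   (samples x variants, entries 0/1/2 counting the risk allele),
#'   `haplotypes` and `variants`.
#' @export
as_genotype_data <- function(panel) {
  h <- panel$haplotypes
  idx <- seq(1, nrow(h), by = 2)
  dosage <- h[idx, , drop = FALSE] + h[idx + 1, , drop = FALSE]
  rownames(dosage) <- panel$samples
  structure(list(dosage = dosage, haplotypes = h, variants = panel$variants),
            class = "genotype_data")
}

#' Simulate exon-level expression with a planted allelic effect
#'
#' Per exon e, the latent trait is `beta_e * z + N(0, noise_sd_e)` where z is
#' the standardized risk-allele dosage; the latent value is mapped to a
#' positive FPKM-like scale by the fixed monotone transform
#' `fpkm = 2^(latent + baseline) - 1`, recorded in the output metadata so the
#' default `log2(x + 1)` analysis transform inverts it exactly.
#'
#' @param dosage numeric dosage vector (one value per sample) or a
#'   `genotype_data` object (the risk variant column is used).
#' @param config a [simulation_config()].
#' @param seed_index replicate index mixed into the stage seed.
#' @return an [expression_matrix()] (features x samples, raw FPKM scale).
#' @export
simulate_exon_expression <- function(dosage, config, seed_index = 0L) {
  if (inherits(dosage, "genotype_data"))
    dosage <- dosage$dosage[, config$risk_variant_index]
  beta <- config$beta_per_exon
  noise <- config$noise_sd %||% sqrt(pmax(0, 1 - beta^2))
  noise <- rep_len(noise, length(beta))
  n <- length(dosage)
  if (stats::var(dosage) == 0) abort_config("dosage has zero variance")
  z <- as.vector(scale(dosage))
  vals <- with_seed(derive_seed(config$seed, "expression", seed_index), {
    t(vapply(seq_along(beta), function(e) {
      latent_to_fpkm(beta[e] * z + stats::rnorm(n, 0, noise[e]),
                     config$fpkm_baseline_log2)
    }, numeric(n)))
  })
  tab <- ell2_exon_table()
  if (length(beta) == nrow(tab)) {
    feats <- sprintf("ELL2:exon%02d:%s:%d-%d", tab$exon, tab$chrom, tab$start, tab$end)
  } else {
    feats <- sprintf("exon%02d", seq_along(beta))
  }
  rownames(vals) <- feats
  colnames(vals) <- sprintf("S%03d", seq_len(n))
  expression_matrix(vals, transform = "raw",
                    meta = list(mapping = "fpkm = 2^(latent + baseline) - 1",
                                baseline_log2 = config$fpkm_baseline_log2))
}

#' Simulate allele-informative sequencing reads
#'
#' Each read embeds exactly one allele key at a random offset with random
#' flanking bases; the allele is alternate with probability
#' `config$allelic_ratio`. Every second read is emitted as the reverse
#' complement of the constructed read. Base qualities are constant "I"
#' (never used by the counting stage). Passing `counts = c(ref =, alt =)`
#' switches to a deterministic interleaving mode that plants exactly those
#' counts, bypassing Bernoulli sampling, for exact bookkeeping tests.
#'
#' @param config a [simulation_config()].
#' @param key_ref,key_alt equal-length allele key sequences differing at one
#'   base; defaults from [ase_keys()].
#' @param counts optional named vector `c(ref =, alt =)` of exact planted counts.
#' @return object of class `read_collection`: list with `sequences`
#'   (a [Biostrings::DNAStringSet]) and `quality` (constant character).
#' @export
simulate_allelic_reads <- function(config, key_ref = ase_keys()[["ref"]],
                                   key_alt = ase_keys()[["alt"]],
                                   counts = NULL) {
  k <- nchar(key_ref)
  if (nchar(key_alt) != k) abort_config("allele keys must have equal length")
  if (key_ref == key_alt) abort_config("allele keys must differ")
  if (config$read_length < k)
    abort_config("read_length shorter than the allele keys")
  if (is.null(counts)) {
    n <- config$n_reads
    alt_flag <- with_seed(derive_seed(config$seed, "reads"),
                          stats::runif(n) < config$allelic_ratio)
  } else {
    n <- sum(counts)
    i <- seq_len(n)
    ## Bresenham interleaving: exactly counts["alt"] TRUEs, evenly spread
    alt_flag <- (i * counts[["alt"]]) %/% n > ((i - 1) * counts[["alt"]]) %/% n
  }
  reads <- with_seed(derive_seed(config$seed, "reads", 1L), {
    offs <- sample.int(config$read_length - k + 1L, n, replace = TRUE) - 1L
    vapply(seq_len(n), function(i) {
      key <- if (alt_flag[i]) key_alt else key_ref
      left <- paste(sample(c("A", "C", "G", "T"), offs[i], replace = TRUE),
                    collapse = "")
      right <- paste(sample(c("A", "C", "G", "T"),
                            config$read_length - k - offs[i], replace = TRUE),
                     collapse = "")
      paste0(left, key, right)
    }, character(1))
  })
  seqs <- Biostrings::DNAStringSet(reads)
  rc <- seq_len(n) %% 2 == 0
  seqs[rc] <- Biostrings::reverseComplement(seqs[rc])
  names(seqs) <- sprintf("read%05d", seq_len(n))
  structure(list(sequences = seqs, quality = "I"), class = "read_collection")
}

#' Simulate a co-expression matrix with planted gene sets
#'
#' An anchor gene ("ELL2") carries the planted allelic effect
#' (`gene_beta * z + noise`). Member genes of each planted set receive a mean
#' shift in their correlation score with the anchor of `shift` null-score SDs
#' (the null SD of a Pearson correlation is ~ 1/sqrt(n)), via loading on the
#' anchor's non-genotype residual; `dosage_shift` plants an additional direct
#' genotype effect with its own sign, so anchor-correlation and genotype
#' signatures can point in independent, planted directions. Non-member genes
#' are exchangeable noise.
#'
#' @param config a [simulation_config()].
#' @param dosage dosage vector or `genotype_data`.
#' @param seed_index replicate index mixed into the stage seed.
#' @return list with `expression` (an [expression_matrix()], anchor gene
#'   first) and `sets` (named list of gene-id vectors, GMT-writable).
#' @export
simulate_coexpression_and_sets <- function(config, dosage, seed_index = 0L) {
  if (inherits(dosage, "genotype_data"))
    dosage <- dosage$dosage[, config$risk_variant_index]
  n <- length(dosage); G <- config$n_genes
  z <- as.vector(scale(dosage))
  genes <- c("ELL2", sprintf("G%04d", seq_len(G - 1)))
  sets <- list(); used <- integer(0)
  for (s in config$planted_sets) {
    idx <- s$members %||% (max(c(0L, used)) + seq_len(s$size))
    if (any(idx %in% used)) abort_config("planted sets must not overlap")
    if (any(idx > G - 1)) abort_config("planted set members exceed n_genes - 1")
    used <- c(used, idx)
    sets[[s$name]] <- genes[idx + 1L]
  }
  out <- with_seed(derive_seed(config$seed, "coexpression", seed_index), {
    eps_a <- stats::rnorm(n)
    anchor <- config$gene_beta * z + sqrt(1 - config$gene_beta^2) * eps_a
    lat <- matrix(stats::rnorm(n * (G - 1)), nrow = G - 1)
    az <- as.vector(scale(eps_a))
    for (s in config$planted_sets) {
      idx <- which(genes[-1] %in% sets[[s$name]])
      cc <- s$shift / sqrt(n)
      dd <- (s$dosage_shift %||% 0) / sqrt(n)
      resid <- sqrt(max(0, 1 - cc^2 - dd^2))
      lat[idx, ] <- cc * matrix(az, length(idx), n, byrow = TRUE) +
        dd * matrix(z, length(idx), n, byrow = TRUE) + resid * lat[idx, ]
    }
    rbind(anchor, lat)
  })
  vals <- latent_to_fpkm(out, config$fpkm_baseline_log2)
  rownames(vals) <- genes
  colnames(vals) <- sprintf("S%03d", seq_len(n))
  list(expression = expression_matrix(vals, transform = "raw",
         meta = list(anchor = "ELL2",
                     baseline_log2 = config$fpkm_baseline_log2)),
       sets = sets)
}

#' Motif fixture: MAF-family count matrix and allelic probe pair
#'
#' Returns a small position count matrix whose consensus matches the G-allele
#' core of a 25-base regulatory probe, plus the two probe sequences with the
#' central G/C swap (1-based position 13). The G allele scores a high-affinity
#' hit; the C allele weakens it by more than fivefold in best-hit P-value.
#'
#' @return list with `pcm` (class `pcm`), `seq_ref` (G allele), `seq_alt`
#'   (C allele) and `variant_offset` (1-based position of the swap).
#' @export
make_motif_fixture <- function() {
  seq_ref <- "ACAGTGCTGACTGAGCTCAAAATAC"
  seq_alt <- "ACAGTGCTGACTCAGCTCAAAATAC"
  consensus <- strsplit("GCTGACTGAGC", "")[[1]]
  L <- length(consensus)
  counts <- matrix(1, nrow = 4, ncol = L, dimnames = list(c("A", "C", "G", "T")))
  for (j in seq_len(L)) counts[consensus[j], j] <- 21
  ## flank columns 1, 6, 11 tolerate a second base at a small score penalty,
  ## widening the score gap between the alleles' tail probabilities
  for (j in c(1, 6, 11)) {
    counts[, j] <- 2
    counts[consensus[j], j] <- 9
    counts[if (consensus[j] == "A") "C" else "A", j] <- 7
  }
  ## variant position (motif column 8) kept moderately informative so the
  ## C allele still clears the per-allele significance threshold
  counts[, 8] <- c(A = 2, C = 6, G = 14, T = 2)
  list(pcm = new_pcm(counts, name = "MAF_like"),
       seq_ref = seq_ref, seq_alt = seq_alt, variant_offset = 13L)
}

#' Simulate GWAS association P-values over the panel variants
#'
#' Per-variant association z-scores decay with LD to the causal variant:
#' `z = sqrt(lambda) * r(v, causal) + N(0, 1)`, two-sided normal P. Stands in
#' for the (out-of-scope) case-control association study as the second axis
#' of the two-dimensional co-localization plot.
#'
#' @param genotypes a `genotype_data`.
#' @param config a [simulation_config()].
#' @param lambda noncentrality at the causal variant (z^2 scale).
#' @return named vector of P-values, one per variant.
#' @export
simulate_gwas_pvalues <- function(genotypes, config, lambda = 40) {
  d <- genotypes$dosage
  r <- suppressWarnings(stats::cor(d, d[, config$risk_variant_index]))
  r[is.na(r)] <- 0
  z <- with_seed(derive_seed(config$seed, "gwas"),
                 sqrt(lambda) * as.vector(r) + stats::rnorm(ncol(d)))
  p <- 2 * stats::pnorm(-abs(z))
  names(p) <- genotypes$variants$id
  p
}
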