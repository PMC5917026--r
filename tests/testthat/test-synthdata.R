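test_that("configuration validation rejects inconsistent parameters", {
  expect_error(simulation_config(ld_block_spec = list(ld_block(4, 2, c(0.6, 0.6)))),
               "sum to 1")
  expect_error(simulation_config(allelic_ratio = 1.5), "\\[0, 1\\]")
  expect_error(simulation_config(n_reads = 0), "positive")
  expect_error(simulation_config(risk_variant_index = 999), "out of range")
  expect_error(simulation_config(n_genes = 50), "at most n_genes - 1")
  expect_error(
    simulation_config(n_genes = 500, planted_sets = list(
      list(name = "a", size = 3, shift = 1, members = 1:3),
      list(name = "b", size = 3, shift = 1, members = 3:5))),
    "overlap")
  cfg <- simulation_config(read_length = 10)
  expect_error(simulate_allelic_reads(cfg), "read_length")
})

test_that("degenerate founder panels produce the expected haplotype structure", {
  one <- simulation_config(n_samples = 20,
                           ld_block_spec = list(ld_block(5, 1)),
                           risk_variant_index = 3, flip_noise = 0)
  p1 <- simulate_haplotype_panel(one)
  expect_true(all(apply(p1$haplotypes, 2, function(x) length(unique(x)) == 1)))

  two <- simulation_config(n_samples = 50,
                           ld_block_spec = list(ld_block(2, 2)),
                           risk_variant_index = 1, flip_noise = 0)
  p2 <- simulate_haplotype_panel(two)
  ld <- ld_pair(p2, 1, 2)
  expect_equal(ld$r2, 1)
  expect_equal(ld$d_prime, 1)
})

test_that("within-block LD exceeds between-block LD in the founder mosaic", {
  cfg <- simulation_config(n_samples = 500,
                           ld_block_spec = list(ld_block(8, 4), ld_block(8, 4)),
                           risk_variant_index = 4, flip_noise = 0.01, seed = 11)
  panel <- simulate_haplotype_panel(cfg)
  r2 <- function(i, j) tryCatch(ld_pair(panel, i, j)$r2, error = function(e) NA)
  within <- c(outer(1:8, 1:8, Vectorize(r2))[upper.tri(diag(8))],
              outer(9:16, 9:16, Vectorize(r2))[upper.tri(diag(8))])
  between <- as.vector(outer(1:8, 9:16, Vectorize(r2)))
  expect_gt(mean(within, na.rm = TRUE), mean(between, na.rm = TRUE))
})

test_that("panel allele frequencies match founder-implied expectations", {
  cfg <- simulation_config(seed = 5)
  panel <- simulate_haplotype_panel(cfg)
  obs <- colMeans(panel$haplotypes)
  exp_f <- panel$expected_freq
  se <- sqrt(exp_f * (1 - exp_f) / nrow(panel$haplotypes))
  z <- abs(obs - exp_f) / se
  expect_true(all(z < 3.5))
  expect_gte(mean(z < 3), 0.95)
})

test_that("planted exon effect sizes are recovered across replicates", {
  ## 200 replicates at n = 185 with a planted -0.24 SD effect: the mean
  ## fitted correlation lands within 0.02 of the planted value and its
  ## spread matches the 1/sqrt(n) sampling theory within 20%
  cfg <- simulation_config(beta_per_exon = -0.24, seed = 3)
  panel <- simulate_haplotype_panel(cfg)
  dosage <- as_genotype_data(panel)$dosage[, cfg$risk_variant_index]
  rs <- vapply(1:200, function(i) {
    e <- simulate_exon_expression(dosage, cfg, seed_index = i)
    pearson_eqtl(dosage, e$values[1, ], transform = "log2")$r
  }, numeric(1))
  expect_lt(abs(mean(rs) - (-0.24)), 0.02)
  expect_lt(abs(sd(rs) - 1 / sqrt(185)) / (1 / sqrt(185)), 0.20)
})

test_that("noiseless and null expression behave at the boundaries", {
  cfg <- simulation_config(n_samples = 30, beta_per_exon = -1, noise_sd = 0,
                           seed = 2)
  panel <- simulate_haplotype_panel(cfg)
  dosage <- as_genotype_data(panel)$dosage[, cfg$risk_variant_index]
  e <- simulate_exon_expression(dosage, cfg)
  expect_equal(cor(log2(e$values[1, ] + 1), dosage), -1, tolerance = 1e-12)

  cfg0 <- simulation_config(beta_per_exon = 0, seed = 4)
  panel0 <- simulate_haplotype_panel(cfg0)
  d0 <- as_genotype_data(panel0)$dosage[, cfg0$risk_variant_index]
  rs <- vapply(1:200, function(i) {
    e <- simulate_exon_expression(d0, cfg0, seed_index = i)
    pearson_eqtl(d0, e$values[1, ])$r
  }, numeric(1))
  ## null effect: mean |r| consistent with the 1/sqrt(n) null scale
  expect_lt(abs(mean(rs)), 3 / sqrt(200 * 185))
})

test_that("null exon effects give uniform association P-values", {
  cfg <- simulation_config(beta_per_exon = 0, seed = 8)
  panel <- simulate_haplotype_panel(cfg)
  d <- as_genotype_data(panel)$dosage[, cfg$risk_variant_index]
  ps <- vapply(1:200, function(i) {
    e <- simulate_exon_expression(d, cfg, seed_index = i)
    pearson_eqtl(d, e$values[1, ])$p
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 0.01)
})

test_that("allelic read simulation respects ratio, boundaries and bookkeeping", {
  cfg0 <- simulation_config(n_reads = 200, seed = 6, allelic_ratio = 0)
  r0 <- simulate_allelic_reads(cfg0)
  expect_equal(count_allelic_reads(r0)$n_alt, 0)

  cfg <- simulation_config(n_reads = 2000, seed = 6)
  counts <- count_allelic_reads(simulate_allelic_reads(cfg))
  se <- sqrt(0.545 * (1 - 0.545) / 2000)
  expect_lt(abs(counts$ratio - 0.545), 3 * se)

  planted <- simulate_allelic_reads(cfg, counts = c(ref = 60, alt = 40))
  got <- count_allelic_reads(planted)
  expect_identical(c(got$n_ref, got$n_alt), c(60L, 40L))
  expect_equal(got$ratio, 0.40)
})

test_that("simulation is deterministic given (config, seed)", {
  cfg <- simulation_config(n_samples = 40, n_genes = 100,
                           planted_sets = list(list(name = "s", size = 10, shift = 1)),
                           seed = 9)
  p1 <- simulate_haplotype_panel(cfg)
  p2 <- simulate_haplotype_panel(cfg)
  expect_identical(p1, p2)
  d <- as_genotype_data(p1)$dosage[, cfg$risk_variant_index]
  expect_identical(simulate_exon_expression(d, cfg), simulate_exon_expression(d, cfg))
  expect_identical(simulate_allelic_reads(cfg)$sequences,
                   simulate_allelic_reads(cfg)$sequences)
  expect_identical(simulate_coexpression_and_sets(cfg, d),
                   simulate_coexpression_and_sets(cfg, d))
})

test_that("planted co-expression sets are detected with power monotone in size", {
  detections <- matrix(NA, nrow = 50, ncol = 2,
                       dimnames = list(NULL, c("big", "small")))
  cfg <- simulation_config(
    n_samples = 185, n_genes = 2000,
    planted_sets = list(list(name = "big", size = 80, shift = 1),
                        list(name = "small", size = 7, shift = 1)))
  panel <- simulate_haplotype_panel(cfg)
  d <- as_genotype_data(panel)$dosage[, cfg$risk_variant_index]
  for (i in seq_len(nrow(detections))) {
    co <- simulate_coexpression_and_sets(cfg, d, seed_index = i)
    sig <- correlation_signature(co$expression, "ELL2", min_mean_fpkm = 0)
    enr <- enrich_sets(sig, co$sets)
    detections[i, ] <- enr$p[match(c("big", "small"), enr$set)] < 0.001
  }
  expect_gte(mean(detections[, "big"]), 0.95)
  expect_lt(mean(detections[, "small"]), mean(detections[, "big"]))
})

test_that("null planted shifts give calibrated enrichment P-values", {
  cfg <- simulation_config(
    n_samples = 60, n_genes = 300,
    planted_sets = list(list(name = "nullset", size = 30, shift = 0)))
  panel <- simulate_haplotype_panel(cfg)
  d <- as_genotype_data(panel)$dosage[, cfg$risk_variant_index]
  ps <- vapply(1:200, function(i) {
    co <- simulate_coexpression_and_sets(cfg, d, seed_index = i)
    sig <- correlation_signature(co$expression, "ELL2", min_mean_fpkm = 0)
    rank_enrichment(sig, co$sets$nullset)$p
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 0.01)
})

test_that("the motif fixture encodes the allelic probe pair", {
  fx <- make_motif_fixture()
  ref <- strsplit(fx$seq_ref, "")[[1]]
  alt <- strsplit(fx$seq_alt, "")[[1]]
  expect_identical(which(ref != alt), 13L)  # 0-based offset 12
  expect_identical(ref[13], "G")
  expect_identical(alt[13], "C")
  expect_identical(nchar(fx$seq_ref), 25L)
  h <- best_allele_pvalue(fx$pcm, fx$seq_ref, fx$seq_alt, fx$variant_offset)
  expect_lt(h$p_ref, 0.0005)
  expect_gt(max(h$p_ref, h$p_alt) / min(h$p_ref, h$p_alt), 5)
  expect_identical(call_gain_loss(h), "loss")
})
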