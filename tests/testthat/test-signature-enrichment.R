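test_that("anchor-correlation signatures score planted structure", {
  cfg <- simulation_config(n_samples = 120, n_genes = 400,
                           planted_sets = list(list(name = "s", size = 40,
                                                    shift = 4)),
                           seed = 61)
  d <- as_genotype_data(simulate_haplotype_panel(cfg))$dosage[, cfg$risk_variant_index]
  co <- simulate_coexpression_and_sets(cfg, d)
  sig <- correlation_signature(co$expression, "ELL2", min_mean_fpkm = 0)
  expect_false("ELL2" %in% sig$gene)  # anchor never reports on itself
  members <- sig$gene %in% co$sets$s
  expect_gt(mean(sig$score[members]), mean(sig$score[!members]))
  expect_true(all(sig$q >= sig$p, na.rm = TRUE))

  ## FPKM filter: raising the floor keeps a strict subset of genes
  floor_med <- median(rowMeans(co$expression$values))
  strict <- correlation_signature(co$expression, "ELL2", min_mean_fpkm = floor_med)
  expect_true(all(strict$gene %in% sig$gene))
  expect_lt(nrow(strict), nrow(sig))

  expect_error(correlation_signature(co$expression, "NOT_A_GENE"), "not found")
  expect_error(correlation_signature(co$expression, rep(1, 120)), "constant")
})

test_that("a global null yields essentially no FDR-significant genes", {
  cfg <- simulation_config(n_samples = 80, n_genes = 500, planted_sets = list(),
                           seed = 62)
  d <- as_genotype_data(simulate_haplotype_panel(cfg))$dosage[, cfg$risk_variant_index]
  hits <- vapply(1:20, function(i) {
    co <- simulate_coexpression_and_sets(cfg, d, seed_index = i)
    sig <- correlation_signature(co$expression, "ELL2", min_mean_fpkm = 0)
    sum(sig$q < 0.05, na.rm = TRUE)
  }, numeric(1))
  expect_lt(mean(hits), 1)
})

test_that("BH step-up q-values match hand computation", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  set.seed(63)
  p <- runif(100)^2
  q <- bh_fdr(p)
  ord <- order(p)
  expect_true(all(diff(q[ord]) >= -1e-15))  # monotone along sorted p
  expect_true(all(q >= p))
})

test_that("moderated t shrinks variances and recovers its own prior", {
  set.seed(64)
  make_groups <- function(tstats_null = TRUE, d0 = 4, s0_sq = 1, G = 5000,
                          na = 3, nb = 3) {
    v <- d0 * s0_sq / rchisq(G, df = d0)  # scaled inverse chi-squared prior
    a <- t(sapply(sqrt(v), function(s) rnorm(na, 8, s)))
    b <- t(sapply(sqrt(v), function(s) rnorm(nb, 8, s)))
    rownames(a) <- rownames(b) <- sprintf("g%04d", seq_len(G))
    ## latent log2 values: map back to FPKM scale for the interface
    list(a = 2^a - 1, b = 2^b - 1)
  }
  g <- make_groups()
  fit <- moderated_t(g$a, g$b)
  expect_gt(fit$params$d0, 2.5)
  expect_lt(fit$params$d0, 6)
  expect_gt(fit$params$s0_sq, 0.8)
  expect_lt(fit$params$s0_sq, 1.25)

  ## independent cross-check against limma's variance shrinkage
  la <- log2(g$a + 1); lb <- log2(g$b + 1)
  s2 <- (rowSums((la - rowMeans(la))^2) + rowSums((lb - rowMeans(lb))^2)) / 4
  sq <- limma::squeezeVar(s2, df = 4)
  expect_equal(fit$params$d0, sq$df.prior, tolerance = 1e-4)
  expect_equal(fit$params$s0_sq, sq$var.prior, tolerance = 1e-4)

  ## identical groups: zero difference, t = 0, p = 1
  same <- moderated_t(g$a, g$a)
  expect_true(all(abs(same$scores$score) < 1e-12))
  expect_true(all(same$scores$p == 1))

  ## d0 forced to 0 reduces to the ordinary t statistic
  ord <- moderated_t(g$a, g$b, d0_override = 0)
  plain_t <- (rowMeans(la) - rowMeans(lb)) / sqrt(s2 * (1 / 3 + 1 / 3))
  expect_equal(ord$scores$score, unname(plain_t), tolerance = 1e-10)
  ## d0 -> Inf gives a constant-variance z-like statistic
  zlike <- moderated_t(g$a, g$b, d0_override = Inf)
  expect_equal(length(unique(round(
    zlike$scores$score / (rowMeans(la) - rowMeans(lb)), 8))), 1L)

  flat_a <- matrix(3, 4, 3, dimnames = list(sprintf("g%d", 1:4)))
  flat_b <- flat_a
  flat_a[1, ] <- 5
  mixed <- moderated_t(rbind(g$a[1:50, ], zero = 7),
                       rbind(g$b[1:50, ], zero = 7))
  expect_true(mixed$scores$zero_variance[51])
  expect_equal(mixed$params$n_zero_variance, 1)
})

test_that("log2-ratio signatures are exact arithmetic", {
  m <- matrix(c(4, 8, 0), 3, 4, dimnames = list(c("g1", "g2", "g3")))
  expect_equal(log2_ratio_signature(m, m)$score, c(0, 0, 0),
               ignore_attr = TRUE)
  doubled <- log2_ratio_signature(2 * m + 0.5, m, floor = 0)
  expect_equal(doubled$score[1:2], c(1, 1) + log2(c(8.5 / 8, 16.5 / 16)),
               ignore_attr = TRUE, tolerance = 1e-12)
  ## floor keeps zero-expression genes finite
  expect_true(is.finite(log2_ratio_signature(m, m * 0)$score[3]))
})

test_that("rank enrichment matches the tie-corrected rank-sum test", {
  ## equal multisets in and out of the set: statistic 0, p = 1
  s <- stats::setNames(rep(c(1, 2, 3, 4, 5), 2), sprintf("g%02d", 1:10))
  res <- rank_enrichment(s, sprintf("g%02d", 1:5))
  expect_equal(res$statistic, 0)
  expect_equal(res$p, 1)

  set.seed(65)
  scores <- stats::setNames(c(rnorm(40, 1), rnorm(160)), sprintf("g%03d", 1:200))
  set_ids <- sprintf("g%03d", 1:40)
  r <- rank_enrichment(scores, set_ids)
  expect_identical(r$direction, "up")
  w <- wilcox.test(scores[set_ids], scores[!names(scores) %in% set_ids],
                   correct = FALSE, exact = FALSE)
  expect_equal(r$p, w$p.value, tolerance = 1e-10)

  ## invariance under strictly monotone score transforms
  r2 <- rank_enrichment(exp(scores), set_ids)
  expect_equal(r2$statistic, r$statistic, tolerance = 1e-12)
  expect_equal(r2$p, r$p, tolerance = 1e-12)

  ## permutation mode agrees with the normal approximation
  rp <- rank_enrichment(scores, set_ids, mode = "permutation", n_perm = 2000,
                        seed = 66)
  expect_lt(abs(log10(max(rp$p, 5e-4)) - log10(max(r$p, 5e-4))), 1)

  expect_error(rank_enrichment(scores, "absent_gene"), "intersect")
  expect_error(rank_enrichment(scores, names(scores)), "covering")
})

test_that("planted directions are recovered in anchor and genotype signatures", {
  ## the anchor carries a negative allelic effect; the planted set correlates
  ## positively with the anchor AND responds positively to dosage - both
  ## planted signs must come back from the two signatures
  cfg <- simulation_config(
    n_samples = 185, n_genes = 1000,
    planted_sets = list(list(name = "RPG", size = 80, shift = 2, dosage_shift = 2),
                        list(name = "DOWN", size = 40, shift = 2, dosage_shift = -4)),
    seed = 67)
  d <- as_genotype_data(simulate_haplotype_panel(cfg))$dosage[, cfg$risk_variant_index]
  co <- simulate_coexpression_and_sets(cfg, d)
  sig_anchor <- correlation_signature(co$expression, "ELL2", min_mean_fpkm = 0)
  sig_geno <- correlation_signature(co$expression, as.numeric(d), min_mean_fpkm = 0)
  ## the anchor itself responds negatively to the risk allele
  expect_lt(cor(log2(co$expression$values["ELL2", ] + 1), d), 0)
  ea <- enrich_sets(sig_anchor, co$sets)
  eg <- enrich_sets(sig_geno, co$sets)
  expect_identical(ea$direction[ea$set == "RPG"], "up")
  expect_identical(eg$direction[eg$set == "RPG"], "up")
  expect_identical(eg$direction[eg$set == "DOWN"], "down")
  expect_lt(eg$p[eg$set == "DOWN"], 0.05)
})

test_that("luciferase effects are renilla-normalized medians of log2 ratios", {
  flat <- data.frame(firefly_risk = c(3, 5, 9), renilla_risk = c(3, 5, 9),
                     firefly_prot = c(3, 5, 9), renilla_prot = c(3, 5, 9))
  expect_equal(luciferase_effect(flat)$effect, 0)

  tri <- data.frame(firefly_risk = c(1, 1, 1), renilla_risk = c(2, 2, 4),
                    firefly_prot = c(1, 1, 1), renilla_prot = c(1, 1, 1))
  expect_equal(luciferase_effect(tri)$effect, log2(0.5))

  scaled <- tri
  scaled$renilla_risk <- tri$renilla_risk * 17
  scaled$renilla_prot <- tri$renilla_prot * 17
  expect_equal(luciferase_effect(scaled)$effect, luciferase_effect(tri)$effect)

  expect_error(luciferase_effect(tri[1:2, ]), "3..7")
  expect_error(luciferase_effect(rbind(tri, tri, tri)), "3..7")
  neg <- tri; neg$firefly_risk[1] <- 0
  expect_error(luciferase_effect(neg), "positive")
})
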