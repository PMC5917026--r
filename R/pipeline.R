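fmt_table <- function(df) {
  for (j in seq_along(df)) {
    if (is.numeric(df[[j]])) {
      x <- signif(df[[j]], 6)
      df[[j]] <- ifelse(is.na(x), NA,
                        ifelse(abs(x) < 1e-3 & x != 0,
                               format(x, scientific = TRUE), format(x)))
    }
  }
  df
}

write_stage_tsv <- function(df, dir, name) {
  path <- file.path(dir, paste0(name, ".tsv"))
  utils::write.table(fmt_table(df), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

#' Run the full synthetic analysis chain
#'
#' Orchestrates simulate -> exon eQTL -> cross-cohort meta-analysis ->
#' allele-specific counting -> LD prioritization -> motif disruption ->
#' signatures -> enrichment from one configuration, with deterministic
#' per-stage seeding, and writes per-stage TSVs plus a YAML run manifest
#' (config snapshot, thresholds, file digests) into `out_dir`.
#'
#' @param config a [simulation_config()] or path to a YAML config.
#' @param out_dir report directory (created if needed).
#' @param thresholds list of analysis thresholds; defaults: r2 >= 0.8
#'   (inclusive), eQTL and GWAS cluster alphas 1e-3, motif P < 5e-4 with
#'   fold change > 5 under the both-allele rule, FDR alpha 0.05, FPKM
#'   filter > 5.
#' @param simulate_only if `TRUE`, emit the simulated inputs and stop.
#' @return (invisibly) list with all stage tables and `out_dir`.
#' @export
run_pipeline <- function(config, out_dir, thresholds = list(), simulate_only = FALSE) {
  if (is.character(config)) config <- read_config(config)
  validate_config(config)
  thr <- utils::modifyList(list(r2 = 0.8, r2_inclusive = TRUE,
                                eqtl_alpha = 1e-3, gwas_alpha = 1e-3,
                                motif_p = 5e-4, motif_fc = 5,
                                motif_rule = "both", fdr_alpha = 0.05,
                                min_mean_fpkm = 5, transform = "log2"),
                           thresholds)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  files <- character(0)
  log_lines <- c(sprintf("seed: %d", config$seed),
                 sprintf("transform: %s", thr$transform),
                 sprintf("thresholds: r2>=%s eqtl_alpha=%s gwas_alpha=%s motif_p=%s motif_fc=%s rule=%s",
                         thr$r2, thr$eqtl_alpha, thr$gwas_alpha, thr$motif_p,
                         thr$motif_fc, thr$motif_rule))

  ## -- simulate ------------------------------------------------------------
  sim <- stage("simulate", {
    panel <- simulate_haplotype_panel(config)
    geno <- as_genotype_data(panel)
    files <- c(files,
               write_haplotypes(panel, file.path(out_dir, "haplotypes.tsv")),
               write_vcf_gt(geno, file.path(out_dir, "genotypes.vcf")),
               write_genotypes_tsv(geno, file.path(out_dir, "genotypes.tsv")),
               write_config(config, file.path(out_dir, "config.yaml")))
    list(panel = panel, geno = geno)
  })
  dosage <- sim$geno$dosage[, config$risk_variant_index]

  ## cohort panels for the meta-analysis (cohort 1 = discovery samples)
  cohorts <- stage("cohorts", lapply(seq_along(config$cohort_n), function(i) {
    if (i == 1 && config$cohort_n[1] == config$n_samples) return(sim$geno)
    ci <- config; ci$n_samples <- config$cohort_n[i]
    ci$seed <- as.integer(derive_seed(config$seed, "cohorts", i))
    as_genotype_data(simulate_haplotype_panel(ci))
  }))
  gene_expr <- stage("cohorts", lapply(seq_along(cohorts), function(i) {
    ci <- config
    ci$n_samples <- config$cohort_n[i]
    ci$beta_per_exon <- config$gene_beta
    ci$noise_sd <- NULL
    ci$seed <- as.integer(derive_seed(config$seed, "cohorts", 100L + i))
    simulate_exon_expression(cohorts[[i]]$dosage[, config$risk_variant_index],
                             ci, seed_index = i)
  }))
  if (simulate_only) {
    manifest <- build_manifest(config, thr, files, out_dir)
    return(invisible(list(out_dir = out_dir, manifest = manifest)))
  }

  ## -- exon-level eQTL (discovery cohort) ----------------------------------
  exon_tab <- stage("eqtl", {
    expr <- simulate_exon_expression(dosage, config)
    files <- c(files, write_expression(expr, file.path(out_dir, "exon_expression.tsv")))
    scan <- eqtl_scan(sim$geno, expr,
                      variants = sim$geno$variants$id[config$risk_variant_index],
                      transform = thr$transform)
    grp <- genotype_group_summary(colMeans(expr$values), dosage)
    list(scan = scan, groups = grp, expr = expr)
  })
  files <- c(files, file.path(out_dir, "exon_expression.tsv"),
             write_stage_tsv(exon_tab$scan, out_dir, "exon_eqtl"),
             write_stage_tsv(exon_tab$groups, out_dir, "genotype_groups"))

  ## -- meta-analysis across cohorts ----------------------------------------
  meta <- stage("meta", {
    per_cohort <- do.call(rbind, lapply(seq_along(cohorts), function(i) {
      pearson_eqtl(cohorts[[i]]$dosage[, config$risk_variant_index],
                   gene_expr[[i]]$values[1, ], transform = thr$transform,
                   feature = "ELL2", variant = "rs_causal")
    }))
    fc <- fisher_combine(per_cohort$p, feature = "ELL2")
    cb <- combine_beta(per_cohort$beta, per_cohort$se)
    fc$beta_combined <- cb$beta
    fc$se_combined <- cb$se
    list(per_cohort = per_cohort, combined = fc)
  })
  files <- c(files, write_stage_tsv(meta$per_cohort, out_dir, "cohort_eqtl"),
             write_stage_tsv(meta$combined, out_dir, "meta"))

  ## -- allele-specific expression ------------------------------------------
  ase <- stage("ase", {
    reads <- simulate_allelic_reads(config)
    files <- c(files, write_reads(reads, file.path(out_dir, "reads.fastq")))
    count_allelic_reads(reads)
  })
  ase_tab <- data.frame(n_ref = ase$n_ref, n_alt = ase$n_alt,
                        ratio = ase$ratio, p_binomial = ase$p_binomial)
  files <- c(files, file.path(out_dir, "reads.fastq"),
             write_stage_tsv(ase_tab, out_dir, "ase"))

  ## -- LD prioritization ----------------------------------------------------
  prio <- stage("prioritize", {
    eqtl_p <- vapply(seq_len(ncol(sim$geno$dosage)), function(v) {
      ps <- vapply(seq_along(cohorts), function(i) {
        tryCatch(pearson_eqtl(cohorts[[i]]$dosage[, v],
                              gene_expr[[i]]$values[1, ],
                              transform = thr$transform)$p,
                 error = function(e) NA_real_)
      }, numeric(1))
      ps <- ps[!is.na(ps)]
      if (!length(ps)) NA_real_ else fisher_combine(ps)$p_combined
    }, numeric(1))
    names(eqtl_p) <- sim$geno$variants$id
    gwas_p <- simulate_gwas_pvalues(sim$geno, config)
    quad <- classify_2d(eqtl_p, gwas_p, eqtl_alpha = thr$eqtl_alpha,
                        gwas_alpha = thr$gwas_alpha)
    nbhd <- ld_neighborhood(sim$panel, "rs_causal", thr$r2,
                            inclusive = thr$r2_inclusive)
    ## regulatory track: an internal-promoter-like interval over ten
    ## variants of the lead block, causal variant included
    vi <- config$risk_variant_index
    pos <- sim$geno$variants$pos
    track <- interval_track("H3K4me3_internal_promoter",
                            data.frame(chrom = "chr5",
                                       start = pos[max(1L, vi - 4L)] - 1L,
                                       end = pos[min(length(pos), vi + 5L)]))
    files <- c(files, write_intervals(track, file.path(out_dir, "regulatory.bed")))
    cand <- select_candidates(nbhd, quad, list(track), sim$geno$variants)
    list(quadrants = quad, neighborhood = nbhd, candidates = cand,
         track = track)
  })
  files <- c(files, file.path(out_dir, "regulatory.bed"),
             write_stage_tsv(prio$quadrants, out_dir, "quadrants"),
             write_stage_tsv(prio$candidates, out_dir, "candidates"))

  ## -- motif disruption ------------------------------------------------------
  motif <- stage("motif", {
    fx <- make_motif_fixture()
    files <- c(files, write_pcm(fx$pcm, file.path(out_dir, "motifs.pcm")))
    scan_variant(list(fx$pcm), fx$seq_ref, fx$seq_alt, fx$variant_offset,
                 p_threshold = thr$motif_p, fc_threshold = thr$motif_fc,
                 rule = thr$motif_rule)
  })
  files <- c(files, file.path(out_dir, "motifs.pcm"),
             write_stage_tsv(motif, out_dir, "motif_hits"))

  ## -- signatures and enrichment --------------------------------------------
  enr <- stage("signatures", {
    co <- simulate_coexpression_and_sets(config, dosage)
    files <- c(files,
               write_expression(co$expression, file.path(out_dir, "coexpression.tsv")),
               write_gene_sets(co$sets, file.path(out_dir, "gene_sets.gmt")))
    sig_anchor <- correlation_signature(co$expression, "ELL2",
                                        min_mean_fpkm = thr$min_mean_fpkm,
                                        transform = thr$transform)
    sig_geno <- correlation_signature(co$expression, as.numeric(dosage),
                                      min_mean_fpkm = thr$min_mean_fpkm,
                                      transform = thr$transform)
    ea <- enrich_sets(sig_anchor, co$sets)
    eg <- enrich_sets(sig_geno, co$sets)
    ea$signature <- "anchor_correlation"
    eg$signature <- "genotype_correlation"
    list(sig_anchor = sig_anchor, sig_geno = sig_geno,
         enrichment = rbind(ea, eg),
         n_fdr = sum(sig_anchor$q < thr$fdr_alpha, na.rm = TRUE))
  })
  files <- c(files, file.path(out_dir, c("coexpression.tsv", "gene_sets.gmt")),
             write_stage_tsv(enr$sig_anchor, out_dir, "signature_anchor"),
             write_stage_tsv(enr$sig_geno, out_dir, "signature_genotype"),
             write_stage_tsv(enr$enrichment, out_dir, "enrichment"))

  ## -- summary and manifest --------------------------------------------------
  summary_tab <- data.frame(
    quantity = c("exon11_p", "meta_p_combined", "beta_combined",
                 "ase_ratio", "ase_p", "n_neighborhood", "n_candidates",
                 "causal_is_candidate", "motif_direction", "motif_fold_change",
                 "n_genes_fdr05", "rpg_anchor_p", "rpg_anchor_direction"),
    value = c(exon_tab$scan$p[11], meta$combined$p_combined,
              meta$combined$beta_combined, ase$ratio, ase$p_binomial,
              length(prio$neighborhood), nrow(prio$candidates),
              "rs_causal" %in% prio$candidates$variant,
              motif$direction[1], motif$fold_change[1], enr$n_fdr,
              enr$enrichment$p[enr$enrichment$set == "RPG" &
                                 enr$enrichment$signature == "anchor_correlation"],
              enr$enrichment$direction[enr$enrichment$set == "RPG" &
                                         enr$enrichment$signature == "anchor_correlation"]),
    stringsAsFactors = FALSE)
  files <- c(files, write_stage_tsv(summary_tab, out_dir, "summary"))
  log_lines <- c(log_lines, sprintf("n_discovery: %d", config$n_samples),
                 sprintf("cohort_n: %s", paste(config$cohort_n, collapse = ",")))
  writeLines(log_lines, file.path(out_dir, "run.log"))
  manifest <- build_manifest(config, thr, unique(files), out_dir)
  invisible(list(out_dir = out_dir, exon_eqtl = exon_tab$scan,
                 genotype_groups = exon_tab$groups, meta = meta,
                 ase = ase, prioritization = prio, motif = motif,
                 signatures = enr, summary = summary_tab, manifest = manifest))
}

build_manifest <- function(config, thresholds, files, out_dir) {
  files <- unique(files[file.exists(files)])
  manifest <- list(seed = config$seed,
                   config = unclass(config),
                   thresholds = thresholds,
                   digests = as.list(tools::md5sum(sort(files))))
  names(manifest$digests) <- basename(sort(files))
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  manifest
}
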