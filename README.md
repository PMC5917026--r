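# allelreg

From a risk allele to its transcriptional program: `allelreg` is an R
package for the inference chain that links a non-coding disease risk allele
to the expression of a nearby gene and to downstream gene-expression
signatures. The motivating system is a GWAS locus where the risk haplotype
lowers expression of an elongation-factor gene in plasma cells, but every
stage is generic.

The chain, and the statistic at the core of each stage:

| Stage | Statistic |
|---|---|
| cis-eQTL testing | Pearson r on dosage vs transformed expression; t = r√(n−2)/√(1−r²), β (SD units) = r |
| Cross-cohort meta-analysis | Fisher's inverse χ²: −2Σln pᵢ ~ χ²₂ₖ; inverse-variance combined β |
| Allele-specific expression | exact substring counts of allele keys (± reverse complement); exact two-sided binomial test vs 0.5 |
| LD + prioritization | D, D′, r² from phased haplotypes; candidate ⟺ r² ≥ 0.8 ∧ significant on both −log₁₀p axes ∧ overlaps a regulatory track |
| Motif disruption | PWM log-odds best hit per allele over placements covering the variant; exact/DP score-distribution tail P; loss/gain at P < 5×10⁻⁴, fold change > 5 |
| Signatures + enrichment | anchor-correlation r with BH FDR; empirical-Bayes moderated t (d₀, s₀² by trigamma moment matching); tie-corrected rank-sum z per gene set |

A synthetic-data generator (founder-mosaic LD blocks, planted allelic
effects in SD units, allele-tagged reads, planted co-expression sets, an
allelic motif fixture) makes the full chain testable end to end without any
external data. All randomness derives from a single seed; identical
configurations give byte-identical reports.

## Worked example

Run the whole chain on the default synthetic scenario (185-sample
discovery cohort, planted gene-level effect −0.24 SD across cohorts of
185/658/183/604, allelic read ratio 0.545, a 72-variant risk LD block, one
regulatory track over the causal variant, a MAF-like motif disrupted by the
risk allele):

```r
library(allelreg)
cfg <- simulation_config(seed = 7)
res <- run_pipeline(cfg, "report")
res$summary
#>              quantity                value
#>              exon11_p  0.00152493370742104
#>       meta_p_combined 1.78405307813927e-24
#>         beta_combined   -0.259249475934507
#>             ase_ratio               0.5325
#>                 ase_p  0.00390905673140387
#>        n_neighborhood                   72
#>          n_candidates                    9
#>   causal_is_candidate                 TRUE
#>       motif_direction                 loss
#>     motif_fold_change                    9
#>          n_genes_fdr05                   0
#>          rpg_anchor_p 2.85253758019297e-07
#>  rpg_anchor_direction                   up
```

Reading the output: the planted negative allelic effect is recovered both
at the exon level (`exon11_p`) and in the four-cohort meta-analysis
(`beta_combined` ≈ −0.26 vs the planted −0.24; `meta_p_combined` far beyond
any single cohort). The heterozygote read counts recover the planted
allelic imbalance (`ase_ratio` 0.53, binomial p < 0.005). The causal
variant sits in a 72-variant r² ≥ 0.8 neighborhood, survives the
two-axis-significance + regulatory-overlap filter (`causal_is_candidate`),
and its risk allele destroys the planted binding motif (`motif_direction`
loss at fold change 9). The planted ribosomal-gene set comes back "up" in
the anchor-correlation signature. `n_genes_fdr05` is ~0 by construction:
non-member genes are exchangeable noise in the generator, unlike a real
transcriptome.

The report directory holds one TSV per stage (exon eQTL table, cohort and
meta rows, ASE counts, quadrant labels, candidate table, motif hits,
signatures, enrichment), the simulated inputs in standard formats (VCF,
TSV, FASTQ, BED, GMT, JASPAR-style PCM, YAML), a run log with every
threshold, and a YAML manifest with MD5 digests of all files.

Individual stages are plain functions: `pearson_eqtl()`, `fisher_combine()`,
`combine_beta()`, `count_allelic_reads()`, `ld_pair()`, `ld_neighborhood()`,
`classify_2d()`, `select_candidates()`, `pcm_to_pwm()`, `score_pvalue()`,
`best_allele_pvalue()`, `scan_variant()`, `correlation_signature()`,
`moderated_t()`, `rank_enrichment()`, `luciferase_effect()`. A thin CLI
wrapper lives at `inst/cli/allelreg.R`
(`Rscript allelreg.R run --config cfg.yaml --out DIR`).

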