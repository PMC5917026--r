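---
title: "Methods: from risk allele to transcriptional program"
author: "allelreg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from risk allele to transcriptional program}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allelreg)
```

# The problem

A common situation in post-GWAS functional genomics: a risk allele at a
non-coding locus is suspected to act by changing the expression of a nearby
gene (here, the motivating system is the multiple-myeloma risk locus at
*ELL2*, where the risk haplotype lowers *ELL2* expression in CD138^+^ plasma
cells). Establishing and dissecting such an effect requires a chain of
distinct computations:

1. **cis-eQTL testing** — associate risk-allele dosage with exon- or
   gene-level expression, per cohort;
2. **meta-analysis** — combine evidence across cohorts that used different
   expression platforms;
3. **allele-specific expression** — confirm the cis effect within
   heterozygotes by counting allele-distinguishing subsequences in raw
   reads;
4. **causal-variant prioritization** — intersect the lead variant's LD
   neighborhood with association evidence on both the expression and
   disease axes, and with regulatory annotation;
5. **motif disruption** — ask whether a candidate variant gains or loses a
   transcription-factor binding motif;
6. **downstream signatures** — correlate the gene (or the genotype) with
   the rest of the transcriptome and test gene sets for coordinated shifts.

`allelreg` implements this chain as reusable, separately testable stages,
plus a synthetic-data generator that emulates the statistical structure the
chain assumes, so the whole pipeline can be exercised and validated without
access to patient-level data, which for plasma-cell eQTL cohorts is
typically shareable only under access agreements.

# Statistical models, stage by stage

## Association testing

Association is Pearson correlation between dosage $d \in \{0,1,2\}$ and
transformed expression, with
$t = r\sqrt{n-2}/\sqrt{1-r^2}$ on $n-2$ df. The effect size is reported in
SD units: the standardized slope, which equals $r$, with
$\mathrm{SE} = \sqrt{(1-r^2)/(n-2)}$. The expression transform is always an
explicit argument — `log2` (log2(FPKM+1), the default), `raw`, or `rank` —
because the choice is analytically consequential and should never be
implicit. Pairs with missing values are removed pairwise, never imputed.
P-values are never reported as exactly zero: underflow is clamped to the
smallest positive double and flagged.

## Meta-analysis

Cohorts are combined by Fisher's inverse $\chi^2$ method,
$\chi^2 = -2\sum_i \ln p_i \sim \chi^2_{2k}$. A zero input P-value is an
error instructing the caller to clamp explicitly, rather than silently
producing $\chi^2 = \infty$. The combined effect size uses inverse-variance
weighting, $\hat\beta = \sum_i \beta_i/s_i^2 \big/ \sum_i 1/s_i^2$. The
combination method for the effect size is a package design choice (the kind
of detail frequently left unstated in publications); it is tagged on the
result so downstream consumers can see it.

## Allele-specific expression

Reads are scanned for exact substring matches of two equal-length allele
keys (27-mers around the exonic marker variant, by default). "Matching the
complement" is implemented as *reverse* complement by default, because read
orientation makes the reverse complement the operationally meaningful
match; a literal base-wise complement mode is provided for comparison. A
read matching both keys counts once per key. Imbalance is tested with the
exact two-sided binomial test against 0.5, the natural exact test for a
two-category count.

## LD and prioritization

From phased haplotypes, $D = p_{AB} - p_A p_B$,
$r^2 = D^2/(p_A(1-p_A)p_B(1-p_B))$, and $D' = |D|/D_{\max}$ with the usual
frequency-dependent $D_{\max}$. The candidate filter is deliberately the
simple, published-style rule — no Bayesian colocalization posterior:
candidate $\iff$ ($r^2 \ge 0.8$ with the lead) $\wedge$ (significant on both
the eQTL and GWAS axes) $\wedge$ (overlaps $\ge 1$ regulatory track). The
$r^2$ cutoff is applied inclusively by default (configurable), and the
two-axis thresholds default to $-\log_{10}p \ge 3$ on each axis. These
cluster thresholds are not derivable from first principles — they are
explicit configuration, logged on every run. Variant positions are 1-based
(VCF convention), intervals 0-based half-open (BED convention), with the
conversion rule ($start < p \le end$) localized in one function.

## Motif disruption

A position count matrix becomes a log-odds PWM with a background-weighted
pseudocount (default total 1.0, uniform background — configurable, since
the upstream tools' backgrounds vary). The tail probability
$\Pr(\mathrm{score}(W) \ge s)$ for a background-random word $W$ is computed
by dynamic programming over the score distribution, discretized at
$\varepsilon = 0.001$ log-odds units; an exact mode (merging identical
floating-point sums, equivalent to exhaustive enumeration) is used for
motifs up to length 10 and is the mode the test oracles check against.
For an allelic pair of windows, the best placement overlapping the variant
on either strand is found per allele and converted to a P-value; a variant
is called a motif **loss** when $p_{ref} < p_{alt}$ (the alternate allele
weakens binding), subject to $P < 5\times10^{-4}$ and fold change $> 5$.
The published defaults read literally as requiring the P threshold for
*both* alleles; that literal rule is the default, with an "either-allele"
mode provided because common practice for this tool family requires only
the stronger allele. Both modes are first-class and the choice is logged.

## Signatures and enrichment

Anchor-correlation signatures score all genes passing a mean-FPKM filter
(default > 5) by Pearson correlation with the anchor, with
Benjamini–Hochberg q-values. Two-group contrasts use an empirical-Bayes moderated t: per-gene
variances $s_g^2$ (pooled, $d_g$ df) are shrunk toward a prior
$(d_0, s_0^2)$ estimated by moment-matching the distribution of
$\log s_g^2$ under the scaled-F model — digamma/trigamma relations with a
Newton trigamma inverse (tolerance $10^{-8}$) — giving posterior variance
$\tilde s^2 = (d_0 s_0^2 + d_g s_g^2)/(d_0 + d_g)$ and $d_0 + d_g$ df. The
implementation is the package's own; the test suite cross-checks it against
an independent reference implementation of variance shrinkage.

Gene-set enrichment uses a tie-corrected two-sided Mann–Whitney rank-sum z
comparing in-set versus out-of-set scores. This statistic is a package
design decision: legacy enrichment tools in this area are often too poorly
documented to reimplement faithfully, so a transparent, well-calibrated
rank statistic was chosen, with a seeded score-permutation P-value (10,000
permutations) as an alternative mode. Rank-based, it is invariant under any
strictly monotone transform of the scores. Small-$n$ rescue-style
contrasts use floored log2 ratios of group means (floor 0.5 FPKM) with no
P-values — a deliberate "score-only" signature where variance estimation is
not meaningful. Luciferase reporter effects are medians over 3–7 replicates
of per-replicate $\log_2$ ratios of renilla-normalized firefly readings
(risk over protective allele), invariant to rescaling of the normalizer.

# The synthetic-data generator

The generator's defaults *are* the study conditions the pipeline emulates:

- **Haplotypes**: a founder-mosaic block model — within each block,
  haplotypes are copies of founder haplotypes drawn at set frequencies with
  per-site flip noise (default 0.01); blocks are independent. The default
  panel is a 72-variant tight block (two founders, matching the ~72-variant
  $r^2>0.8$ neighborhood of the motivating locus) flanked by two 24-variant
  4-founder blocks. This yields tunable $r^2$ structure without demographic
  realism, which the chain does not need.
- **Expression**: per exon, latent trait
  $\beta_e z + \mathcal{N}(0, \sigma_e)$ with $z$ the standardized dosage.
  When $\sigma_e$ is unset it defaults to $\sqrt{1-\beta_e^2}$ so the latent
  trait has unit variance and the planted standardized effect equals the
  expected correlation — this is what "β in SD units" means operationally.
  Default per-exon effects are the twelve values of
  `ell2_exon_table()` (−0.04 to −0.20); the gene-level/meta scenario plants
  β = −0.24 across cohorts of 185/658/183/604 samples. The latent value maps
  to FPKM by the fixed monotone transform $2^{(\mathrm{latent}+b)}-1$
  (baseline $b = 5$, recorded in metadata) so the default log2(x+1) analysis
  transform inverts it exactly.
- **Reads**: each read embeds one allele key at a random offset in random
  flanking sequence; the alternate allele is drawn Bernoulli(π = 0.545);
  every second read is reverse-complemented; qualities are constant "I" and
  never used. A deterministic interleaving mode plants exact counts for
  bookkeeping tests. The per-experiment read depth (default 2000) is a free
  parameter: the real per-sample depth at the variant site is not published.
- **Co-expression**: an anchor gene carries the allelic effect; planted set
  members load on the anchor's non-genotype residual by `shift` null-SD
  units (null SD of a correlation ≈ $1/\sqrt{n}$) and, independently, on
  dosage by `dosage_shift`. Planting the two directions separately is what
  lets the generator reproduce the empirically observed pattern in which a
  gene set correlates *positively* with the anchor while also moving in the
  direction of the risk allele that *lowers* the anchor.
- **Motif fixture**: an 11-column MAF-family-like count matrix whose
  consensus matches the G-allele core of the 25-bp regulatory probe with the
  central G/C swap. Column compositions were chosen at design time so the
  fixture meets its specified behavior (both alleles significant at
  $5\times10^{-4}$, fold change > 5, loss call): strong consensus columns
  (21/1/1/1), three tolerant flank columns (9/7/2/2) that widen the allelic
  tail-probability gap, and a moderately informative variant column
  (G14/C6/A2/T2).

What the generator does **not** emulate: sequencing error, mappability or
GC bias, population structure and relatedness, splicing, and — importantly
for interpreting the signature stage — the pervasive correlation structure
of real transcriptomes. Non-member genes are exchangeable noise, so a
"number of FDR-significant genes" computed on synthetic data is near zero
by construction and says nothing about the thousands of correlated genes a
real dataset shows. Passing tests demonstrate calibration and recovery of
*planted* structure, not biological realism.

# Numerical and design choices

- **Determinism**: every stochastic stage derives its seed from the single
  run seed via a fixed documented mapping (`derive_seed`); no stage reads
  ambient global random state, and the global RNG state is restored after
  each draw. Identical (config, seed) gives byte-identical reports; the
  manifest records MD5 digests of every emitted file.
- **Score discretization**: refining $\varepsilon$ tenfold moves fixture
  tail probabilities by under $10^{-6}$; word scoring accumulates partial
  sums stepwise so they round identically to the DP recursion.
- **Degenerate inputs**: constant dosage or expression, monomorphic
  variants, empty read sets, empty track lists, zero-variance genes and
  all-zero P-values all have defined, tested behaviors (errors or flags,
  never silent drops).
- **Tie-breaks**: enrichment uses midranks with the standard tie-corrected
  variance; equal allelic P-values give direction "none"; equal multisets
  of scores give z = 0, p = 1 exactly.

# Problem sizes used in validation

The test suite runs the statistical checks at the sizes the analysis is
designed for: effect-size recovery over 200 replicates at n = 185;
meta-recovery over 100 replicates of the four cohort sizes; type-I error of
the association test over 2000 null replicates; enrichment null calibration
over 2000 random 80-gene draws from a 5000-gene signature; set-detection
power over 50 replicates of a 2000-gene matrix; BH FDR control over 100
replicates of a 2000-gene, 10%-non-null mixture. Exhaustive PWM enumeration
oracles run at motif lengths 4–8.

# Known limitations

- The candidate filter is threshold-based; it inherits the arbitrariness of
  its thresholds and provides no posterior probability of colocalization.
- The founder-mosaic panel produces block-constant LD, not the decaying
  $r^2$ of real recombination maps; neighborhood sizes on synthetic panels
  are exact block sizes.
- The moderated-t prior fit assumes the scaled-F model; it is accurate when
  per-gene variances genuinely exchange information, and degrades to the
  ordinary t (d0 → 0) when they do not.
- The exact PWM mode is limited to motif length 10; longer motifs use the
  discretized DP, whose error is bounded by the granularity refinement
  check rather than by exhaustive enumeration.
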