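Package: allelreg
Title: Allelic Regulation Analysis: cis-eQTL Mapping, Causal-Variant
    Prioritization and Downstream Signatures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline linking a risk allele to cis gene expression
    and downstream transcriptional programs. Provides exon-level eQTL testing
    by Pearson correlation with Fisher inverse chi-squared cross-cohort
    meta-analysis, allele-specific expression from raw reads by exact
    subsequence counting, linkage-disequilibrium metrics (r-squared, D-prime)
    from phased haplotypes with regulatory-annotation candidate selection,
    position-weight-matrix allelic motif-disruption scoring with exact
    score-distribution P-values, empirical-Bayes moderated-t and rank-based
    gene-set enrichment of expression signatures, and a synthetic-data
    generator that emulates the statistical structure of plasma-cell eQTL
    studies so the full chain is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    Biostrings,
    vcfR,
    fgsea
Suggests:
    testthat (>= 3.0.0),
    limma,
    withr,
    optparse
Config/testthat/edition: 3
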