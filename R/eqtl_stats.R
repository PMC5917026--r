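#' Exon-level eQTL test by Pearson correlation
#'
#' Association between risk-allele dosage and (transformed) expression.
#' The effect size is reported in SD units: the standardized regression slope,
#' which equals the Pearson correlation r. Statistics follow the t transform
#' `t = r * sqrt(n - 2) / sqrt(1 - r^2)` with a two-sided tail on n - 2
#' degrees of freedom; `se = sqrt((1 - r^2) / (n - 2))`. Pairs with missing
#' dosage or expression are removed pairwise, never imputed.
#'
#' @param dosage numeric dosage vector (0/1/2, NA allowed).
#' @param expression numeric expression vector on the raw FPKM scale.
#' @param transform expression transform applied before testing; always an
#'   explicit choice (default `log2(x + 1)`).
#' @param feature,variant id labels carried into the result.
#' @return one-row data.frame of class `eqtl_result`: feature, variant, n, r,
#'   beta, se, r2, p, p_clamped.
#' @export
pearson_eqtl <- function(dosage, expression, transform = c("log2", "raw", "rank"),
                         feature = "feature", variant = "variant") {
  transform <- match.arg(transform)
  keep <- stats::complete.cases(dosage, expression)
  x <- dosage[keep]
  y <- apply_transform(expression[keep], transform)
  n <- length(x)
  if (n < 3) stop("need at least 3 complete (dosage, expression) pairs")
  if (stats::var(x) == 0) stop("constant dosage: correlation undefined")
  if (stats::var(y) == 0) stop("constant expression: correlation undefined")
  ct <- stats::cor.test(x, y, method = "pearson")
  r <- unname(ct$estimate)
  p <- clamp_p(ct$p.value)
  structure(data.frame(feature = feature, variant = variant, n = n, r = r,
                       beta = r, se = sqrt((1 - r^2) / (n - 2)), r2 = r^2,
                       p = as.numeric(p), p_clamped = isTRUE(attr(p, "clamped")),
                       stringsAsFactors = FALSE),
            class = c("eqtl_result", "data.frame"))
}

#' Two-sided Pearson P-value from a correlation and sample size
#'
#' The t transform used by [pearson_eqtl()]:
#' `t = r * sqrt(n - 2) / sqrt(1 - r^2)`, two-sided tail on n - 2 df.
#' Useful for reproducing printed association tables from their (r, n).
#'
#' @param r Pearson correlation.
#' @param n sample size (>= 3).
#' @return two-sided P-value.
#' @export
pearson_p_from_r <- function(r, n) {
  stopifnot(n >= 3, abs(r) <= 1)
  t <- r * sqrt(n - 2) / sqrt(1 - r^2)
  as.numeric(clamp_p(2 * stats::pt(-abs(t), df = n - 2)))
}

#' Scan all feature x variant pairs
#'
#' One [pearson_eqtl()] per (feature, variant). Samples are matched by id
#' (intersection of the two inputs); features failing test preconditions
#' (e.g. constant expression) are flagged in the `note` column, never dropped
#' silently.
#'
#' @param genotypes a `genotype_data`.
#' @param expression an [expression_matrix()] on the raw scale.
#' @param variants variant ids to test (default: all in `genotypes`).
#' @param transform expression transform, passed to [pearson_eqtl()].
#' @return data.frame with one row per (feature, variant).
#' @export
eqtl_scan <- function(genotypes, expression, variants = NULL,
                      transform = c("log2", "raw", "rank")) {
  transform <- match.arg(transform)
  variants <- variants %||% colnames(genotypes$dosage)
  common <- intersect(rownames(genotypes$dosage), colnames(expression$values))
  if (!length(common)) stop("no samples shared between genotypes and expression")
  dos <- genotypes$dosage[common, variants, drop = FALSE]
  vals <- expression$values[, common, drop = FALSE]
  out <- lapply(rownames(vals), function(f) {
    do.call(rbind, lapply(variants, function(v) {
      res <- tryCatch(pearson_eqtl(dos[, v], vals[f, ], transform = transform,
                                   feature = f, variant = v),
                      error = function(e) {
                        data.frame(feature = f, variant = v, n = NA_integer_,
                                   r = NA_real_, beta = NA_real_, se = NA_real_,
                                   r2 = NA_real_, p = NA_real_, p_clamped = FALSE,
                                   note = conditionMessage(e),
                                   stringsAsFactors = FALSE)
                      })
      if (is.null(res$note)) res$note <- ""
      res
    }))
  })
  do.call(rbind, out)
}

#' Fisher inverse chi-squared combination of P-values
#'
#' `chi2 = -2 * sum(log(p_i))` referred to the upper tail of a chi-squared
#' distribution with 2k degrees of freedom.
#'
#' @param p_values vector of P-values, each in (0, 1].
#' @param feature feature label carried into the result.
#' @return one-row data.frame of class `meta_result`: feature, k, chi2, df,
#'   p_combined.
#' @export
fisher_combine <- function(p_values, feature = "feature") {
  if (!length(p_values)) stop("need at least one P-value")
  if (any(p_values <= 0))
    stop("P-value of 0 supplied: clamp explicitly at the minimum positive ",
         "representable value before combining")
  if (any(p_values > 1)) stop("P-values must lie in (0, 1]")
  k <- length(p_values)
  chi2 <- -2 * sum(log(p_values))
  p <- clamp_p(stats::pchisq(chi2, df = 2 * k, lower.tail = FALSE))
  structure(data.frame(feature = feature, k = k, chi2 = chi2, df = 2 * k,
                       p_combined = as.numeric(p),
                       p_clamped = isTRUE(attr(p, "clamped")),
                       combine_method = "fisher_inverse_chisq",
                       stringsAsFactors = FALSE),
            class = c("meta_result", "data.frame"))
}

#' Inverse-variance weighted combined effect size
#'
#' `beta = sum(beta_i / se_i^2) / sum(1 / se_i^2)` with
#' `se = sqrt(1 / sum(1 / se_i^2))`. Infinite standard errors receive zero
#' weight.
#'
#' @param betas per-study effect sizes (SD units).
#' @param ses per-study standard errors (> 0).
#' @return list with `beta` and `se`.
#' @export
combine_beta <- function(betas, ses) {
  if (length(betas) != length(ses)) stop("betas and ses must have equal length")
  if (any(ses <= 0)) stop("standard errors must be positive")
  w <- 1 / ses^2
  w[!is.finite(w)] <- 0
  list(beta = sum(w * betas) / sum(w), se = sqrt(1 / sum(w)))
}

#' Count allele-distinguishing subsequences in raw reads
#'
#' A read counts toward an allele when it contains an exact substring match
#' of that allele's key or, under the default `complement_mode = "reverse"`,
#' of its reverse complement (read orientation makes reverse complement the
#' operationally meaningful match; `"literal"` matches the base-wise
#' complement instead, `"none"` the forward key only). A read matching both
#' keys counts once per key it matches. The imbalance test is the exact
#' two-sided binomial test of `n_alt` against Binomial(n_ref + n_alt, 0.5).
#'
#' @param reads a `read_collection`.
#' @param key_ref,key_alt equal-length allele keys differing at >= 1 base.
#' @param complement_mode `"reverse"`, `"literal"` or `"none"`.
#' @return list of class `allelic_count`: n_ref, n_alt, ratio
#'   (= n_alt / total), p_binomial.
#' @export
count_allelic_reads <- function(reads, key_ref = ase_keys()[["ref"]],
                                key_alt = ase_keys()[["alt"]],
                                complement_mode = c("reverse", "literal", "none")) {
  complement_mode <- match.arg(complement_mode)
  if (nchar(key_ref) != nchar(key_alt)) stop("allele keys must have equal length")
  if (key_ref == key_alt) stop("allele keys must differ at >= 1 base")
  if (!length(reads$sequences)) stop("empty read set: allelic ratio undefined")
  second_key <- function(key) {
    d <- Biostrings::DNAString(key)
    switch(complement_mode,
           reverse = as.character(Biostrings::reverseComplement(d)),
           literal = as.character(Biostrings::complement(d)),
           none = NULL)
  }
  hits <- function(key) {
    h <- Biostrings::vcountPattern(key, reads$sequences) > 0
    k2 <- second_key(key)
    if (!is.null(k2)) h <- h | Biostrings::vcountPattern(k2, reads$sequences) > 0
    sum(h)
  }
  n_ref <- hits(key_ref)
  n_alt <- hits(key_alt)
  total <- n_ref + n_alt
  bt <- if (total > 0) stats::binom.test(n_alt, total, p = 0.5)$p.value else NA_real_
  structure(list(n_ref = n_ref, n_alt = n_alt,
                 ratio = if (total > 0) n_alt / total else NA_real_,
                 p_binomial = bt),
            class = "allelic_count")
}

#' Per-genotype-group expression summary
#'
#' Group means on the raw FPKM scale by dosage group (0, 1, 2 risk alleles)
#' and the percent change of each group versus the dosage-0 group,
#' `100 * (1 - mean_g / mean_0)`. Groups with a single sample are flagged
#' low-n; empty groups give a missing contrast.
#'
#' @param expression raw-scale expression vector.
#' @param dosage dosage vector (0/1/2).
#' @return data.frame with dosage, n, mean, pct_change_vs_0, low_n.
#' @export
genotype_group_summary <- function(expression, dosage) {
  keep <- stats::complete.cases(expression, dosage)
  expression <- expression[keep]; dosage <- dosage[keep]
  out <- data.frame(dosage = 0:2)
  out$n <- vapply(out$dosage, function(g) sum(dosage == g), integer(1))
  out$mean <- vapply(out$dosage, function(g)
    if (any(dosage == g)) mean(expression[dosage == g]) else NA_real_, numeric(1))
  out$pct_change_vs_0 <- 100 * (1 - out$mean / out$mean[out$dosage == 0])
  out$low_n <- out$n == 1
  out
}
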