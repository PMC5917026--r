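#' Anchor-correlation expression signature
#'
#' Scores every expressed gene by its Pearson correlation with an anchor
#' (a gene's expression profile, or an external vector such as risk-allele
#' dosage). Genes are filtered on mean raw FPKM before scoring; correlations
#' are computed on the chosen transform. P-values use the t transform of r
#' and are BH-adjusted.
#'
#' @param expression an [expression_matrix()] on the raw FPKM scale.
#' @param anchor a gene id present in `expression` (excluded from its own
#'   signature) or a numeric vector with one value per sample.
#' @param min_mean_fpkm expression filter: keep genes with mean raw FPKM
#'   strictly above this value (default 5).
#' @param transform transform under which correlations are computed.
#' @return data.frame of class `gene_score`: gene, score (r), score_type,
#'   n, p, q.
#' @export
correlation_signature <- function(expression, anchor, min_mean_fpkm = 5,
                                  transform = c("log2", "raw", "rank")) {
  transform <- match.arg(transform)
  stopifnot(expression$transform == "raw")
  vals <- expression$values
  if (is.character(anchor)) {
    if (!anchor %in% rownames(vals)) stop("anchor gene not found")
    anchor_vec <- apply_transform(vals[anchor, ], transform)
    vals <- vals[setdiff(rownames(vals), anchor), , drop = FALSE]
  } else {
    if (length(anchor) != ncol(vals)) stop("anchor vector length != n samples")
    anchor_vec <- anchor
  }
  if (ncol(vals) < 3) stop("need at least 3 samples")
  if (stats::var(anchor_vec) == 0) stop("anchor is constant")
  keep <- rowMeans(vals) > min_mean_fpkm
  if (!any(keep)) stop("no genes pass the mean-FPKM filter")
  vals <- vals[keep, , drop = FALSE]
  tv <- apply_transform(vals, transform)
  n <- ncol(tv)
  r <- suppressWarnings(as.vector(stats::cor(t(tv), anchor_vec)))
  tstat <- r * sqrt(n - 2) / sqrt(pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[is.na(r)] <- NA
  structure(data.frame(gene = rownames(vals), score = r,
                       score_type = "pearson_r", n = n, p = p, q = bh_fdr(p),
                       stringsAsFactors = FALSE),
            class = c("gene_score", "data.frame"))
}

#' Benjamini-Hochberg step-up q-values
#'
#' `q_(i) = min_{j >= i} (p_(j) * m / j)`, capped at 1; delegates to
#' [stats::p.adjust()] with `method = "BH"`.
#'
#' @param p_values vector of P-values in \[0, 1\] (NA allowed).
#' @return vector of q-values in the input order.
#' @export
bh_fdr <- function(p_values) stats::p.adjust(p_values, method = "BH")

## Newton inversion of the trigamma function, used by the empirical-Bayes
## variance-prior fit; tolerance 1e-8 on the relative step.
trigamma_inverse <- function(y) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:60) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2)
    x <- x + dif
    if (abs(dif) / x < 1e-8) break
  }
  x
}

#' Empirical-Bayes moderated t-statistics between two groups
#'
#' Per-gene mean differences on log2(FPKM + 1) with variance moderation:
#' per-gene sample variances s_g^2 (pooled within groups, d_g residual df)
#' are shrunk toward a prior (d0, s0^2) estimated by moment-matching the
#' distribution of log s_g^2 under the scaled-F model, using digamma /
#' trigamma relations with a Newton trigamma inverse. The posterior variance
#' is `(d0 s0^2 + d_g s_g^2) / (d0 + d_g)` and the moderated t has
#' `d0 + d_g` degrees of freedom. Genes with zero variance in both groups
#' are flagged and excluded from the prior fit.
#'
#' @param group_a,group_b [expression_matrix()] objects or numeric matrices
#'   (raw FPKM scale) with identical feature sets and >= 2 samples each.
#' @param d0_override optional forced prior df (e.g. 0 for ordinary t,
#'   `Inf` for a constant-variance z-like statistic).
#' @return list with `scores` (gene, score = moderated t, diff, p, q,
#'   zero_variance flag) and `params` (d0, s0_sq, d_g).
#' @export
moderated_t <- function(group_a, group_b, d0_override = NULL) {
  ga <- if (inherits(group_a, "expression_matrix")) group_a$values else group_a
  gb <- if (inherits(group_b, "expression_matrix")) group_b$values else group_b
  stopifnot(identical(rownames(ga), rownames(gb)))
  na <- ncol(ga); nb <- ncol(gb)
  if (na < 2 || nb < 2) stop("need >= 2 samples per group")
  la <- log2(ga + 1); lb <- log2(gb + 1)
  ma <- rowMeans(la); mb <- rowMeans(lb)
  va <- apply(la, 1, stats::var); vb <- apply(lb, 1, stats::var)
  d_g <- na + nb - 2
  s2 <- ((na - 1) * va + (nb - 1) * vb) / d_g
  zero_var <- s2 <= 0
  fit_s2 <- s2[!zero_var]
  if (!is.null(d0_override)) {
    d0 <- d0_override
    s0_sq <- if (length(fit_s2)) stats::median(fit_s2) else 1
  } else if (length(fit_s2) >= 2) {
    e <- log(fit_s2) - digamma(d_g / 2) + log(d_g / 2)
    emean <- mean(e)
    rhs <- stats::var(e) - trigamma(d_g / 2)
    if (rhs > 0) {
      d0 <- 2 * trigamma_inverse(rhs)
      s0_sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
    } else {
      d0 <- Inf
      s0_sq <- exp(emean)
    }
  } else {
    d0 <- 0; s0_sq <- 1
  }
  post <- if (is.infinite(d0)) rep(s0_sq, length(s2))
          else (d0 * s0_sq + d_g * s2) / (d0 + d_g)
  diff <- ma - mb
  tstat <- diff / sqrt(post * (1 / na + 1 / nb))
  df_total <- d0 + d_g
  p <- if (is.infinite(df_total)) 2 * stats::pnorm(-abs(tstat))
       else 2 * stats::pt(-abs(tstat), df = df_total)
  p[!is.finite(tstat)] <- NA
  scores <- structure(
    data.frame(gene = rownames(ga), score = tstat, score_type = "moderated_t",
               diff = diff, p = p, q = bh_fdr(p), zero_variance = zero_var,
               stringsAsFactors = FALSE),
    class = c("gene_score", "data.frame"))
  list(scores = scores,
       params = list(d0 = d0, s0_sq = s0_sq, d_g = d_g,
                     n_zero_variance = sum(zero_var)))
}

#' Floored log2-ratio signature between two groups
#'
#' Score-only contrast: per gene, `log2((mean_a + floor) / (mean_b + floor))`
#' on raw FPKM means. Used for small-n contrasts where a variance estimate is
#' not meaningful; no P-values are produced.
#'
#' @param group_a,group_b [expression_matrix()] objects or numeric matrices
#'   on the raw FPKM scale with identical feature sets.
#' @param floor additive floor in FPKM (default 0.5).
#' @return data.frame of class `gene_score`: gene, score, score_type.
#' @export
log2_ratio_signature <- function(group_a, group_b, floor = 0.5) {
  ga <- if (inherits(group_a, "expression_matrix")) group_a$values else group_a
  gb <- if (inherits(group_b, "expression_matrix")) group_b$values else group_b
  stopifnot(identical(rownames(ga), rownames(gb)))
  score <- log2((rowMeans(ga) + floor) / (rowMeans(gb) + floor))
  structure(data.frame(gene = rownames(ga), score = score,
                       score_type = "log2_ratio", stringsAsFactors = FALSE),
            class = c("gene_score", "data.frame"))
}

#' Rank-based gene-set enrichment of a score signature
#'
#' Compares in-set versus out-of-set scores with a tie-corrected two-sided
#' Mann-Whitney rank-sum z statistic (normal approximation). The direction is
#' `up` when the mean rank of the set exceeds that of its complement. A
#' score-permutation P-value (set membership permuted, seeded) is available
#' as an alternative mode.
#'
#' @param scores a `gene_score` data.frame (columns gene, score) or a named
#'   numeric vector.
#' @param gene_set character vector of member gene ids.
#' @param set_name label carried into the result.
#' @param mode `"ranksum"` or `"permutation"`.
#' @param n_perm permutations for the permutation mode.
#' @param seed seed for the permutation mode.
#' @return one-row data.frame of class `enrichment_result`: set, n_in, n_out,
#'   statistic (z), direction, p.
#' @export
rank_enrichment <- function(scores, gene_set, set_name = "set",
                            mode = c("ranksum", "permutation"),
                            n_perm = 10000, seed = 1L) {
  mode <- match.arg(mode)
  if (is.data.frame(scores)) {
    s <- scores$score; names(s) <- scores$gene
  } else s <- scores
  s <- s[!is.na(s)]
  in_set <- names(s) %in% gene_set
  n1 <- sum(in_set); n2 <- sum(!in_set); N <- n1 + n2
  if (n1 < 1 || n2 < 1)
    stop("gene set must intersect the scored genes without covering them all")
  zstat <- function(flag) {
    rk <- rank(s)
    R1 <- sum(rk[flag])
    mu <- n1 * (N + 1) / 2
    ties <- table(s)
    sigma2 <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    if (sigma2 <= 0) return(0)
    (R1 - mu) / sqrt(sigma2)
  }
  z <- zstat(in_set)
  p <- if (mode == "ranksum") {
    min(1, 2 * stats::pnorm(-abs(z)))
  } else {
    zs <- with_seed(derive_seed(seed, "permutation"),
                    replicate(n_perm, zstat(sample(in_set))))
    (1 + sum(abs(zs) >= abs(z))) / (n_perm + 1)
  }
  structure(data.frame(set = set_name, n_in = n1, n_out = n2, statistic = z,
                       direction = if (z >= 0) "up" else "down", p = p,
                       stringsAsFactors = FALSE),
            class = c("enrichment_result", "data.frame"))
}

#' Enrichment of several gene sets against one signature
#' @param scores as in [rank_enrichment()].
#' @param sets named list of gene-id vectors.
#' @inheritParams rank_enrichment
#' @return data.frame, one row per set.
#' @export
enrich_sets <- function(scores, sets, mode = "ranksum", n_perm = 10000,
                        seed = 1L) {
  do.call(rbind, lapply(names(sets), function(nm)
    rank_enrichment(scores, sets[[nm]], set_name = nm, mode = mode,
                    n_perm = n_perm, seed = seed)))
}

#' Allelic luciferase reporter effect
#'
#' Per replicate, firefly readings are normalized by the renilla
#' co-transfection control for each allele; the effect is the median over
#' replicates of `log2((firefly_risk / renilla_risk) /
#' (firefly_prot / renilla_prot))`. Between 3 and 7 replicate pairs are
#' required; non-positive readings are an error.
#'
#' @param measurements data.frame with columns `firefly_risk`,
#'   `renilla_risk`, `firefly_prot`, `renilla_prot`, one row per replicate.
#' @param construct construct label.
#' @return list of class `luciferase_effect`: construct, effect,
#'   n_replicates, log2_ratios.
#' @export
luciferase_effect <- function(measurements, construct = "construct") {
  need <- c("firefly_risk", "renilla_risk", "firefly_prot", "renilla_prot")
  stopifnot(all(need %in% names(measurements)))
  m <- measurements[need]
  if (any(as.matrix(m) <= 0)) stop("luciferase readings must be positive")
  n <- nrow(m)
  if (n < 3 || n > 7) stop("replicate count must lie in 3..7")
  ratios <- log2((m$firefly_risk / m$renilla_risk) /
                   (m$firefly_prot / m$renilla_prot))
  structure(list(construct = construct, effect = stats::median(ratios),
                 n_replicates = n, log2_ratios = ratios),
            class = "luciferase_effect")
}
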