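#' Pairwise linkage disequilibrium from phased haplotypes
#'
#' With haplotype frequencies p_A, p_B (alternate-allele frequencies at the
#' two variants) and p_AB (joint), `D = p_AB - p_A * p_B`,
#' `r2 = D^2 / (p_A (1 - p_A) p_B (1 - p_B))`, and `d_prime = |D| / D_max`
#' where `D_max = min(p_A (1 - p_B), (1 - p_A) p_B)` when D > 0 and
#' `min(p_A p_B, (1 - p_A)(1 - p_B))` when D < 0; `d_prime = 0` when D = 0.
#'
#' @param panel a `haplotype_panel` (or `genotype_data` carrying haplotypes).
#' @param v1,v2 variant ids or column indices.
#' @return list of class `ld_result`: v1, v2, D, d_prime, r2.
#' @export
ld_pair <- function(panel, v1, v2) {
  h <- panel$haplotypes
  if (is.null(h)) stop("phased haplotypes required for LD")
  a <- h[, v1]; b <- h[, v2]
  pa <- mean(a); pb <- mean(b)
  if (pa %in% c(0, 1) || pb %in% c(0, 1))
    stop("monomorphic variant: LD undefined")
  pab <- mean(a & b)
  D <- pab - pa * pb
  r2 <- D^2 / (pa * (1 - pa) * pb * (1 - pb))
  d_max <- if (D > 0) min(pa * (1 - pb), (1 - pa) * pb)
           else min(pa * pb, (1 - pa) * (1 - pb))
  d_prime <- if (D == 0) 0 else abs(D) / d_max
  structure(list(v1 = v1, v2 = v2, D = D, d_prime = d_prime, r2 = r2),
            class = "ld_result")
}

#' Variants in the r-squared neighborhood of a lead variant
#'
#' All segregating variants whose r2 with the lead meets the threshold
#' (inclusive by default; set `inclusive = FALSE` for a strict `>`), the lead
#' itself included, sorted by position.
#'
#' @param panel a `haplotype_panel`.
#' @param lead_variant lead variant id.
#' @param r2_threshold r-squared cutoff (default 0.8).
#' @param inclusive apply the cutoff as `>=` (default) rather than `>`.
#' @return character vector of variant ids.
#' @export
ld_neighborhood <- function(panel, lead_variant, r2_threshold = 0.8,
                            inclusive = TRUE) {
  h <- panel$haplotypes
  lead <- h[, lead_variant]
  if (mean(lead) %in% c(0, 1)) stop("lead variant is monomorphic")
  ids <- colnames(h)
  r2 <- vapply(ids, function(v) {
    p <- mean(h[, v])
    if (p %in% c(0, 1)) return(NA_real_)
    ld_pair(panel, lead_variant, v)$r2
  }, numeric(1))
  pass <- !is.na(r2) & if (inclusive) r2 >= r2_threshold else r2 > r2_threshold
  pass[ids == lead_variant] <- TRUE
  sel <- ids[pass]
  if (!is.null(panel$variants$pos)) {
    pos <- panel$variants$pos[match(sel, panel$variants$id)]
    sel <- sel[order(pos)]
  }
  sel
}

#' Two-dimensional significance classification
#'
#' Labels each variant by thresholding -log10(p) on the eQTL and GWAS axes:
#' `both`, `eqtl_only`, `gwas_only` or `neither`. Variants missing a P-value
#' on either axis are labeled `neither` and flagged.
#'
#' @param eqtl_p,gwas_p named vectors of P-values.
#' @param variants variant ids to classify (default: union of names).
#' @param eqtl_alpha,gwas_alpha significance thresholds on the P scale
#'   (defaults 1e-3, i.e. -log10 p >= 3 on each axis; the cluster thresholds
#'   are explicit configuration, always logged by the pipeline).
#' @return data.frame with variant, eqtl_p, gwas_p, quadrant, missing.
#' @export
classify_2d <- function(eqtl_p, gwas_p, variants = NULL,
                        eqtl_alpha = 1e-3, gwas_alpha = 1e-3) {
  variants <- variants %||% union(names(eqtl_p), names(gwas_p))
  ep <- unname(eqtl_p[variants]); gp <- unname(gwas_p[variants])
  missing <- is.na(ep) | is.na(gp)
  e_sig <- !is.na(ep) & -log10(ep) >= -log10(eqtl_alpha)
  g_sig <- !is.na(gp) & -log10(gp) >= -log10(gwas_alpha)
  quadrant <- ifelse(missing, "neither",
               ifelse(e_sig & g_sig, "both",
                ifelse(e_sig, "eqtl_only",
                 ifelse(g_sig, "gwas_only", "neither"))))
  data.frame(variant = variants, eqtl_p = ep, gwas_p = gp,
             quadrant = quadrant, missing = missing, stringsAsFactors = FALSE)
}

#' Select candidate causal variants
#'
#' A variant is a candidate iff it (i) lies in the LD neighborhood of the
#' lead, (ii) is significant on both the eQTL and GWAS axes (`quadrant ==
#' "both"`), and (iii) overlaps at least one regulatory track. Each candidate
#' lists the tracks it hits.
#'
#' @param neighborhood variant ids from [ld_neighborhood()].
#' @param quadrants data.frame from [classify_2d()].
#' @param tracks list of [interval_track()] objects.
#' @param variants variant table with `id`, `chrom`, `pos` (1-based).
#' @return data.frame with one row per candidate: variant, eqtl_p, gwas_p,
#'   quadrant, tracks_hit (comma-joined track names).
#' @export
select_candidates <- function(neighborhood, quadrants, tracks, variants) {
  if (!length(tracks)) {
    return(data.frame(variant = character(0), eqtl_p = numeric(0),
                      gwas_p = numeric(0), quadrant = character(0),
                      tracks_hit = character(0), stringsAsFactors = FALSE))
  }
  q <- quadrants[match(neighborhood, quadrants$variant), ]
  vt <- variants[match(neighborhood, variants$id), ]
  hit_names <- lapply(seq_along(neighborhood), function(i) {
    nm <- vapply(tracks, function(tr) tr$name, character(1))
    nm[vapply(tracks, function(tr)
      positions_in_track(vt$chrom[i], vt$pos[i], tr), logical(1))]
  })
  keep <- q$quadrant == "both" & lengths(hit_names) > 0
  keep[is.na(keep)] <- FALSE
  data.frame(variant = neighborhood[keep],
             eqtl_p = q$eqtl_p[keep], gwas_p = q$gwas_p[keep],
             quadrant = q$quadrant[keep],
             tracks_hit = vapply(hit_names[keep], paste, character(1),
                                 collapse = ","),
             stringsAsFactors = FALSE)
}
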