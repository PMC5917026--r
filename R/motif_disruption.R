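#' Convert a position count matrix to a log-odds scored PWM
#'
#' `weight[b, j] = ln((count[b, j] + pseudocount * background[b]) /
#' (total_j + pseudocount)) - ln(background[b])`. The pseudocount is
#' distributed over the alphabet by the background weights.
#'
#' @param pcm a [new_pcm()].
#' @param pseudocount total pseudocount per column (> 0 unless every column
#'   total is positive).
#' @param background base composition (A, C, G, T), summing to 1; default
#'   uniform.
#' @return object of class `scored_pwm`: weights (4 x L), background, name.
#' @export
pcm_to_pwm <- function(pcm, pseudocount = 1,
                       background = c(0.25, 0.25, 0.25, 0.25)) {
  if (abs(sum(background) - 1) > 1e-8) stop("background must sum to 1")
  if (pseudocount < 0) stop("pseudocount must be nonnegative")
  totals <- colSums(pcm$counts)
  if (pseudocount == 0 && any(totals == 0))
    stop("zero-total PCM column with zero pseudocount")
  w <- log((pcm$counts + pseudocount * background) /
             rep(totals + pseudocount, each = 4)) - log(background)
  rownames(w) <- c("A", "C", "G", "T")
  structure(list(weights = w, background = background, name = pcm$name,
                 length = ncol(w)),
            class = "scored_pwm")
}

BASE_IDX <- c(A = 1L, C = 2L, G = 3L, T = 4L)
COMP_IDX <- c(4L, 3L, 2L, 1L)  # A<->T, C<->G

#' Score a word against a PWM
#' @param pwm a `scored_pwm`.
#' @param word character string of length equal to the motif.
#' @return log-odds score (sum over positions).
#' @export
score_word <- function(pwm, word) {
  b <- BASE_IDX[strsplit(toupper(word), "")[[1]]]
  if (anyNA(b)) stop("non-ACGT character in word")
  if (length(b) != pwm$length) stop("word length must equal motif length")
  ## stepwise accumulation (not sum()) so partial sums round exactly as in
  ## the score-distribution dynamic programming
  acc <- 0
  for (j in seq_along(b)) acc <- acc + pwm$weights[b[j], j]
  acc
}

reverse_complement_pwm <- function(pwm) {
  w <- pwm$weights[COMP_IDX, rev(seq_len(pwm$length)), drop = FALSE]
  rownames(w) <- c("A", "C", "G", "T")
  structure(list(weights = w, background = pwm$background[COMP_IDX],
                 name = pwm$name, length = pwm$length),
            class = "scored_pwm")
}

#' Tail probability of the PWM score distribution
#'
#' `Pr(score(W) >= threshold)` for a random word W drawn per position from
#' the background. `mode = "dp"` runs dynamic programming over the score
#' distribution discretized at `granularity` log-odds units; `mode = "exact"`
#' propagates exact floating-point scores (merging equal sums), equivalent to
#' exhaustive enumeration, and is intended for motifs of length <= 10.
#' `mode = "auto"` picks exact for short motifs.
#'
#' @param pwm a `scored_pwm`.
#' @param threshold score threshold (finite).
#' @param granularity discretization step for the DP mode (default 0.001).
#' @param mode `"auto"`, `"dp"` or `"exact"`.
#' @return probability in \[0, 1\].
#' @export
score_pvalue <- function(pwm, threshold, granularity = 0.001,
                         mode = c("auto", "dp", "exact")) {
  mode <- match.arg(mode)
  if (!is.finite(threshold)) stop("threshold must be finite")
  if (mode == "auto") mode <- if (pwm$length <= 10) "exact" else "dp"
  bg <- pwm$background
  if (mode == "exact") {
    if (pwm$length > 10) stop("exact mode supports motif length <= 10; use dp")
    dist <- 1
    scores <- 0
    for (j in seq_len(pwm$length)) {
      new_scores <- as.vector(outer(scores, pwm$weights[, j], `+`))
      new_probs <- as.vector(outer(dist, bg, `*`))
      key <- format(new_scores, digits = 17)
      agg <- rowsum(new_probs, key)
      dist <- as.vector(agg)
      scores <- new_scores[match(rownames(agg), key)]
    }
    return(sum(dist[scores >= threshold]))
  }
  ints <- round(pwm$weights / granularity)
  mins <- apply(ints, 2, min)
  p <- 1
  for (j in seq_len(pwm$length)) {
    width <- max(ints[, j]) - mins[j]
    new <- numeric(length(p) + width)
    for (b in 1:4) {
      sh <- ints[b, j] - mins[j]
      idx <- seq_along(p) + sh
      new[idx] <- new[idx] + p * bg[b]
    }
    p <- new
  }
  base <- sum(mins)
  t_int <- ceiling(threshold / granularity - 1e-9)
  keep <- (base + seq_along(p) - 1) >= t_int
  min(1, max(0, sum(p[keep])))
}

#' Best-hit P-values for the two alleles of a variant
#'
#' For each allele window, the best log-odds score over all motif placements
#' that overlap the variant position, on both strands, converted to a tail
#' P-value with [score_pvalue()]. Placements that do not cover the variant
#' are excluded from the search.
#'
#' @param pwm a `scored_pwm` (or [new_pcm()], converted with defaults).
#' @param window_ref,window_alt equal-length sequences identical except at
#'   `variant_offset`; length must be at least `2L - 1` so every placement
#'   overlapping the variant fits.
#' @param variant_offset 1-based position of the variant in the windows.
#' @param granularity,mode passed to [score_pvalue()].
#' @return list with p_ref, p_alt, score_ref, score_alt, best_ref, best_alt
#'   (each a list with offset and strand).
#' @export
best_allele_pvalue <- function(pwm, window_ref, window_alt, variant_offset,
                               granularity = 0.001, mode = "auto") {
  if (inherits(pwm, "pcm")) pwm <- pcm_to_pwm(pwm)
  if (nchar(window_ref) != nchar(window_alt))
    stop("allele windows must have equal length")
  diffs <- which(strsplit(window_ref, "")[[1]] != strsplit(window_alt, "")[[1]])
  if (length(diffs) > 1) stop("allele windows differ at more than one position")
  if (length(diffs) == 1 && diffs != variant_offset)
    stop("allele windows differ away from variant_offset")
  L <- pwm$length
  nw <- nchar(window_ref)
  if (nw < 2 * L - 1)
    stop("window must be at least 2L - 1 bases so all placements overlap the variant")
  rc <- reverse_complement_pwm(pwm)
  best <- function(window) {
    starts <- max(1, variant_offset - L + 1):min(nw - L + 1, variant_offset)
    sc <- -Inf; at <- list(offset = NA, strand = NA)
    for (s in starts) {
      sub <- substr(window, s, s + L - 1)
      for (strand in c("+", "-")) {
        v <- score_word(if (strand == "+") pwm else rc, sub)
        if (v > sc) { sc <- v; at <- list(offset = s, strand = strand) }
      }
    }
    list(score = sc, at = at)
  }
  br <- best(window_ref); ba <- best(window_alt)
  list(p_ref = score_pvalue(pwm, br$score, granularity, mode),
       p_alt = score_pvalue(pwm, ba$score, granularity, mode),
       score_ref = br$score, score_alt = ba$score,
       best_ref = br$at, best_alt = ba$at)
}

#' Call motif gain or loss for a variant
#'
#' Direction is `loss` when `p_ref < p_alt` (the alternate/risk allele
#' weakens binding) and `gain` when `p_alt < p_ref`, subject to the
#' significance and fold-change thresholds. Under the default
#' `rule = "both"`, both alleles' P-values must pass `p_threshold` (the
#' literal reading of the published default); `rule = "either"` requires only
#' the stronger allele to pass, matching common practice for this tool
#' family.
#'
#' @param hit list with `p_ref` and `p_alt` (e.g. from
#'   [best_allele_pvalue()]).
#' @param p_threshold per-allele significance threshold (default 5e-4).
#' @param fc_threshold minimum P-value fold change (default 5).
#' @param rule `"both"` or `"either"`.
#' @return character: `"gain"`, `"loss"` or `"none"`.
#' @export
call_gain_loss <- function(hit, p_threshold = 5e-4, fc_threshold = 5,
                           rule = c("both", "either")) {
  rule <- match.arg(rule)
  p_ref <- hit$p_ref; p_alt <- hit$p_alt
  if (p_ref == p_alt) return("none")
  fc <- max(p_ref, p_alt) / min(p_ref, p_alt)
  sig <- switch(rule,
                both = p_ref < p_threshold && p_alt < p_threshold,
                either = min(p_ref, p_alt) < p_threshold)
  if (!sig || fc <= fc_threshold) return("none")
  if (p_ref < p_alt) "loss" else "gain"
}

#' Screen a variant against a motif library
#'
#' Applies [best_allele_pvalue()] and [call_gain_loss()] per motif; hits are
#' returned sorted by decreasing fold change. Duplicated motifs yield
#' duplicated hits (no deduplication).
#'
#' @param pwm_library list of [new_pcm()] or `scored_pwm` objects.
#' @param window_ref,window_alt,variant_offset as in [best_allele_pvalue()].
#' @param p_threshold,fc_threshold,rule as in [call_gain_loss()].
#' @param granularity,mode as in [score_pvalue()].
#' @return data.frame with motif, p_ref, p_alt, fold_change, direction,
#'   offset/strand of the best hit per allele.
#' @export
scan_variant <- function(pwm_library, window_ref, window_alt, variant_offset,
                         p_threshold = 5e-4, fc_threshold = 5,
                         rule = c("both", "either"),
                         granularity = 0.001, mode = "auto") {
  rule <- match.arg(rule)
  if (!length(pwm_library)) {
    return(data.frame(motif = character(0), p_ref = numeric(0),
                      p_alt = numeric(0), fold_change = numeric(0),
                      direction = character(0), stringsAsFactors = FALSE))
  }
  rows <- lapply(pwm_library, function(m) {
    pwm <- if (inherits(m, "pcm")) pcm_to_pwm(m) else m
    h <- best_allele_pvalue(pwm, window_ref, window_alt, variant_offset,
                            granularity, mode)
    data.frame(motif = pwm$name, p_ref = h$p_ref, p_alt = h$p_alt,
               fold_change = max(h$p_ref, h$p_alt) / min(h$p_ref, h$p_alt),
               direction = call_gain_loss(h, p_threshold, fc_threshold, rule),
               ref_offset = h$best_ref$offset, ref_strand = h$best_ref$strand,
               alt_offset = h$best_alt$offset, alt_strand = h$best_alt$strand,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(-out$fold_change), , drop = FALSE]
}
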