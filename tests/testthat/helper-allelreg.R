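## Shared fixture builders. Everything is generated in code; no binary data.

## Haplotype panel built directly from a 2x2 haplotype count table
## (AB, Ab, aB, ab) for two variants; A/B denote the alternate alleles.
panel_from_counts <- function(ab = 40, aB = 10, Ab = 10, AB = 40) {
  h <- rbind(
    matrix(rep(c(1, 1), AB), ncol = 2, byrow = TRUE),
    matrix(rep(c(1, 0), Ab), ncol = 2, byrow = TRUE),
    matrix(rep(c(0, 1), aB), ncol = 2, byrow = TRUE),
    matrix(rep(c(0, 0), ab), ncol = 2, byrow = TRUE)
  )
  colnames(h) <- c("v1", "v2")
  structure(list(haplotypes = h,
                 variants = data.frame(id = c("v1", "v2"), chrom = "chr5",
                                       pos = c(100L, 200L))),
            class = "haplotype_panel")
}

## Random small panel for property tests
random_panel <- function(n_hap, n_var, seed) {
  set.seed(seed)
  repeat {
    h <- matrix(rbinom(n_hap * n_var, 1, runif(1, 0.2, 0.8)), n_hap, n_var)
    if (all(colMeans(h) > 0 & colMeans(h) < 1)) break
  }
  colnames(h) <- sprintf("v%02d", seq_len(n_var))
  structure(list(haplotypes = h,
                 variants = data.frame(id = colnames(h), chrom = "chr1",
                                       pos = seq_len(n_var) * 10L)),
            class = "haplotype_panel")
}

## Independent first-principles LD from two 0/1 haplotype vectors
brute_force_ld <- function(a, b) {
  pa <- mean(a); pb <- mean(b); pab <- mean(a == 1 & b == 1)
  D <- pab - pa * pb
  dmax <- if (D >= 0) min(pa * (1 - pb), (1 - pa) * pb)
          else min(pa * pb, (1 - pa) * (1 - pb))
  list(D = D, r2 = D^2 / (pa * (1 - pa) * pb * (1 - pb)),
       d_prime = if (D == 0) 0 else abs(D) / dmax)
}

## Read collection built from explicit sequences
reads_from_sequences <- function(seqs) {
  s <- Biostrings::DNAStringSet(seqs)
  names(s) <- sprintf("r%03d", seq_along(seqs))
  structure(list(sequences = s, quality = "I"), class = "read_collection")
}

## Random PCM for motif property tests
random_pcm <- function(L, seed, name = "rand") {
  set.seed(seed)
  counts <- matrix(sample(0:20, 4 * L, replace = TRUE), nrow = 4,
                   dimnames = list(c("A", "C", "G", "T")))
  counts[, colSums(counts) == 0] <- 1
  new_pcm(counts, name = name)
}

## Exhaustive enumeration oracle for the PWM score tail: iterates all 4^L
## words, scoring each with score_word, and returns Pr(score >= threshold)
## under the background.
enumerate_score_tail <- function(pwm, threshold,
                                 background = pwm$background) {
  L <- pwm$length
  grid <- as.matrix(expand.grid(rep(list(1:4), L)))
  probs <- apply(grid, 1, function(b) prod(background[b]))
  scores <- apply(grid, 1, function(b) {
    acc <- 0
    for (j in seq_len(L)) acc <- acc + pwm$weights[b[j], j]
    acc
  })
  sum(probs[scores >= threshold])
}

## Small expression matrix from a value matrix
expr_from_matrix <- function(m) {
  if (is.null(rownames(m))) rownames(m) <- sprintf("g%03d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("S%03d", seq_len(ncol(m)))
  expression_matrix(m, transform = "raw")
}
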