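#' @keywords internal
"_PACKAGE"

## Seed derivation: every stochastic stage draws from a seed derived
## deterministically from the single run seed, so stages can be re-run in
## isolation and no stage reads ambient global random state.
stage_offsets <- c(
  panel = 101L, expression = 211L, reads = 307L, coexpression = 401L,
  gwas = 503L, cohorts = 601L, permutation = 701L
)

#' Derive a per-stage seed from a run seed
#'
#' Deterministic mapping from (seed, stage, index) into the 32-bit signed
#' integer range, used by every simulation stage so that all randomness
#' flows from one documented source.
#'
#' @param seed integer run seed.
#' @param stage stage name, one of `names(allelreg:::stage_offsets)`.
#' @param index optional replicate index (e.g. cohort number).
#' @return a single integer usable with [set.seed()].
#' @export
derive_seed <- function(seed, stage, index = 0L) {
  stage <- match.arg(stage, names(stage_offsets))
  off <- stage_offsets[[stage]]
  ((as.double(seed) %% 1e6) * 1009 + off * 97 + as.double(index) * 131) %% 2147483647
}

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

## P-values are never reported as exactly zero: underflow clamps to the
## smallest positive double and the clamp is flagged on the result.
clamp_p <- function(p) {
  clamped <- is.finite(p) & p < .Machine$double.xmin
  p[clamped] <- .Machine$double.xmin
  structure(p, clamped = any(clamped))
}

#' Transform an expression vector or matrix
#'
#' The three transforms the association stage supports: `"raw"` (FPKM scale,
#' untouched), `"log2"` (log2(x + 1)) and `"rank"` (ranks, average ties).
#' The transform is always an explicit argument downstream, never implicit.
#'
#' @param x numeric vector or matrix on the raw FPKM scale.
#' @param transform one of `"log2"`, `"raw"`, `"rank"`.
#' @return transformed numeric object of the same shape.
#' @export
apply_transform <- function(x, transform = c("log2", "raw", "rank")) {
  transform <- match.arg(transform)
  switch(transform,
    raw = x,
    log2 = log2(x + 1),
    rank = if (is.matrix(x)) t(apply(x, 1, rank)) else rank(x)
  )
}

## Latent Gaussian -> FPKM-like positive scale. The mapping is
## fpkm = 2^(latent + baseline_log2) - 1, so log2(fpkm + 1) recovers the
## latent value (plus a constant) exactly; recorded in output metadata.
latent_to_fpkm <- function(latent, baseline_log2 = 5) {
  pmax(2^(latent + baseline_log2) - 1, 0)
}

fpkm_to_latent <- function(fpkm, baseline_log2 = 5) {
  log2(fpkm + 1) - baseline_log2
}

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_config <- function(msg) stop(structure(
  class = c("allelreg_config_error", "error", "condition"),
  list(message = msg, call = sys.call(-1))
))
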