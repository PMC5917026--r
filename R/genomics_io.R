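#' Expression matrix container
#'
#' Features (exons or genes) by samples on a nonnegative FPKM-like scale,
#' carrying its transform tag and free-form metadata.
#'
#' @param values numeric matrix, features x samples, with unique rownames.
#' @param transform one of `"raw"`, `"log2"`, `"rank"` describing the scale
#'   `values` is currently on.
#' @param meta list of metadata (e.g. the latent-to-FPKM mapping).
#' @return object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, transform = "raw", meta = list()) {
  stopifnot(is.matrix(values), !is.null(rownames(values)), !is.null(colnames(values)))
  if (anyDuplicated(rownames(values))) stop("duplicate feature ids")
  if (transform == "raw" && any(values < 0, na.rm = TRUE))
    stop("negative values in raw (FPKM-scale) expression")
  structure(list(values = values, transform = transform, meta = meta),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d features x %d samples (%s scale)\n",
              nrow(x$values), ncol(x$values), x$transform))
  invisible(x)
}

#' Read and write expression matrices as TSV
#'
#' Features x samples with a `feature` id column and sample-named columns.
#'
#' @param path file path.
#' @param transform transform tag to attach on read.
#' @return [expression_matrix()] for the reader; invisible path for writers.
#' @export
read_expression <- function(path, transform = "raw") {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "feature") stop("expression TSV must start with a 'feature' column")
  if (anyDuplicated(df$feature)) stop("duplicate feature ids in ", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$feature
  expression_matrix(m, transform = transform)
}

#' @rdname read_expression
#' @param x an [expression_matrix()].
#' @export
write_expression <- function(x, path) {
  df <- data.frame(feature = rownames(x$values), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## ---- genotypes -------------------------------------------------------------

risk_allele_code <- function(variants) ifelse(variants$risk_is_alt %||% TRUE, 1L, 0L)

#' Write genotypes as TSV or minimal VCF
#'
#' The TSV dialect stores the variant table followed by per-sample dosages;
#' the VCF dialect is a GT-only subset, phased ("0|1") when the haplotype
#' panel is available, with the risk allele recorded as `RISK=ALT`/`RISK=REF`
#' in INFO.
#'
#' @param genotypes a `genotype_data`.
#' @param path output path.
#' @export
write_genotypes_tsv <- function(genotypes, path) {
  v <- genotypes$variants
  df <- cbind(v[c("id", "chrom", "pos", "ref", "alt", "risk_is_alt")],
              as.data.frame(t(genotypes$dosage), check.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_genotypes_tsv
#' @export
write_vcf_gt <- function(genotypes, path) {
  v <- genotypes$variants
  h <- genotypes$haplotypes
  samples <- rownames(genotypes$dosage)
  gt <- if (!is.null(h)) {
    i <- seq(1, nrow(h), by = 2)
    matrix(paste0(t(h[i, , drop = FALSE]), "|", t(h[i + 1, , drop = FALSE])),
           nrow = nrow(v))
  } else {
    codes <- c("0/0", "0/1", "1/1")
    apply(genotypes$dosage, 1, function(d) ifelse(is.na(d), ".", codes[d + 1L]))
  }
  info <- ifelse(v$risk_is_alt %||% TRUE, "RISK=ALT", "RISK=REF")
  body <- cbind(v$chrom, v$pos, v$id, v$ref, v$alt, ".", "PASS", info, "GT", gt)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##INFO=<ID=RISK,Number=1,Type=String,Description=\"Risk allele\">",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", samples), collapse = "\t")), con)
  utils::write.table(body, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read genotypes from TSV or a GT-only VCF
#'
#' Returns the phased haplotype panel when phase marks are present, plus the
#' per-sample risk-allele dosage matrix (0/1/2, missing allowed). Dosage counts
#' the risk allele: the ALT allele when INFO carries `RISK=ALT` (the default),
#' otherwise REF.
#'
#' @param path input path.
#' @param dialect `"vcf_gt"` or `"tsv"`.
#' @param phased if `TRUE`, unphased genotypes are an error (phase is
#'   required for LD computation).
#' @return a `genotype_data` (with `haplotypes = NULL` when unphased).
#' @export
read_genotypes <- function(path, dialect = c("vcf_gt", "tsv"), phased = FALSE) {
  dialect <- match.arg(dialect)
  if (dialect == "tsv") {
    df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    meta_cols <- c("id", "chrom", "pos", "ref", "alt", "risk_is_alt")
    variants <- df[meta_cols]
    dosage <- t(as.matrix(df[, setdiff(names(df), meta_cols), drop = FALSE]))
    colnames(dosage) <- variants$id
    if (phased) stop("TSV dialect carries dosages only; phase requires vcf_gt")
    return(structure(list(dosage = dosage, haplotypes = NULL, variants = variants),
                     class = "genotype_data"))
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  samples <- colnames(gt)
  ok <- grepl("^([0-9]+|\\.)([|/]([0-9]+|\\.))?$", gt) | is.na(gt)
  if (!all(ok)) {
    bad <- which(!ok, arr.ind = TRUE)[1, ]
    stop(sprintf("malformed GT at variant line %d, sample %s",
                 bad[1], samples[bad[2]]))
  }
  n_alleles <- nchar(gsub("[^|/]", "", gt)) + 1L
  n_alleles[is.na(gt)] <- NA_integer_
  if (length(unique(stats::na.omit(as.vector(n_alleles)))) > 1) {
    bad <- which(n_alleles != 2)[1]
    stop(sprintf("mixed ploidy at variant line %d",
                 (bad - 1L) %% nrow(gt) + 1L))
  }
  has_phase <- grepl("|", gt, fixed = TRUE)
  if (phased && any(!has_phase & !is.na(gt)))
    stop(sprintf("unphased genotype at variant line %d: phase required for LD",
                 which(!has_phase & !is.na(gt), arr.ind = TRUE)[1, 1]))
  a1 <- matrix(suppressWarnings(as.integer(sub("[|/].*$", "", gt))),
               nrow = nrow(gt))
  a2 <- matrix(suppressWarnings(as.integer(sub("^.*[|/]", "", gt))),
               nrow = nrow(gt))
  risk_is_alt <- !grepl("RISK=REF", fix$INFO %||% "")
  risk <- ifelse(risk_is_alt, 1L, 0L)
  d1 <- 1L * (a1 == rep(risk, length.out = length(a1)))
  d2 <- 1L * (a2 == rep(risk, length.out = length(a2)))
  dosage <- t(matrix(d1 + d2, nrow = nrow(gt)))
  variants <- data.frame(id = fix$ID, chrom = fix$CHROM,
                         pos = as.integer(fix$POS), ref = fix$REF,
                         alt = fix$ALT, risk_is_alt = risk_is_alt,
                         stringsAsFactors = FALSE)
  rownames(dosage) <- samples
  colnames(dosage) <- variants$id
  haplotypes <- NULL
  if (all(has_phase | is.na(gt))) {
    haplotypes <- matrix(0L, nrow = 2 * length(samples), ncol = nrow(gt))
    haplotypes[seq(1, nrow(haplotypes), 2), ] <- t(a1)
    haplotypes[seq(2, nrow(haplotypes), 2), ] <- t(a2)
    rownames(haplotypes) <- paste0(rep(samples, each = 2), c("_h1", "_h2"))
    colnames(haplotypes) <- variants$id
  }
  structure(list(dosage = dosage, haplotypes = haplotypes, variants = variants),
            class = "genotype_data")
}

#' Write and read a haplotype panel as TSV
#'
#' One row per haplotype (two consecutive rows per sample), 0/1 entries.
#' @param panel a `haplotype_panel`.
#' @param path file path.
#' @export
write_haplotypes <- function(panel, path) {
  df <- data.frame(haplotype = rownames(panel$haplotypes), panel$haplotypes,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_haplotypes
#' @export
read_haplotypes <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  h <- as.matrix(df[, -1, drop = FALSE])
  rownames(h) <- df$haplotype
  samples <- unique(sub("_h[12]$", "", df$haplotype))
  structure(list(haplotypes = h,
                 variants = data.frame(id = colnames(h)),
                 samples = samples),
            class = "haplotype_panel")
}

## ---- intervals (BED) -------------------------------------------------------

#' Regulatory interval track
#'
#' Intervals follow the BED convention: 0-based start (inclusive), end
#' exclusive. Strand is ignored (histone tracks are unstranded).
#'
#' @param name track label.
#' @param intervals data.frame with columns `chrom`, `start`, `end`.
#' @return object of class `interval_track`.
#' @export
interval_track <- function(name, intervals) {
  stopifnot(all(c("chrom", "start", "end") %in% names(intervals)))
  if (any(intervals$start >= intervals$end)) stop("interval start must be < end")
  if (any(intervals$start < 0)) stop("negative interval start")
  structure(list(name = name,
                 intervals = intervals[order(intervals$chrom, intervals$start), ]),
            class = "interval_track")
}

#' Read a BED file as an interval track
#' @param path BED path (0-based half-open).
#' @param name track label; default the file base name.
#' @export
read_intervals <- function(path, name = sub("\\.bed$", "", basename(path))) {
  df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  names(df)[1:3] <- c("chrom", "start", "end")
  interval_track(name, df[1:3])
}

#' @rdname read_intervals
#' @param track an [interval_track()].
#' @export
write_intervals <- function(track, path) {
  utils::write.table(track$intervals, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

## Coordinate-convention bridge, localized here: a 1-based variant position p
## lies in a 0-based half-open interval (start, end] iff start < p <= end.
#' Test 1-based positions for membership in an interval track
#'
#' @param chrom,pos chromosome labels and 1-based positions (recycled).
#' @param track an [interval_track()].
#' @return logical vector, one per position.
#' @export
positions_in_track <- function(chrom, pos, track) {
  iv <- track$intervals
  vapply(seq_along(pos), function(i) {
    any(iv$chrom == chrom[min(i, length(chrom))] & iv$start < pos[i] & pos[i] <= iv$end)
  }, logical(1))
}

## ---- gene sets (GMT) -------------------------------------------------------

#' Read and write gene sets in GMT format
#'
#' GMT lines are: set name, description, then member gene ids, tab-separated.
#' Reading delegates to [fgsea::gmtPathways()].
#'
#' @param path GMT path.
#' @return named list of character vectors.
#' @export
read_gene_sets <- function(path) fgsea::gmtPathways(path)

#' @rdname read_gene_sets
#' @param sets named list of member-id vectors.
#' @param description description field (recycled).
#' @export
write_gene_sets <- function(sets, path, description = "na") {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, description, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

## ---- position count matrices (JASPAR-style) --------------------------------

#' Position count matrix
#'
#' @param counts 4 x L nonnegative matrix with rows A, C, G, T.
#' @param name motif name.
#' @return object of class `pcm`.
#' @export
new_pcm <- function(counts, name = "motif") {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4) stop("PCM must have 4 rows (A, C, G, T)")
  rn <- rownames(counts) %||% c("A", "C", "G", "T")
  if (!identical(rn, c("A", "C", "G", "T")))
    stop("PCM rows must be ordered A, C, G, T; non-ACGT alphabet not supported")
  if (any(counts < 0)) stop("negative counts in PCM")
  rownames(counts) <- c("A", "C", "G", "T")
  structure(list(name = name, counts = counts, length = ncol(counts)),
            class = "pcm")
}

#' Read/write JASPAR-style position count matrices
#'
#' Text format: a `>name` header followed by four rows `A [ n n ... ]`,
#' `C [...]`, `G [...]`, `T [...]`, in that order. Files may hold several
#' matrices; [read_pcm()] returns the first, [read_pcm_library()] all.
#'
#' @param path file path.
#' @export
read_pcm <- function(path) read_pcm_library(path)[[1]]

#' @rdname read_pcm
#' @export
read_pcm_library <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  starts <- grep("^>", lines)
  if (!length(starts)) stop("no '>' motif headers in ", path)
  out <- lapply(seq_along(starts), function(i) {
    nm <- trimws(sub("^>\\s*", "", lines[starts[i]]))
    rows <- lines[starts[i] + 1:4]
    bases <- toupper(substr(trimws(rows), 1, 1))
    if (!identical(bases, c("A", "C", "G", "T")))
      stop("PCM rows must be A, C, G, T in order (motif ", nm, ")")
    parsed <- lapply(rows, function(r) {
      nums <- gsub("^[ACGTacgt]\\s*\\[?|\\]\\s*$", "", trimws(r))
      as.numeric(strsplit(trimws(nums), "\\s+")[[1]])
    })
    if (length(unique(lengths(parsed))) != 1)
      stop("ragged PCM rows (motif ", nm, ")")
    counts <- do.call(rbind, parsed)
    rownames(counts) <- c("A", "C", "G", "T")
    new_pcm(counts, name = nm)
  })
  names(out) <- vapply(out, function(p) p$name, character(1))
  out
}

#' @rdname read_pcm
#' @param pcm a [new_pcm()] object or list of them.
#' @export
write_pcm <- function(pcm, path) {
  if (inherits(pcm, "pcm")) pcm <- list(pcm)
  con <- file(path, "w"); on.exit(close(con))
  for (p in pcm) {
    writeLines(paste0(">", p$name), con)
    for (b in c("A", "C", "G", "T"))
      writeLines(sprintf("%s [ %s ]", b, paste(p$counts[b, ], collapse = " ")), con)
  }
  invisible(path)
}

## ---- reads (FASTQ) ---------------------------------------------------------

#' Read and write sequencing reads as FASTQ
#'
#' Qualities are constant-"I" placeholders; the allele-counting stage never
#' consults them.
#'
#' @param path FASTQ path.
#' @return a `read_collection`.
#' @export
read_reads <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path, format = "fastq")
  structure(list(sequences = seqs, quality = "I"), class = "read_collection")
}

#' @rdname read_reads
#' @param reads a `read_collection`.
#' @export
write_reads <- function(reads, path) {
  q <- Biostrings::BStringSet(strrep(reads$quality,
                                     Biostrings::width(reads$sequences)))
  Biostrings::writeXStringSet(reads$sequences, path, format = "fastq",
                              qualities = q)
  invisible(path)
}

## ---- config (YAML) ---------------------------------------------------------

#' Read and write a simulation configuration as YAML
#' @param config a [simulation_config()].
#' @param path YAML path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$n_variants <- NULL
  raw$ld_block_spec <- lapply(raw$ld_block_spec, function(b)
    ld_block(b$n_variants, b$n_founders, unlist(b$founder_freqs)))
  raw$beta_per_exon <- unlist(raw$beta_per_exon)
  raw$cohort_n <- unlist(raw$cohort_n)
  if (!is.null(raw$noise_sd)) raw$noise_sd <- unlist(raw$noise_sd)
  do.call(simulation_config, raw)
}
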