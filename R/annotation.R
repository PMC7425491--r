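# Transcript models and annotation parsing (refGene flat TSV and GTF).
#
# All coordinates are stored 0-based half-open on the forward strand,
# regardless of the source dialect. Exons are sorted in genomic order and
# non-overlapping; the CDS, when present, is the genomic span
# [cds_start, cds_end) and must lie inside the exon union.

#' Construct a transcript model
#'
#' @param transcript_id,gene_id Identifiers.
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exon_starts,exon_ends Integer vectors of 0-based half-open exon
#'   coordinates, sorted in genomic order.
#' @param cds_start,cds_end Genomic CDS span (0-based half-open), or `NA` for
#'   a non-coding transcript.
#' @return An object of class `TranscriptModel`.
#' @export
transcript_model <- function(transcript_id, gene_id, chrom, strand,
                             exon_starts, exon_ends,
                             cds_start = NA_integer_, cds_end = NA_integer_) {
  exon_starts <- as.integer(exon_starts)
  exon_ends <- as.integer(exon_ends)
  if (length(exon_starts) != length(exon_ends) || length(exon_starts) == 0L)
    stopf("transcript %s: exon start/end vectors must be non-empty and equal length",
          transcript_id)
  if (any(exon_ends <= exon_starts))
    stopf("transcript %s: empty or inverted exon", transcript_id)
  if (is.unsorted(exon_starts, strictly = TRUE) ||
      any(exon_starts[-1] < exon_ends[-length(exon_ends)]))
    stopf("transcript %s: exons must be sorted and non-overlapping", transcript_id)
  if (!strand %in% c("+", "-"))
    stopf("transcript %s: strand must be + or -", transcript_id)
  m <- list(transcript_id = transcript_id, gene_id = gene_id,
            chrom = chrom, strand = strand,
            exon_starts = exon_starts, exon_ends = exon_ends,
            cds_start = as.integer(cds_start), cds_end = as.integer(cds_end))
  class(m) <- "TranscriptModel"
  m
}

has_cds <- function(model) {
  !is.na(model$cds_start) && !is.na(model$cds_end) &&
    model$cds_end > model$cds_start
}

exonic_length <- function(model) sum(model$exon_ends - model$exon_starts)

tx_start <- function(model) model$exon_starts[1L]
tx_end <- function(model) model$exon_ends[length(model$exon_ends)]

# Is every base of [start,end) inside the exon union?
span_in_exons <- function(model, start, end) {
  keep <- pmax(model$exon_starts, start) < pmin(model$exon_ends, end)
  covered <- sum(pmin(model$exon_ends[keep], end) - pmax(model$exon_starts[keep], start))
  covered == (end - start)
}

# Introns implied by consecutive exons, as a data.frame of junction spans.
model_introns <- function(model) {
  n <- length(model$exon_starts)
  if (n < 2L)
    return(data.frame(chrom = character(), strand = character(),
                      intron_start = integer(), intron_end = integer(),
                      stringsAsFactors = FALSE))
  data.frame(chrom = model$chrom, strand = model$strand,
             intron_start = model$exon_ends[-n],
             intron_end = model$exon_starts[-1L],
             stringsAsFactors = FALSE)
}

#' Load transcript annotation
#'
#' Reads either a UCSC refGene-dialect flat TSV (with or without the leading
#' `bin` column) or a GTF file, returning one [transcript_model()] per
#' transcript with coordinates normalized to 0-based half-open. Transcripts
#' whose CDS falls outside their exon union are skipped with a warning;
#' `cdsStart == cdsEnd` marks a non-coding transcript.
#'
#' @param path Annotation file. Format is taken from the extension
#'   (`.gtf`/`.gff` vs anything else) unless `format` is given.
#' @param format `"auto"`, `"refgene"` or `"gtf"`.
#' @return List of `TranscriptModel` objects.
#' @export
load_annotation <- function(path, format = c("auto", "refgene", "gtf")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.g[tf]f[0-9]?(\\.gz)?$", path, ignore.case = TRUE))
      "gtf" else "refgene"
  }
  models <- switch(format,
                   refgene = parse_refgene(path),
                   gtf = parse_gtf(path))
  bad <- vapply(models, function(m) {
    has_cds(m) && !span_in_exons(m, m$cds_start, m$cds_start + 1L) ||
      has_cds(m) && !span_in_exons(m, m$cds_end - 1L, m$cds_end)
  }, logical(1))
  if (any(bad)) {
    warnf("skipping %d transcript(s) with CDS outside the exon union: %s",
          sum(bad),
          paste(vapply(models[bad], `[[`, "", "transcript_id"), collapse = ", "))
    models <- models[!bad]
  }
  models
}

parse_int_list <- function(s) {
  as.integer(strsplit(sub(",$", "", s), ",", fixed = TRUE)[[1]])
}

parse_refgene <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  models <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    # UCSC refGene has 16 columns with a leading integer bin; tolerate the
    # 15-column variant without it.
    if (length(f) == 16L) f <- f[-1L]
    if (length(f) < 11L)
      stopf("%s line %d: expected a refGene row (>=11 tab fields), got %d",
            path, i, length(f))
    exon_starts <- parse_int_list(f[9])
    exon_ends <- parse_int_list(f[10])
    n_exp <- suppressWarnings(as.integer(f[8]))
    cds_start <- suppressWarnings(as.integer(f[6]))
    cds_end <- suppressWarnings(as.integer(f[7]))
    if (anyNA(c(exon_starts, exon_ends, n_exp, cds_start, cds_end)))
      stopf("%s line %d: non-integer coordinate field", path, i)
    if (length(exon_starts) != n_exp || length(exon_ends) != n_exp)
      stopf("%s line %d: exonCount disagrees with exon lists", path, i)
    if (cds_start == cds_end) cds_start <- cds_end <- NA_integer_
    models[[i]] <- transcript_model(
      transcript_id = f[1], gene_id = if (length(f) >= 12L) f[12] else f[1],
      chrom = f[2], strand = f[3],
      exon_starts = exon_starts, exon_ends = exon_ends,
      cds_start = cds_start, cds_end = cds_end)
  }
  models
}

parse_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  meta <- S4Vectors::mcols(gr)
  type <- as.character(meta$type)
  txid <- as.character(meta$transcript_id)
  gid <- if ("gene_id" %in% names(meta)) as.character(meta$gene_id) else txid
  keep <- type %in% c("exon", "CDS") & !is.na(txid)
  gr <- gr[keep]; type <- type[keep]; txid <- txid[keep]; gid <- gid[keep]
  models <- list()
  for (tx in unique(txid)) {
    sel <- txid == tx
    ex <- gr[sel & type == "exon"]
    if (length(ex) == 0L) next
    o <- order(BiocGenerics::start(ex))
    ex <- ex[o]
    cds <- gr[sel & type == "CDS"]
    cds_start <- cds_end <- NA_integer_
    if (length(cds) > 0L) {
      cds_start <- min(BiocGenerics::start(cds)) - 1L   # GTF is 1-based inclusive
      cds_end <- max(BiocGenerics::end(cds))
    }
    models[[tx]] <- transcript_model(
      transcript_id = tx, gene_id = gid[sel][1],
      chrom = as.character(GenomeInfoDb::seqnames(ex))[1],
      strand = as.character(BiocGenerics::strand(ex))[1],
      exon_starts = BiocGenerics::start(ex) - 1L,
      exon_ends = BiocGenerics::end(ex),
      cds_start = cds_start, cds_end = cds_end)
  }
  unname(models)
}

#' Write transcript models as a refGene-dialect flat TSV
#'
#' Inverse of the refGene reader; used by the fixture generator and for the
#' annotation round-trip guarantee.
#'
#' @param models List of `TranscriptModel`.
#' @param path Output path.
#' @export
write_refgene <- function(models, path) {
  rows <- vapply(models, function(m) {
    cds_s <- if (has_cds(m)) m$cds_start else tx_start(m)
    cds_e <- if (has_cds(m)) m$cds_end else tx_start(m)
    paste(c("0", m$transcript_id, m$chrom, m$strand,
            tx_start(m), tx_end(m), cds_s, cds_e,
            length(m$exon_starts),
            paste0(paste(m$exon_starts, collapse = ","), ","),
            paste0(paste(m$exon_ends, collapse = ","), ","),
            "0", m$gene_id, "cmpl", "cmpl",
            paste0(paste(rep(0L, length(m$exon_starts)), collapse = ","), ",")),
          collapse = "\t")
  }, character(1))
  writeLines(rows, path)
}

# Lightweight interval index over a model list: one row per transcript.
index_models <- function(models) {
  data.frame(
    i = seq_along(models),
    transcript_id = vapply(models, `[[`, "", "transcript_id"),
    chrom = vapply(models, `[[`, "", "chrom"),
    strand = vapply(models, `[[`, "", "strand"),
    tx_start = vapply(models, tx_start, integer(1)),
    tx_end = vapply(models, tx_end, integer(1)),
    stringsAsFactors = FALSE)
}
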