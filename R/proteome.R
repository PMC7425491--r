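# Reference proteome extraction and the normal peptide index.

#' Extract the reference proteome
#'
#' Translates the spliced CDS of every coding transcript, strand-aware,
#' from the annotated start codon to the first stop codon. Codons containing
#' ambiguous bases translate to `X`.
#'
#' @param models List of `TranscriptModel`.
#' @param genome `DNAStringSet` from [read_genome()].
#' @return Named character vector of protein sequences (names are
#'   transcript ids); non-coding transcripts are omitted.
#' @export
extract_reference_proteome <- function(models, genome) {
  coding <- Filter(has_cds, models)
  prots <- vapply(coding, function(m) {
    nt <- spliced_cds_sequence(m$exon_starts, m$exon_ends, m$cds_start,
                               m$cds_end, m$chrom, m$strand, genome)
    translate_cds(nt, what = paste0("CDS of ", m$transcript_id))$protein
  }, character(1))
  names(prots) <- vapply(coding, `[[`, "", "transcript_id")
  prots
}

# Concatenate the exon/CDS intersection in genomic order and orient 5'->3'.
spliced_cds_sequence <- function(exon_starts, exon_ends, cds_start, cds_end,
                                 chrom, strand, genome) {
  ps <- pmax(exon_starts, cds_start)
  pe <- pmin(exon_ends, cds_end)
  keep <- ps < pe
  if (!any(keep)) stopf("CDS does not intersect the exon chain")
  spliced_sequence(genome, chrom, strand, ps[keep], pe[keep])
}

#' Build the normal peptide index
#'
#' Exact-membership k-mer sets (default k = 8..11) over the normal proteome,
#' retaining the full protein sequences for nearest-normal-peptide search.
#' k-mers containing non-canonical residues are not indexed.
#'
#' @param normal_proteins Character vector of protein sequences.
#' @param ks Integer vector of peptide lengths to index.
#' @return A `NormalPeptideIndex`.
#' @export
build_normal_peptide_index <- function(normal_proteins, ks = 8:11) {
  normal_proteins <- unname(normal_proteins[nchar(normal_proteins) > 0L])
  if (length(normal_proteins) == 0L) stopf("no normal proteins supplied")
  canon <- sprintf("^[%s]+$", paste(AA20, collapse = ""))
  kmer_sets <- lapply(ks, function(k) {
    km <- unlist(lapply(normal_proteins, function(p) {
      n <- nchar(p)
      if (n < k) return(character(0))
      substring(p, 1:(n - k + 1L), k:n)
    }), use.names = FALSE)
    km <- unique(km)
    radix_sort(km[grepl(canon, km)])
  })
  names(kmer_sets) <- as.character(ks)
  idx <- list(ks = as.integer(ks), kmer_sets = kmer_sets,
              proteins = normal_proteins)
  class(idx) <- "NormalPeptideIndex"
  idx
}

#' Exact k-mer membership in the normal peptide index
#'
#' @param index A `NormalPeptideIndex`.
#' @param peptides Character vector (lengths must all be indexed ks).
#' @return Logical vector: is each peptide a substring of a normal protein?
#' @export
index_has_peptide <- function(index, peptides) {
  k <- nchar(peptides)
  bad <- !k %in% index$ks
  if (any(bad))
    stopf("peptide length(s) %s not indexed", paste(unique(k[bad]), collapse = ","))
  out <- logical(length(peptides))
  for (kk in unique(k)) {
    sel <- k == kk
    out[sel] <- peptides[sel] %in% index$kmer_sets[[as.character(kk)]]
  }
  out
}

#' @export
print.NormalPeptideIndex <- function(x, ...) {
  cat(sprintf("NormalPeptideIndex: %d proteins; k-mers: %s\n",
              length(x$proteins),
              paste(sprintf("%s=%d", names(x$kmer_sets),
                            vapply(x$kmer_sets, length, integer(1))),
                    collapse = ", ")))
  invisible(x)
}

#' Write / read the normal peptide index cache
#'
#' The cache stores the protein sequences and the indexed k list under a
#' format-version header; k-mer sets are rebuilt on read.
#'
#' @param index A `NormalPeptideIndex`.
#' @param path File path.
#' @export
write_normal_peptide_index <- function(index, path) {
  writeLines(c("#spliceneo-peptide-index\tv1",
               paste0("#ks\t", paste(index$ks, collapse = ",")),
               index$proteins), path)
  invisible(path)
}

#' @rdname write_normal_peptide_index
#' @export
read_normal_peptide_index <- function(path) {
  lines <- readLines(path)
  if (!startsWith(lines[1], "#spliceneo-peptide-index"))
    stopf("%s: not a spliceneo peptide index cache", path)
  ks <- as.integer(strsplit(strsplit(lines[2], "\t")[[1]][2], ",")[[1]])
  build_normal_peptide_index(lines[-(1:2)], ks = ks)
}

#' Assemble the normal proteome
#'
#' The normal proteome is the reference proteome plus, optionally, the
#' proteins produced by running the junction-insertion and translation
#' machinery on every panel-supported normal junction that the annotation
#' does not already explain. Those proteins are what a normal cell would
#' plausibly make from commonly observed non-annotated splicing, so their
#' peptides must not be called tumor-specific.
#'
#' @param models List of `TranscriptModel`.
#' @param genome Genome `DNAStringSet`.
#' @param db Optional `NormalJunctionDB` whose panel-only junctions are
#'   translated into additional normal proteins.
#' @param include_junction_proteins Include the panel-junction-derived
#'   proteins (default `TRUE`).
#' @param min_protein_len Shortest retained protein (strict `>`).
#' @return Named character vector of normal protein sequences.
#' @export
normal_proteome <- function(models, genome, db = NULL,
                            include_junction_proteins = TRUE,
                            min_protein_len = 30L) {
  prots <- extract_reference_proteome(models, genome)
  if (include_junction_proteins && !is.null(db)) {
    midx <- index_models(models)
    extra <- character(0)
    for (key in panel_only_keys(db)) {
      f <- strsplit(key, ":", fixed = TRUE)[[1]]
      j <- list(chrom = f[1], strand = f[2],
                intron_start = as.integer(f[3]), intron_end = as.integer(f[4]))
      pl <- map_junction_to_isoforms(j, models, midx)
      if (nrow(pl) == 0L || any(pl$tag == 0L)) next
      pl <- pl[pl$tag == min(pl$tag), , drop = FALSE]
      for (r in seq_len(nrow(pl))) {
        iso <- insert_junction(models[[pl$model_i[r]]], j, pl$tag[r])
        if (is_rejection(iso)) next
        pr <- translate_isoform(iso, genome, min_protein_len = min_protein_len)
        if (is_rejection(pr)) next
        extra[pr$isoform_id] <- pr$sequence
      }
    }
    prots <- c(prots, extra)
  }
  prots
}
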