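# Translation of novel isoforms, peptide chopping, normal-proteome
# subtraction and nearest-normal-peptide search.

#' Translate a novel isoform in the annotated reading frame
#'
#' One-frame translation: the spliced transcript is assembled 5'->3'
#' (strand-aware) and translated from the inherited start-codon position, in
#' its original frame, to the first stop codon (`frame_status =
#' "stop_found"`) or the transcript end (`"ran_off_end"`). Insertions that
#' excise the start codon are rejected (`"start_lost"`); proteins not
#' strictly longer than `min_protein_len` are rejected (`"short_protein"`).
#'
#' @param iso A `NovelIsoform` from [insert_junction()].
#' @param genome Genome `DNAStringSet`.
#' @param min_protein_len Strict lower length bound (default 30).
#' @return A `ProteinRecord` (list with `sequence`, `isoform_id`,
#'   `frame_status`) or a rejection marker.
#' @export
translate_isoform <- function(iso, genome, min_protein_len = 30L) {
  # genomic position of the first base of the start codon, in reading order
  start_base <- if (iso$strand == "-") iso$cds_end - 1L else iso$cds_start
  off <- transcript_offset(iso$exon_starts, iso$exon_ends, iso$strand, start_base)
  if (is.na(off)) return(rejection("start_lost"))
  mrna <- spliced_sequence(genome, iso$chrom, iso$strand,
                           iso$exon_starts, iso$exon_ends)
  tr <- translate_cds(substr(mrna, off + 1L, nchar(mrna)), warn_frame = FALSE)
  if (nchar(tr$protein) <= min_protein_len) return(rejection("short_protein"))
  rec <- list(sequence = tr$protein, isoform_id = iso$id,
              frame_status = tr$frame_status)
  class(rec) <- "ProteinRecord"
  rec
}

# 0-based offset of a genomic position within the spliced transcript
# (transcript orientation), or NA if the position is not exonic.
transcript_offset <- function(exon_starts, exon_ends, strand, pos) {
  i <- which(exon_starts <= pos & pos < exon_ends)
  if (length(i) != 1L) return(NA_integer_)
  if (strand == "-") {
    later <- exon_starts > pos
    sum(exon_ends[later] - exon_starts[later]) + (exon_ends[i] - 1L - pos)
  } else {
    earlier <- exon_ends <= pos
    sum(exon_ends[earlier] - exon_starts[earlier]) + (pos - exon_starts[i])
  }
}

#' Chop a protein into k-mers
#'
#' @param protein Protein sequence (character scalar) or `ProteinRecord`.
#' @param ks Integer vector of peptide lengths (default 8:11).
#' @return data.frame with `peptide`, `k`, `start` (0-based offset in the
#'   protein); `max(0, len - k + 1)` rows per k.
#' @export
chop_peptides <- function(protein, ks = 8:11) {
  if (inherits(protein, "ProteinRecord")) protein <- protein$sequence
  n <- nchar(protein)
  out <- lapply(sort(as.integer(ks)), function(k) {
    if (n < k) return(NULL)
    data.frame(peptide = substring(protein, 1:(n - k + 1L), k:n),
               k = k, start = 0:(n - k), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(peptide = character(), k = integer(), start = integer(),
                      stringsAsFactors = FALSE)
  out
}

#' Subtract normal peptides from candidate k-mers
#'
#' Removes k-mers containing non-canonical residues (untestable by binding
#' predictors) and k-mers occurring verbatim in the normal peptide index,
#' then deduplicates survivors by sequence, merging provenance.
#'
#' @param kmers data.frame with columns `peptide` plus optional provenance
#'   columns `protein_id` and `junction_key`.
#' @param index `NormalPeptideIndex`.
#' @return data.frame of unique candidates: `peptide`, `k`, `protein_ids`,
#'   `junction_keys` (comma-joined sorted provenance), sorted by peptide.
#' @export
filter_normal_peptides <- function(kmers, index) {
  if (nrow(kmers) == 0L)
    return(data.frame(peptide = character(), k = integer(),
                      protein_ids = character(), junction_keys = character(),
                      stringsAsFactors = FALSE))
  canon <- sprintf("^[%s]+$", paste(AA20, collapse = ""))
  kmers <- kmers[grepl(canon, kmers$peptide), , drop = FALSE]
  if (nrow(kmers) > 0L)
    kmers <- kmers[!index_has_peptide(index, kmers$peptide), , drop = FALSE]
  if (is.null(kmers$protein_id)) kmers$protein_id <- ""
  if (is.null(kmers$junction_key)) kmers$junction_key <- ""
  peps <- radix_sort(unique(kmers$peptide))
  merged <- function(col) vapply(peps, function(p)
    paste(radix_sort(unique(kmers[[col]][kmers$peptide == p])), collapse = ","),
    character(1))
  data.frame(peptide = peps, k = nchar(peps),
             protein_ids = merged("protein_id"),
             junction_keys = merged("junction_key"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Nearest normal peptide and mismatch count
#'
#' Scans every equal-length window of every normal protein and returns the
#' window with the smallest Hamming distance to the candidate (ties broken
#' by lexicographically smallest window, C locale). The candidate must not
#' itself be a normal peptide, so the distance `M` is at least 1.
#'
#' @param candidate Candidate peptide (not present in the index).
#' @param index `NormalPeptideIndex`.
#' @return List with `peptide` (the nearest normal window) and `M`
#'   (mismatch count).
#' @export
nearest_normal_peptide <- function(candidate, index) {
  k <- nchar(candidate)
  if (index_has_peptide(index, candidate))
    stopf("candidate %s is itself a normal peptide", candidate)
  windows <- unlist(lapply(index$proteins, function(p) {
    n <- nchar(p)
    if (n < k) return(character(0))
    substring(p, 1:(n - k + 1L), k:n)
  }), use.names = FALSE)
  if (length(windows) == 0L)
    stopf("no normal protein of length >= %d for nearest-peptide search", k)
  cand_chars <- strsplit(candidate, "", fixed = TRUE)[[1]]
  dist <- integer(length(windows))
  for (i in seq_len(k))
    dist <- dist + (substr(windows, i, i) != cand_chars[i])
  m <- min(dist)
  best <- radix_sort(unique(windows[dist == m]))[1]
  list(peptide = best, M = as.integer(m))
}

# Vectorized wrapper: one row per candidate.
nearest_normal_batch <- function(candidates, index) {
  res <- lapply(candidates, nearest_normal_peptide, index = index)
  data.frame(peptide = candidates,
             normal_peptide = vapply(res, `[[`, "", "peptide"),
             M = vapply(res, `[[`, integer(1), "M"),
             stringsAsFactors = FALSE)
}
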