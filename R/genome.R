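# Genome sequence access (FASTA-backed, strand-aware extraction).

#' Read a genome FASTA
#'
#' @param path FASTA file. Sequence names are truncated at the first
#'   whitespace.
#' @return A named `DNAStringSet` (uppercase).
#' @export
read_genome <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

#' Extract a genomic interval
#'
#' Returns the `end - start` bases of `[start, end)` (0-based half-open) on
#' the forward strand, reverse-complemented when `strand == "-"`.
#'
#' @param genome A `DNAStringSet` from [read_genome()].
#' @param chrom Chromosome name.
#' @param start,end 0-based half-open interval.
#' @param strand `"+"` or `"-"`.
#' @return Uppercase character scalar of length `end - start`.
#' @export
genome_slice <- function(genome, chrom, start, end, strand = "+") {
  if (!chrom %in% names(genome)) stopf("chromosome %s not in genome", chrom)
  if (end <= start) stopf("empty interval [%d,%d)", start, end)
  s <- Biostrings::subseq(genome[[chrom]], start = start + 1L, end = end)
  if (strand == "-") s <- Biostrings::reverseComplement(s)
  toupper(as.character(s))
}

# Spliced sequence of an exon chain, 5'->3' in transcript orientation.
spliced_sequence <- function(genome, chrom, strand, exon_starts, exon_ends) {
  parts <- vapply(seq_along(exon_starts), function(i)
    genome_slice(genome, chrom, exon_starts[i], exon_ends[i], "+"), character(1))
  s <- paste(parts, collapse = "")
  if (strand == "-")
    s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  s
}

# Translate a CDS nucleotide string: codons after the first in-frame stop are
# discarded; codons containing N translate to X. Returns list(protein,
# frame_status) where frame_status records whether a stop was reached.
translate_cds <- function(nt, warn_frame = TRUE, what = "CDS") {
  n <- nchar(nt)
  if (n %% 3L != 0L) {
    if (warn_frame)
      warnf("%s length %d not divisible by 3; translating %d codons",
            what, n, n %/% 3L)
    nt <- substr(nt, 1L, (n %/% 3L) * 3L)
  }
  if (nchar(nt) == 0L) return(list(protein = "", frame_status = "ran_off_end"))
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(nt),
                                           if.fuzzy.codon = "X"))
  stop_at <- regexpr("*", aa, fixed = TRUE)
  if (stop_at > 0L)
    list(protein = substr(aa, 1L, stop_at - 1L), frame_status = "stop_found")
  else
    list(protein = aa, frame_status = "ran_off_end")
}
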