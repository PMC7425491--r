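# Small hand-built fixtures shared across tests.

# In-memory genome from named nucleotide strings.
toy_genome <- function(...) {
  seqs <- list(...)
  g <- Biostrings::DNAStringSet(unlist(seqs))
  names(g) <- names(seqs)
  g
}

# Independent naive translator: string slicing + the standard codon table.
naive_translate <- function(nt) {
  code <- Biostrings::GENETIC_CODE
  n <- (nchar(nt) %/% 3L) * 3L
  out <- character(0)
  for (i in seq(1L, n, by = 3L)) {
    codon <- substr(nt, i, i + 2L)
    aa <- if (grepl("[^ACGT]", codon)) "X" else unname(code[codon])
    if (identical(aa, "*")) break
    out <- c(out, aa)
  }
  paste(out, collapse = "")
}

reverse_complement_chr <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "", fixed = TRUE)[[1]]),
        collapse = "")
}

# A plus-strand three-exon coding gene on a deterministic random background;
# CDS is stop-free with a terminal stop. Returns genome, model and the CDS
# mRNA string.
toy_three_exon_gene <- function(seed = 42) {
  set.seed(seed)
  nonstop <- setdiff(as.vector(outer(outer(c("A","C","G","T"), c("A","C","G","T"),
                                           paste0), c("A","C","G","T"), paste0)),
                     c("TAA", "TAG", "TGA"))
  # exons [100,200) [300,390) [500,620); CDS [131,560): 69 + 90 + 60 = 219 nt
  # = 73 codons; exon 2 is fully coding, 90 nt, and codon-aligned (the CDS
  # portion of exon 1 is a multiple of 3), so skipping it preserves frame
  cds <- paste(c("ATG", sample(nonstop, 71, replace = TRUE), "TAA"), collapse = "")
  chars <- sample(c("A", "C", "G", "T"), 700, replace = TRUE)
  model <- transcript_model("toyTx", "toyGene", "chrT", "+",
                            exon_starts = c(100L, 300L, 500L),
                            exon_ends = c(200L, 390L, 620L),
                            cds_start = 131L, cds_end = 560L)
  segs <- rbind(c(131, 200), c(300, 390), c(500, 560))
  off <- 0L
  for (i in seq_len(nrow(segs))) {
    len <- segs[i, 2] - segs[i, 1]
    chars[(segs[i, 1] + 1):segs[i, 2]] <-
      strsplit(substr(cds, off + 1L, off + len), "")[[1]]
    off <- off + len
  }
  list(genome = toy_genome(chrT = paste(chars, collapse = "")),
       model = model, cds = cds)
}

write_tmp <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

default_fixture_config <- function(fx, out_dir = NULL, ...) {
  m <- fx$manifest
  spliceneo_config(
    genome = fx$paths$genome, annotation = fx$paths$annotation,
    junctions = fx$paths$junctions, panel = fx$paths$panel,
    counts = fx$paths$counts, total_mapped_reads = m$total_mapped_reads,
    epitopes = fx$paths$epitopes, hla = unlist(m$alleles),
    out_dir = out_dir, ...)
}
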