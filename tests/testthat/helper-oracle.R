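# Independent brute-force oracle for the end-to-end candidate-peptide set.
#
# Reimplements splicing, translation and k-mer subtraction from first
# principles (string slicing + the standard codon table), driven only by
# the fixture files and the manifest's junction classes. Deliberately
# shares no code with the package's isoform/translation path.

oracle_read_fasta <- function(path) {
  lines <- readLines(path)
  idx <- grep("^>", lines)
  seqs <- vapply(seq_along(idx), function(i) {
    from <- idx[i] + 1L
    to <- if (i < length(idx)) idx[i + 1L] - 1L else length(lines)
    paste(lines[from:to], collapse = "")
  }, character(1))
  names(seqs) <- sub("^>", "", sub("\\s.*", "", lines[idx]))
  toupper(seqs)
}

oracle_parse_refgene <- function(path) {
  rows <- strsplit(readLines(path), "\t", fixed = TRUE)
  lapply(rows, function(f) {
    if (length(f) == 16L) f <- f[-1L]
    list(tx = f[1], chrom = f[2], strand = f[3],
         es = as.integer(strsplit(sub(",$", "", f[9]), ",")[[1]]),
         ee = as.integer(strsplit(sub(",$", "", f[10]), ",")[[1]]),
         cds_s = as.integer(f[6]), cds_e = as.integer(f[7]))
  })
}

oracle_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "", fixed = TRUE)[[1]]),
        collapse = "")
}

# translate from a 0-based transcript offset to the first stop
oracle_translate_from <- function(mrna, off) {
  code <- Biostrings::GENETIC_CODE
  aa <- character(0)
  i <- off + 1L
  while (i + 2L <= nchar(mrna)) {
    codon <- substr(mrna, i, i + 2L)
    a <- if (grepl("[^ACGT]", codon)) "X" else unname(code[codon])
    if (identical(a, "*")) break
    aa <- c(aa, a)
    i <- i + 3L
  }
  paste(aa, collapse = "")
}

# novel exon chain for one manifest junction class
oracle_modified_exons <- function(es, ee, a, b, class) {
  if (class == "tag1_skip") {
    keep <- !(es >= a & ee <= b)
    list(es = es[keep], ee = ee[keep])
  } else if (class == "tag2_shift") {
    if (a %in% ee) {            # acceptor side is novel: move an exon start to b
      i <- which(es < b & b < ee)
      es[i] <- b
    } else {                    # donor side is novel: move an exon end to a
      i <- which(es < a & a < ee)
      ee[i] <- a
    }
    keep <- !(es >= a & ee <= b)
    list(es = es[keep], ee = ee[keep])
  } else if (class == "tag3_split") {
    i <- which(es < a & b < ee)
    list(es = sort(c(es, b)), ee = sort(c(ee, a)))
  } else stop("unknown junction class: ", class)
}

oracle_protein <- function(chrom_seq, tx, es, ee, strand, cds_s, cds_e) {
  mrna <- paste(vapply(seq_along(es), function(i)
    substr(chrom_seq, es[i] + 1L, ee[i]), character(1)), collapse = "")
  if (strand == "-") mrna <- oracle_revcomp(mrna)
  start_base <- if (strand == "-") cds_e - 1L else cds_s
  hit <- which(es <= start_base & start_base < ee)
  if (length(hit) != 1L) return(NULL)     # start codon excised
  off <- if (strand == "-")
    sum((ee - es)[es > start_base]) + (ee[hit] - 1L - start_base)
  else sum((ee - es)[ee <= start_base]) + (start_base - es[hit])
  oracle_translate_from(mrna, off)
}

oracle_kmers <- function(prot, ks) {
  unlist(lapply(ks, function(k) {
    n <- nchar(prot)
    if (n < k) return(character(0))
    substring(prot, 1:(n - k + 1L), k:n)
  }), use.names = FALSE)
}

# Brute-force final candidate set for a fixture bundle: all 8-11-mers of
# manually spliced/translated novel proteins minus all normal k-mers
# (reference proteome + proteins of panel-normal junctions).
oracle_candidate_set <- function(fx, ks = 8:11, min_protein_len = 30L) {
  manifest <- fx$manifest
  chrom_seq <- oracle_read_fasta(fx$paths$genome)[[manifest$chrom]]
  models <- oracle_parse_refgene(fx$paths$annotation)
  names(models) <- vapply(models, `[[`, "", "tx")

  normal_prots <- vapply(models, function(m)
    oracle_protein(chrom_seq, m$tx, m$es, m$ee, m$strand, m$cds_s, m$cds_e),
    character(1))

  novel_kmers <- character(0)
  for (j in manifest$junctions) {
    m <- models[[j$host]]
    mod <- oracle_modified_exons(m$es, m$ee, j$intron_start, j$intron_end, j$class)
    prot <- oracle_protein(chrom_seq, m$tx, mod$es, mod$ee, m$strand,
                           m$cds_s, m$cds_e)
    if (is.null(prot) || nchar(prot) <= min_protein_len) next
    if (identical(j$expected_fate, "retained"))
      novel_kmers <- c(novel_kmers, oracle_kmers(prot, ks))
    else if (identical(j$expected_fate, "normal"))
      normal_prots <- c(normal_prots, prot)   # panel junction extends normals
  }
  normal_kmers <- unlist(lapply(normal_prots, oracle_kmers, ks = ks),
                         use.names = FALSE)
  cands <- setdiff(unique(novel_kmers), normal_kmers)
  sort(cands[!grepl("[^ACDEFGHIKLMNPQRSTVWY]", cands)], method = "radix")
}
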