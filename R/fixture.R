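# Synthetic fixture generation.
#
# Builds a complete miniature study: a genome, a refGene-dialect annotation
# of five protein-coding genes (one on the minus strand), an aligner-style
# junction table containing all annotated junctions plus twelve planted
# novel junctions, a normal-junction panel matrix, per-transcript read
# counts, an epitope library, and a manifest recording the expected fate of
# every planted junction. Reference CDSs are built from random stop-free
# codons so every in-frame planted event yields a long, well-defined novel
# protein; planted junctions sit exactly on the pipeline's decision
# boundaries (reads = 10, exon modification = 1 bp, intron = 50 bp,
# protein length <= 30, RPKM < 1) so each filter is exercised at its edge.

STOP_CODONS <- c("TAA", "TAG", "TGA")

all_codons <- function() {
  b <- c("A", "C", "G", "T")
  as.vector(outer(outer(b, b, paste0), b, paste0))
}

# Random stop-free CDS of n_codons codons: ATG ... TAA.
random_cds <- function(n_codons) {
  nonstop <- setdiff(all_codons(), STOP_CODONS)
  paste(c("ATG", sample(nonstop, n_codons - 2L, replace = TRUE), "TAA"),
        collapse = "")
}

# Exon coordinates from an offset and alternating exon/intron lengths.
exon_chain <- function(offset, exon_lens, intron_lens) {
  es <- integer(length(exon_lens)); ee <- integer(length(exon_lens))
  pos <- offset
  for (i in seq_along(exon_lens)) {
    es[i] <- pos; ee[i] <- pos + exon_lens[i]
    pos <- ee[i] + if (i < length(exon_lens)) intron_lens[i] else 0L
  }
  list(starts = es, ends = ee)
}

# Write a CDS (mRNA orientation) into the chromosome character vector over
# the exon/CDS intersection; returns the modified vector.
fill_cds <- function(chars, model, cds_mrna) {
  ps <- pmax(model$exon_starts, model$cds_start)
  pe <- pmin(model$exon_ends, model$cds_end)
  keep <- ps < pe
  ps <- ps[keep]; pe <- pe[keep]
  genomic <- if (model$strand == "-")
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(cds_mrna)))
  else cds_mrna
  off <- 0L
  for (i in seq_along(ps)) {
    len <- pe[i] - ps[i]
    chars[(ps[i] + 1L):pe[i]] <-
      strsplit(substr(genomic, off + 1L, off + len), "", fixed = TRUE)[[1]]
    off <- off + len
  }
  chars
}

# Expected novel protein after excising [at, at+len) from the CDS mRNA
# string (codon-aligned in all planted retained events).
excised_protein <- function(cds_mrna, at, len) {
  translate_cds(paste0(substr(cds_mrna, 1L, at),
                       substr(cds_mrna, at + len + 1L, nchar(cds_mrna))),
                warn_frame = FALSE)$protein
}

#' Generate a synthetic fixture bundle
#'
#' Writes `genome.fa`, `annotation.refGene.txt`, `SJ.out.tab`, `panel.tsv`,
#' `counts.tsv`, `epitopes.fa` and `manifest.json` into `dir`. The bundle
#' is byte-identical for a fixed seed. The manifest lists each planted
#' junction with its class and expected pipeline fate (`retained`,
#' `low_reads`, `low_psi`, `normal`, `exon_mod`, `intron_length`,
#' `non_coding`, `start_lost`, `short_protein`, and with
#' `include_low_rpkm_gene`, `low_rpkm`), plus the expected novel protein of
#' every retained event.
#'
#' @param seed Integer seed; the caller's RNG state is left untouched.
#' @param dir Output directory (created if needed).
#' @param n_panel_samples Number of normal panel samples.
#' @param alleles HLA-I alleles written into the manifest.
#' @param include_low_rpkm_gene Add a sixth, weakly expressed gene whose
#'   planted junction must fail the RPKM gate.
#' @return Invisibly, a list with `paths` (named file paths) and
#'   `manifest` (the manifest as a list).
#' @export
generate_fixture <- function(seed, dir,
                             n_panel_samples = 50L,
                             alleles = c("HLA-A*02:01", "HLA-B*07:02"),
                             include_low_rpkm_gene = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  with_preserved_seed(as.integer(seed) %% 2147483647L, {
    chrom <- "chr1"
    chrom_len <- 17000L
    chars <- sample(c("A", "C", "G", "T"), chrom_len, replace = TRUE)

    gene_defs <- list(
      A = list(offset = 1000L, strand = "+",
               exon_lens = c(150L, 90L, 120L, 300L, 200L),
               intron_lens = c(400L, 450L, 380L, 420L),
               ann_reads = c(100L, 100L, 200L, 100L)),
      B = list(offset = 4500L, strand = "+",
               exon_lens = c(150L, 90L, 500L, 200L),
               intron_lens = c(400L, 350L, 450L),
               ann_reads = c(100L, 100L, 100L)),
      C = list(offset = 7600L, strand = "-",
               exon_lens = c(250L, 150L, 102L, 200L),
               intron_lens = c(380L, 420L, 360L),
               ann_reads = c(100L, 100L, 100L)),
      D = list(offset = 10400L, strand = "+",
               exon_lens = c(150L, 120L, 180L, 200L),
               intron_lens = c(400L, 380L, 360L),
               ann_reads = c(100L, 100L, 100L)),
      E = list(offset = 13200L, strand = "+",
               exon_lens = c(60L, 33L, 90L),
               intron_lens = c(300L, 340L),
               ann_reads = c(100L, 100L)))
    if (include_low_rpkm_gene)
      gene_defs$F <- list(offset = 14500L, strand = "+",
                          exon_lens = c(150L, 90L, 150L),
                          intron_lens = c(350L, 400L),
                          ann_reads = c(100L, 100L))

    models <- list()
    cds_mrna <- list()
    for (g in names(gene_defs)) {
      def <- gene_defs[[g]]
      ch <- exon_chain(def$offset, def$exon_lens, def$intron_lens)
      es <- ch$starts; ee <- ch$ends
      cds <- switch(g,
        A = c(es[1] + 30L, es[5] + 66L),
        B = c(es[1] + 30L, es[4] + 91L),
        C = c(es[1] + 40L, es[4] + 141L),   # minus strand: start codon at cds_end
        D = c(es[2] + 15L, es[3] + 90L),
        E = c(es[1] + 12L, es[3] + 30L),
        F = c(es[1] + 30L, es[3] + 60L))
      m <- transcript_model(paste0("tx", g), paste0("gene", g), chrom,
                            def$strand, es, ee, cds[1], cds[2])
      ps <- pmax(es, cds[1]); pe <- pmin(ee, cds[2])
      L <- sum(pmax(0L, pe - ps))
      stopifnot(L %% 3L == 0L)
      cds_mrna[[g]] <- random_cds(L %/% 3L)
      chars <- fill_cds(chars, m, cds_mrna[[g]])
      models[[g]] <- m
    }

    ex <- lapply(models, function(m) list(s = m$exon_starts, e = m$exon_ends))
    J <- function(gene, a, b, reads, class, fate, protein = NULL) {
      m <- models[[gene]]
      list(key = junction_key(chrom, m$strand, a, b), chrom = chrom,
           strand = m$strand, intron_start = a, intron_end = b,
           unique_reads = reads, class = class, host = m$transcript_id,
           expected_fate = fate, expected_protein = protein)
    }
    planted <- list(
      J("A", ex$A$e[1], ex$A$s[3], 50L, "tag1_skip", "retained",
        excised_protein(cds_mrna$A, 120L, 90L)),
      J("A", ex$A$e[2], ex$A$s[4], 10L, "tag1_skip", "low_reads"),
      J("A", ex$A$e[3], ex$A$s[5], 15L, "tag1_skip", "low_psi"),
      J("B", ex$B$e[1], ex$B$s[3], 60L, "tag1_skip", "normal"),
      J("B", ex$B$e[2], ex$B$s[3] + 9L, 40L, "tag2_shift", "retained",
        excised_protein(cds_mrna$B, 210L, 9L)),
      J("B", ex$B$e[2], ex$B$s[3] + 1L, 35L, "tag2_shift", "exon_mod"),
      J("B", ex$B$s[3] + 198L, ex$B$s[3] + 258L, 30L, "tag3_split", "retained",
        excised_protein(cds_mrna$B, 408L, 60L)),
      J("B", ex$B$s[3] + 102L, ex$B$s[3] + 152L, 30L, "tag3_split", "intron_length"),
      J("C", ex$C$e[2], ex$C$s[4], 45L, "tag1_skip", "retained",
        excised_protein(cds_mrna$C, 141L, 102L)),
      J("D", ex$D$e[1], ex$D$s[3], 40L, "tag1_skip", "start_lost"),
      J("D", ex$D$e[3], ex$D$s[4] + 12L, 30L, "tag2_shift", "non_coding"),
      J("E", ex$E$e[1], ex$E$s[3], 40L, "tag1_skip", "short_protein"))
    if (include_low_rpkm_gene)
      planted <- c(planted, list(
        J("F", ex$F$e[1], ex$F$s[3], 40L, "tag1_skip", "low_rpkm")))

    # annotated junctions carried in the sample junction table
    ann_rows <- do.call(rbind, lapply(names(gene_defs), function(g) {
      intr <- model_introns(models[[g]])
      intr$unique_reads <- gene_defs[[g]]$ann_reads
      intr$annotated <- 1L
      intr
    }))
    pl_rows <- do.call(rbind, lapply(planted, function(j)
      data.frame(chrom = j$chrom, strand = j$strand,
                 intron_start = j$intron_start, intron_end = j$intron_end,
                 unique_reads = j$unique_reads, annotated = 0L,
                 stringsAsFactors = FALSE)))
    sj <- rbind(ann_rows, pl_rows)
    sj <- sj[order(sj$intron_start, sj$intron_end, method = "radix"), ]
    sj_lines <- paste(sj$chrom, sj$intron_start + 1L, sj$intron_end,
                      match(sj$strand, c("+", "-")),     # 1 = +, 2 = -
                      0L, sj$annotated, sj$unique_reads,
                      pmax(0L, round(sj$unique_reads * 0.1)), 50L, sep = "\t")

    # panel: all annotated junctions everywhere, the planted "normal"
    # junction in 60% of samples, and a decoy never reaching 2 reads
    normal_j <- planted[[4]]
    decoy <- list(chrom = chrom, strand = "+",
                  intron_start = ex$A$e[5] + 50L, intron_end = ex$A$e[5] + 400L)
    panel_keys <- rbind(
      ann_rows[, c("chrom", "strand", "intron_start", "intron_end")],
      data.frame(chrom = normal_j$chrom, strand = normal_j$strand,
                 intron_start = normal_j$intron_start,
                 intron_end = normal_j$intron_end, stringsAsFactors = FALSE),
      data.frame(chrom = decoy$chrom, strand = decoy$strand,
                 intron_start = decoy$intron_start,
                 intron_end = decoy$intron_end, stringsAsFactors = FALSE))
    n_ann <- nrow(ann_rows)
    counts_mat <- matrix(0L, nrow = nrow(panel_keys), ncol = n_panel_samples)
    counts_mat[seq_len(n_ann), ] <-
      2L + stats::rpois(n_ann * n_panel_samples, 20)
    seen <- seq_len(max(1L, round(0.6 * n_panel_samples)))
    counts_mat[n_ann + 1L, seen] <- 2L + stats::rpois(length(seen), 5)
    counts_mat[n_ann + 2L, ] <- sample(0:1, n_panel_samples, replace = TRUE)
    colnames(counts_mat) <- sprintf("N%03d", seq_len(n_panel_samples))
    panel <- cbind(panel_keys, as.data.frame(counts_mat))

    # expression: all genes well expressed except the optional low-RPKM one
    counts <- stats::setNames(rep(1000L, length(models)),
                              vapply(models, `[[`, "", "transcript_id"))
    if (include_low_rpkm_gene) counts[["txF"]] <- 3L
    total_mapped_reads <- 1e7

    # epitope library: random peptides plus 9-mers of the expected novel
    # proteins centred on each retained event's junction codon, so the
    # recognition term sees epitopes resembling true junction peptides
    epi <- vapply(1:12, function(i) {
      k <- sample(9:11, 1L)
      paste(sample(AA20, k, replace = TRUE), collapse = "")
    }, character(1))
    ret_idx <- which(vapply(planted, function(j)
      !is.null(j$expected_protein), logical(1)))
    junction_codon <- c(40L, 70L, 136L, 47L)   # junction aa offsets, in ret_idx order
    epi <- c(epi, vapply(seq_along(ret_idx), function(i)
      substr(planted[[ret_idx[i]]]$expected_protein,
             junction_codon[i] - 3L, junction_codon[i] + 5L),
      character(1), USE.NAMES = FALSE))
    names(epi) <- sprintf("epi%02d", seq_along(epi))

    paths <- list(
      genome = file.path(dir, "genome.fa"),
      annotation = file.path(dir, "annotation.refGene.txt"),
      junctions = file.path(dir, "SJ.out.tab"),
      panel = file.path(dir, "panel.tsv"),
      counts = file.path(dir, "counts.tsv"),
      epitopes = file.path(dir, "epitopes.fa"),
      manifest = file.path(dir, "manifest.json"))
    gseq <- Biostrings::DNAStringSet(paste(chars, collapse = ""))
    names(gseq) <- chrom
    Biostrings::writeXStringSet(gseq, paths$genome, width = 70L)
    write_refgene(models, paths$annotation)
    writeLines(sj_lines, paths$junctions)
    write_panel(panel, paths$panel)
    utils::write.table(
      data.frame(transcript_id = names(counts), count = unname(counts)),
      paths$counts, sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(paste0(">", names(epi), "\n", epi), paths$epitopes)

    ann_reads <- stats::setNames(
      ann_rows$unique_reads,
      junction_key(ann_rows$chrom, ann_rows$strand,
                   ann_rows$intron_start, ann_rows$intron_end))
    manifest <- list(
      seed = as.integer(seed), chrom = chrom, chrom_len = chrom_len,
      alleles = alleles, total_mapped_reads = total_mapped_reads,
      n_panel_samples = as.integer(n_panel_samples),
      junctions = lapply(planted, function(j)
        j[!vapply(j, is.null, logical(1))]),
      annotated_junction_reads = as.list(ann_reads),
      paths = lapply(paths, basename))
    jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
    invisible(list(paths = paths, manifest = manifest))
  })
}
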