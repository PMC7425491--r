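# End-to-end pipeline: configuration, orchestration, output writing.

#' Build and validate a pipeline configuration
#'
#' @param genome,annotation,junctions Input file paths (FASTA; refGene or
#'   GTF; junction table).
#' @param epitopes Epitope library FASTA (recognition term).
#' @param hla Character vector of HLA-I alleles.
#' @param junction_format `"sj"` or `"bed6"` ([parse_junction_table()]).
#' @param panel Normal-junction panel TSV path, or `NULL`.
#' @param normal_db Prebuilt normal-junction DB path (overrides `panel`).
#' @param counts Per-transcript read-count TSV (`transcript_id`, `count`).
#' @param total_mapped_reads Library size for RPKM; defaults to the column
#'   sum of `counts` when absent.
#' @param min_unique_reads,min_psi,min_rpkm,min_exon_mod,max_exon_mod,min_intron,min_protein_len,rank_threshold,hin_cutoff
#'   Filter thresholds (see the stage functions for semantics).
#' @param lengths Peptide lengths, a subset of 8:11.
#' @param predictor `"surrogate"` (built-in deterministic predictor).
#' @param include_junction_proteins Extend the normal proteome with
#'   panel-junction-derived proteins (see [normal_proteome()]).
#' @param seed Seed forwarded to the surrogate predictor.
#' @param threads Worker count for the per-junction stage; results are
#'   gathered and canonically ordered, so the value never changes output.
#' @param out_dir Output directory.
#' @return A validated `PipelineConfig` list.
#' @export
spliceneo_config <- function(genome, annotation, junctions, epitopes, hla,
                             junction_format = "sj",
                             panel = NULL, normal_db = NULL,
                             counts = NULL, total_mapped_reads = NULL,
                             min_unique_reads = 10L, min_psi = 0.1,
                             min_rpkm = 1.0, min_exon_mod = 2L,
                             max_exon_mod = 250L, min_intron = 50L,
                             min_protein_len = 30L, lengths = 8:11,
                             rank_threshold = 2.0, hin_cutoff = 1e-8,
                             predictor = "surrogate",
                             include_junction_proteins = TRUE,
                             seed = 1L, threads = 1L, out_dir = NULL) {
  for (p in c(genome, annotation, junctions, epitopes, panel, normal_db, counts))
    if (!is.null(p) && !file.exists(p)) stopf("input file not found: %s", p)
  if (!all(lengths %in% 8:11)) stopf("peptide lengths must be within 8..11")
  if (length(hla) == 0L) stopf("at least one HLA allele is required")
  for (v in c(min_unique_reads = min_unique_reads, min_psi = min_psi,
              min_rpkm = min_rpkm, min_exon_mod = min_exon_mod,
              max_exon_mod = max_exon_mod, min_intron = min_intron,
              min_protein_len = min_protein_len,
              rank_threshold = rank_threshold, hin_cutoff = hin_cutoff))
    if (v <= 0) stopf("thresholds must be positive")
  cfg <- list(genome = genome, annotation = annotation, junctions = junctions,
              junction_format = junction_format, panel = panel,
              normal_db = normal_db, counts = counts,
              total_mapped_reads = total_mapped_reads, epitopes = epitopes,
              hla = hla, min_unique_reads = min_unique_reads,
              min_psi = min_psi, min_rpkm = min_rpkm,
              min_exon_mod = min_exon_mod, max_exon_mod = max_exon_mod,
              min_intron = min_intron, min_protein_len = min_protein_len,
              lengths = sort(as.integer(lengths)),
              rank_threshold = rank_threshold, hin_cutoff = hin_cutoff,
              predictor = predictor,
              include_junction_proteins = include_junction_proteins,
              seed = as.integer(seed), threads = as.integer(threads),
              out_dir = out_dir)
  class(cfg) <- "PipelineConfig"
  cfg
}

# process one junction past the filter stage: placement, host selection,
# insertion, translation. Returns fate + any novel isoforms/proteins.
process_junction <- function(jrow, models, midx, rpkm, genome, cfg) {
  j <- as.list(jrow)
  pl <- map_junction_to_isoforms(j, models, midx)
  sel <- select_hosts(pl, rpkm, min_rpkm = cfg$min_rpkm)
  if (nrow(sel$selected) == 0L)
    return(list(key = j$key, fate = sel$reason, isoforms = list(),
                proteins = list()))
  reason_rank <- c(non_coding = 1, site_in_intron = 1, tag3_multi_exon = 1,
                   exon_mod = 2, intron_length = 2, start_lost = 3,
                   short_protein = 4)
  isoforms <- list(); proteins <- list(); reasons <- character(0)
  for (r in seq_len(nrow(sel$selected))) {
    row <- sel$selected[r, ]
    iso <- insert_junction(models[[row$model_i]], j, row$tag,
                           min_exon_mod = cfg$min_exon_mod,
                           max_exon_mod = cfg$max_exon_mod,
                           min_intron = cfg$min_intron,
                           rpkm_of_host = row$rpkm)
    if (is_rejection(iso)) { reasons <- c(reasons, iso$reason); next }
    isoforms[[iso$id]] <- iso
    pr <- translate_isoform(iso, genome, min_protein_len = cfg$min_protein_len)
    if (is_rejection(pr)) { reasons <- c(reasons, pr$reason); next }
    proteins[[pr$isoform_id]] <- pr
  }
  fate <- if (length(proteins) > 0L) "retained"
  else reasons[which.max(reason_rank[reasons])]
  list(key = j$key, fate = fate, isoforms = isoforms, proteins = proteins)
}

#' Run the full neoantigen discovery pipeline
#'
#' Executes junction filtering, isoform construction, translation, peptide
#' generation, normal-proteome subtraction, binding prediction and immune
#' scoring, and (when `out_dir` is set) writes the score table, candidate
#' peptide FASTA, novel-isoform GTF, per-junction fate table and a JSON run
#' summary. Identical configurations and seeds produce identical outputs
#' regardless of `threads`.
#'
#' @param config A `PipelineConfig` from [spliceneo_config()].
#' @return List with `records` (scored neoantigen table), `junction_fates`
#'   (per input junction: `key`, `fate`), `candidates` (pre-binding unique
#'   peptides), `summary` (stage counts) and `paths` (written files, if
#'   any).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  genome <- read_genome(config$genome)
  models <- load_annotation(config$annotation)
  midx <- index_models(models)

  db <- if (!is.null(config$normal_db)) read_normal_junction_db(config$normal_db)
  else build_normal_junction_db(
    if (is.null(config$panel)) NULL else read_panel(config$panel), models)

  counts <- if (is.null(config$counts))
    stats::setNames(numeric(0), character(0))
  else {
    ct <- utils::read.table(config$counts, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    stats::setNames(ct$count, ct$transcript_id)
  }
  total <- if (!is.null(config$total_mapped_reads)) config$total_mapped_reads
  else max(1, sum(counts))
  rpkm <- rpkm_table(models, counts, total)

  normals <- normal_proteome(
    models, genome, db,
    include_junction_proteins = config$include_junction_proteins,
    min_protein_len = config$min_protein_len)
  index <- build_normal_peptide_index(normals, ks = config$lengths)

  junc <- parse_junction_table(config$junctions, format = config$junction_format)
  junc <- compute_psi(junc)
  filt <- filter_junctions(junc, db, min_unique_reads = config$min_unique_reads,
                           min_psi = config$min_psi)

  rows <- split(filt$retained, seq_len(nrow(filt$retained)))
  worker <- function(jrow) process_junction(jrow, models, midx, rpkm, genome, config)
  stage2 <- if (config$threads > 1L && .Platform$OS.type == "unix")
    parallel::mclapply(rows, worker, mc.cores = config$threads)
  else lapply(rows, worker)

  junction_fates <- rbind(
    data.frame(key = filt$removed$key, fate = filt$removed$reason,
               stringsAsFactors = FALSE),
    data.frame(key = vapply(stage2, `[[`, "", "key"),
               fate = vapply(stage2, `[[`, "", "fate"),
               stringsAsFactors = FALSE))
  junction_fates <- junction_fates[match(junc$key, junction_fates$key), ]
  rownames(junction_fates) <- NULL

  isoforms <- do.call(c, c(list(list()), unname(lapply(stage2, `[[`, "isoforms"))))
  proteins <- do.call(c, c(list(list()), unname(lapply(stage2, `[[`, "proteins"))))
  iso_junction <- stats::setNames(vapply(isoforms, `[[`, "", "junction_key"),
                                  vapply(isoforms, `[[`, "", "id"))

  kmers <- do.call(rbind, c(
    list(data.frame(peptide = character(), k = integer(), start = integer(),
                    protein_id = character(), junction_key = character(),
                    stringsAsFactors = FALSE)),
    lapply(proteins, function(pr) {
      km <- chop_peptides(pr$sequence, ks = config$lengths)
      if (nrow(km) == 0L) return(NULL)
      km$protein_id <- pr$isoform_id
      km$junction_key <- unname(iso_junction[pr$isoform_id])
      km
    })))
  candidates <- filter_normal_peptides(kmers, index)

  epitopes <- {
    aa <- Biostrings::readAAStringSet(config$epitopes)
    as.character(aa)
  }
  predictor <- surrogate_binding_predictor(seed = config$seed)
  records <- score_candidates(candidates, config$hla, index, epitopes,
                              predictor, rank_threshold = config$rank_threshold,
                              hin_cutoff = config$hin_cutoff)

  fate_counts <- table(factor(junction_fates$fate))
  summary <- list(
    n_input_junctions = nrow(junc),
    junction_fates = as.list(fate_counts),
    n_junctions_retained = sum(junction_fates$fate == "retained"),
    n_novel_isoforms = length(isoforms),
    n_novel_proteins = length(proteins),
    n_normal_proteins = length(index$proteins),
    n_kmers = nrow(kmers),
    n_candidate_peptides = nrow(candidates),
    n_scored_pairs = nrow(records),
    n_unique_neopeptides = length(unique(records$peptide)),
    n_hin = sum(records$HIN))

  paths <- list()
  if (!is.null(config$out_dir)) {
    paths <- write_outputs(records, config$out_dir,
                           junctions = cbind(junc, fate = junction_fates$fate),
                           isoforms = isoforms, summary = summary,
                           config = config)
  }
  list(records = records, junction_fates = junction_fates,
       candidates = candidates, summary = summary, paths = paths)
}

#' Write pipeline outputs
#'
#' Score table as TSV sorted by descending score (ties: peptide, then
#' allele, lexicographic), candidate peptides as FASTA (id = sequence),
#' per-junction table with psi and fates, novel isoforms as GTF, and a JSON
#' run summary. Fails before writing anything if the directory cannot be
#' created.
#'
#' @param records Scored neoantigen data.frame.
#' @param out_dir Output directory.
#' @param junctions Optional junction table with fates.
#' @param isoforms Optional list of `NovelIsoform`.
#' @param summary,config Optional summary list and `PipelineConfig` echoed
#'   into `summary.json`.
#' @return Named list of written paths.
#' @export
write_outputs <- function(records, out_dir, junctions = NULL, isoforms = NULL,
                          summary = NULL, config = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir) || file.access(out_dir, 2L) != 0L)
    stopf("output directory %s is not writable", out_dir)
  paths <- list(score_table = file.path(out_dir, "score_table.tsv"),
                peptides = file.path(out_dir, "neopeptides.fa"))
  records <- records[order(-records$S, records$peptide, records$allele,
                           method = "radix"), , drop = FALSE]
  utils::write.table(records, paths$score_table, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  peps <- unique(records$peptide)
  writeLines(if (length(peps)) paste0(">", peps, "\n", peps) else character(0),
             paths$peptides)
  if (!is.null(junctions)) {
    paths$junctions <- file.path(out_dir, "junctions.tsv")
    utils::write.table(junctions, paths$junctions, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(isoforms)) {
    paths$novel_isoforms <- file.path(out_dir, "novel_isoforms.gtf")
    write_novel_isoforms_gtf(isoforms, paths$novel_isoforms)
  }
  if (!is.null(summary)) {
    paths$summary <- file.path(out_dir, "summary.json")
    echo <- if (is.null(config)) NULL else
      config[!vapply(config, is.null, logical(1))]
    jsonlite::write_json(list(summary = summary, config = echo),
                         paths$summary, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
  }
  paths
}
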