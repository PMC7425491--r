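# Junction-to-isoform placement, classification (tags 0-3), host selection
# and junction insertion into reference isoforms.
#
# Tag semantics for a junction tested against one host isoform:
#   0 - junction equals an intron of the host (annotated in context);
#   1 - both splice sites coincide with annotated exon boundaries of the
#       host, but the pair is not a host intron (e.g. exon skipping);
#   2 - exactly one site is an annotated boundary (alternative donor or
#       acceptor);
#   3 - neither site is annotated.

#' Map a junction onto candidate host isoforms and classify it
#'
#' A transcript is a candidate host when it lies on a compatible strand
#' (equal, or any strand for strand-unknown junctions) and its genomic span
#' contains both junction endpoints. Each placement is classified with the
#' tag scheme above; exon-boundary matching is exact (0 bp tolerance).
#'
#' @param j List or one-row data.frame with `chrom`, `strand`,
#'   `intron_start`, `intron_end`.
#' @param models List of `TranscriptModel`.
#' @param model_index Optional precomputed [index_models()] data.frame.
#' @return data.frame of placements: `key`, `transcript_id`, `model_i`,
#'   `tag`, `donor_annotated`, `acceptor_annotated` (zero rows when no host
#'   matches).
#' @export
map_junction_to_isoforms <- function(j, models, model_index = NULL) {
  if (is.null(model_index)) model_index <- index_models(models)
  a <- j$intron_start; b <- j$intron_end
  hit <- model_index$chrom == j$chrom &
    (j$strand == "*" | model_index$strand == j$strand) &
    model_index$tx_start <= a & b <= model_index$tx_end
  rows <- lapply(which(hit), function(i) {
    m <- models[[model_index$i[i]]]
    cls <- classify_junction_tag(m, a, b)
    data.frame(key = junction_key(j$chrom, j$strand, a, b),
               transcript_id = m$transcript_id, model_i = model_index$i[i],
               tag = cls$tag, donor_annotated = cls$donor_annotated,
               acceptor_annotated = cls$acceptor_annotated,
               stringsAsFactors = FALSE)
  })
  if (length(rows) == 0L)
    return(data.frame(key = character(), transcript_id = character(),
                      model_i = integer(), tag = integer(),
                      donor_annotated = logical(), acceptor_annotated = logical(),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

# Classify intron [a,b) against one host. In genomic coordinates the
# upstream side of the intron must match an exon end and the downstream side
# an exon start, irrespective of strand (biological donor/acceptor roles
# swap on the minus strand but the coordinate test is the same).
classify_junction_tag <- function(model, a, b) {
  n <- length(model$exon_starts)
  upstream_ok <- a %in% model$exon_ends
  downstream_ok <- b %in% model$exon_starts
  is_intron <- n >= 2L &&
    any(model$exon_ends[-n] == a & model$exon_starts[-1L] == b)
  tag <- if (is_intron) 0L
  else if (upstream_ok && downstream_ok) 1L
  else if (upstream_ok || downstream_ok) 2L
  else 3L
  donor_annotated <- if (model$strand == "-") downstream_ok else upstream_ok
  acceptor_annotated <- if (model$strand == "-") upstream_ok else downstream_ok
  list(tag = tag, donor_annotated = donor_annotated,
       acceptor_annotated = acceptor_annotated)
}

#' RPKM of a transcript
#'
#' @param model `TranscriptModel` (its exonic length is the denominator).
#' @param exon_read_count Reads assigned to the transcript's exon union.
#' @param total_mapped_reads Library size.
#' @return `exon_read_count * 1e9 / (total_mapped_reads * exonic_length)`.
#' @export
compute_rpkm <- function(model, exon_read_count, total_mapped_reads) {
  len <- exonic_length(model)
  if (len == 0L) stopf("transcript %s has zero exonic length", model$transcript_id)
  if (total_mapped_reads <= 0) stopf("total_mapped_reads must be positive")
  exon_read_count * 1e9 / (total_mapped_reads * len)
}

# RPKM for every model given a named count vector.
rpkm_table <- function(models, counts, total_mapped_reads) {
  v <- vapply(models, function(m) {
    cnt <- counts[m$transcript_id]
    if (is.na(cnt)) cnt <- 0
    compute_rpkm(m, cnt, total_mapped_reads)
  }, numeric(1))
  stats::setNames(v, vapply(models, `[[`, "", "transcript_id"))
}

#' Select host isoforms for a junction
#'
#' Any tag-0 placement means the junction is annotated in context and
#' produces no novel isoform. Otherwise the placements with the smallest tag
#' are kept, then gated on host expression `rpkm > min_rpkm` (strict).
#'
#' @param placements data.frame from [map_junction_to_isoforms()].
#' @param rpkm Named numeric vector of per-transcript RPKM (missing hosts
#'   count as 0).
#' @param min_rpkm Strict lower expression threshold.
#' @return List with `selected` (possibly zero-row placements data.frame)
#'   and `reason` (`NA` if any host survives, else `"annotated"`,
#'   `"no_host"` or `"low_rpkm"`).
#' @export
select_hosts <- function(placements, rpkm, min_rpkm = 1.0) {
  none <- placements[integer(0), , drop = FALSE]
  if (nrow(placements) == 0L) return(list(selected = none, reason = "no_host"))
  if (any(placements$tag == 0L)) return(list(selected = none, reason = "annotated"))
  best <- placements[placements$tag == min(placements$tag), , drop = FALSE]
  host_rpkm <- rpkm[best$transcript_id]
  host_rpkm[is.na(host_rpkm)] <- 0
  best$rpkm <- unname(host_rpkm)
  keep <- best$rpkm > min_rpkm
  if (!any(keep)) return(list(selected = none, reason = "low_rpkm"))
  list(selected = best[keep, , drop = FALSE], reason = NA_character_)
}

# Rejection marker shared by insertion and translation steps.
rejection <- function(reason) structure(list(reason = reason), class = "spliceneo_rejection")

#' Is an object a rejection marker?
#' @param x Result of [insert_junction()] or [translate_isoform()].
#' @export
is_rejection <- function(x) inherits(x, "spliceneo_rejection")

#' Insert a junction into a host isoform
#'
#' Builds the novel isoform implied by one classified placement:
#' tag 1 removes the exons strictly between donor and acceptor (exon
#' skipping); tag 2 moves the novel-side exon boundary to the novel site,
#' subject to the exon-modification bound `min_exon_mod <= d <= max_exon_mod`
#' on the absolute length change `d`; tag 3 with both sites inside one exon
#' splits that exon, subject to the novel intron being strictly longer than
#' `min_intron`. A junction whose intron span does not intersect the host's
#' genomic CDS span is rejected (`"non_coding"`): only coding-region
#' perturbations can yield neoantigens. Novel sites falling in host introns
#' (`"site_in_intron"`) and tag-3 sites in two different exons
#' (`"tag3_multi_exon"`) are rejected rather than modeled.
#'
#' @param model Host `TranscriptModel` (must be coding).
#' @param j Junction (list with `chrom`, `strand`, `intron_start`,
#'   `intron_end`).
#' @param tag Placement tag (1, 2 or 3).
#' @param min_exon_mod,max_exon_mod Inclusive bounds on the tag-2 exon
#'   length change, in bp.
#' @param min_intron Strict lower bound on the tag-3 novel intron length.
#' @param rpkm_of_host Host expression, carried into the isoform record.
#' @return A `NovelIsoform` (list with exon chain, inherited CDS span, tag,
#'   provenance and id), or a rejection marker ([is_rejection()]).
#' @export
insert_junction <- function(model, j, tag,
                            min_exon_mod = 2L, max_exon_mod = 250L,
                            min_intron = 50L, rpkm_of_host = NA_real_) {
  a <- j$intron_start; b <- j$intron_end
  if (a < tx_start(model) || b > tx_end(model))
    stopf("junction [%d,%d) outside host %s span", a, b, model$transcript_id)
  if (!tag %in% 1:3) stopf("insertable placements must have tag 1, 2 or 3")
  if (!has_cds(model)) return(rejection("non_coding"))
  if (!(a < model$cds_end && b > model$cds_start))
    return(rejection("non_coding"))

  es <- model$exon_starts; ee <- model$exon_ends
  inner <- es >= a & ee <= b          # exons wholly inside the intron: drop
  exon_of <- function(pos) {          # exon strictly containing pos, else 0
    w <- which(es < pos & pos < ee)
    if (length(w) == 1L) w else 0L
  }
  if (tag == 1L) {
    up <- which(ee == a); down <- which(es == b)
    if (length(up) != 1L || length(down) != 1L || up >= down)
      stopf("inconsistent tag-1 placement on %s", model$transcript_id)
    keep <- !inner
    new_es <- es[keep]; new_ee <- ee[keep]
  } else if (tag == 2L) {
    up_annot <- a %in% ee
    novel <- if (up_annot) b else a
    ei <- exon_of(novel)
    if (ei == 0L) return(rejection("site_in_intron"))
    if (up_annot) {
      d <- novel - es[ei]             # acceptor shift: exon start moves right
      new_start <- novel; new_end <- ee[ei]
    } else {
      d <- ee[ei] - novel             # donor shift: exon end moves left
      new_start <- es[ei]; new_end <- novel
    }
    if (d < min_exon_mod || d > max_exon_mod) return(rejection("exon_mod"))
    keep <- !inner; keep[ei] <- TRUE
    new_es <- es; new_ee <- ee
    new_es[ei] <- new_start; new_ee[ei] <- new_end
    new_es <- new_es[keep]; new_ee <- new_ee[keep]
  } else {
    ea <- exon_of(a); eb <- exon_of(b)
    if (ea == 0L || eb == 0L) return(rejection("site_in_intron"))
    if (ea != eb) return(rejection("tag3_multi_exon"))
    if (b - a <= min_intron) return(rejection("intron_length"))
    new_es <- append(es, b, after = ea)
    new_ee <- append(ee, a, after = ea - 1L)
  }
  key <- junction_key(j$chrom, j$strand, a, b)
  iso <- list(id = paste0(model$transcript_id, "|", key, "|tag", tag),
              chrom = model$chrom, strand = model$strand,
              exon_starts = as.integer(new_es), exon_ends = as.integer(new_ee),
              source_transcript_id = model$transcript_id,
              junction_key = key, tag = as.integer(tag),
              cds_start = model$cds_start, cds_end = model$cds_end,
              rpkm_of_host = rpkm_of_host)
  class(iso) <- "NovelIsoform"
  stopifnot(all(iso$exon_ends > iso$exon_starts),
            !is.unsorted(iso$exon_starts, strictly = TRUE),
            all(iso$exon_starts[-1] >= iso$exon_ends[-length(iso$exon_ends)]))
  iso
}

#' Write novel isoforms as GTF
#'
#' @param isoforms List of `NovelIsoform`.
#' @param path Output path.
#' @export
write_novel_isoforms_gtf <- function(isoforms, path) {
  lines <- unlist(lapply(isoforms, function(iso) {
    attrs <- sprintf('transcript_id "%s"; source_transcript "%s"; junction "%s"; tag "%d";',
                     iso$id, iso$source_transcript_id, iso$junction_key, iso$tag)
    vapply(seq_along(iso$exon_starts), function(i)
      paste(iso$chrom, "spliceneo", "exon",
            iso$exon_starts[i] + 1L, iso$exon_ends[i], ".",
            iso$strand, ".", attrs, sep = "\t"), character(1))
  }))
  writeLines(if (is.null(lines)) character(0) else lines, path)
  invisible(path)
}
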