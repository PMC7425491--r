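# Panel-of-normals junction database.
#
# A junction is "normal" (and hence discarded as non-tumor-specific) if it
# was seen with at least `min_reads` reads in at least
# ceiling(min_sample_frac * n_samples) normal panel samples, or if it is an
# intron of any annotated transcript.

#' Build the normal-junction database
#'
#' @param panel Panel count matrix as a data.frame with columns
#'   `chrom`, `strand`, `intron_start`, `intron_end` (0-based half-open)
#'   followed by one integer count column per normal sample, or `NULL` for an
#'   annotation-only database.
#' @param models Transcript models; every intron implied by consecutive
#'   exons enters the database with provenance `"annotation"`.
#' @param min_reads Minimum read count for a junction to count as detected
#'   in a sample (inclusive).
#' @param min_sample_frac Minimum fraction of panel samples in which the
#'   junction must be detected; the sample threshold is
#'   `ceiling(min_sample_frac * n_samples)` and the comparison is `>=`.
#' @return A `NormalJunctionDB`: sorted key set plus per-key provenance.
#' @export
build_normal_junction_db <- function(panel, models,
                                     min_reads = 2L, min_sample_frac = 0.01) {
  if (!is.null(panel) && (min_sample_frac <= 0 || min_sample_frac > 1))
    stopf("min_sample_frac must be in (0, 1]")
  panel_keys <- character(0)
  n_samples <- 0L
  if (is.null(panel) || nrow(panel) == 0L || ncol(panel) <= 4L) {
    warnf("empty normal panel: database contains annotation junctions only")
  } else {
    counts <- as.matrix(panel[, -(1:4), drop = FALSE])
    n_samples <- ncol(counts)
    need <- ceiling(min_sample_frac * n_samples)
    detected <- rowSums(counts >= min_reads)
    keep <- detected >= need
    panel_keys <- junction_key(panel$chrom[keep], panel$strand[keep],
                               panel$intron_start[keep], panel$intron_end[keep])
  }
  ann <- do.call(rbind, lapply(models, model_introns))
  ann_keys <- if (is.null(ann) || nrow(ann) == 0L) character(0) else
    junction_key(ann$chrom, ann$strand, ann$intron_start, ann$intron_end)
  keys <- radix_sort(unique(c(panel_keys, ann_keys)))
  prov <- vapply(keys, function(k) {
    paste(c("annotation"[k %in% ann_keys], "panel"[k %in% panel_keys]),
          collapse = ",")
  }, character(1))
  db <- list(keys = keys, provenance = prov, n_panel_samples = n_samples)
  class(db) <- "NormalJunctionDB"
  db
}

#' Test membership in a normal-junction database
#'
#' @param db A `NormalJunctionDB`.
#' @param keys Junction keys ([junction_key()]). Strand-unknown keys
#'   (`"*"`) match if either stranded form is present.
#' @return Logical vector.
#' @export
has_junction <- function(db, keys) {
  hit <- keys %in% db$keys
  unk <- grepl(":\\*:", keys)
  if (any(unk)) {
    plus <- sub(":\\*:", ":+:", keys[unk])
    minus <- sub(":\\*:", ":-:", keys[unk])
    hit[unk] <- plus %in% db$keys | minus %in% db$keys
  }
  hit
}

# Panel-only junctions (those not explained by the annotation); these are
# run through the isoform/translation machinery to extend the normal
# proteome.
panel_only_keys <- function(db) db$keys[db$provenance == "panel"]

#' @export
print.NormalJunctionDB <- function(x, ...) {
  cat(sprintf("NormalJunctionDB: %d junctions (%d annotation, %d panel-supported; %d panel samples)\n",
              length(x$keys), sum(grepl("annotation", x$provenance)),
              sum(grepl("panel", x$provenance)), x$n_panel_samples))
  invisible(x)
}

#' Write / read a normal-junction database as sorted TSV
#'
#' @param db A `NormalJunctionDB`.
#' @param path File path.
#' @export
write_normal_junction_db <- function(db, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("#spliceneo-normal-junction-db\tv1",
               sprintf("#n_panel_samples\t%d", db$n_panel_samples),
               "chrom\tstrand\tintron_start\tintron_end\tprovenance"), con)
  if (length(db$keys) > 0L) {
    parts <- do.call(rbind, strsplit(db$keys, ":", fixed = TRUE))
    writeLines(paste(parts[, 1], parts[, 2], parts[, 3], parts[, 4],
                     db$provenance, sep = "\t"), con)
  }
  invisible(path)
}

#' @rdname write_normal_junction_db
#' @export
read_normal_junction_db <- function(path) {
  lines <- readLines(path)
  if (!startsWith(lines[1], "#spliceneo-normal-junction-db"))
    stopf("%s: not a spliceneo normal-junction database", path)
  n_samples <- as.integer(strsplit(lines[2], "\t")[[1]][2])
  body <- lines[-(1:3)]
  keys <- character(0); prov <- character(0)
  if (length(body) > 0L) {
    f <- do.call(rbind, strsplit(body, "\t", fixed = TRUE))
    keys <- junction_key(f[, 1], f[, 2], f[, 3], f[, 4])
    prov <- f[, 5]
  }
  o <- order(keys, method = "radix")
  db <- list(keys = keys[o], provenance = stats::setNames(prov[o], keys[o]),
             n_panel_samples = n_samples)
  class(db) <- "NormalJunctionDB"
  db
}

#' Read / write a junction panel count matrix
#'
#' TSV with columns `chrom`, `strand`, `intron_start`, `intron_end`
#' (0-based half-open) then one count column per normal sample.
#'
#' @param path File path.
#' @export
read_panel <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' @rdname read_panel
#' @param panel Panel data.frame.
#' @export
write_panel <- function(panel, path) {
  utils::write.table(panel, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
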