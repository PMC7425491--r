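# Splice-junction table parsing, percent-spliced-in, and junction filters.

#' Parse a splice-junction table
#'
#' Reads the 9-column aligner junction dialect (`SJ.out.tab`: chrom,
#' 1-based inclusive intron start/end, strand code 0/1/2, motif, annotated
#' flag, unique reads, multi-mapping reads, max overhang) or a 6-column
#' BED-like TSV (chrom, 0-based intron start, intron end, name, unique
#' reads, strand). Coordinates are normalized to the internal 0-based
#' half-open convention and strand codes mapped 0 to `"*"`, 1 to `"+"`,
#' 2 to `"-"`.
#'
#' @param path Junction file.
#' @param format `"sj"` (default) or `"bed6"`.
#' @return data.frame with columns `chrom`, `strand`, `intron_start`,
#'   `intron_end`, `unique_reads`, `annotated_flag`, `key`.
#' @export
parse_junction_table <- function(path, format = c("sj", "bed6")) {
  format <- match.arg(format)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  empty <- data.frame(chrom = character(), strand = character(),
                      intron_start = integer(), intron_end = integer(),
                      unique_reads = integer(), annotated_flag = logical(),
                      key = character(), stringsAsFactors = FALSE)
  if (length(lines) == 0L) return(empty)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- if (format == "sj") 9L else 6L
  nf <- lengths(fields)
  if (any(nf != ncols))
    stopf("%s line %d: expected %d tab-separated columns, got %d",
          path, which(nf != ncols)[1], ncols, nf[nf != ncols][1])
  m <- do.call(rbind, fields)
  to_int <- function(col, name) {
    v <- suppressWarnings(as.integer(m[, col]))
    if (anyNA(v))
      stopf("%s line %d: non-integer %s", path, which(is.na(v))[1], name)
    v
  }
  if (format == "sj") {
    start1 <- to_int(2, "intron start")
    end1 <- to_int(3, "intron end")
    code <- to_int(4, "strand code")
    if (any(!code %in% 0:2))
      stopf("%s: strand code must be 0, 1 or 2", path)
    j <- data.frame(chrom = m[, 1],
                    strand = c("*", "+", "-")[code + 1L],
                    intron_start = start1 - 1L,   # 1-based inclusive -> 0-based half-open
                    intron_end = end1,
                    unique_reads = to_int(7, "unique read count"),
                    annotated_flag = to_int(6, "annotated flag") > 0L,
                    stringsAsFactors = FALSE)
  } else {
    j <- data.frame(chrom = m[, 1],
                    strand = ifelse(m[, 6] %in% c("+", "-"), m[, 6], "*"),
                    intron_start = to_int(2, "intron start"),
                    intron_end = to_int(3, "intron end"),
                    unique_reads = to_int(5, "unique read count"),
                    annotated_flag = FALSE,
                    stringsAsFactors = FALSE)
  }
  if (any(j$intron_end <= j$intron_start))
    stopf("%s line %d: intron end must exceed intron start", path,
          which(j$intron_end <= j$intron_start)[1])
  if (any(j$unique_reads < 0L)) stopf("%s: negative read count", path)
  j$key <- junction_key(j$chrom, j$strand, j$intron_start, j$intron_end)
  j
}

#' Compute percent-spliced-in (psi5 / psi3)
#'
#' psi5 of a junction is its unique-read support divided by the total
#' support of all junctions sharing its donor (5') splice site; psi3 is the
#' analogous fraction over the shared acceptor (3') site. On the plus strand
#' the donor is the intron start and the acceptor the intron end; on the
#' minus strand they are reversed. Strand-unknown junctions group among
#' themselves. psi is computed on the full, unfiltered table so denominators
#' reflect all observed junctions.
#'
#' @param junctions data.frame from [parse_junction_table()].
#' @return The input with numeric `psi5` and `psi3` columns added.
#' @export
compute_psi <- function(junctions) {
  j <- junctions
  if (nrow(j) == 0L) {
    j$psi5 <- numeric(0); j$psi3 <- numeric(0)
    return(j)
  }
  donor <- ifelse(j$strand == "-", j$intron_end, j$intron_start)
  acceptor <- ifelse(j$strand == "-", j$intron_start, j$intron_end)
  donor_g <- paste(j$chrom, j$strand, donor, sep = ":")
  acceptor_g <- paste(j$chrom, j$strand, acceptor, sep = ":")
  tot5 <- stats::ave(j$unique_reads, donor_g, FUN = sum)
  tot3 <- stats::ave(j$unique_reads, acceptor_g, FUN = sum)
  if (any(tot5 == 0L) || any(tot3 == 0L))
    warnf("splice-site group(s) with zero total reads: psi set to 0")
  j$psi5 <- ifelse(tot5 == 0L, 0, j$unique_reads / tot5)
  j$psi3 <- ifelse(tot3 == 0L, 0, j$unique_reads / tot3)
  j
}

#' Filter junctions by read support, psi and the normal-junction database
#'
#' A junction is retained iff `unique_reads > min_unique_reads`,
#' `psi5 > min_psi`, `psi3 > min_psi` (all strict) and its key is not in the
#' normal-junction database. Removal reasons are assigned with the fixed
#' precedence reads, then psi, then normal.
#'
#' @param junctions data.frame with psi columns ([compute_psi()]).
#' @param db `NormalJunctionDB`.
#' @param min_unique_reads,min_psi Strict lower thresholds.
#' @return List with `retained` (input rows passing, order preserved),
#'   `removed` (data.frame `key`, `reason`), and `summary` (named counts;
#'   reasons sum to the input size together with `retained`).
#' @export
filter_junctions <- function(junctions, db,
                             min_unique_reads = 10L, min_psi = 0.1) {
  j <- junctions
  if (is.null(j$psi5) || is.null(j$psi3))
    stopf("psi must be computed before filtering (see compute_psi)")
  reason <- rep(NA_character_, nrow(j))
  low_reads <- j$unique_reads <= min_unique_reads
  low_psi <- j$psi5 <= min_psi | j$psi3 <= min_psi
  normal <- has_junction(db, j$key)
  reason[normal] <- "normal"
  reason[low_psi] <- "low_psi"
  reason[low_reads] <- "low_reads"
  keep <- is.na(reason)
  list(
    retained = j[keep, , drop = FALSE],
    removed = data.frame(key = j$key[!keep], reason = reason[!keep],
                         stringsAsFactors = FALSE),
    summary = c(input = nrow(j),
                removed_low_reads = sum(reason == "low_reads", na.rm = TRUE),
                removed_low_psi = sum(reason == "low_psi", na.rm = TRUE),
                removed_normal = sum(reason == "normal", na.rm = TRUE),
                retained = sum(keep)))
}
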