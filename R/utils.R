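# Shared internal helpers.

# The 20 canonical amino acids (alphabet of all peptide-level operations).
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Canonical junction key
#'
#' Junctions are identified throughout the package by their intron span in
#' 0-based half-open genomic coordinates together with chromosome and strand.
#'
#' @param chrom Chromosome name.
#' @param strand `"+"`, `"-"` or `"*"` (unknown).
#' @param intron_start 0-based first intronic base.
#' @param intron_end 0-based position one past the last intronic base.
#' @return Character vector of keys `"chrom:strand:start:end"`.
#' @export
junction_key <- function(chrom, strand, intron_start, intron_end) {
  paste(chrom, strand, intron_start, intron_end, sep = ":")
}

# Evaluate expr under a fixed RNG seed without disturbing the caller's RNG
# stream. Used by the surrogate predictors so scoring is deterministic and
# independent of surrounding code.
with_preserved_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Numerically safe log(sum(exp(x))).
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Platform-stable (C locale) character sort.
radix_sort <- function(x) sort(x, method = "radix")

# Deterministic small-integer hash of a string (for allele-keyed seeding).
string_seed <- function(s) {
  v <- utf8ToInt(s)
  h <- 0
  for (x in v) h <- (h * 131 + x) %% 2147483647
  as.integer(h)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

# package-level cache (BLOSUM62 etc.)
.pkg_cache <- new.env(parent = emptyenv())

blosum62 <- function() {
  if (is.null(.pkg_cache$BLOSUM62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .pkg_cache$BLOSUM62 <- e$BLOSUM62
  }
  .pkg_cache$BLOSUM62
}
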