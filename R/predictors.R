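# Pluggable MHC-binding / antigen-processing predictors.
#
# The scoring schema composes several per-peptide quantities that in
# production come from external licensed tools (MHC-I binding percentile
# ranks; combined cleavage/TAP/binding processing scores). Both sit behind
# a small predictor interface so the pipeline is agnostic to the backend:
# the built-in surrogate is a deterministic pure function (position-specific
# scoring with a seeded random-peptide rank calibration), and text-output
# parsers are provided for recorded runs of the external tools.

#' Deterministic surrogate MHC-I binding predictor
#'
#' Scores a peptide against an allele with an allele-keyed position-specific
#' scoring matrix (anchor positions 2 and C-terminus up-weighted), then
#' converts the score to a percentile rank against a fixed seeded background
#' of random peptides of the same length: the %rank is the percentage of
#' background peptides scoring at least as high. Lower is stronger, ranks
#' are in [0, 100], and results are reproducible for a fixed seed.
#'
#' @param seed Integer seed of the surrogate (part of its version).
#' @param n_background Background sample size per peptide length.
#' @return A predictor object usable with [predict_percent_rank()].
#' @export
surrogate_binding_predictor <- function(seed = 1L, n_background = 2000L) {
  p <- list(name = "surrogate-pssm", version = "1",
            seed = as.integer(seed), n_background = as.integer(n_background),
            cache = new.env(parent = emptyenv()))
  class(p) <- c("surrogate_binder", "spliceneo_predictor")
  p
}

# allele+length -> 20 x k PSSM, deterministic in (predictor seed, allele, k)
surrogate_pssm <- function(predictor, allele, k) {
  key <- paste0("pssm:", allele, ":", k)
  if (!is.null(predictor$cache[[key]])) return(predictor$cache[[key]])
  s <- (string_seed(allele) + predictor$seed * 1000003L + k * 97L) %% 2147483647L
  w <- with_preserved_seed(s, matrix(stats::rnorm(20L * k), nrow = 20L,
                                     dimnames = list(AA20, NULL)))
  w[, c(2L, k)] <- w[, c(2L, k)] * 3   # anchor residues dominate
  predictor$cache[[key]] <- w
  w
}

surrogate_peptide_scores <- function(pssm, peptides) {
  k <- ncol(pssm)
  vapply(peptides, function(p) {
    idx <- match(strsplit(p, "", fixed = TRUE)[[1]], AA20)
    if (anyNA(idx)) stopf("non-canonical residue in peptide %s", p)
    sum(pssm[cbind(idx, seq_len(k))])
  }, numeric(1), USE.NAMES = FALSE)
}

surrogate_background <- function(predictor, allele, k) {
  key <- paste0("bg:", allele, ":", k)
  if (!is.null(predictor$cache[[key]])) return(predictor$cache[[key]])
  peps <- with_preserved_seed(predictor$seed * 31L + k, {
    m <- matrix(sample(AA20, predictor$n_background * k, replace = TRUE),
                ncol = k)
    apply(m, 1L, paste, collapse = "")
  })
  sc <- sort(surrogate_peptide_scores(surrogate_pssm(predictor, allele, k), peps))
  predictor$cache[[key]] <- sc
  sc
}

#' Percentile binding ranks for peptide/allele pairs
#'
#' @param predictor A predictor object (e.g.
#'   [surrogate_binding_predictor()]).
#' @param peptides Character vector of peptides.
#' @param alleles Character vector of HLA-I alleles (e.g.
#'   `"HLA-A*02:01"`); every peptide is scored against every allele.
#' @return data.frame `peptide`, `allele`, `rank` (one row per pair).
#' @export
predict_percent_rank <- function(predictor, peptides, alleles) {
  UseMethod("predict_percent_rank")
}

#' @export
predict_percent_rank.surrogate_binder <- function(predictor, peptides, alleles) {
  bad <- !grepl("^HLA-[A-C]\\*\\d{2}:\\d{2,3}$", alleles)
  if (any(bad))
    stopf("malformed HLA allele(s): %s", paste(alleles[bad], collapse = ", "))
  grid <- expand.grid(peptide = peptides, allele = alleles,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  if (nrow(grid) == 0L) {
    grid$rank <- numeric(0)
    return(grid)
  }
  grid$rank <- NA_real_
  for (al in alleles) {
    for (k in unique(nchar(peptides))) {
      sel <- grid$allele == al & nchar(grid$peptide) == k
      if (!any(sel)) next
      pssm <- surrogate_pssm(predictor, al, k)
      bg <- surrogate_background(predictor, al, k)
      sc <- surrogate_peptide_scores(pssm, grid$peptide[sel])
      # percent of background scoring >= peptide (sorted bg: binary search)
      ge <- length(bg) - findInterval(sc - 1e-12, bg)
      grid$rank[sel] <- 100 * ge / length(bg)
    }
  }
  grid
}

#' Parse recorded NetMHCpan-4.0 text output
#'
#' Reads the whitespace-delimited result block of a recorded NetMHCpan run
#' by column name (`Peptide`, `HLA`/`MHC`, `%Rank`/`Rank`), for use as an
#' external predictor backend.
#'
#' @param path Recorded output file.
#' @return data.frame `peptide`, `allele`, `rank`.
#' @export
parse_netmhcpan_output <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  hdr_i <- grep("\\bPeptide\\b", lines)[1]
  if (is.na(hdr_i)) stopf("%s: no header line naming a Peptide column", path)
  hdr <- strsplit(lines[hdr_i], "\\s+")[[1]]
  pep_c <- which(hdr == "Peptide")[1]
  hla_c <- which(hdr %in% c("HLA", "MHC"))[1]
  rank_c <- grep("Rank", hdr)[1]
  if (anyNA(c(pep_c, hla_c, rank_c)))
    stopf("%s: need Peptide, HLA/MHC and %%Rank columns", path)
  body <- lines[-(1:hdr_i)]
  body <- body[nzchar(body) & !grepl("^[-#=]", body)]
  f <- strsplit(body, "\\s+")
  f <- f[lengths(f) >= max(pep_c, hla_c, rank_c)]
  data.frame(peptide = vapply(f, `[[`, "", pep_c),
             allele = vapply(f, `[[`, "", hla_c),
             rank = as.numeric(vapply(f, `[[`, "", rank_c)),
             stringsAsFactors = FALSE)
}

#' Parse recorded NetCTLpan text output
#'
#' Extracts the combined processing score column (`Comb`) together with the
#' peptide and allele from a recorded NetCTLpan run.
#'
#' @param path Recorded output file.
#' @return data.frame `peptide`, `allele`, `C`.
#' @export
parse_netctlpan_output <- function(path) {
  lines <- trimws(readLines(path))
  hdr_i <- grep("\\bPeptide\\b", lines)[1]
  if (is.na(hdr_i)) stopf("%s: no header line naming a Peptide column", path)
  hdr <- strsplit(lines[hdr_i], "\\s+")[[1]]
  pep_c <- which(hdr == "Peptide")[1]
  hla_c <- which(hdr %in% c("Allele", "HLA", "MHC"))[1]
  comb_c <- grep("^Comb", hdr)[1]
  if (anyNA(c(pep_c, hla_c, comb_c)))
    stopf("%s: need Peptide, Allele and Comb columns", path)
  body <- lines[-(1:hdr_i)]
  body <- body[nzchar(body) & !grepl("^[-#=]", body)]
  f <- strsplit(body, "\\s+")
  f <- f[lengths(f) >= max(pep_c, hla_c, comb_c)]
  data.frame(peptide = vapply(f, `[[`, "", pep_c),
             allele = vapply(f, `[[`, "", hla_c),
             C = as.numeric(vapply(f, `[[`, "", comb_c)),
             stringsAsFactors = FALSE)
}

# --- documented constant tables for the processing surrogate ------------

# C-terminal proteasomal cleavage propensity (0-1): the proteasome prefers
# hydrophobic and basic P1 residues and essentially never cuts after Pro.
CLEAVAGE_CTERM <- c(
  A = 0.55, C = 0.45, D = 0.15, E = 0.20, F = 0.90, G = 0.35, H = 0.45,
  I = 0.75, K = 0.80, L = 0.90, M = 0.70, N = 0.30, P = 0.05, Q = 0.35,
  R = 0.75, S = 0.40, T = 0.40, V = 0.70, W = 0.85, Y = 0.85)

# TAP transport efficiency by C-terminal residue (0-1): TAP favors
# hydrophobic and basic C-termini and transports acidic ones poorly.
TAP_CTERM <- c(
  A = 0.50, C = 0.45, D = 0.10, E = 0.15, F = 0.90, G = 0.30, H = 0.50,
  I = 0.80, K = 0.80, L = 0.85, M = 0.70, N = 0.35, P = 0.05, Q = 0.40,
  R = 0.85, S = 0.35, T = 0.40, V = 0.75, W = 0.80, Y = 0.85)
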