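# The immune score schema.
#
# A putative neoantigen (candidate peptide p bound by allele a) is scored
#
#   S = C * L(Rm) * (1 - L(Rn) / 2^M) * H * R
#
# where Rm and Rn are the MHC binding percentile ranks of the candidate and
# of its nearest normal peptide (same allele), M the Hamming mismatch count
# to that normal peptide, C the combined processing (binding + proteasomal
# C-terminal cleavage + TAP transport) score, H a hydrophobicity-based
# presentation propensity, R the T-cell recognition probability from
# similarity to known epitopes, and L the logistic transform
# L(x) = 1 / (1 + exp(5 * (x - 2))) centred on the conventional 2% binder
# threshold. All factors lie in [0, 1], so S does too; the self-similarity
# factor (1 - L(Rn)/2^M) discounts candidates that are close to a
# well-presented normal peptide.

#' Logistic transform of a binding percentile rank
#'
#' `L(x) = 1 / (1 + exp(5 * (x - 2)))`: strictly decreasing, `L(2) = 0.5`.
#'
#' @param x Percentile rank(s).
#' @return Values in (0, 1).
#' @export
logistic_rank <- function(x) 1 / (1 + exp(5 * (x - 2)))

#' Score peptide/allele pairs and retain putative binders
#'
#' Every pair is scored with the predictor; pairs with
#' `rank < rank_threshold` (strict) are the putative neopeptides.
#'
#' @param peptides,alleles Character vectors (full grid is scored).
#' @param predictor Binding predictor ([surrogate_binding_predictor()]).
#' @param rank_threshold Strict upper %rank bound (default 2).
#' @return List with `all` (full rank table) and `retained` (rows with
#'   `rank < rank_threshold`).
#' @export
predict_binding <- function(peptides, alleles, predictor, rank_threshold = 2.0) {
  tab <- predict_percent_rank(predictor, peptides, alleles)
  list(all = tab, retained = tab[tab$rank < rank_threshold, , drop = FALSE])
}

#' Combined processing score C (surrogate)
#'
#' `C = (w_b * (1 - min(Rm, 10)/10) + w_c * cleavage + w_t * tap) / sum(w)`,
#' with the cleavage and TAP terms taken from documented per-residue
#' propensity tables (C-terminal position; the penultimate residue
#' contributes 20% of the cleavage term). Weights default to the
#' binding-dominant convention of combined processing predictors.
#'
#' @param peptides Character vector.
#' @param Rm Binding percentile rank(s) of the peptides.
#' @param weights Named numeric `c(binding=, cleavage=, tap=)`.
#' @return Numeric vector in [0, 1].
#' @export
processing_score_C <- function(peptides, Rm,
                               weights = c(binding = 1, cleavage = 0.225,
                                           tap = 0.025)) {
  last <- substr(peptides, nchar(peptides), nchar(peptides))
  penult <- substr(peptides, nchar(peptides) - 1L, nchar(peptides) - 1L)
  if (anyNA(match(c(last, penult), AA20)))
    stopf("non-canonical residue at peptide C-terminus")
  cleav <- 0.8 * CLEAVAGE_CTERM[last] + 0.2 * CLEAVAGE_CTERM[penult]
  tap <- TAP_CTERM[last]
  bind <- 1 - pmin(Rm, 10) / 10
  unname((weights[["binding"]] * bind + weights[["cleavage"]] * cleav +
            weights[["tap"]] * tap) / sum(weights))
}

# Kyte-Doolittle hydropathy scale.
KYTE_DOOLITTLE <- c(
  A = 1.8, C = 2.5, D = -3.5, E = -3.5, F = 2.8, G = -0.4, H = -3.2,
  I = 4.5, K = -3.9, L = 3.8, M = 1.9, N = -3.5, P = -1.6, Q = -3.5,
  R = -4.5, S = -0.8, T = -0.7, V = 4.2, W = -0.9, Y = -1.3)

#' Hydrophobicity score H (surrogate)
#'
#' Logistic transform of the mean Kyte-Doolittle hydropathy over the
#' TCR-contact positions 3..(k-1): `H = plogis(0.09 + 0.5 * mean_KD)`.
#' The anchor-adjacent positions 1, 2 and k do not contribute. The
#' coefficients place an all-alanine peptide near 0.73.
#'
#' @param peptides Character vector (canonical residues only).
#' @return Numeric vector in (0, 1).
#' @export
hydrophobicity_score_H <- function(peptides) {
  vapply(peptides, function(p) {
    k <- nchar(p)
    aa <- strsplit(p, "", fixed = TRUE)[[1]]
    if (anyNA(match(aa, AA20)))
      stopf("non-canonical residue in peptide %s", p)
    contact <- aa[3:(k - 1L)]
    stats::plogis(0.09 + 0.5 * mean(KYTE_DOOLITTLE[contact]))
  }, numeric(1), USE.NAMES = FALSE)
}

# Best gapless alignment score of two peptides under BLOSUM62: the shorter
# sequence slides along the longer, fully overlapped, and the maximum
# summed substitution score over offsets is returned.
gapless_align_score <- function(p, e, mat = blosum62()) {
  pa <- strsplit(p, "", fixed = TRUE)[[1]]
  ea <- strsplit(e, "", fixed = TRUE)[[1]]
  if (length(pa) > length(ea)) { tmp <- pa; pa <- ea; ea <- tmp }
  ns <- length(pa); nl <- length(ea)
  max(vapply(0:(nl - ns), function(off)
    sum(mat[cbind(pa, ea[(off + 1L):(off + ns)])]), numeric(1)))
}

#' T-cell recognition probability R
#'
#' Epitope-similarity ("fitness") model: for each known epitope e the
#' gapless BLOSUM62 alignment score `|s,e|` is computed and
#' `R = Z / (1 + Z)` with `Z = sum_e exp(k_steep * (|s,e| - a))`, evaluated
#' in log space for numerical stability. High similarity to any known
#' epitope drives R toward 1.
#'
#' @param peptides Character vector of candidates.
#' @param epitopes Non-empty character vector of known epitope sequences.
#' @param a Alignment-score midpoint (default 26).
#' @param k_steep Steepness (default 4.87).
#' @return Numeric vector in (0, 1).
#' @export
recognition_probability_R <- function(peptides, epitopes, a = 26, k_steep = 4.87) {
  if (length(epitopes) == 0L) stopf("epitope library is empty")
  mat <- blosum62()
  vapply(peptides, function(p) {
    terms <- vapply(epitopes, function(e)
      k_steep * (gapless_align_score(p, e, mat) - a), numeric(1))
    stats::plogis(logsumexp(terms))
  }, numeric(1), USE.NAMES = FALSE)
}

#' The immune score S
#'
#' `S = C * L(Rm) * (1 - L(Rn) / 2^M) * H * R` (vectorized).
#'
#' @param Rm,Rn Candidate / normal-peptide binding percentile ranks.
#' @param M Mismatches to the nearest normal peptide (>= 0).
#' @param C,H,R Processing, hydrophobicity and recognition components.
#' @return Numeric score(s).
#' @export
immune_score <- function(Rm, Rn, M, C, H, R) {
  C * logistic_rank(Rm) * (1 - logistic_rank(Rn) / 2^M) * H * R
}

#' Flag high-immunogenicity neopeptides (HIN)
#'
#' @param scores Immune scores.
#' @param hin_cutoff Strict cutoff (default 1e-8).
#' @return Logical: `scores > hin_cutoff`.
#' @export
label_hin <- function(scores, hin_cutoff = 1e-8) scores > hin_cutoff

#' Score a set of candidate peptides end-to-end
#'
#' Runs binding prediction over the candidate x allele grid, keeps putative
#' binders (`Rm < rank_threshold`), attaches each candidate's nearest
#' normal peptide and its same-allele rank `Rn`, computes C, H, R and the
#' immune score, and flags HINs.
#'
#' @param candidates data.frame from [filter_normal_peptides()] (columns
#'   `peptide`, `protein_ids`, `junction_keys`).
#' @param alleles HLA-I alleles.
#' @param index `NormalPeptideIndex` (nearest-normal search).
#' @param epitopes Epitope library (character vector).
#' @param predictor Binding predictor.
#' @param rank_threshold Strict %rank cutoff for putative binders.
#' @param hin_cutoff Strict HIN score cutoff.
#' @return data.frame, one row per retained (peptide, allele) pair:
#'   `peptide`, `allele`, `Rm`, `normal_peptide`, `Rn`, `M`, `C`, `H`, `R`,
#'   `S`, `HIN`, `junction_keys`, `protein_ids`.
#' @export
score_candidates <- function(candidates, alleles, index, epitopes, predictor,
                             rank_threshold = 2.0, hin_cutoff = 1e-8) {
  empty <- data.frame(peptide = character(), allele = character(),
                      Rm = numeric(), normal_peptide = character(),
                      Rn = numeric(), M = integer(), C = numeric(),
                      H = numeric(), R = numeric(), S = numeric(),
                      HIN = logical(), junction_keys = character(),
                      protein_ids = character(), stringsAsFactors = FALSE)
  if (nrow(candidates) == 0L) return(empty)
  bind <- predict_binding(candidates$peptide, alleles, predictor, rank_threshold)
  ret <- bind$retained
  if (nrow(ret) == 0L) return(empty)
  nn <- nearest_normal_batch(unique(ret$peptide), index)
  ret$normal_peptide <- nn$normal_peptide[match(ret$peptide, nn$peptide)]
  ret$M <- nn$M[match(ret$peptide, nn$peptide)]
  # Rn: rank of the normal peptide on the candidate's allele
  ret$Rn <- NA_real_
  for (al in unique(ret$allele)) {
    sel <- ret$allele == al
    ntab <- predict_percent_rank(predictor, unique(ret$normal_peptide[sel]), al)
    ret$Rn[sel] <- ntab$rank[match(ret$normal_peptide[sel], ntab$peptide)]
  }
  ret$C <- processing_score_C(ret$peptide, ret$rank)
  ret$H <- hydrophobicity_score_H(ret$peptide)
  rtab <- recognition_probability_R(unique(ret$peptide), epitopes)
  ret$R <- rtab[match(ret$peptide, unique(ret$peptide))]
  ret$S <- immune_score(ret$rank, ret$Rn, ret$M, ret$C, ret$H, ret$R)
  ret$HIN <- label_hin(ret$S, hin_cutoff)
  prov <- match(ret$peptide, candidates$peptide)
  out <- data.frame(peptide = ret$peptide, allele = ret$allele, Rm = ret$rank,
                    normal_peptide = ret$normal_peptide, Rn = ret$Rn,
                    M = ret$M, C = ret$C, H = ret$H, R = ret$R, S = ret$S,
                    HIN = ret$HIN,
                    junction_keys = candidates$junction_keys[prov],
                    protein_ids = candidates$protein_ids[prov],
                    stringsAsFactors = FALSE)
  out[order(-out$S, out$peptide, out$allele, method = "radix"), , drop = FALSE]
}
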