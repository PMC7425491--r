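test_that("the rank logistic is centred at 2 with the stated steepness", {
  expect_identical(logistic_rank(2), 0.5)
  expect_equal(logistic_rank(0), 1 / (1 + exp(-10)))
  for (d in seq(0.1, 5, by = 0.7))
    expect_equal(logistic_rank(2 - d) + logistic_rank(2 + d), 1,
                 tolerance = 1e-12)
  x <- seq(-5, 10, by = 0.25)
  expect_true(all(diff(logistic_rank(x)) < 0))
})

test_that("the immune score matches its closed form", {
  # direct evaluation: S = C * L(Rm) * (1 - L(Rn)/2^M) * H * R
  s <- immune_score(Rm = 0.5, Rn = 10, M = 3, C = 0.8, H = 0.9, R = 0.7)
  expect_equal(s, 0.8 * logistic_rank(0.5) * (1 - logistic_rank(10) / 8) *
                 0.9 * 0.7, tolerance = 1e-15)
  expect_equal(round(s, 5), 0.50372)
  expect_identical(immune_score(0.5, 10, 3, C = 0, H = 0.9, R = 0.7), 0)
})

test_that("the immune score is decreasing in Rm and increasing in M", {
  Rm <- seq(0, 10, by = 0.5)
  s <- immune_score(Rm, Rn = 1, M = 2, C = 0.8, H = 0.9, R = 0.7)
  expect_true(all(diff(s) < 0))
  s_m <- vapply(1:8, function(m)
    immune_score(0.5, Rn = 1, M = m, C = 0.8, H = 0.9, R = 0.7), numeric(1))
  expect_true(all(diff(s_m) > 0))
  # self-dissimilarity factor lies in (0,1] and saturates at large M
  f <- 1 - logistic_rank(0.1) / 2^(1:60)
  expect_true(all(f > 0 & f <= 1))
  expect_equal(f[60], 1, tolerance = 1e-12)
})

test_that("a dissimilar strong binder outscores a near-self candidate", {
  far <- immune_score(0.5, Rn = 40, M = 6, C = 0.8, H = 0.9, R = 0.7)
  near <- immune_score(0.5, Rn = 0.2, M = 1, C = 0.8, H = 0.9, R = 0.7)
  expect_gt(far, near)
})

test_that("HIN labeling is strict at the cutoff", {
  expect_false(label_hin(1e-8))
  expect_true(label_hin(1.9e-07))
  expect_false(any(label_hin(rep(0, 5))))
})

test_that("surrogate binding ranks are deterministic and the <2 gate is strict", {
  pred <- surrogate_binding_predictor(seed = 5)
  peps <- c("MKANPALTM", "IHFLSLLNF", "AAAAAAAAA", "WWWWWWWWWW")
  res <- predict_binding(peps, c("HLA-A*02:01", "HLA-B*07:02"), pred)
  expect_equal(nrow(res$all), 8)
  expect_true(all(res$all$rank >= 0))
  expect_equal(res$retained, res$all[res$all$rank < 2, ])
  # brute-force filter of the full table is the retained set
  pred2 <- surrogate_binding_predictor(seed = 5)
  res2 <- predict_binding(peps, c("HLA-A*02:01", "HLA-B*07:02"), pred2)
  expect_identical(res$all, res2$all)
  # boundary: a rank of exactly the threshold is not retained
  fake <- res$all
  fake$rank[1] <- 2.0
  expect_false(1 %in% which(fake$rank < 2))
  expect_error(predict_percent_rank(pred, "MKANPALTM", "HLA-A02:01"),
               "malformed")
})

test_that("surrogate ranks are approximately uniform on random peptides", {
  set.seed(77)
  peps <- vapply(1:400, function(i)
    paste(sample(spliceneo:::AA20, 9, replace = TRUE), collapse = ""),
    character(1))
  pred <- surrogate_binding_predictor(seed = 5)
  r <- predict_percent_rank(pred, peps, "HLA-A*02:01")$rank
  expect_gt(mean(r < 2), 0.002)  # some strong binders exist
  expect_lt(mean(r < 2), 0.10)
  expect_gt(mean(r), 35); expect_lt(mean(r), 65)
})

test_that("the processing score C is bounded, monotone in cleavage, and zero at the floor", {
  C <- processing_score_C(c("MKANPALTM", "IHFLSLLNF"), Rm = c(0.1, 5))
  expect_true(all(C >= 0 & C <= 1))
  # C-terminal L cleaves better than C-terminal P
  cl <- processing_score_C(c("AAAAAAAAL", "AAAAAAAAP"), Rm = c(5, 5))
  expect_gt(cl[1], cl[2])
  # with zero cleavage/TAP weight and Rm at the cap, C collapses to zero
  expect_equal(processing_score_C("AAAAAAAAL", Rm = 10,
                                  weights = c(binding = 1, cleavage = 0,
                                              tap = 0)), 0)
})

test_that("recorded NetMHCpan/NetCTLpan outputs parse by column name", {
  mhc <- c("# NetMHCpan version 4.0",
           " Pos          HLA     Peptide       Core Of Gp Gl Ip Il        Icore        Identity   Score %Rank",
           "--------------------------------------------------------------------------------------",
           "   1  HLA-A*02:01   MKANPALTM  MKANPALTM  0  0  0  0  0    MKANPALTM        PEPLIST 0.25000  1.90",
           "   2  HLA-A*02:01   AAAAAAAAA  AAAAAAAAA  0  0  0  0  0    AAAAAAAAA        PEPLIST 0.01000 45.00",
           "--------------------------------------------------------------------------------------")
  tab <- parse_netmhcpan_output(write_tmp(mhc))
  expect_equal(tab$peptide, c("MKANPALTM", "AAAAAAAAA"))
  expect_equal(tab$rank, c(1.9, 45))
  ctl <- c("# NetCTLpan 1.1",
           " Number  Name      Allele      Peptide   MHC   TAP   Cle   Comb  %Rank",
           "----------------------------------------------------------------------",
           "   0  prot1  HLA-A*02:01  MKANPALTM  0.80  0.50  0.90  0.7352  2.00",
           "----------------------------------------------------------------------")
  tab2 <- parse_netctlpan_output(write_tmp(ctl))
  expect_equal(tab2$peptide, "MKANPALTM")
  expect_equal(tab2$C, 0.7352)
})

test_that("hydrophobicity scores live in (0,1), rank I above R, ignore anchors", {
  hI <- hydrophobicity_score_H(strrep("I", 9))
  hR <- hydrophobicity_score_H(strrep("R", 9))
  expect_gt(hI, hR)
  expect_equal(hydrophobicity_score_H(strrep("A", 9)), 0.73, tolerance = 0.01)
  # positions 1, 2 and k are not TCR-contact positions
  expect_equal(hydrophobicity_score_H("WWAAAAAAW"),
               hydrophobicity_score_H("GGAAAAAAG"))
  set.seed(13)
  peps <- vapply(1:300, function(i)
    paste(sample(spliceneo:::AA20, sample(8:11, 1), replace = TRUE),
          collapse = ""), character(1))
  h <- hydrophobicity_score_H(peps)
  expect_true(all(h > 0 & h < 1))
  expect_error(hydrophobicity_score_H("MKANPXLTM"), "non-canonical")
})

test_that("recognition probability matches the epitope-sum closed form", {
  pep <- "MKANPALTM"
  # self-epitope: alignment score far above the midpoint drives R -> 1
  expect_gt(recognition_probability_R(pep, pep), 0.999999)
  # a single unrelated epitope drives R -> 0
  expect_lt(recognition_probability_R(pep, "DDDDDDDDD"), 1e-6)
  # three-epitope toy library vs an independent evaluation of the sum
  library_ <- c("MKANPALTW", "IHFLSLLNF", "MKANPFLTM")
  data(BLOSUM62, package = "Biostrings", envir = environment())
  score_one <- function(p, e) {
    pa <- strsplit(p, "")[[1]]; ea <- strsplit(e, "")[[1]]
    sum(BLOSUM62[cbind(pa, ea)])
  }
  z <- sum(exp(4.87 * (vapply(library_, score_one, numeric(1), p = pep) - 26)))
  expect_equal(recognition_probability_R(pep, library_), z / (1 + z),
               tolerance = 1e-12)
  # unequal lengths: gapless sliding, maximum over offsets
  s_slid <- max(score_one(pep, substr("AMKANPALTMV", 1, 9)),
                score_one(pep, substr("AMKANPALTMV", 2, 10)),
                score_one(pep, substr("AMKANPALTMV", 3, 11)))
  z2 <- exp(4.87 * (s_slid - 26))
  expect_equal(recognition_probability_R(pep, "AMKANPALTMV"), z2 / (1 + z2),
               tolerance = 1e-12)
  expect_error(recognition_probability_R(pep, character(0)), "empty")
})

test_that("score_candidates assembles per-allele rows sorted by score", {
  idx <- build_normal_peptide_index(
    c("MKANPALTMQWERTYIPASDF", "GHKLCVNMTRAEDSAPLIWY"), ks = 9L)
  cands <- data.frame(peptide = c("MKANPALTW", "IHFLSLLNF"), k = 9L,
                      protein_ids = "p1", junction_keys = "j1",
                      stringsAsFactors = FALSE)
  pred <- surrogate_binding_predictor(seed = 5)
  out <- score_candidates(cands, c("HLA-A*02:01", "HLA-B*07:02"), idx,
                          epitopes = c("MKANPALTM", "WYSTRAAGH"),
                          predictor = pred, rank_threshold = 100)
  expect_equal(nrow(out), 4)  # every pair retained at threshold 100
  expect_true(all(diff(out$S) <= 0))
  expect_true(all(out$M >= 1))
  expect_equal(nchar(out$normal_peptide), nchar(out$peptide))
  # S recomputable from its own components
  expect_equal(out$S, immune_score(out$Rm, out$Rn, out$M, out$C, out$H, out$R),
               tolerance = 1e-12)
})
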