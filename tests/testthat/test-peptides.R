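test_that("a frame-preserving exon skip deletes an in-frame protein segment", {
  fx <- toy_three_exon_gene()
  ref <- unname(extract_reference_proteome(list(fx$model), fx$genome))
  j <- list(chrom = "chrT", strand = "+", intron_start = 200L, intron_end = 500L)
  iso <- insert_junction(fx$model, j, 1L)
  pr <- translate_isoform(iso, fx$genome)
  expect_false(is_rejection(pr))
  expect_equal(pr$frame_status, "stop_found")
  # CDS part of exon 1 is 69 nt (23 codons); exon 2 is 90 nt (30 codons)
  expect_equal(pr$sequence, paste0(substr(ref, 1, 23),
                                   substr(ref, 54, nchar(ref))))
  expect_equal(nchar(pr$sequence), nchar(ref) - 30)
})

test_that("a frameshifting shift diverges at the junction codon", {
  fx <- toy_three_exon_gene()
  ref <- unname(extract_reference_proteome(list(fx$model), fx$genome))
  # acceptor shift of 5 bp into exon 2: frameshift after exon 1
  j <- list(chrom = "chrT", strand = "+", intron_start = 200L, intron_end = 305L)
  pr <- translate_isoform(insert_junction(fx$model, j, 2L), fx$genome,
                          min_protein_len = 1L)
  expect_false(is_rejection(pr))
  expect_equal(substr(pr$sequence, 1, 23), substr(ref, 1, 23))
  expect_false(identical(substr(pr$sequence, 24, 24), substr(ref, 24, 24)) &&
                 identical(substr(pr$sequence, 25, 25), substr(ref, 25, 25)))
})

test_that("short proteins are rejected with a strict length threshold", {
  fx <- toy_three_exon_gene()
  j <- list(chrom = "chrT", strand = "+", intron_start = 200L, intron_end = 500L)
  iso <- insert_junction(fx$model, j, 1L)
  pr <- translate_isoform(iso, fx$genome, min_protein_len = 1000L)
  expect_true(is_rejection(pr))
  expect_equal(pr$reason, "short_protein")
  # boundary: a protein of exactly min_protein_len is rejected
  len <- nchar(translate_isoform(iso, fx$genome, min_protein_len = 1L)$sequence)
  expect_equal(translate_isoform(iso, fx$genome, min_protein_len = len)$reason,
               "short_protein")
})

test_that("excising the start codon is a start-lost rejection", {
  fx <- toy_three_exon_gene()
  m2 <- fx$model
  m2$cds_start <- 310L   # start codon now inside exon 2
  j <- list(chrom = "chrT", strand = "+", intron_start = 200L, intron_end = 500L)
  iso <- insert_junction(m2, j, 1L)
  pr <- translate_isoform(iso, fx$genome)
  expect_true(is_rejection(pr))
  expect_equal(pr$reason, "start_lost")
})

test_that("chopping produces every k-mer with its offset", {
  p <- paste(rep("ACDEFGHIKL", 2), collapse = "")   # length 20
  km <- chop_peptides(p, ks = 9L)
  expect_equal(nrow(km), 12)
  expect_equal(km$peptide[1], "ACDEFGHIK")
  expect_equal(km$start, 0:11)
  km2 <- chop_peptides(substr(p, 1, 12), ks = 8:11)
  expect_equal(nrow(km2), sum(12 - 8:11 + 1))
  expect_equal(nrow(chop_peptides("MK", ks = 9L)), 0)
  expect_equal(chop_peptides("MKANPALTM", ks = 9L)$peptide, "MKANPALTM")
})

test_that("normal-peptide subtraction equals the brute-force set difference", {
  set.seed(21)
  normals <- vapply(1:5, function(i)
    paste(sample(AA <- spliceneo:::AA20, 40, replace = TRUE), collapse = ""),
    character(1))
  novel <- paste0(substr(normals[1], 1, 20),
                  paste(sample(spliceneo:::AA20, 12, replace = TRUE), collapse = ""))
  idx <- build_normal_peptide_index(normals, ks = 8:11)
  km <- chop_peptides(novel, ks = 8:11)
  km$protein_id <- "nv1"; km$junction_key <- "jk1"
  out <- filter_normal_peptides(km, idx)
  # brute force: every k-mer of the novel protein not a substring of normals
  brute <- unlist(lapply(8:11, function(k)
    substring(novel, 1:(nchar(novel) - k + 1), k:nchar(novel))))
  brute <- sort(unique(brute[!vapply(brute, function(p)
    any(grepl(p, normals, fixed = TRUE)), logical(1))]), method = "radix")
  expect_equal(out$peptide, brute)
  expect_false(any(index_has_peptide(idx, out$peptide)))
})

test_that("survivors are deduplicated with merged provenance", {
  idx <- build_normal_peptide_index("WWWWWWWWWWWW", ks = 9L)
  km <- data.frame(peptide = c("MKANPALTM", "MKANPALTM", "AAAAAAAAC"),
                   k = 9L, start = 0L,
                   protein_id = c("p1", "p2", "p1"),
                   junction_key = c("j1", "j2", "j1"),
                   stringsAsFactors = FALSE)
  out <- filter_normal_peptides(km, idx)
  expect_equal(nrow(out), 2)
  expect_equal(out$protein_ids[out$peptide == "MKANPALTM"], "p1,p2")
  expect_equal(out$junction_keys[out$peptide == "MKANPALTM"], "j1,j2")
})

test_that("peptides containing non-canonical residues are dropped", {
  idx <- build_normal_peptide_index("WWWWWWWWWWWW", ks = 9L)
  km <- data.frame(peptide = c("MKANPXLTM", "MKANPALTM"), k = 9L, start = 0L,
                   stringsAsFactors = FALSE)
  expect_equal(filter_normal_peptides(km, idx)$peptide, "MKANPALTM")
})

test_that("nearest normal peptide minimizes Hamming distance with lexicographic ties", {
  idx <- build_normal_peptide_index(c("MKANPALTMQ", "MKCNPALTMQ"), ks = 9L)
  # one mismatch from MKANPALTM
  nn <- nearest_normal_peptide("MKANPALTW", idx)
  expect_equal(nn$peptide, "MKANPALTM")
  expect_equal(nn$M, 1L)
  # MKWNPALTM is 1 mismatch from both MKANPALTM and MKCNPALTM: the
  # lexicographically smaller window wins the tie
  nn2 <- nearest_normal_peptide("MKWNPALTM", idx)
  expect_equal(nn2$peptide, "MKANPALTM")
  expect_equal(nn2$M, 1L)
  expect_error(nearest_normal_peptide("MKANPALTM", idx), "normal peptide")
})

test_that("nearest-normal search is invariant to protein scan order", {
  set.seed(31)
  prots <- vapply(1:6, function(i)
    paste(sample(spliceneo:::AA20, 30, replace = TRUE), collapse = ""),
    character(1))
  idx1 <- build_normal_peptide_index(prots, ks = 9L)
  idx2 <- build_normal_peptide_index(rev(prots), ks = 9L)
  for (i in 1:20) {
    cand <- paste(sample(spliceneo:::AA20, 9, replace = TRUE), collapse = "")
    if (index_has_peptide(idx1, cand)) next
    expect_identical(nearest_normal_peptide(cand, idx1),
                     nearest_normal_peptide(cand, idx2))
  }
})
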