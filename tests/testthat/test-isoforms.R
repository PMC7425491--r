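# 4-exon toy model used throughout: exons [0,100) [200,300) [400,500) [600,700)
toy4 <- transcript_model("tx4", "g4", "c1", "+",
                         exon_starts = c(0L, 200L, 400L, 600L),
                         exon_ends = c(100L, 300L, 500L, 700L),
                         cds_start = 10L, cds_end = 690L)

test_that("junction tags follow the annotated-site rules", {
  tag_of <- function(a, b)
    map_junction_to_isoforms(list(chrom = "c1", strand = "+",
                                  intron_start = a, intron_end = b),
                             list(toy4))$tag
  expect_equal(tag_of(100L, 200L), 0L)   # an existing intron
  expect_equal(tag_of(100L, 400L), 1L)   # skips exon 2
  expect_equal(tag_of(100L, 250L), 2L)   # acceptor inside exon 2
  expect_equal(tag_of(420L, 460L), 3L)   # both sites inside exon 3
})

test_that("tag classification is exhaustive, exclusive, and matches set-rule labels", {
  # enumerate a <  b over a position grid covering boundaries, exon
  # interiors and intron interiors
  grid <- sort(unique(c(toy4$exon_starts, toy4$exon_ends,
                        toy4$exon_starts + 37L, toy4$exon_ends + 41L,
                        toy4$exon_starts - 13L, 50L, 450L)))
  grid <- grid[grid >= 0L & grid <= 700L]
  introns <- paste(c(100L, 300L, 500L), c(200L, 400L, 600L))
  n_checked <- 0L
  for (a in grid) for (b in grid) {
    if (b <= a) next
    pl <- map_junction_to_isoforms(list(chrom = "c1", strand = "+",
                                        intron_start = a, intron_end = b),
                                   list(toy4))
    expect_equal(nrow(pl), 1L)
    # independent labels straight from the definitions
    up <- a %in% toy4$exon_ends
    down <- b %in% toy4$exon_starts
    expected <- if (paste(a, b) %in% introns) 0L
    else if (up && down) 1L else if (up || down) 2L else 3L
    expect_identical(pl$tag, expected)
    n_checked <- n_checked + 1L
  }
  expect_gt(n_checked, 100L)
})

test_that("junctions outside a transcript span or on the wrong strand do not map", {
  j_out <- list(chrom = "c1", strand = "+", intron_start = 650L, intron_end = 900L)
  expect_equal(nrow(map_junction_to_isoforms(j_out, list(toy4))), 0L)
  j_minus <- list(chrom = "c1", strand = "-", intron_start = 100L, intron_end = 200L)
  expect_equal(nrow(map_junction_to_isoforms(j_minus, list(toy4))), 0L)
  j_unknown <- list(chrom = "c1", strand = "*", intron_start = 100L, intron_end = 200L)
  expect_equal(nrow(map_junction_to_isoforms(j_unknown, list(toy4))), 1L)
})

test_that("host selection keeps the smallest tag and applies the strict RPKM gate", {
  pl <- data.frame(key = "k", transcript_id = c("t1", "t2", "t3"),
                   model_i = 1:3, tag = c(1L, 2L, 2L),
                   donor_annotated = TRUE, acceptor_annotated = TRUE,
                   stringsAsFactors = FALSE)
  sel <- select_hosts(pl, c(t1 = 5, t2 = 5, t3 = 5))
  expect_equal(sel$selected$transcript_id, "t1")

  # rpkm exactly at the threshold is removed (strict >)
  sel2 <- select_hosts(pl[1, ], c(t1 = 1.0))
  expect_equal(nrow(sel2$selected), 0L)
  expect_equal(sel2$reason, "low_rpkm")

  # a tag-0 placement anywhere marks the junction annotated-in-context
  pl0 <- pl; pl0$tag <- c(0L, 2L, 2L)
  sel3 <- select_hosts(pl0, c(t1 = 5, t2 = 5, t3 = 5))
  expect_equal(nrow(sel3$selected), 0L)
  expect_equal(sel3$reason, "annotated")

  # missing rpkm counts as zero
  sel4 <- select_hosts(pl[1, ], c(other = 5))
  expect_equal(sel4$reason, "low_rpkm")
})

test_that("RPKM follows its defining formula", {
  m <- transcript_model("t", "g", "c", "+", 0L, 1000L)
  expect_equal(compute_rpkm(m, 1000L, 1e7), 100)
  expect_equal(compute_rpkm(m, 0L, 1e7), 0)
  expect_equal(compute_rpkm(m, 1000L, 2e7), 50)
  expect_error(compute_rpkm(m, 10L, 0), "positive")
})

jx <- function(a, b) list(chrom = "c1", strand = "+",
                          intron_start = a, intron_end = b)

test_that("tag-1 insertion removes the skipped exons and keeps the CDS anchors", {
  iso <- insert_junction(toy4, jx(100L, 400L), 1L)
  expect_false(is_rejection(iso))
  expect_equal(iso$exon_starts, c(0L, 400L, 600L))
  expect_equal(iso$exon_ends, c(100L, 500L, 700L))
  expect_equal(iso$cds_start, 10L)
  # intron set = host introns minus skipped plus the novel junction
  got <- paste(iso$exon_ends[-3], iso$exon_starts[-1])
  expect_setequal(got, c("100 400", "500 600"))
})

test_that("tag-2 insertion shifts one boundary within the 2-250 bp window", {
  iso <- insert_junction(toy4, jx(100L, 250L), 2L)
  expect_equal(iso$exon_starts, c(0L, 250L, 400L, 600L))
  expect_equal(sum(iso$exon_ends - iso$exon_starts),
               sum(toy4$exon_ends - toy4$exon_starts) - 50L)

  expect_equal(insert_junction(toy4, jx(100L, 201L), 2L)$reason, "exon_mod")   # d = 1
  expect_false(is_rejection(insert_junction(toy4, jx(100L, 202L), 2L)))        # d = 2
  # donor-side shift: exon 1 end moves to 55, d = 45 -> allowed
  expect_false(is_rejection(insert_junction(toy4, jx(55L, 200L), 2L)))
  # a shift larger than 250 bp is rejected
  wide <- transcript_model("tw", "g", "c1", "+", c(0L, 600L), c(400L, 700L),
                           cds_start = 10L, cds_end = 690L)
  expect_equal(insert_junction(wide, jx(49L, 600L), 2L)$reason, "exon_mod")    # d = 351
})

test_that("tag-3 insertion splits one exon only for introns longer than 50 bp", {
  expect_equal(insert_junction(toy4, jx(420L, 470L), 3L)$reason, "intron_length")
  iso <- insert_junction(toy4, jx(420L, 471L), 3L)
  expect_false(is_rejection(iso))
  expect_equal(iso$exon_starts, c(0L, 200L, 400L, 471L, 600L))
  expect_equal(iso$exon_ends, c(100L, 300L, 420L, 500L, 700L))
  expect_equal(sum(iso$exon_ends - iso$exon_starts),
               sum(toy4$exon_ends - toy4$exon_starts) - 51L)
})

test_that("insertions outside the CDS or in introns are rejected with reasons", {
  utr <- transcript_model("tu", "g", "c1", "+",
                          exon_starts = c(0L, 200L, 400L),
                          exon_ends = c(100L, 300L, 500L),
                          cds_start = 10L, cds_end = 80L)
  expect_equal(insert_junction(utr, jx(200L, 250L), 2L)$reason, "non_coding")
  expect_equal(insert_junction(toy4, jx(100L, 150L), 2L)$reason, "site_in_intron")
  expect_equal(insert_junction(toy4, jx(250L, 450L), 3L)$reason, "tag3_multi_exon")
  nc <- transcript_model("tn", "g", "c1", "+", 0L, 700L)
  expect_equal(insert_junction(nc, jx(100L, 200L), 3L)$reason, "non_coding")
  expect_error(insert_junction(toy4, jx(100L, 900L), 1L), "outside")
})

test_that("novel isoforms never contain overlapping exons", {
  cases <- list(c(100L, 400L, 1L), c(100L, 250L, 2L), c(420L, 480L, 3L),
                c(100L, 600L, 1L), c(30L, 400L, 2L))
  for (cs in cases) {
    iso <- insert_junction(toy4, jx(cs[1], cs[2]), cs[3])
    if (is_rejection(iso)) next
    expect_true(all(iso$exon_ends > iso$exon_starts))
    n <- length(iso$exon_starts)
    expect_true(all(iso$exon_starts[-1] >= iso$exon_ends[-n]))
  }
})
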