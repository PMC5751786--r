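ref_toy <- mk_anno(
  simple_tx("refPCG.1", "chr1", "+", list(c(150, 250), c(400, 500)),
            biotype = "protein_coding"),
  simple_tx("refPCGm.1", "chr1", "-", list(c(1150, 1250)),
            biotype = "protein_coding"),
  simple_tx("refLNC.1", "chr1", "+", list(c(2000, 2400)), biotype = "lncRNA"))

test_that("transcript classes follow the precedence order", {
  q <- mk_anno(
    simple_tx("a.1", "chr1", "+", list(c(100, 200)), biotype = "unknown"),
    simple_tx("b.1", "chr1", "+", list(c(1100, 1200)), biotype = "unknown"),
    simple_tx("c.1", "chr1", "+", list(c(2100, 2300)), biotype = "unknown"),
    simple_tx("d.1", "chr1", "+", list(c(5000, 5400)), biotype = "unknown"),
    simple_tx("e.1", "chr1", "+", list(c(5000, 5100), c(5300, 5400)),
              biotype = "unknown"),
    simple_tx("f.1", "chr1", "+", list(c(300, 320)), biotype = "unknown"))
  cls <- classify_transcripts(q, ref_toy)
  expect_equal(unname(cls[c("a.1", "b.1", "c.1", "d.1", "e.1")]),
               c("pcg_overlap",         # same-strand exon overlap with PCG
                 "antisense_overlap",   # opposite strand only
                 "known_lncrna_match",  # same-strand overlap with lncRNA
                 "single_exon_novel",   # no exonic overlap, one exon
                 "multi_exon_novel"))
  # intron-contained: no exonic overlap, falls through to novel
  expect_equal(unname(cls["f.1"]), "single_exon_novel")
})

test_that("chromosomes absent from the reference classify as novel with a message", {
  q <- mk_anno(simple_tx("x.1", "chrZ", "+", list(c(0, 300), c(400, 500)),
                         biotype = "unknown"))
  expect_message(cls <- classify_transcripts(q, ref_toy), "chrZ")
  expect_equal(unname(cls["x.1"]), "multi_exon_novel")
})

test_that("the filter cascade keeps exactly the passing transcripts", {
  # one transcript per removal reason plus boundary and all-pass cases
  q <- mk_anno(
    simple_tx("short.1", "chr1", "+", list(c(5000, 5150)), biotype = "unknown"),
    simple_tx("coding.1", "chr1", "+", list(c(6000, 6150), c(6200, 6400)),
              biotype = "unknown"),
    simple_tx("silent.1", "chr1", "+", list(c(7000, 7150), c(7200, 7400)),
              biotype = "unknown"),
    simple_tx("anti.1", "chr1", "+", list(c(1100, 1300)), biotype = "unknown"),
    simple_tx("single.1", "chr1", "+", list(c(8000, 8400)), biotype = "unknown"),
    simple_tx("pcgov.1", "chr1", "+", list(c(100, 250), c(400, 500)),
              biotype = "unknown"),
    simple_tx("bound.1", "chr1", "+", list(c(9000, 9100), c(9200, 9300)),
              biotype = "unknown"),
    simple_tx("pass.1", "chr1", "+", list(c(10000, 10250), c(10300, 10550)),
              biotype = "unknown"),
    simple_tx("known.1", "chr1", "+", list(c(2000, 2400)), biotype = "unknown"))
  scores <- c(short.1 = 0.1, coding.1 = 0.6, silent.1 = 0.2, anti.1 = 0.1,
              single.1 = 0.1, pcgov.1 = 0.1, bound.1 = 0.5, pass.1 = 0.2,
              known.1 = 0.1)
  v <- matrix(1, nrow = 8, ncol = 2,
              dimnames = list(setdiff(names(scores), "silent.1"),
                              c("s1", "s2")))
  expr <- mk_expr(v)
  res <- filter_lncrna_candidates(q, scores, expr, ref_toy)
  expect_setequal(res$kept, c("bound.1", "pass.1", "known.1"))
  reasons <- stats::setNames(res$report$removal_reason,
                             res$report$transcript_id)
  expect_equal(unname(reasons[c("short.1", "coding.1", "silent.1", "anti.1",
                                "single.1", "pcgov.1")]),
               c("too_short", "coding", "not_expressed", "class", "class",
                 "class"))
  # boundary semantics: length exactly 200 and score exactly 0.5 are kept
  bnd <- res$report[res$report$transcript_id == "bound.1", ]
  expect_equal(bnd$spliced_length, 200)
  expect_equal(bnd$coding_potential, 0.5)
  expect_true(bnd$kept)
  # removal_reason records the FIRST failing rule: short + coding -> too_short
  q2 <- mk_anno(simple_tx("sc.1", "chr1", "+", list(c(5000, 5100)),
                          biotype = "unknown"))
  r2 <- filter_lncrna_candidates(q2, c(sc.1 = 0.9), NULL, ref_toy)
  expect_equal(r2$report$removal_reason, "too_short")
  # missing coding score names the transcript
  expect_error(filter_lncrna_candidates(q2, c(other = 0.1), NULL, ref_toy),
               "sc.1")
})

test_that("identical intron chains deduplicate, preferring the annotated id", {
  q <- mk_anno(
    simple_tx("refLNC.1", "chr1", "+", list(c(2000, 2400)), biotype = "unknown"),
    simple_tx("asm.1", "chr1", "+", list(c(2000, 2400)), biotype = "unknown"))
  scores <- c(refLNC.1 = 0.1, asm.1 = 0.1)
  v <- matrix(1, 2, 1, dimnames = list(names(scores), "s1"))
  res <- filter_lncrna_candidates(q, scores, mk_expr(v), ref_toy)
  expect_equal(res$kept, "refLNC.1")
  expect_equal(res$report$removal_reason[res$report$transcript_id == "asm.1"],
               "duplicate")
})

test_that("family grouping is single-linkage, strand-restricted", {
  # [100,500)+ and [400,900)+ chain into one family spanning [100,900)
  a <- mk_anno(simple_tx("A.1", "chr1", "+", list(c(100, 500))),
               simple_tx("B.1", "chr1", "+", list(c(400, 900))),
               simple_tx("C.1", "chr1", "-", list(c(400, 900))))
  fam <- group_families(a)
  expect_equal(nrow(fam$families), 2L)
  plus <- fam$families[fam$families$strand == "+", ]
  expect_equal(c(plus$start, plus$end), c(100, 900))
  expect_equal(plus$n_members, 2L)
  # transitive chain A-B, B-C, with A and C disjoint -> one family
  b <- mk_anno(simple_tx("A.1", "chr1", "+", list(c(0, 300))),
               simple_tx("B.1", "chr1", "+", list(c(250, 600))),
               simple_tx("C.1", "chr1", "+", list(c(550, 900))))
  fam2 <- group_families(b)
  expect_equal(nrow(fam2$families), 1L)
  expect_equal(sort(fam2$members$transcript_id), c("A.1", "B.1", "C.1"))
  # book-ended spans (zero overlap) stay separate
  c3 <- mk_anno(simple_tx("A.1", "chr1", "+", list(c(0, 300))),
                simple_tx("B.1", "chr1", "+", list(c(300, 600))))
  expect_equal(nrow(group_families(c3)$families), 2L)
})

test_that("families partition the kept set on synthetic data", {
  g <- generate_genomes(small_config(seed = 2))
  lnc <- subset_transcripts(g$assembled_a,
                            c(g$truth$lnc_tx_a, g$truth$multi_isoform_lnc_a))
  fam <- group_families(lnc)
  expect_setequal(fam$members$transcript_id, lnc$transcripts$transcript_id)
  expect_equal(anyDuplicated(fam$members$transcript_id), 0L)
  # multi-isoform loci collapse into one family each
  multi <- fam$members[fam$members$transcript_id %in%
                         g$truth$multi_isoform_lnc_a, ]
  first <- sub("\\.2$", ".1", multi$transcript_id)
  expect_equal(multi$family_id,
               fam$members$family_id[match(first, fam$members$transcript_id)])
})
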