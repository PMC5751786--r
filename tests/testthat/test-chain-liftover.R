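test_that("chain files parse with validated headers and blocks", {
  f <- withr::local_tempfile(fileext = ".chain")
  writeLines(c("chain 100 chrA 1000 + 0 1000 chrB 1000 + 0 1000 1",
               "1000", "",
               "chain 50 chrA 1000 + 0 300 chrB 1000 - 0 350 2",
               "100\t50\t100", "150", ""), f)
  chains <- read_chain(f)
  expect_length(chains, 2L)
  expect_equal(nrow(chains[[1]]$blocks), 1L)
  expect_equal(chains[[2]]$blocks$size, c(100, 150))
  expect_equal(chains[[2]]$q_strand, "-")
  # block sums disagreeing with the header span name the chain id
  writeLines(c("chain 100 chrA 1000 + 0 900 chrB 1000 + 0 1000 7", "1000", ""), f)
  expect_error(read_chain(f), "chain 7")
})

test_that("chain write/read round trip preserves every field", {
  set.seed(41)
  chains <- lapply(1:5, function(i) rand_chain(as.character(i)))
  f <- withr::local_tempfile(fileext = ".chain")
  write_chain(chains, f)
  back <- read_chain(f)
  expect_equal(back, chains)
})

test_that("identity chain maps intervals onto themselves", {
  ch <- chain(100, "chrA", 1000, 0, 1000, "chrB", 1000, "+", 0, 1000,
              data.frame(size = 1000, dt = 0, dq = 0), "1")
  r <- lift_interval(genome_interval("chrA", 100, 200, "+"), list(ch))
  expect_equal(r$status, "mapped")
  expect_equal(c(r$mapped$start, r$mapped$end), c(100, 200))
  expect_equal(r$mapped$strand, "+")
  expect_equal(r$match_fraction, 1.0)
})

test_that("reverse-strand chains emit forward coordinates with flipped strand", {
  # single block t:[0,1000) -> q:[0,1000) on the reversed strand, q_size 1000
  ch <- chain(100, "chrA", 1000, 0, 1000, "chrB", 1000, "-", 0, 1000,
              data.frame(size = 1000, dt = 0, dq = 0), "1")
  r <- lift_interval(genome_interval("chrA", 100, 200, "+"), list(ch))
  expect_equal(r$status, "mapped")
  expect_equal(c(r$mapped$start, r$mapped$end), c(800, 900))
  expect_equal(r$mapped$strand, "-")
  expect_equal(r$match_fraction, 1.0)
})

test_that("gapped chains yield partial status below min_match with no interval", {
  # blocks t[0,100)->q[0,100), target gap 100, t[200,300)->q[100,200)
  ch <- chain(100, "chrA", 1000, 0, 300, "chrB", 1000, "+", 0, 200,
              data.frame(size = c(100, 100), dt = c(100, 0), dq = c(0, 0)), "1")
  r <- lift_interval(genome_interval("chrA", 50, 250, "+"), list(ch))
  expect_equal(r$status, "partial")
  expect_equal(r$match_fraction, 0.5)
  expect_null(r$mapped)
})

test_that("transcript lifts carry ids, compose strands, and report unmapped", {
  ch <- chain(100, "chrA", 1000, 0, 1000, "chrB", 1000, "+", 0, 1000,
              data.frame(size = 1000, dt = 0, dq = 0), "1")
  anno <- mk_anno(
    simple_tx("in.1", "chrA", "-", list(c(100, 200), c(300, 400))),
    simple_tx("off.1", "chrZ", "+", list(c(100, 400))))
  res <- lift_transcripts(anno, list(ch))
  expect_equal(res[["in.1"]]$status, "mapped")
  expect_equal(res[["in.1"]]$match_fraction, 1.0)
  expect_equal(res[["in.1"]]$mapped$strand, "-")  # '-' query through '+' chain
  expect_equal(c(res[["in.1"]]$mapped$start, res[["in.1"]]$mapped$end),
               c(100, 400))
  expect_equal(res[["off.1"]]$status, "unmapped")
})

test_that("lift_interval agrees with the per-base brute-force mapper", {
  set.seed(17)
  for (rep in 1:40) {
    chains <- lapply(seq_len(sample(1:3, 1)), function(i)
      rand_chain(as.character(i)))
    for (j in 1:10) {
      s <- sample(0:9800, 1)
      iv <- genome_interval("chrT", s, s + sample(10:300, 1),
                            sample(c("+", "-", "."), 1))
      got <- lift_interval(iv, chains)
      exp <- brute_lift(iv, chains)
      expect_equal(got$status, exp$status)
      expect_equal(got$match_fraction, exp$match_fraction)
      if (got$status == "mapped") {
        expect_equal(got$mapped$start, exp$mapped$start)
        expect_equal(got$mapped$end, exp$mapped$end)
        expect_equal(got$mapped$strand, exp$mapped$strand)
      }
    }
  }
})

test_that("fully-contained intervals round-trip through the inverted chain", {
  set.seed(23)
  for (rep in 1:60) {
    ch <- rand_chain("c")
    inv <- invert_chain(ch)
    co <- ch$blocks
    # pick a random sub-interval of a random aligned block
    t0 <- ch$t_start + cumsum(c(0, (co$size + co$dt)[-nrow(co)]))
    b <- sample(nrow(co), 1)
    if (co$size[b] < 4) next
    a <- t0[b] + sample(0:(co$size[b] - 3), 1)
    iv <- genome_interval("chrT", a, a + sample(2:(co$size[b] - (a - t0[b])), 1), "+")
    fwd <- lift_interval(iv, list(ch))
    expect_equal(fwd$status, "mapped")
    back <- lift_interval(fwd$mapped, list(inv))
    expect_equal(back$status, "mapped")
    expect_equal(back$mapped$start, iv$start)
    expect_equal(back$mapped$end, iv$end)
    expect_equal(back$mapped$strand, "+")
  }
})

test_that("mapping is monotone within a forward-strand chain", {
  set.seed(29)
  for (rep in 1:20) {
    ch <- rand_chain("c")
    if (ch$q_strand == "-") next
    xs <- sort(sample(ch$t_start:(ch$t_end - 2), 4))
    a <- genome_interval("chrT", xs[1], xs[2] + 1, "+")
    b <- genome_interval("chrT", xs[3] + 1, xs[4] + 2, "+")
    ra <- lift_interval(a, list(ch), min_match = 1e-9)
    rb <- lift_interval(b, list(ch), min_match = 1e-9)
    if (ra$status == "mapped" && rb$status == "mapped")
      expect_lte(ra$mapped$end, rb$mapped$start)
  }
})

test_that("ambiguous status arises when two chains both reach min_match", {
  mk <- function(id, score, q_off) chain(score, "chrA", 1000, 0, 1000,
    "chrB", 2000, "+", q_off, q_off + 1000,
    data.frame(size = 1000, dt = 0, dq = 0), id)
  r <- lift_interval(genome_interval("chrA", 10, 20, "+"),
                     list(mk("1", 100, 0), mk("2", 50, 500)))
  expect_equal(r$status, "ambiguous")
  expect_equal(r$chain_id, "1")  # reported through the higher-scoring chain
})

test_that("BED batch lifting writes mapped intervals", {
  ch <- chain(100, "chrA", 1000, 0, 1000, "chrB", 1000, "-", 0, 1000,
              data.frame(size = 1000, dt = 0, dq = 0), "1")
  fin <- withr::local_tempfile(fileext = ".bed")
  fout <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chrA\t100\t200\tx\t0\t+", "chrZ\t0\t50\ty\t0\t+"), fin)
  res <- lift_bed(fin, list(ch), fout)
  expect_equal(res$status, c("mapped", "unmapped"))
  out <- read.table(fout, sep = "\t")
  expect_equal(unlist(out[1, 1:4], use.names = FALSE),
               c("chrB", "800", "900", "x"))
})
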