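test_that("generator honors the planted counts and distances", {
  cfg <- synthetic_config(seed = 3, n_conserved_lnc = 10, n_bidirectional = 3,
                          bidirectional_distances = c(500, 2000, 2001),
                          n_monotone_up = 4, n_monotone_down = 3)
  g <- generate_genomes(cfg)
  tr <- g$truth
  expect_equal(nrow(tr$conserved_pairs), 10L)
  expect_equal(length(g$chains), 10L)
  a_bid <- tr$bidirectional_pairs[tr$bidirectional_pairs$genome == "A", ]
  expect_equal(nrow(a_bid), 3L)
  expect_equal(a_bid$distance, c(500, 2000, 2001))
  expect_equal(sum(tr$trend_labels$trend == "up"), 4L)
  expect_equal(sum(tr$trend_labels$trend == "down"), 3L)
  # every id in the truth exists in the emitted annotations
  all_ids <- c(g$assembled_a$transcripts$transcript_id,
               g$ref_a$transcripts$transcript_id,
               g$anno_b$transcripts$transcript_id)
  expect_true(all(tr$conserved_pairs$a_id %in% all_ids))
  expect_true(all(tr$conserved_pairs$b_id %in% all_ids))
  expect_true(all(tr$bidirectional_pairs$lncrna_id %in% all_ids))
  expect_true(all(tr$bidirectional_pairs$pcg_id %in% all_ids))
})

test_that("identical seeds give byte-identical study artifacts", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  simulate_study(small_config(seed = 5), d1)
  simulate_study(small_config(seed = 5), d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = paste("md5 of", f))
  }
})

test_that("planted gene loci never overlap within a genome", {
  g <- generate_genomes(small_config(seed = 9))
  for (anno in list(g$anno_b)) {
    tx <- anno$transcripts
    for (ch in unique(tx$chrom)) {
      sub <- tx[tx$chrom == ch, ]
      sub <- sub[order(sub$start), ]
      # bidirectional partners share a slot but must not overlap either
      expect_true(all(sub$start[-1] >= sub$end[-nrow(sub)]))
    }
  }
})

test_that("module expression hits the target correlation structure", {
  cfg <- synthetic_config(seed = 21, within_module_cor = 0.9, noise_sd = 0.1,
                          n_samples = 50)
  g <- generate_genomes(cfg)
  em <- generate_expression(cfg, g$truth, "A")
  expect_true(all(em$values >= 0))
  ma <- g$truth$module_assignment
  within <- numeric(0)
  for (m in unique(ma$module)) {
    cc <- cor(t(em$values[ma$id[ma$module == m], ]))
    within <- c(within, cc[upper.tri(cc)])
  }
  expect_gt(mean(within), 0.8)
  expect_lt(mean(within), 0.95)
  # between-module correlation centred at zero
  m1 <- ma$id[ma$module == 1]; m2 <- ma$id[ma$module == 2]
  between <- cor(t(em$values[m1, ]), t(em$values[m2, ]))
  expect_lt(abs(mean(between)), 0.15)
})

test_that("zero within-module correlation leaves genes uncorrelated", {
  cfg <- synthetic_config(seed = 22, within_module_cor = 0, n_samples = 100)
  g <- generate_genomes(cfg)
  em <- generate_expression(cfg, g$truth, "A")
  ids <- sample(rownames(em$values), 40)
  cc <- cor(t(em$values[ids, ]))
  expect_lt(mean(abs(cc[upper.tri(cc)])), 0.2)
})

test_that("temporal plants are exactly monotone when noiseless", {
  cfg <- small_config(seed = 13, temporal_noise_sd = 0)
  g <- generate_genomes(cfg)
  tm <- generate_temporal(cfg, g$truth)
  sm <- stage_expression(tm, cfg$stages)
  calls <- classify_trend(sm)
  tr <- stats::setNames(g$truth$trend_labels$trend, g$truth$trend_labels$b_id)
  expect_equal(unname(calls[names(tr)]), unname(tr))
  # planted up genes have strictly increasing stage means
  up1 <- names(tr)[tr == "up"][1]
  expect_true(all(diff(sm[up1, ]) > 0))
  # everything not planted is flat, hence 'none'
  others <- setdiff(rownames(sm), names(tr))
  expect_true(all(calls[others] == "none"))
})

test_that("GO plants enrich at the configured fold over background", {
  cfg <- synthetic_config(seed = 31, go_background_rate = 0.02,
                          n_pcg = 200, module_size = 52, chrom_length = 1.5e6,
                          enriched_terms = data.frame(term = "GO:0000001",
                                                      module = 1, fold = 10))
  g <- generate_genomes(cfg)
  ma <- g$truth$module_assignment
  mod_pcg <- ma$id[ma$module == 1 & ma$node_type == "PCG"]  # 50 genes
  n_out <- length(setdiff(g$truth$pcg_tx_a, mod_pcg))
  k_in <- k_out <- numeric(5)
  for (s in 1:5) {
    cfg$seed <- 30L + s
    go <- generate_go(cfg, g$truth)
    members <- go$gene_id[go$term_id == "GO:0000001"]
    k_in[s] <- length(intersect(members, mod_pcg))
    k_out[s] <- length(setdiff(members, mod_pcg))
  }
  # binomial expectations: ~0.2 * 50 = 10 inside, rate ~0.02 outside
  expect_gt(mean(k_in), 6); expect_lt(mean(k_in), 14)
  expect_lt(mean(k_out / n_out), 0.05)
  # invalid fold is rejected up front
  expect_error(synthetic_config(go_background_rate = 0.2,
                                enriched_terms = data.frame(term = "t",
                                                            module = 1,
                                                            fold = 10)),
               "exceeds 1")
})

test_that("conservation track plants its group means", {
  cfg <- small_config(seed = 8)
  g <- generate_genomes(cfg)
  # noiseless: every PCG exon base scores exactly the PCG mean
  tr0 <- generate_conservation_track(cfg, g, noise_sd = 0)
  pcg_ids <- g$ref_a$transcripts$transcript_id[
    g$ref_a$transcripts$biotype == "protein_coding"]
  s0 <- suppressWarnings(transcript_score(g$ref_a, tr0, ids = pcg_ids))
  expect_true(all(abs(s0 - 0.6) < 1e-12))
  # noisy track: group means recovered within 0.02, all scores in [0, 1]
  trk <- generate_conservation_track(cfg, g)
  expect_true(all(trk$score >= 0 & trk$score <= 1))
  lnc <- suppressWarnings(transcript_score(
    g$assembled_a, trk, ids = g$truth$lnc_tx_a))
  expect_lt(abs(mean(lnc, na.rm = TRUE) - 0.4), 0.02)
  pcg <- suppressWarnings(transcript_score(g$ref_a, trk, ids = pcg_ids))
  expect_lt(abs(mean(pcg, na.rm = TRUE) - 0.6), 0.02)
})

test_that("generator rejects configurations it cannot honor", {
  expect_error(synthetic_config(n_conserved_lnc = 10, n_lncrna = 5),
               "n_conserved_lnc")
  expect_error(synthetic_config(n_samples = 2) |>
                 (\(cfg) generate_expression(cfg, generate_genomes(cfg)$truth))(),
               "n_samples")
  expect_error(generate_genomes(synthetic_config(chrom_length = 5e4)),
               "cannot place")
})
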