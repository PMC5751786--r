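#' Collect the three evidence streams into a family-level table
#'
#' A family carries an evidence flag iff at least one member carries the
#' corresponding evidence: `coexpression` (member annotated with an
#' enriched module term), `bidirectional` (member in a divergent
#' lncRNA-PCG pair), `temporal` (member's conserved partner has a monotone
#' trend). A family is `annotated` iff any flag is set. Evidence
#' referencing a transcript outside every family raises a consistency
#' error.
#'
#' @param families Family grouping from [group_families()].
#' @param lnc_annotations data.frame(lncrna_id, term_id, ...) from
#'   [annotate_lncrnas()].
#' @param bidir_pairs data.frame(lncrna_id, pcg_id, ...) from
#'   [find_bidirectional_pairs()].
#' @param trend_table data.frame(a_id, trend) from
#'   [map_trends_to_partner()].
#' @return An `evidence_table` data.frame: family_id, coexpression,
#'   bidirectional, temporal, annotated, terms, partner_pcg, trend.
#' @export
collect_evidence <- function(families, lnc_annotations, bidir_pairs,
                             trend_table) {
  members <- families$members
  fam_of <- stats::setNames(members$family_id, members$transcript_id)
  check <- function(ids, what) {
    unknown <- setdiff(ids, names(fam_of))
    if (length(unknown))
      stop(what, " references transcript(s) in no family: ",
           paste(unknown, collapse = ", "))
  }
  check(lnc_annotations$lncrna_id, "coexpression evidence")
  check(bidir_pairs$lncrna_id, "bidirectional evidence")
  check(trend_table$a_id, "temporal evidence")
  fams <- unique(members$family_id)
  join <- function(x) if (length(x)) paste(sort(unique(x)), collapse = ",") else ""
  rows <- lapply(fams, function(f) {
    ids <- members$transcript_id[members$family_id == f]
    co <- lnc_annotations[lnc_annotations$lncrna_id %in% ids, , drop = FALSE]
    bd <- bidir_pairs[bidir_pairs$lncrna_id %in% ids, , drop = FALSE]
    tr <- trend_table[trend_table$a_id %in% ids, , drop = FALSE]
    data.frame(family_id = f,
               coexpression = nrow(co) > 0,
               bidirectional = nrow(bd) > 0,
               temporal = nrow(tr) > 0,
               annotated = nrow(co) > 0 || nrow(bd) > 0 || nrow(tr) > 0,
               terms = join(co$term_id),
               partner_pcg = join(bd$pcg_id),
               trend = join(tr$trend),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$family_id), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("evidence_table", "data.frame"))
}

#' Coverage summary and Venn partition of the evidence table
#'
#' @param table An `evidence_table` from [collect_evidence()].
#' @return List with `n_families`, `n_annotated`, `fraction`, and `venn`
#'   (named counts for the 7 non-empty combinations of Coexpression /
#'   Bidirectional / Temporal flags; they sum to `n_annotated`).
#' @export
coverage_summary <- function(table) {
  if (!nrow(table)) stop("empty evidence table")
  key <- paste0(ifelse(table$coexpression, "C", ""),
                ifelse(table$bidirectional, "B", ""),
                ifelse(table$temporal, "T", ""))
  combos <- c("C", "B", "T", "CB", "CT", "BT", "CBT")
  venn <- vapply(combos, function(k) sum(key == k), integer(1))
  list(n_families = nrow(table),
       n_annotated = sum(table$annotated),
       fraction = sum(table$annotated) / nrow(table),
       venn = venn)
}

#' Run the full conserved-lncRNA pipeline
#'
#' Executes filter -> liftover -> pairing -> conservation scoring ->
#' co-expression network -> enrichment -> bidirectional pairs -> temporal
#' trends -> evidence integration, reading every input from files and
#' writing every intermediate table plus a JSON run manifest. With
#' `simulate = TRUE` (the default) the synthetic study is generated first
#' under `file.path(outdir, "inputs")`. Reruns with identical inputs and
#' seed produce byte-identical outputs.
#'
#' @param outdir Output directory.
#' @param config A `synthetic_config`; also carries the seed.
#' @param simulate Generate synthetic inputs (only supported source of a
#'   full input bundle; for real data, pass `inputs`).
#' @param inputs Optional named list of file paths as produced by
#'   [simulate_study()] (`ref_a`, `assembled_a`, `anno_b`, `chain`,
#'   `coding`, `expr_a`, `samples_a`, `expr_b`, `samples_b`, `temporal`,
#'   `temporal_samples`, `go_map`, `interactions`, `pcg_orthologs`,
#'   `track`).
#' @param params List of stage parameters: `min_len`, `max_coding`,
#'   `min_match`, `min_overlap`, `beta`, `min_module_size`, `cut_height`,
#'   `tom_edge_cutoff`, `alpha`, `max_dist`, `min_ratio`,
#'   `interaction_threshold`, `n_random_regions`.
#' @return Invisibly, a list with every stage result.
#' @export
run_pipeline <- function(outdir, config = synthetic_config(),
                         simulate = TRUE, inputs = NULL,
                         params = list()) {
  pd <- list(min_len = 200, max_coding = 0.5, min_match = 0.95,
             min_overlap = 1, beta = 12, min_module_size = 30,
             cut_height = 0.9, tom_edge_cutoff = 0.2, alpha = 0.05,
             max_dist = 2000, min_ratio = 1.0, interaction_threshold = 50,
             n_random_regions = 60)
  pd[names(params)] <- params
  params <- pd
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (simulate) {
    sim <- simulate_study(config, file.path(outdir, "inputs"))
    inputs <- sim$paths
  }
  inputs <- as.list(inputs)
  need <- c("ref_a", "assembled_a", "anno_b", "chain", "coding", "expr_a",
            "samples_a", "expr_b", "samples_b", "temporal",
            "temporal_samples", "go_map", "interactions", "pcg_orthologs",
            "track")
  for (k in need)
    if (is.null(inputs[[k]]) || !file.exists(inputs[[k]]))
      stop("pipeline aborted at stage 'inputs': missing input '", k, "'",
           if (!is.null(inputs[[k]])) paste0(" (", inputs[[k]], ")") else "")
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline aborted at stage '", name, "': ", conditionMessage(e),
           call. = FALSE))
  }
  tsv <- function(x, f) utils::write.table(x, file.path(outdir, f),
                                           sep = "\t", quote = FALSE,
                                           row.names = FALSE)

  ref_a <- stage("read", read_gtf(inputs$ref_a))
  assembled_a <- stage("read", read_gtf(inputs$assembled_a))
  anno_b <- stage("read", read_gtf(inputs$anno_b))
  chains <- stage("read", read_chain(inputs$chain))
  coding <- stage("read", utils::read.delim(inputs$coding,
                                            stringsAsFactors = FALSE))
  expr_a <- stage("read", read_expression(inputs$expr_a, inputs$samples_a))
  expr_b <- stage("read", read_expression(inputs$expr_b, inputs$samples_b))
  temporal <- stage("read", read_expression(inputs$temporal,
                                            inputs$temporal_samples))
  go_map <- stage("read", utils::read.delim(inputs$go_map,
                                            stringsAsFactors = FALSE))
  interactions <- stage("read", utils::read.delim(inputs$interactions,
                                                  stringsAsFactors = FALSE))
  pcg_orthologs <- stage("read", utils::read.delim(inputs$pcg_orthologs,
                                                   stringsAsFactors = FALSE))
  track <- stage("read", read_bedgraph(inputs$track))

  # 1. filter cascade + families
  filt <- stage("filter", filter_lncrna_candidates(
    assembled_a, coding, expr_a, ref_a,
    min_len = params$min_len, max_coding = params$max_coding))
  kept_a <- subset_transcripts(assembled_a, filt$kept)
  fams <- stage("filter", group_families(kept_a))
  tsv(filt$report, "filter_report.tsv")
  tsv(fams$members, "families.tsv")

  # 2. liftover + 3. conserved pairing
  lifted <- stage("liftover", lift_transcripts(kept_a, chains,
                                               min_match = params$min_match))
  status <- vapply(lifted, `[[`, character(1), "status")
  pairs <- stage("pair", pair_conserved(lifted, anno_b,
                                        min_overlap = params$min_overlap))
  cons <- stage("pair", summarize_conservation(pairs, fams))
  tsv(data.frame(a_id = names(lifted), status = unname(status),
                 match_fraction = vapply(lifted, `[[`, numeric(1),
                                         "match_fraction")), "liftover.tsv")
  tsv(pairs, "conserved_pairs.tsv")

  # 3b. cross-species correlation of summary expression, per gene class
  lnc_pairs <- unique(pairs[, c("a_id", "b_id")])
  if (nrow(lnc_pairs)) lnc_pairs$class <- "lncRNA"
  po <- pcg_orthologs[, c("a_id", "b_id")]
  if (nrow(po)) po$class <- "protein_coding"
  xp <- rbind(lnc_pairs, po)
  xp <- xp[xp$a_id %in% rownames(expr_a$values) &
             xp$b_id %in% rownames(expr_b$values), , drop = FALSE]
  xsp <- if (all(table(factor(xp$class,
                              c("lncRNA", "protein_coding"))) >= 3))
    stage("pair", cross_species_expression_correlation(xp, expr_a, expr_b))
  else NULL
  if (!is.null(xsp)) tsv(xsp, "cross_species_correlation.tsv")

  # 4. conservation-score comparison (PCG vs lncRNA vs random background)
  set.seed((config$seed + 8L) %% .Machine$integer.max)
  pcg_tx <- ref_a$transcripts[ref_a$transcripts$biotype == "protein_coding", ]
  genome_sizes <- stats::setNames(rep(config$chrom_length,
                                      config$n_chroms),
                                  sprintf("chrA%d", seq_len(config$n_chroms)))
  lnc_spans <- kept_a$transcripts$end - kept_a$transcripts$start
  ex_tx <- rbind(ref_a$transcripts, assembled_a$transcripts)
  excl <- annotation_set(data.frame(
    transcript_id = sprintf("EX_%05d.1", seq_len(nrow(ex_tx))),
    gene_id = sprintf("EX_%05d", seq_len(nrow(ex_tx))),
    chrom = ex_tx$chrom, strand = "+", start = ex_tx$start, end = ex_tx$end,
    biotype = "unknown", stringsAsFactors = FALSE))
  rnd <- stage("conscore", sample_random_regions(
    genome_sizes, lnc_spans, params$n_random_regions, exclusions = excl))
  rnd_anno <- annotation_set(data.frame(
    transcript_id = sprintf("RND_%04d.1", seq_len(nrow(rnd))),
    gene_id = sprintf("RND_%04d", seq_len(nrow(rnd))),
    chrom = rnd$chrom, strand = "+", start = rnd$start, end = rnd$end,
    biotype = "unknown", stringsAsFactors = FALSE))
  scores <- stage("conscore", list(
    pcg = suppressWarnings(transcript_score(ref_a, track, ids = pcg_tx$transcript_id)),
    lncRNA = suppressWarnings(transcript_score(kept_a, track)),
    random = suppressWarnings(transcript_score(rnd_anno, track))))
  grp <- stage("conscore", compare_groups(scores))
  tsv(data.frame(group = rep(names(scores), lengths(scores)),
                 transcript_id = unlist(lapply(scores, names)),
                 mean_score = unlist(scores, use.names = FALSE)),
      "conservation_scores.tsv")
  tsv(grp$p_values, "conservation_comparison.tsv")

  # 5. co-expression network on conserved lncRNAs + PCGs (genome A)
  conserved_a <- unique(pairs$a_id)
  net_feats <- intersect(c(conserved_a, pcg_tx$transcript_id),
                         rownames(expr_a$values))
  node_types <- stats::setNames(
    ifelse(net_feats %in% conserved_a, "lncRNA", "PCG"), net_feats)
  adj <- stage("network", signed_adjacency(
    expr_a$values[net_feats, , drop = FALSE], beta = params$beta,
    log_transform = TRUE))
  tom <- stage("network", topological_overlap(adj))
  part <- stage("network", detect_modules(
    tom, min_module_size = params$min_module_size,
    cut_height = params$cut_height))
  conn <- stage("network", module_connectivity(
    tom, part, tom_edge_cutoff = params$tom_edge_cutoff,
    node_types = node_types))
  conn_cmp <- stage("network", compare_connectivity(conn))
  tsv(data.frame(node_id = names(part), module = unname(part)),
      "modules.tsv")
  tsv(conn, "connectivity.tsv")

  # 6. GO enrichment + lncRNA annotation transfer
  universe <- intersect(pcg_tx$transcript_id, rownames(expr_a$values))
  enr <- stage("enrich", enrich_modules(part, go_map, universe,
                                        alpha = params$alpha,
                                        genes_of = universe))
  lnc_ann <- stage("enrich", annotate_lncrnas(
    part, enr, go_map, intersect(conserved_a, names(part)),
    interactions = interactions,
    score_threshold = params$interaction_threshold))
  tsv(enr, "enrichment.tsv")
  tsv(lnc_ann, "lncrna_annotations.tsv")

  # 7. bidirectional pairs + conserved-neighbor check
  lnc_b <- subset_transcripts(anno_b,
    anno_b$transcripts$transcript_id[anno_b$transcripts$biotype == "lncRNA"])
  pcg_b <- subset_transcripts(anno_b,
    anno_b$transcripts$transcript_id[anno_b$transcripts$biotype == "protein_coding"])
  pcg_a_anno <- subset_transcripts(ref_a, pcg_tx$transcript_id)
  bidir_a <- stage("bidir", find_bidirectional_pairs(
    kept_a, pcg_a_anno, max_dist = params$max_dist))
  bidir_cons <- stage("bidir", conserved_neighbor_check(
    bidir_a, pairs[, c("a_id", "b_id")], pcg_orthologs, lnc_b, pcg_b,
    max_dist = params$max_dist))
  tsv(bidir_a, "bidirectional_a.tsv")
  tsv(bidir_cons$conserved, "bidirectional_conserved.tsv")

  # 8. temporal trends on conserved genome-B lncRNAs, mapped back to A
  stage_means <- stage("temporal", stage_expression(temporal,
                                                    stages = config$stages))
  calls <- stage("temporal", classify_trend(
    stage_means[intersect(unique(pairs$b_id), rownames(stage_means)), ,
                drop = FALSE], min_ratio = params$min_ratio))
  trend_a <- stage("temporal", map_trends_to_partner(
    calls, pairs[, c("a_id", "b_id")]))
  tsv(data.frame(b_id = names(calls), trend = unname(calls)), "trends_b.tsv")
  tsv(trend_a, "trends_a.tsv")

  # 9. evidence integration over conserved families
  cons_fams <- unique(cons$family_pairs$family_id)
  fams_cons <- list(
    members = fams$members[fams$members$family_id %in% cons_fams, , drop = FALSE],
    families = fams$families[fams$families$family_id %in% cons_fams, , drop = FALSE])
  evid <- stage("integrate", collect_evidence(
    fams_cons,
    lnc_ann[lnc_ann$lncrna_id %in% fams_cons$members$transcript_id, , drop = FALSE],
    bidir_a[bidir_a$lncrna_id %in% fams_cons$members$transcript_id, , drop = FALSE],
    trend_a[trend_a$a_id %in% fams_cons$members$transcript_id, , drop = FALSE]))
  cov <- stage("integrate", coverage_summary(evid))
  tsv(evid, "evidence.tsv")

  manifest <- list(
    package = "lncord",
    version = as.character(utils::packageVersion("lncord")),
    seed = config$seed,
    simulate = simulate,
    params = params,
    n_kept_lncrna = length(filt$kept),
    n_conserved_a = cons$n_a_conserved,
    n_conserved_b = cons$n_b_conserved,
    n_conserved_families = cons$n_a_families,
    n_modules = length(attr(part, "modules")),
    coverage = cov)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(inputs = inputs, filter = filt, families = fams,
                 lifted = lifted, pairs = pairs, conservation = cons,
                 cross_species = xsp,
                 scores = scores, score_comparison = grp,
                 partition = part, connectivity = conn,
                 connectivity_comparison = conn_cmp, enrichment = enr,
                 lnc_annotations = lnc_ann, bidirectional_a = bidir_a,
                 bidirectional_conserved = bidir_cons,
                 stage_means = stage_means, trend_calls = calls,
                 trends_a = trend_a, evidence = evid, coverage = cov,
                 manifest = manifest))
}
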