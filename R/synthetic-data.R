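#' Configuration for the two-genome synthetic study
#'
#' Defines the conditions of the simulated cross-species study: two toy
#' genomes with protein-coding genes (PCGs) and lncRNAs, a chain alignment
#' with planted conserved lncRNA loci, latent-factor co-expression modules
#' whose hubs are lncRNAs, planted GO enrichments, divergent
#' (bidirectional) lncRNA-PCG promoter pairs at fixed TSS distances, and a
#' four-stage temporal series with planted monotone genes.
#'
#' @param seed Integer seed; every generator output is byte-reproducible
#'   under it.
#' @param n_chroms Chromosomes per genome.
#' @param chrom_length Chromosome length in bases.
#' @param n_pcg,n_lncrna Gene counts per genome.
#' @param n_conserved_lnc Number of planted conserved lncRNA loci (mapped
#'   by a chain block between the genomes).
#' @param frac_minus Fraction of conserved loci placed on the `-` strand of
#'   genome B (exercises reverse-strand chains).
#' @param flank Chain-block flank around each conserved locus, bases.
#' @param split_chains When `TRUE`, conserved-locus chains are emitted as
#'   two blocks separated by `split_gap` bases (exercises partial mapping).
#' @param split_gap Gap size for split chains.
#' @param n_modules,module_size Planted co-expression modules and genes per
#'   module (PCGs plus `lnc_per_module` conserved lncRNAs).
#' @param lnc_per_module Conserved lncRNAs planted as hubs in each module.
#' @param within_module_cor Target pairwise correlation within a module.
#' @param n_samples Expression samples per species.
#' @param noise_sd Extra expression noise on the latent scale.
#' @param stages Ordered developmental stage labels for the temporal series.
#' @param n_reps_per_stage Replicates per stage.
#' @param n_monotone_up,n_monotone_down Planted monotone genes (conserved
#'   genome-B lncRNAs).
#' @param trend_step Log-scale step between consecutive stage means.
#' @param temporal_noise_sd Replicate noise (log scale) in the temporal
#'   series.
#' @param n_bidirectional Planted divergent lncRNA-PCG pairs (conserved
#'   subset, replicated in both genomes).
#' @param bidirectional_distances TSS distances of the planted pairs,
#'   recycled to `n_bidirectional`.
#' @param n_go_terms Number of GO terms in the synthetic gene-term map.
#' @param go_background_rate Background probability that a gene carries a
#'   term.
#' @param enriched_terms data.frame(term, module, fold) of planted
#'   enrichments; default one fold-10 term per module.
#' @param cons_means Named conservation-score means for `pcg`, `lnc`,
#'   `background` bases.
#' @param cons_noise_sd Per-interval noise of the conservation track.
#' @param cross_species_sd Named jitter (log scale) between the shared
#'   baselines of conserved lncRNA pairs and PCG orthologs; smaller jitter
#'   means higher cross-species expression correlation.
#' @param n_distractor_each Copies of each filter-distractor kind (too
#'   short, coding, zero TPM, antisense, single exon, PCG overlap) in the
#'   assembled set.
#' @param n_multi_isoform Non-conserved genome-A lncRNA loci given a second
#'   overlapping isoform (exercises family grouping).
#' @return A validated `synthetic_config` list.
#' @export
synthetic_config <- function(seed = 1L,
                             n_chroms = 2L,
                             chrom_length = 1e6,
                             n_pcg = 150L,
                             n_lncrna = 60L,
                             n_conserved_lnc = 30L,
                             frac_minus = 0.3,
                             flank = 500L,
                             split_chains = FALSE,
                             split_gap = 50L,
                             n_modules = 3L,
                             module_size = 50L,
                             lnc_per_module = 2L,
                             within_module_cor = 0.75,
                             n_samples = 80L,
                             noise_sd = 0.1,
                             stages = c("W2", "W6", "W21", "W104"),
                             n_reps_per_stage = 3L,
                             n_monotone_up = 5L,
                             n_monotone_down = 5L,
                             trend_step = 0.8,
                             temporal_noise_sd = 0.1,
                             n_bidirectional = 4L,
                             bidirectional_distances = c(500, 1000, 2000, 2001),
                             n_go_terms = 30L,
                             go_background_rate = 0.05,
                             enriched_terms = NULL,
                             cons_means = c(pcg = 0.6, lnc = 0.4, background = 0.2),
                             cons_noise_sd = 0.05,
                             cross_species_sd = c(lncRNA = 1.25, pcg = 0.75),
                             n_distractor_each = 2L,
                             n_multi_isoform = 4L) {
  cfg <- as.list(environment())
  if (is.null(enriched_terms)) {
    cfg$enriched_terms <- data.frame(
      term = sprintf("GO:%07d", seq_len(n_modules)),
      module = seq_len(n_modules),
      fold = 10,
      stringsAsFactors = FALSE)
  }
  counts <- c(cfg$n_pcg, cfg$n_lncrna, cfg$n_conserved_lnc, cfg$n_modules,
              cfg$module_size, cfg$n_samples, cfg$n_monotone_up,
              cfg$n_monotone_down, cfg$n_bidirectional, cfg$n_go_terms,
              cfg$n_distractor_each, cfg$n_multi_isoform)
  if (any(counts < 0)) stop("counts must be >= 0")
  if (cfg$n_conserved_lnc > cfg$n_lncrna)
    stop("n_conserved_lnc cannot exceed n_lncrna")
  if (cfg$n_bidirectional > cfg$n_conserved_lnc)
    stop("n_bidirectional cannot exceed n_conserved_lnc")
  if (cfg$n_monotone_up + cfg$n_monotone_down > cfg$n_conserved_lnc)
    stop("monotone plants cannot exceed n_conserved_lnc")
  if (cfg$n_modules * (cfg$module_size - cfg$lnc_per_module) > cfg$n_pcg)
    stop("module plants need more PCGs than n_pcg provides")
  if (cfg$n_modules * cfg$lnc_per_module > cfg$n_conserved_lnc)
    stop("module plants need more conserved lncRNAs than available")
  if (any(cfg$enriched_terms$fold * cfg$go_background_rate > 1))
    stop("enrichment fold times background rate exceeds 1")
  if (cfg$within_module_cor < 0 || cfg$within_module_cor >= 1)
    stop("within_module_cor must be in [0, 1)")
  if (cfg$n_distractor_each > 0 && cfg$n_pcg < 25 + cfg$n_distractor_each)
    stop("distractor placement needs n_pcg >= ", 25 + cfg$n_distractor_each)
  cfg$bidirectional_distances <-
    rep_len(cfg$bidirectional_distances, cfg$n_bidirectional)
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "synthetic_config")
}

# geometry shared by both genomes
.LNC_EXON_OFF <- c(0, 500, 1000); .LNC_EXON_LEN <- 200   # span 1200, spliced 600
.PCG_EXON_OFF <- c(0, 700, 1400); .PCG_EXON_LEN <- 300   # span 1700, spliced 900
.SLOT_WIDTH <- 5200; .SLOT_GAP <- 2800; .SLOT_MARGIN <- 5000
.EXP_SCALE <- 0.3  # latent-to-log-TPM scale

.exon_rows <- function(tid, gid, chrom, strand, origin, offs, len, biotype) {
  data.frame(transcript_id = tid, gene_id = gid, chrom = chrom,
             strand = strand, start = origin + offs, end = origin + offs + len,
             biotype = biotype, stringsAsFactors = FALSE)
}

# deterministic slot layout for one genome; returns data.frame(chrom, origin)
.slots <- function(cfg, genome, n_needed) {
  stride <- .SLOT_WIDTH + .SLOT_GAP
  per_chrom <- floor((cfg$chrom_length - 2 * .SLOT_MARGIN) / stride)
  total <- cfg$n_chroms * per_chrom
  if (n_needed > total)
    stop("cannot place ", n_needed, " loci without overlap: only ", total,
         " slots at chrom_length ", cfg$chrom_length,
         "; increase chrom_length or n_chroms")
  idx <- sample.int(total, n_needed)
  chrom_i <- (idx - 1L) %/% per_chrom + 1L
  slot_j <- (idx - 1L) %% per_chrom
  data.frame(chrom = sprintf("chr%s%d", genome, chrom_i),
             origin = .SLOT_MARGIN + slot_j * stride +
               sample.int(400L, n_needed, replace = TRUE),
             stringsAsFactors = FALSE)
}

#' Generate the two synthetic genomes, their chain alignment, and the truth
#'
#' Places non-overlapping gene loci on each genome; every planted conserved
#' lncRNA locus gets one alignment chain mapping its genome-A span (plus
#' flank) onto its genome-B span, a configurable fraction on the reverse
#' strand of B. Non-conserved loci fall outside every chain block. The
#' assembled transcript set for genome A carries the planted lncRNAs
#' (biotype unknown, as an assembler would emit) plus one distractor group
#' per filter rule.
#'
#' @param config A `synthetic_config`.
#' @return List with `ref_a` (genome-A reference annotation: PCGs plus the
#'   annotated lncRNA subset), `assembled_a` (assembled transcripts to be
#'   filtered), `anno_b` (genome-B annotation), `chains`, and `truth` (a
#'   `synthetic_truth` list: conserved_pairs, pcg_orthologs,
#'   module_assignment, trend_labels, bidirectional_pairs, enriched,
#'   distractors, annotated_lnc_a).
#' @export
generate_genomes <- function(config) {
  cfg <- config
  set.seed(cfg$seed)
  n_lnc <- cfg$n_lncrna; n_cons <- cfg$n_conserved_lnc
  n_bid <- cfg$n_bidirectional
  lnc_gene_a <- sprintf("GLNC_A_%04d", seq_len(n_lnc))
  lnc_tx_a <- sprintf("LNC_A_%04d.1", seq_len(n_lnc))
  lnc_gene_b <- sprintf("GLNC_B_%04d", seq_len(n_lnc))
  lnc_tx_b <- sprintf("LNC_B_%04d.1", seq_len(n_lnc))
  pcg_gene_a <- sprintf("GPCG_A_%04d", seq_len(cfg$n_pcg))
  pcg_tx_a <- sprintf("PCG_A_%04d.1", seq_len(cfg$n_pcg))
  pcg_tx_b <- sprintf("PCG_B_%04d.1", seq_len(cfg$n_pcg))
  bid_pcg_a <- sprintf("BPCG_A_%04d.1", seq_len(n_bid))
  bid_pcg_b <- sprintf("BPCG_B_%04d.1", seq_len(n_bid))
  kinds <- c("too_short", "coding", "zero_tpm", "antisense", "single_exon",
             "pcg_overlap")
  n_each <- cfg$n_distractor_each
  dist_ids <- unlist(lapply(kinds, function(k)
    sprintf("DIST_%s_%02d.1", k, seq_len(n_each))))
  dist_kind <- rep(kinds, each = n_each)

  # strand plans
  bid_idx <- seq_len(n_bid)                       # conserved loci 1..n_bid are divergent plants
  minus_eligible <- setdiff(seq_len(n_cons), bid_idx)
  n_minus <- round(cfg$frac_minus * length(minus_eligible))
  minus_idx <- if (n_minus > 0) sort(sample(minus_eligible, n_minus)) else integer()
  lnc_strand_a <- ifelse(seq_len(n_lnc) %in% bid_idx, "-",
                         sample(c("+", "-"), n_lnc, replace = TRUE))
  # loci lifted through a '-'-strand chain appear on the flipped strand of B
  lnc_strand_b <- lnc_strand_a
  lnc_strand_b[minus_idx] <- ifelse(lnc_strand_a[minus_idx] == "+", "-", "+")

  # slot layout, genome A: lncRNAs, PCGs, then standalone distractors
  n_standalone <- sum(dist_kind %in% c("too_short", "coding", "zero_tpm", "single_exon"))
  slots_a <- .slots(cfg, "A", n_lnc + cfg$n_pcg + n_standalone)
  slots_b <- .slots(cfg, "B", n_lnc + cfg$n_pcg)

  exons <- list()
  # genome A lncRNAs (bidirectional plants carry their PCG partner in-slot)
  for (i in seq_len(n_lnc)) {
    o <- slots_a$origin[i]; ch <- slots_a$chrom[i]
    exons[[length(exons) + 1L]] <- .exon_rows(lnc_tx_a[i], lnc_gene_a[i], ch,
      lnc_strand_a[i], o, .LNC_EXON_OFF, .LNC_EXON_LEN, "lncRNA")
    if (i %in% bid_idx) {
      d <- cfg$bidirectional_distances[i]
      po <- o + 1200 + d
      exons[[length(exons) + 1L]] <- .exon_rows(bid_pcg_a[i],
        sub("\\.1$", "", bid_pcg_a[i]), ch, "+", po, .PCG_EXON_OFF,
        .PCG_EXON_LEN, "protein_coding")
    }
  }
  # second isoforms for the last n_multi_isoform non-conserved A lncRNAs
  multi_idx <- if (cfg$n_multi_isoform > 0 && n_lnc > n_cons)
    utils::tail(setdiff(seq_len(n_lnc), seq_len(n_cons)),
                min(cfg$n_multi_isoform, n_lnc - n_cons)) else integer()
  for (i in multi_idx) {
    o <- slots_a$origin[i] + 300
    exons[[length(exons) + 1L]] <- .exon_rows(
      sub("\\.1$", ".2", lnc_tx_a[i]), lnc_gene_a[i], slots_a$chrom[i],
      lnc_strand_a[i], o, .LNC_EXON_OFF, .LNC_EXON_LEN, "lncRNA")
  }
  # genome A PCGs
  for (i in seq_len(cfg$n_pcg)) {
    j <- n_lnc + i
    exons[[length(exons) + 1L]] <- .exon_rows(pcg_tx_a[i], pcg_gene_a[i],
      slots_a$chrom[j], "+", slots_a$origin[j], .PCG_EXON_OFF, .PCG_EXON_LEN,
      "protein_coding")
  }
  a_gene_exons <- do.call(rbind, exons)

  # genome A distractors (assembled-only transcripts)
  dx <- list(); standalone_slot <- n_lnc + cfg$n_pcg
  for (k in seq_along(dist_ids)) {
    id <- dist_ids[k]; kind <- dist_kind[k]
    gid <- sub("\\.1$", "", id)
    if (kind %in% c("too_short", "coding", "zero_tpm", "single_exon")) {
      standalone_slot <- standalone_slot + 1L
      o <- slots_a$origin[standalone_slot]; ch <- slots_a$chrom[standalone_slot]
      dx[[k]] <- switch(kind,
        too_short = .exon_rows(id, gid, ch, "+", o, c(0, 300), 80, "unknown"),
        coding = .exon_rows(id, gid, ch, "+", o, .LNC_EXON_OFF, .LNC_EXON_LEN, "unknown"),
        zero_tpm = .exon_rows(id, gid, ch, "+", o, .LNC_EXON_OFF, .LNC_EXON_LEN, "unknown"),
        single_exon = .exon_rows(id, gid, ch, "+", o, 0, 400, "unknown"))
    } else {
      # overlap a PCG locus (opposite strand for antisense, same for pcg_overlap)
      base <- if (kind == "antisense") 20L else 25L
      host <- n_lnc + base + match(id, dist_ids[dist_kind == kind])
      o <- slots_a$origin[host] + 100; ch <- slots_a$chrom[host]
      st <- if (kind == "antisense") "-" else "+"
      dx[[k]] <- .exon_rows(id, gid, ch, st, o, c(0, 600), 250, "unknown")
    }
  }
  distractor_exons <- do.call(rbind, dx)

  # genome B: conserved lncRNAs mirror genome A structure; bidirectional
  # geometry replicated with the same distances
  exb <- list()
  for (i in seq_len(n_lnc)) {
    o <- slots_b$origin[i]; ch <- slots_b$chrom[i]
    exb[[length(exb) + 1L]] <- .exon_rows(lnc_tx_b[i], lnc_gene_b[i], ch,
      lnc_strand_b[i], o, .LNC_EXON_OFF, .LNC_EXON_LEN, "lncRNA")
    if (i %in% bid_idx) {
      d <- cfg$bidirectional_distances[i]
      po <- o + 1200 + d
      exb[[length(exb) + 1L]] <- .exon_rows(bid_pcg_b[i],
        sub("\\.1$", "", bid_pcg_b[i]), ch, "+", po, .PCG_EXON_OFF,
        .PCG_EXON_LEN, "protein_coding")
    }
  }
  for (i in seq_len(cfg$n_pcg)) {
    j <- n_lnc + i
    exb[[length(exb) + 1L]] <- .exon_rows(pcg_tx_b[i],
      sprintf("GPCG_B_%04d", i), slots_b$chrom[j], "+", slots_b$origin[j],
      .PCG_EXON_OFF, .PCG_EXON_LEN, "protein_coding")
  }
  anno_b <- annotation_set(do.call(rbind, exb))

  # chains: one per conserved locus, target = A span +/- flank
  chains <- vector("list", n_cons)
  span <- 1200; fl <- cfg$flank
  for (i in seq_len(n_cons)) {
    t_start <- slots_a$origin[i] - fl; t_end <- slots_a$origin[i] + span + fl
    f_start <- slots_b$origin[i] - fl; f_end <- slots_b$origin[i] + span + fl
    qs <- if (i %in% minus_idx) "-" else "+"
    gap <- if (cfg$split_chains) cfg$split_gap else 0L
    if (qs == "+") { q0 <- f_start; q1 <- f_end + gap } else {
      q0 <- cfg$chrom_length - (f_end + gap); q1 <- cfg$chrom_length - f_start
    }
    total <- t_end - t_start
    blocks <- if (gap > 0) {
      h <- floor(total / 2)
      data.frame(size = c(h, total - h), dt = c(gap, 0), dq = c(gap, 0))
    } else data.frame(size = total, dt = 0, dq = 0)
    chains[[i]] <- chain(score = 1000 + n_cons - i,
      t_name = slots_a$chrom[i], t_size = cfg$chrom_length,
      t_start = t_start, t_end = t_end + gap,
      q_name = slots_b$chrom[i], q_size = cfg$chrom_length, q_strand = qs,
      q_start = q0, q_end = q1, blocks = blocks, id = as.character(i))
  }

  # reference annotation A: PCGs + every third lncRNA marked as annotated
  ann_lnc_idx <- which(seq_len(n_lnc) %% 3 == 0)
  ref_exons <- a_gene_exons[
    a_gene_exons$biotype == "protein_coding" |
      a_gene_exons$transcript_id %in%
        c(lnc_tx_a[ann_lnc_idx], sub("\\.1$", ".2", lnc_tx_a[intersect(ann_lnc_idx, multi_idx)])), ,
    drop = FALSE]
  ref_a <- annotation_set(ref_exons)

  # assembled set A: all planted lncRNA isoforms (biotype unknown) + distractors
  asm_exons <- a_gene_exons[a_gene_exons$biotype == "lncRNA", , drop = FALSE]
  asm_exons$biotype <- "unknown"
  assembled_a <- annotation_set(rbind(asm_exons, distractor_exons))

  # module assignment: consecutive PCG blocks + lnc hubs per module
  mod_rows <- list()
  pcg_per_mod <- cfg$module_size - cfg$lnc_per_module
  for (m in seq_len(cfg$n_modules)) {
    pids <- pcg_tx_a[((m - 1) * pcg_per_mod + 1):(m * pcg_per_mod)]
    lids <- lnc_tx_a[((m - 1) * cfg$lnc_per_module + 1):(m * cfg$lnc_per_module)]
    mod_rows[[m]] <- data.frame(
      id = c(pids, lids), module = m,
      node_type = c(rep("PCG", length(pids)), rep("lncRNA", length(lids))),
      stringsAsFactors = FALSE)
  }
  module_assignment <- do.call(rbind, mod_rows)

  trend_labels <- data.frame(
    b_id = lnc_tx_b[seq_len(n_cons)],
    trend = c(rep("up", cfg$n_monotone_up), rep("down", cfg$n_monotone_down),
              rep("none", n_cons - cfg$n_monotone_up - cfg$n_monotone_down)),
    stringsAsFactors = FALSE)

  bid_pairs <- if (n_bid > 0) rbind(
    data.frame(genome = "A", lncrna_id = lnc_tx_a[bid_idx],
               pcg_id = bid_pcg_a, distance = cfg$bidirectional_distances,
               stringsAsFactors = FALSE),
    data.frame(genome = "B", lncrna_id = lnc_tx_b[bid_idx],
               pcg_id = bid_pcg_b, distance = cfg$bidirectional_distances,
               stringsAsFactors = FALSE)) else
    data.frame(genome = character(), lncrna_id = character(),
               pcg_id = character(), distance = numeric())

  truth <- structure(list(
    conserved_pairs = data.frame(a_id = lnc_tx_a[seq_len(n_cons)],
                                 b_id = lnc_tx_b[seq_len(n_cons)],
                                 q_strand = ifelse(seq_len(n_cons) %in% minus_idx, "-", "+"),
                                 stringsAsFactors = FALSE),
    pcg_orthologs = data.frame(a_id = c(pcg_tx_a, bid_pcg_a),
                               b_id = c(pcg_tx_b, bid_pcg_b),
                               stringsAsFactors = FALSE),
    module_assignment = module_assignment,
    trend_labels = trend_labels,
    bidirectional_pairs = bid_pairs,
    enriched = cfg$enriched_terms,
    distractors = data.frame(id = dist_ids, kind = dist_kind,
                             stringsAsFactors = FALSE),
    annotated_lnc_a = lnc_tx_a[ann_lnc_idx],
    multi_isoform_lnc_a = if (length(multi_idx))
      sub("\\.1$", ".2", lnc_tx_a[multi_idx]) else character(),
    lnc_tx_a = lnc_tx_a, lnc_tx_b = lnc_tx_b,
    pcg_tx_a = c(pcg_tx_a, bid_pcg_a), pcg_tx_b = c(pcg_tx_b, bid_pcg_b)),
    class = "synthetic_truth")

  list(ref_a = ref_a, assembled_a = assembled_a, anno_b = anno_b,
       chains = chains, truth = truth)
}

# shared per-gene log-baselines; conserved pairs / orthologs get correlated
# baselines across species (the cross-species expression coupling)
.gene_baselines <- function(cfg, truth) {
  set.seed((cfg$seed + 104729L) %% .Machine$integer.max)
  a_feats <- c(truth$lnc_tx_a, truth$multi_isoform_lnc_a, truth$pcg_tx_a,
               truth$distractors$id)
  mu_a <- stats::setNames(stats::rnorm(length(a_feats), mean = 2, sd = 1), a_feats)
  b_feats <- c(truth$lnc_tx_b, truth$pcg_tx_b)
  mu_b <- stats::setNames(stats::rnorm(length(b_feats), mean = 2, sd = 1), b_feats)
  cp <- truth$conserved_pairs
  mu_b[cp$b_id] <- mu_a[cp$a_id] +
    stats::rnorm(nrow(cp), sd = cfg$cross_species_sd[["lncRNA"]])
  po <- truth$pcg_orthologs
  mu_b[po$b_id] <- mu_a[po$a_id] +
    stats::rnorm(nrow(po), sd = cfg$cross_species_sd[["pcg"]])
  list(a = mu_a, b = mu_b)
}

#' Generate a TPM expression matrix for one species
#'
#' Genome A carries the planted module structure: gene g in module m draws
#' `x = lambda_g * f_m + noise`, with lncRNA hubs given the largest
#' loadings, and TPM = exp(mu_g + 0.3 x), which keeps values positive
#' without changing rank structure. Genome B expression shares the per-gene
#' baselines of conserved pairs and PCG orthologs (jittered by
#' `cross_species_sd`), inducing positive cross-species correlation of
#' per-gene summary expression.
#'
#' @param config A `synthetic_config`.
#' @param truth Truth object from [generate_genomes()].
#' @param species `"A"` or `"B"`.
#' @return An `expression_matrix` (samples carry species metadata, no
#'   stage).
#' @export
generate_expression <- function(config, truth, species = c("A", "B")) {
  cfg <- config; species <- match.arg(species)
  if (cfg$n_samples < 3) stop("n_samples must be >= 3")
  mu <- .gene_baselines(cfg, truth)[[tolower(species)]]
  set.seed((cfg$seed + if (species == "A") 1L else 2L) %% .Machine$integer.max)
  feats <- names(mu)
  n <- length(feats); ns <- cfg$n_samples
  x <- matrix(stats::rnorm(n * ns), n, ns, dimnames = list(feats, NULL))
  if (species == "A" && cfg$within_module_cor > 0 && cfg$n_modules > 0) {
    rho <- cfg$within_module_cor
    sigma <- sqrt((1 - rho) / rho + cfg$noise_sd^2)
    f <- matrix(stats::rnorm(cfg$n_modules * ns), cfg$n_modules, ns)
    ma <- truth$module_assignment
    lambda <- ifelse(ma$node_type == "lncRNA", 1.4,
                     stats::runif(nrow(ma), 0.8, 1.0))
    for (r in seq_len(nrow(ma))) {
      g <- ma$id[r]
      x[g, ] <- lambda[r] * f[ma$module[r], ] + sigma * stats::rnorm(ns)
    }
  }
  tpm <- exp(sweep(.EXP_SCALE * x, 1, mu, `+`))
  zero <- truth$distractors$id[truth$distractors$kind == "zero_tpm"]
  if (species == "A" && length(zero)) tpm[intersect(zero, feats), ] <- 0
  samples <- sprintf("S_%s_%02d", species, seq_len(ns))
  colnames(tpm) <- samples
  expression_matrix(tpm, data.frame(sample_id = samples,
                                    species = paste0("genome", species),
                                    stage = NA_character_,
                                    stringsAsFactors = FALSE))
}

#' Generate the staged temporal expression matrix (genome B)
#'
#' Planted "up" genes get strictly increasing stage means (log-scale step
#' `trend_step` per stage), "down" genes strictly decreasing, all other
#' genome-B lncRNAs flat; replicates add lognormal noise of scale
#' `temporal_noise_sd` (0 gives noiseless, exactly monotone data).
#'
#' @param config A `synthetic_config`.
#' @param truth Truth object from [generate_genomes()].
#' @return An `expression_matrix` whose samples carry stage metadata.
#' @export
generate_temporal <- function(config, truth) {
  cfg <- config
  if (length(cfg$stages) < 2) stop("need at least 2 stages")
  if (cfg$n_reps_per_stage < 1) stop("need >= 1 replicate per stage")
  mu <- .gene_baselines(cfg, truth)$b
  set.seed((cfg$seed + 3L) %% .Machine$integer.max)
  feats <- truth$lnc_tx_b
  ns <- length(cfg$stages) * cfg$n_reps_per_stage
  stage_of <- rep(cfg$stages, each = cfg$n_reps_per_stage)
  dir <- stats::setNames(rep(0, length(feats)), feats)
  tl <- truth$trend_labels
  dir[tl$b_id[tl$trend == "up"]] <- 1
  dir[tl$b_id[tl$trend == "down"]] <- -1
  tpm <- matrix(0, length(feats), ns, dimnames = list(feats, NULL))
  stage_idx <- rep(seq_along(cfg$stages), each = cfg$n_reps_per_stage)
  for (g in seq_along(feats)) {
    means <- exp(mu[feats[g]] + dir[g] * cfg$trend_step * (stage_idx - 1))
    noise <- if (cfg$temporal_noise_sd > 0)
      exp(stats::rnorm(ns, sd = cfg$temporal_noise_sd)) else 1
    tpm[g, ] <- means * noise
  }
  samples <- sprintf("T_B_%02d", seq_len(ns))
  colnames(tpm) <- samples
  expression_matrix(tpm, data.frame(sample_id = samples, species = "genomeB",
                                    stage = stage_of, stringsAsFactors = FALSE))
}

#' Generate the synthetic gene-to-GO-term map
#'
#' Every genome-A PCG carries each term with the background probability;
#' for each planted (module, term, fold) the term's membership probability
#' inside that module's PCGs is multiplied by `fold`.
#'
#' @param config A `synthetic_config`.
#' @param truth Truth object from [generate_genomes()].
#' @return data.frame(gene_id, term_id).
#' @export
generate_go <- function(config, truth) {
  cfg <- config
  set.seed((cfg$seed + 4L) %% .Machine$integer.max)
  genes <- truth$pcg_tx_a
  terms <- sprintf("GO:%07d", seq_len(cfg$n_go_terms))
  ma <- truth$module_assignment
  rows <- list()
  for (t in seq_along(terms)) {
    p <- rep(cfg$go_background_rate, length(genes))
    et <- cfg$enriched_terms
    hit <- which(et$term == terms[t])
    for (h in hit) {
      mod_genes <- ma$id[ma$module == et$module[h] & ma$node_type == "PCG"]
      p[genes %in% mod_genes] <-
        pmin(1, cfg$go_background_rate * et$fold[h])
    }
    member <- genes[stats::runif(length(genes)) < p]
    if (length(member))
      rows[[t]] <- data.frame(gene_id = member, term_id = terms[t],
                              stringsAsFactors = FALSE)
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_id = character(), term_id = character())
}

#' Generate lncRNA-protein interaction scores (lncPro-style 0-100 scale)
#'
#' Module lncRNA hubs get high scores (around 75) with their own module's
#' PCGs and low scores (around 20) with a random sample of outside PCGs.
#'
#' @param config A `synthetic_config`.
#' @param truth Truth object from [generate_genomes()].
#' @return data.frame(lncrna_id, gene_id, score).
#' @export
generate_interactions <- function(config, truth) {
  cfg <- config
  set.seed((cfg$seed + 6L) %% .Machine$integer.max)
  ma <- truth$module_assignment
  rows <- list()
  for (m in unique(ma$module)) {
    lncs <- ma$id[ma$module == m & ma$node_type == "lncRNA"]
    pcgs <- ma$id[ma$module == m & ma$node_type == "PCG"]
    out_pcgs <- sample(setdiff(truth$pcg_tx_a, pcgs), min(10, length(pcgs)))
    for (l in lncs) {
      rows[[length(rows) + 1L]] <- data.frame(
        lncrna_id = l, gene_id = c(pcgs, out_pcgs),
        score = c(pmin(100, pmax(0, stats::rnorm(length(pcgs), 75, 8))),
                  pmax(0, stats::rnorm(length(out_pcgs), 20, 8))),
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(lncrna_id = character(), gene_id = character(), score = numeric())
}

#' Generate the per-base conservation track
#'
#' Emits a bedGraph-style interval table with planted means: PCG exon bases
#' score around `cons_means["pcg"]`, lncRNA exon bases around
#' `cons_means["lnc"]`, everything else around `cons_means["background"]`
#' (tiled in 1 kb bins), with per-interval Gaussian noise clipped to [0, 1].
#' Bases covered by both a PCG and an lncRNA exon take the PCG mean.
#'
#' @param config A `synthetic_config`.
#' @param genomes Output of [generate_genomes()].
#' @param noise_sd Per-interval noise; default `config$cons_noise_sd`.
#' @return A `score_track` data.frame (chrom, start, end, score).
#' @export
generate_conservation_track <- function(config, genomes, noise_sd = NULL) {
  cfg <- config
  if (is.null(noise_sd)) noise_sd <- cfg$cons_noise_sd
  set.seed((cfg$seed + 5L) %% .Machine$integer.max)
  ex_ref <- genomes$ref_a$exons
  ex_asm <- genomes$assembled_a$exons
  pcg_ex <- ex_ref[ex_ref$biotype == "protein_coding", , drop = FALSE]
  lnc_ids <- c(genomes$truth$lnc_tx_a, genomes$truth$multi_isoform_lnc_a)
  lnc_ex <- ex_asm[ex_asm$transcript_id %in% lnc_ids, , drop = FALSE]
  rows <- list()
  for (ch in sort(unique(c(pcg_ex$chrom, lnc_ex$chrom)))) {
    p <- IRanges::reduce(.iranges_of(pcg_ex$start[pcg_ex$chrom == ch],
                                     pcg_ex$end[pcg_ex$chrom == ch]))
    l0 <- IRanges::reduce(.iranges_of(lnc_ex$start[lnc_ex$chrom == ch],
                                      lnc_ex$end[lnc_ex$chrom == ch]))
    l <- IRanges::setdiff(l0, p)
    whole <- IRanges::IRanges(1L, as.integer(cfg$chrom_length))
    bg <- IRanges::setdiff(whole, IRanges::union(p, l0))
    # tile background into <= 1 kb pieces
    tile <- unlist(IRanges::slidingWindows(bg, width = 1000L, step = 1000L))
    seg <- function(ir, mean) if (length(ir)) data.frame(
      chrom = ch, start = IRanges::start(ir) - 1L, end = IRanges::end(ir),
      score = pmin(1, pmax(0, mean + if (noise_sd > 0)
        stats::rnorm(length(ir), sd = noise_sd) else 0)),
      stringsAsFactors = FALSE) else NULL
    rows[[length(rows) + 1L]] <- rbind(seg(p, cfg$cons_means[["pcg"]]),
                                       seg(l, cfg$cons_means[["lnc"]]),
                                       seg(tile, cfg$cons_means[["background"]]))
  }
  tr <- do.call(rbind, rows)
  tr <- tr[order(tr$chrom, tr$start), , drop = FALSE]
  rownames(tr) <- NULL
  structure(tr, class = c("score_track", "data.frame"))
}

#' Write every synthetic-study artifact to a directory
#'
#' Emits the two genome GTFs, the assembled-transcript GTF, the chain file,
#' coding-potential scores, expression matrices with sample metadata, the
#' temporal series, the gene-to-GO map, interaction scores, the PCG
#' ortholog table, the conservation bedGraph, and the ground truth as JSON.
#'
#' @param config A `synthetic_config`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, a list with the generated objects and file paths.
#' @export
simulate_study <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  g <- generate_genomes(config)
  expr_a <- generate_expression(config, g$truth, "A")
  expr_b <- generate_expression(config, g$truth, "B")
  temporal <- generate_temporal(config, g$truth)
  go_map <- generate_go(config, g$truth)
  interactions <- generate_interactions(config, g$truth)
  track <- generate_conservation_track(config, g)
  set.seed((config$seed + 7L) %% .Machine$integer.max)
  asm <- g$assembled_a$transcripts
  coding <- data.frame(
    transcript_id = asm$transcript_id,
    score = round(ifelse(
      asm$transcript_id %in% g$truth$distractors$id[g$truth$distractors$kind == "coding"],
      stats::runif(nrow(asm), 0.7, 0.95), stats::runif(nrow(asm), 0.05, 0.4)), 4),
    stringsAsFactors = FALSE)
  p <- function(f) file.path(dir, f)
  write_gtf(g$ref_a, p("ref_a.gtf"))
  write_gtf(g$assembled_a, p("assembled_a.gtf"))
  write_gtf(g$anno_b, p("anno_b.gtf"))
  write_chain(g$chains, p("alignment.chain"))
  utils::write.table(coding, p("coding_scores.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_expression(expr_a, p("expr_a.tsv"), p("samples_a.tsv"))
  write_expression(expr_b, p("expr_b.tsv"), p("samples_b.tsv"))
  write_expression(temporal, p("temporal_b.tsv"), p("temporal_samples.tsv"))
  utils::write.table(go_map, p("go_map.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(interactions, p("interactions.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(g$truth$pcg_orthologs, p("pcg_orthologs.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_bedgraph(track, p("conservation.bedGraph"))
  jsonlite::write_json(unclass(g$truth), p("truth.json"), dataframe = "columns",
                       digits = NA)
  invisible(list(config = config, genomes = g, expr_a = expr_a,
                 expr_b = expr_b, temporal = temporal, go_map = go_map,
                 interactions = interactions, coding_scores = coding,
                 track = track,
                 paths = stats::setNames(
                   file.path(dir, c("ref_a.gtf", "assembled_a.gtf", "anno_b.gtf",
                                    "alignment.chain", "coding_scores.tsv",
                                    "expr_a.tsv", "samples_a.tsv", "expr_b.tsv",
                                    "samples_b.tsv", "temporal_b.tsv",
                                    "temporal_samples.tsv", "go_map.tsv",
                                    "interactions.tsv", "pcg_orthologs.tsv",
                                    "conservation.bedGraph", "truth.json")),
                   c("ref_a", "assembled_a", "anno_b", "chain", "coding",
                     "expr_a", "samples_a", "expr_b", "samples_b", "temporal",
                     "temporal_samples", "go_map", "interactions",
                     "pcg_orthologs", "track", "truth"))))
}
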