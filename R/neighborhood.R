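#' Transcription start sites of an annotation set
#'
#' TSS is the 5' end of the transcript span: `start` for `+` transcripts,
#' `end` for `-` transcripts (half-open convention).
#'
#' @param anno An `annotation_set`.
#' @return data.frame(transcript_id, chrom, strand, tss).
#' @export
transcript_tss <- function(anno) {
  tx <- anno$transcripts
  data.frame(transcript_id = tx$transcript_id, chrom = tx$chrom,
             strand = tx$strand,
             tss = ifelse(tx$strand == "-", tx$end, tx$start),
             stringsAsFactors = FALSE)
}

#' Find bidirectional (divergent) lncRNA-PCG pairs
#'
#' A pair is emitted iff the two transcripts lie on opposite strands in
#' head-to-head (divergent) orientation -- the `-` element's TSS at or
#' 5'-ward of the `+` element's TSS -- with TSS distance
#' `0 <= tss(+) - tss(-) <= max_dist`, and no other transcript of either
#' input set has a TSS strictly between them (adjacency). Overlapping
#' divergent transcripts (negative distance) are excluded unless
#' `allow_overlap`.
#'
#' @param lncrnas,pcgs `annotation_set`s on one genome.
#' @param max_dist Maximum TSS-to-TSS distance, bases (2000, boundary
#'   inclusive).
#' @param allow_overlap Permit negative TSS distances.
#' @return data.frame(lncrna_id, pcg_id, tss_distance).
#' @export
find_bidirectional_pairs <- function(lncrnas, pcgs, max_dist = 2000,
                                     allow_overlap = FALSE) {
  lt <- transcript_tss(lncrnas)
  pt <- transcript_tss(pcgs)
  all_tss <- rbind(lt, pt)
  rows <- list()
  for (i in seq_len(nrow(lt))) for (j in seq_len(nrow(pt))) {
    l <- lt[i, ]; p <- pt[j, ]
    if (l$chrom != p$chrom) next
    if (l$strand == p$strand || !all(c(l$strand, p$strand) %in% c("+", "-"))) next
    tss_minus <- if (l$strand == "-") l$tss else p$tss
    tss_plus <- if (l$strand == "+") l$tss else p$tss
    d <- tss_plus - tss_minus
    if (!allow_overlap && d < 0) next
    if (d > max_dist || (allow_overlap && -d > max_dist)) next
    lo <- min(tss_minus, tss_plus); hi <- max(tss_minus, tss_plus)
    between <- all_tss$chrom == l$chrom & all_tss$tss > lo & all_tss$tss < hi &
      !(all_tss$transcript_id %in% c(l$transcript_id, p$transcript_id))
    if (any(between)) next
    rows[[length(rows) + 1L]] <- data.frame(
      lncrna_id = l$transcript_id, pcg_id = p$transcript_id,
      tss_distance = d, stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(lncrna_id = character(), pcg_id = character(),
               tss_distance = numeric(), stringsAsFactors = FALSE)
  out <- out[order(out$lncrna_id, out$pcg_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Check conservation of bidirectional pairs in the second genome
#'
#' A genome-A divergent pair (l_a, p_a) is conserved-bidirectional iff some
#' conserved partner l_b of l_a forms a divergent pair (same rule, same
#' `max_dist`) with the PCG ortholog of p_a in genome B. PCGs without an
#' ortholog entry are treated as non-conserved and counted.
#'
#' @param pairs_a Genome-A pair table from [find_bidirectional_pairs()].
#' @param conserved_pairs data.frame(a_id, b_id) of conserved lncRNA pairs.
#' @param pcg_orthologs data.frame(a_id, b_id) mapping genome-A PCGs to
#'   genome-B PCGs (an external homology table).
#' @param lncrnas_b,pcgs_b Genome-B `annotation_set`s.
#' @param max_dist Maximum TSS distance on both sides.
#' @return List with `conserved` (data.frame lncrna_a, pcg_a, distance_a,
#'   lncrna_b, pcg_b, distance_b) and `n_missing_ortholog`.
#' @export
conserved_neighbor_check <- function(pairs_a, conserved_pairs, pcg_orthologs,
                                     lncrnas_b, pcgs_b, max_dist = 2000) {
  pairs_b <- find_bidirectional_pairs(lncrnas_b, pcgs_b, max_dist)
  ortho <- stats::setNames(pcg_orthologs$b_id, pcg_orthologs$a_id)
  rows <- list(); n_missing <- 0L
  for (i in seq_len(nrow(pairs_a))) {
    l_a <- pairs_a$lncrna_id[i]; p_a <- pairs_a$pcg_id[i]
    p_b <- ortho[p_a]
    if (is.na(p_b)) {
      n_missing <- n_missing + 1L
      message("no ortholog for PCG ", p_a, "; pair treated as non-conserved")
      next
    }
    partners <- conserved_pairs$b_id[conserved_pairs$a_id == l_a]
    hit <- pairs_b[pairs_b$lncrna_id %in% partners & pairs_b$pcg_id == p_b, ,
                   drop = FALSE]
    if (nrow(hit))
      rows[[length(rows) + 1L]] <- data.frame(
        lncrna_a = l_a, pcg_a = p_a, distance_a = pairs_a$tss_distance[i],
        lncrna_b = hit$lncrna_id[1], pcg_b = unname(p_b),
        distance_b = hit$tss_distance[1], stringsAsFactors = FALSE)
  }
  conserved <- if (length(rows)) do.call(rbind, rows) else
    data.frame(lncrna_a = character(), pcg_a = character(),
               distance_a = numeric(), lncrna_b = character(),
               pcg_b = character(), distance_b = numeric(),
               stringsAsFactors = FALSE)
  rownames(conserved) <- NULL
  list(conserved = conserved, n_missing_ortholog = n_missing)
}
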