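#' Classify assembled transcripts against a reference annotation
#'
#' Each query transcript receives exactly one class by exon-to-exon overlap
#' (>= 1 base) with the reference, in precedence order:
#' \enumerate{
#'   \item same-strand exonic overlap with a protein-coding reference
#'     transcript -> `pcg_overlap`
#'   \item same-strand exonic overlap with a reference lncRNA ->
#'     `known_lncrna_match`
#'   \item opposite-strand exonic overlap with any reference transcript ->
#'     `antisense_overlap`
#'   \item no reference exonic overlap, single exon -> `single_exon_novel`
#'   \item otherwise -> `multi_exon_novel`
#' }
#' Intron-contained transcripts have no exonic overlap and fall through to
#' the novel classes. Query chromosomes absent from the reference are
#' classified against an empty annotation (classes 4/5), with a message.
#'
#' @param query An `annotation_set` of assembled transcripts.
#' @param ref Reference `annotation_set` on the same genome.
#' @return Named character vector of classes, one per query transcript.
#' @export
classify_transcripts <- function(query, ref) {
  qtx <- query$transcripts
  qex <- query$exons
  rex <- ref$exons
  off_ref <- setdiff(unique(qtx$chrom), unique(rex$chrom))
  if (length(off_ref))
    message("chromosome(s) absent from reference, classified as novel: ",
            paste(off_ref, collapse = ", "))
  hits <- .overlap_pairs(qex$chrom, qex$start, qex$end,
                         rex$chrom, rex$start, rex$end)
  same <- qex$strand[hits$q] == rex$strand[hits$s]
  q_id <- qex$transcript_id[hits$q]
  r_bt <- rex$biotype[hits$s]
  cls <- stats::setNames(rep(NA_character_, nrow(qtx)), qtx$transcript_id)
  pcg_ids <- unique(q_id[same & r_bt == "protein_coding"])
  lnc_ids <- unique(q_id[same & r_bt == "lncRNA"])
  anti_ids <- unique(q_id[!same])
  any_ids <- unique(q_id)
  cls[] <- ifelse(names(cls) %in% pcg_ids, "pcg_overlap",
           ifelse(names(cls) %in% lnc_ids, "known_lncrna_match",
           ifelse(names(cls) %in% anti_ids, "antisense_overlap",
           ifelse(!(names(cls) %in% any_ids) & qtx$n_exons == 1L,
                  "single_exon_novel", "multi_exon_novel"))))
  cls
}

#' Apply the lncRNA filter cascade
#'
#' A transcript is kept iff its spliced length is at least `min_len` (200
#' bp default), its coding-potential score is at most `max_coding` (0.5
#' default; both boundaries inclusive on the keep side), its maximum TPM
#' across samples is strictly positive, and its class against the reference
#' is `known_lncrna_match` or `multi_exon_novel`. The removal reason records
#' the first failing rule in the order length, coding, expression, class;
#' membership of the kept set does not depend on that order. Kept
#' transcripts with an identical chrom/strand/exon chain are deduplicated,
#' preferring the annotation-matched copy.
#'
#' @param transcripts An `annotation_set` of assembled transcripts.
#' @param coding_scores Named numeric vector (or data.frame with columns
#'   `transcript_id`, `score`) of coding-potential scores in [0, 1]; every
#'   transcript must have one.
#' @param expr An `expression_matrix` or `NULL`; transcripts absent from it
#'   are treated as max TPM 0.
#' @param ref Reference `annotation_set` for classification.
#' @param min_len Minimum spliced length, bases.
#' @param max_coding Maximum coding-potential score.
#' @return List with `kept` (character vector of transcript ids) and
#'   `report` (data.frame: transcript_id, spliced_length, coding_potential,
#'   max_tpm, class, kept, removal_reason).
#' @export
filter_lncrna_candidates <- function(transcripts, coding_scores, expr, ref,
                                     min_len = 200, max_coding = 0.5) {
  tx <- transcripts$transcripts
  if (is.data.frame(coding_scores))
    coding_scores <- stats::setNames(coding_scores$score,
                                     coding_scores$transcript_id)
  missing <- setdiff(tx$transcript_id, names(coding_scores))
  if (length(missing))
    stop("missing coding score for transcript(s): ",
         paste(missing, collapse = ", "))
  score <- unname(coding_scores[tx$transcript_id])
  max_tpm <- rep(0, nrow(tx))
  if (!is.null(expr)) {
    in_expr <- tx$transcript_id %in% rownames(expr$values)
    if (any(in_expr))
      max_tpm[in_expr] <- apply(
        expr$values[tx$transcript_id[in_expr], , drop = FALSE], 1, max)
  }
  cls <- classify_transcripts(transcripts, ref)[tx$transcript_id]
  reason <- character(nrow(tx))
  reason[reason == "" & tx$spliced_length < min_len] <- "too_short"
  reason[reason == "" & score > max_coding] <- "coding"
  reason[reason == "" & max_tpm <= 0] <- "not_expressed"
  reason[reason == "" & !cls %in% c("known_lncrna_match", "multi_exon_novel")] <- "class"
  kept <- reason == ""
  report <- data.frame(transcript_id = tx$transcript_id,
                       spliced_length = tx$spliced_length,
                       coding_potential = score, max_tpm = max_tpm,
                       class = unname(cls), kept = kept,
                       removal_reason = reason, stringsAsFactors = FALSE)
  kept_ids <- tx$transcript_id[kept]
  # dedup identical intron chains among kept, preferring annotated matches
  if (length(kept_ids) > 1L) {
    ex <- transcripts$exons[transcripts$exons$transcript_id %in% kept_ids, ]
    key <- vapply(split(ex, ex$transcript_id), function(e)
      paste(e$chrom[1], e$strand[1],
            paste(e$start, e$end, collapse = ","), sep = "|"), character(1))
    pref <- order(names(key) %in% ref$transcripts$transcript_id,
                  decreasing = TRUE)
    dup <- names(key)[pref][duplicated(key[pref])]
    if (length(dup)) {
      report$kept[report$transcript_id %in% dup] <- FALSE
      report$removal_reason[report$transcript_id %in% dup] <- "duplicate"
      kept_ids <- setdiff(kept_ids, dup)
    }
  }
  list(kept = kept_ids, report = report)
}

#' Group lncRNA isoforms into families
#'
#' Isoforms whose genomic spans overlap by at least one base on the same
#' chromosome and strand are merged into one family (single linkage); the
#' family span is the hull of its members' spans. Families partition the
#' input.
#'
#' @param anno An `annotation_set`.
#' @param ids Optional subset of transcript ids to group.
#' @return List with `members` (data.frame family_id, transcript_id) and
#'   `families` (data.frame family_id, chrom, strand, start, end,
#'   n_members).
#' @export
group_families <- function(anno, ids = NULL) {
  tx <- anno$transcripts
  if (!is.null(ids)) tx <- tx[tx$transcript_id %in% ids, , drop = FALSE]
  if (!nrow(tx))
    return(list(members = data.frame(family_id = character(),
                                     transcript_id = character()),
                families = data.frame(family_id = character(),
                                      chrom = character(), strand = character(),
                                      start = numeric(), end = numeric(),
                                      n_members = integer())))
  tx$group <- paste(tx$chrom, tx$strand, sep = "|")
  fam_rows <- list(); mem_rows <- list()
  for (g in unique(tx$group)) {
    sub <- tx[tx$group == g, , drop = FALSE]
    ir <- .iranges_of(sub$start, sub$end)
    merged <- IRanges::reduce(ir, min.gapwidth = 0L)  # >= 1 base overlap only
    comp <- S4Vectors::subjectHits(IRanges::findOverlaps(ir, merged))
    fam_rows[[g]] <- data.frame(chrom = sub$chrom[1], strand = sub$strand[1],
                                start = IRanges::start(merged) - 1,
                                end = as.numeric(IRanges::end(merged)),
                                n_members = as.integer(table(comp)),
                                stringsAsFactors = FALSE)
    mem_rows[[g]] <- data.frame(transcript_id = sub$transcript_id,
                                chrom = sub$chrom[1], strand = sub$strand[1],
                                start = IRanges::start(merged)[comp] - 1,
                                stringsAsFactors = FALSE)
  }
  fams <- do.call(rbind, fam_rows)
  fams <- fams[order(fams$chrom, fams$start, fams$strand), , drop = FALSE]
  fams$family_id <- sprintf("FAM_%04d", seq_len(nrow(fams)))
  mem <- do.call(rbind, mem_rows)
  key_f <- paste(fams$chrom, fams$start, fams$strand)
  mem$family_id <- fams$family_id[match(paste(mem$chrom, mem$start, mem$strand),
                                        key_f)]
  members <- mem[order(mem$family_id, mem$transcript_id),
                 c("family_id", "transcript_id"), drop = FALSE]
  rownames(members) <- NULL
  fams <- fams[, c("family_id", "chrom", "strand", "start", "end", "n_members")]
  rownames(fams) <- NULL
  list(members = members, families = fams)
}
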