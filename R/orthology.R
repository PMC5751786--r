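#' Pair conserved lncRNAs across genomes from lifted coordinates
#'
#' For every successfully mapped lift result, emits one pair per
#' destination-genome lncRNA whose transcript span overlaps the lifted
#' region by at least `min_overlap` bases. Matching is strand-agnostic
#' (liftOver output strand depends on chain orientation) and many-to-many
#' pairs are allowed: one lifted region over k destination isoforms yields
#' k pairs.
#'
#' @param lifted Named list of `lift_result` (names are source transcript
#'   ids), as from [lift_transcripts()].
#' @param b_anno Destination-genome `annotation_set`; only `lncRNA`
#'   transcripts can be paired.
#' @param min_overlap Minimum overlap in bases (default 1).
#' @return data.frame(a_id, b_id, chrom, lifted_start, lifted_end,
#'   overlap_bases).
#' @export
pair_conserved <- function(lifted, b_anno, min_overlap = 1) {
  mapped <- Filter(function(r) r$status == "mapped", lifted)
  empty <- data.frame(a_id = character(), b_id = character(),
                      chrom = character(), lifted_start = numeric(),
                      lifted_end = numeric(), overlap_bases = numeric(),
                      stringsAsFactors = FALSE)
  if (!length(mapped)) return(empty)
  reg <- data.frame(a_id = names(mapped),
                    chrom = vapply(mapped, function(r) r$mapped$chrom, character(1)),
                    start = vapply(mapped, function(r) r$mapped$start, numeric(1)),
                    end = vapply(mapped, function(r) r$mapped$end, numeric(1)),
                    stringsAsFactors = FALSE)
  btx <- b_anno$transcripts
  btx <- btx[btx$biotype == "lncRNA", , drop = FALSE]
  hits <- .overlap_pairs(reg$chrom, reg$start, reg$end,
                         btx$chrom, btx$start, btx$end)
  if (!nrow(hits)) return(empty)
  ov <- pmin(reg$end[hits$q], btx$end[hits$s]) -
    pmax(reg$start[hits$q], btx$start[hits$s])
  keep <- ov >= min_overlap
  out <- data.frame(a_id = reg$a_id[hits$q], b_id = btx$transcript_id[hits$s],
                    chrom = reg$chrom[hits$q],
                    lifted_start = reg$start[hits$q],
                    lifted_end = reg$end[hits$q],
                    overlap_bases = ov, stringsAsFactors = FALSE)[keep, , drop = FALSE]
  out <- out[order(out$a_id, out$b_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Summarize conservation at the transcript and family level
#'
#' @param pairs Pair table from [pair_conserved()].
#' @param a_families Family grouping from [group_families()] over the
#'   source-genome lncRNAs; every `a_id` in `pairs` must belong to a
#'   family.
#' @return List with `n_a_conserved`, `n_b_conserved`, `n_a_families`,
#'   and `family_pairs` (data.frame family_id, a_id, b_id).
#' @export
summarize_conservation <- function(pairs, a_families) {
  members <- a_families$members
  unknown <- setdiff(pairs$a_id, members$transcript_id)
  if (length(unknown))
    stop("pair references transcript(s) in no family: ",
         paste(unknown, collapse = ", "))
  fam_of <- stats::setNames(members$family_id, members$transcript_id)
  family_pairs <- data.frame(family_id = unname(fam_of[pairs$a_id]),
                             a_id = pairs$a_id, b_id = pairs$b_id,
                             stringsAsFactors = FALSE)
  list(n_a_conserved = length(unique(pairs$a_id)),
       n_b_conserved = length(unique(pairs$b_id)),
       n_a_families = length(unique(family_pairs$family_id)),
       family_pairs = family_pairs)
}

#' Cross-species correlation of summary expression over conserved pairs
#'
#' For each pair, each species' expression is collapsed to one summary
#' value per transcript (median TPM across that species' samples by
#' default; the two species' sample sets need not correspond), then the
#' Spearman rank correlation of the two summaries is computed across
#' pairs, separately per gene class when a `class` column is present.
#'
#' @param pairs data.frame with columns `a_id`, `b_id` and optionally
#'   `class` (e.g. lncRNA / protein_coding).
#' @param expr_a,expr_b `expression_matrix` objects containing the paired
#'   features.
#' @param summary_stat `"median"` (default) or `"mean"`.
#' @return data.frame(class, n_pairs, rho).
#' @export
cross_species_expression_correlation <- function(pairs, expr_a, expr_b,
                                                 summary_stat = c("median", "mean")) {
  summary_stat <- match.arg(summary_stat)
  stat <- if (summary_stat == "median") stats::median else mean
  if (is.null(pairs$class)) pairs$class <- "all"
  missing_a <- setdiff(pairs$a_id, rownames(expr_a$values))
  missing_b <- setdiff(pairs$b_id, rownames(expr_b$values))
  if (length(missing_a) || length(missing_b))
    stop("paired feature(s) absent from expression: ",
         paste(c(missing_a, missing_b), collapse = ", "))
  out <- lapply(split(pairs, pairs$class), function(p) {
    if (nrow(p) < 3)
      stop("need >= 3 pairs per class for a rank correlation (class ",
           p$class[1], " has ", nrow(p), ")")
    sa <- apply(expr_a$values[p$a_id, , drop = FALSE], 1, stat)
    sb <- apply(expr_b$values[p$b_id, , drop = FALSE], 1, stat)
    data.frame(class = p$class[1], n_pairs = nrow(p),
               rho = stats::cor(sa, sb, method = "spearman"),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
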