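#' Read a bedGraph conservation track
#'
#' @param path bedGraph path (chrom, start, end, score; 0-based half-open).
#' @return A `score_track` data.frame with scores validated to [0, 1].
#' @export
read_bedgraph <- function(path) {
  tr <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                          col.names = c("chrom", "start", "end", "score"))
  if (any(tr$score < 0 | tr$score > 1))
    stop("conservation scores must lie in [0, 1]")
  structure(tr, class = c("score_track", "data.frame"))
}

#' Write a score track as bedGraph
#' @param track A `score_track` data.frame.
#' @param path Output path.
#' @export
write_bedgraph <- function(track, path) {
  utils::write.table(
    data.frame(track$chrom, as.integer(track$start), as.integer(track$end),
               track$score),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Mean conservation score per transcript
#'
#' Averages track scores over each transcript's exonic bases (or its
#' genomic span with `mode = "span"`). Bases without a score are excluded
#' from numerator and denominator; with `missing_as_zero = TRUE` they count
#' as zeros instead. Transcripts with no scored base get `NA` with a
#' warning (batch mode never fails on them).
#'
#' @param anno An `annotation_set`.
#' @param track A `score_track` (sparse coverage is fine).
#' @param ids Optional subset of transcript ids.
#' @param mode Average over `"exon"` bases (default) or the `"span"` hull.
#' @param missing_as_zero Treat unscored bases as score 0.
#' @return Named numeric vector of mean scores (NA where undefined).
#' @export
transcript_score <- function(anno, track, ids = NULL,
                             mode = c("exon", "span"),
                             missing_as_zero = FALSE) {
  mode <- match.arg(mode)
  tx <- anno$transcripts
  if (!is.null(ids)) tx <- tx[tx$transcript_id %in% ids, , drop = FALSE]
  if (mode == "exon") {
    iv <- anno$exons[anno$exons$transcript_id %in% tx$transcript_id, , drop = FALSE]
  } else {
    iv <- tx[, c("transcript_id", "chrom", "start", "end")]
  }
  hits <- .overlap_pairs(iv$chrom, iv$start, iv$end,
                         track$chrom, track$start, track$end)
  w <- pmin(iv$end[hits$q], track$end[hits$s]) -
    pmax(iv$start[hits$q], track$start[hits$s])
  tid <- iv$transcript_id[hits$q]
  num <- tapply(w * track$score[hits$s], tid, sum)
  den <- tapply(w, tid, sum)
  out <- stats::setNames(rep(NA_real_, nrow(tx)), tx$transcript_id)
  out[names(num)] <- num / den
  if (missing_as_zero) {
    total <- tapply(iv$end - iv$start, iv$transcript_id, sum)
    out[names(num)] <- num / total[names(num)]
    out[is.na(out)] <- 0
  } else {
    und <- names(out)[is.na(out)]
    if (length(und))
      warning("no scored bases for transcript(s), skipped: ",
              paste(und, collapse = ", "))
  }
  out
}

#' Sample random genomic regions matched on a length distribution
#'
#' Draws `n` intervals with lengths resampled from `template_lengths`,
#' placed uniformly on chromosomes (weighted by size) and rejected when
#' they overlap `exclusions`. Deterministic under `seed`.
#'
#' @param genome_sizes Named numeric vector of chromosome lengths.
#' @param template_lengths Lengths to resample from (e.g. lncRNA span
#'   lengths).
#' @param n Number of intervals.
#' @param seed Optional integer seed.
#' @param exclusions Optional `annotation_set` whose transcript spans are
#'   avoided.
#' @return data.frame(chrom, start, end) of 0-based half-open intervals.
#' @export
sample_random_regions <- function(genome_sizes, template_lengths, n,
                                  seed = NULL, exclusions = NULL) {
  if (!length(template_lengths)) stop("template_lengths must be non-empty")
  if (!is.null(seed)) set.seed(seed)
  ex <- if (!is.null(exclusions)) exclusions$transcripts else NULL
  out <- vector("list", n)
  got <- 0L; tries <- 0L
  max_tries <- max(1000L, 100L * n)
  while (got < n) {
    if (tries >= max_tries)
      stop("rejection rate too high: placed ", got, " of ", n,
           " regions in ", tries, " draws")
    tries <- tries + 1L
    len <- template_lengths[sample.int(length(template_lengths), 1L)]
    ch <- names(genome_sizes)[sample.int(length(genome_sizes), 1L,
                                         prob = genome_sizes)]
    if (genome_sizes[[ch]] <= len) next
    s <- floor(stats::runif(1, 0, genome_sizes[[ch]] - len))
    e <- s + len
    if (!is.null(ex) &&
        any(ex$chrom == ch & ex$start < e & ex$end > s)) next
    got <- got + 1L
    out[[got]] <- data.frame(chrom = ch, start = s, end = e,
                             stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Compare conservation-score distributions between gene groups
#'
#' One-sided Wilcoxon rank-sum test (first group greater) for every ordered
#' pair of groups, plus per-group medians.
#'
#' @param scores_by_group Named list of numeric score vectors (>= 2 groups,
#'   each with >= 3 finite values).
#' @return A `group_comparison`: list with `medians` and `p_values`
#'   (data.frame group_a, group_b, p_value for the alternative
#'   `group_a > group_b`).
#' @export
compare_groups <- function(scores_by_group) {
  scores_by_group <- lapply(scores_by_group, function(x) x[is.finite(x)])
  if (length(scores_by_group) < 2) stop("need >= 2 groups")
  small <- names(scores_by_group)[vapply(scores_by_group, length, 1L) < 3]
  if (length(small))
    stop("group(s) with < 3 scores: ", paste(small, collapse = ", "))
  gs <- names(scores_by_group)
  rows <- list()
  for (a in gs) for (b in gs) {
    if (a == b) next
    p <- suppressWarnings(stats::wilcox.test(scores_by_group[[a]],
                                             scores_by_group[[b]],
                                             alternative = "greater"))$p.value
    rows[[paste(a, b)]] <- data.frame(group_a = a, group_b = b, p_value = p,
                                      stringsAsFactors = FALSE)
  }
  structure(list(medians = vapply(scores_by_group, stats::median, numeric(1)),
                 p_values = do.call(rbind, rows)),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("group_comparison over", length(x$medians), "groups\n  medians:",
      paste(names(x$medians), round(x$medians, 4), sep = "=", collapse = ", "),
      "\n")
  print(x$p_values, row.names = FALSE)
  invisible(x)
}
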