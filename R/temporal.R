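#' Mean expression per developmental stage
#'
#' @param expr An `expression_matrix` whose sample metadata carries a
#'   non-missing `stage` for every sample.
#' @param stages Optional ordered stage labels; default is the order of
#'   first appearance in the metadata.
#' @return Numeric matrix features x stages of mean TPM, columns in
#'   chronological order.
#' @export
stage_expression <- function(expr, stages = NULL) {
  meta <- expr$sample_meta
  no_stage <- meta$sample_id[is.na(meta$stage) | meta$stage == ""]
  if (length(no_stage))
    stop("sample(s) without a stage label: ", paste(no_stage, collapse = ", "))
  if (is.null(stages)) stages <- unique(meta$stage)
  empty <- setdiff(stages, meta$stage)
  if (length(empty))
    stop("stage(s) with no samples: ", paste(empty, collapse = ", "))
  out <- sapply(stages, function(s)
    rowMeans(expr$values[, meta$sample_id[meta$stage == s], drop = FALSE]))
  out <- matrix(out, nrow = nrow(expr$values),
                dimnames = list(rownames(expr$values), stages))
  out
}

#' Classify monotone expression trends across stages
#'
#' A transcript is `up` iff each stage mean strictly exceeds the previous
#' one times `min_ratio`, `down` iff each is strictly below the previous
#' divided by `min_ratio`, otherwise `none`. The default `min_ratio = 1`
#' is strict monotonicity (ties break the trend); larger values demand a
#' fold-change margin at every step.
#'
#' @param stage_means Numeric vector of ordered stage means, or a matrix
#'   (features x stages) as from [stage_expression()].
#' @param min_ratio Per-step fold-change requirement (>= 1).
#' @return Character `up`/`down`/`none`, named per feature for matrix
#'   input.
#' @export
classify_trend <- function(stage_means, min_ratio = 1.0) {
  if (min_ratio < 1) stop("min_ratio must be >= 1")
  one <- function(m) {
    if (length(m) < 2) return("none")
    prev <- m[-length(m)]; nxt <- m[-1]
    if (all(nxt > prev * min_ratio)) "up"
    else if (all(nxt < prev / min_ratio)) "down"
    else "none"
  }
  if (is.matrix(stage_means))
    apply(stage_means, 1, one)
  else one(as.numeric(stage_means))
}

#' Map destination-genome trend calls back to source-genome partners
#'
#' Each source (genome A) lncRNA is listed with the trend of its conserved
#' partners' calls; partners called `none` are ignored, lncRNAs whose
#' partners disagree are flagged `mixed`, and lncRNAs with no up/down
#' partner are absent from the table.
#'
#' @param calls Named character vector of trend calls on genome-B
#'   transcripts (from [classify_trend()]).
#' @param conserved_pairs data.frame(a_id, b_id).
#' @return data.frame(a_id, trend, n_partners).
#' @export
map_trends_to_partner <- function(calls, conserved_pairs) {
  cp <- conserved_pairs[conserved_pairs$b_id %in% names(calls), , drop = FALSE]
  cp$trend <- unname(calls[cp$b_id])
  cp <- cp[cp$trend %in% c("up", "down"), , drop = FALSE]
  if (!nrow(cp))
    return(data.frame(a_id = character(), trend = character(),
                      n_partners = integer(), stringsAsFactors = FALSE))
  rows <- lapply(split(cp, cp$a_id), function(p) {
    tr <- unique(p$trend)
    data.frame(a_id = p$a_id[1],
               trend = if (length(tr) == 1) tr else "mixed",
               n_partners = nrow(p), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$a_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
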