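#' Upper-tail hypergeometric test
#'
#' Probability of drawing at least `k` annotated genes when `n` genes are
#' drawn without replacement from a universe of `N` genes of which `K`
#' carry the annotation: `P(X >= k)`, `X ~ Hypergeometric(N, K, n)`.
#'
#' @param k Observed overlap.
#' @param n Drawn set size (module size).
#' @param K Annotated set size (term size).
#' @param N Universe size.
#' @return The p-value.
#' @export
hypergeom_test <- function(k, n, K, N) {
  if (!(k >= 0 && k <= min(n, K) && min(n, K) <= N && n <= N && K <= N))
    stop("need 0 <= k <= min(n, K) <= N")
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

# normalize a gene->term map: data.frame(gene_id, term_id) -> list term -> genes
.term_list <- function(term_map) {
  if (is.list(term_map) && !is.data.frame(term_map)) return(term_map)
  split(term_map$gene_id, term_map$term_id)
}

#' Hypergeometric GO enrichment of one module's gene set
#'
#' One upper-tail test per term present in the universe; results are
#' flagged significant at `p < alpha` (raw, mirroring the usual P < 0.05
#' reading) or at `adjusted_p < alpha` under Benjamini-Hochberg correction,
#' and returned sorted by p-value.
#'
#' @param module_genes Character vector of gene ids; genes outside the
#'   universe are dropped with a warning.
#' @param term_map data.frame(gene_id, term_id) or list term -> gene ids.
#' @param universe Character vector of background genes (e.g. all expressed
#'   protein-coding genes).
#' @param alpha Significance level.
#' @param correction `"none"` (default) or `"BH"`.
#' @return data.frame(term_id, k, n, K, N, p_value, adjusted_p,
#'   significant), ascending in p.
#' @export
enrich_module <- function(module_genes, term_map, universe, alpha = 0.05,
                          correction = c("none", "BH")) {
  correction <- match.arg(correction)
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe")
  outside <- setdiff(module_genes, universe)
  if (length(outside)) {
    warning("dropping ", length(outside), " module gene(s) outside universe")
    module_genes <- intersect(module_genes, universe)
  }
  terms <- lapply(.term_list(term_map), function(g) intersect(unique(g), universe))
  terms <- terms[lengths(terms) >= 1]
  N <- length(universe); n <- length(module_genes)
  res <- data.frame(
    term_id = names(terms),
    k = vapply(terms, function(g) length(intersect(g, module_genes)), 1L),
    n = n,
    K = lengths(terms),
    N = N,
    stringsAsFactors = FALSE)
  res$p_value <- mapply(hypergeom_test, res$k, res$n, res$K, res$N)
  res$adjusted_p <- if (correction == "BH")
    stats::p.adjust(res$p_value, "BH") else NA_real_
  res$significant <- if (correction == "BH")
    res$adjusted_p < alpha else res$p_value < alpha
  res <- res[order(res$p_value, res$term_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Run enrichment for every module of a partition
#'
#' @param partition A `module_partition`.
#' @param term_map,universe,alpha,correction See [enrich_module()].
#' @param genes_of Optional filter applied to each module's members before
#'   testing (e.g. restrict to protein-coding genes).
#' @return data.frame of [enrich_module()] results with a leading `module`
#'   column.
#' @export
enrich_modules <- function(partition, term_map, universe, alpha = 0.05,
                           correction = c("none", "BH"), genes_of = NULL) {
  mods <- attr(partition, "modules")
  rows <- lapply(names(mods), function(m) {
    genes <- mods[[m]]
    if (!is.null(genes_of)) genes <- intersect(genes, genes_of)
    if (!length(genes)) return(NULL)
    r <- suppressWarnings(
      enrich_module(genes, term_map, universe, alpha, correction))
    if (nrow(r)) cbind(module = m, r, stringsAsFactors = FALSE) else NULL
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(module = character(), term_id = character(),
                      k = integer(), n = integer(), K = integer(),
                      N = integer(), p_value = numeric(),
                      adjusted_p = numeric(), significant = logical())
  rownames(out) <- NULL
  out
}

#' Transfer enriched module terms to the module's lncRNAs
#'
#' Every lncRNA inherits the significant terms of its module; unassigned
#' lncRNAs get nothing. When interaction scores are supplied, each
#' (lncRNA, term) is flagged `interaction_supported` if the lncRNA scores
#' above `score_threshold` with at least one module gene annotated to that
#' term.
#'
#' @param partition A `module_partition`.
#' @param results Module enrichment table from [enrich_modules()].
#' @param term_map data.frame(gene_id, term_id) or list term -> genes.
#' @param lncrna_ids LncRNA node ids within the partition.
#' @param interactions Optional data.frame(lncrna_id, gene_id, score) on a
#'   0-100 scale.
#' @param score_threshold Interaction-support cutoff (50, the usual
#'   mid-scale cut).
#' @return data.frame(lncrna_id, module, term_id, p_value,
#'   interaction_supported).
#' @export
annotate_lncrnas <- function(partition, results, term_map, lncrna_ids,
                             interactions = NULL, score_threshold = 50) {
  sig <- results[results$significant, , drop = FALSE]
  terms <- .term_list(term_map)
  rows <- list()
  for (l in lncrna_ids) {
    m <- unname(partition[l])
    if (is.na(m) || m == "unassigned") next
    st <- sig[sig$module == m, , drop = FALSE]
    if (!nrow(st)) next
    supported <- rep(NA, nrow(st))
    if (!is.null(interactions)) {
      hi <- interactions$gene_id[interactions$lncrna_id == l &
                                   interactions$score > score_threshold]
      mod_genes <- names(partition)[partition == m]
      supported <- vapply(st$term_id, function(t)
        length(intersect(intersect(terms[[t]], mod_genes), hi)) > 0, logical(1))
    }
    rows[[l]] <- data.frame(lncrna_id = l, module = m, term_id = st$term_id,
                            p_value = st$p_value,
                            interaction_supported = supported,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(lncrna_id = character(), module = character(),
                      term_id = character(), p_value = numeric(),
                      interaction_supported = logical())
  rownames(out) <- NULL
  out
}
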