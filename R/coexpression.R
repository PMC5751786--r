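#' Signed weighted adjacency from an expression matrix
#'
#' `a_ij = ((1 + cor(x_i, x_j)) / 2)^beta` with a zero diagonal. The signed
#' transform maps correlation -1 to adjacency 0 and +1 to 1, so
#' anticorrelated genes are disconnected rather than linked, distinguishing
#' up- from down-regulation.
#'
#' @param expr An `expression_matrix` or a features x samples numeric
#'   matrix. Constant features are dropped with a warning.
#' @param beta Soft-threshold power (integer >= 1); 12 is the signed-network
#'   convention.
#' @param correlation `"pearson"` (default) or `"spearman"`.
#' @param log_transform Apply `log2(x + 1)` before correlating (usual for
#'   TPM input).
#' @return Symmetric adjacency matrix in [0, 1] with zero diagonal.
#' @export
signed_adjacency <- function(expr, beta = 12, correlation = c("pearson", "spearman"),
                             log_transform = FALSE) {
  correlation <- match.arg(correlation)
  if (beta < 1) stop("beta must be >= 1")
  x <- if (inherits(expr, "expression_matrix")) expr$values else as.matrix(expr)
  if (ncol(x) < 3) stop("need >= 3 samples")
  if (log_transform) x <- log2(x + 1)
  sds <- apply(x, 1, stats::sd)
  if (any(sds == 0)) {
    warning("dropping ", sum(sds == 0), " constant feature(s)")
    x <- x[sds > 0, , drop = FALSE]
  }
  a <- ((1 + stats::cor(t(x), method = correlation)) / 2)^beta
  diag(a) <- 0
  a
}

#' Pick the soft-threshold power by scale-free topology fit
#'
#' Returns the smallest power whose connectivity distribution fits a
#' power law with signed R-squared at least `target_r2` (log-log
#' regression of binned frequency on connectivity, requiring a negative
#' slope), falling back to `fallback` when none qualifies.
#'
#' @param expr Input accepted by [signed_adjacency()].
#' @param powers Candidate powers.
#' @param target_r2 Required fit.
#' @param fallback Power used when no candidate fits (12, the signed
#'   WGCNA convention).
#' @param ... Passed to [signed_adjacency()].
#' @return List with `beta` and `fits` (data.frame power, r_squared).
#' @export
pick_soft_threshold <- function(expr, powers = 1:20, target_r2 = 0.8,
                                fallback = 12, ...) {
  x <- if (inherits(expr, "expression_matrix")) expr$values else as.matrix(expr)
  a1 <- signed_adjacency(x, beta = 1, ...)
  fits <- data.frame(power = powers, r_squared = NA_real_)
  for (i in seq_along(powers)) {
    k <- rowSums(a1^powers[i])
    fits$r_squared[i] <- .scale_free_r2(k)
  }
  ok <- which(fits$r_squared >= target_r2)
  list(beta = if (length(ok)) powers[ok[1]] else fallback, fits = fits)
}

.scale_free_r2 <- function(k, n_breaks = 10) {
  k <- k[k > 0]
  if (length(k) < n_breaks) return(NA_real_)
  bins <- cut(k, breaks = n_breaks)
  freq <- tapply(k, bins, length)
  mids <- tapply(k, bins, mean)
  keep <- !is.na(freq) & freq > 0
  if (sum(keep) < 3) return(NA_real_)
  fit <- stats::lm(log10(freq[keep]) ~ log10(mids[keep]))
  r2 <- summary(fit)$r.squared
  if (stats::coef(fit)[2] >= 0) -r2 else r2
}

#' Topological overlap matrix
#'
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` for
#' i != j (the sum excludes u in {i, j}, which holds automatically for a
#' zero-diagonal adjacency), with `TOM_ii = 1`. With no shared neighbors
#' TOM reduces to the adjacency itself.
#'
#' @param a Symmetric adjacency matrix in [0, 1] with zero diagonal.
#' @return TOM matrix (symmetric, in [0, 1], unit diagonal).
#' @export
topological_overlap <- function(a) {
  a <- as.matrix(a)
  if (nrow(a) != ncol(a)) stop("adjacency must be square")
  if (any(abs(a - t(a)) > 1e-12)) stop("adjacency must be symmetric")
  if (any(diag(a) != 0)) stop("adjacency must have a zero diagonal")
  k <- rowSums(a)
  num <- a %*% a + a
  den <- outer(k, k, pmin) + 1 - a
  tom <- num / den
  diag(tom) <- 1
  dimnames(tom) <- dimnames(a)
  tom
}

#' Detect co-expression modules from a TOM
#'
#' Average-linkage hierarchical clustering on the dissimilarity `1 - TOM`,
#' cut at a fixed height; clusters smaller than `min_module_size` become
#' `"unassigned"`. Module labels are deterministic: `M1` is the largest
#' module, ties broken by the lexicographically smallest member id.
#'
#' @param tom TOM matrix (symmetric, [0, 1], with dimnames).
#' @param min_module_size Minimum genes per module (30 is the usual
#'   setting).
#' @param cut_height Static cut height on `1 - TOM` (0.9, the WGCNA
#'   static-cut convention; TOM dissimilarities concentrate near 1).
#' @return A `module_partition`: named character vector node -> module
#'   label, with attributes `modules` (list of member ids) and `params`.
#' @export
detect_modules <- function(tom, min_module_size = 30, cut_height = 0.9) {
  if (is.null(rownames(tom))) stop("tom needs dimnames")
  d <- stats::as.dist(1 - tom)
  hc <- stats::hclust(d, method = "average")
  raw <- stats::cutree(hc, h = cut_height)
  names(raw) <- rownames(tom)
  sizes <- table(raw)
  big <- names(sizes)[sizes >= min_module_size]
  lab <- rep("unassigned", length(raw))
  names(lab) <- names(raw)
  if (length(big)) {
    first_member <- vapply(big, function(cl) min(names(raw)[raw == cl]),
                           character(1))
    ord <- big[order(-as.integer(sizes[big]), first_member)]
    for (i in seq_along(ord)) lab[raw == ord[i]] <- paste0("M", i)
  } else {
    warning("no cluster reaches min_module_size; all nodes unassigned")
  }
  mods <- split(names(lab), lab)
  mods <- mods[setdiff(names(mods), "unassigned")]
  structure(lab, class = "module_partition", modules = mods,
            params = list(min_module_size = min_module_size,
                          cut_height = cut_height))
}

#' @export
print.module_partition <- function(x, ...) {
  mods <- attr(x, "modules")
  cat("module_partition:", length(mods), "module(s),",
      sum(x == "unassigned"), "unassigned of", length(x), "nodes\n")
  if (length(mods))
    cat("  sizes:", paste(names(mods), lengths(mods), sep = "=",
                          collapse = ", "), "\n")
  invisible(x)
}

#' Per-node connectivity within modules
#'
#' An edge joins two nodes of the same module when their topological
#' overlap exceeds `tom_edge_cutoff` (0.2, the usual hard threshold).
#' Degree is the edge count; connectivity is the node's degree divided by
#' the module's total degree, so connectivities sum to 1 in every module
#' with at least one edge. With `weighted = TRUE` degree is the sum of
#' above-cutoff TOM values instead.
#'
#' @param tom TOM matrix.
#' @param partition A `module_partition` over the same nodes.
#' @param tom_edge_cutoff Hard TOM threshold defining edges.
#' @param node_types Optional named vector (node -> `lncRNA` / `PCG`).
#' @param weighted Use TOM-weighted degree.
#' @return data.frame(node_id, module, degree, connectivity, node_type).
#' @export
module_connectivity <- function(tom, partition, tom_edge_cutoff = 0.2,
                                node_types = NULL, weighted = FALSE) {
  nodes <- rownames(tom)
  stopifnot(!is.null(nodes), all(nodes %in% names(partition)))
  out <- data.frame(node_id = nodes,
                    module = unname(partition[nodes]),
                    degree = 0, connectivity = 0,
                    node_type = if (is.null(node_types)) NA_character_
                                else unname(node_types[nodes]),
                    stringsAsFactors = FALSE)
  for (m in setdiff(unique(out$module), "unassigned")) {
    ids <- nodes[out$module == m]
    sub <- tom[ids, ids, drop = FALSE]
    adj <- sub > tom_edge_cutoff
    diag(adj) <- FALSE
    deg <- if (weighted) rowSums(sub * adj) else rowSums(adj)
    tot <- sum(deg)
    out$degree[match(ids, out$node_id)] <- deg
    out$connectivity[match(ids, out$node_id)] <- if (tot > 0) deg / tot else 0
  }
  out
}

#' Compare connectivity between lncRNAs and protein-coding genes
#'
#' One-sided two-sample Wilcoxon rank-sum test of the alternative that
#' lncRNA connectivities (pooled across modules) exceed PCG
#' connectivities.
#'
#' @param conn_table Output of [module_connectivity()] with `node_type`
#'   filled.
#' @return List with `statistic`, `p_value`, `medians` (named: lncRNA,
#'   PCG), and group sizes.
#' @export
compare_connectivity <- function(conn_table) {
  ct <- conn_table[conn_table$module != "unassigned", , drop = FALSE]
  l <- ct$connectivity[ct$node_type == "lncRNA"]
  p <- ct$connectivity[ct$node_type == "PCG"]
  if (length(l) < 3 || length(p) < 3)
    stop("need >= 3 assigned nodes of each type (lncRNA: ", length(l),
         ", PCG: ", length(p), ")")
  wt <- suppressWarnings(stats::wilcox.test(l, p, alternative = "greater"))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       medians = c(lncRNA = stats::median(l), PCG = stats::median(p)),
       n = c(lncRNA = length(l), PCG = length(p)))
}
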