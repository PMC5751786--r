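# Independent oracles and small fixture builders (all generated in code).

# brute-force per-base chain mapper: maps every base of iv through every
# candidate chain, then applies the same status semantics as lift_interval
brute_lift <- function(iv, chains, min_match = 0.95) {
  map_chain <- function(ch) {
    b <- ch$blocks
    t0 <- ch$t_start + cumsum(c(0, (b$size + b$dt)[-nrow(b)]))
    q0 <- ch$q_start + cumsum(c(0, (b$size + b$dq)[-nrow(b)]))
    fwd <- c()
    for (pos in seq(iv$start, iv$end - 1)) {
      for (i in seq_len(nrow(b))) {
        if (pos >= t0[i] && pos < t0[i] + b$size[i]) {
          qn <- q0[i] + (pos - t0[i])
          fwd <- c(fwd, if (ch$q_strand == "-") ch$q_size - 1 - qn else qn)
          break
        }
      }
    }
    fwd
  }
  cand <- Filter(function(ch) ch$t_name == iv$chrom &&
                   ch$t_start < iv$end && ch$t_end > iv$start, chains)
  if (!length(cand))
    return(list(status = "unmapped", mapped = NULL, match_fraction = 0))
  width <- iv$end - iv$start
  maps <- lapply(cand, map_chain)
  fracs <- vapply(maps, length, 1L) / width
  ok <- which(fracs >= min_match)
  if (length(ok) >= 2L) {
    best <- ok[which.max(vapply(cand[ok], `[[`, numeric(1), "score"))]
    return(list(status = "ambiguous", mapped = NULL,
                match_fraction = fracs[best]))
  }
  if (length(ok) == 1L) {
    ch <- cand[[ok]]; fwd <- maps[[ok]]
    st <- if (iv$strand == ".") "." else if (iv$strand == ch$q_strand) "+" else "-"
    return(list(status = "mapped",
                mapped = list(chrom = ch$q_name, start = min(fwd),
                              end = max(fwd) + 1, strand = st),
                match_fraction = fracs[ok]))
  }
  best <- order(-fracs, -vapply(cand, `[[`, numeric(1), "score"))[1]
  if (fracs[best] > 0)
    return(list(status = "partial", mapped = NULL,
                match_fraction = fracs[best]))
  list(status = "unmapped", mapped = NULL, match_fraction = 0)
}

# random valid chain on chrT -> chrQ
rand_chain <- function(id, t_size = 10000, q_size = 10000) {
  n_blocks <- sample(1:4, 1)
  size <- sample(30:250, n_blocks, replace = TRUE)
  dt <- c(sample(0:120, max(0, n_blocks - 1), replace = TRUE), 0)
  dq <- c(sample(0:120, max(0, n_blocks - 1), replace = TRUE), 0)
  t_span <- sum(size + dt); q_span <- sum(size + dq)
  t_start <- sample(0:(t_size - t_span), 1)
  q_start <- sample(0:(q_size - q_span), 1)
  chain(score = sample(100:10000, 1), t_name = "chrT", t_size = t_size,
        t_start = t_start, t_end = t_start + t_span,
        q_name = "chrQ", q_size = q_size,
        q_strand = sample(c("+", "-"), 1),
        q_start = q_start, q_end = q_start + q_span,
        blocks = data.frame(size = size, dt = dt, dq = dq), id = id)
}

# triple-loop TOM oracle
tom_loop <- function(a) {
  n <- nrow(a)
  k <- rowSums(a)
  out <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    num <- a[i, j]
    for (u in seq_len(n)) if (u != i && u != j) num <- num + a[i, u] * a[u, j]
    out[i, j] <- num / (min(k[i], k[j]) + 1 - a[i, j])
  }
  out
}

# exhaustive hypergeometric upper tail by enumerating all C(N, n) draws
hyper_enum <- function(k, n, K, N) {
  if (n == 0) return(as.numeric(k == 0))
  draws <- utils::combn(N, n)
  succ <- colSums(draws <= K)
  mean(succ >= k)
}

# single-transcript annotation builder: exons is a list of c(start, end)
simple_tx <- function(id, chrom, strand, exons, biotype = "lncRNA",
                      gene = sub("\\..*$", "", id)) {
  do.call(rbind, lapply(exons, function(e)
    data.frame(transcript_id = id, gene_id = gene, chrom = chrom,
               strand = strand, start = e[1], end = e[2], biotype = biotype,
               stringsAsFactors = FALSE)))
}

mk_anno <- function(...) annotation_set(do.call(rbind, list(...)))

# tiny expression matrix with trivial metadata
mk_expr <- function(values, species = "genomeA", stage = NA_character_) {
  expression_matrix(values, data.frame(
    sample_id = colnames(values), species = species,
    stage = rep_len(stage, ncol(values)), stringsAsFactors = FALSE))
}

# small, fast synthetic configuration for pipeline-level tests
small_config <- function(seed = 1L, ...) {
  synthetic_config(seed = seed, n_pcg = 60, n_lncrna = 24,
                   n_conserved_lnc = 12, n_modules = 2, module_size = 20,
                   lnc_per_module = 2, n_samples = 30, n_monotone_up = 3,
                   n_monotone_down = 3, n_bidirectional = 3,
                   bidirectional_distances = c(500, 2000, 2001),
                   n_go_terms = 12, chrom_length = 6e5, ...)
}

# direct geometric re-check of one divergent pair (independent of the
# implementation's search order)
bidir_predicates_hold <- function(l_row, p_row, all_tss, max_dist) {
  if (l_row$strand == p_row$strand) return(FALSE)
  if (l_row$chrom != p_row$chrom) return(FALSE)
  tss_minus <- if (l_row$strand == "-") l_row$tss else p_row$tss
  tss_plus <- if (l_row$strand == "+") l_row$tss else p_row$tss
  d <- tss_plus - tss_minus
  if (d < 0 || d > max_dist) return(FALSE)
  lo <- min(tss_minus, tss_plus); hi <- max(tss_minus, tss_plus)
  between <- all_tss$chrom == l_row$chrom & all_tss$tss > lo &
    all_tss$tss < hi &
    !(all_tss$transcript_id %in% c(l_row$transcript_id, p_row$transcript_id))
  !any(between)
}

# random stranded annotation for property tests
rand_tss_anno <- function(n, chrom = "chrR", biotype = "lncRNA",
                          prefix = "T", max_pos = 50000) {
  starts <- sample(0:max_pos, n)
  rows <- lapply(seq_len(n), function(i)
    simple_tx(sprintf("%s%03d.1", prefix, i), chrom,
              sample(c("+", "-"), 1),
              list(c(starts[i], starts[i] + sample(200:800, 1))),
              biotype = biotype))
  do.call(mk_anno, rows)
}
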