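#' Construct a UCSC alignment chain
#'
#' A chain aligns an interval of the target (source) genome to an interval
#' of the query (destination) genome through ordered gapped blocks. Query
#' coordinates are stored in the chain's native convention: when
#' `q_strand == "-"` they refer to the reversed query strand, exactly as in
#' UCSC chain files; conversion to forward-strand coordinates happens only
#' when a lift result is emitted.
#'
#' @param score Alignment score.
#' @param t_name,t_size,t_start,t_end Target (source genome) header fields;
#'   target strand is always `+` (UCSC convention).
#' @param q_name,q_size,q_strand,q_start,q_end Query (destination genome)
#'   header fields.
#' @param blocks data.frame with columns `size`, `dt`, `dq` (aligned bases,
#'   gap on target after block, gap on query after block; the last block has
#'   `dt = dq = 0`).
#' @param id Chain id.
#' @return An object of class `chain`.
#' @export
chain <- function(score, t_name, t_size, t_start, t_end,
                  q_name, q_size, q_strand, q_start, q_end, blocks, id) {
  blocks <- as.data.frame(blocks)
  stopifnot(all(c("size", "dt", "dq") %in% names(blocks)), nrow(blocks) >= 1L)
  if (any(blocks$size <= 0) || any(blocks$dt < 0) || any(blocks$dq < 0))
    stop("chain ", id, ": block sizes must be > 0 and gaps >= 0")
  if (!q_strand %in% c("+", "-")) stop("chain ", id, ": q_strand must be + or -")
  if (sum(blocks$size + blocks$dt) != t_end - t_start)
    stop("chain ", id, ": blocks sum to ", sum(blocks$size + blocks$dt),
         " on target but header span is ", t_end - t_start)
  if (sum(blocks$size + blocks$dq) != q_end - q_start)
    stop("chain ", id, ": blocks sum to ", sum(blocks$size + blocks$dq),
         " on query but header span is ", q_end - q_start)
  structure(list(score = score, t_name = t_name, t_size = t_size,
                 t_start = t_start, t_end = t_end, q_name = q_name,
                 q_size = q_size, q_strand = q_strand, q_start = q_start,
                 q_end = q_end, blocks = blocks, id = as.character(id)),
            class = "chain")
}

#' @export
print.chain <- function(x, ...) {
  cat(sprintf("chain %s (score %g): %s:[%d,%d)+ -> %s:[%d,%d)%s, %d block(s)\n",
              x$id, x$score, x$t_name, x$t_start, x$t_end,
              x$q_name, x$q_start, x$q_end, x$q_strand, nrow(x$blocks)))
  invisible(x)
}

#' Read a UCSC chain file
#'
#' @param path Chain file path.
#' @return List of `chain` objects. Header/block consistency is validated
#'   per chain; a mismatch raises an error naming the chain id.
#' @export
read_chain <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  chains <- list()
  i <- 1L
  while (i <= length(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln)) { i <- i + 1L; next }
    f <- strsplit(ln, "\\s+")[[1]]
    if (f[1] != "chain" || length(f) != 13L)
      stop("malformed chain header at line ", i)
    hdr <- f
    blocks <- list(); j <- i + 1L
    repeat {
      if (j > length(lines)) stop("chain ", hdr[13], ": truncated block list")
      bl <- trimws(lines[j])
      if (!nzchar(bl)) stop("chain ", hdr[13], ": truncated block list")
      bf <- as.numeric(strsplit(bl, "\\s+")[[1]])
      if (length(bf) == 3L) {
        blocks[[length(blocks) + 1L]] <- c(bf[1], bf[2], bf[3])
      } else if (length(bf) == 1L) {
        blocks[[length(blocks) + 1L]] <- c(bf[1], 0, 0)
        j <- j + 1L
        break
      } else stop("chain ", hdr[13], ": malformed block line ", j)
      j <- j + 1L
    }
    bdf <- as.data.frame(do.call(rbind, blocks))
    names(bdf) <- c("size", "dt", "dq")
    chains[[length(chains) + 1L]] <- chain(
      score = as.numeric(hdr[2]),
      t_name = hdr[3], t_size = as.numeric(hdr[4]),
      t_start = as.numeric(hdr[6]), t_end = as.numeric(hdr[7]),
      q_name = hdr[8], q_size = as.numeric(hdr[9]), q_strand = hdr[10],
      q_start = as.numeric(hdr[11]), q_end = as.numeric(hdr[12]),
      blocks = bdf, id = hdr[13])
    i <- j
  }
  chains
}

#' Write chains to a UCSC chain file
#' @param chains List of `chain` objects.
#' @param path Output path.
#' @export
write_chain <- function(chains, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (ch in chains) {
    writeLines(sprintf("chain %g %s %g + %g %g %s %g %s %g %g %s",
                       ch$score, ch$t_name, ch$t_size, ch$t_start, ch$t_end,
                       ch$q_name, ch$q_size, ch$q_strand, ch$q_start,
                       ch$q_end, ch$id), con)
    b <- ch$blocks
    n <- nrow(b)
    if (n > 1L)
      writeLines(sprintf("%g\t%g\t%g", b$size[-n], b$dt[-n], b$dq[-n]), con)
    writeLines(sprintf("%g", b$size[n]), con)
    writeLines("", con)
  }
  invisible(path)
}

# per-block cumulative coordinates in chain-native space:
# t0/t1 on target forward strand, q0/q1 on query strand q_strand
.chain_coords <- function(ch) {
  b <- ch$blocks
  t0 <- ch$t_start + cumsum(c(0, (b$size + b$dt)[-nrow(b)]))
  q0 <- ch$q_start + cumsum(c(0, (b$size + b$dq)[-nrow(b)]))
  data.frame(t0 = t0, t1 = t0 + b$size, q0 = q0, q1 = q0 + b$size)
}

.compose_strand <- function(iv_strand, q_strand) {
  if (iv_strand == ".") return(".")
  if (iv_strand == q_strand) "+" else "-"
}

# map iv through one chain; returns list(bases, lo, hi) with destination
# forward-strand hull of mapped bases (lo/hi NULL when bases == 0)
.map_through_chain <- function(iv, ch) {
  co <- .chain_coords(ch)
  os <- pmax(iv$start, co$t0)
  oe <- pmin(iv$end, co$t1)
  w <- pmax(0, oe - os)
  hit <- which(w > 0)
  if (!length(hit)) return(list(bases = 0))
  qlo <- co$q0[hit] + (os[hit] - co$t0[hit])
  qhi <- qlo + w[hit]
  if (ch$q_strand == "-") {
    fwd_lo <- ch$q_size - qhi
    fwd_hi <- ch$q_size - qlo
  } else {
    fwd_lo <- qlo; fwd_hi <- qhi
  }
  list(bases = sum(w), lo = min(fwd_lo), hi = max(fwd_hi))
}

#' Lift a genome interval through alignment chains
#'
#' Reproduces liftOver's default behavior: the interval is mapped base-wise
#' through chains whose target side overlaps it; the result is the
#' forward-strand hull of mapped destination bases. Status is `mapped` when
#' exactly one chain maps at least `min_match` of the interval's bases,
#' `ambiguous` when a second chain also reaches `min_match`, `partial` when
#' some but too few bases map, and `unmapped` otherwise.
#'
#' @param iv A `genome_interval` on the chains' target genome.
#' @param chains List of `chain` objects (as from [read_chain()]).
#' @param min_match Minimum fraction of bases that must map (liftOver
#'   default 0.95).
#' @return A `lift_result`: list with `status`, `mapped` (a
#'   `genome_interval` or `NULL`), `match_fraction`, `chain_id`.
#' @export
lift_interval <- function(iv, chains, min_match = 0.95) {
  res <- function(status, mapped = NULL, frac = 0, id = NA_character_)
    structure(list(status = status, mapped = mapped, match_fraction = frac,
                   chain_id = id), class = "lift_result")
  cand <- Filter(function(ch) ch$t_name == iv$chrom &&
                   ch$t_start < iv$end && ch$t_end > iv$start, chains)
  if (!length(cand)) return(res("unmapped"))
  width <- iv$end - iv$start
  maps <- lapply(cand, .map_through_chain, iv = iv)
  fracs <- vapply(maps, function(m) m$bases / width, numeric(1))
  ok <- which(fracs >= min_match)
  if (length(ok) >= 2L) {
    best <- ok[which.max(vapply(cand[ok], `[[`, numeric(1), "score"))]
    return(res("ambiguous", frac = fracs[best], id = cand[[best]]$id))
  }
  if (length(ok) == 1L) {
    ch <- cand[[ok]]; m <- maps[[ok]]
    mapped <- genome_interval(ch$q_name, m$lo, m$hi,
                              .compose_strand(iv$strand, ch$q_strand))
    return(res("mapped", mapped, fracs[ok], ch$id))
  }
  # no chain reaches min_match: report through the best partial chain
  best <- order(-fracs, -vapply(cand, `[[`, numeric(1), "score"))[1]
  if (fracs[best] > 0)
    return(res("partial", frac = fracs[best], id = cand[[best]]$id))
  res("unmapped")
}

#' @export
print.lift_result <- function(x, ...) {
  cat("lift_result:", x$status,
      sprintf("(fraction %.3f, chain %s)\n", x$match_fraction, x$chain_id))
  if (!is.null(x$mapped)) print(x$mapped)
  invisible(x)
}

#' Lift transcript spans through alignment chains
#'
#' Lifts each transcript's genomic span (hull of its exons) and carries the
#' transcript id through.
#'
#' @param anno An `annotation_set` on the chains' target genome.
#' @param chains List of `chain` objects.
#' @param min_match Minimum mapped-base fraction; see [lift_interval()].
#' @param ids Optional subset of transcript ids to lift.
#' @return Named list of `lift_result`, one per transcript.
#' @export
lift_transcripts <- function(anno, chains, min_match = 0.95, ids = NULL) {
  tx <- anno$transcripts
  if (!is.null(ids)) tx <- tx[tx$transcript_id %in% ids, , drop = FALSE]
  out <- lapply(seq_len(nrow(tx)), function(i)
    lift_interval(genome_interval(tx$chrom[i], tx$start[i], tx$end[i],
                                  tx$strand[i]), chains, min_match))
  stats::setNames(out, tx$transcript_id)
}

#' Invert a chain
#'
#' Swaps target and query so that lifting can be done in the opposite
#' direction. The inverted chain keeps the UCSC convention of a
#' forward-strand target: for a `-`-strand chain the block list is reversed
#' and both coordinate systems are re-expressed accordingly.
#'
#' @param ch A `chain`.
#' @return The inverted `chain` (id suffixed `_inv`).
#' @export
invert_chain <- function(ch) {
  b <- ch$blocks
  if (ch$q_strand == "+") {
    chain(ch$score, ch$q_name, ch$q_size, ch$q_start, ch$q_end,
          ch$t_name, ch$t_size, "+", ch$t_start, ch$t_end,
          data.frame(size = b$size, dt = b$dq, dq = b$dt),
          paste0(ch$id, "_inv"))
  } else {
    n <- nrow(b)
    # reverse block order; the inter-block gaps reverse with them
    size <- rev(b$size)
    dt <- c(rev(b$dq[-n]), 0)
    dq <- c(rev(b$dt[-n]), 0)
    chain(ch$score, ch$q_name, ch$q_size,
          ch$q_size - ch$q_end, ch$q_size - ch$q_start,
          ch$t_name, ch$t_size, "-",
          ch$t_size - ch$t_end, ch$t_size - ch$t_start,
          data.frame(size = size, dt = dt, dq = dq),
          paste0(ch$id, "_inv"))
  }
}

#' Lift a BED file through a chain file
#'
#' Batch convenience wrapper: reads BED (0-based half-open), lifts every
#' interval, writes mapped intervals to `path_out` and returns the full
#' result table.
#'
#' @param path_in Input BED path (3-6 columns).
#' @param chains List of `chain` objects.
#' @param path_out Optional output BED path for mapped intervals.
#' @param min_match Minimum mapped-base fraction.
#' @return data.frame with input coordinates, status, fraction and mapped
#'   coordinates.
#' @export
lift_bed <- function(path_in, chains, path_out = NULL, min_match = 0.95) {
  bed <- utils::read.table(path_in, sep = "\t", stringsAsFactors = FALSE)
  names(bed)[1:3] <- c("chrom", "start", "end")
  name <- if (ncol(bed) >= 4) bed[[4]] else sprintf("iv%d", seq_len(nrow(bed)))
  strand <- if (ncol(bed) >= 6) bed[[6]] else rep(".", nrow(bed))
  rows <- lapply(seq_len(nrow(bed)), function(i) {
    r <- lift_interval(genome_interval(bed$chrom[i], bed$start[i], bed$end[i],
                                       strand[i]), chains, min_match)
    data.frame(chrom = bed$chrom[i], start = bed$start[i], end = bed$end[i],
               name = name[i], status = r$status,
               match_fraction = r$match_fraction,
               mapped_chrom = if (is.null(r$mapped)) NA_character_ else r$mapped$chrom,
               mapped_start = if (is.null(r$mapped)) NA_real_ else r$mapped$start,
               mapped_end = if (is.null(r$mapped)) NA_real_ else r$mapped$end,
               mapped_strand = if (is.null(r$mapped)) NA_character_ else r$mapped$strand,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(path_out)) {
    m <- out[out$status == "mapped", , drop = FALSE]
    utils::write.table(
      data.frame(m$mapped_chrom, as.integer(m$mapped_start),
                 as.integer(m$mapped_end), m$name, 0L, m$mapped_strand),
      path_out, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  out
}
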