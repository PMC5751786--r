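#' Create a genome interval
#'
#' Intervals are 0-based half-open (BED convention) throughout the package;
#' conversion to/from 1-based inclusive GTF coordinates happens only at file
#' boundaries.
#'
#' @param chrom Chromosome name (non-empty string).
#' @param start 0-based start offset.
#' @param end End offset (exclusive); must satisfy `start < end`.
#' @param strand One of `"+"`, `"-"`, `"."`.
#' @return An object of class `genome_interval`.
#' @export
genome_interval <- function(chrom, start, end, strand = ".") {
  stopifnot(is.character(chrom), length(chrom) == 1L, nzchar(chrom))
  start <- as.numeric(start); end <- as.numeric(end)
  if (!(start >= 0 && start < end))
    stop("invalid interval: need 0 <= start < end, got [", start, ", ", end, ")")
  if (!strand %in% c("+", "-", "."))
    stop("strand must be one of '+', '-', '.'")
  structure(list(chrom = chrom, start = start, end = end, strand = strand),
            class = "genome_interval")
}

#' @export
print.genome_interval <- function(x, ...) {
  cat(sprintf("%s:[%d,%d)%s\n", x$chrom, x$start, x$end, x$strand))
  invisible(x)
}

#' Build an annotation set from an exon table
#'
#' @param exons data.frame with columns `transcript_id`, `gene_id`, `chrom`,
#'   `strand`, `start`, `end`, `biotype` (0-based half-open exon coordinates).
#'   Biotype is one of `protein_coding`, `lncRNA`, `unknown`.
#' @return An `annotation_set`: a list with `$exons` (sorted exon table) and
#'   `$transcripts` (one row per transcript: span, exon count, spliced length).
#' @export
annotation_set <- function(exons) {
  needed <- c("transcript_id", "gene_id", "chrom", "strand", "start", "end", "biotype")
  missing <- setdiff(needed, names(exons))
  if (length(missing)) stop("exon table lacks columns: ", paste(missing, collapse = ", "))
  exons <- exons[needed]
  exons$start <- as.numeric(exons$start)
  exons$end <- as.numeric(exons$end)
  if (nrow(exons)) {
    if (any(exons$start < 0 | exons$start >= exons$end))
      stop("exon coordinates must satisfy 0 <= start < end")
    if (!all(exons$strand %in% c("+", "-", ".")))
      stop("exon strand must be '+', '-' or '.'")
    if (!all(exons$biotype %in% c("protein_coding", "lncRNA", "unknown")))
      stop("biotype must be protein_coding, lncRNA or unknown")
    exons <- exons[order(exons$transcript_id, exons$start), , drop = FALSE]
    rownames(exons) <- NULL
    # per-transcript consistency: single chrom/strand, non-overlapping exons
    by_tx <- split(seq_len(nrow(exons)), exons$transcript_id)
    for (idx in by_tx) {
      if (length(unique(exons$chrom[idx])) != 1L ||
          length(unique(exons$strand[idx])) != 1L)
        stop("transcript ", exons$transcript_id[idx[1]],
             " has exons on multiple chromosomes or strands")
      if (length(idx) > 1L) {
        s <- exons$start[idx]; e <- exons$end[idx]
        if (any(s[-1] < e[-length(e)]))
          stop("transcript ", exons$transcript_id[idx[1]], " has overlapping exons")
      }
    }
    first <- !duplicated(exons$transcript_id)
    tx <- data.frame(
      transcript_id = exons$transcript_id[first],
      gene_id = exons$gene_id[first],
      chrom = exons$chrom[first],
      strand = exons$strand[first],
      start = as.numeric(tapply(exons$start, exons$transcript_id, min)[exons$transcript_id[first]]),
      end = as.numeric(tapply(exons$end, exons$transcript_id, max)[exons$transcript_id[first]]),
      n_exons = as.integer(tapply(exons$start, exons$transcript_id, length)[exons$transcript_id[first]]),
      spliced_length = as.numeric(tapply(exons$end - exons$start, exons$transcript_id, sum)[exons$transcript_id[first]]),
      biotype = exons$biotype[first],
      stringsAsFactors = FALSE
    )
    tx <- tx[order(tx$chrom, tx$start, tx$transcript_id), , drop = FALSE]
    rownames(tx) <- NULL
  } else {
    tx <- data.frame(transcript_id = character(), gene_id = character(),
                     chrom = character(), strand = character(),
                     start = numeric(), end = numeric(), n_exons = integer(),
                     spliced_length = numeric(), biotype = character(),
                     stringsAsFactors = FALSE)
  }
  structure(list(transcripts = tx, exons = exons), class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat("annotation_set:", nrow(x$transcripts), "transcripts,",
      nrow(x$exons), "exons on",
      length(unique(x$transcripts$chrom)), "chromosome(s)\n")
  tb <- table(x$transcripts$biotype)
  if (length(tb)) cat("  biotypes:", paste(names(tb), tb, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Subset an annotation set by transcript id
#' @param anno An `annotation_set`.
#' @param ids Transcript ids to keep.
#' @export
subset_transcripts <- function(anno, ids) {
  annotation_set(anno$exons[anno$exons$transcript_id %in% ids, , drop = FALSE])
}

#' Default Ensembl-style biotype collapse map
#'
#' Maps Ensembl (sub-)biotypes onto the package's three-value vocabulary;
#' anything absent from the map becomes `unknown`.
#' @return Named character vector (raw biotype -> collapsed biotype).
#' @export
default_biotype_map <- function() {
  c(protein_coding = "protein_coding",
    lncRNA = "lncRNA", lincRNA = "lncRNA", antisense = "lncRNA",
    sense_intronic = "lncRNA", sense_overlapping = "lncRNA",
    processed_transcript = "lncRNA", `3prime_overlapping_ncRNA` = "lncRNA",
    bidirectional_promoter_lncRNA = "lncRNA", macro_lncRNA = "lncRNA")
}

.parse_gtf_attr <- function(attr, key) {
  m <- regmatches(attr, regexec(paste0(key, '\\s+"([^"]*)"'), attr))
  vapply(m, function(x) if (length(x) == 2L) x[2] else NA_character_, character(1))
}

#' Read transcript models from a GTF file
#'
#' Only `exon` features are used. 1-based inclusive GTF coordinates are
#' converted to 0-based half-open. Biotype is taken from the first of
#' `gene_biotype`, `transcript_biotype`, `biotype` attributes and collapsed
#' through `biotype_map`; unmapped values become `unknown`.
#'
#' @param path GTF file path.
#' @param biotype_map Named character vector collapsing raw biotypes; see
#'   [default_biotype_map()].
#' @return An `annotation_set`.
#' @export
read_gtf <- function(path, biotype_map = default_biotype_map()) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  rows <- vector("list", sum(keep))
  n <- 0L
  for (i in which(keep)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) != 9L)
      stop("malformed GTF line ", i, ": expected 9 tab-separated fields, got ",
           length(f))
    if (f[3] != "exon") next
    start1 <- suppressWarnings(as.numeric(f[4])); end1 <- suppressWarnings(as.numeric(f[5]))
    if (is.na(start1) || is.na(end1))
      stop("malformed GTF line ", i, ": non-numeric coordinates")
    tid <- .parse_gtf_attr(f[9], "transcript_id")
    if (is.na(tid))
      stop("malformed GTF line ", i, ": exon without transcript_id attribute")
    gid <- .parse_gtf_attr(f[9], "gene_id")
    bt <- .parse_gtf_attr(f[9], "gene_biotype")
    if (is.na(bt)) bt <- .parse_gtf_attr(f[9], "transcript_biotype")
    if (is.na(bt)) bt <- .parse_gtf_attr(f[9], "biotype")
    n <- n + 1L
    rows[[n]] <- data.frame(
      transcript_id = tid,
      gene_id = if (is.na(gid)) tid else gid,
      chrom = f[1], strand = f[7],
      start = start1 - 1, end = end1,
      biotype = if (!is.na(bt) && bt %in% names(biotype_map)) unname(biotype_map[bt]) else "unknown",
      stringsAsFactors = FALSE)
  }
  exons <- if (n) do.call(rbind, rows[seq_len(n)]) else
    data.frame(transcript_id = character(), gene_id = character(),
               chrom = character(), strand = character(),
               start = numeric(), end = numeric(), biotype = character(),
               stringsAsFactors = FALSE)
  annotation_set(exons)
}

#' Write an annotation set as GTF
#'
#' Emits one `exon` line per exon with `gene_id`, `transcript_id` and
#' `biotype` attributes, in deterministic (chrom, transcript start,
#' transcript id, exon start) order. `write_gtf` then `read_gtf` is the
#' identity on the annotation set.
#'
#' @param anno An `annotation_set`.
#' @param path Output path.
#' @export
write_gtf <- function(anno, path) {
  ex <- anno$exons
  tx <- anno$transcripts
  ord <- order(tx$chrom, tx$start, tx$transcript_id)
  tx_rank <- stats::setNames(seq_along(ord), tx$transcript_id[ord])
  ex <- ex[order(tx_rank[ex$transcript_id], ex$start), , drop = FALSE]
  lines <- sprintf(
    '%s\tlncord\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s"; biotype "%s";',
    ex$chrom, as.integer(ex$start) + 1L, as.integer(ex$end), ex$strand,
    ex$gene_id, ex$transcript_id, ex$biotype)
  writeLines(lines, path)
  invisible(path)
}

#' Construct an expression matrix with sample metadata
#'
#' @param values Numeric matrix, features x samples, non-negative TPM; must
#'   carry unique row and column names.
#' @param sample_meta data.frame with columns `sample_id`, `species`, `stage`
#'   covering every column of `values`.
#' @return An `expression_matrix` (list with `$values`, `$sample_meta`).
#' @export
expression_matrix <- function(values, sample_meta) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) && nrow(values) == 0L) rownames(values) <- character()
  if (is.null(colnames(values)) && ncol(values) == 0L) colnames(values) <- character()
  if (anyDuplicated(rownames(values))) {
    dup <- rownames(values)[duplicated(rownames(values))][1]
    stop("duplicate feature id: ", dup)
  }
  if (length(values) && any(values < 0))
    stop("expression values must be non-negative (TPM)")
  if (!all(c("sample_id", "species", "stage") %in% names(sample_meta)))
    stop("sample_meta needs columns sample_id, species, stage")
  missing <- setdiff(colnames(values), sample_meta$sample_id)
  if (length(missing))
    stop("sample(s) missing from metadata: ", paste(missing, collapse = ", "))
  extra <- setdiff(sample_meta$sample_id, colnames(values))
  if (length(extra)) {
    warning("metadata sample(s) absent from matrix ignored: ",
            paste(extra, collapse = ", "))
    sample_meta <- sample_meta[sample_meta$sample_id %in% colnames(values), , drop = FALSE]
  }
  sample_meta <- sample_meta[match(colnames(values), sample_meta$sample_id), , drop = FALSE]
  rownames(sample_meta) <- NULL
  structure(list(values = values, sample_meta = sample_meta),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("expression_matrix:", nrow(x$values), "features x", ncol(x$values),
      "samples\n")
  sp <- table(x$sample_meta$species)
  if (length(sp)) cat("  species:", paste(names(sp), sp, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Read an expression matrix and its sample metadata from TSV
#'
#' The matrix file has a header row of sample ids and feature ids in the
#' first column; the metadata file has columns `sample_id`, `species`,
#' `stage`.
#'
#' @param path Matrix TSV path.
#' @param meta_path Metadata TSV path.
#' @return An `expression_matrix`.
#' @export
read_expression <- function(path, meta_path) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  meta <- utils::read.delim(meta_path, stringsAsFactors = FALSE)
  if (ncol(tab) < 1L) stop("empty expression table: ", path)
  ids <- as.character(tab[[1]])
  if (anyDuplicated(ids)) stop("duplicate feature id: ", ids[duplicated(ids)][1])
  values <- as.matrix(tab[, -1, drop = FALSE])
  mode(values) <- "numeric"
  if (length(values) && any(is.na(values))) stop("non-numeric expression value in ", path)
  if (length(values) && any(values < 0)) stop("negative expression value in ", path)
  rownames(values) <- ids
  expression_matrix(values, meta)
}

#' Write an expression matrix (and optionally its metadata) to TSV
#' @param em An `expression_matrix`.
#' @param path Matrix TSV path.
#' @param meta_path Optional metadata TSV path.
#' @export
write_expression <- function(em, path, meta_path = NULL) {
  df <- data.frame(feature_id = rownames(em$values), em$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(meta_path))
    utils::write.table(em$sample_meta, meta_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(path)
}

# IRanges view of a 0-based half-open table (1-based closed shift)
.iranges_of <- function(start, end) IRanges::IRanges(start = start + 1L, end = end)

# overlap pairs between two 0-based tables restricted to equal chrom;
# returns data.frame(q, s) of row indices with >= 1 base overlap
.overlap_pairs <- function(q_chrom, q_start, q_end, s_chrom, s_start, s_end) {
  out <- list()
  for (ch in intersect(unique(q_chrom), unique(s_chrom))) {
    qi <- which(q_chrom == ch); si <- which(s_chrom == ch)
    hits <- IRanges::findOverlaps(.iranges_of(q_start[qi], q_end[qi]),
                                  .iranges_of(s_start[si], s_end[si]),
                                  minoverlap = 1L)
    if (length(hits))
      out[[ch]] <- data.frame(q = qi[S4Vectors::queryHits(hits)],
                              s = si[S4Vectors::subjectHits(hits)])
  }
  if (length(out)) do.call(rbind, out) else data.frame(q = integer(), s = integer())
}
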