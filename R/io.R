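## Readers and writers for the simple tabular dialects used at file
## boundaries.  On disk, placement coordinates are 0-based half-open
## (columns sample_id, read_id, contig_id, start, end); in memory they are
## IRanges/GRanges (1-based closed), converted only here.

#' Write placements and totals to TSV
#'
#' @param pset a \code{\link{PlacementSet}}.
#' @param placements_file,totals_file output paths.
#' @return invisibly, \code{NULL}.
#' @export
writePlacementsTSV <- function(pset, placements_file, totals_file) {
  gr <- placements(pset)
  df <- data.frame(
    sample_id = S4Vectors::mcols(gr)$sample_id,
    read_id = S4Vectors::mcols(gr)$read_id,
    contig_id = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr))
  write.table(df, placements_file, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(data.frame(sample_id = names(sampleTotals(pset)),
                         total_reads = unname(sampleTotals(pset))),
              totals_file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}

#' Read placements and totals from TSV
#'
#' @param placements_file TSV with sample_id, read_id, contig_id, start,
#'   end (0-based half-open).
#' @param totals_file TSV with sample_id, total_reads.
#' @return a \code{\link{PlacementSet}}.
#' @export
readPlacementsTSV <- function(placements_file, totals_file) {
  df <- read.delim(placements_file, stringsAsFactors = FALSE)
  tot <- read.delim(totals_file, stringsAsFactors = FALSE)
  gr <- GenomicRanges::GRanges(
    seqnames = df$contig_id,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    sample_id = df$sample_id,
    read_id = if ("read_id" %in% names(df)) df$read_id else
      sprintf("read%07d", seq_len(nrow(df))))
  PlacementSet(gr, setNames(tot$total_reads, tot$sample_id))
}

## reference-space width of a CIGAR string (M/D/N/=/X consume reference)
cigarRefWidth <- function(cigar) {
  vapply(cigar, function(cg) {
    ops <- gregexpr("[0-9]+[MIDNSHP=X]", cg)[[1]]
    if (ops[1] == -1) return(0L)
    toks <- regmatches(cg, gregexpr("[0-9]+[MIDNSHP=X]", cg))[[1]]
    lens <- as.integer(sub("[A-Z=]$", "", toks))
    op <- sub("^[0-9]+", "", toks)
    sum(lens[op %in% c("M", "D", "N", "=", "X")])
  }, integer(1), USE.NAMES = FALSE)
}

#' Read placements from plain-text SAM files
#'
#' Adapter for real read mappings: each SAM file contributes one sample;
#' mapped records (FLAG without 0x4, primary placements only, i.e. not
#' secondary 0x100 or supplementary 0x800) become placement intervals of
#' their reference-space CIGAR width.
#'
#' @param sam_files named character vector: sample_id -> SAM path.
#' @param totals named numeric vector of per-sample total reads; defaults
#'   to the number of records per file.
#' @return a \code{\link{PlacementSet}}.
#' @export
readPlacementsSAM <- function(sam_files, totals = NULL) {
  stopifnot(!is.null(names(sam_files)))
  rows <- list(); nrec <- numeric(length(sam_files))
  names(nrec) <- names(sam_files)
  for (s in names(sam_files)) {
    ln <- readLines(sam_files[[s]])
    ln <- ln[!startsWith(ln, "@")]
    nrec[s] <- length(ln)
    if (!length(ln)) next
    f <- strsplit(ln, "\t", fixed = TRUE)
    flag <- vapply(f, function(x) as.integer(x[2]), integer(1))
    keep <- bitwAnd(flag, 0x4) == 0 & bitwAnd(flag, 0x100) == 0 &
      bitwAnd(flag, 0x800) == 0
    f <- f[keep]
    if (!length(f)) next
    rows[[s]] <- data.frame(
      sample_id = s,
      read_id = vapply(f, `[`, "", 1),
      contig_id = vapply(f, `[`, "", 3),
      pos = vapply(f, function(x) as.integer(x[4]), integer(1)),
      w = cigarRefWidth(vapply(f, `[`, "", 6)),
      stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows)
  if (is.null(totals)) totals <- nrec
  gr <- if (is.null(df)) GenomicRanges::GRanges() else
    GenomicRanges::GRanges(
      seqnames = df$contig_id,
      ranges = IRanges::IRanges(start = df$pos, width = pmax(1L, df$w)),
      sample_id = df$sample_id, read_id = df$read_id)
  PlacementSet(gr, totals)
}

#' Read a 12/13-column tabular alignment file
#'
#' The standard 12-column tabular alignment dialect (query, subject,
#' percent identity, alignment length, mismatches, gap opens, qstart,
#' qend, sstart, send, evalue, bitscore), optionally with query length as
#' a 13th column; otherwise supply \code{query_lengths}.
#'
#' @param file path to the tabular file (no header).
#' @param query_lengths named vector of query lengths (used when no 13th
#'   column is present).
#' @return data.frame in the shape \code{\link{screenProphageHits}} expects.
#' @export
readAlignmentTable <- function(file, query_lengths = NULL) {
  df <- read.delim(file, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 12) stop("expected at least 12 tab-separated columns")
  out <- data.frame(query_id = df[[1]], subject_id = df[[2]],
                    pct_identity = df[[3]], aln_len = df[[4]],
                    bitscore = df[[12]], evalue = df[[11]],
                    stringsAsFactors = FALSE)
  out$query_len <- if (ncol(df) >= 13) df[[13]] else {
    if (is.null(query_lengths))
      stop("supply query_lengths or a 13-column file")
    as.integer(query_lengths[out$query_id])
  }
  out
}

#' Read a host taxonomy TSV
#'
#' @param file TSV with columns host_id and taxonomy (semicolon-separated
#'   lineage) or one column per rank after host_id.
#' @return named character vector host_id -> lineage.
#' @export
readTaxonomyTSV <- function(file) {
  df <- read.delim(file, stringsAsFactors = FALSE)
  if ("taxonomy" %in% names(df))
    return(setNames(df$taxonomy, df$host_id))
  setNames(apply(df[, -1, drop = FALSE], 1, paste, collapse = ";"),
           df[[1]])
}
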