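## Breadth-gated RPKM abundance: a contig is considered present in a sample
## only when reads cover at least 75% of its length; abundance is
## mapped reads x 10^9 / (total reads x contig length).

#' Breadth of coverage of a contig in one sample
#'
#' Fraction of the contig covered by at least one read: the length of the
#' union of placement intervals divided by the contig length.  Unknown
#' contig/sample combinations have breadth 0.
#'
#' @param pset a \code{\link{PlacementSet}}.
#' @param contig_id,sample_id identifiers.
#' @param contig_len contig length in bp.
#' @return breadth in [0, 1].
#' @export
computeBreadth <- function(pset, contig_id, sample_id, contig_len) {
  stopifnot(contig_len > 0)
  gr <- placements(pset)
  sel <- as.character(GenomicRanges::seqnames(gr)) == contig_id &
    S4Vectors::mcols(gr)$sample_id == sample_id
  if (!any(sel)) return(0)
  covered <- sum(IRanges::width(IRanges::reduce(IRanges::ranges(gr[sel]))))
  min(1, covered / contig_len)
}

#' RPKM of a contig
#'
#' \code{mapped_reads * 1e9 / (total_reads * contig_len)}.
#'
#' @param mapped_reads reads mapped to the contig in the sample.
#' @param total_reads total reads in the sample (> 0).
#' @param contig_len contig length in bp (> 0).
#' @return non-negative RPKM value.
#' @export
computeRPKM <- function(mapped_reads, total_reads, contig_len) {
  if (any(total_reads <= 0)) stop("total_reads must be positive")
  if (any(contig_len <= 0)) stop("contig_len must be positive")
  mapped_reads * 1e9 / (total_reads * contig_len)
}

#' Build a breadth-gated vOTU abundance table
#'
#' Abundance of a vOTU in a sample is the RPKM of its representative (seed)
#' contig; a vOTU is present only when the seed's breadth of coverage is at
#' least \code{breadth_min} (inclusive), and its RPKM is set to 0 where
#' absent.
#'
#' @param votus clustering result from \code{\link{clusterVOTUs}} (or any
#'   data.frame with seed_id/member_id columns).
#' @param pset a \code{\link{PlacementSet}}; its totals define the sample
#'   set and RPKM denominators.
#' @param contig_lengths named vector of contig lengths (must cover seeds).
#' @param breadth_min presence threshold (default 0.75).
#' @return a \code{\link{VOTUTable}} (rows = vOTUs, columns = samples).
#' @export
buildVOTUTable <- function(votus, pset, contig_lengths, breadth_min = 0.75) {
  memb <- if (is.data.frame(votus)) votus else votus$votus
  seeds <- unique(memb$seed_id)
  if (!all(seeds %in% names(contig_lengths)))
    stop("every vOTU seed needs an entry in contig_lengths")
  samples <- names(sampleTotals(pset))
  gr <- placements(pset)
  key <- paste(as.character(GenomicRanges::seqnames(gr)),
               S4Vectors::mcols(gr)$sample_id, sep = "\r")
  counts <- table(key)
  rpkm <- pres <- matrix(0, length(seeds), length(samples),
                         dimnames = list(seeds, samples))
  for (sd in seeds) for (sm in samples) {
    n <- counts[paste(sd, sm, sep = "\r")]
    n <- if (is.na(n)) 0L else as.integer(n)
    br <- computeBreadth(pset, sd, sm, contig_lengths[[sd]])
    present <- br >= breadth_min
    pres[sd, sm] <- present
    rpkm[sd, sm] <- if (present)
      computeRPKM(n, sampleTotals(pset)[[sm]], contig_lengths[[sd]]) else 0
  }
  n_members <- table(memb$seed_id)[seeds]
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(rpkm = rpkm, presence = pres > 0),
    rowData = S4Vectors::DataFrame(
      seed_length = as.integer(contig_lengths[seeds]),
      n_members = as.integer(n_members)),
    colData = S4Vectors::DataFrame(
      total_reads = sampleTotals(pset)[samples], row.names = samples))
  new("VOTUTable", se)
}

#' Per-sample richness, total abundance and Shannon diversity
#'
#' Richness counts present vOTUs; total abundance sums RPKM; Shannon
#' diversity (natural log) is computed on the relative RPKM of present
#' vOTUs and reported as \code{NA} for all-absent samples.
#'
#' @param table a \code{\link{VOTUTable}}.
#' @return data.frame with sample_id, richness, total_abundance, shannon.
#' @export
summarizeSamples <- function(table) {
  r <- rpkmMatrix(table); p <- presenceMatrix(table)
  data.frame(
    sample_id = colnames(r),
    richness = colSums(p),
    total_abundance = colSums(r),
    shannon = apply(r, 2, function(col)
      if (all(col == 0)) NA_real_ else shannonDiversity(col)),
    row.names = NULL)
}
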