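## Marker-gene guild profiling: length filters for DsrA/DsrD/McrA, contig
## RPKM abundance matrices, diversity, paired tests and rank-abundance.

#' Filter marker-gene hits by protein length and dsrA direction
#'
#' Retains hits whose protein length meets the per-marker minimum
#' (inclusive); dsrA hits are additionally restricted to the reductive
#' type.  Hits of markers without a configured threshold are retained with
#' a warning.
#'
#' @param hits data.frame with columns gene_id, contig_id, marker,
#'   protein_len, taxon, direction.
#' @param min_len named vector of minimum lengths in amino acids
#'   (default c(dsrA = 302, dsrD = 57, mcrA = 150)).
#' @return filtered data.frame.
#' @export
filterMarkerHits <- function(hits, min_len = c(dsrA = 302, dsrD = 57,
                                               mcrA = 150)) {
  stopifnot(all(c("marker", "protein_len") %in% names(hits)))
  unknown <- setdiff(unique(hits$marker), names(min_len))
  if (length(unknown))
    warning("no length threshold for marker(s): ",
            paste(unknown, collapse = ", "), "; retained unfiltered")
  thr <- min_len[hits$marker]
  keep <- is.na(thr) | hits$protein_len >= thr
  if ("direction" %in% names(hits))
    keep <- keep & (hits$marker != "dsrA" | hits$direction == "reductive")
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-sample RPKM matrix of marker-gene-containing contigs
#'
#' One column per marker-containing contig; cell values are the contig's
#' RPKM in each sample (same formula as for vOTUs).  No breadth gating is
#' applied to marker contigs.
#'
#' @param hits (filtered) marker hit data.frame.
#' @param pset a \code{\link{PlacementSet}}.
#' @param contig_lengths named vector of contig lengths.
#' @return list with \code{rpkm} (samples x contigs matrix),
#'   \code{marker} and \code{taxon} (named by contig).
#' @export
buildMarkerMatrix <- function(hits, pset, contig_lengths) {
  contigs <- unique(hits$contig_id)
  if (!all(contigs %in% names(contig_lengths)))
    stop("missing contig lengths for some marker hits")
  samples <- names(sampleTotals(pset))
  gr <- placements(pset)
  key <- paste(as.character(GenomicRanges::seqnames(gr)),
               S4Vectors::mcols(gr)$sample_id, sep = "\r")
  counts <- table(key)
  m <- matrix(0, length(samples), length(contigs),
              dimnames = list(samples, contigs))
  for (cg in contigs) for (sm in samples) {
    n <- counts[paste(cg, sm, sep = "\r")]
    n <- if (is.na(n)) 0L else as.integer(n)
    m[sm, cg] <- computeRPKM(n, sampleTotals(pset)[[sm]], contig_lengths[[cg]])
  }
  list(rpkm = m,
       marker = setNames(hits$marker[match(contigs, hits$contig_id)], contigs),
       taxon = setNames(hits$taxon[match(contigs, hits$contig_id)], contigs))
}

#' Shannon diversity (natural log)
#'
#' \code{H = -sum(p_i * ln p_i)} over the positive entries of the vector
#' normalized to proportions.
#'
#' @param x non-negative abundance vector with at least one positive entry.
#' @return Shannon H in nats.
#' @export
shannonDiversity <- function(x) {
  if (any(x < 0)) stop("abundances must be non-negative")
  x <- x[x > 0]
  if (!length(x)) stop("all-zero vector: Shannon diversity undefined")
  p <- x / sum(x)
  -sum(p * log(p))
}

#' Paired t test on positionally paired vectors
#'
#' Two-sided paired t test (wraps \code{\link[stats]{t.test}}); errors on
#' degenerate all-identical pairs.
#'
#' @param x,y numeric vectors of equal length >= 2, paired by position.
#' @return list with \code{t}, \code{df}, \code{p}.
#' @export
pairedTTest <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 2) stop("need at least two pairs")
  if (isTRUE(all.equal(var(x - y), 0)) || all(x == y))
    stop("zero-variance differences: paired t test undefined")
  tt <- t.test(x, y, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = unname(tt$p.value))
}

#' Per-group rank-abundance curves
#'
#' For each group, features are ranked by their mean abundance (descending,
#' ties broken lexicographically by feature name).
#'
#' @param matrix samples x features abundance matrix.
#' @param group_map named vector or factor mapping sample -> group.
#' @return data.frame with group, rank, feature, mean_abundance.
#' @export
rankAbundance <- function(matrix, group_map) {
  g <- group_map[rownames(matrix)]
  if (any(is.na(g))) stop("group_map must cover every sample")
  out <- lapply(unique(as.character(g)), function(grp) {
    mu <- colMeans(matrix[as.character(g) == grp, , drop = FALSE])
    ord <- order(-mu, names(mu))
    data.frame(group = grp, rank = seq_along(ord), feature = names(mu)[ord],
               mean_abundance = unname(mu[ord]), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
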