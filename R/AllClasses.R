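#' Read placements on contigs across samples
#'
#' A \code{PlacementSet} stores simulated or parsed read placements as a
#' \link[GenomicRanges]{GRanges} (seqnames = contig ids, 0-based half-open
#' intervals stored as 1-based closed \code{IRanges}, with a \code{sample_id}
#' and \code{read_id} metadata column) together with the per-sample total
#' read counts used as RPKM denominators.
#'
#' @slot placements a \code{GRanges} of read intervals.
#' @slot totals named numeric vector, total (QC'd) reads per sample.
#'
#' @export
setClass("PlacementSet",
  representation(placements = "GRanges", totals = "numeric"))

setValidity("PlacementSet", function(object) {
  gr <- object@placements
  msg <- character()
  if (length(gr) && !"sample_id" %in% colnames(S4Vectors::mcols(gr)))
    msg <- c(msg, "placements must carry a 'sample_id' metadata column")
  if (is.null(names(object@totals)) && length(object@totals))
    msg <- c(msg, "totals must be a named vector")
  if (length(gr)) {
    samp <- unique(as.character(S4Vectors::mcols(gr)$sample_id))
    if (!all(samp %in% names(object@totals)))
      msg <- c(msg, "every sample with placements needs an entry in totals")
    counts <- table(S4Vectors::mcols(gr)$sample_id)
    tot <- object@totals[names(counts)]
    if (any(tot < as.numeric(counts)))
      msg <- c(msg, "totals must be >= mapped read counts per sample")
  }
  if (any(object@totals <= 0)) msg <- c(msg, "totals must be positive")
  if (length(msg)) msg else TRUE
})

#' Construct a PlacementSet
#'
#' @param placements \code{GRanges} with \code{sample_id} metadata column.
#' @param totals named numeric vector of per-sample total read counts.
#' @return a \code{PlacementSet}.
#' @export
PlacementSet <- function(placements = GenomicRanges::GRanges(), totals = numeric()) {
  new("PlacementSet", placements = placements, totals = totals)
}

#' @describeIn PlacementSet the placement \code{GRanges}.
#' @param x a \code{PlacementSet}.
#' @export
placements <- function(x) x@placements

#' @describeIn PlacementSet per-sample total read counts.
#' @export
sampleTotals <- function(x) x@totals

setMethod("show", "PlacementSet", function(object) {
  cat("PlacementSet with", length(object@placements), "placements across",
      length(object@totals), "samples\n")
  if (length(object@totals))
    cat("  samples:", paste(head(names(object@totals), 6), collapse = ", "),
        if (length(object@totals) > 6) "..." else "", "\n")
})

#' Viral population (vOTU) abundance table
#'
#' Extends \link[SummarizedExperiment]{SummarizedExperiment}: rows are vOTUs
#' (named by their representative/seed contig), columns are samples.  Two
#' assays: \code{rpkm} (breadth-gated RPKM of the representative contig) and
#' \code{presence} (logical; breadth of coverage >= the presence threshold).
#' Row metadata records seed length and member count.
#'
#' @export
setClass("VOTUTable", contains = "SummarizedExperiment")

setValidity("VOTUTable", function(object) {
  msg <- character()
  an <- SummarizedExperiment::assayNames(object)
  if (!all(c("rpkm", "presence") %in% an))
    msg <- c(msg, "assays 'rpkm' and 'presence' are required")
  else {
    r <- SummarizedExperiment::assay(object, "rpkm")
    p <- SummarizedExperiment::assay(object, "presence")
    if (any(r < 0)) msg <- c(msg, "rpkm must be non-negative")
    if (any(r[!p] != 0)) msg <- c(msg, "rpkm must be 0 where presence is FALSE")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn VOTUTable the RPKM matrix (vOTUs x samples).
#' @param x a \code{VOTUTable}.
#' @export
rpkmMatrix <- function(x) SummarizedExperiment::assay(x, "rpkm")

#' @describeIn VOTUTable the logical presence matrix (vOTUs x samples).
#' @export
presenceMatrix <- function(x) SummarizedExperiment::assay(x, "presence")

#' Markov model of a host genome for likelihood-based host prediction
#'
#' Transition log-probabilities over all nucleotide contexts of the given
#' order, estimated from a host genome with one pseudo-count per cell, used
#' to score viral contigs by mean log-likelihood per base.
#'
#' @slot host_id host genome identifier.
#' @slot order context length (bases conditioned on).
#' @slot log_word_prob numeric vector of length \code{4^(order+1)}:
#'   log P(next base | context), indexed by (order+1)-mer.
#' @slot trained_bp bases the model was trained on.
#' @slot taxonomy semicolon-separated lineage (may be \code{NA}).
#'
#' @export
setClass("MarkovHostModel",
  representation(host_id = "character", order = "integer",
                 log_word_prob = "numeric", trained_bp = "integer",
                 taxonomy = "character"))

setValidity("MarkovHostModel", function(object) {
  k <- object@order + 1L
  if (length(object@log_word_prob) != 4^k)
    return(sprintf("log_word_prob must have length 4^%d", k))
  p <- exp(object@log_word_prob)
  sums <- rowSums(matrix(p, ncol = 4L, byrow = TRUE))
  if (any(abs(sums - 1) > 1e-8))
    return("conditional probabilities must sum to 1 per context")
  TRUE
})

setMethod("show", "MarkovHostModel", function(object) {
  cat("MarkovHostModel for", object@host_id, "- order", object@order,
      "- trained on", object@trained_bp, "bp\n")
})

#' Hierarchical clustering with bootstrap branch support
#'
#' @slot hclust the \code{\link[stats]{hclust}} tree over columns.
#' @slot support per-internal-branch bootstrap proportion in [0, 1], named by
#'   merge step.
#' @slot n_boot number of bootstrap resamples.
#' @slot support_min threshold used to flag well-supported branches.
#'
#' @export
setClass("DendrogramWithSupport",
  representation(hclust = "ANY", support = "numeric", n_boot = "integer",
                 support_min = "numeric"))

setMethod("show", "DendrogramWithSupport", function(object) {
  cat("DendrogramWithSupport over", length(object@hclust$labels),
      "leaves;", object@n_boot, "bootstrap resamples\n")
  cat("  branches with support >=", object@support_min, ":",
      sum(object@support >= object@support_min), "/", length(object@support), "\n")
})

#' @describeIn DendrogramWithSupport bootstrap support per internal branch.
#' @param x a \code{DendrogramWithSupport}.
#' @export
branchSupport <- function(x) x@support
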