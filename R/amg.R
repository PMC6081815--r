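## Screen for putative virally encoded (auxiliary) metabolic genes.

#' Default allow-list for host-metabolism-only gene products
#'
#' A small, user-overridable vocabulary of products that act only in host
#' cell metabolism (not in the viral replication cycle), e.g. sulfur and
#' carbon cycling genes commonly reported as auxiliary metabolic genes.
#'
#' @return character vector of product labels.
#' @export
defaultAMGAllowList <- function() {
  c("cysH", "dsrC", "psbA", "psbD", "nifU", "speD", "folE", "queE",
    "ahbD", "cobS", "mazG", "pstS")
}

#' Screen gene annotations for candidate auxiliary metabolic genes
#'
#' Applies four criteria: (i) the gene is in the middle of its contig (not
#' among the first or last two genes); (ii) the contig is clearly viral
#' (carries at least one hallmark phage gene, e.g. tail or capsid protein);
#' (iii) the product occurs on at least \code{min_contigs} distinct viral
#' contigs; (iv) the product can only act in host cell metabolism, decided
#' by membership in \code{allow_list}.
#'
#' @param annotations data.frame with columns contig_id, gene_id,
#'   gene_index (0-based along the contig), n_genes_on_contig, product,
#'   category (one of \code{"viral_hallmark"}, \code{"metabolic"},
#'   \code{"other"}).
#' @param min_contigs criterion (iii) threshold (default 3).
#' @param allow_list criterion (iv) vocabulary (default
#'   \code{\link{defaultAMGAllowList}}).
#' @return data.frame of passing gene records with an \code{n_contigs}
#'   column; zero rows when nothing passes.
#' @export
screenMetabolicGenes <- function(annotations, min_contigs = 3L,
                                 allow_list = defaultAMGAllowList()) {
  req <- c("contig_id", "gene_index", "n_genes_on_contig", "product", "category")
  stopifnot(all(req %in% names(annotations)))
  ngc <- tapply(annotations$n_genes_on_contig, annotations$contig_id,
                function(x) length(unique(x)))
  if (any(ngc != 1))
    stop("inconsistent n_genes_on_contig within a contig")
  bad <- annotations$gene_index < 0 |
    annotations$gene_index >= annotations$n_genes_on_contig
  if (any(bad)) stop("gene_index out of range for its contig")

  hallmark_contigs <- unique(
    annotations$contig_id[annotations$category == "viral_hallmark"])
  cand <- annotations[annotations$category == "metabolic", , drop = FALSE]
  ## (i) interior position: exclude first two and last two genes
  cand <- cand[cand$gene_index >= 2 &
                 cand$gene_index <= cand$n_genes_on_contig - 3, , drop = FALSE]
  ## (ii) hallmark-bearing contig
  cand <- cand[cand$contig_id %in% hallmark_contigs, , drop = FALSE]
  ## (iv) host-metabolism-only product
  cand <- cand[cand$product %in% allow_list, , drop = FALSE]
  ## (iii) product present on >= min_contigs distinct viral contigs
  per_prod <- tapply(annotations$contig_id, annotations$product,
                     function(x) length(unique(x)))
  cand$n_contigs <- as.integer(per_prod[cand$product])
  cand <- cand[cand$n_contigs >= min_contigs, , drop = FALSE]
  rownames(cand) <- NULL
  cand
}
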