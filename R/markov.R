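## WIsH-style host prediction: per-host Markov models score viral contigs
## by mean log-likelihood per base; a Gaussian null over each virus's
## scores across candidate hosts yields a p-value, and the lowest common
## ancestor of the best five hosts' lineages is reported as the host.

#' Train a Markov model of a host genome
#'
#' Transition probabilities over all contexts of the given order are
#' estimated from observed (order+1)-mer counts with one pseudo-count per
#' cell, so unseen contexts fall back to a uniform distribution and no
#' valid input scores to -Inf.
#'
#' @param host host record (1-sequence \code{DNAStringSet}) or character.
#' @param order context length (default 8, the conventional choice for
#'   k-mer-likelihood host prediction).
#' @param taxonomy optional semicolon-separated lineage.
#' @return a \code{\link{MarkovHostModel}}.
#' @export
trainMarkovModel <- function(host, order = 8L, taxonomy = NA_character_) {
  host_id <- if (is(host, "DNAStringSet")) names(host)[1] else "host"
  if (is(host, "DNAStringSet") &&
      !is.null(S4Vectors::mcols(host)$taxonomy) && is.na(taxonomy))
    taxonomy <- S4Vectors::mcols(host)$taxonomy[1]
  s <- asSequenceChar(host)
  if (!nchar(s)) stop("empty sequence")
  counts <- Biostrings::oligonucleotideFrequency(Biostrings::DNAString(s),
                                                 width = order + 1L)
  m <- matrix(counts + 1, ncol = 4L, byrow = TRUE)   # rows = contexts
  p <- m / rowSums(m)
  new("MarkovHostModel", host_id = host_id, order = as.integer(order),
      log_word_prob = as.numeric(t(log(p))), trained_bp = nchar(s),
      taxonomy = as.character(taxonomy))
}

#' Score a viral contig under a host model
#'
#' Mean log-likelihood per base over the circularized contig (the first
#' \code{order} bases are appended to the end, so every base is scored in
#' context); phage genomes are commonly circular and this makes the score
#' exactly invariant to rotation and to self-concatenation.
#'
#' @param virus sequence (character or Biostrings).
#' @param model a \code{\link{MarkovHostModel}}.
#' @return mean log-likelihood per base.
#' @export
scoreMarkov <- function(virus, model) {
  s <- asSequenceChar(virus)
  ord <- model@order
  if (nchar(s) <= ord) stop("virus shorter than model order")
  circ <- paste0(s, substr(s, 1L, ord))
  counts <- Biostrings::oligonucleotideFrequency(Biostrings::DNAString(circ),
                                                 width = ord + 1L)
  sum(counts * model@log_word_prob) / sum(counts)
}

#' Score viruses against host models and link by Gaussian-null p-value
#'
#' For each virus the scores across all candidate models form the null; a
#' Gaussian is fit to them and the upper-tail probability of the best score
#' is the p-value.  When \code{p < p_max} (strict), a link is emitted whose
#' host taxonomy is the lowest common ancestor of the \code{n_best}
#' highest-scoring hosts' lineages.
#'
#' @param viruses \code{DNAStringSet}.
#' @param models list of \code{\link{MarkovHostModel}} (>= 3; with fewer
#'   candidates the Gaussian null is unstable and the d2* method should be
#'   used instead).
#' @param p_max strict p-value threshold (default 0.001).
#' @param n_best number of top hosts aggregated by LCA (default 5; all
#'   models when fewer are available).
#' @return data.frame with one row per virus: virus_id, host_id (best hit),
#'   method ("markov"), score (the p-value), loglik (best mean
#'   log-likelihood/bp), passed, lca_taxonomy.
#' @export
scoreAndLinkMarkov <- function(viruses, models, p_max = 0.001, n_best = 5L) {
  if (length(models) < 3)
    stop("need at least 3 host models for the Gaussian null; ",
         "use the d2* method for smaller candidate sets")
  host_ids <- vapply(models, function(m) m@host_id, character(1))
  rows <- lapply(seq_along(viruses), function(i) {
    sc <- vapply(models, function(m)
      scoreMarkov(as.character(viruses[[i]]), m), numeric(1))
    best <- which.max(sc)
    p <- pnorm(sc[best], mean = mean(sc), sd = sd(sc), lower.tail = FALSE)
    top <- order(sc, decreasing = TRUE)[seq_len(min(n_best, length(sc)))]
    lca <- lcaLineage(vapply(models[top], function(m) m@taxonomy, character(1)))
    data.frame(virus_id = names(viruses)[i], host_id = host_ids[best],
               method = "markov", score = p, loglik = sc[best],
               passed = p < p_max, lca_taxonomy = lca,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Lowest common ancestor of semicolon-separated lineages
#'
#' Ranks are compared coarse-to-fine; the LCA is the shared prefix.
#' Truncated lineages act as wildcards below their truncation point, i.e.
#' they constrain only the ranks they state.
#'
#' @param lineages character vector of semicolon-separated lineages
#'   (\code{NA} entries are ignored).
#' @return the LCA lineage string, or \code{"unclassified"} when no rank is
#'   shared.
#' @export
lcaLineage <- function(lineages) {
  lineages <- lineages[!is.na(lineages)]
  if (!length(lineages)) return("unclassified")
  parts <- strsplit(lineages, ";", fixed = TRUE)
  depth <- max(lengths(parts))
  out <- character(0)
  for (r in seq_len(depth)) {
    vals <- unique(unlist(lapply(parts, function(p)
      if (length(p) >= r) p[r] else NULL)))
    if (length(vals) == 1L) out <- c(out, vals) else break
  }
  if (!length(out)) "unclassified" else paste(out, collapse = ";")
}
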