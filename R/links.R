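## Integrate the four evidence lines into one virus-host table and score
## recovery against recorded ground truth.

#' Integrate virus-host links across prediction methods
#'
#' Union semantics: any pair passing at least one method appears, with
#' per-method pass flags, per-method scores and a method count.
#'
#' @param all_links data.frame (or list of data.frames) of links with
#'   virus_id, host_id, method, score, passed columns (e.g. rbound outputs
#'   of \code{\link{screenProphageHits}}, \code{\link{matchSpacers}},
#'   \code{\link{linkByD2Star}}, \code{\link{scoreAndLinkMarkov}}).
#' @return data.frame: virus_id, host_id, blast, crispr, d2star, markov
#'   (logicals), score_<method> columns, n_methods, lca_taxonomy (from the
#'   markov method when available).
#' @export
integrateLinks <- function(all_links) {
  if (is.list(all_links) && !is.data.frame(all_links)) {
    keep <- c("virus_id", "host_id", "method", "score", "passed",
              "lca_taxonomy")
    all_links <- do.call(rbind, lapply(all_links, function(d) {
      if (!"lca_taxonomy" %in% names(d)) d$lca_taxonomy <- NA_character_
      d[, keep]
    }))
  }
  methods <- c("blast", "crispr", "d2star", "markov")
  pass <- all_links[all_links$passed, , drop = FALSE]
  if (!nrow(pass)) {
    out <- data.frame(virus_id = character(), host_id = character())
    for (m in methods) { out[[m]] <- logical(); out[[paste0("score_", m)]] <- numeric() }
    out$n_methods <- integer(); out$lca_taxonomy <- character()
    return(out)
  }
  key <- unique(pass[, c("virus_id", "host_id")])
  rownames(key) <- NULL
  for (m in methods) {
    sub <- all_links[all_links$method == m, , drop = FALSE]
    idx <- match(paste(key$virus_id, key$host_id),
                 paste(sub$virus_id, sub$host_id))
    key[[m]] <- !is.na(idx) & sub$passed[idx]
    key[[m]][is.na(key[[m]])] <- FALSE
    key[[paste0("score_", m)]] <- sub$score[idx]
  }
  key$n_methods <- rowSums(as.matrix(key[, methods]))
  if ("lca_taxonomy" %in% names(all_links)) {
    mk <- all_links[all_links$method == "markov", , drop = FALSE]
    key$lca_taxonomy <- mk$lca_taxonomy[
      match(paste(key$virus_id, key$host_id),
            paste(mk$virus_id, mk$host_id))]
  }
  key[order(key$virus_id, key$host_id), , drop = FALSE]
}

#' Precision and recall of linkage methods against ground truth
#'
#' For prophages the truth is the set of implanted (virus, host) pairs.
#' CRISPR evidence is scored at the family level (a spacer legitimately
#' matches every population member carrying it, not just the sampled
#' source contig): predicted and truth pairs are collapsed to
#' (viral family, host).  For the composition-based methods (d2*, Markov)
#' the truth is the compositional source host of each viral contig.
#'
#' @param links integrated link table from \code{\link{integrateLinks}}.
#' @param truth the \code{truth} element of \code{\link{makeCommunity}}.
#' @return data.frame with method, tp, fp, fn, precision, recall.
#' @export
linkRecovery <- function(links, truth) {
  pairKey <- function(v, h) paste(v, h, sep = "\r")
  fam <- truth$votu_membership
  vh <- truth$virus_host[!is.na(truth$virus_host)]
  truth_sets <- list(
    blast = with(truth$prophage_links, pairKey(virus_id, host_id)),
    crispr = with(unique(truth$crispr_links[, c("virus_id", "host_id")]),
                  unique(pairKey(fam[virus_id], host_id))),
    d2star = pairKey(names(vh), vh),
    markov = pairKey(names(vh), vh))
  rows <- lapply(names(truth_sets), function(m) {
    pv <- links$virus_id[links[[m]]]
    if (m == "crispr") pv <- fam[pv]
    pred <- unique(pairKey(pv, links$host_id[links[[m]]]))
    ts <- unique(truth_sets[[m]])
    tp <- sum(pred %in% ts); fp <- length(pred) - tp
    fn <- sum(!ts %in% pred)
    data.frame(method = m, tp = tp, fp = fp, fn = fn,
               precision = if (length(pred)) tp / length(pred) else NA_real_,
               recall = if (length(ts)) tp / length(ts) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
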