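## Prophage evidence: screen tabular alignment hits of viral contigs
## against host genomes.  The alignment search itself is delegated to an
## external aligner for real data; an exact-substring scanner is provided
## for closed-loop synthetic tests.

#' Screen alignment hits for prophage-based virus-host links
#'
#' A hit becomes a link iff query coverage (aln_len / query_len) >=
#' \code{min_qcov}, percent identity >= \code{min_id}, bit score >=
#' \code{min_bits} and e-value <= \code{max_e}; all comparisons inclusive.
#'
#' @param hits data.frame with columns query_id, subject_id, pct_identity,
#'   aln_len, bitscore, evalue, query_len.
#' @param min_qcov minimum fraction of the viral contig aligned (0.75).
#' @param min_id minimum percent identity (70).
#' @param min_bits minimum bit score (50).
#' @param max_e maximum e-value (0.001).
#' @return data.frame of host links: virus_id, host_id, method ("blast"),
#'   score (qcov * identity/100 composite), passed (all TRUE).
#' @export
screenProphageHits <- function(hits, min_qcov = 0.75, min_id = 70,
                               min_bits = 50, max_e = 0.001) {
  req <- c("query_id", "subject_id", "pct_identity", "aln_len", "bitscore",
           "evalue", "query_len")
  stopifnot(all(req %in% names(hits)))
  if (any(is.na(hits$query_len)) || any(hits$query_len <= 0))
    stop("query_len must be known and positive for every hit")
  qcov <- hits$aln_len / hits$query_len
  keep <- qcov >= min_qcov & hits$pct_identity >= min_id &
    hits$bitscore >= min_bits & hits$evalue <= max_e
  out <- data.frame(virus_id = hits$query_id[keep],
                    host_id = hits$subject_id[keep],
                    method = rep("blast", sum(keep)),
                    score = qcov[keep] * hits$pct_identity[keep] / 100,
                    passed = rep(TRUE, sum(keep)),
                    stringsAsFactors = FALSE)
  unique(out)
}

#' Exact-substring prophage scanner
#'
#' Finds viral contigs occurring verbatim (either strand) inside host
#' genomes and reports them as full-coverage, 100\%-identity alignment hits
#' in the same tabular shape \code{\link{screenProphageHits}} consumes.
#' Useful for closed-loop tests on implanted prophages; real data should
#' come from an external aligner's tabular output.
#'
#' @param viruses,hosts \code{DNAStringSet}s.
#' @return data.frame of alignment hits.
#' @export
scanProphagesExact <- function(viruses, hosts) {
  rows <- list()
  for (i in seq_along(viruses)) {
    pat <- viruses[[i]]
    for (strand_pat in list(pat, Biostrings::reverseComplement(pat))) {
      n <- Biostrings::vcountPattern(strand_pat, hosts)
      for (j in which(n > 0)) {
        rows[[length(rows) + 1L]] <- data.frame(
          query_id = names(viruses)[i], subject_id = names(hosts)[j],
          pct_identity = 100, aln_len = length(pat),
          bitscore = 2 * length(pat), evalue = 0,
          query_len = length(pat), stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows)) unique(do.call(rbind, rows)) else
    data.frame(query_id = character(), subject_id = character(),
               pct_identity = numeric(), aln_len = integer(),
               bitscore = numeric(), evalue = numeric(),
               query_len = integer())
}
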