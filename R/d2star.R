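## d2*: alignment-free dissimilarity between two sequences from k-mer
## counts centered by their expectation under a background Markov model
## fit to each sequence (strand-summed).

## strand-summed oligonucleotide counts of all words of width w
strandCounts <- function(x, w) {
  d <- Biostrings::DNAString(x)
  Biostrings::oligonucleotideFrequency(d, width = w) +
    Biostrings::oligonucleotideFrequency(Biostrings::reverseComplement(d),
                                         width = w)
}

## per-word background probabilities p_w for all 4^k words under a Markov
## model of order m fit to the sequence's strand-summed counts
markovWordProbs <- function(x, k, m) {
  words <- names(Biostrings::oligonucleotideFrequency(Biostrings::DNAString("A"),
                                                      width = k)) # canonical order
  if (m == 0L) {
    c1 <- strandCounts(x, 1L)
    p1 <- c1 / sum(c1)
    lp <- log(p1)
    logp <- vapply(words, function(w)
      sum(lp[strsplit(w, "")[[1]]]), numeric(1))
    return(exp(logp))
  }
  cm <- strandCounts(x, m)
  cm1 <- strandCounts(x, m + 1L)
  pm <- cm / sum(cm)
  ctx_of <- substr(names(cm1), 1L, m)
  denom <- tapply(cm1, ctx_of, sum)[ctx_of]
  trans <- ifelse(denom > 0, cm1 / denom, 0)
  names(trans) <- names(cm1)
  p <- pm[substr(words, 1L, m)]
  for (i in seq_len(k - m)) {
    p <- p * trans[substr(words, i, i + m)]
  }
  p[is.na(p)] <- 0
  names(p) <- words
  p
}

#' d2* dissimilarity between two sequences
#'
#' Strand-summed k-mer counts are centered by their expected counts under a
#' background Markov model of order \code{background_order} fit to each
#' sequence, then compared by the normalized d2* statistic, which maps to a
#' dissimilarity in [0, 1] (0 for identical sequences).  Words whose
#' background probability is zero in either sequence contribute nothing.
#'
#' @param a,b sequences (character, \code{DNAString} or 1-sequence
#'   \code{DNAStringSet}).
#' @param k word size (default 6).
#' @param background_order Markov order of the background model (default 2).
#' @return d2* dissimilarity in [0, 1].
#' @export
computeD2Star <- function(a, b, k = 6L, background_order = 2L) {
  sa <- asSequenceChar(a); sb <- asSequenceChar(b)
  if (nchar(sa) < k || nchar(sb) < k) stop("sequences shorter than k")
  if (min(nchar(sa), nchar(sb)) < 10 * 4^background_order)
    warning("sequence shorter than recommended for the background order")
  d2StarFromStats(d2Stats(sa, k, background_order),
                  d2Stats(sb, k, background_order))
}

## precomputed per-sequence quantities for d2*
d2Stats <- function(x, k, m) {
  X <- strandCounts(x, k)
  p <- markovWordProbs(x, k, m)
  list(counts = X, p = p, n = sum(X))
}

d2StarFromStats <- function(A, B) {
  Xt <- A$counts - A$n * A$p
  Yt <- B$counts - B$n * B$p
  ok <- A$p > 0 & B$p > 0
  num <- sum(Xt[ok] * Yt[ok] / sqrt(A$n * A$p[ok] * B$n * B$p[ok]))
  dx <- sqrt(sum(Xt[ok]^2 / (A$n * A$p[ok])))
  dy <- sqrt(sum(Yt[ok]^2 / (B$n * B$p[ok])))
  if (dx == 0 || dy == 0) return(0)
  0.5 * (1 - num / (dx * dy))
}

#' Link viruses to hosts by d2* dissimilarity
#'
#' Every virus-host pair is scored; a pair is a link iff
#' \code{d2* <= threshold} (inclusive).
#'
#' @param viruses,hosts \code{DNAStringSet}s.
#' @param threshold link threshold (default 0.2).
#' @param k,background_order passed to \code{\link{computeD2Star}}.
#' @return data.frame with virus_id, host_id, method ("d2star"), score
#'   (the d2* value) and passed for every pair.
#' @export
linkByD2Star <- function(viruses, hosts, threshold = 0.2, k = 6L,
                         background_order = 2L) {
  vstats <- lapply(seq_along(viruses), function(i)
    d2Stats(as.character(viruses[[i]]), k, background_order))
  hstats <- lapply(seq_along(hosts), function(i)
    d2Stats(as.character(hosts[[i]]), k, background_order))
  grid <- expand.grid(v = seq_along(viruses), h = seq_along(hosts))
  score <- mapply(function(v, h) d2StarFromStats(vstats[[v]], hstats[[h]]),
                  grid$v, grid$h)
  data.frame(virus_id = names(viruses)[grid$v],
             host_id = names(hosts)[grid$h],
             method = "d2star", score = as.numeric(score),
             passed = as.numeric(score) <= threshold,
             stringsAsFactors = FALSE)
}
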