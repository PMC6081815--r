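## CRISPR evidence: a CRT-style direct-repeat finder and spacer-to-virus
## matching (full-length, Hamming distance <= 1, either strand).

#' Detect CRISPR arrays in a host genome
#'
#' CRT-style detector: a short anchor k-mer (the minimum repeat length)
#' that recurs at least \code{min_repeats} times with consecutive gaps
#' compatible with repeat + spacer geometry seeds a candidate array; the
#' repeat is then extended outwards while all copies agree, degenerate
#' extra copies (<= 1 mismatch to the consensus) are picked up by a rescan,
#' and overlapping candidates are merged.
#'
#' @param host host record (1-sequence \code{DNAStringSet}) or character.
#' @param repeat_len_range direct-repeat length bounds (default 21-48 bp).
#' @param spacer_len_range spacer length bounds (default 20-50 bp).
#' @param min_repeats minimum repeat copies (default 4, i.e. >= 3 spacers).
#' @return list of arrays; each is a list with \code{host_id},
#'   \code{repeat_consensus}, \code{spacers} (data.frame: seq, start, end;
#'   1-based closed host coordinates) and \code{array_span}.  Empty list
#'   when no array is found.
#' @export
detectCrisprArrays <- function(host, repeat_len_range = c(21L, 48L),
                               spacer_len_range = c(20L, 50L),
                               min_repeats = 4L) {
  host_id <- if (is(host, "DNAStringSet")) names(host)[1] else "host"
  s <- asSequenceChar(host)
  n <- nchar(s)
  k0 <- repeat_len_range[1]
  gap_min <- k0 + spacer_len_range[1]
  gap_max <- repeat_len_range[2] + spacer_len_range[2]
  if (n < min_repeats * k0 + (min_repeats - 1L) * spacer_len_range[1])
    return(list())
  km <- kmerVector(s, k0)
  tab <- table(km)
  anchors <- names(tab)[tab >= min_repeats]
  if (!length(anchors)) return(list())
  x <- strsplit(s, "", fixed = TRUE)[[1]]
  cands <- list()
  for (a in anchors) {
    pos <- which(km == a)
    ## maximal runs with plausible repeat+spacer periodicity; a gap of two
    ## periods is tolerated (a degenerate copy breaks its exact anchor and
    ## is recovered later by the consensus rescan)
    run <- list(pos[1])
    for (i in seq_along(pos)[-1]) {
      g <- pos[i] - run[[length(run)]][length(run[[length(run)]])]
      if ((g >= gap_min && g <= gap_max) ||
          (g >= 2 * gap_min && g <= 2 * gap_max))
        run[[length(run)]] <- c(run[[length(run)]], pos[i])
      else if (g > 0 && g < gap_min) next   # overlapping/self-periodic: skip
      else run[[length(run) + 1L]] <- pos[i]
    }
    for (r in run) {
      if (length(r) < min_repeats) next
      ## extend repeat outwards while every copy agrees (unanimity)
      ext_l <- 0L
      while (k0 + ext_l < repeat_len_range[2] && min(r) - ext_l > 1L &&
             length(unique(x[r - ext_l - 1L])) == 1L &&
             min(diff(r)) - (k0 + ext_l) > spacer_len_range[1])
        ext_l <- ext_l + 1L
      ext_r <- 0L
      while (k0 + ext_l + ext_r < repeat_len_range[2] &&
             max(r) + k0 + ext_r <= n &&
             length(unique(x[r + k0 + ext_r])) == 1L &&
             min(diff(r)) - (k0 + ext_l + ext_r) > spacer_len_range[1])
        ext_r <- ext_r + 1L
      starts <- r - ext_l
      rl <- k0 + ext_l + ext_r
      consensus <- substr(s, starts[1], starts[1] + rl - 1L)
      ## rescan: pull in degenerate copies (<= 1 mismatch) continuing the run
      mp <- Biostrings::matchPattern(consensus, Biostrings::DNAString(s),
                                     max.mismatch = 1)
      extra <- setdiff(IRanges::start(mp), starts)
      for (e in sort(extra)) {
        gaps_ok <- function(v) {
          d <- diff(sort(v))
          all(d - rl >= spacer_len_range[1] & d - rl <= spacer_len_range[2])
        }
        if (gaps_ok(c(starts, e))) starts <- sort(c(starts, e))
      }
      spacer_start <- starts[-length(starts)] + rl
      spacer_end <- starts[-1] - 1L
      sp_len <- spacer_end - spacer_start + 1L
      if (any(sp_len < spacer_len_range[1] | sp_len > spacer_len_range[2]))
        next
      cands[[length(cands) + 1L]] <- list(
        host_id = host_id, repeat_consensus = consensus,
        spacers = data.frame(
          seq = substring(s, spacer_start, spacer_end),
          start = spacer_start, end = spacer_end, stringsAsFactors = FALSE),
        array_span = c(starts[1], starts[length(starts)] + rl - 1L),
        n_repeats = length(starts))
    }
  }
  if (!length(cands)) return(list())
  ## merge overlapping candidates: prefer more repeats, then longer repeat
  ord <- order(-vapply(cands, `[[`, 0L, "n_repeats"),
               -nchar(vapply(cands, `[[`, "", "repeat_consensus")))
  kept <- list()
  for (i in ord) {
    sp <- cands[[i]]$array_span
    clash <- any(vapply(kept, function(kk)
      sp[1] <= kk$array_span[2] && kk$array_span[1] <= sp[2], logical(1)))
    if (!clash) kept[[length(kept) + 1L]] <- cands[[i]]
  }
  kept[order(vapply(kept, function(a) a$array_span[1], 0))]
}

## minimal Hamming distance of pattern against every window of subject,
## end-to-end, no indels; Inf when pattern is longer than subject
minHammingWindow <- function(pattern, subject) {
  lp <- nchar(pattern); ls <- nchar(subject)
  if (lp > ls) return(Inf)
  p <- Biostrings::DNAString(pattern)
  s <- Biostrings::DNAString(subject)
  for (mm in 0:2) {
    if (Biostrings::countPattern(p, s, max.mismatch = mm) > 0) return(mm)
  }
  Inf
}

#' Match CRISPR spacers to viral contigs
#'
#' A spacer links its host to a virus iff it aligns end-to-end (full spacer
#' length, no indels, either strand) with at most \code{max_mismatch}
#' mismatches.  The score is the minimal mismatch count.
#'
#' @param arrays result of \code{\link{detectCrisprArrays}} (list of
#'   arrays), or a data.frame with host_id and spacer_seq columns.
#' @param viruses \code{DNAStringSet} of viral contigs.
#' @param max_mismatch maximum Hamming distance (default 1).
#' @return data.frame of host links: virus_id, host_id, method ("crispr"),
#'   score (mismatches), passed.
#' @export
matchSpacers <- function(arrays, viruses, max_mismatch = 1L) {
  if (is.data.frame(arrays)) {
    spdf <- data.frame(host_id = arrays$host_id, seq = arrays$spacer_seq,
                       stringsAsFactors = FALSE)
  } else {
    spdf <- do.call(rbind, lapply(arrays, function(a)
      data.frame(host_id = a$host_id, seq = a$spacers$seq,
                 stringsAsFactors = FALSE)))
  }
  if (is.null(spdf) || !nrow(spdf)) stop("no spacers to match")
  rows <- list()
  for (i in seq_len(nrow(spdf))) {
    sp <- spdf$seq[i]
    spr <- revcompChar(sp)
    for (j in seq_along(viruses)) {
      v <- as.character(viruses[[j]])
      mm <- min(minHammingWindow(sp, v), minHammingWindow(spr, v))
      if (mm <= max_mismatch) {
        rows[[length(rows) + 1L]] <- data.frame(
          virus_id = names(viruses)[j], host_id = spdf$host_id[i],
          method = "crispr", score = mm, passed = TRUE,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows))
    return(data.frame(virus_id = character(), host_id = character(),
                      method = character(), score = numeric(),
                      passed = logical()))
  agg <- do.call(rbind, rows)
  ## one row per (virus, host): best (minimal) mismatch count
  key <- paste(agg$virus_id, agg$host_id)
  best <- tapply(agg$score, key, min)
  out <- agg[!duplicated(key), , drop = FALSE]
  out$score <- as.numeric(best[paste(out$virus_id, out$host_id)])
  rownames(out) <- NULL
  out
}
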