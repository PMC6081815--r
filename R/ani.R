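## ANI/aligned-fraction estimation and greedy vOTU clustering.
## Populations are defined at >= 95% average nucleotide identity over
## >= 80% of the shorter contig's length, the community standard for
## species-rank viral populations.

## k-mer vector of a character sequence (positions 1..n-k+1)
kmerVector <- function(x, k) {
  n <- nchar(x)
  if (n < k) return(character(0))
  substring(x, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L)
}

#' Estimate pairwise ANI and aligned fraction
#'
#' Alignment-free ANI estimate from chained exact k-mer anchors with
#' ungapped extension.  Shared k-mers are grouped by diagonal (offset);
#' diagonals are chained greedily (largest anchor support first, spans
#' non-overlapping on the shorter sequence) and identity is computed
#' base-by-base over each chained span.  The aligned fraction uses the
#' shorter contig's length as denominator.  The result is symmetric in its
#' arguments.
#'
#' @param a,b sequences (character, \code{DNAString} or 1-sequence
#'   \code{DNAStringSet}).
#' @param k anchor k-mer size (default 15).
#' @return list with \code{ani} (NA when nothing aligns),
#'   \code{aligned_fraction} and \code{aligned_bp}.
#' @export
estimatePairwiseANI <- function(a, b, k = 15L) {
  sa <- asSequenceChar(a); sb <- asSequenceChar(b)
  if (nchar(sa) < k || nchar(sb) < k)
    stop("sequences must be at least k bases long")
  ## canonical order => symmetry: longer sequence is the subject
  if (nchar(sa) < nchar(sb) || (nchar(sa) == nchar(sb) && sa > sb)) {
    tmp <- sa; sa <- sb; sb <- tmp
  }
  shorter <- nchar(sb)
  ka <- kmerVector(sa, k); kb <- kmerVector(sb, k)
  hit <- match(kb, ka)                       # first occurrence in subject
  qpos <- which(!is.na(hit))
  if (!length(qpos))
    return(list(ani = NA_real_, aligned_fraction = 0, aligned_bp = 0L))
  diag <- hit[qpos] - qpos                   # subject offset minus query offset
  xa <- strsplit(sa, "", fixed = TRUE)[[1]]
  xb <- strsplit(sb, "", fixed = TRUE)[[1]]
  covered <- rep(FALSE, shorter)
  matches <- 0L; aligned <- 0L
  ## ungapped extension: carry through an isolated mismatch when at least
  ## 6 of the next 8 bases still match (keeps edge bases of diverged but
  ## homologous pairs; virtually never extends into unrelated sequence)
  extendable <- function(pos, dd, step) {
    nxt <- pos + step
    if (nxt < 1L || nxt > shorter || nxt + dd < 1L || nxt + dd > nchar(sa))
      return(FALSE)
    if (xb[nxt] == xa[nxt + dd]) return(TRUE)
    look <- nxt + step * (1:8)
    look <- look[look >= 1L & look <= shorter &
                   look + dd >= 1L & look + dd <= nchar(sa)]
    length(look) >= 4L && sum(xb[look] == xa[look + dd]) >= 0.75 * length(look)
  }
  for (d in names(sort(table(diag), decreasing = TRUE))) {
    dd <- as.integer(d)
    qp <- qpos[diag == dd]
    from <- min(qp); to <- max(qp) + k - 1L
    while (extendable(from, dd, -1L)) from <- from - 1L
    while (extendable(to, dd, 1L)) to <- to + 1L
    span <- from:to
    span <- span[!covered[span] & span + dd >= 1L & span + dd <= nchar(sa)]
    if (!length(span)) next
    covered[span] <- TRUE
    matches <- matches + sum(xb[span] == xa[span + dd])
    aligned <- aligned + length(span)
  }
  list(ani = if (aligned > 0) matches / aligned else NA_real_,
       aligned_fraction = aligned / shorter,
       aligned_bp = aligned)
}

#' Cluster viral contigs into populations (vOTUs)
#'
#' Greedy centroid clustering: contigs longer than \code{min_len} are sorted
#' by decreasing length (ties broken lexicographically by id); each contig
#' joins the first existing seed it matches at \code{ani >= ani_min} and
#' \code{aligned_fraction >= af_min} (both inclusive), otherwise it founds a
#' new vOTU.  Contigs of length <= \code{min_len} are excluded from
#' clustering and reported separately.
#'
#' @param contigs \code{DNAStringSet} with unique names.
#' @param min_len pool threshold in bp; only contigs strictly longer enter
#'   clustering (default 5000).
#' @param ani_min,af_min inclusive thresholds (defaults 0.95 and 0.80).
#' @param k anchor k-mer size passed to \code{\link{estimatePairwiseANI}}.
#' @return list with \code{votus} (data.frame: seed_id, member_id,
#'   seed_length) and \code{short} (ids excluded by \code{min_len}).
#' @export
clusterVOTUs <- function(contigs, min_len = 5000L, ani_min = 0.95,
                         af_min = 0.80, k = 15L) {
  if (!length(contigs))
    return(list(votus = data.frame(seed_id = character(),
                                   member_id = character(),
                                   seed_length = integer()),
                short = character()))
  ids <- names(contigs)
  if (is.null(ids) || anyDuplicated(ids))
    stop("contig ids must be present and unique")
  w <- Biostrings::width(contigs)
  pool <- ids[w > min_len]
  short <- ids[w <= min_len]
  if (!length(pool))
    return(list(votus = data.frame(seed_id = character(),
                                   member_id = character(),
                                   seed_length = integer()),
                short = short))
  ord <- pool[order(-w[match(pool, ids)], pool)]
  seqs <- lapply(setNames(ord, ord), function(i) asSequenceChar(contigs[i]))
  seeds <- character(0)
  assign_to <- character(length(ord)); names(assign_to) <- ord
  for (id in ord) {
    placed <- FALSE
    for (s in seeds) {
      r <- estimatePairwiseANI(seqs[[s]], seqs[[id]], k = k)
      if (!is.na(r$ani) && r$ani >= ani_min && r$aligned_fraction >= af_min) {
        assign_to[id] <- s; placed <- TRUE; break
      }
    }
    if (!placed) { seeds <- c(seeds, id); assign_to[id] <- id }
  }
  votus <- data.frame(seed_id = unname(assign_to), member_id = names(assign_to),
                      stringsAsFactors = FALSE)
  votus$seed_length <- w[match(votus$seed_id, ids)]
  votus <- votus[order(votus$seed_id, votus$member_id), , drop = FALSE]
  rownames(votus) <- NULL
  list(votus = votus, short = short)
}
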