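## Independent oracles used across the suite.  These deliberately share no
## code with the package implementations they check.

library(Biostrings)

## global-alignment identity (fraction) via pairwiseAlignment
globalIdentity <- function(a, b) {
  pa <- Biostrings::pairwiseAlignment(asChar1(a), asChar1(b), type = "global")
  Biostrings::pid(pa) / 100
}

asChar1 <- function(x) {
  if (is(x, "DNAStringSet")) as.character(x[[1]])
  else if (is(x, "DNAString")) as.character(x)
  else x
}

## transitive-closure clustering at (ani, af) thresholds via union-find
bruteForceClusters <- function(contigs, ani_min = 0.95, af_min = 0.80) {
  ids <- names(contigs)
  parent <- seq_along(ids)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_along(ids)[-length(ids)]) for (j in (i + 1):length(ids)) {
    r <- estimatePairwiseANI(contigs[ids[i]], contigs[ids[j]])
    if (!is.na(r$ani) && r$ani >= ani_min && r$aligned_fraction >= af_min) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  vapply(seq_along(ids), find, integer(1))
}

## brute-force d2*: explicit loops over all 4^6 words, sliding-window
## counting, per-word Markov probability as an explicit product
bfWordCount <- function(seq, w) {
  n <- nchar(seq)
  words <- substring(seq, 1:(n - w + 1), w:n)
  rc <- asChar1(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  words_rc <- substring(rc, 1:(n - w + 1), w:n)
  all_w <- apply(expand.grid(rep(list(c("A", "C", "G", "T")), w),
                             stringsAsFactors = FALSE)[, w:1, drop = FALSE],
                 1, paste, collapse = "")
  cnt <- setNames(numeric(length(all_w)), sort(all_w))
  for (ww in names(cnt)) cnt[ww] <- sum(words == ww) + sum(words_rc == ww)
  cnt
}

bruteForceD2Star <- function(a, b, k = 6, m = 2) {
  stats <- lapply(c(a, b), function(s) {
    s <- asChar1(s)
    X <- bfWordCount(s, k)
    cm <- bfWordCount(s, m)
    cm1 <- bfWordCount(s, m + 1)
    pm <- cm / sum(cm)
    p <- setNames(numeric(length(X)), names(X))
    for (w in names(X)) {
      pr <- pm[[substr(w, 1, m)]]
      if (is.na(pr)) pr <- 0
      for (i in 1:(k - m)) {
        ctx <- substr(w, i, i + m - 1)
        tot <- 0
        for (bb in c("A", "C", "G", "T")) tot <- tot + cm1[[paste0(ctx, bb)]]
        pr <- pr * (if (tot > 0) cm1[[substr(w, i, i + m)]] / tot else 0)
      }
      p[w] <- pr
    }
    list(X = X, p = p, n = sum(X))
  })
  A <- stats[[1]]; B <- stats[[2]]
  num <- 0; dx <- 0; dy <- 0
  for (w in names(A$X)) {
    if (A$p[[w]] <= 0 || B$p[[w]] <= 0) next
    xt <- A$X[[w]] - A$n * A$p[[w]]
    yt <- B$X[[w]] - B$n * B$p[[w]]
    num <- num + xt * yt / sqrt(A$n * A$p[[w]] * B$n * B$p[[w]])
    dx <- dx + xt^2 / (A$n * A$p[[w]])
    dy <- dy + yt^2 / (B$n * B$p[[w]])
  }
  0.5 * (1 - num / (sqrt(dx) * sqrt(dy)))
}

## exhaustive sliding-window Hamming match (both strands, no indels)
slidingMinHamming <- function(spacer, virus) {
  virus <- asChar1(virus)
  best <- Inf
  for (sp in c(spacer,
               asChar1(Biostrings::reverseComplement(Biostrings::DNAString(spacer))))) {
    ls <- nchar(sp); lv <- nchar(virus)
    if (ls > lv) next
    spv <- strsplit(sp, "")[[1]]
    vv <- strsplit(virus, "")[[1]]
    for (i in 1:(lv - ls + 1)) {
      mm <- sum(spv != vv[i:(i + ls - 1)])
      if (mm < best) best <- mm
    }
  }
  best
}

## fixtures: one modest community shared by the linkage tests (generated
## once per test run)
sharedCommunity <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- makeCommunity(seed = 20240811L, n_samples_per_group = 2L,
                              host_len = 30000L)
    cache
  }
})
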