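test_that("prophage screen applies all four thresholds inclusively", {
  hit <- data.frame(query_id = "v", subject_id = "h", pct_identity = 70,
                    aln_len = 750, bitscore = 50, evalue = 1e-3,
                    query_len = 1000)
  expect_equal(nrow(screenProphageHits(hit)), 1)  # all boundaries inclusive
  for (fail in list(c(aln_len = 740), c(pct_identity = 69.9),
                    c(bitscore = 49), c(evalue = 2e-3))) {
    h2 <- hit; h2[[names(fail)]] <- fail[[1]]
    expect_equal(nrow(screenProphageHits(h2)), 0)
  }
  expect_error(screenProphageHits(transform(hit, query_len = NA)), "query_len")

  ## pure filter: idempotent, output subset of input pairs
  hits <- rbind(hit, transform(hit, query_id = "v2", aln_len = 600))
  l1 <- screenProphageHits(hits)
  expect_equal(l1$virus_id, "v")
})

test_that("exact scanner recovers implanted prophages", {
  host <- makeGenome(20000, 0.5, 0, seed = 1, id = "H1")
  virus <- makeGenome(3000, 0.5, 0, seed = 2, id = "V1", role = "viral")
  res <- implantProphage(host, virus, 7000)
  hits <- scanProphagesExact(virus, res$host)
  links <- screenProphageHits(hits)
  expect_equal(links$virus_id, "V1")
  expect_equal(links$host_id, "H1")
})

test_that("CRISPR detector finds implanted arrays exactly", {
  host <- makeGenome(20000, 0.5, 0, seed = 3, id = "H1")
  vir <- do.call(c, lapply(1:4, function(i)
    makeGenome(1500, 0.5, 0, seed = 20 + i, id = paste0("V", i),
               role = "viral")))
  res <- implantCrisprArray(host, vir, n_spacers = 3, repeat_len = 30,
                            spacer_len = 34, position = 9000, seed = 4)
  arr <- detectCrisprArrays(res$host)
  expect_length(arr, 1)
  expect_equal(arr[[1]]$repeat_consensus, res$repeat_seq)
  expect_equal(nrow(arr[[1]]$spacers), 3)
  expect_setequal(arr[[1]]$spacers$seq, res$truth$spacer_seq)

  ## two arrays far apart are reported separately with correct order
  res2 <- implantCrisprArray(res$host, vir, n_spacers = 3, repeat_len = 24,
                             spacer_len = 28, position = 2000, seed = 5)
  arr2 <- detectCrisprArrays(res2$host)
  expect_length(arr2, 2)
  expect_lt(arr2[[1]]$array_span[1], arr2[[2]]$array_span[1])
})

test_that("CRISPR detector tolerates a degenerate repeat copy", {
  host <- makeGenome(15000, 0.5, 0, seed = 6, id = "H1")
  vir <- do.call(c, lapply(1:5, function(i)
    makeGenome(1500, 0.5, 0, seed = 30 + i, id = paste0("V", i),
               role = "viral")))
  res <- implantCrisprArray(host, vir, n_spacers = 4, repeat_len = 28,
                            spacer_len = 32, position = 6000, seed = 7)
  ## corrupt one base in the middle of the third repeat copy
  s <- as.character(res$host[[1]])
  arr0 <- detectCrisprArrays(res$host)[[1]]
  third_start <- arr0$array_span[1] + 2 * (28 + 32)
  at <- third_start + 14
  b <- substr(s, at, at)
  substr(s, at, at) <- setdiff(c("A", "C", "G", "T"), b)[1]
  arr <- detectCrisprArrays(Biostrings::DNAStringSet(setNames(s, "H1")))
  expect_length(arr, 1)
  expect_equal(nrow(arr[[1]]$spacers), 4)
})

test_that("random hosts yield no CRISPR arrays", {
  empties <- vapply(1:20, function(s)
    length(detectCrisprArrays(makeGenome(50000, 0.5, 0, seed = 1000 + s,
                                         id = "H"))), integer(1))
  expect_gte(mean(empties == 0), 0.99)
})

test_that("spacer matching is exact-Hamming on both strands", {
  virus <- makeGenome(2000, 0.5, 0, seed = 8, id = "V1", role = "viral")
  v <- as.character(virus[[1]])
  sp0 <- substr(v, 501, 532)
  flip <- function(x, at) {
    b <- substr(x, at, at)
    substr(x, at, at) <- setdiff(c("A", "C", "G", "T"), b)[1]
    x
  }
  sp1 <- flip(sp0, 10)
  sp2 <- flip(sp1, 20)
  sprc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(sp0)))
  arrays <- data.frame(host_id = "H1",
                       spacer_seq = c(sp0, sp1, sp2, sprc))
  links <- matchSpacers(arrays[1, , drop = FALSE], virus)
  expect_equal(links$score, 0)
  expect_equal(matchSpacers(arrays[2, , drop = FALSE], virus)$score, 1)
  expect_equal(nrow(matchSpacers(arrays[3, , drop = FALSE], virus)), 0)
  expect_equal(matchSpacers(arrays[4, , drop = FALSE], virus)$score, 0)

  ## agreement with the exhaustive sliding-window oracle
  for (sp in arrays$spacer_seq) {
    mm <- slidingMinHamming(sp, virus)
    link <- matchSpacers(data.frame(host_id = "H", spacer_seq = sp), virus)
    if (mm <= 1) expect_equal(link$score, mm) else expect_equal(nrow(link), 0)
  }
})

test_that("d2* is zero on identity, symmetric, and matches brute force", {
  a <- makeGenome(800, 0.45, 0, seed = 1, id = "a")
  expect_lt(abs(computeD2Star(a, a)), 1e-12)
  b <- makeGenome(700, 0.60, 0, seed = 2, id = "b")
  expect_equal(computeD2Star(a, b), computeD2Star(b, a))
  expect_gte(computeD2Star(a, b), 0)
  for (s in 1:5) {
    x <- as.character(makeGenome(600, 0.4 + 0.03 * s, 0, seed = s)[[1]])
    y <- as.character(makeGenome(800, 0.65 - 0.03 * s, 0, seed = s + 9)[[1]])
    expect_lt(abs(computeD2Star(x, y) - bruteForceD2Star(x, y)), 1e-10)
  }
  expect_error(computeD2Star("ACG", a), "shorter")
})

test_that("d2* separates hosts by shared composition", {
  hitA <- 0L
  for (s in 1:10) {
    cuA <- withr::with_seed(s, virolink:::randomCodonUsage(0.40))
    cuB <- withr::with_seed(s + 100, virolink:::randomCodonUsage(0.60))
    hostA <- virolink:::codonGenome(20000, cuA, seed = s, id = "A")
    hostB <- virolink:::codonGenome(20000, cuB, seed = s + 200, id = "B")
    vir <- virolink:::codonGenome(8000, cuA, seed = s + 300, id = "v",
                                  role = "viral")
    dA <- computeD2Star(vir, hostA); dB <- computeD2Star(vir, hostB)
    hitA <- hitA + (dA < dB)
  }
  expect_gte(hitA / 10, 0.95)
})

test_that("d2* link threshold is inclusive", {
  vir <- makeGenome(2000, 0.5, 0, seed = 1, id = "v", role = "viral")
  host <- makeGenome(5000, 0.5, 0, seed = 2, id = "h")
  s <- computeD2Star(vir, host)
  at <- linkByD2Star(vir, host, threshold = s)
  expect_true(at$passed)
  expect_equal(at$score, s)
  below <- linkByD2Star(vir, host, threshold = s - 1e-9)
  expect_false(below$passed)
  ## self-comparison of a genome listed as both virus and host
  self <- linkByD2Star(host, host, threshold = 0.2)
  expect_true(self$passed)
  expect_lt(self$score, 1e-12)
})

test_that("Markov host models are normalized and score self higher", {
  hostA <- makeGenome(30000, 0.40, 0, seed = 1, id = "A")
  hostB <- makeGenome(30000, 0.60, 0, seed = 2, id = "B")
  mA <- trainMarkovModel(hostA, order = 4)
  p <- exp(mA@log_word_prob)
  sums <- rowSums(matrix(p, ncol = 4, byrow = TRUE))
  expect_true(all(abs(sums - 1) < 1e-12))

  ## homopolymer limit
  homo <- trainMarkovModel(paste(rep("A", 5000), collapse = ""), order = 2)
  expect_gt(exp(homo@log_word_prob[1]), 0.99)  # P(A | AA)

  ## subsequence of A scores higher under A's model than B's
  mB <- trainMarkovModel(hostB, order = 4)
  sub <- substr(as.character(hostA[[1]]), 5000, 15000)
  expect_gt(scoreMarkov(sub, mA), scoreMarkov(sub, mB))

  ## circular scoring: exact rotation and self-concatenation invariance
  v <- as.character(makeGenome(3000, 0.5, 0, seed = 3)[[1]])
  rot <- paste0(substr(v, 1001, 3000), substr(v, 1, 1000))
  expect_equal(scoreMarkov(v, mA), scoreMarkov(rot, mA), tolerance = 1e-12)
  expect_lt(abs(scoreMarkov(v, mA) - scoreMarkov(paste0(v, v), mA)), 1e-9)
})

test_that("Markov linking uses a Gaussian null and LCA aggregation", {
  expect_error(scoreAndLinkMarkov(makeGenome(1000, .5, 0, seed = 1),
                                  list(trainMarkovModel("ACGTACGTACGT", 1),
                                       trainMarkovModel("ACGTACGTACGT", 1))),
               "at least 3")
  lin <- c("Bacteria;Proteo;Alpha;Rhizo;Fam1;GenusG;sp1",
           "Bacteria;Proteo;Alpha;Rhizo;Fam1;GenusG;sp2",
           "Bacteria;Proteo;Alpha;Rhizo;Fam1;GenusG;sp3")
  expect_equal(lcaLineage(lin),
               "Bacteria;Proteo;Alpha;Rhizo;Fam1;GenusG")
  expect_equal(lcaLineage(c("Bacteria;Proteo;x", "Bacteria;Firmicutes;y")),
               "Bacteria")
  expect_equal(lcaLineage(c("Bacteria;Proteo", "Archaea;Halo")),
               "unclassified")
  ## truncated lineages act as wildcards below their truncation
  expect_equal(lcaLineage(c("Bacteria;Proteo;Alpha", "Bacteria;Proteo")),
               "Bacteria;Proteo;Alpha")
})

test_that("link integration uses union semantics with method flags", {
  bl <- data.frame(virus_id = "v1", host_id = "h1", method = "blast",
                   score = 0.9, passed = TRUE)
  cr <- data.frame(virus_id = "v1", host_id = "h1", method = "crispr",
                   score = 0, passed = TRUE)
  d2 <- data.frame(virus_id = c("v1", "v2"), host_id = c("h2", "h1"),
                   method = "d2star", score = c(0.5, 0.6),
                   passed = c(FALSE, FALSE))
  tab <- integrateLinks(list(bl, cr, d2))
  expect_equal(nrow(tab), 1)            # v1-h2 and v2-h1 fail all methods
  expect_true(tab$blast & tab$crispr)
  expect_false(tab$d2star)
  expect_equal(tab$n_methods, 2)
})
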