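test_that("makeGenome respects length, GC target and determinism", {
  g <- makeGenome(1000, 0.5, 0, seed = 1)
  expect_equal(Biostrings::width(g), 1000)
  gc <- Biostrings::letterFrequency(g[[1]], "GC", as.prob = TRUE)[[1]]
  expect_lt(abs(gc - 0.5), 0.05)

  g7 <- makeGenome(10000, 0.65, 0, seed = 7)
  gc7 <- Biostrings::letterFrequency(g7[[1]], "GC", as.prob = TRUE)[[1]]
  expect_lt(abs(gc7 - 0.65), 0.02)

  expect_identical(as.character(makeGenome(1000, 0.5, 0, seed = 1)[[1]]),
                   as.character(g[[1]]))
  for (ord in 1:2) {
    gm <- makeGenome(2000, 0.4, ord, seed = 3)
    expect_equal(Biostrings::width(gm), 2000)
    expect_identical(as.character(makeGenome(2000, 0.4, ord, seed = 3)[[1]]),
                     as.character(gm[[1]]))
  }
  expect_error(makeGenome(50, 0.5), "length_bp")
  expect_error(makeGenome(1000, 1.2), "fraction")
})

test_that("mutateSequence divergence tracks the nominal substitution rate", {
  g <- makeGenome(10000, 0.5, 0, seed = 2, id = "parent")
  same <- mutateSequence(g, 0, 0, seed = 1)
  expect_identical(as.character(same[[1]]), as.character(g[[1]]))

  mut <- mutateSequence(g, 0.05, 0, seed = 3)
  d <- mean(strsplit(as.character(g[[1]]), "")[[1]] !=
              strsplit(as.character(mut[[1]]), "")[[1]])
  expect_lt(abs(d - 0.05), 0.01)

  ## realized ANI of a 10% mutant against the global-alignment oracle
  p6 <- makeGenome(6000, 0.5, 0, seed = 4, id = "p6")
  m6 <- mutateSequence(p6, 0.10, 0, seed = 5)
  r <- estimatePairwiseANI(p6, m6)
  expect_lt(abs(r$ani - 0.90), 0.01)
  expect_lt(abs(r$ani - globalIdentity(p6, m6)), 0.01)

  ## indels change length but stay near the nominal rate
  mi <- mutateSequence(p6, 0, 0.02, seed = 6)
  expect_false(Biostrings::width(mi) == 6000 &&
                 as.character(mi[[1]]) == as.character(p6[[1]]))
  expect_error(mutateSequence(g, 0.6), "rates")
})

test_that("implantation conserves flanks and records truth", {
  host <- makeGenome(5000, 0.5, 0, seed = 1, id = "H")
  virus <- makeGenome(1200, 0.5, 0, seed = 2, id = "V", role = "viral")
  res <- implantProphage(host, virus, 0)
  expect_equal(Biostrings::width(res$host), 6200)
  expect_true(startsWith(as.character(res$host[[1]]),
                         as.character(virus[[1]])))

  res2 <- implantProphage(host, virus, 2500)
  s <- as.character(res2$host[[1]])
  expect_identical(substr(s, 2501, 3700), as.character(virus[[1]]))
  expect_identical(substr(s, 1, 2500),
                   substr(as.character(host[[1]]), 1, 2500))   # left flank
  expect_identical(substr(s, 3701, 6200),
                   substr(as.character(host[[1]]), 2501, 5000)) # right flank
  expect_equal(res2$truth$insert_start, 2500)
  expect_error(implantProphage(host, virus, 9999), "bounds")
})

test_that("implanted CRISPR arrays have the repeat-spacer geometry", {
  host <- makeGenome(8000, 0.5, 0, seed = 1, id = "H")
  vir <- do.call(c, lapply(1:4, function(i)
    makeGenome(1500, 0.5, 0, seed = 10 + i, id = paste0("V", i),
               role = "viral")))
  res <- implantCrisprArray(host, vir, n_spacers = 3, repeat_len = 28,
                            spacer_len = 32, position = 4000, seed = 2)
  s <- as.character(res$host[[1]])
  ## n_spacers + 1 identical repeat copies
  expect_equal(Biostrings::countPattern(res$repeat_seq,
                                        Biostrings::DNAString(s)), 4)
  ## length conservation: 4 repeats + 3 spacers inserted
  expect_equal(nchar(s), 8000 + 4 * 28 + 3 * 32)
  ## each truth spacer occurs verbatim in its source virus
  for (i in seq_len(nrow(res$truth)))
    expect_equal(slidingMinHamming(res$truth$spacer_seq[i],
                                   vir[res$truth$virus_id[i]]), 0)
  expect_error(implantCrisprArray(host, vir, n_spacers = 2), "n_spacers")
})

test_that("simulatePlacements matches its Poisson depth model", {
  contig <- makeGenome(10000, 0.5, 0, seed = 1, id = "C1")
  des0 <- matrix(c(0, 20), 1, 2, dimnames = list("s1", c("C0", "C1")))
  contigs <- c(makeGenome(8000, 0.5, 0, seed = 2, id = "C0"), contig)
  ps <- simulatePlacements(contigs, des0, read_len = 100, seed = 5)
  gr <- placements(ps)
  expect_equal(sum(GenomicRanges::seqnames(gr) == "C0"), 0)    # zero depth
  ## seed-averaged mapped count within 5% of depth*len/read_len = 2000
  counts <- vapply(1:5, function(s)
    length(placements(simulatePlacements(contigs, des0, 100, seed = s))),
    numeric(1))
  expect_lt(abs(mean(counts) - 2000) / 2000, 0.05)
  ## breadth of a 20x contig is essentially saturated
  expect_gt(computeBreadth(ps, "C1", "s1", 10000), 0.99)
  ## determinism
  ps2 <- simulatePlacements(contigs, des0, read_len = 100, seed = 5)
  expect_identical(GenomicRanges::start(placements(ps2)),
                   GenomicRanges::start(gr))
  expect_error(simulatePlacements(contigs, des0, read_len = 20000), "read_len")
})

test_that("makeCommunityDesign applies group effects to the right features", {
  d <- makeCommunityDesign(6, c("P7", "P8"), 40, effect_size = 4,
                           dispersion = 0.5, seed = 1)
  expect_equal(dim(d$abundance), c(12, 40))
  expect_true(all(d$abundance > 0))
  expect_equal(levels(d$groups), c("P7", "P8"))
  ## affected features are enriched in group 2 by ~4x on the log scale
  lfc <- colMeans(log(d$abundance[d$groups == "P8", ])) -
    colMeans(log(d$abundance[d$groups == "P7", ]))
  expect_gt(mean(lfc[d$affected]), log(4) - 0.5)
  expect_lt(abs(mean(lfc[-d$affected])), 0.5)
  ## null design is exchangeable in expectation
  d0 <- makeCommunityDesign(6, c("P7", "P8"), 40, effect_size = 1, seed = 2)
  lfc0 <- colMeans(log(d0$abundance[d0$groups == "P8", ])) -
    colMeans(log(d0$abundance[d0$groups == "P7", ]))
  expect_lt(abs(mean(lfc0)), 0.2)
})

test_that("generators are byte-identical under a fixed seed", {
  c1 <- makeCommunity(seed = 99, n_hosts = 4, n_families = 3, n_viruses = 6,
                      n_short = 2, n_prophages = 2, n_crispr = 1,
                      host_len = 12000, n_samples_per_group = 2)
  c2 <- makeCommunity(seed = 99, n_hosts = 4, n_families = 3, n_viruses = 6,
                      n_short = 2, n_prophages = 2, n_crispr = 1,
                      host_len = 12000, n_samples_per_group = 2)
  expect_identical(as.character(c1$hosts), as.character(c2$hosts))
  expect_identical(as.character(c1$viruses), as.character(c2$viruses))
  expect_identical(c1$design, c2$design)
  expect_identical(c1$truth, c2$truth)
})
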