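test_that("ANI estimator agrees with the global-alignment oracle", {
  a <- makeGenome(6000, 0.5, 0, seed = 3, id = "A")
  expect_equal(estimatePairwiseANI(a, a)$ani, 1.0)
  expect_equal(estimatePairwiseANI(a, a)$aligned_fraction, 1.0)

  b <- mutateSequence(a, 0.05, 0, seed = 4, id = "B")
  r <- estimatePairwiseANI(a, b)
  expect_lt(abs(r$ani - 0.95), 0.01)
  expect_gte(r$aligned_fraction, 0.95)
  expect_lt(abs(r$ani - globalIdentity(a, b)), 0.01)

  ## unrelated sequences fail the aligned-fraction threshold
  r0 <- estimatePairwiseANI(makeGenome(6000, 0.5, 0, seed = 5),
                            makeGenome(6000, 0.5, 0, seed = 6))
  expect_lt(r0$aligned_fraction, 0.8)

  ## symmetry over seeded pairs of mixed divergence
  for (s in 1:5) {
    x <- makeGenome(1500, 0.45, 0, seed = s, id = "x")
    y <- mutateSequence(x, s * 0.02, 0, seed = s + 50, id = "y")
    r1 <- estimatePairwiseANI(x, y); r2 <- estimatePairwiseANI(y, x)
    expect_identical(r1, r2)
  }
  expect_error(estimatePairwiseANI("ACGT", a), "at least k")
})

test_that("greedy vOTU clustering obeys thresholds, tie-breaks and pooling", {
  a <- makeGenome(6000, 0.5, 0, seed = 1, id = "ctgA")
  dup <- Biostrings::DNAStringSet(setNames(
    c(as.character(a[[1]]), as.character(a[[1]])), c("ctgB", "ctgA")))
  cl <- clusterVOTUs(dup)
  expect_equal(length(unique(cl$votus$seed_id)), 1)
  expect_equal(unique(cl$votus$seed_id), "ctgA")   # lexicographic tie-break

  ## 10% divergence is below the 95% ANI threshold: two populations
  div <- mutateSequence(a, 0.10, 0, seed = 2, id = "ctgC")
  two <- clusterVOTUs(c(a, div))
  expect_equal(length(unique(two$votus$seed_id)), 2)

  ## pool boundary: exactly 5000 bp is excluded, 5001 bp enters
  p5000 <- makeGenome(5000, 0.5, 0, seed = 3, id = "len5000")
  p5001 <- makeGenome(5001, 0.5, 0, seed = 4, id = "len5001")
  cl2 <- clusterVOTUs(c(p5000, p5001))
  expect_identical(cl2$short, "len5000")
  expect_identical(cl2$votus$member_id, "len5001")

  expect_equal(nrow(clusterVOTUs(Biostrings::DNAStringSet())$votus), 0)
  expect_error(clusterVOTUs(dup[c(1, 1)]), "unique")
})

test_that("every vOTU member links to its seed at the thresholds", {
  comm <- sharedCommunity()
  pool <- comm$viruses[Biostrings::width(comm$viruses) > 5000]
  pool <- pool[seq_len(min(20, length(pool)))]
  cl <- clusterVOTUs(pool)
  nonseed <- cl$votus[cl$votus$member_id != cl$votus$seed_id, ]
  for (i in seq_len(nrow(nonseed))) {
    r <- estimatePairwiseANI(pool[nonseed$seed_id[i]],
                             pool[nonseed$member_id[i]])
    expect_gte(r$ani, 0.95)
    expect_gte(r$aligned_fraction, 0.80)
  }
})

test_that("breadth is the interval-union coverage fraction", {
  gr <- GenomicRanges::GRanges(
    c("c1", "c1"), IRanges::IRanges(start = c(1, 41), end = c(50, 80)),
    sample_id = "s1", read_id = c("r1", "r2"))
  ps <- PlacementSet(gr, c(s1 = 1000))
  expect_equal(computeBreadth(ps, "c1", "s1", 100), 0.8)
  expect_equal(computeBreadth(ps, "c1", "s2", 100), 0)   # unknown sample
  expect_equal(computeBreadth(ps, "cX", "s1", 100), 0)   # unknown contig
  ## saturation
  tile <- GenomicRanges::GRanges(
    "c1", IRanges::IRanges(start = seq(1, 91, 10), width = 10),
    sample_id = "s1", read_id = paste0("t", 1:10))
  expect_equal(computeBreadth(PlacementSet(tile, c(s1 = 100)), "c1", "s1", 100), 1)
})

test_that("RPKM follows mapped * 1e9 / (total * length)", {
  expect_equal(computeRPKM(0, 1e6, 1e4), 0)
  expect_equal(computeRPKM(100, 1e6, 1e4), 10)
  expect_equal(computeRPKM(1, 1e9, 1), 1)
  expect_error(computeRPKM(1, 0, 10), "total_reads")
  expect_error(computeRPKM(1, 10, 0), "contig_len")
})

test_that("vOTU table gates presence at breadth >= 0.75 inclusive", {
  ## contig of length 100; tiles covering exactly 75 and 74 bases
  mk <- function(cov) GenomicRanges::GRanges(
    "seed1", IRanges::IRanges(start = 1, end = cov),
    sample_id = "s1", read_id = "r1")
  votus <- data.frame(seed_id = "seed1", member_id = "seed1")
  t75 <- buildVOTUTable(votus, PlacementSet(mk(75), c(s1 = 1e6)),
                        c(seed1 = 100))
  expect_true(presenceMatrix(t75)["seed1", "s1"])
  expect_equal(rpkmMatrix(t75)["seed1", "s1"], computeRPKM(1, 1e6, 100))
  t74 <- buildVOTUTable(votus, PlacementSet(mk(74), c(s1 = 1e6)),
                        c(seed1 = 100))
  expect_false(presenceMatrix(t74)["seed1", "s1"])
  expect_equal(rpkmMatrix(t74)["seed1", "s1"], 0)
})

test_that("RPKM additivity and presence masking hold on simulated data", {
  contigs <- c(makeGenome(10000, 0.5, 0, seed = 1, id = "v1"),
               makeGenome(8000, 0.5, 0, seed = 2, id = "v2"))
  des <- matrix(c(20, 0, 0, 20), 2, 2,
                dimnames = list(c("s1", "s2"), c("v1", "v2")))
  ps <- simulatePlacements(contigs, des, read_len = 100,
                           totals = c(s1 = 1e6, s2 = 1e6), seed = 9)
  votus <- data.frame(seed_id = c("v1", "v2"), member_id = c("v1", "v2"))
  vt <- buildVOTUTable(votus, ps, c(v1 = 10000, v2 = 8000))
  expect_true(presenceMatrix(vt)["v1", "s1"])
  expect_false(presenceMatrix(vt)["v1", "s2"])
  ## present cell within 5% of the analytic expectation
  exp_rpkm <- 20 * 10000 / 100 * 1e9 / (1e6 * 10000)
  expect_lt(abs(rpkmMatrix(vt)["v1", "s1"] - exp_rpkm) / exp_rpkm, 0.05)

  ## doubling the placements (totals fixed) exactly doubles RPKM
  gr <- placements(ps)
  ps2 <- PlacementSet(c(gr, gr), sampleTotals(ps))
  vt2 <- buildVOTUTable(votus, ps2, c(v1 = 10000, v2 = 8000))
  expect_equal(rpkmMatrix(vt2), 2 * rpkmMatrix(vt))
})

test_that("per-sample summaries count presence and use natural-log Shannon", {
  rpkm <- matrix(c(2, 2, 2, 2,  5, 0, 0, 0,  0, 0, 0, 0), 4, 3,
                 dimnames = list(paste0("v", 1:4), c("s1", "s2", "s3")))
  pres <- rpkm > 0
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(rpkm = rpkm, presence = pres))
  vt <- new("VOTUTable", se)
  s <- summarizeSamples(vt)
  expect_equal(s$richness, c(4, 1, 0))
  expect_equal(s$total_abundance, c(8, 5, 0))
  expect_equal(s$shannon[1], log(4))
  expect_equal(s$shannon[2], 0)
  expect_true(is.na(s$shannon[3]))
})

test_that("AMG screen enforces all four criteria", {
  ann <- rbind(
    ## three hallmark-bearing contigs with interior cysH -> candidate
    do.call(rbind, lapply(1:3, function(i) data.frame(
      contig_id = paste0("v", i), gene_id = paste0("v", i, "_g", 1:8),
      gene_index = 0:7, n_genes_on_contig = 8,
      product = c("capsid protein", "hyp", "hyp", "cysH", "hyp", "hyp",
                  "tail protein", "hyp"),
      category = c("viral_hallmark", "other", "other", "metabolic", "other",
                   "other", "viral_hallmark", "other")))),
    ## edge position (second gene) -> rejected
    data.frame(contig_id = "v4", gene_id = paste0("v4_g", 1:8),
               gene_index = 0:7, n_genes_on_contig = 8,
               product = c("hyp", "cysH", "hyp", "hyp", "hyp", "hyp",
                           "capsid protein", "hyp"),
               category = c("other", "metabolic", rep("other", 4),
                            "viral_hallmark", "other")),
    ## psbA on only two contigs -> rejected by criterion (iii)
    do.call(rbind, lapply(5:6, function(i) data.frame(
      contig_id = paste0("v", i), gene_id = paste0("v", i, "_g", 1:8),
      gene_index = 0:7, n_genes_on_contig = 8,
      product = c("capsid protein", "hyp", "hyp", "psbA", "hyp", "hyp",
                  "hyp", "hyp"),
      category = c("viral_hallmark", "other", "other", "metabolic",
                   rep("other", 4))))))
  out <- screenMetabolicGenes(ann)
  expect_setequal(unique(out$product), "cysH")
  expect_setequal(out$contig_id, c("v1", "v2", "v3"))

  ## gene on a contig without hallmark genes is rejected
  no_hall <- ann[ann$contig_id == "v1", ]
  no_hall$category[no_hall$category == "viral_hallmark"] <- "other"
  no_hall$contig_id <- "v9"; no_hall$gene_id <- paste0("v9_g", 1:8)
  expect_equal(nrow(screenMetabolicGenes(rbind(ann[ann$contig_id %in%
    c("v2", "v3"), ], no_hall))), 2)  # v9's cysH dropped, v2/v3 kept (3 contigs total)

  bad <- ann; bad$n_genes_on_contig[1] <- 9
  expect_error(screenMetabolicGenes(bad), "inconsistent")
})
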