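test_that("Bray-Curtis follows its definition and matches vegan", {
  m <- rbind(a = c(2, 2), b = c(1, 1), c = c(1, 0), d = c(0, 1))
  d <- as.matrix(brayCurtis(m))
  expect_equal(d["a", "b"], 1 / 3)
  expect_equal(d["c", "d"], 1)
  expect_equal(d["a", "a"], 0)
  set.seed(1)
  r <- matrix(rexp(30), 5, 6)
  expect_equal(as.numeric(brayCurtis(r)),
               as.numeric(vegan::vegdist(r, "bray")), tolerance = 1e-12)
  expect_error(brayCurtis(rbind(c(0, 0), c(0, 0))), "all-zero")
})

test_that("Hellinger transform normalizes rows to unit sum of squares", {
  h <- hellinger(matrix(c(1, 1, 2), 1))
  expect_equal(as.numeric(h), c(0.5, 0.5, sqrt(0.5)), tolerance = 1e-12)
  set.seed(2)
  m <- matrix(rexp(40), 5, 8)
  H <- hellinger(m)
  expect_equal(rowSums(H^2), rep(1, 5), ignore_attr = TRUE)
  expect_equal(hellinger(3 * m), H)                    # scale invariance
  expect_equal(unname(H), unname(vegan::decostand(m, "hellinger")),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(hellinger(rbind(c(0, 0))), "all-zero")
})

test_that("PERMANOVA matches vegan's pseudo-F and honours the +1 convention", {
  d <- makeCommunityDesign(5, c("g1", "g2"), 30, effect_size = 3, seed = 4)
  bc <- brayCurtis(d$abundance)
  pm <- permanova(bc, d$groups, n_perm = 199, seed = 1)
  ad <- vegan::adonis2(bc ~ g, data = data.frame(g = d$groups),
                       permutations = 2)
  expect_equal(pm$statistic, ad$F[1], tolerance = 1e-10)
  expect_equal(pm$R2, ad$R2[1], tolerance = 1e-10)
  ## p is a multiple of 1/(n_perm + 1) and deterministic under the seed
  expect_equal(pm$p_value * 200, round(pm$p_value * 200))
  expect_identical(pm$p_value, permanova(bc, d$groups, 199, seed = 1)$p_value)
  expect_error(permanova(bc, rep("g", 10)), "two groups")

  ## euclidean univariate limit: pseudo-F equals classical one-way ANOVA F
  x <- c(1.2, 0.7, 1.9, 5.2, 4.8, 6.1)
  g <- rep(c("a", "b"), each = 3)
  pmu <- permanova(dist(x), g, n_perm = 99, seed = 2)
  expect_equal(pmu$statistic,
               summary(aov(x ~ g))[[1]]$`F value`[1], tolerance = 1e-10)
})

test_that("NMDS recovers planar configurations and decreases stress", {
  set.seed(5)
  X <- matrix(rnorm(20), 10, 2)
  nm <- nmdsOrdination(dist(X), k = 2, n_starts = 5, seed = 1)
  expect_lt(nm$stress, 0.01)
  expect_true(all(diff(nm$stress_history) <= 1e-8))

  ## two-cluster fixture: rank correlation between input dissimilarities
  ## and output distances
  d <- makeCommunityDesign(6, c("a", "b"), 40, effect_size = 5,
                           dispersion = 0.35, seed = 6)
  bc <- brayCurtis(d$abundance)
  nm2 <- nmdsOrdination(bc, seed = 2, n_starts = 10)
  rc <- cor(as.numeric(bc), as.numeric(dist(nm2$coordinates)),
            method = "spearman")
  expect_gte(rc, 0.95)

  ## stress is invariant under relabeling of the distance matrix
  perm <- sample(12)
  bcp <- as.dist(as.matrix(bc)[perm, perm])
  nm3 <- nmdsOrdination(bcp, seed = 2, n_starts = 10)
  expect_lt(abs(nm3$stress - nm2$stress), 1e-3)
})

test_that("Procrustes correlation is 1 for similarity transforms", {
  set.seed(7)
  X <- matrix(rnorm(24), 12, 2)
  th <- pi / 7
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  Y <- 3 * X %*% R + 5
  pr <- procrustesProtest(X, Y, n_perm = 99, seed = 1)
  expect_equal(pr$correlation, 1, tolerance = 1e-10)
  expect_equal(pr$m2, 0, tolerance = 1e-10)
  ## axis relabeling of Y is subsumed by the rotation
  pr2 <- procrustesProtest(X, Y[, 2:1], n_perm = 99, seed = 1)
  expect_equal(pr2$correlation, 1, tolerance = 1e-10)
  ## agreement with vegan's protest statistic
  Z <- matrix(rnorm(24), 12, 2)
  expect_equal(procrustesProtest(X, Z, n_perm = 49, seed = 1)$correlation,
               vegan::protest(X, Z, permutations = 2)$t0, tolerance = 1e-10)
  expect_error(procrustesProtest(X, Z[1:5, ]), "same number of rows")
})

test_that("PCA explains variance fractions that sum to one", {
  set.seed(8)
  x <- rnorm(50)
  tab <- cbind(a = x, b = 2 * x, c = rnorm(50))
  expect_warning(p0 <- pcaOrdination(cbind(tab, zv = 1)), "zero-variance")
  p <- pcaOrdination(tab[, c("a", "b")])
  expect_equal(p$variance_explained[1], 1, tolerance = 1e-10)
  p3 <- pcaOrdination(tab)
  expect_equal(sum(p3$variance_explained), 1, tolerance = 1e-12)

  ## planted 2-factor structure: recovered subspace within 10 degrees
  n <- 100
  f <- matrix(rnorm(2 * n), n, 2)
  load <- matrix(rnorm(12), 2, 6)
  obs <- f %*% load + matrix(rnorm(6 * n, sd = 0.1), n, 6)
  pr <- pcaOrdination(obs, standardize = FALSE)
  V <- pr$loadings[, 1:2]
  W <- qr.Q(qr(t(load)))
  ang <- acos(pmin(1, svd(crossprod(qr.Q(qr(V)), W))$d)) * 180 / pi
  expect_lt(max(ang), 10)
})

test_that("RDA forward selection requires a significant global test", {
  set.seed(9)
  resp <- hellinger(makeCommunityDesign(6, c("a", "b"), 30, effect_size = 1,
                                        seed = 10)$abundance)
  noise <- matrix(rnorm(12 * 4), 12, 4,
                  dimnames = list(rownames(resp), paste0("x", 1:4)))
  r0 <- rdaForwardSelect(resp, noise, n_perm = 199, seed = 3)
  expect_gte(r0$global$p, 0.05)
  expect_null(r0$selected)

  ## generative recovery: response driven by g1
  d <- makeCommunityDesign(6, c("a", "b"), 30, effect_size = 4, seed = 11)
  resp2 <- hellinger(d$abundance)
  g1 <- as.numeric(d$groups) + rnorm(12, sd = 0.2)
  pred <- cbind(g1 = g1, x2 = rnorm(12), x3 = rnorm(12))
  rownames(pred) <- rownames(resp2)
  r1 <- rdaForwardSelect(resp2, pred, n_perm = 199, seed = 4)
  expect_lt(r1$global$p, 0.05)
  expect_equal(r1$selected[1], "g1")
  expect_true(r1$adj_r2 > 0 && r1$adj_r2 <= 1)

  ## a duplicate of a selected predictor is collinear, dropped, never chosen
  pred2 <- cbind(pred, g1dup = g1)
  expect_warning(r2 <- rdaForwardSelect(resp2, pred2, n_perm = 199, seed = 4),
                 "collinear")
  expect_false("g1dup" %in% r2$selected)
})
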