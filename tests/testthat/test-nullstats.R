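test_that("tip shuffling permutes labels but nothing else", {
  tr <- randTree(16, seed = 1)
  sh <- withr::with_seed(2, shuffleTipLabels(tr))
  expect_setequal(sh$tip.label, tr$tip.label)
  expect_identical(sh$edge, tr$edge)
  expect_identical(sh$edge.length, tr$edge.length)
  expect_identical(shapeString(sh), shapeString(tr))
  # restricted shuffle leaves the rest alone
  sub <- tr$tip.label[1:2]
  sh2 <- withr::with_seed(3, shuffleTipLabels(tr, sub))
  expect_identical(sh2$tip.label[-(1:2)], tr$tip.label[-(1:2)])
  # seeded replay
  expect_identical(withr::with_seed(7, shuffleTipLabels(tr)),
                   withr::with_seed(7, shuffleTipLabels(tr)))
  expect_error(shuffleTipLabels(tr, "nope"), "nope")
})

test_that("dispersion percentiles follow the (count+1)/(n+1) rule", {
  # clustered sample on a structured tree: observed far below all nulls
  sp <- simSpec(seed = 31)
  tr <- simulateTree(sp)
  tax <- simulateTaxonomy(tr, sp)
  tab <- simulateCommunities(tr, sp, tax)
  m <- speciesCounts(tab)
  cnt <- m[1, m[1, ] > 0]
  res <- alphaDispersionTest(tr, cnt, metric = "weighted_mpd",
                             nPerm = 199, seed = 5)
  expect_equal(res@percentile,
               (sum(res@nullValues <= res@observed) + 1) / 200)
  expect_length(res@nullValues, 199)
  # degenerate geometry: every shuffle yields the observed value
  star <- parseNewick("(a:1,b:1,c:1,d:1);")
  res2 <- alphaDispersionTest(star, c(a = 3, b = 1, c = 2, d = 5),
                              metric = "weighted_mpd", nPerm = 49,
                              seed = 6)
  expect_true(all(res2@nullValues == res2@observed))
  expect_equal(res2@percentile, 1)
  expect_equal(res2@call, "not-significant")
  # metacommunity must contain the sample
  expect_error(alphaDispersionTest(tr, cnt, metacommunity = names(cnt)[-1],
                                   nPerm = 9, seed = 1),
               "metacommunity")
})

test_that("dispersion tests agree with a picante-style manual shuffle", {
  skip_if_not_installed("picante")
  # same machinery, independent route: shuffle labels with
  # picante::tipShuffle and recompute the metric by its definition
  tr <- randTree(12, seed = 41)
  cnt <- randCounts(tr$tip.label, 6, seed = 41)
  res <- alphaDispersionTest(tr, cnt, metric = "weighted_mpd",
                             nPerm = 99, seed = 8)
  manual <- vapply(1:99, function(i) {
    sh <- withr::with_seed(1000 + i, picante::tipShuffle(tr))
    meanPairwiseDist(sh, cnt)
  }, numeric(1))
  # both null distributions describe the same permutation population
  expect_gt(stats::ks.test(res@nullValues, manual)$p.value, 1e-4)
})

test_that("pseudo-F matches the hand-derived four-sample case", {
  D <- matrix(2, 4, 4); D[1, 2] <- D[2, 1] <- 1; D[3, 4] <- D[4, 3] <- 1
  diag(D) <- 0
  rownames(D) <- colnames(D) <- paste0("s", 1:4)
  res <- permanovaF(D, c("a", "a", "b", "b"))
  tb <- res@table
  expect_equal(tb$SumOfSqs, c(3.5, 1.0, 4.5), tolerance = 1e-12)
  expect_equal(tb$F[1], 7, tolerance = 1e-12)
  expect_equal(tb$R2[1], 3.5 / 4.5, tolerance = 1e-12)
  # all-equal distances: F = 1
  De <- matrix(1, 4, 4); diag(De) <- 0
  rownames(De) <- colnames(De) <- paste0("s", 1:4)
  expect_equal(unname(pseudoF(permanovaF(De, c("a", "a", "b", "b")))["F"]),
               1, tolerance = 1e-12)
  # consistent relabeling leaves the table unchanged
  res2 <- permanovaF(D, c("x", "x", "y", "y"))
  expect_equal(res2@table[, -1], tb[, -1])
  expect_error(permanovaF(D, c("a", "a", "a", "b")), "singleton")
})

test_that("pseudo-F agrees with vegan::adonis2 on random matrices", {
  for (s in 1:8) {
    N <- withr::with_seed(s, sample(6:12, 1))
    pts <- withr::with_seed(100 + s, matrix(rnorm(N * 3), N))
    D <- dist(pts)
    g <- rep(c("a", "b", "c"), length.out = N)
    mine <- unname(pseudoF(permanovaF(D, g))[c("F", "R2")])
    van <- vegan::adonis2(D ~ g, permutations = 2)
    expect_equal(mine[1], van$F[1], tolerance = 1e-10)
    expect_equal(mine[2], van$R2[1], tolerance = 1e-10)
  }
})

test_that("free permutation p has the exceedance-count form", {
  sp <- simSpec(nSamples = 12L, structure = "clustered",
                groupByClade = TRUE, cladeLevel = "family", richness = 6L,
                seed = 51)
  tr <- simulateTree(sp)
  tab <- simulateCommunities(tr, sp, NULL)
  d <- betaDistanceMatrix(tab, metric = "bray_curtis")
  res <- permanovaFreeTest(d, sampleGroups(tab), nPerm = 199, seed = 9)
  expect_equal(unname(pseudoF(res)["p"]),
               (sum(res@nullF >= res@table$F[1]) + 1) / 200)
  # strong separation drives p to (or near) the permutation floor; only a
  # permutation that re-creates the observed split can tie the observed F
  expect_lte(unname(pseudoF(res)["p"]), 0.02)
  # nPerm = 1 can only give 1/2 or 1
  r1 <- permanovaFreeTest(d, sampleGroups(tab), nPerm = 1, seed = 10)
  expect_true(pseudoF(r1)["p"] %in% c(0.5, 1))
})

test_that("tip-shuffle PERMANOVA is inert on shuffle-invariant geometry", {
  star <- parseNewick("(a:1,b:1,c:1,d:1,e:1,f:1);")
  m <- rbind(s1 = c(a = 5L, b = 3L, c = 0L, d = 0L, e = 1L, f = 0L),
             s2 = c(a = 4L, b = 4L, c = 1L, d = 0L, e = 0L, f = 0L),
             s3 = c(a = 0L, b = 0L, c = 5L, d = 5L, e = 0L, f = 2L),
             s4 = c(a = 0L, b = 1L, c = 4L, d = 6L, e = 0L, f = 1L))
  tab <- communityTable(m, groups = c(s1 = "x", s2 = "x", s3 = "y",
                                      s4 = "y"))
  res <- permanovaTipShuffleTest(star, tab, nPerm = 99, seed = 11)
  expect_equal(unname(pseudoF(res)["p"]), 1)
  expect_true(all(abs(res@nullF - res@table$F[1]) < 1e-12))
})

test_that("tip-shuffle PERMANOVA detects clade-locked group structure", {
  sp <- simSpec(nSamples = 10L, structure = "clustered",
                groupByClade = TRUE, cladeLevel = "family", richness = 6L,
                seed = 61)
  tr <- simulateTree(sp)
  tab <- simulateCommunities(tr, sp)
  res <- permanovaTipShuffleTest(tr, tab, nPerm = 199, seed = 12)
  expect_lt(unname(pseudoF(res)["p"]), 0.05)
})

test_that("Holm adjustment matches the step-down arithmetic", {
  expect_equal(holmAdjust(c(0.001, 0.001, 0.001)), rep(0.003, 3))
  expect_equal(holmAdjust(c(0.01, 0.02, 0.03)), c(0.03, 0.04, 0.04))
  expect_equal(holmAdjust(0.2), 0.2)
  expect_error(holmAdjust(numeric(0)), "empty")
  expect_error(holmAdjust(c(0.5, 0)), "0, 1")
})

test_that("pairwise PERMANOVA composes per-pair tests with Holm", {
  sp <- simSpec(nSamples = 18L, nGroups = 3L, structure = "clustered",
                groupByClade = TRUE, cladeLevel = "family", richness = 6L,
                fanout = c(phylum = 3L, class = 1L, order = 1L,
                           family = 1L, genus = 2L),
                seed = 71)
  tr <- simulateTree(sp)
  tab <- simulateCommunities(tr, sp)
  d <- betaDistanceMatrix(tab, metric = "bray_curtis")
  out <- pairwisePermanova(d, sampleGroups(tab), mode = "free",
                           nPerm = 399, seed = 13)
  expect_equal(nrow(out), 3L)
  expect_equal(out$p_adj, holmAdjust(out$p))
  # fully separated groups stay significant after Holm
  expect_true(all(out$significant))
  # two groups: adjustment is the identity
  sel <- sampleGroups(tab) %in% c("g1", "g2")
  d2 <- as.dist(as.matrix(d)[sel, sel])
  out2 <- pairwisePermanova(d2, sampleGroups(tab)[sel], mode = "free",
                            nPerm = 99, seed = 14)
  expect_equal(out2$p_adj, out2$p)
})
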