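test_that("species-based alpha metrics match closed forms", {
  m <- alphaSpeciesMetrics(c(5, 5, 5, 5))
  expect_equal(unname(m["richness"]), 4)
  expect_equal(unname(m["shannon"]), log(4), tolerance = 1e-12)
  expect_equal(unname(m["simpson"]), 0.75, tolerance = 1e-12)
  expect_equal(unname(alphaSpeciesMetrics(c(7))), c(1, 0, 0))
  # scale invariance
  expect_equal(alphaSpeciesMetrics(c(2, 3, 5)),
               alphaSpeciesMetrics(10 * c(2, 3, 5)))
  expect_error(alphaSpeciesMetrics(c(0, 0)), "zero total")
})

test_that("Faith's PD is the spanning-subtree length", {
  tr <- t1()
  expect_equal(faithPD(tr, tr$tip.label), 6)
  expect_equal(faithPD(tr, c("A", "B")), 2)
  expect_equal(faithPD(tr, "A"), 0)
  expect_error(faithPD(tr, "Z"), "missing from tree")
})

test_that("weighted Faith matches the hand-enumerated edge sums", {
  tr <- parseNewick("((A:1,B:2):1,C:4);")
  expect_equal(weightedFaith(tr, c(A = 3, B = 1, C = 4)), 9.2,
               tolerance = 1e-12)
  expect_equal(weightedFaith(t1(), c(A = 4, B = 4)), 2, tolerance = 1e-12)
})

test_that("mean pairwise distance matches hand values and picante", {
  skip_if_not_installed("picante")
  tr <- parseNewick("((A:1,B:2):1,C:4);")
  cnt <- c(A = 3, B = 1, C = 4)
  expect_equal(meanPairwiseDist(tr, cnt), 109 / 19, tolerance = 1e-12)
  expect_equal(meanPairwiseDist(t1(), c(A = 1, B = 1, C = 1, D = 1)),
               10 / 3, tolerance = 1e-12)
  # two species: the pair distance regardless of weights
  expect_equal(meanPairwiseDist(t1(), c(A = 9, C = 1)), 4)
  expect_error(meanPairwiseDist(t1(), c(A = 2)), "at least 2")
  # picante includes i==j weight terms; convert exactly and compare
  for (s in 1:10) {
    tr <- randTree(12, seed = 300 + s)
    cnt <- randCounts(tr$tip.label, 6, seed = s)
    samp <- matrix(0, 1, 12, dimnames = list("s1", tr$tip.label))
    samp[1, names(cnt)] <- cnt
    pic <- picante::mpd(samp, ape::cophenetic.phylo(tr),
                        abundance.weighted = TRUE)
    S <- sum(cnt); ssq <- sum(cnt^2)
    expect_equal(meanPairwiseDist(tr, cnt), pic * S^2 / (S^2 - ssq),
                 tolerance = 1e-10)
    pic0 <- picante::mpd(samp, ape::cophenetic.phylo(tr),
                         abundance.weighted = FALSE)
    expect_equal(meanPairwiseDist(tr, cnt, weighted = FALSE), pic0,
                 tolerance = 1e-10)
  }
})

test_that("faith PD agrees with picante on random communities", {
  skip_if_not_installed("picante")
  for (s in 1:10) {
    tr <- randTree(16, seed = 400 + s)
    present <- withr::with_seed(s, sample(tr$tip.label, 5))
    samp <- matrix(0, 1, 16, dimnames = list("s1", tr$tip.label))
    samp[1, present] <- 1
    expect_equal(faithPD(tr, present),
                 picante::pd(samp, tr, include.root = FALSE)$PD,
                 tolerance = 1e-10)
  }
})

test_that("Bray-Curtis follows its formula and bounds", {
  expect_equal(brayCurtis(c(a = 6, b = 2), c(a = 2, b = 2)), 1 / 3)
  expect_equal(brayCurtis(c(a = 5, b = 1), c(a = 5, b = 1)), 0)
  expect_equal(brayCurtis(c(a = 5), c(b = 3)), 1)
  expect_equal(brayCurtis(c(a = 6, b = 2), c(a = 2, b = 2),
                          weighted = FALSE), 0)
  expect_error(brayCurtis(c(a = 0), c(a = 1)), "zero-total")
})

test_that("UniFrac matches the spec'd edge-wise examples", {
  tr <- t1()
  x <- c(A = 1, B = 1); y <- c(C = 1, D = 1)
  expect_equal(uniFrac(tr, x, y, weighted = FALSE), 1)
  expect_equal(uniFrac(tr, x, y, weighted = TRUE), 4)
  expect_equal(uniFrac(tr, c(A = 1), c(A = 1, B = 1), weighted = FALSE),
               1 / 3, tolerance = 1e-12)
  expect_equal(uniFrac(tr, x, x, weighted = TRUE), 0)
  expect_equal(uniFrac(tr, x, x, weighted = FALSE), 0)
  expect_error(uniFrac(tr, c(Z = 1), y), "missing from tree")
})

test_that("distance matrices equal elementwise metric calls", {
  sp <- simSpec(nSamples = 5L, structure = "random", richness = 6L,
                seed = 21)
  tr <- simulateTree(sp)
  tab <- simulateCommunities(tr, sp)
  m <- speciesCounts(tab)
  for (w in c(TRUE, FALSE)) {
    dbc <- as.matrix(betaDistanceMatrix(tab, metric = "bray_curtis",
                                        weighted = w))
    duf <- as.matrix(betaDistanceMatrix(tab, tr, metric = "unifrac",
                                        weighted = w))
    for (i in 1:4) for (j in (i + 1):5) {
      x <- m[i, m[i, ] > 0]; y <- m[j, m[j, ] > 0]
      expect_equal(dbc[i, j], brayCurtis(x, y, w), tolerance = 1e-12)
      expect_equal(duf[i, j], uniFrac(tr, x, y, weighted = w),
                   tolerance = 1e-12)
    }
    expect_true(all(abs(dbc - t(dbc)) < 1e-15) && all(diag(dbc) == 0))
    expect_true(all(duf >= 0) && all(diag(duf) == 0))
    if (!w) expect_true(all(duf <= 1 + 1e-12))
  }
  # identical samples give a zero matrix
  mm <- m[c(1, 1, 1), , drop = FALSE]
  rownames(mm) <- paste0("r", 1:3)
  same <- communityTable(mm)
  expect_true(all(as.matrix(betaDistanceMatrix(same,
                                               metric = "bray_curtis")) == 0))
})

test_that("a zero-abundance grafted species changes no metric", {
  tr <- t1()
  node <- mrcaNode(tr, c("A", "B"))
  big <- graftQueries(tr, data.frame(label = "Q", taxid = 9L, node = node,
                                     pendant = 1.7))
  cnt <- c(A = 3, B = 1, C = 4, D = 2)
  expect_equal(weightedFaith(big, cnt), weightedFaith(tr, cnt))
  expect_equal(meanPairwiseDist(big, cnt), meanPairwiseDist(tr, cnt))
  expect_equal(uniFrac(big, cnt[c("A", "B")], cnt[c("C", "D")]),
               uniFrac(tr, cnt[c("A", "B")], cnt[c("C", "D")]))
})

test_that("alphaDiversity assembles all metrics per sample", {
  m <- rbind(s1 = c(A = 5L, B = 5L, C = 5L, D = 5L),
             s2 = c(A = 8L, B = 0L, C = 0L, D = 0L))
  out <- alphaDiversity(communityTable(m), t1())
  expect_equal(out$richness, c(4, 1))
  expect_equal(out$faith_pd, c(6, 0))
  expect_equal(out$weighted_faith[1], 6)
  expect_true(is.na(out$mpd[2]))
})
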