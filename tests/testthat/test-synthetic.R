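test_that("simulated trees are rooted, bifurcating and reproducible", {
  sp <- simSpec(seed = 81)
  tr <- simulateTree(sp)
  expect_equal(ape::Ntip(tr), 32L)
  expect_equal(tr$Nnode, 31L)
  expect_true(all(tr$edge.length > 0))
  expect_true(ape::is.rooted(tr))
  expect_identical(writeNewick(simulateTree(sp)), writeNewick(tr))
  expect_false(identical(writeNewick(simulateTree(simSpec(seed = 82))),
                         writeNewick(tr)))
})

test_that("simulated taxonomies are congruent with the tree", {
  sp <- simSpec(seed = 83)
  tr <- simulateTree(sp)
  tax <- simulateTaxonomy(tr, sp)
  expect_equal(nrow(tax$tipTable), 32L)
  # every tip lineage has all seven ranks
  for (tx in tax$tipTable$taxid) {
    lin <- canonicalLineage(tax$db, tx)
    expect_false(anyNA(lin))
  }
  # every taxon at every rank is exactly one clade: the tips sharing it
  # are all descendants of their MRCA, and nothing else is
  for (rank in c("genus", "family", "phylum")) {
    byTaxon <- split(tax$tipTable$tip_label,
                     vapply(tax$tipTable$taxid, function(x)
                       unname(canonicalLineage(tax$db, x)[rank]),
                       integer(1)))
    for (tips in byTaxon) {
      if (length(tips) == 1L) next
      node <- mrcaNode(tr, tips)
      expect_setequal(spanningSubtree(tr, tips)$tip.label, tips)
      expect_length(distancesFromNode(tr, node, tips), length(tips))
      desc <- ape::extract.clade(tr, node)$tip.label
      expect_setequal(desc, tips)
    }
  }
  # round-trips through the taxdump dialect
  dir <- withr::local_tempdir()
  writeTaxdump(tax$db, dir)
  db2 <- loadTaxdump(file.path(dir, "nodes.dmp"),
                     file.path(dir, "names.dmp"))
  expect_equal(db2@nodes$taxid, tax$db@nodes$taxid)
  expect_equal(db2@nodes$rank, tax$db@nodes$rank)
})

test_that("clustered communities are clade-restricted, random ones are not", {
  sp <- simSpec(nSamples = 12L, seed = 84)
  tr <- simulateTree(sp)
  tax <- simulateTaxonomy(tr, sp)
  tab <- simulateCommunities(tr, sp, tax)
  m <- speciesCounts(tab)
  genusOf <- vapply(tax$tipTable$taxid, function(x)
    unname(canonicalLineage(tax$db, x)["genus"]), integer(1))
  names(genusOf) <- tax$tipTable$tip_label
  for (i in seq_len(nrow(m))) {
    present <- colnames(m)[m[i, ] > 0]
    expect_length(unique(genusOf[present]), 1L)
    expect_true(all(m[i, present] > 0))
  }
  # random mode spreads occupancy across the whole tree
  spr <- simSpec(nSamples = 40L, structure = "random", richness = 8L,
                 seed = 85)
  tabr <- simulateCommunities(tr, spr)
  occ <- colSums(speciesCounts(tabr) > 0)
  expect_gt(sum(occ > 0), 28)
  # occupancy consistent with uniform sampling (chi-square, generous alpha)
  chi <- sum((occ - mean(occ))^2 / mean(occ))
  expect_lt(chi, stats::qchisq(1 - 1e-3, df = 31))
})

test_that("clustered assembly lowers weighted MPD relative to random", {
  diffs <- vapply(1:25, function(s) {
    spC <- simSpec(nSamples = 4L, structure = "clustered", seed = 9000 + s)
    spR <- simSpec(nSamples = 4L, structure = "random", seed = 9000 + s)
    tr <- simulateTree(spC)
    mC <- speciesCounts(simulateCommunities(tr, spC))
    mR <- speciesCounts(simulateCommunities(tr, spR))
    mean(vapply(1:4, function(i)
      meanPairwiseDist(tr, mR[i, mR[i, ] > 0]) -
        meanPairwiseDist(tr, mC[i, mC[i, ] > 0]), numeric(1)))
  }, numeric(1))
  expect_gt(mean(diffs), 0)
})

test_that("leave-one-out cases record the expected pruned-tree placement", {
  sp <- simSpec(seed = 86)
  tr <- simulateTree(sp)
  tax <- simulateTaxonomy(tr, sp)
  cases <- leaveOneOutCases(tr, tax$tipTable, tax$db, 6, seed = 87)
  expect_length(cases, 6L)
  for (cs in cases) {
    expect_equal(ape::Ntip(cs$tree), 31L)
    expect_equal(cs$node, mrcaNode(cs$tree, cs$congeners))
    expect_equal(cs$pendant,
                 mean(distancesFromNode(cs$tree, cs$node, cs$congeners)))
  }
  expect_equal(vapply(leaveOneOutCases(tr, tax$tipTable, tax$db, 6,
                                       seed = 87),
                      `[[`, integer(1), "query"),
               vapply(cases, `[[`, integer(1), "query"))
})
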