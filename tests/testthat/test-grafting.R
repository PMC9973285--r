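test_that("tip annotation joins taxids and resolves merged ids", {
  db <- toyTaxdump()
  aphy <- annotateTips(t1(), t1TipTable(), db)
  expect_equal(nrow(tipData(aphy)), 4L)
  expect_equal(tipData(aphy)$species_taxid, c(817L, 818L, 21L, 22L))
  expect_equal(tipData(aphy)$genus, c(14L, 14L, 20L, 20L))
  # merged taxid on a tip is redirected and logged
  tt <- t1TipTable(); tt$taxid[1] <- 666L
  aphy2 <- annotateTips(t1(), tt, db)
  expect_equal(tipData(aphy2)$species_taxid[1], 817L)
  expect_match(aphy2@changes$record, "666 merged into 817", all = FALSE)
  # missing tip is a hard error naming the tip
  expect_error(annotateTips(t1(), t1TipTable()[-2, ], db), "B")
})

test_that("mapping rank is the lowest rank shared with any tip", {
  db <- toyTaxdump()
  aphy <- annotateTips(t1(), t1TipTable(), db)
  # a new congener of genus 14 maps at genus rank to tips A and B
  lin <- canonicalLineage(db, 817)
  lin["species"] <- 9999L
  mp <- determineMappingRank(lin, aphy)
  expect_equal(mp$status, "insert")
  expect_equal(mp$rank, "genus")
  expect_setequal(mp$candidates, c("A", "B"))
  # species already on the tree
  expect_equal(determineMappingRank(canonicalLineage(db, 818), aphy)$status,
               "already_present")
  # nothing shared at any rank
  alien <- stats::setNames(c(51L, 52L, 53L, 54L, 55L, 56L, 57L),
                           names(lin))
  expect_equal(determineMappingRank(alien, aphy)$status, "unplaceable")
})

test_that("mapping rank moves upward when candidates disappear", {
  db <- toyTaxdump()
  lin <- canonicalLineage(db, 817); lin["species"] <- 9999L
  ranks <- c("species", "genus", "family", "order", "class", "phylum",
             "superkingdom")
  full <- annotateTips(t1(), t1TipTable(), db)
  rankFull <- match(determineMappingRank(lin, full)$rank, ranks)
  # drop the congeners: only family-level relatives remain
  sub <- spanningSubtree(t1(), c("C", "D"))
  reduced <- annotateTips(sub, t1TipTable()[3:4, ], db)
  rankReduced <- match(determineMappingRank(lin, reduced)$rank, ranks)
  expect_true(rankReduced >= rankFull)
  expect_equal(determineMappingRank(lin, reduced)$rank, "family")
})

test_that("outlier filtering applies the Tukey fence only with >= 4 tips", {
  # star-ish tree with distances 1, 1.1, 0.9, 9 from the MRCA
  tr <- parseNewick("(w:1,x:1.1,y:0.9,z:9);")
  flt <- filterOutlierTips(tr, c("w", "x", "y", "z"))
  expect_equal(flt$outliers, "z")
  expect_setequal(flt$retained, c("w", "x", "y"))
  # fewer than four candidates: no filtering
  expect_equal(filterOutlierTips(tr, c("w", "x", "z"))$outliers,
               character(0))
  # all-equal distances sit on the fence and are kept
  eq <- parseNewick("(w:1,x:1,y:1,z:1);")
  expect_equal(filterOutlierTips(eq, eq$tip.label)$outliers, character(0))
})

test_that("placement parameters follow the subtree-root mean-distance rule", {
  tr <- parseNewick("((t1:1,t2:3):1,(t3:1,t4:1):1);")
  pp <- placementParams(tr, c("t1", "t2"))
  expect_equal(pp$node, mrcaNode(tr, c("t1", "t2")))
  expect_equal(pp$pendant, 2)
  ppAll <- placementParams(tr, tr$tip.label)
  expect_equal(ppAll$node, ape::Ntip(tr) + 1L)
  expect_equal(ppAll$pendant, 2.5)
  pp1 <- placementParams(tr, "t3")
  expect_equal(pp1$node, tr$edge[tr$edge[, 2] == 3, 1])
  expect_equal(pp1$pendant, 1)
})

test_that("batch grafting is order-independent and distance-preserving", {
  tr <- t1()
  node <- mrcaNode(tr, c("A", "B"))
  pl <- data.frame(label = c("Q1", "Q2"), taxid = c(91L, 92L),
                   node = c(node, node), pendant = c(1, 1.5))
  g12 <- graftQueries(tr, pl)
  g21 <- graftQueries(tr, pl[2:1, ])
  expect_identical(writeNewick(g12), writeNewick(g21))
  # two queries at one node form a polytomy
  expect_equal(sum(g12$edge[, 1] == mrcaNode(g12, c("A", "B"))), 4L)
  # original pairwise distances untouched
  expect_equal(patristicMatrix(g12, tr$tip.label), patristicMatrix(tr),
               tolerance = 1e-12)
  expect_error(graftQueries(tr, pl[c(1, 1), ]), "duplicate")
})

test_that("duplicate species are pruned to the smallest tip label", {
  db <- toyTaxdump()
  tr <- parseNewick("((A2:1,A1:1):1,(C:1,D:1):1);")
  tt <- data.frame(tip_label = c("A1", "A2", "C", "D"),
                   taxid = c(817L, 817L, 21L, 22L))
  pruned <- pruneDuplicateSpecies(annotateTips(tr, tt, db))
  expect_setequal(phyloTree(pruned)$tip.label, c("A1", "C", "D"))
  # no duplicates: identity
  aphy <- annotateTips(t1(), t1TipTable(), db)
  expect_identical(phyloTree(pruneDuplicateSpecies(aphy)), phyloTree(aphy))
})

test_that("the full expansion pipeline honours its output contract", {
  db <- toyTaxdump()
  # queries: one new congener is impossible in the toy taxonomy (all
  # species known), so use: already present (818), merged (666 -> 817,
  # also already present), strain promoted to species (819 -> 817 dup -> use
  # 22 instead), unknown (12345 is an error at resolve, reported not fatal)
  res <- expandPhylogeny(t1(), t1TipTable(), c(818L, 12345L), db)
  pl <- placementSummary(res)
  expect_equal(pl$status, c("already_present", "unplaceable"))
  expect_equal(ape::Ntip(phyloTree(res)), 4L)
  expect_equal(res@lengthAfter, res@lengthBefore)
  expect_error(expandPhylogeny(t1(), t1TipTable(), integer(0), db),
               "empty query")
})

test_that("expansion inserts novel congeners and logs taxid changes", {
  sp <- simSpec(seed = 11)
  tr <- simulateTree(sp)
  tax <- simulateTaxonomy(tr, sp)
  # drop three congeneric tips of one genus and re-add their species
  g <- canonicalLineage(tax$db, tax$tipTable$taxid[1])["genus"]
  genusTips <- tax$tipTable$tip_label[vapply(tax$tipTable$taxid, function(x)
    unname(canonicalLineage(tax$db, x)["genus"]) == g, logical(1))]
  drop <- genusTips[1:3]
  pruned <- ape::drop.tip(tr, drop)
  keep <- !(tax$tipTable$tip_label %in% drop)
  queries <- tax$tipTable$taxid[!keep]
  res <- expandPhylogeny(pruned, tax$tipTable[keep, ], queries, tax$db)
  pl <- placementSummary(res)
  expect_equal(sum(pl$status == "inserted"), 3L)
  expect_equal(ape::Ntip(phyloTree(res)), ape::Ntip(pruned) + 3L)
  expect_equal(res@lengthAfter,
               res@lengthBefore + sum(pl$pendant_length, na.rm = TRUE),
               tolerance = 1e-9)
  # original distances preserved through the whole pipeline
  expect_equal(patristicMatrix(phyloTree(res), pruned$tip.label),
               patristicMatrix(pruned), tolerance = 1e-12)
})

test_that("the output bundle contains the four trees and both logs", {
  sp <- simSpec(seed = 12)
  tr <- simulateTree(sp)
  tax <- simulateTaxonomy(tr, sp)
  drop <- tax$tipTable$tip_label[1:2]
  pruned <- ape::drop.tip(tr, drop)
  keep <- !(tax$tipTable$tip_label %in% drop)
  res <- expandPhylogeny(pruned, tax$tipTable[keep, ],
                         tax$tipTable$taxid[!keep], tax$db)
  dir <- withr::local_tempdir()
  writeExpansionBundle(res, dir)
  expect_true(all(file.exists(file.path(dir, c(
    "comprehensive_names.tree", "comprehensive_taxIDs.tree",
    "user_names.tree", "user_taxIDs.tree", "placement_summary.tsv",
    "taxid_changes.txt")))))
  comp <- parseNewick(file = file.path(dir, "comprehensive_names.tree"))
  expect_equal(ape::Ntip(comp), ape::Ntip(phyloTree(res)))
  user <- parseNewick(file = file.path(dir, "user_names.tree"))
  expect_equal(ape::Ntip(user), length(res@queryTips))
})
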