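# Validation studies: simulation experiments that characterize the
# grafting rule and the permutation tests on synthetic data with known
# ground truth.  Used by the test suite and the acceptance report alike.

#' Leave-one-out placement recovery study
#'
#' Simulates taxonomy-congruent trees, removes one tip at a time, re-grafts
#' its species through the full pipeline, and compares the realized
#' insertion node and pendant length against the expected genus-MRCA
#' placement recorded by [leaveOneOutCases()].
#'
#' @param nCases Total number of leave-one-out cases.
#' @param seed Master seed.
#' @param nSpeciesRange Range of tree sizes to draw from.
#' @param tol Absolute tolerance on the pendant length (default 1e-12).
#' @return List: `nExact` (cases matching node and pendant within `tol`),
#'   `n`, `maxPendantError`.
#' @export
placementRecoveryStudy <- function(nCases = 200L, seed = 1L,
                                   nSpeciesRange = c(32L, 64L),
                                   tol = 1e-12) {
  seeds <- childSeeds(seed, 3L)
  nTrees <- max(1L, ceiling(nCases / 10L))
  # genera of four species: removing one tip leaves three congeners, the
  # regime in which the mean-distance rule is an exact identity (the
  # outlier fence only arms itself at four or more candidates)
  sizes <- withSeed(seeds[1L],
                    sample(seq(nSpeciesRange[1L], nSpeciesRange[2L],
                               by = 16L),
                           nTrees, replace = TRUE))
  caseSeeds <- childSeeds(seeds[2L], nTrees)
  nExact <- 0L; n <- 0L; maxErr <- 0
  for (t in seq_len(nTrees)) {
    spec <- simSpec(nSpecies = sizes[t],
                    fanout = c(phylum = 2L, class = 1L, order = 1L,
                               family = 2L, genus = sizes[t] %/% 16L),
                    seed = caseSeeds[t])
    tree <- simulateTree(spec)
    tax <- simulateTaxonomy(tree, spec)
    perTree <- min(10L, nCases - n)
    if (perTree <= 0L) break
    cases <- leaveOneOutCases(tree, tax$tipTable, tax$db, perTree,
                              seed = caseSeeds[t] + 1L)
    for (cs in cases) {
      n <- n + 1L
      keep <- tax$tipTable$tip_label %in% cs$tree$tip.label
      res <- expandPhylogeny(cs$tree, tax$tipTable[keep, ], cs$query,
                             tax$db)
      pl <- res@placements
      err <- abs(pl$pendant_length[1L] - cs$pendant)
      maxErr <- max(maxErr, err)
      # Realized node: MRCA of the congeners in the expanded tree must be
      # the grafted tip's parent.
      lab <- pl$tip_label[1L]
      tipIdx <- match(lab, res@tree$tip.label)
      parent <- res@tree$edge[res@tree$edge[, 2L] == tipIdx, 1L]
      expNode <- mrcaNode(res@tree, cs$congeners)
      if (pl$status[1L] == "inserted" && pl$mapping_rank[1L] == "genus" &&
          parent == expNode && err <= tol)
        nExact <- nExact + 1L
    }
  }
  list(nExact = nExact, n = n, maxPendantError = maxErr)
}

#' Type-I error calibration of the PERMANOVA permutation schemes
#'
#' Simulates communities with no group structure and no phylogenetic
#' structure relative to the groups, assigns random group labels, and
#' measures the rejection rate at alpha = 0.05 of either the
#' free-permutation test (on weighted Bray-Curtis) or the tip-shuffle test
#' (on weighted UniFrac).
#'
#' @param nReplicates Number of simulated datasets (default 500).
#' @param mode `"free"` or `"tipshuffle"`.
#' @param nPerm Permutations per test (default 199).
#' @param nSamples,nSpecies Dataset shape per replicate.
#' @param seed Master seed.
#' @return List: `rate` (rejection rate), `n`, `pvalues`.
#' @export
typeIErrorStudy <- function(nReplicates = 500L, mode = c("free", "tipshuffle"),
                            nPerm = 199L, nSamples = 12L, nSpecies = 32L,
                            seed = 1L) {
  mode <- match.arg(mode)
  seeds <- childSeeds(seed, nReplicates * 2L)
  p <- numeric(nReplicates)
  for (r in seq_len(nReplicates)) {
    spec <- simSpec(nSpecies = nSpecies, nSamples = nSamples,
                    structure = "random", richness = 6L,
                    nGroups = 2L, seed = seeds[r])
    tree <- simulateTree(spec)
    tab <- simulateCommunities(tree, spec)
    groups <- sampleGroups(tab)
    p[r] <- if (mode == "free") {
      d <- betaDistanceMatrix(tab, metric = "bray_curtis", weighted = TRUE)
      pseudoF(permanovaFreeTest(d, groups, nPerm = nPerm,
                                seed = seeds[nReplicates + r]))["p"]
    } else {
      pseudoF(permanovaTipShuffleTest(tree, tab, groups, weighted = TRUE,
                                      nPerm = nPerm,
                                      seed = seeds[nReplicates + r]))["p"]
    }
  }
  list(rate = mean(p <= 0.05), n = nReplicates, pvalues = p)
}

#' Dispersion-detection study on clustered vs random communities
#'
#' Simulates one structured tree and a set of communities that are either
#' clade-restricted (clustered) or assembled uniformly at random, runs the
#' tip-shuffling dispersion test on every sample, and reports the fraction
#' called under-dispersed at the 5% percentile.
#'
#' @param structure `"clustered"` or `"random"`.
#' @param nSamples Number of samples (default 20).
#' @param nPerm Shuffles per test (default 999).
#' @param metric Dispersion metric (default weighted MPD).
#' @param seed Master seed.
#' @return List: `fracUnderDispersed`, `n`, `calls`.
#' @export
dispersionDetectionStudy <- function(structure = c("clustered", "random"),
                                     nSamples = 20L, nPerm = 999L,
                                     metric = "weighted_mpd", seed = 1L) {
  structure <- match.arg(structure)
  spec <- simSpec(nSamples = nSamples, structure = structure,
                  richness = 4L, seed = seed)
  tree <- simulateTree(spec)
  tax <- simulateTaxonomy(tree, spec)
  tab <- simulateCommunities(tree, spec, tax)
  m <- tab@counts
  meta <- colnames(m)[colSums(m) > 0]
  seeds <- childSeeds(seed + 1L, nrow(m))
  calls <- character(nrow(m))
  for (i in seq_len(nrow(m))) {
    cnt <- m[i, m[i, ] > 0]
    res <- alphaDispersionTest(tree, cnt, metric = metric,
                               metacommunity = meta, nPerm = nPerm,
                               seed = seeds[i])
    calls[i] <- res@call
  }
  list(fracUnderDispersed = mean(calls == "under-dispersed"),
       n = nrow(m), calls = calls)
}
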