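# Synthetic data: taxonomy-congruent trees, toy taxdumps, structured
# community matrices, and leave-one-out grafting cases.  These emulate the
# shapes of real classifier + reference-tree data so the grafting rule and
# the null-model statistics can be validated against known ground truth.

#' Simulation specification
#'
#' @param nSpecies Number of species (tips); default the product of
#'   `fanout`.
#' @param fanout Named integer vector: children per parent at each rank,
#'   top-down (`phylum` = number of phyla).  The product bounds the number
#'   of genera; species are distributed over genera as evenly as possible.
#' @param branchScale Mean of the exponential branch-length distribution
#'   for within-genus edges.
#' @param depthScaling Factor by which the branch-length scale grows per
#'   rank level above genus (default 2), so that genera are shallow
#'   relative to between-clade divergence, as in real reference
#'   phylogenies.
#' @param nSamples Number of community samples.
#' @param structure `"clustered"` (each sample drawn from one clade) or
#'   `"random"` (species drawn uniformly).
#' @param cladeLevel Rank of the clade pool for clustered sampling
#'   (`"genus"` or `"family"`).
#' @param richness Species per sample.
#' @param abundanceSigma Log-normal shape of the per-species counts.
#' @param abundanceMeanlog Log-normal location (default `log(200)` reads).
#' @param nGroups Number of sample groups.
#' @param groupByClade In clustered mode, samples of the same group draw
#'   from the same clade (default `FALSE`).
#' @param seed Master seed for all generators.
#' @return A list of class `simSpec`.
#' @export
simSpec <- function(nSpecies = NULL,
                    fanout = c(phylum = 2L, class = 1L, order = 1L,
                               family = 2L, genus = 2L),
                    branchScale = 0.5, depthScaling = 2,
                    nSamples = 20L,
                    structure = c("clustered", "random"),
                    cladeLevel = c("genus", "family"), richness = 4L,
                    abundanceSigma = 1, abundanceMeanlog = log(200),
                    nGroups = 2L, groupByClade = FALSE, seed = 1L) {
  structure <- match.arg(structure)
  cladeLevel <- match.arg(cladeLevel)
  nGenera <- prod(fanout)
  speciesPerGenus <- 4L
  nSpecies <- nSpecies %||% (nGenera * speciesPerGenus)
  if (nSpecies < nGenera)
    stop("fanout product exceeds nSpecies", call. = FALSE)
  stopifnot(branchScale > 0, depthScaling >= 1, abundanceSigma > 0,
            richness >= 1L)
  structure(list(nSpecies = as.integer(nSpecies), fanout = fanout,
                 branchScale = branchScale, depthScaling = depthScaling,
                 nSamples = as.integer(nSamples),
                 structure = structure, cladeLevel = cladeLevel,
                 richness = as.integer(richness),
                 abundanceSigma = abundanceSigma,
                 abundanceMeanlog = abundanceMeanlog,
                 nGroups = as.integer(nGroups),
                 groupByClade = isTRUE(groupByClade),
                 seed = as.integer(seed)),
            class = "simSpec")
}

# Random bifurcating join of a list of newick fragments (no trailing ";").
.joinRand <- function(parts, scale) {
  while (length(parts) > 1L) {
    i <- sample.int(length(parts), 2L)
    merged <- sprintf("(%s:%s,%s:%s)", parts[[i[1L]]],
                      .fmtLen(rexp(1, 1 / scale)), parts[[i[2L]]],
                      .fmtLen(rexp(1, 1 / scale)))
    parts <- c(parts[-i], merged)
  }
  parts[[1L]]
}

#' Simulate a rooted bifurcating tree with taxonomically nested clades
#'
#' Species are organized into genera, families, orders, classes and phyla
#' per `spec$fanout`; each taxon's subtree is assembled by random
#' bifurcating joins with exponential branch lengths, so every taxon is
#' monophyletic by construction.  Tip labels are `t001, t002, ...`.
#'
#' @param spec A [simSpec()] object.
#' @return An `ape::phylo` tree, deterministic under `spec$seed`.
#' @export
simulateTree <- function(spec) {
  stopifnot(inherits(spec, "simSpec"), spec$nSpecies >= 2L)
  withSeed(spec$seed, {
    fo <- spec$fanout
    nGenera <- prod(fo)
    sizes <- rep(spec$nSpecies %/% nGenera, nGenera)
    extra <- spec$nSpecies %% nGenera
    if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
    labs <- sprintf("t%03d", seq_len(spec$nSpecies))
    tipIdx <- split(seq_len(spec$nSpecies),
                    rep(seq_len(nGenera), times = sizes))
    scale <- spec$branchScale
    parts <- lapply(tipIdx, function(ix) {
      if (length(ix) == 1L) labs[ix] else .joinRand(as.list(labs[ix]),
                                                    scale)
    })
    # Fold genera into families, families into orders, ... per fanout
    # (children-per-parent counts, bottom-up).  The branch-length scale
    # grows with each level, keeping low ranks shallow and high ranks
    # deep, as in real reference phylogenies.
    for (f in rev(fo[-1L])) {
      scale <- scale * spec$depthScaling
      grp <- rep(seq_len(ceiling(length(parts) / f)), each = f,
                 length.out = length(parts))
      parts <- lapply(split(parts, grp), function(p)
        if (length(p) == 1L) p[[1L]] else .joinRand(p, scale))
    }
    top <- if (length(parts) == 1L) parts[[1L]]
           else .joinRand(parts, scale * spec$depthScaling)
    parseNewick(paste0(top, ";"))
  })
}

# Partition a clade's tips (index vector) into k monophyletic parts by
# repeatedly splitting the largest part at its MRCA.
.splitClade <- function(tree, tipsUnder, tips, k) {
  parts <- list(tips)
  while (length(parts) < k) {
    sizes <- lengths(parts)
    cand <- which(sizes >= 2L)
    if (!length(cand)) stop("fanout infeasible for tip count", call. = FALSE)
    i <- cand[which.max(sizes[cand])]
    node <- if (length(parts[[i]]) == 1L) parts[[i]]
            else ape::getMRCA(tree, parts[[i]])
    kids <- tree$edge[tree$edge[, 1L] == node, 2L]
    sub <- lapply(kids, function(ch) intersect(tipsUnder[[ch]], parts[[i]]))
    sub <- sub[lengths(sub) > 0L]
    parts <- c(parts[-i], sub)
  }
  parts
}

#' Derive a taxonomy congruent with a tree
#'
#' Partitions the tree's tips into nested monophyletic clades (phyla down to
#' genera, clade counts following `spec$fanout`) and assigns fresh taxids,
#' yielding a toy NCBI-style taxonomy in which every taxon of every rank is
#' exactly one clade.  Optionally swaps two tips' taxids to create
#' deliberate tree/taxonomy incongruence for stress-testing the outlier
#' filter.
#'
#' @param tree An `ape::phylo` tree (typically from [simulateTree()]).
#' @param spec A [simSpec()] object.
#' @param swapTips Number of tip pairs whose species taxids are swapped
#'   (default 0).
#' @return A list: `db` ([TaxonomyDB-class]), `tipTable` (data.frame
#'   `tip_label`, `taxid`).
#' @export
simulateTaxonomy <- function(tree, spec, swapTips = 0L) {
  ranks <- c("phylum", "class", "order", "family", "genus")
  fo <- spec$fanout[ranks]
  nt <- ape::Ntip(tree)
  tu <- .tipsUnderList(tree)
  withSeed(spec$seed + 1L, {
    nodes <- data.frame(taxid = c(1L, 2L), parent = c(1L, 1L),
                        rank = c("no rank", "superkingdom"),
                        name = c("root", "Bacteria"),
                        stringsAsFactors = FALSE)
    nextId <- 10L
    # level[[r]]: list of (tips, taxid) at rank r; start from superkingdom.
    parents <- list(list(tips = seq_len(nt), taxid = 2L))
    counters <- c(phylum = 0L, class = 0L, order = 0L, family = 0L,
                  genus = 0L)
    for (r in ranks) {
      children <- list()
      for (p in parents) {
        parts <- .splitClade(tree, tu, p$tips, min(fo[[r]], length(p$tips)))
        for (tipSet in parts) {
          counters[r] <- counters[r] + 1L
          nodes <- rbind(nodes, data.frame(
            taxid = nextId, parent = p$taxid, rank = r,
            name = sprintf("%s%d", substr(r, 1L, 1L), counters[r]),
            stringsAsFactors = FALSE))
          children[[length(children) + 1L]] <- list(tips = tipSet,
                                                    taxid = nextId)
          nextId <- nextId + 1L
        }
      }
      parents <- children
    }
    spTaxid <- integer(nt)
    for (g in parents) {
      for (tip in g$tips) {
        nodes <- rbind(nodes, data.frame(
          taxid = nextId, parent = g$taxid, rank = "species",
          name = sprintf("%s sp%03d", nodes$name[nodes$taxid == g$taxid],
                         tip),
          stringsAsFactors = FALSE))
        spTaxid[tip] <- nextId
        nextId <- nextId + 1L
      }
    }
    if (swapTips > 0L) {
      for (s in seq_len(swapTips)) {
        pr <- sample.int(nt, 2L)
        spTaxid[pr] <- spTaxid[rev(pr)]
      }
    }
    list(db = taxonomyDB(nodes),
         tipTable = data.frame(tip_label = tree$tip.label, taxid = spTaxid,
                               stringsAsFactors = FALSE))
  })
}

# Clade pool (list of tip-label vectors) at a rank, from a taxonomy or by
# re-partitioning the tree.
.cladePool <- function(tree, spec, taxonomy) {
  if (!is.null(taxonomy)) {
    db <- taxonomy$db; tt <- taxonomy$tipTable
    rk <- vapply(tt$taxid, function(x)
      unname(canonicalLineage(db, x)[spec$cladeLevel]), integer(1))
    return(split(tt$tip_label, rk))
  }
  fo <- spec$fanout[c("phylum", "class", "order", "family", "genus")]
  upto <- switch(spec$cladeLevel, genus = 5L, family = 4L)
  k <- prod(fo[seq_len(upto)])
  tu <- .tipsUnderList(tree)
  parts <- .splitClade(tree, tu, seq_len(ape::Ntip(tree)), k)
  lapply(parts, function(ix) tree$tip.label[ix])
}

#' Simulate structured community samples on a tree
#'
#' Clustered mode draws each sample's species from one monophyletic clade
#' (genus or family), emulating phylogenetically under-dispersed
#' communities; random mode draws species uniformly from all tips.  Counts
#' are log-normal, emulating the dominance patterns of real metagenomic
#' communities.
#'
#' @param tree An `ape::phylo` tree.
#' @param spec A [simSpec()] object.
#' @param taxonomy Optional result of [simulateTaxonomy()]; without it,
#'   clustered mode re-derives clades from the tree topology.
#' @return A [CommunityTable-class]; species columns are tip labels, groups
#'   `g1..gK`.
#' @export
simulateCommunities <- function(tree, spec, taxonomy = NULL) {
  withSeed(spec$seed + 2L, {
    clades <- if (spec$structure == "clustered")
      .cladePool(tree, spec, taxonomy) else NULL
    samples <- sprintf("s%02d", seq_len(spec$nSamples))
    groups <- sprintf("g%d", rep_len(seq_len(spec$nGroups), spec$nSamples))
    names(groups) <- samples
    rows <- vector("list", spec$nSamples)
    for (i in seq_len(spec$nSamples)) {
      if (spec$structure == "clustered") {
        pool <- if (spec$groupByClade)
          clades[[1L + (rep_len(seq_len(spec$nGroups),
                                spec$nSamples)[i] - 1L) %% length(clades)]]
        else clades[[sample.int(length(clades), 1L)]]
        if (length(pool) < spec$richness)
          stop(sprintf("clade of size %d smaller than richness %d",
                       length(pool), spec$richness), call. = FALSE)
        sp <- sample(pool, spec$richness)
      } else {
        sp <- sample(tree$tip.label, spec$richness)
      }
      cnt <- pmax(1, round(rlnorm(spec$richness, spec$abundanceMeanlog,
                                  spec$abundanceSigma)))
      v <- as.integer(cnt)
      names(v) <- sp
      rows[[i]] <- v
    }
    names(rows) <- samples
    communityTable(rows, groups)
  })
}

#' Leave-one-out grafting cases for placement validation
#'
#' Samples tips whose genus retains at least two other species, removes each
#' from the tree, and records the expected re-graft position: the MRCA of
#' the remaining congeners in the pruned tree, with pendant length equal to
#' their mean distance from that node.
#'
#' @param tree An `ape::phylo` tree.
#' @param tipTable Tip -> species taxid table (from [simulateTaxonomy()]).
#' @param db A [TaxonomyDB-class] for genus lookup.
#' @param nCases Number of cases (tips sampled with replacement).
#' @param seed Integer seed.
#' @return List of cases: `tree` (pruned), `query` (species taxid),
#'   `congeners` (labels), `node` (expected insertion node in the pruned
#'   tree), `pendant` (expected pendant length).
#' @export
leaveOneOutCases <- function(tree, tipTable, db, nCases, seed) {
  genus <- vapply(tipTable$taxid, function(x)
    unname(canonicalLineage(db, x)["genus"]), integer(1))
  sizes <- table(genus)
  eligible <- which(genus %in% as.integer(names(sizes)[sizes >= 3L]))
  if (!length(eligible))
    stop("no tip with >= 2 congeners", call. = FALSE)
  withSeed(seed, {
    picks <- sample(eligible, nCases, replace = TRUE)
    lapply(picks, function(i) {
      lab <- tipTable$tip_label[i]
      congeners <- tipTable$tip_label[genus == genus[i] &
                                        tipTable$tip_label != lab]
      pruned <- ape::drop.tip(tree, lab)
      pruned$root.edge <- NULL
      node <- mrcaNode(pruned, congeners)
      pendant <- mean(distancesFromNode(pruned, node, congeners))
      list(tree = pruned, query = tipTable$taxid[i], congeners = congeners,
           node = node, pendant = pendant)
    })
  })
}
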