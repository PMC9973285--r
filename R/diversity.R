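# Alpha and beta diversity: species-based metrics (via vegan), Faith's PD
# and its abundance-weighted extension, (weighted) mean pairwise distance,
# Bray-Curtis and UniFrac dissimilarities.

.alignCounts <- function(counts) {
  if (is.null(names(counts))) stop("counts must be named by species",
                                   call. = FALSE)
  counts <- counts[counts > 0]
  if (sum(counts) <= 0) stop("zero total count", call. = FALSE)
  counts
}

.congruence <- function(tree, species) {
  miss <- setdiff(species, tree$tip.label)
  if (length(miss))
    stop(sprintf("species missing from tree: %s",
                 paste(head(miss, 10L), collapse = ", ")), call. = FALSE)
}

#' Species-based alpha diversity of one sample
#'
#' Richness is the number of species with positive count, Shannon uses the
#' natural logarithm, and Simpson is reported in complement form
#' (1 - sum p_i^2).
#'
#' @param counts Non-negative numeric vector of species counts.
#' @return Named numeric vector `richness`, `shannon`, `simpson`.
#' @export
alphaSpeciesMetrics <- function(counts) {
  counts <- counts[counts > 0]
  if (sum(counts) <= 0) stop("zero total count", call. = FALSE)
  c(richness = sum(counts > 0),
    shannon = unname(vegan::diversity(counts, index = "shannon")),
    simpson = unname(vegan::diversity(counts, index = "simpson")))
}

#' Faith's phylogenetic diversity
#'
#' Total branch length of the subtree spanning the present species (the
#' edge above the spanning subtree's root excluded).  A single species has
#' PD 0.
#'
#' @param tree An `ape::phylo` tree.
#' @param present Character vector of present tip labels.
#' @return Branch-length units.
#' @export
faithPD <- function(tree, present) {
  present <- unique(present)
  .congruence(tree, present)
  if (length(present) < 2L) return(0)
  totalBranchLength(spanningSubtree(tree, present))
}

# Core weighted-Faith computation on a spanning subtree: abundances aligned
# to sub$tip.label.
.weightedFaithCore <- function(sub, ab) {
  B <- .edgeTipMatrix(sub)
  abar <- as.vector(B %*% ab) / rowSums(B)
  nrow(B) * sum(sub$edge.length * abar) / sum(abar)
}

#' Abundance-weighted Faith's phylogenetic diversity
#'
#' On the spanning subtree of the present species with `E` edges,
#' `PDw = E * sum_b(l_b * Abar_b) / sum_b(Abar_b)`, where `Abar_b` is the
#' mean abundance over the tips descending from edge `b`.  Under equal
#' abundances this reduces exactly to Faith's PD.
#'
#' @param tree An `ape::phylo` tree.
#' @param counts Named non-negative vector of species counts (names are tip
#'   labels); total must be positive.
#' @return Branch-length units (0 for a single-species community).
#' @export
weightedFaith <- function(tree, counts) {
  counts <- .alignCounts(counts)
  .congruence(tree, names(counts))
  if (length(counts) < 2L) return(0)
  sub <- spanningSubtree(tree, names(counts))
  .weightedFaithCore(sub, counts[sub$tip.label])
}

#' Mean pairwise phylogenetic distance
#'
#' Weighted form: `sum_{i<j} d_ij a_i a_j / sum_{i<j} a_i a_j` over distinct
#' present species pairs; unweighted form is the plain mean of the pairwise
#' patristic distances.
#'
#' @param tree An `ape::phylo` tree.
#' @param counts Named non-negative vector of species counts.
#' @param weighted Use abundance weighting (default `TRUE`).
#' @return Branch-length units.
#' @export
meanPairwiseDist <- function(tree, counts, weighted = TRUE) {
  counts <- .alignCounts(counts)
  if (length(counts) < 2L)
    stop("mean pairwise distance needs at least 2 species", call. = FALSE)
  .congruence(tree, names(counts))
  D <- patristicMatrix(tree, names(counts))
  a <- if (weighted) as.numeric(counts) else rep(1, length(counts))
  num <- as.numeric(a %*% D %*% a) / 2
  den <- (sum(a)^2 - sum(a^2)) / 2
  num / den
}

#' Bray-Curtis dissimilarity between two samples
#'
#' Weighted: `sum |x_i - y_i| / sum (x_i + y_i)`; unweighted applies the
#' same formula to presence/absence indicators.
#'
#' @param x,y Named non-negative count vectors over the same species
#'   universe (names aligned by union; absences are 0).
#' @param weighted Use abundances (default `TRUE`).
#' @return Dissimilarity in `[0, 1]`.
#' @export
brayCurtis <- function(x, y, weighted = TRUE) {
  if (sum(x) <= 0 || sum(y) <= 0) stop("zero-total sample", call. = FALSE)
  sp <- union(names(x), names(y))
  xv <- numeric(length(sp)); names(xv) <- sp; xv[names(x)] <- x
  yv <- numeric(length(sp)); names(yv) <- sp; yv[names(y)] <- y
  if (!weighted) { xv <- as.numeric(xv > 0); yv <- as.numeric(yv > 0) }
  sum(abs(xv - yv)) / sum(xv + yv)
}

# UniFrac core on precomputed edge geometry.  B: edges x tips logical
# (column order = tip order); len: edge lengths; mat: samples x tips counts
# aligned to B's columns; tipPerm: optional permutation of tip positions
# (tip-label shuffle).  Returns a dense samples x samples matrix.
.unifracCore <- function(B, len, mat, weighted, normalized = FALSE,
                         tipPerm = NULL) {
  if (!is.null(tipPerm)) mat <- mat[, tipPerm, drop = FALSE]
  tot <- rowSums(mat)
  if (weighted) {
    P <- B %*% t(mat / tot)                    # edges x samples
    W <- t(P * len)                            # samples x edges
    d <- as.matrix(dist(W, method = "manhattan"))
    if (normalized) {
      s <- rowSums(W)
      d <- d / outer(s, s, "+")
      d[outer(s, s, "+") == 0] <- 0
    }
  } else {
    I <- (B %*% t(mat > 0)) > 0                # edges x samples
    WI <- t(I * len)                           # samples x edges
    s <- rowSums(WI)
    andM <- WI %*% I                           # shared branch length
    either <- outer(s, s, "+") - andM
    uniq <- outer(s, s, "+") - 2 * andM
    d <- ifelse(either > 0, uniq / either, 0)
  }
  diag(d) <- 0
  rownames(d) <- colnames(d) <- rownames(mat)
  d
}

#' UniFrac distance between two samples
#'
#' Edge-wise over the tree, with `P_b(s)` the proportion of sample `s`'s
#' total count on tips below edge `b`.  Weighted (default non-normalized):
#' `sum_b l_b |P_b(x) - P_b(y)|`, optionally divided by
#' `sum_b l_b (P_b(x) + P_b(y))`.  Unweighted: branch length unique to one
#' sample over branch length covered by either.
#'
#' @param tree An `ape::phylo` tree containing all present species.
#' @param x,y Named non-negative count vectors.
#' @param weighted Abundance-weighted variant (default `TRUE`).
#' @param normalized Normalize the weighted variant into `[0, 1]` (default
#'   `FALSE`).
#' @return The dissimilarity.
#' @export
uniFrac <- function(tree, x, y, weighted = TRUE, normalized = FALSE) {
  x <- .alignCounts(x); y <- .alignCounts(y)
  .congruence(tree, union(names(x), names(y)))
  mat <- communityTable(list(x = x, y = y))@counts
  full <- matrix(0, 2L, ape::Ntip(tree),
                 dimnames = list(rownames(mat), tree$tip.label))
  full[, colnames(mat)] <- mat
  B <- .edgeTipMatrix(tree)
  d <- .unifracCore(B, tree$edge.length, full, weighted, normalized)
  d["x", "y"]
}

#' Pairwise beta-diversity distance matrix for a community table
#'
#' @param table A [CommunityTable-class] object.
#' @param tree An `ape::phylo` tree (required for UniFrac; ignored for
#'   Bray-Curtis).
#' @param metric `"bray_curtis"` or `"unifrac"`.
#' @param weighted Abundance-weighted variant (default `TRUE`).
#' @param normalized Normalize weighted UniFrac (default `FALSE`).
#' @return A `dist` object with attributes `metric`, `weighted`,
#'   `normalized`.
#' @export
betaDistanceMatrix <- function(table, tree = NULL,
                               metric = c("bray_curtis", "unifrac"),
                               weighted = TRUE, normalized = FALSE) {
  metric <- match.arg(metric)
  m <- table@counts
  if (any(rowSums(m) <= 0)) stop("zero-total sample in table", call. = FALSE)
  if (metric == "bray_curtis") {
    d <- vegan::vegdist(if (weighted) m else (m > 0) * 1, method = "bray")
  } else {
    if (is.null(tree)) stop("UniFrac requires a tree", call. = FALSE)
    .congruence(tree, colnames(m)[colSums(m) > 0])
    full <- matrix(0, nrow(m), ape::Ntip(tree),
                   dimnames = list(rownames(m), tree$tip.label))
    keep <- intersect(colnames(m), tree$tip.label)
    full[, keep] <- m[, keep]
    B <- .edgeTipMatrix(tree)
    d <- as.dist(.unifracCore(B, tree$edge.length, full, weighted,
                              normalized))
  }
  attr(d, "metric") <- metric
  attr(d, "weighted") <- weighted
  attr(d, "normalized") <- normalized
  d
}

#' Per-sample alpha diversity table
#'
#' Species-based metrics always; phylogeny-based metrics (Faith's PD,
#' weighted Faith, MPD, weighted MPD) when a tree is supplied.  MPD is `NA`
#' for single-species samples.
#'
#' @param table A [CommunityTable-class] object.
#' @param tree Optional `ape::phylo` tree covering all species in `table`.
#' @return data.frame with one row per sample.
#' @export
alphaDiversity <- function(table, tree = NULL) {
  m <- table@counts
  out <- data.frame(sample = rownames(m),
                    t(apply(m, 1L, alphaSpeciesMetrics)),
                    stringsAsFactors = FALSE)
  if (!is.null(tree)) {
    .congruence(tree, colnames(m)[colSums(m) > 0])
    pd <- wf <- mp <- wmp <- rep(NA_real_, nrow(m))
    for (i in seq_len(nrow(m))) {
      cnt <- m[i, ]
      cnt <- cnt[cnt > 0]
      pd[i] <- faithPD(tree, names(cnt))
      wf[i] <- weightedFaith(tree, cnt)
      if (length(cnt) >= 2L) {
        mp[i] <- meanPairwiseDist(tree, cnt, weighted = FALSE)
        wmp[i] <- meanPairwiseDist(tree, cnt, weighted = TRUE)
      }
    }
    out$faith_pd <- pd; out$weighted_faith <- wf
    out$mpd <- mp; out$weighted_mpd <- wmp
  }
  rownames(out) <- NULL
  out
}
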