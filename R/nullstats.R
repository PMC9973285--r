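# Tip-shuffling null models, alpha dispersion tests, PERMANOVA under free
# and tip-shuffle permutation schemes, and Holm-adjusted post hoc tests.

#' NullTestResult: a permutation test outcome
#'
#' @slot observed Observed statistic.
#' @slot nullValues Permuted statistics (length `nPerm`).
#' @slot percentile Lower-tail percentile `(#null <= observed + 1) /
#'   (nPerm + 1)`.
#' @slot call `"under-dispersed"`, `"over-dispersed"` or
#'   `"not-significant"`.
#' @slot metric Metric name.
#' @slot seed Master seed used.
#' @export
setClass("NullTestResult",
         representation(observed = "numeric", nullValues = "numeric",
                        percentile = "numeric", call = "character",
                        metric = "character", seed = "integer"))

setValidity("NullTestResult", function(object) {
  if (length(object@nullValues) < 1L) return("need at least 1 permutation")
  if (object@percentile <= 0 || object@percentile > 1)
    return("percentile must lie in (0, 1]")
  TRUE
})

setMethod("show", "NullTestResult", function(object) {
  cat(sprintf("NullTestResult (%s): observed %.6g, %d permutations\n",
              object@metric, object@observed, length(object@nullValues)))
  cat(sprintf("  lower-tail percentile %.4g -> %s\n", object@percentile,
              object@call))
})

#' PermanovaResult: a PERMANOVA table
#'
#' @slot table data.frame with rows Among/Residual/Total and columns `Df`,
#'   `SumOfSqs`, `MeanSqs`, `F`, `R2`, `p`.
#' @slot mode `"none"`, `"free"` or `"tipshuffle"`.
#' @slot nullF Permuted pseudo-F values (empty when `mode = "none"`).
#' @slot nPerm Number of permutations.
#' @slot seed Master seed used.
#' @export
setClass("PermanovaResult",
         representation(table = "data.frame", mode = "character",
                        nullF = "numeric", nPerm = "integer",
                        seed = "integer"))

setValidity("PermanovaResult", function(object) {
  tb <- object@table
  if (abs(tb$SumOfSqs[1L] + tb$SumOfSqs[2L] - tb$SumOfSqs[3L]) > 1e-9 *
      max(1, tb$SumOfSqs[3L]))
    return("sums of squares do not add up")
  r2 <- tb$R2[1L]
  # non-Euclidean dissimilarities can give a slightly negative among-group
  # sum of squares under the null; only the upper bound is structural
  if (!is.na(r2) && r2 > 1 + 1e-12) return("R2 above 1")
  TRUE
})

setMethod("show", "PermanovaResult", function(object) {
  cat(sprintf("PERMANOVA (%s permutation%s)\n", object@mode,
              if (object@mode == "none") "" else
                sprintf(", n = %d", object@nPerm)))
  print(format(object@table, digits = 5))
})

#' Pseudo-F accessor
#' @param x A [PermanovaResult-class] object.
#' @return Named numeric vector `F`, `R2`, `p`.
#' @export
setGeneric("pseudoF", function(x) standardGeneric("pseudoF"))

#' @rdname pseudoF
setMethod("pseudoF", "PermanovaResult", function(x) {
  c(F = x@table$F[1L], R2 = x@table$R2[1L], p = x@table$p[1L])
})

#' Shuffle tip labels within a subset
#'
#' Permutes the labels within `subset` uniformly at random (drawing from the
#' current RNG stream); topology and branch lengths are untouched and labels
#' outside the subset stay put.
#'
#' @param tree An `ape::phylo` tree.
#' @param subset Tip labels to shuffle among themselves; default all tips.
#' @return The relabeled tree.
#' @export
shuffleTipLabels <- function(tree, subset = tree$tip.label) {
  idx <- .checkTips(tree, subset)
  tree$tip.label[idx] <- tree$tip.label[idx[sample.int(length(idx))]]
  tree
}

# Internal dispatcher computing one alpha metric from a position-aligned
# abundance vector (zeros = absent) on a fixed tree; D is the full
# patristic matrix for metric "weighted_mpd".
.alphaMetricAt <- function(tree, ab, metric, D = NULL) {
  present <- which(ab > 0)
  if (metric == "weighted_mpd") {
    a <- ab[present]
    Dp <- D[present, present, drop = FALSE]
    num <- as.numeric(a %*% Dp %*% a) / 2
    den <- (sum(a)^2 - sum(a^2)) / 2
    return(num / den)
  }
  sub <- spanningSubtree(tree, tree$tip.label[present])
  .weightedFaithCore(sub, ab[match(sub$tip.label, tree$tip.label)])
}

#' Tip-shuffling dispersion test for one community
#'
#' The tree is pruned to the metacommunity, the observed phylogeny-based
#' metric is computed, and each permutation shuffles the metacommunity tip
#' labels and recomputes the metric.  The lower-tail percentile
#' `(#null <= observed + 1)/(nPerm + 1)` at or below 5% is called
#' under-dispersed (phylogenetic clustering); the upper tail at or below 5%
#' over-dispersed.
#'
#' @param tree An `ape::phylo` tree.
#' @param counts Named non-negative species counts (one sample); at least
#'   two present species.
#' @param metric `"weighted_mpd"` or `"weighted_faith"`.
#' @param metacommunity Species pool whose labels are shuffled; must contain
#'   all present species.  Default: every tip of `tree`.
#' @param nPerm Number of shuffles (default 999).
#' @param seed Master seed; per-permutation child seeds are derived from it.
#' @return A [NullTestResult-class] object.
#' @export
alphaDispersionTest <- function(tree, counts,
                                metric = c("weighted_mpd", "weighted_faith"),
                                metacommunity = NULL, nPerm = 999,
                                seed = NULL) {
  metric <- match.arg(metric)
  counts <- .alignCounts(counts)
  metacommunity <- metacommunity %||% tree$tip.label
  extra <- setdiff(names(counts), metacommunity)
  if (length(extra))
    stop(sprintf("metacommunity does not contain present species: %s",
                 paste(head(extra, 5L), collapse = ", ")), call. = FALSE)
  .congruence(tree, metacommunity)
  pool <- spanningSubtree(tree, metacommunity)
  nt <- ape::Ntip(pool)
  ab <- numeric(nt)
  ab[match(names(counts), pool$tip.label)] <- counts
  D <- if (metric == "weighted_mpd") patristicMatrix(pool) else NULL
  if (!is.null(D)) D <- D[pool$tip.label, pool$tip.label]
  observed <- .alphaMetricAt(pool, ab, metric, D)
  seeds <- childSeeds(seed %||% sample.int(1e9, 1L), nPerm)
  nulls <- vapply(seq_len(nPerm), function(k) {
    perm <- withSeed(seeds[k], sample.int(nt))
    .alphaMetricAt(pool, ab[perm], metric, D)
  }, numeric(1))
  # ties between null and observed values must count as ties even when the
  # permuted arithmetic reorders floating-point sums
  eps <- 1e-9 * (abs(observed) + 1)
  perc <- (sum(nulls <= observed + eps) + 1) / (nPerm + 1)
  upper <- (sum(nulls >= observed - eps) + 1) / (nPerm + 1)
  call <- if (perc <= 0.05) "under-dispersed"
          else if (upper <= 0.05) "over-dispersed" else "not-significant"
  new("NullTestResult", observed = observed, nullValues = nulls,
      percentile = perc, call = call, metric = metric,
      seed = as.integer(seed %||% NA_integer_))
}

# groups -> list of index vectors; validates group sizes.
.groupIndex <- function(groups, n) {
  g <- as.character(groups)
  if (length(g) != n) stop("groups length must match samples", call. = FALSE)
  idx <- split(seq_len(n), g)
  if (length(idx) < 2L) stop("need at least 2 groups", call. = FALSE)
  sizes <- lengths(idx)
  if (any(sizes < 2L))
    stop(sprintf("singleton group(s): %s",
                 paste(names(idx)[sizes < 2L], collapse = ", ")),
         call. = FALSE)
  idx
}

# Fast pseudo-F from a dense squared-distance matrix and group index list.
.pseudoFFromD2 <- function(D2, idx, N) {
  k <- length(idx)
  ssT <- sum(D2) / (2 * N)
  ssW <- sum(vapply(idx, function(i)
    sum(D2[i, i]) / (2 * length(i)), numeric(1)))
  ssA <- ssT - ssW
  Fv <- (ssA / (k - 1)) / (ssW / (N - k))
  c(ssT = ssT, ssW = ssW, ssA = ssA, F = Fv)
}

.permanovaTable <- function(stats, k, N, p = NA_real_) {
  if (!is.finite(stats["F"]))
    warning("zero residual sum of squares; F is infinite")
  data.frame(
    term = c("Among", "Residual", "Total"),
    Df = c(k - 1L, N - k, N - 1L),
    SumOfSqs = c(stats["ssA"], stats["ssW"], stats["ssT"]),
    MeanSqs = c(stats["ssA"] / (k - 1), stats["ssW"] / (N - k), NA),
    F = c(stats["F"], NA, NA),
    R2 = c(stats["ssA"] / stats["ssT"], stats["ssW"] / stats["ssT"], 1),
    p = c(p, NA, NA), row.names = NULL)
}

#' PERMANOVA pseudo-F for a distance matrix (no permutation p-value)
#'
#' `SS_total = (1/N) sum_{i<j} d_ij^2`, `SS_resid` sums the within-group
#' pair terms weighted by `1/n_g`, and
#' `F = (SS_among/(k-1)) / (SS_resid/(N-k))`.
#'
#' @param d A `dist` or symmetric matrix of dissimilarities.
#' @param groups Group labels, one per sample (>= 2 groups, each >= 2
#'   samples).
#' @return A [PermanovaResult-class] with `p = NA`.
#' @export
permanovaF <- function(d, groups) {
  D <- as.matrix(d)
  N <- nrow(D)
  idx <- .groupIndex(groups, N)
  st <- .pseudoFFromD2(D^2, idx, N)
  new("PermanovaResult", table = .permanovaTable(st, length(idx), N),
      mode = "none", nullF = numeric(0), nPerm = 0L, seed = NA_integer_)
}

#' PERMANOVA with free permutation of group labels
#'
#' The distance matrix is fixed; group labels are shuffled across samples.
#' `p = (#{F_perm >= F_obs} + 1)/(nPerm + 1)`.
#'
#' @inheritParams permanovaF
#' @param nPerm Number of permutations (default 999).
#' @param seed Master seed.
#' @return A [PermanovaResult-class] object.
#' @export
permanovaFreeTest <- function(d, groups, nPerm = 999, seed = NULL) {
  D2 <- as.matrix(d)^2
  N <- nrow(D2)
  g <- as.character(groups)
  idx <- .groupIndex(g, N)
  k <- length(idx)
  obs <- .pseudoFFromD2(D2, idx, N)
  seeds <- childSeeds(seed %||% sample.int(1e9, 1L), nPerm)
  nullF <- vapply(seq_len(nPerm), function(j) {
    gp <- withSeed(seeds[j], g[sample.int(N)])
    .pseudoFFromD2(D2, split(seq_len(N), gp), N)["F"]
  }, numeric(1))
  p <- (sum(nullF >= obs["F"] - 1e-9 * (abs(obs["F"]) + 1)) + 1) /
    (nPerm + 1)
  new("PermanovaResult", table = .permanovaTable(obs, k, N, p),
      mode = "free", nullF = unname(nullF), nPerm = as.integer(nPerm),
      seed = as.integer(seed %||% NA_integer_))
}

#' PERMANOVA with tip-shuffle permutation of the phylogeny
#'
#' The observed pseudo-F comes from the UniFrac matrix on the true tree,
#' pruned to the species present anywhere in the table.  Each permutation
#' shuffles the tip labels of that pruned subtree, recomputes the full
#' UniFrac matrix for the same (never permuted) community data and group
#' labels, and recomputes F.  This tests whether the group separation
#' depends on the actual evolutionary relatedness of the community members.
#'
#' @param tree An `ape::phylo` tree covering all species in `table`.
#' @param table A [CommunityTable-class] object.
#' @param groups Group labels; default taken from `table`.
#' @param weighted,normalized UniFrac variant flags.
#' @param nPerm Number of shuffles (default 999).
#' @param seed Master seed.
#' @return A [PermanovaResult-class] object.
#' @export
permanovaTipShuffleTest <- function(tree, table, groups = NULL,
                                    weighted = TRUE, normalized = FALSE,
                                    nPerm = 999, seed = NULL) {
  m <- table@counts
  groups <- groups %||% sampleGroups(table)
  if (!length(groups)) stop("no group labels available", call. = FALSE)
  species <- colnames(m)[colSums(m) > 0]
  .congruence(tree, species)
  sub <- spanningSubtree(tree, species)
  mat <- matrix(0, nrow(m), ape::Ntip(sub),
                dimnames = list(rownames(m), sub$tip.label))
  mat[, species] <- m[, species]
  B <- .edgeTipMatrix(sub)
  len <- sub$edge.length
  N <- nrow(mat)
  idx <- .groupIndex(groups, N)
  k <- length(idx)
  Dobs <- .unifracCore(B, len, mat, weighted, normalized)
  obs <- .pseudoFFromD2(Dobs^2, idx, N)
  nt <- ncol(mat)
  seeds <- childSeeds(seed %||% sample.int(1e9, 1L), nPerm)
  nullF <- vapply(seq_len(nPerm), function(j) {
    perm <- withSeed(seeds[j], sample.int(nt))
    Dp <- .unifracCore(B, len, mat, weighted, normalized, tipPerm = perm)
    .pseudoFFromD2(Dp^2, idx, N)["F"]
  }, numeric(1))
  p <- (sum(nullF >= obs["F"] - 1e-9 * (abs(obs["F"]) + 1)) + 1) /
    (nPerm + 1)
  new("PermanovaResult", table = .permanovaTable(obs, k, N, p),
      mode = "tipshuffle", nullF = unname(nullF), nPerm = as.integer(nPerm),
      seed = as.integer(seed %||% NA_integer_))
}

#' Holm step-down adjustment of p-values
#'
#' @param p Numeric vector of raw p-values in `(0, 1]`.
#' @return Adjusted p-values in input order.
#' @export
holmAdjust <- function(p) {
  if (length(p) == 0L) stop("empty p-value list", call. = FALSE)
  if (any(p <= 0 | p > 1)) stop("p-values must lie in (0, 1]", call. = FALSE)
  p.adjust(p, method = "holm")
}

#' Pairwise post hoc PERMANOVA with Holm adjustment
#'
#' Runs a two-group PERMANOVA on every unordered pair of groups (on the
#' sub-matrix / sub-table of those groups' samples) and adjusts the raw
#' p-values across all pairs with the Holm method.
#'
#' @param x A `dist`/matrix (for `mode = "free"`) or a
#'   [CommunityTable-class] (for `mode = "tipshuffle"`).
#' @param groups Group labels, one per sample; default from the table.
#' @param mode `"free"` or `"tipshuffle"`.
#' @param tree Tree for tip-shuffle mode.
#' @param weighted,normalized UniFrac variant flags (tip-shuffle mode).
#' @param nPerm Permutations per pair (default 999).
#' @param seed Master seed (one child seed per pair).
#' @return data.frame with columns `group1`, `group2`, `F`, `R2`, `p`,
#'   `p_adj`, `significant` (adjusted p <= 0.05).
#' @export
pairwisePermanova <- function(x, groups = NULL, mode = c("free", "tipshuffle"),
                              tree = NULL, weighted = TRUE,
                              normalized = FALSE, nPerm = 999, seed = NULL) {
  mode <- match.arg(mode)
  if (is(x, "CommunityTable")) {
    groups <- groups %||% sampleGroups(x)
    samples <- rownames(x@counts)
  } else {
    samples <- rownames(as.matrix(x))
  }
  g <- as.character(groups)
  lv <- sort(unique(g))
  pairs <- utils::combn(lv, 2L, simplify = FALSE)
  seeds <- childSeeds(seed %||% sample.int(1e9, 1L), length(pairs))
  rows <- lapply(seq_along(pairs), function(i) {
    pr <- pairs[[i]]
    sel <- g %in% pr
    if (mode == "free") {
      Dm <- as.matrix(x)[sel, sel, drop = FALSE]
      res <- permanovaFreeTest(as.dist(Dm), g[sel], nPerm = nPerm,
                               seed = seeds[i])
    } else {
      if (is.null(tree)) stop("tip-shuffle mode requires a tree",
                              call. = FALSE)
      sub <- communityTable(x@counts[sel, , drop = FALSE])
      res <- permanovaTipShuffleTest(tree, sub, groups = g[sel],
                                     weighted = weighted,
                                     normalized = normalized,
                                     nPerm = nPerm, seed = seeds[i])
    }
    st <- pseudoF(res)
    data.frame(group1 = pr[1L], group2 = pr[2L], F = st["F"],
               R2 = st["R2"], p = st["p"], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- holmAdjust(out$p)
  out$significant <- out$p_adj <= 0.05
  rownames(out) <- NULL
  out
}
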