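# Shared fixtures and independent brute-force oracles.

# The four-tip reference tree used throughout: ((A:1,B:1):1,(C:1,D:1):1);
t1 <- function() parseNewick("((A:1,B:1):1,(C:1,D:1):1);")

# Toy taxdump: full seven-rank chain with two genera, three species, one
# strain, one merged id (666 -> 817) and one deleted id (999).
toyTaxdumpLines <- function() {
  nodes <- c(
    "1\t|\t1\t|\tno rank\t|",
    "2\t|\t1\t|\tsuperkingdom\t|",
    "10\t|\t2\t|\tphylum\t|",
    "11\t|\t10\t|\tclass\t|",
    "12\t|\t11\t|\torder\t|",
    "13\t|\t12\t|\tfamily\t|",
    "14\t|\t13\t|\tgenus\t|",
    "817\t|\t14\t|\tspecies\t|",
    "818\t|\t14\t|\tspecies\t|",
    "819\t|\t817\t|\tstrain\t|",
    "20\t|\t13\t|\tgenus\t|",
    "21\t|\t20\t|\tspecies\t|",
    "22\t|\t20\t|\tspecies\t|")
  names <- c(
    "1\t|\troot\t|\t\t|\tscientific name\t|",
    "2\t|\tBacteria\t|\t\t|\tscientific name\t|",
    "10\t|\tp1\t|\t\t|\tscientific name\t|",
    "11\t|\tc1\t|\t\t|\tscientific name\t|",
    "12\t|\to1\t|\t\t|\tscientific name\t|",
    "13\t|\tf1\t|\t\t|\tscientific name\t|",
    "14\t|\tg1\t|\t\t|\tscientific name\t|",
    "817\t|\tg1 spA\t|\t\t|\tscientific name\t|",
    "818\t|\tg1 spB\t|\t\t|\tscientific name\t|",
    "819\t|\tg1 spA strainX\t|\t\t|\tscientific name\t|",
    "20\t|\tg2\t|\t\t|\tscientific name\t|",
    "21\t|\tg2 spC\t|\t\t|\tscientific name\t|",
    "22\t|\tg2 spD\t|\t\t|\tscientific name\t|")
  merged <- "666\t|\t817\t|"
  delnodes <- "999\t|"
  list(nodes = nodes, names = names, merged = merged, delnodes = delnodes)
}

toyTaxdump <- function() {
  tl <- toyTaxdumpLines()
  loadTaxdump(tl$nodes, tl$names, tl$merged, tl$delnodes)
}

# T1 tips mapped to the toy taxonomy: A,B in genus 14; C,D in genus 20.
t1TipTable <- function() {
  data.frame(tip_label = c("A", "B", "C", "D"),
             taxid = c(817L, 818L, 21L, 22L))
}

randTree <- function(n, seed) {
  withr::with_seed(seed, {
    tr <- ape::rtree(n)
    tr$edge.length <- round(tr$edge.length, 6)
    tr
  })
}

# --- independent oracles -------------------------------------------------

# Edge indices on the root-to-tip path of every tip.
.rootPaths <- function(tree) {
  lapply(seq_len(ape::Ntip(tree)), function(tip) {
    path <- integer(0)
    node <- tip
    repeat {
      e <- which(tree$edge[, 2L] == node)
      if (!length(e)) break
      path <- c(path, e)
      node <- tree$edge[e, 1L]
    }
    path
  })
}

# Patristic distances via symmetric differences of root paths.
oraclePatristic <- function(tree) {
  paths <- .rootPaths(tree)
  n <- ape::Ntip(tree)
  D <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    sym <- c(setdiff(paths[[i]], paths[[j]]),
             setdiff(paths[[j]], paths[[i]]))
    D[i, j] <- sum(tree$edge.length[sym])
  }
  D
}

# UniFrac recomputed from scratch: per-edge tip-descendant sets derived
# from root paths, then the edge-wise definitions applied in plain loops.
oracleUniFrac <- function(tree, x, y, weighted, normalized = FALSE) {
  paths <- .rootPaths(tree)
  labs <- tree$tip.label
  xs <- numeric(length(labs)); names(xs) <- labs; xs[names(x)] <- x
  ys <- numeric(length(labs)); names(ys) <- labs; ys[names(y)] <- y
  px <- xs / sum(xs); py <- ys / sum(ys)
  num <- den <- uniq <- either <- 0
  for (e in seq_len(nrow(tree$edge))) {
    under <- which(vapply(paths, function(p) e %in% p, logical(1)))
    Px <- sum(px[under]); Py <- sum(py[under])
    l <- tree$edge.length[e]
    num <- num + l * abs(Px - Py)
    den <- den + l * (Px + Py)
    if (Px > 0 && Py == 0 || Py > 0 && Px == 0) uniq <- uniq + l
    if (Px > 0 || Py > 0) either <- either + l
  }
  if (!weighted) return(uniq / either)
  if (normalized) num / den else num
}

# Pseudo-F straight from the definitional sums over sample pairs.
oraclePermanovaF <- function(D, groups) {
  N <- nrow(D)
  ssT <- 0
  for (i in seq_len(N - 1L)) for (j in (i + 1L):N) ssT <- ssT + D[i, j]^2
  ssT <- ssT / N
  ssW <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    s <- 0
    for (i in idx) for (j in idx) if (i < j) s <- s + D[i, j]^2
    ssW <- ssW + s / length(idx)
  }
  k <- length(unique(groups))
  ssA <- ssT - ssW
  (ssA / (k - 1)) / (ssW / (N - k))
}

# Label-free canonical shape string (topology hash for shuffle tests).
shapeString <- function(tree) {
  ntip <- ape::Ntip(tree)
  kids <- split(tree$edge[, 2L], tree$edge[, 1L])
  build <- function(node) {
    if (node <= ntip) return("L")
    sub <- sort(vapply(kids[[as.character(node)]], build, ""))
    paste0("(", paste(sub, collapse = ","), ")")
  }
  build(ntip + 1L)
}

randCounts <- function(species, richness, seed) {
  withr::with_seed(seed, {
    sp <- sample(species, richness)
    v <- sample(1:50, richness, replace = TRUE)
    names(v) <- sp
    v
  })
}
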