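# Rooted-phylogeny primitives on ape "phylo" trees: newick I/O with a
# canonical writer, MRCA, node-to-tip distances, spanning subtrees.

.checkTips <- function(tree, tips) {
  miss <- setdiff(tips, tree$tip.label)
  if (length(miss))
    stop(sprintf("tip(s) not in tree: %s",
                 paste(head(miss, 5L), collapse = ", ")), call. = FALSE)
  match(tips, tree$tip.label)
}

#' Parse a newick string or file into a rooted phylogeny
#'
#' Thin validating wrapper around [ape::read.tree()]: rejects unbalanced or
#' otherwise malformed strings (which ape only warns about), rejects
#' duplicate tip labels and negative branch lengths, and defaults missing
#' branch lengths to 0 with a warning.  Polytomies are allowed.
#'
#' @param text A newick string (used when `file` is `NULL`).
#' @param file Path to a newick file.
#' @return An [ape::phylo] tree.
#' @export
parseNewick <- function(text = NULL, file = NULL) {
  if (is.null(text)) text <- paste(readLines(file), collapse = "")
  stripped <- gsub("'[^']*'", "", text)
  if (lengths(regmatches(stripped, gregexpr("\\(", stripped))) !=
      lengths(regmatches(stripped, gregexpr("\\)", stripped))))
    stop("newick parse error: unbalanced parentheses", call. = FALSE)
  tree <- withCallingHandlers(
    tryCatch(ape::read.tree(text = text),
             error = function(e)
               stop("newick parse error: ", conditionMessage(e),
                    call. = FALSE)),
    warning = function(w) {
      stop("newick parse error: ", conditionMessage(w), call. = FALSE)
    })
  if (is.null(tree)) stop("newick parse error: unreadable input",
                          call. = FALSE)
  if (anyDuplicated(tree$tip.label))
    stop(sprintf("duplicate tip label(s): %s",
                 paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
                       collapse = ", ")), call. = FALSE)
  if (is.null(tree$edge.length)) {
    warning("tree has no branch lengths; defaulting all to 0")
    tree$edge.length <- rep(0, nrow(tree$edge))
  }
  if (anyNA(tree$edge.length)) {
    warning("missing branch lengths defaulted to 0")
    tree$edge.length[is.na(tree$edge.length)] <- 0
  }
  if (any(tree$edge.length < 0))
    stop("negative branch length(s) in tree", call. = FALSE)
  tree
}

.fmtLen <- function(x) {
  format(x, digits = 15, trim = TRUE, scientific = FALSE)
}

# Children lists per node, from the edge matrix.
.childrenList <- function(tree) {
  nnode <- ape::Ntip(tree) + tree$Nnode
  kids <- vector("list", nnode)
  for (i in seq_len(nrow(tree$edge)))
    kids[[tree$edge[i, 1L]]] <- c(kids[[tree$edge[i, 1L]]], i)
  kids
}

#' Write a phylogeny as a canonical newick string
#'
#' Children are ordered lexicographically by the minimum tip label of their
#' subtree (radix/C ordering), so the same tree always serializes to the
#' same bytes.  With `labels = "taxids"` tips are renamed to their taxid;
#' every tip must then be annotated.
#'
#' @param tree An [ape::phylo] tree.
#' @param file Optional path; when given the string is written there.
#' @param labels `"names"` (tip labels as-is) or `"taxids"`.
#' @param tipTaxids Named integer vector tip label -> taxid, required for
#'   `labels = "taxids"`.
#' @return The newick string, invisibly when `file` is given.
#' @export
writeNewick <- function(tree, file = NULL, labels = c("names", "taxids"),
                        tipTaxids = NULL) {
  labels <- match.arg(labels)
  if (labels == "taxids") {
    miss <- setdiff(tree$tip.label, names(tipTaxids %||% integer(0)))
    miss <- c(miss,
              names(tipTaxids)[is.na(tipTaxids)][
                names(tipTaxids)[is.na(tipTaxids)] %in% tree$tip.label])
    if (length(miss))
      stop(sprintf("tips without taxid annotation: %s",
                   paste(head(sort(miss), 5L), collapse = ", ")),
           call. = FALSE)
    tree$tip.label <- as.character(tipTaxids[tree$tip.label])
  }
  ntip <- ape::Ntip(tree)
  root <- ntip + 1L
  kids <- .childrenList(tree)
  nlab <- tree$node.label
  build <- function(node, edgeIdx) {
    if (node <= ntip) {
      lab <- tree$tip.label[node]
      str <- if (grepl("[(),:; \t]", lab)) paste0("'", lab, "'") else lab
    } else {
      sub <- lapply(kids[[node]], function(e) build(tree$edge[e, 2L], e))
      ord <- order(vapply(sub, `[[`, "", "min"), method = "radix")
      str <- paste0("(",
                    paste(vapply(sub[ord], `[[`, "", "str"),
                          collapse = ","), ")")
      lab <- if (!is.null(nlab) && !is.na(nlab[node - ntip]) &&
                 nzchar(nlab[node - ntip])) nlab[node - ntip] else ""
      str <- paste0(str, lab)
      lab <- sort(vapply(sub, `[[`, "", "min"), method = "radix")[1L]
    }
    if (!is.null(edgeIdx))
      str <- paste0(str, ":", .fmtLen(tree$edge.length[edgeIdx]))
    list(str = str, min = lab)
  }
  out <- if (ntip == 1L && tree$Nnode >= 1L) {
    paste0("(", tree$tip.label[1L], ":",
           .fmtLen(tree$edge.length[1L] %||% 0), ");")
  } else {
    paste0(build(root, NULL)$str, ";")
  }
  if (!is.null(file)) {
    writeLines(out, file)
    return(invisible(out))
  }
  out
}

#' Most recent common ancestor of a set of tips
#'
#' @param tree An [ape::phylo] tree.
#' @param tips Non-empty character vector of tip labels.
#' @return The node number (a tip's own number when `tips` has length 1).
#' @export
mrcaNode <- function(tree, tips) {
  idx <- .checkTips(tree, unique(tips))
  if (length(idx) == 0L) stop("empty tip set", call. = FALSE)
  if (length(idx) == 1L) return(idx)
  ape::getMRCA(tree, idx)
}

# Tip indices descending from each node (list over all node numbers).
.tipsUnderList <- function(tree) {
  ntip <- ape::Ntip(tree)
  res <- vector("list", ntip + tree$Nnode)
  res[seq_len(ntip)] <- as.list(seq_len(ntip))
  po <- ape::reorder.phylo(tree, "postorder")
  for (i in seq_len(nrow(po$edge))) {
    p <- po$edge[i, 1L]; ch <- po$edge[i, 2L]
    res[[p]] <- c(res[[p]], res[[ch]])
  }
  res
}

# Logical matrix edges x tips: TRUE when the tip descends from the edge's
# child node.  Rows follow tree$edge order.
.edgeTipMatrix <- function(tree) {
  tu <- .tipsUnderList(tree)
  ntip <- ape::Ntip(tree)
  m <- matrix(FALSE, nrow(tree$edge), ntip,
              dimnames = list(NULL, tree$tip.label))
  for (i in seq_len(nrow(tree$edge)))
    m[i, tu[[tree$edge[i, 2L]]]] <- TRUE
  m
}

# Depth (root-to-node path length) for every node.
.nodeDepths <- function(tree) ape::node.depth.edgelength(tree)

#' Path lengths from a node down to a set of descendant tips
#'
#' @param tree An [ape::phylo] tree.
#' @param node A node number.
#' @param tips Character vector of tip labels, all descendants of `node`.
#' @return Named numeric vector of path lengths.
#' @export
distancesFromNode <- function(tree, node, tips) {
  idx <- .checkTips(tree, tips)
  under <- .tipsUnderList(tree)[[node]]
  bad <- setdiff(idx, under)
  if (length(bad))
    stop(sprintf("tip(s) not descendants of node %d: %s", node,
                 paste(tree$tip.label[bad], collapse = ", ")), call. = FALSE)
  d <- .nodeDepths(tree)
  out <- d[idx] - d[node]
  names(out) <- tips
  out
}

#' Patristic distance matrix among tips
#'
#' @param tree An [ape::phylo] tree.
#' @param tips Tip labels (>= 2); default all tips.
#' @return Symmetric matrix of path lengths, zero diagonal.
#' @export
patristicMatrix <- function(tree, tips = tree$tip.label) {
  .checkTips(tree, tips)
  if (length(tips) < 2L) stop("need at least 2 tips", call. = FALSE)
  ape::cophenetic.phylo(tree)[tips, tips]
}

#' Minimal rooted subtree spanning a tip set
#'
#' The subtree's root is the MRCA of `tips`; the edge above it is discarded
#' and unary nodes are suppressed with their lengths summed (ape's pruning
#' semantics).  A single tip yields a one-tip tree of total length 0.
#'
#' @param tree An [ape::phylo] tree.
#' @param tips Non-empty character vector of tip labels.
#' @return An [ape::phylo] tree.
#' @export
spanningSubtree <- function(tree, tips) {
  .checkTips(tree, tips)
  tips <- unique(tips)
  if (length(tips) == 1L) {
    out <- structure(list(edge = matrix(c(2L, 1L), 1L, 2L),
                          tip.label = tips, edge.length = 0,
                          Nnode = 1L), class = "phylo", order = "cladewise")
    return(out)
  }
  sub <- ape::keep.tip(tree, tips)
  sub$root.edge <- NULL
  sub
}

#' Total branch length of a tree
#' @param tree An [ape::phylo] tree.
#' @return Sum of all edge lengths.
#' @export
totalBranchLength <- function(tree) sum(tree$edge.length)
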