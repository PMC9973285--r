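# Taxonomy-guided grafting: annotate reference tips with lineages, find the
# lowest shared rank for each query species, filter outlier reference tips,
# and insert each query as a new tip at the subtree root with a pendant
# branch equal to the mean child-tip distance.

#' AnnotatedPhylo: a reference phylogeny with lineage-annotated tips
#'
#' Produced by [annotateTips()].  `tipData` has one row per tip with the
#' resolved taxid, the species-level taxid and the seven canonical lineage
#' ranks; `changes` logs taxid redirections encountered on the way.
#'
#' @slot tree An `ape::phylo` tree.
#' @slot tipData data.frame: `tip_label`, `input_taxid`, `taxid`,
#'   `species_taxid`, plus one integer column per canonical rank.
#' @slot changes data.frame: `context`, `record`.
#' @export
setClass("AnnotatedPhylo",
         representation(tree = "ANY", tipData = "data.frame",
                        changes = "data.frame"))

setValidity("AnnotatedPhylo", function(object) {
  if (!inherits(object@tree, "phylo")) return("tree must be an ape phylo")
  if (nrow(object@tipData) != ape::Ntip(object@tree))
    return("tipData must have one row per tip")
  if (!setequal(object@tipData$tip_label, object@tree$tip.label))
    return("tipData labels do not match tree tips")
  TRUE
})

setMethod("show", "AnnotatedPhylo", function(object) {
  n <- ape::Ntip(object@tree)
  sp <- sum(!is.na(object@tipData$species_taxid))
  cat(sprintf(
    "AnnotatedPhylo: %d tips (%d resolved to species rank), %d taxid change(s)\n",
    n, sp, nrow(object@changes)))
})

#' Tree accessor
#' @param x An [AnnotatedPhylo-class] or [ExpansionResult-class] object.
#' @return The underlying `ape::phylo` tree.
#' @export
setGeneric("phyloTree", function(x) standardGeneric("phyloTree"))

#' @rdname phyloTree
setMethod("phyloTree", "AnnotatedPhylo", function(x) x@tree)

#' Tip annotation accessor
#' @param x An [AnnotatedPhylo-class] object.
#' @return The tip annotation data.frame.
#' @export
setGeneric("tipData", function(x) standardGeneric("tipData"))

#' @rdname tipData
setMethod("tipData", "AnnotatedPhylo", function(x) x@tipData)

#' Annotate reference-tree tips with resolved taxids and lineages
#'
#' Every tip label must appear in the mapping table.  Tip taxids are passed
#' through [resolveTaxid()] (merged IDs redirected and logged) and expanded
#' into canonical lineages; tips that cannot be resolved to species rank are
#' kept in the tree but carry `NA` in `species_taxid`, which excludes them
#' from all candidate sets.
#'
#' @param tree An `ape::phylo` tree.
#' @param tipTable data.frame with columns `tip_label` and `taxid` (extra
#'   columns ignored), or a path to a two-column TSV (header optional).
#' @param db A [TaxonomyDB-class].
#' @return An [AnnotatedPhylo-class] object.
#' @export
annotateTips <- function(tree, tipTable, db) {
  if (is.character(tipTable) && length(tipTable) == 1L)
    tipTable <- readTipTable(tipTable)
  miss <- setdiff(tree$tip.label, tipTable$tip_label)
  if (length(miss))
    stop(sprintf("tip(s) missing from taxid table: %s",
                 paste(head(sort(miss), 5L), collapse = ", ")),
         call. = FALSE)
  tipTable <- tipTable[match(tree$tip.label, tipTable$tip_label), ]
  n <- nrow(tipTable)
  lins <- matrix(NA_integer_, n, length(CANONICAL_RANKS),
                 dimnames = list(NULL, CANONICAL_RANKS))
  resolved <- rep(NA_integer_, n)
  changes <- list()
  for (i in seq_len(n)) {
    res <- tryCatch(resolveTaxid(db, tipTable$taxid[i]),
                    phylograftUnplaceableError = function(e) NULL)
    if (is.null(res)) {
      changes[[length(changes) + 1L]] <-
        data.frame(context = tipTable$tip_label[i],
                   record = sprintf("taxid %d unknown; tip excluded",
                                    as.integer(tipTable$taxid[i])))
      next
    }
    resolved[i] <- res$taxid
    if (!is.null(res$change))
      changes[[length(changes) + 1L]] <-
        data.frame(context = tipTable$tip_label[i], record = res$change)
    lin <- tryCatch(canonicalLineage(db, res$taxid),
                    phylograftLineageError = function(e) NULL)
    if (!is.null(lin)) lins[i, ] <- lin
  }
  td <- data.frame(tip_label = tipTable$tip_label,
                   input_taxid = as.integer(tipTable$taxid),
                   taxid = resolved,
                   species_taxid = lins[, "species"],
                   stringsAsFactors = FALSE)
  td <- cbind(td, as.data.frame(lins))
  ch <- if (length(changes)) do.call(rbind, changes)
        else data.frame(context = character(0), record = character(0))
  new("AnnotatedPhylo", tree = tree, tipData = td, changes = ch)
}

#' Read a tip -> taxid mapping table
#' @param file Two-column TSV (`tip_label`, `ncbi_taxid`); header optional.
#' @return data.frame with columns `tip_label`, `taxid`.
#' @export
readTipTable <- function(file) {
  first <- strsplit(readLines(file, n = 1L), "\t")[[1L]]
  hasHeader <- is.na(suppressWarnings(as.integer(first[2L])))
  tab <- read.delim(file, header = hasHeader, stringsAsFactors = FALSE)
  names(tab)[1:2] <- c("tip_label", "taxid")
  tab$taxid <- as.integer(tab$taxid)
  tab[, c("tip_label", "taxid")]
}

#' Lowest shared taxonomic rank between a query and the reference tips
#'
#' Scans the canonical ranks from species up to superkingdom; the first rank
#' at which the query's lineage entry matches at least one annotated tip's
#' entry determines the mapping.  A species-rank match means the query is
#' already present (no insertion); no match at any rank means the query is
#' unplaceable.
#'
#' @param queryLineage Named integer lineage from [canonicalLineage()]; the
#'   species entry must be present.
#' @param aphy An [AnnotatedPhylo-class] object.
#' @return A list: `status` (`"insert"`, `"already_present"` or
#'   `"unplaceable"`), `rank` and `candidates` (tip labels) when relevant.
#' @export
determineMappingRank <- function(queryLineage, aphy) {
  if (is.na(queryLineage["species"]))
    stop("query lineage has no species entry", call. = FALSE)
  td <- aphy@tipData
  usable <- !is.na(td$species_taxid)
  for (r in CANONICAL_RANKS) {
    q <- queryLineage[[r]]
    if (is.na(q)) next
    hit <- usable & !is.na(td[[r]]) & td[[r]] == q
    if (!any(hit)) next
    if (r == "species")
      return(list(status = "already_present", rank = r,
                  candidates = td$tip_label[hit]))
    return(list(status = "insert", rank = r,
                candidates = td$tip_label[hit]))
  }
  list(status = "unplaceable", rank = NA_character_,
       candidates = character(0))
}

#' Remove outlier reference tips from a candidate subtree
#'
#' With at least four candidates, each candidate's distance to the candidate
#' MRCA is computed and tips beyond the Tukey fence (Q3 + 1.5 IQR, type-7
#' quantiles) are flagged as outliers.  Fewer than four candidates, or a
#' fence that would remove everything, disables filtering.
#'
#' @param tree An `ape::phylo` tree.
#' @param candidates Non-empty character vector of tip labels.
#' @return `list(retained = <labels>, outliers = <labels>)`.
#' @export
filterOutlierTips <- function(tree, candidates) {
  candidates <- unique(candidates)
  if (length(candidates) < 4L)
    return(list(retained = candidates, outliers = character(0)))
  node <- mrcaNode(tree, candidates)
  d <- distancesFromNode(tree, node, candidates)
  qs <- quantile(d, c(0.25, 0.75), type = 7, names = FALSE)
  fence <- qs[2L] + 1.5 * (qs[2L] - qs[1L])
  out <- d > fence
  if (all(out)) return(list(retained = candidates, outliers = character(0)))
  list(retained = candidates[!out], outliers = candidates[out])
}

#' Insertion node and pendant branch length for a set of reference tips
#'
#' With two or more retained tips the insertion node is their MRCA and the
#' pendant length is the mean distance from that node to each tip.  A single
#' retained tip degenerates to its parent node with the tip's own branch
#' length.
#'
#' @param tree An `ape::phylo` tree.
#' @param retained Non-empty character vector of tip labels.
#' @return `list(node = <node number>, pendant = <length>)`.
#' @export
placementParams <- function(tree, retained) {
  retained <- unique(retained)
  if (length(retained) == 0L) stop("empty retained set", call. = FALSE)
  if (length(retained) >= 2L) {
    node <- mrcaNode(tree, retained)
    return(list(node = node,
                pendant = mean(distancesFromNode(tree, node, retained))))
  }
  idx <- .checkTips(tree, retained)
  e <- which(tree$edge[, 2L] == idx)
  list(node = tree$edge[e, 1L], pendant = tree$edge.length[e])
}

# Batch-add new tips as children of existing internal nodes (polytomies
# allowed).  `nodes` are node numbers in the *input* tree; all additions are
# applied in one renumbering pass, so the result is order-independent.
.addTipsAtNodes <- function(tree, nodes, labels, lengths) {
  k <- length(labels)
  if (k == 0L) return(tree)
  n <- ape::Ntip(tree)
  if (any(nodes <= n)) stop("insertion node must be internal", call. = FALSE)
  edge <- tree$edge
  edge[edge > n] <- edge[edge > n] + k
  tree$edge <- rbind(edge, cbind(nodes + k, n + seq_len(k)))
  tree$edge.length <- c(tree$edge.length, lengths)
  tree$tip.label <- c(tree$tip.label, labels)
  attr(tree, "order") <- NULL
  ape::reorder.phylo(tree, "cladewise")
}

#' Graft a batch of placed queries onto the tree
#'
#' All placements must have been computed against the same original tree;
#' they are applied in one pass, so insertion order cannot matter.  Queries
#' sharing an insertion node form a polytomy.
#'
#' @param tree The original `ape::phylo` tree.
#' @param placements data.frame with columns `label`, `taxid`, `node`,
#'   `pendant`.
#' @return The expanded `ape::phylo` tree.
#' @export
graftQueries <- function(tree, placements) {
  if (nrow(placements) == 0L) return(tree)
  if (anyDuplicated(placements$taxid))
    stop("duplicate query taxids in placements", call. = FALSE)
  if (any(placements$label %in% tree$tip.label))
    stop("query label collides with existing tip", call. = FALSE)
  .addTipsAtNodes(tree, placements$node, placements$label,
                  placements$pendant)
}

#' Prune duplicate species down to one representative tip
#'
#' For every species taxid represented by more than one tip, the
#' lexicographically smallest tip label is kept; unary nodes left behind are
#' suppressed.  Tips without a species-level taxid are never pruned.
#'
#' @param aphy An [AnnotatedPhylo-class] object.
#' @return An [AnnotatedPhylo-class] with at most one tip per species.
#' @export
pruneDuplicateSpecies <- function(aphy) {
  td <- aphy@tipData
  hasSp <- !is.na(td$species_taxid)
  keep <- rep(TRUE, nrow(td))
  for (sp in unique(td$species_taxid[hasSp])) {
    idx <- which(hasSp & td$species_taxid == sp)
    if (length(idx) > 1L) {
      rep_ <- idx[order(td$tip_label[idx], method = "radix")][1L]
      keep[setdiff(idx, rep_)] <- FALSE
    }
  }
  if (all(keep)) return(aphy)
  tree <- ape::keep.tip(aphy@tree, td$tip_label[keep])
  tree$root.edge <- NULL
  td <- td[keep, , drop = FALSE]
  td <- td[match(tree$tip.label, td$tip_label), , drop = FALSE]
  rownames(td) <- NULL
  new("AnnotatedPhylo", tree = tree, tipData = td, changes = aphy@changes)
}

#' ExpansionResult: the outcome of a full grafting run
#'
#' @slot tree The expanded `ape::phylo` tree (tips labeled by name).
#' @slot tipTaxids Named integer vector: tip label -> taxid (species taxid
#'   for reference tips after deduplication; query taxid for grafted tips).
#' @slot placements data.frame, one row per input query: `taxid`, `name`,
#'   `status`, `mapping_rank`, `pendant_length`, `n_reference_tips`,
#'   `outlier_tips`.
#' @slot changes data.frame of taxid redirections (`context`, `record`).
#' @slot queryTips Tip labels of the query species present in `tree`
#'   (grafted plus already-present representatives).
#' @slot lengthBefore,lengthAfter Total branch length before/after grafting.
#' @export
setClass("ExpansionResult",
         representation(tree = "ANY", tipTaxids = "integer",
                        placements = "data.frame", changes = "data.frame",
                        queryTips = "character", lengthBefore = "numeric",
                        lengthAfter = "numeric"))

setValidity("ExpansionResult", function(object) {
  if (!inherits(object@tree, "phylo")) return("tree must be an ape phylo")
  st <- object@placements$status
  counts <- c(sum(st == "inserted"), sum(st == "already_present"),
              sum(st == "unplaceable"))
  if (sum(counts) != nrow(object@placements))
    return("placement statuses must partition the queries")
  TRUE
})

setMethod("show", "ExpansionResult", function(object) {
  st <- object@placements$status
  cat(sprintf("ExpansionResult: %d tips\n", ape::Ntip(object@tree)))
  cat(sprintf("  queries: %d inserted, %d already present, %d unplaceable\n",
              sum(st == "inserted"), sum(st == "already_present"),
              sum(st == "unplaceable")))
  cat(sprintf("  total branch length: %.6g -> %.6g\n",
              object@lengthBefore, object@lengthAfter))
})

#' @rdname phyloTree
setMethod("phyloTree", "ExpansionResult", function(x) x@tree)

#' Placement summary accessor
#' @param x An [ExpansionResult-class] object.
#' @return data.frame with one row per query.
#' @export
setGeneric("placementSummary", function(x) standardGeneric("placementSummary"))

#' @rdname placementSummary
setMethod("placementSummary", "ExpansionResult", function(x) x@placements)

#' Expand a reference phylogeny with a set of query species
#'
#' The full grafting pipeline: resolve query taxids (redirecting merged IDs
#' and promoting sub-species ranks to species), annotate and deduplicate the
#' reference tips, determine each query's mapping rank, filter outlier
#' reference tips, compute all placements against the unmodified tree, and
#' graft them in one batch.
#'
#' @param tree An `ape::phylo` reference tree, or a newick file path.
#' @param tipTable Tip -> taxid mapping (data.frame or TSV path, see
#'   [annotateTips()]).
#' @param queries Integer vector of NCBI taxids, or a path to a plain-text
#'   file with one taxid per line.
#' @param db A [TaxonomyDB-class].
#' @return An [ExpansionResult-class] object.
#' @export
expandPhylogeny <- function(tree, tipTable, queries, db) {
  if (is.character(tree) && length(tree) == 1L)
    tree <- parseNewick(file = tree)
  if (is.character(queries) && length(queries) == 1L &&
      file.exists(queries))
    queries <- readLines(queries)
  queries <- as.integer(queries[nzchar(trimws(as.character(queries)))])
  if (length(queries) == 0L) stop("empty query list", call. = FALSE)

  aphy <- annotateTips(tree, tipTable, db)
  aphy <- pruneDuplicateSpecies(aphy)
  ref <- aphy@tree
  changes <- aphy@changes

  # Resolve queries to species-level lineages.
  qrows <- vector("list", length(queries))
  lineages <- vector("list", length(queries))
  for (i in seq_along(queries)) {
    q <- queries[i]
    status <- NA_character_
    name <- NA_character_
    resolved <- NA_integer_
    res <- tryCatch(resolveTaxid(db, q),
                    phylograftUnplaceableError = function(e) NULL)
    if (is.null(res)) {
      status <- "unplaceable"
      changes <- rbind(changes, data.frame(
        context = sprintf("query %d", q),
        record = sprintf("taxid %d unknown or deleted; not grafted", q)))
    } else {
      if (!is.null(res$change))
        changes <- rbind(changes, data.frame(
          context = sprintf("query %d", q), record = res$change))
      lin <- tryCatch(canonicalLineage(db, res$taxid),
                      phylograftLineageError = function(e) NULL)
      if (is.null(lin) || is.na(lin["species"])) {
        status <- "unplaceable"
        changes <- rbind(changes, data.frame(
          context = sprintf("query %d", q),
          record = sprintf("taxid %d has no species-rank lineage; not grafted",
                           res$taxid)))
      } else {
        resolved <- unname(lin["species"])
        if (resolved != res$taxid)
          changes <- rbind(changes, data.frame(
            context = sprintf("query %d", q),
            record = sprintf("%d promoted to species %d", res$taxid,
                             resolved)))
        name <- taxonName(db, resolved)
        lineages[[i]] <- lin
      }
    }
    qrows[[i]] <- data.frame(taxid = resolved, input_taxid = q, name = name,
                             status = status, stringsAsFactors = FALSE)
  }
  qdf <- do.call(rbind, qrows)
  dup <- duplicated(qdf$taxid) & !is.na(qdf$taxid)
  if (any(dup))
    stop(sprintf("duplicate query species taxid(s): %s",
                 paste(unique(qdf$taxid[dup]), collapse = ", ")),
         call. = FALSE)

  # Per-query mapping, outlier filter and placement (all on the original
  # deduplicated reference tree).
  n <- nrow(qdf)
  rank <- rep(NA_character_, n); pendant <- rep(NA_real_, n)
  nref <- rep(NA_integer_, n); outliers <- rep("", n)
  node <- rep(NA_integer_, n); label <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    if (!is.na(qdf$status[i])) next
    mp <- determineMappingRank(lineages[[i]], aphy)
    if (mp$status == "unplaceable") { qdf$status[i] <- "unplaceable"; next }
    rank[i] <- mp$rank
    if (mp$status == "already_present") {
      qdf$status[i] <- "already_present"
      nref[i] <- length(mp$candidates)
      label[i] <- mp$candidates[1L]
      next
    }
    flt <- filterOutlierTips(ref, mp$candidates)
    pp <- placementParams(ref, flt$retained)
    qdf$status[i] <- "inserted"
    node[i] <- pp$node; pendant[i] <- pp$pendant
    nref[i] <- length(flt$retained)
    outliers[i] <- paste(flt$outliers, collapse = ";")
    lab <- qdf$name[i]
    if (is.na(lab) || !nzchar(lab)) lab <- sprintf("taxid_%d", qdf$taxid[i])
    label[i] <- lab
  }
  ins <- which(qdf$status == "inserted")
  label[ins] <- make.unique(label[ins], sep = "_")
  label[ins][label[ins] %in% ref$tip.label] <-
    sprintf("%s_q", label[ins][label[ins] %in% ref$tip.label])

  placed <- data.frame(label = label[ins], taxid = qdf$taxid[ins],
                       node = node[ins], pendant = pendant[ins],
                       stringsAsFactors = FALSE)
  expanded <- graftQueries(ref, placed)

  tipTaxids <- aphy@tipData$taxid
  names(tipTaxids) <- aphy@tipData$tip_label
  add <- placed$taxid
  names(add) <- placed$label
  tipTaxids <- c(tipTaxids, add)[expanded$tip.label]

  placements <- data.frame(
    taxid = qdf$taxid, input_taxid = qdf$input_taxid, name = qdf$name,
    status = qdf$status, mapping_rank = rank, pendant_length = pendant,
    n_reference_tips = nref, outlier_tips = outliers,
    tip_label = label, stringsAsFactors = FALSE)

  res <- new("ExpansionResult", tree = expanded, tipTaxids = tipTaxids,
             placements = placements, changes = changes,
             queryTips = label[qdf$status %in% c("inserted",
                                                 "already_present")],
             lengthBefore = totalBranchLength(ref),
             lengthAfter = totalBranchLength(expanded))
  validObject(res)
  res
}

#' Write the four-tree output bundle of an expansion run
#'
#' Emits `comprehensive_names.tree`, `comprehensive_taxIDs.tree`,
#' `user_names.tree`, `user_taxIDs.tree` (canonical newick),
#' `placement_summary.tsv` and `taxid_changes.txt` under `dir`.
#'
#' @param result An [ExpansionResult-class] object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeExpansionBundle <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tree <- result@tree
  writeNewick(tree, file.path(dir, "comprehensive_names.tree"))
  writeNewick(tree, file.path(dir, "comprehensive_taxIDs.tree"),
              labels = "taxids", tipTaxids = result@tipTaxids)
  if (length(result@queryTips)) {
    user <- spanningSubtree(tree, result@queryTips)
    writeNewick(user, file.path(dir, "user_names.tree"))
    writeNewick(user, file.path(dir, "user_taxIDs.tree"),
                labels = "taxids", tipTaxids = result@tipTaxids)
  }
  write.table(result@placements, file.path(dir, "placement_summary.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(if (nrow(result@changes))
               sprintf("%s\t%s", result@changes$context,
                       result@changes$record)
             else character(0),
             file.path(dir, "taxid_changes.txt"))
  invisible(dir)
}
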