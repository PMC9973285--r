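# NCBI taxdump parsing, taxid resolution and canonical lineages.

CANONICAL_RANKS <- c("species", "genus", "family", "order", "class",
                     "phylum", "superkingdom")

# NCBI ranks strictly below species; a taxid at one of these is promoted to
# its species ancestor before any lineage-based operation.
SUBSPECIES_RANKS <- c("subspecies", "strain", "varietas", "subvariety",
                      "forma", "forma specialis", "serotype", "serogroup",
                      "biotype", "genotype", "isolate", "pathogroup",
                      "morph")

#' TaxonomyDB: an in-memory NCBI taxonomy
#'
#' Holds the node table of a taxdump (taxid, parent, rank, scientific name),
#' the merged-ID redirection map and the deleted-ID set.  Construct with
#' [loadTaxdump()] or [taxonomyDB()].
#'
#' @slot nodes data.frame with columns `taxid`, `parent`, `rank`, `name`.
#' @slot merged named integer vector: `merged["old"]` is the current taxid.
#' @slot deleted integer vector of retired taxids with no replacement.
#' @export
setClass("TaxonomyDB",
         representation(nodes = "data.frame", merged = "integer",
                        deleted = "integer"))

setValidity("TaxonomyDB", function(object) {
  nd <- object@nodes
  need <- c("taxid", "parent", "rank", "name")
  if (!all(need %in% names(nd)))
    return(sprintf("nodes must have columns %s", paste(need, collapse = ", ")))
  if (anyDuplicated(nd$taxid)) return("duplicate taxids in nodes")
  if (length(object@merged) &&
      any(names(object@merged) %in% as.character(nd$taxid)))
    return("merged keys overlap current taxids")
  bad <- setdiff(nd$parent, nd$taxid)
  if (length(bad))
    return(sprintf("dangling parent taxid(s): %s",
                   paste(head(bad, 5L), collapse = ", ")))
  TRUE
})

setMethod("show", "TaxonomyDB", function(object) {
  cat(sprintf("TaxonomyDB: %d nodes, %d merged ids, %d deleted ids\n",
              nrow(object@nodes), length(object@merged),
              length(object@deleted)))
  rk <- table(object@nodes$rank)
  rk <- rk[intersect(CANONICAL_RANKS, names(rk))]
  if (length(rk))
    cat("  canonical ranks:",
        paste(sprintf("%s=%d", names(rk), rk), collapse = ", "), "\n")
})

#' Construct a TaxonomyDB from in-memory tables
#'
#' @param nodes data.frame with columns `taxid`, `parent`, `rank`, `name`.
#' @param merged named integer vector mapping old taxids (names) to current
#'   ones, or `NULL`.
#' @param deleted integer vector of deleted taxids, or `NULL`.
#' @return A [TaxonomyDB-class] object.
#' @export
taxonomyDB <- function(nodes, merged = NULL, deleted = NULL) {
  nodes$taxid <- as.integer(nodes$taxid)
  nodes$parent <- as.integer(nodes$parent)
  nodes$rank <- tolower(trimws(as.character(nodes$rank)))
  nodes$name <- as.character(nodes$name)
  m <- as.integer(merged %||% integer(0))
  names(m) <- names(merged %||% integer(0))
  new("TaxonomyDB", nodes = nodes, merged = m,
      deleted = as.integer(deleted %||% integer(0)))
}

# Split taxdump records: fields separated by "\t|\t", record ends "\t|".
.parseDmp <- function(lines, nfields, what) {
  lines <- sub("\t\\|$", "", lines)
  parts <- strsplit(lines, "\t\\|\t")
  bad <- which(vapply(parts, length, 1L) < nfields)
  if (length(bad))
    stop(sprintf("malformed %s record at line %d", what, bad[1L]),
         call. = FALSE)
  parts
}

.readSource <- function(x) {
  if (length(x) == 1L && file.exists(x)) readLines(x) else as.character(x)
}

#' Load an NCBI taxdump
#'
#' Parses `nodes.dmp`, `names.dmp` and (optionally) `merged.dmp` /
#' `delnodes.dmp` in the standard taxdump dialect (fields separated by
#' `"\t|\t"`, records terminated by `"\t|"`).  Only names of class
#' `"scientific name"` are kept.
#'
#' @param nodes,names,merged,delnodes Either a file path or a character
#'   vector of raw lines.  `names`, `merged` and `delnodes` may be `NULL`.
#' @return A [TaxonomyDB-class] object.
#' @examples
#' nd <- c("1\t|\t1\t|\tno rank\t|",
#'         "2\t|\t1\t|\tsuperkingdom\t|")
#' nm <- c("1\t|\troot\t|\t\t|\tscientific name\t|",
#'         "2\t|\tBacteria\t|\t\t|\tscientific name\t|")
#' db <- loadTaxdump(nd, nm)
#' @export
loadTaxdump <- function(nodes, names = NULL, merged = NULL, delnodes = NULL) {
  np <- .parseDmp(.readSource(nodes), 3L, "nodes.dmp")
  taxid <- as.integer(vapply(np, `[[`, "", 1L))
  parent <- as.integer(vapply(np, `[[`, "", 2L))
  rank <- vapply(np, `[[`, "", 3L)
  if (anyNA(taxid) || anyNA(parent))
    stop("malformed nodes.dmp record: non-integer taxid", call. = FALSE)
  nm <- rep(NA_character_, length(taxid))
  if (!is.null(names)) {
    pp <- .parseDmp(.readSource(names), 4L, "names.dmp")
    cls <- vapply(pp, `[[`, "", 4L)
    sci <- pp[trimws(cls) == "scientific name"]
    id <- as.integer(vapply(sci, `[[`, "", 1L))
    nm[match(id, taxid)] <- vapply(sci, `[[`, "", 2L)
  }
  mg <- integer(0)
  if (!is.null(merged)) {
    mp <- .parseDmp(.readSource(merged), 2L, "merged.dmp")
    mg <- as.integer(vapply(mp, `[[`, "", 2L))
    names(mg) <- vapply(mp, `[[`, "", 1L)
  }
  dl <- integer(0)
  if (!is.null(delnodes)) {
    dp <- .parseDmp(.readSource(delnodes), 1L, "delnodes.dmp")
    dl <- as.integer(vapply(dp, `[[`, "", 1L))
  }
  db <- taxonomyDB(data.frame(taxid = taxid, parent = parent, rank = rank,
                              name = nm, stringsAsFactors = FALSE),
                   merged = mg, deleted = dl)
  validObject(db)
  db
}

.unplaceable <- function(taxid, msg) {
  stop(errorCondition(msg, taxid = taxid,
                      class = c("phylograftUnplaceableError", "error")))
}

#' Resolve a possibly outdated taxid
#'
#' Returns the input unchanged when it is a current node; follows the merged
#' map (recording the redirection) otherwise.  Deleted taxids raise a
#' condition of class `phylograftDeletedError`, unknown ones
#' `phylograftUnplaceableError`.
#'
#' @param db A [TaxonomyDB-class].
#' @param taxid A single positive integer.
#' @return `list(taxid = <resolved>, change = <character or NULL>)`.
#' @export
resolveTaxid <- function(db, taxid) {
  taxid <- as.integer(taxid)
  stopifnot(length(taxid) == 1L, !is.na(taxid), taxid > 0L)
  if (taxid %in% db@nodes$taxid) return(list(taxid = taxid, change = NULL))
  key <- as.character(taxid)
  if (key %in% names(db@merged)) {
    new <- unname(db@merged[key])
    return(list(taxid = new,
                change = sprintf("%d merged into %d", taxid, new)))
  }
  if (taxid %in% db@deleted)
    stop(errorCondition(sprintf("taxid %d has been deleted", taxid),
                        taxid = taxid,
                        class = c("phylograftDeletedError",
                                  "phylograftUnplaceableError", "error")))
  .unplaceable(taxid, sprintf("taxid %d not found in taxonomy", taxid))
}

# Parent-chain walk from taxid to the root; errors on cycles.
.ancestorChain <- function(db, taxid) {
  idx <- match(taxid, db@nodes$taxid)
  chain <- integer(0)
  seen <- 0L
  while (TRUE) {
    chain <- c(chain, db@nodes$taxid[idx])
    p <- db@nodes$parent[idx]
    if (p == db@nodes$taxid[idx]) break
    idx <- match(p, db@nodes$taxid)
    seen <- seen + 1L
    if (seen > nrow(db@nodes)) stop("cycle in taxonomy parent chain")
  }
  chain
}

#' Canonical seven-rank lineage of a taxid
#'
#' Walks the ancestor chain collecting the seven canonical ranks (species,
#' genus, family, order, class, phylum, superkingdom).  A taxid below species
#' rank (strain, subspecies, ...) is first promoted to its nearest ancestor
#' of rank species; non-canonical intermediate ranks are skipped.  A taxid
#' at genus rank or above yields a partial lineage with the species entry
#' absent.
#'
#' @param db A [TaxonomyDB-class].
#' @param taxid A single taxid (resolved via [resolveTaxid()] internally).
#' @return Named integer vector over the seven canonical ranks; `NA` marks
#'   absent ranks.
#' @export
canonicalLineage <- function(db, taxid) {
  taxid <- resolveTaxid(db, taxid)$taxid
  chain <- .ancestorChain(db, taxid)
  ranks <- db@nodes$rank[match(chain, db@nodes$taxid)]
  lin <- rep(NA_integer_, length(CANONICAL_RANKS))
  names(lin) <- CANONICAL_RANKS
  for (i in seq_along(chain)) {
    r <- ranks[i]
    if (r %in% CANONICAL_RANKS && is.na(lin[r])) lin[r] <- chain[i]
  }
  ownRank <- ranks[1L]
  if (is.na(lin["species"]) && !(ownRank %in% CANONICAL_RANKS)) {
    hasCanonical <- any(ranks %in% CANONICAL_RANKS)
    if (ownRank %in% SUBSPECIES_RANKS || !hasCanonical)
      stop(errorCondition(
        sprintf("taxid %d has no species-rank ancestor; lineage incomplete",
                taxid),
        taxid = taxid,
        class = c("phylograftLineageError", "error")))
  }
  lin
}

#' Scientific name of a taxid
#' @param db A [TaxonomyDB-class].
#' @param taxid Integer vector of taxids (must be current IDs).
#' @return Character vector of scientific names (`NA` when absent).
#' @export
taxonName <- function(db, taxid) {
  db@nodes$name[match(as.integer(taxid), db@nodes$taxid)]
}

#' Rank of a taxid
#' @inheritParams taxonName
#' @return Character vector of normalized rank strings.
#' @export
taxonRank <- function(db, taxid) {
  db@nodes$rank[match(as.integer(taxid), db@nodes$taxid)]
}

#' Write a TaxonomyDB back out in taxdump format
#'
#' Emits `nodes.dmp`, `names.dmp`, `merged.dmp` and `delnodes.dmp` (the
#' latter two only when non-empty) under `dir`, bit-exact in the taxdump
#' dialect, so that synthetic taxonomies round-trip through [loadTaxdump()].
#'
#' @param db A [TaxonomyDB-class].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeTaxdump <- function(db, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nd <- db@nodes
  writeLines(sprintf("%d\t|\t%d\t|\t%s\t|", nd$taxid, nd$parent, nd$rank),
             file.path(dir, "nodes.dmp"))
  has <- !is.na(nd$name)
  writeLines(sprintf("%d\t|\t%s\t|\t\t|\tscientific name\t|",
                     nd$taxid[has], nd$name[has]),
             file.path(dir, "names.dmp"))
  if (length(db@merged))
    writeLines(sprintf("%s\t|\t%d\t|", names(db@merged), db@merged),
               file.path(dir, "merged.dmp"))
  if (length(db@deleted))
    writeLines(sprintf("%d\t|", db@deleted), file.path(dir, "delnodes.dmp"))
  invisible(dir)
}
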