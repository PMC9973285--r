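# Community tables: classifier-output parsing, relative-abundance
# filtering, and rarefaction to a common depth.

#' CommunityTable: samples x species counts with optional grouping
#'
#' @slot counts Non-negative integer matrix; rows are samples, columns are
#'   species identifiers (taxids or tip labels).
#' @slot groups Named character vector sample -> group label (possibly
#'   empty).
#' @export
setClass("CommunityTable",
         representation(counts = "matrix", groups = "character"))

setValidity("CommunityTable", function(object) {
  m <- object@counts
  if (is.null(rownames(m)) || (ncol(m) > 0L && is.null(colnames(m))))
    return("counts must have sample rownames and species colnames")
  if (anyDuplicated(colnames(m))) return("duplicate species in counts")
  if (anyDuplicated(rownames(m))) return("duplicate sample names")
  if (any(m < 0)) return("negative counts")
  if (any(m != round(m))) return("counts must be integers")
  if (length(object@groups) &&
      !all(names(object@groups) %in% rownames(m)))
    return("groups refer to unknown samples")
  TRUE
})

setMethod("show", "CommunityTable", function(object) {
  cat(sprintf("CommunityTable: %d samples x %d species\n",
              nrow(object@counts), ncol(object@counts)))
  tot <- rowSums(object@counts)
  cat(sprintf("  totals: min %s, median %s, max %s\n",
              format(min(tot)), format(median(tot)), format(max(tot))))
  if (length(object@groups))
    cat("  groups:", paste(sprintf("%s=%d", names(table(object@groups)),
                                   table(object@groups)), collapse = ", "),
        "\n")
})

#' Construct a CommunityTable
#'
#' @param counts Matrix (samples x species) or a named list of per-sample
#'   count vectors as returned by [readAbundance()]; list entries are
#'   aligned on the union of species, absent species getting 0.
#' @param groups Optional named character vector sample -> group.
#' @return A [CommunityTable-class] object.
#' @export
communityTable <- function(counts, groups = NULL) {
  if (is.list(counts) && !is.matrix(counts)) {
    species <- sort(unique(unlist(lapply(counts, names))))
    m <- matrix(0, length(counts), length(species),
                dimnames = list(names(counts), species))
    for (s in names(counts)) m[s, names(counts[[s]])] <- counts[[s]]
    counts <- m
  }
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  g <- as.character(groups %||% character(0))
  names(g) <- names(groups %||% character(0))
  obj <- new("CommunityTable", counts = counts, groups = g)
  validObject(obj)
  obj
}

#' Counts accessor
#' @param x A [CommunityTable-class] object.
#' @return The samples x species count matrix.
#' @export
setGeneric("speciesCounts", function(x) standardGeneric("speciesCounts"))

#' @rdname speciesCounts
setMethod("speciesCounts", "CommunityTable", function(x) x@counts)

#' Sample grouping accessor
#' @param x A [CommunityTable-class] object.
#' @return Named character vector sample -> group (aligned to sample order).
#' @export
setGeneric("sampleGroups", function(x) standardGeneric("sampleGroups"))

#' @rdname sampleGroups
setMethod("sampleGroups", "CommunityTable", function(x) {
  if (!length(x@groups)) return(character(0))
  x@groups[rownames(x@counts)]
})

#' Read one sample's species abundances from a classifier report
#'
#' Supported dialects: `bracken` (columns `name`, `taxonomy_id`,
#' `taxonomy_lvl`, `kraken_assigned_reads`, `added_reads`, `new_est_reads`,
#' `fraction_total_reads`; species-level rows only, counts from
#' `new_est_reads`), `kaiju` (columns `file`, `percent`, `reads`,
#' `taxon_id`, `taxon_name`), and `tsv` (two columns `taxid`, `count`,
#' header optional).  Duplicate taxids are summed with a warning.
#'
#' @param file Path to the report.
#' @param dialect One of `"bracken"`, `"kaiju"`, `"tsv"`.
#' @return Named integer vector taxid -> count.
#' @export
readAbundance <- function(file, dialect = c("bracken", "kaiju", "tsv")) {
  dialect <- match.arg(dialect)
  if (dialect == "tsv") {
    first <- strsplit(readLines(file, n = 1L), "\t")[[1L]]
    hasHeader <- is.na(suppressWarnings(as.numeric(first[2L])))
    tab <- read.delim(file, header = hasHeader, stringsAsFactors = FALSE)
    if (ncol(tab) < 2L) stop("tsv dialect needs two columns", call. = FALSE)
    ids <- tab[[1L]]; cnt <- tab[[2L]]
  } else if (dialect == "bracken") {
    tab <- read.delim(file, stringsAsFactors = FALSE)
    need <- c("taxonomy_id", "taxonomy_lvl", "new_est_reads")
    if (!all(need %in% names(tab)))
      stop(sprintf("bracken report missing column(s): %s",
                   paste(setdiff(need, names(tab)), collapse = ", ")),
           call. = FALSE)
    tab <- tab[tab$taxonomy_lvl == "S", ]
    ids <- tab$taxonomy_id; cnt <- tab$new_est_reads
  } else {
    tab <- read.delim(file, stringsAsFactors = FALSE)
    need <- c("taxon_id", "reads")
    if (!all(need %in% names(tab)))
      stop(sprintf("kaiju table missing column(s): %s",
                   paste(setdiff(need, names(tab)), collapse = ", ")),
           call. = FALSE)
    ids <- tab$taxon_id; cnt <- tab$reads
  }
  cntNum <- suppressWarnings(as.numeric(cnt))
  if (anyNA(cntNum) || any(cntNum != round(cntNum)))
    stop("non-integer count in abundance report", call. = FALSE)
  ids <- as.character(as.integer(ids))
  if (anyDuplicated(ids)) {
    warning("duplicate taxids in report; counts summed")
    agg <- tapply(cntNum, ids, sum)
    out <- as.integer(agg)
    names(out) <- names(agg)
  } else {
    out <- as.integer(cntNum)
    names(out) <- ids
  }
  out[order(as.integer(names(out)))]
}

#' Read a merged multi-sample count matrix
#' @param file TSV with species taxids as rows and samples as columns.
#' @return Samples x species matrix.
#' @export
readCommunityMatrix <- function(file) {
  tab <- read.delim(file, row.names = 1L, check.names = FALSE)
  t(as.matrix(tab))
}

#' Read a sample -> group metadata table
#' @param file TSV with columns `sample` and `group` (header required).
#' @return Named character vector sample -> group.
#' @export
readGroups <- function(file) {
  tab <- read.delim(file, stringsAsFactors = FALSE)
  g <- as.character(tab[[2L]])
  names(g) <- as.character(tab[[1L]])
  g
}

#' Zero out species below a relative-abundance threshold
#'
#' Per sample, species whose relative abundance is strictly below
#' `threshold` are set to 0 (a species exactly at the threshold is kept);
#' species that become zero everywhere are dropped from the table.
#'
#' @param table A [CommunityTable-class] object.
#' @param threshold Fraction in `[0, 1)`; default 0.001 (0.1%).
#' @return A filtered [CommunityTable-class].
#' @export
filterRelativeAbundance <- function(table, threshold = 0.001) {
  stopifnot(threshold >= 0, threshold < 1)
  m <- table@counts
  tot <- rowSums(m)
  keepMask <- m / ifelse(tot > 0, tot, 1) >= threshold
  m[!keepMask] <- 0
  empty <- rowSums(m) == 0 & tot > 0
  if (any(empty))
    warning(sprintf("sample(s) emptied by filtering: %s",
                    paste(rownames(m)[empty], collapse = ", ")))
  m <- m[, colSums(m) > 0, drop = FALSE]
  communityTable(m, if (length(table@groups)) table@groups else NULL)
}

#' Rarefy each sample to a common depth
#'
#' Subsamples every sample without replacement (multivariate hypergeometric)
#' to exactly `depth` reads; the default depth is the smallest sample total.
#'
#' @param table A [CommunityTable-class] object.
#' @param depth Target depth; must not exceed any sample total.
#' @param seed Integer seed (required; rarefaction is a logged, reproducible
#'   step).
#' @return A rarefied [CommunityTable-class].
#' @export
rarefyTable <- function(table, depth = NULL, seed) {
  m <- table@counts
  tot <- rowSums(m)
  depth <- depth %||% min(tot)
  low <- tot < depth
  if (any(low))
    stop(sprintf("depth %d exceeds total of sample(s): %s", depth,
                 paste(rownames(m)[low], collapse = ", ")), call. = FALSE)
  # depths are validated above; rrarefy's remaining warning (a heuristic
  # about count magnitudes) does not apply here
  r <- withSeed(seed, suppressWarnings(vegan::rrarefy(m, depth)))
  communityTable(r, if (length(table@groups)) table@groups else NULL)
}
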