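# End-to-end analysis pipelines: filter -> rarefy -> metrics -> null tests.
# Defaults are pinned to the method's stated analysis settings: 0.1%
# relative-abundance filter, rarefaction to the smallest community, 999
# permutations, 5% dispersion percentile, Holm adjustment.

.pipelineHeader <- function(tree, table, seed, nPerm, depth) {
  c(sprintf("# phylograft %s", as.character(utils::packageVersion("phylograft"))),
    sprintf("# tree_hash=%s", strHash(writeNewick(tree))),
    sprintf("# table_hash=%s",
            strHash(apply(table@counts, 1L, paste, collapse = ","))),
    sprintf("# seed=%d n_perm=%d rarefaction_depth=%d", seed, nPerm, depth))
}

.writeTsv <- function(df, file, header) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(header, con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Alpha-diversity pipeline with dispersion null tests
#'
#' Filters species below the relative-abundance threshold, rarefies every
#' sample to the smallest community, computes species-based and
#' phylogeny-based alpha metrics, and runs a tip-shuffling dispersion test
#' per sample for both weighted MPD and weighted Faith.  The metacommunity
#' defaults to the union of species observed across all samples.
#'
#' @param table A [CommunityTable-class] object (species = tip labels of
#'   `tree`).
#' @param tree An `ape::phylo` tree covering all species in `table`.
#' @param metacommunity Species pool for tip shuffling; default the union
#'   of species present in any sample after filtering.
#' @param threshold Relative-abundance filter (default 0.001).
#' @param depth Rarefaction depth (default: smallest sample total).
#' @param nPerm Shuffles per dispersion test (default 999).
#' @param seed Master seed driving rarefaction and all null tests.
#' @param outDir Optional output directory for TSV reports.
#' @return List: `alpha` (per-sample metric table), `dispersion` (per
#'   sample x metric: observed, percentile, call), `nulls` (named list of
#'   null-value vectors), `table` (the filtered, rarefied table).
#' @export
runAlphaPipeline <- function(table, tree, metacommunity = NULL,
                             threshold = 0.001, depth = NULL, nPerm = 999,
                             seed = 1L, outDir = NULL) {
  filt <- filterRelativeAbundance(table, threshold)
  rare <- rarefyTable(filt, depth, seed = seed)
  m <- rare@counts
  metacommunity <- metacommunity %||% colnames(m)[colSums(m) > 0]
  .congruence(tree, metacommunity)
  alpha <- alphaDiversity(rare, tree)
  metrics <- c("weighted_mpd", "weighted_faith")
  seeds <- childSeeds(seed, nrow(m) * length(metrics))
  rows <- list(); nulls <- list()
  k <- 0L
  for (metric in metrics) {
    for (i in seq_len(nrow(m))) {
      k <- k + 1L
      cnt <- m[i, m[i, ] > 0]
      if (length(cnt) < 2L) next
      res <- alphaDispersionTest(tree, cnt, metric = metric,
                                 metacommunity = metacommunity,
                                 nPerm = nPerm, seed = seeds[k])
      rows[[k]] <- data.frame(sample = rownames(m)[i], metric = metric,
                              observed = res@observed,
                              percentile = res@percentile,
                              call = res@call, stringsAsFactors = FALSE)
      nulls[[sprintf("%s.%s", rownames(m)[i], metric)]] <- res@nullValues
    }
  }
  disp <- do.call(rbind, rows)
  rownames(disp) <- NULL
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    hdr <- .pipelineHeader(tree, rare, seed, nPerm, min(rowSums(m)))
    .writeTsv(alpha, file.path(outDir, "alpha_diversity.tsv"), hdr)
    .writeTsv(disp, file.path(outDir, "alpha_dispersion.tsv"), hdr)
    nv <- data.frame(test = rep(names(nulls), lengths(nulls)),
                     null_value = unlist(nulls, use.names = FALSE))
    .writeTsv(nv, file.path(outDir, "alpha_null_values.tsv"), hdr)
  }
  list(alpha = alpha, dispersion = disp, nulls = nulls, table = rare)
}

#' Beta-diversity pipeline with free and tip-shuffle PERMANOVA
#'
#' Filters and rarefies the table, computes the four distance matrices
#' (Bray-Curtis and UniFrac, weighted and unweighted), runs free-permutation
#' PERMANOVA on all four and tip-shuffle PERMANOVA on the two UniFrac
#' matrices, and (for significant overall tests with more than two groups)
#' Holm-adjusted pairwise post hoc tests.
#'
#' @inheritParams runAlphaPipeline
#' @param groups Group labels; default from `table`.
#' @return List: `distances` (named list of `dist`), `permanova` (data.frame
#'   with metric, weighting, permutation mode, Df, SS, MS, F, R2, p),
#'   `pairwise` (named list of post hoc tables), `table`.
#' @export
runBetaPipeline <- function(table, tree, groups = NULL, threshold = 0.001,
                            depth = NULL, nPerm = 999, seed = 1L,
                            outDir = NULL) {
  filt <- filterRelativeAbundance(table, threshold)
  rare <- rarefyTable(filt, depth, seed = seed)
  groups <- groups %||% sampleGroups(rare)
  if (!length(groups)) stop("no group labels available", call. = FALSE)
  m <- rare@counts
  .congruence(tree, colnames(m)[colSums(m) > 0])

  specs <- list(
    bray_w   = list(metric = "bray_curtis", weighted = TRUE),
    bray_u   = list(metric = "bray_curtis", weighted = FALSE),
    unifrac_w = list(metric = "unifrac", weighted = TRUE),
    unifrac_u = list(metric = "unifrac", weighted = FALSE))
  dists <- lapply(specs, function(s)
    betaDistanceMatrix(rare, tree, metric = s$metric,
                       weighted = s$weighted))
  seeds <- childSeeds(seed + 1L, 2L * length(specs))
  rows <- list(); pairwise <- list()
  k <- 0L
  for (nm in names(specs)) {
    k <- k + 1L
    s <- specs[[nm]]
    modes <- if (s$metric == "unifrac") c("free", "tipshuffle") else "free"
    for (mode in modes) {
      res <- if (mode == "free")
        permanovaFreeTest(dists[[nm]], groups, nPerm = nPerm,
                          seed = seeds[k])
      else
        permanovaTipShuffleTest(tree, rare, groups, weighted = s$weighted,
                                nPerm = nPerm,
                                seed = seeds[length(specs) + k])
      tb <- res@table
      rows[[paste(nm, mode)]] <- data.frame(
        metric = s$metric, weighted = s$weighted, mode = mode,
        Df = tb$Df[1L], SumOfSqs = tb$SumOfSqs[1L],
        MeanSqs = tb$MeanSqs[1L], F = tb$F[1L], R2 = tb$R2[1L],
        p = tb$p[1L], stringsAsFactors = FALSE)
      if (tb$p[1L] <= 0.05 && length(unique(groups)) > 2L) {
        pairwise[[paste(nm, mode)]] <- if (mode == "free")
          pairwisePermanova(dists[[nm]], groups, mode = "free",
                            nPerm = nPerm, seed = seeds[k])
        else
          pairwisePermanova(rare, groups, mode = "tipshuffle", tree = tree,
                            weighted = s$weighted, nPerm = nPerm,
                            seed = seeds[length(specs) + k])
      }
    }
  }
  perm <- do.call(rbind, rows)
  rownames(perm) <- NULL
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    hdr <- .pipelineHeader(tree, rare, seed, nPerm, min(rowSums(m)))
    .writeTsv(perm, file.path(outDir, "permanova.tsv"), hdr)
    for (nm in names(dists))
      .writeTsv(data.frame(sample = labels(dists[[nm]]),
                           as.matrix(dists[[nm]]), check.names = FALSE),
                file.path(outDir, sprintf("dist_%s.tsv", nm)), hdr)
    for (nm in names(pairwise))
      .writeTsv(pairwise[[nm]],
                file.path(outDir,
                          sprintf("pairwise_%s.tsv", gsub(" ", "_", nm))),
                hdr)
  }
  list(distances = dists, permanova = perm, pairwise = pairwise,
       table = rare)
}
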