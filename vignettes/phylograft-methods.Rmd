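---
title: "Grafting classified species onto reference phylogenies: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grafting classified species onto reference phylogenies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phylograft)
```

## Why taxonomy-guided grafting

Phylogeny-aware diversity metrics need every community member on the tree.
Classifier reports and reference phylogenies never line up exactly: the
classifier's database and the tree's genome set differ, taxids get merged
or retired, and sub-species entries must be collapsed. The usual options —
dropping unmatched species or re-estimating a tree from marker genes — are
either lossy or expensive. phylograft takes the third route: each missing
species is attached where its *taxonomy* says it belongs. Placement is
purely taxonomic; no alignment or likelihood placement is attempted, and no
branch lengths are re-estimated. The result is deliberately modest — a
pendant tip at a rank-determined node — but it is deterministic, fast, and
makes the tree exactly congruent with the community table, which is the
precondition for everything downstream.

## The placement model

For a query species $q$ with canonical lineage $(q_\text{species},
q_\text{genus}, \dots, q_\text{superkingdom})$, the **mapping rank** is the
lowest rank $r$ at which some reference tip shares $q_r$. The tips sharing
$q_r$ span a subtree with root $m$ (their MRCA); $q$ becomes a new child of
$m$ with pendant length

$$\ell(q) = \frac{1}{|T|}\sum_{t \in T} d(m, t),$$

the mean distance from $m$ to the retained candidate tips $T$. The intent:
absent better information, the new species is as far from the shared
ancestor as its relatives are on average, so it neither shortens nor
inflates the local branch-length scale.

Choices the model leaves open, and what this package does:

* **Outlier candidates.** Reference annotations are imperfect; a stray tip
  mislabeled into a genus would drag the MRCA toward the root and distort
  the pendant. Candidates whose distance to the candidate MRCA exceeds the
  Tukey fence ($Q_3 + 1.5\,\mathrm{IQR}$, type-7 quantiles) are dropped
  before the MRCA and pendant are computed. A scale-free quartile rule
  needs no tuning constant with units. It arms itself only at $\ge 4$
  candidates (quartiles of three points are not meaningful), keeps ties at
  the fence, and backs off entirely if it would remove everything. Outliers
  are removed first, then the MRCA of the retained set is taken.
* **Single-candidate degeneracy.** With one candidate tip the literal rule
  would graft a zero-length child of a tip. Instead the query attaches at
  the candidate's parent with the candidate's own branch length, and the
  placement is flagged in the summary.
* **Batch semantics.** All placements are computed against the unmodified
  tree, then applied at once; queries mapping to the same node form a
  polytomy. Insertion order therefore cannot influence the result, and
  grafting never changes any distance among pre-existing tips.
* **Duplicate genomes.** Reference trees often carry several genomes per
  species. Deduplication (keep the lexicographically smallest tip label)
  happens *before* candidate search, so candidate counts are species
  counts.
* **Superkingdom matches** graft at the tree root — the natural limit of
  the rule; queries sharing no rank at all are reported as unplaceable,
  never fatal.

Taxonomy handling follows NCBI taxdump conventions: merged IDs are
redirected (and logged in the change file), deleted and unknown IDs are
distinct signalled conditions, sub-species ranks (strain, subspecies, ...)
are promoted to their species ancestor, and non-canonical intermediate
ranks are skipped. The seven canonical ranks are a total order, which the
lowest-shared-rank scan requires. A non-canonically-ranked node with no
species ancestor gets a partial lineage if it has canonical ancestors
(it is then a clade above species) and is rejected as lineage-incomplete
otherwise; the taxdump format does not distinguish these cases explicitly,
so this is the package's reading.

## Diversity metrics

With counts $a_i$, abundances $p_i = a_i/\sum a$, patristic distances
$d_{ij}$ and community-subtree edges $b$ with lengths $\ell_b$:

* Shannon uses the natural logarithm; Simpson is reported in complement
  form $1-\sum p_i^2$. Both are conventions, stated here because downstream
  comparisons care.
* Faith's PD is the spanning-subtree length; the edge above the subtree
  root is excluded, so a single-species community has PD 0 and MPD is
  undefined there (an error at the metric level, `NA` in tables).
* Weighted Faith: $PD_w = E \cdot \sum_b \ell_b \bar A_b / \sum_b \bar
  A_b$ with $\bar A_b$ the mean count over tips below $b$ and $E$ the edge
  count of the community subtree. The factor $E$ makes the uniform limit
  exact: equal abundances give $PD_w = PD$, the identity the test suite
  checks on 200 random trees. $\bar A_b$ uses raw counts — any rescaling
  cancels.
* Weighted MPD: $\sum_{i<j} d_{ij} a_i a_j / \sum_{i<j} a_i a_j$ over
  distinct pairs. (picante's abundance-weighted MPD also counts $i=j$
  weight terms in the denominator; the two agree after the exact algebraic
  conversion, which a test verifies.)
* UniFrac is computed edge-wise over the supplied tree with $P_b(s)$ the
  proportion of sample $s$ on tips below $b$: weighted
  $\sum_b \ell_b |P_b(x)-P_b(y)|$, unweighted the unique-over-either
  branch-length ratio. The weighted form defaults to *non-normalized*
  (values can exceed 1); a `normalized` flag divides by
  $\sum_b \ell_b (P_b(x)+P_b(y))$. Non-normalized is the default because
  it is what the surrounding PERMANOVA machinery consumes, where only
  relative magnitudes matter.

## Null models and inference

**Dispersion.** The tree is pruned to the metacommunity (default: the
union of species observed across samples), the observed metric computed,
and tip labels shuffled `nPerm` times. The lower-tail percentile
$(\#\{null \le obs\}+1)/(n_{perm}+1)$ can never be 0; at or below 5% the
sample is called under-dispersed, at or above 95% over-dispersed. The
one-sided 5% rule is the package's reporting convention; two-sided
interpretation is left to the user.

**PERMANOVA.** $SS_{total} = \frac1N \sum_{i<j} d_{ij}^2$, within-group
sums weighted by $1/n_g$, $F = (SS_A/(k-1))/(SS_W/(N-k))$. Two permutation
schemes: *free* (group labels shuffled; tests any compositional
difference) and *tip-shuffle* (the phylogeny pruned to the observed
species is relabeled and the whole UniFrac matrix recomputed; community
data and groups never move). Tip-shuffle asks a sharper question — does
the separation depend on actual relatedness? — and controls the type-I
inflation that arises when free permutation is applied to
phylogenetically structured metrics. Note that on non-Euclidean
dissimilarities (UniFrac is one) $SS_A$ can come out slightly negative on
null data, so permuted $R^2$ values may dip below 0; that is a property of
pseudo-F, not a defect. Post hoc pairwise tests run per group pair on the
pair's sub-matrix with `nPerm` permutations each and Holm adjustment
across pairs.

**Seeds.** Every test takes one master seed from which per-permutation
child seeds are drawn, so results are reproducible and permutations could
be evaluated in any order. Rarefaction takes a required seed for the same
reason.

Numerical care: tied null and observed statistics must count as ties even
when permuted arithmetic reorders floating-point sums, so exceedance
counts use a relative tolerance of $10^{-9}$. Without it, a star tree —
where every tip shuffle yields the identical distance matrix — would
report p slightly below 1 instead of exactly 1.

## Community tables

Bracken (species-level rows, `new_est_reads`), Kaiju (`taxon_id`,
`reads`) and generic two-column TSVs are read into taxid → count vectors;
duplicate taxids are summed with a warning. The relative-abundance filter
(default 0.1%) zeroes species *strictly below* the threshold per sample —
the boundary is kept, a choice the format descriptions leave open —
and runs *before* rarefaction. Rarefaction subsamples without replacement
(multivariate hypergeometric, via `vegan::rrarefy`) to the smallest
community by default. Species present in a table but absent from the tree
are a hard error at analysis time: congruence is the package's premise,
and silently dropping reads would bias every metric.

## What the synthetic generator emulates — and what it does not

`simulateTree()` builds trees by random bifurcating joins nested inside a
taxonomic hierarchy (genera inside families inside orders ...), so every
taxon of every rank is monophyletic by construction — the ground truth the
grafting tests need. Branch-length scale doubles per rank level above
genus (`depthScaling = 2`), keeping genera shallow relative to deep
splits, the shape real reference phylogenies have and the regime in which
clade-restricted communities are genuinely under-dispersed.
`simulateTaxonomy()` re-derives the clades by repeatedly splitting the
largest clade at its root, assigns fresh taxids, and can deliberately swap
tips to create incongruence for stress-testing the outlier filter.
`simulateCommunities()` draws each clustered sample's species from one
genus (log-normal counts, default median ≈ 200 reads, shape σ = 1,
emulating the dominance patterns of real metagenomes) or uniformly at
random.

What passing tests on these data do **not** show: real trees are not
perfectly congruent with the NCBI taxonomy (paraphyletic genera are
common, and grafting then depends on the outlier filter's judgment); real
communities have uneven richness, shared species across samples, and
compositional noise the log-normal draw does not model; and real taxdumps
contain homonyms and name-level ambiguity this package sidesteps by
requiring numeric IDs on input.

The validation studies run at fixed, stated sizes: 200 leave-one-out
cases on trees of 32–64 tips with four-species genera (three remaining
congeners keep the outlier fence inactive, the regime in which the
mean-congener-distance identity is exact); 500 null replicates at 199
permutations for type-I calibration; 20 samples at 999 shuffles for
dispersion detection.

## Known limitations

* Placement resolution is bounded by the taxonomy: congeners placed by
  rank, not sequence, carry no signal about within-genus branching, and a
  set of taxa grafted at one node forms an unresolved polytomy.
* Pendant lengths are averages; rate heterogeneity within the candidate
  subtree is ignored, and no smoothing is attempted.
* The exact outlier statistic used by other implementations of this idea
  is not standardized; the Tukey fence here is a documented, testable
  choice, not the only defensible one.
* Holm adjustment is implemented exactly as defined (step-down, running
  maximum, capped at 1). In particular the largest-rank p-value gets
  multiplier 1 and is left unchanged when below 1; conventions that round
  near-1 values up to exactly 1 are not step-down Holm and are not
  matched here.
* Trees are rooted throughout and the reference root is trusted; there is
  no re-rooting, no unrooted-tree support.
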