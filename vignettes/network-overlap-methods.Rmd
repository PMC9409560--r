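---
title: "Methods: interactome overlap between disease genes and drug targets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: interactome overlap between disease genes and drug targets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The scientific question

Given a disease's risk genes (set A) and the targets of the drugs used to
treat it (set B), netoverlap asks two related questions. First, do the sets
overlap more than chance as plain lists? Second — because most risk genes
are not themselves targets — do the two sets occupy the *same neighbourhood*
of the protein–protein interaction (PPI) network, so that drugs act on the
disease module even where they miss the risk genes proper? The package
implements the standard network-medicine toolkit for both questions,
together with cell-type localisation of the joint network via single-cell
expression.

All graph machinery operates on an undirected simple graph over gene
symbols (igraph underneath); distances are unweighted hop counts, since PPI
edge lists carry no meaningful weights. Gene matching is case-sensitive
exact match after whitespace trimming, with an optional force-to-uppercase
at load time — symbol case conventions differ between species (human
`GABRA1`, mouse `Gabra1`), so silent case folding would corrupt
human–mouse workflows; the ortholog mapper exists for that conversion and
keeps only one-to-one pairs, because 1:many ortholog assignments have no
defensible automatic resolution.

# Set overlap

`fisher_overlap()` builds the 2×2 table of memberships over a background
universe and reports the two-sided Fisher exact p (the point-probability
rule, i.e. the sum of all table probabilities at the observed margins not
exceeding the observed one). Two design points deserve note:

* **The universe is an explicit input**, either a gene list or an integer
  (e.g. 20,000 for the protein-coding genome). Overlap significance is
  meaningless without it, and no universally correct default exists; for
  network-derived queries the natural choice is the interactome's gene set.
* **The odds ratio reported is the sample OR** `ad/bc`, with the
  conditional-MLE estimate (what `fisher.test()` prints) as a second field.
  The two differ slightly at extreme tables and published ORs rarely state
  which estimator they used, so both are exposed. `b·c = 0` yields `Inf`,
  reported as such rather than floored.

P-values below `.Machine$double`'s comfortable range are reported at full
precision, never floored at 2.2e-16.

`gmt_enrichment()` applies the same machinery one-sidedly: upper-tail
hypergeometric `P(X ≥ overlap)` per GMT set, BH-FDR and Bonferroni columns
over the tested collection. Adjustment is delegated to `p.adjust()`;
brute-force re-derivations exist in the test suite as oracles only.

# Topology of an induced subnetwork

`topology_metrics()` characterises the subgraph induced by a gene set with
seven parameters. The non-obvious conventions:

* **Mean degree is `E/N`**, edges per mapped node, not the usual `2E/N`.
  On a disconnected 235-node module with 247 edges this is the only
  convention producing a mean degree near 1; `degree_convention =
  "2E_over_N"` switches to the textbook definition.
* **Closeness** uses the Wasserman–Faust component-scaled form
  `((r−1)/(n−1)) · ((r−1)/Σd)` with `r` the node's reachable count. Induced
  disease modules are almost always disconnected, and this is the standard
  closeness generalisation that neither discards unreachable nodes nor
  returns 0/Inf artifacts; isolated nodes score 0.
* **Mean shortest distance** averages over *connected* unordered pairs
  within the induced subgraph, the only convention finite on disconnected
  modules; it is `NA` when no pair connects.
* **Clustering** is the mean local clustering coefficient with degree-<2
  nodes contributing 0 (so the mean is over all mapped nodes, not only
  closed-triple candidates).
* **Betweenness** is normalised by `(n−1)(n−2)/2`, endpoints excluded, and
  averaged over nodes.

# Localization permutation test

`localization_test()` draws `n_perm` node sets of size `|genes ∩ nodes|`
uniformly without replacement from all interactome nodes and recomputes the
seven metrics per draw. The p-value is the plain empirical fraction
`r/n_perm` with ties counted toward rejection — the conservative convention,
and the only one that can produce the `p = 0.000` a permutation report
prints when no random draw reaches the observed value. A
`pseudocount = TRUE` option gives `(r+1)/(n_perm+1)` for users who prefer
never-zero p-values. Sampling is uniform rather than degree-matched (the
null hypothesis is "an arbitrary same-size gene set"); `sampling =
"degree_binned"` offers a degree-decile-matched null for sensitivity
analysis. One seeded generator drives all replicates in sequence, making
runs bit-reproducible.

Directionality: all metrics reject through the `greater` tail except mean
shortest distance, where localization means *smaller* distances. Replicates
with no connected pair have undefined mean shortest distance and are
treated as `+Inf` — never evidence of localization — with their count
reported. A power caveat at small scale: on a sparse background, random
induced subgraphs contain almost no connected pairs beyond direct edges, so
their mean shortest distance concentrates near 1 and the `less`-tail test
has little power even for genuinely compact modules. On dense genome-scale
interactomes (mean degree in the tens) random sets reach distances well
above 1 and the test discriminates as intended.

# Network proximity (separation)

`module_distance()` implements the nearest-neighbour convention: every
mapped gene contributes its hop distance to the closest member of the other
set; for the within-set distances `d_A`, `d_B` the closest *other* member.
`separation()` is then exactly `s_AB = d_AB − (d_A + d_B)/2`, the standard
network-separation score; negative values mean the sets interleave on the
network. An `all_pairs` convention (plain mean over cross pairs) is
available, but nearest-neighbour is the default because the separation
formula is defined in those terms.

Distances are computed on the interactome's largest connected component
(LCC): restricting to the LCC is the conventional way to avoid undefined
cross-component distances, and genome-scale interactomes are ~99% one
component. Edge cases pinned down deliberately:

* A gene present in both sets counts at distance 0 in `d_AB`
  (`cross_self = "exclude"` applies the other-member rule across sets too).
* When A and B are *equal as sets*, the other-member rule is applied
  symmetrically so that `s_AB(A, A) = 0` identically — a set cannot be
  separated from itself.
* A singleton set has within-set distance 0.

`proximity_test()` permutes by drawing random node sets of the mapped sizes
independently (they may overlap, as real A and B do) uniformly from LCC
nodes, and reports the one-sided `P(random s_AB ≤ observed)`, ties
inclusive. The implementation precomputes the full LCC distance matrix when
the LCC has ≤ 4000 nodes (a few MB; permutation replicates then reduce to
matrix subsetting) and falls back to per-replicate BFS beyond that.

# Expression-weighted cell-type enrichment

`specificity_matrix()` condenses an annotated genes × cells matrix to genes
× cell types: mean expression per type, row-normalised so each gene's
specificities sum to 1. The statistic `ewce_test()` bootstraps is the *sum*
of specificities of the query genes per cell type (equivalent to the mean,
since query size is fixed); each bootstrap draws the same number of genes
uniformly without replacement from the background — by default all genes in
the specificity matrix, restrictable via `background=`. The per-type
p-value is the plain inclusive fraction of bootstraps at or above the
observed statistic, Bonferroni-corrected across cell types. Specificity is
invariant to global rescaling of expression, so counts, CPM or any
proportional normalisation give identical results. Transcript-length or
GC-controlled sampling, as in more elaborate EWCE implementations, is out
of scope here.

# Synthetic data and what the tests demonstrate

The generators in `sim_config()` / `simulate_*()` produce every input with
known ground truth:

* **Interactome**: Erdős–Rényi (default `p = 4e-4` on 10,000 nodes, mean
  degree 4 — sparse like curated physical-interaction networks),
  Barabási–Albert (m-seed construction, exactly `(n−m)m` edges,
  degree-skewed), or duplication–divergence (the classic PPI growth model).
* **Planted module**: a snowball (random-walk) sample — started inside the
  host LCC so the module lives where LCC-restricted distances are measured,
  and connected by construction — with internal edges added at
  `module_edge_prob = 0.3`, an order of magnitude above background density.
* **Overlapping sets**: two sets carved from one planted module with a
  controlled number of shared genes; their expected `s_AB` is negative and
  decreases with sharing.
* **Expression**: negative-binomial counts (`mu = 2`, `theta = 2`, the
  standard overdispersed scRNA-seq model) over 4 cell types × 100 cells,
  with 40 disjoint marker genes per type at 5× baseline mean —
  `marker_fold = 1` gives a structureless null.
* **GMT**: one planted set containing 80% of a query plus 49 random sets.

Test and validation runs use scaled-down instances chosen as the smallest
sizes at which each property is comfortably identifiable: oracle
equivalence on graphs ≤ 30 nodes against O(n³) brute-force
reimplementations; null calibration at 200 trials × 200 permutations
(Kolmogorov–Smirnov distance ≤ 0.15 — sampling noise `1/√200 ≈ 0.07` plus
permutation-grid discreteness — and an exact-binomial 99% band on the
fraction below 0.05, tracked on continuous-valued statistics: closeness for
localization, `s_AB`, and the EWCE sum); and planted-structure recovery on
2000-node backgrounds at 500–1000 permutations. Calibration for
count-valued metrics such as `all_edges` is conservative by construction
(heavy ties under a sparse null push empirical p toward 1), which is the
expected behaviour of inclusive-tie empirical p-values, not an artifact.

What passing these tests does *not* show: the generators emulate none of
the degree correlations, study bias (well-studied genes have more recorded
interactions), or annotation incompleteness of real interactomes, nor
batch effects, doublets or library-size variation in real scRNA-seq. Results
on real data inherit those biases — notably, uniform (non-degree-matched)
permutation nulls are anti-conservative for high-degree gene sets, which is
why the degree-binned sampling option exists.

# Bundled gene lists

`inst/extdata/` ships small plain-text lists for the worked examples: the
published 17-gene risk/target overlap and 22-gene co-expression-network
overlap are real published symbols, embedded in *synthetic stand-in* lists
(`synthetic_*.txt`, filler symbols `RVG*`/`CVG*`/`DTG*`) sized to the
published list sizes (102 + 16 = 118 risk genes, 151 targets) and
constructed so every published intersection is reproduced exactly. They
demonstrate the set-overlap machinery; they are not the original
supplementary tables.

# Known limitations

* Permutation and bootstrap p-values are granular at `1/n_perm`; with the
  plain-fraction rule, `p = 0` means "beyond resolution", not zero.
* The uniform localization null ignores degree; use `degree_binned` for
  hub-heavy gene sets.
* `proximity_test`'s full-matrix fast path assumes the LCC fits in memory
  (~130 MB at the 4000-node cutoff); larger graphs pay per-replicate BFS.
* EWCE here uses the plain uniform bootstrap; expression-level-matched
  nulls are not implemented.
* All analyses treat the interactome as static and unweighted; confidence
  scores, tissue specificity and directionality are out of scope.
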