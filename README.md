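# netoverlap

Network-medicine analysis of the relationship between two gene sets on a
protein–protein interaction (PPI) network — built around the question of
whether the risk genes of a disease and the targets of the drugs that treat
it occupy the same neighbourhood of the interactome. The motivating use case
is epilepsy: do anti-epileptic drug targets overlap epilepsy risk genes, in
plain set terms and in network terms?

The package implements five complementary analyses:

1. **Gene-set overlap** — Fisher's exact test on the 2×2 membership table of
   two gene sets over a background universe, with the sample odds ratio
   `ad/bc`.
2. **Network localization** — the seven topological parameters of the
   subgraph induced by a gene set (edge count, largest connected component,
   mean degree `E/N`, Wasserman–Faust closeness, mean shortest distance over
   connected pairs, mean local clustering, normalized betweenness), each
   tested against random node sets of equal size: empirical
   `p = #(random ≥ observed) / n_perm` (ties inclusive; the `less` tail for
   mean shortest distance).
3. **Network proximity** — the separation score
   `s_AB = d_AB − (d_A + d_B)/2`, where `d_A`, `d_B` are mean
   nearest-neighbour distances within each set and `d_AB` between sets, all
   on the interactome's largest connected component; significance from a
   permutation null of equally sized random node sets, one-sided toward
   negative separation (= interactome overlap).
4. **Gene-set (GMT) enrichment** — upper-tail hypergeometric tests of a
   query list against a GMT collection, with BH-FDR and Bonferroni columns.
5. **Expression-weighted cell-type enrichment (EWCE)** — a specificity
   matrix from annotated single-cell expression (each gene's mean expression
   per cell type, row-normalised), and a bootstrap test of whether a gene
   list's summed specificity in each cell type exceeds that of random
   same-size gene lists (Bonferroni across types).

A seeded synthetic-data module generates every input with planted ground
truth (localized modules, overlapping gene sets, cell-type markers, enriched
GMT sets), and `run_pipeline()` orchestrates all stages from one YAML
config. A thin CLI lives at `inst/cli/netoverlap.R`.

## Worked example

```r
library(netoverlap)

## synthetic interactome with a planted 60-gene module; two gene sets
## sampled from it
base <- simulate_interactome(sim_config(seed = 101, n_nodes = 2000,
                                        model_params = list(p = 0.002)))
mod <- plant_module(base, size = 60, edge_prob = 0.3, seed = 102)
set.seed(103)
A <- sample(mod$genes$genes, 30); B <- sample(mod$genes$genes, 30)

localization_test(mod$net, union(A, B), n_perm = 1000, seed = 104)
#> Network localization test: 47 mapped nodes, 1000 permutations
#>                  metric observed random_mean random_sd p_value    tail
#>               all_edges 337.0000   2.359e+00 1.604e+00   0.000 greater
#>      largest_subnetwork  47.0000   2.145e+00 6.931e-01   0.000 greater
#>             mean_degree   7.1700   5.019e-02 3.413e-02   0.000 greater
#>    closeness_centrality   0.5908   2.280e-03 1.681e-03   0.000 greater
#>  mean_shortest_distance   1.6980   1.062e+00 1.372e-01   0.893    less
#>  clustering_coefficient   0.3162   5.950e-04 5.968e-03   0.000 greater
#>  betweenness_centrality   0.0155   7.832e-06 2.927e-05   0.000 greater

proximity_test(mod$net, A, B, n_perm = 1000, seed = 105)
#> Network proximity (separation) test
#>   mapped genes: |A| = 30, |B| = 30 (nearest convention)
#>   d_A = 1.000, d_B = 1.000, d_AB = 0.567
#>   s_AB = -0.4333  (random mean -0.0715, sd 0.2104)
#>   one-sided p = 0.041  (1000 permutations)
```

The planted module is flagged as localized: its 337 internal edges dwarf the
~2.4 expected for 47 random genes (`p = 0`, i.e. no random draw reached it in
1000 permutations). The two gene sets drawn from that module separate
negatively (`s_AB = −0.43 < 0`): they sit closer to each other on the network
than within themselves, the network signature of a shared mechanism. Note
the mean-shortest-distance null on so sparse a background is dominated by
random sets whose only connected pairs are direct edges, so its `less`-tail
test has little power at this scale.

Set overlap on the bundled gene lists (synthetic stand-ins that carry the
published overlap structure — see `inst/extdata/`):

```r
fisher_overlap(
  read_gene_set(system.file("extdata", "synthetic_risk_genes.txt", package = "netoverlap")),
  read_gene_set(system.file("extdata", "synthetic_drug_targets.txt", package = "netoverlap")),
  universe = 20000)
#> Gene-set overlap (Fisher's exact test)
#>   overlap 17 | A-only 101 | B-only 134 | neither 19748 (universe 20000)
#>   sample OR = 24.805 (CMLE 24.772), two-sided p = 2.444e-17
#>   overlap genes: CACNA1A, CHRNA4, CHRNA7, GABRA1, GABRA2, GABRB2, GABRG2,
#>   GRIK1, GRIN1, GRIN2B, KCNQ2, KCNQ3, SCN1A, SCN2A, SCN3A, SCN8A, SCN9A
```

17 of 151 drug targets are risk genes — a ~25-fold enrichment over the
20,000-gene protein-coding background, far beyond any reporting floor.

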