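# GECluster

Protein complexes are groups of physically interacting proteins that show up
as dense clusters in protein–protein interaction (PPI) networks. Purely
topological clusterers work on the *static* PPI network — the union of all
interactions ever observed for an organism — and therefore cluster proteins
that are never co-expressed. GECluster instead predicts complexes from a
**condition-specific** view of the interactome:

1. **Dynamic network.** Given a time-course expression matrix, a gene is
   *active* at a time point when its expression there is at least its own
   temporal mean, `val(g, t) ≥ mean(g)`. The dynamic network keeps only
   static edges whose two endpoints are active over the selected time
   points; proteins with no expression record are dropped.
2. **Combined network.** Every protein pair sharing GO-slim annotations gets
   an edge weighted by the shared-term count `w(u,v) = |terms(u) ∩ terms(v)|`;
   dynamic PPI edges are always retained (possibly at weight 0).
3. **Seed expansion.** Seeds are visited in decreasing combined-network
   degree. A cluster grows from its seed by admitting, one at a time, the
   neighbouring candidate that (a) has **FS-Weight** functional similarity
   ≥ `FS_Weight_min` with *every* current member and (b) does not decrease
   the cluster density `Cluster_Coefficient = 2m / (n(n−1))`. FS-Weight for
   proteins *i*, *j* with closed neighbourhoods `N_i`, `N_j` is

   ```
   FS(i,j) = [2c / (|N_i−N_j| + 2c + λ_ij)] · [2c / (|N_j−N_i| + 2c + λ_ji)]
   c       = |N_i ∩ N_j|           (including i and j themselves)
   λ_ij    = max(0, N_avg − |N_i|) with N_avg the network's average degree
   ```

4. **Evaluation.** A predicted complex *P* matches a reference complex *C*
   when the matching score `M(C,P) = |C ∩ P|² / (|C|·|P|)` reaches
   `M_thres = 0.2`; complex-level `Recall = N_mc/N_c`,
   `Precision = N_mp/N_p`, `F1 = 2RP/(R+P)`.

The package also maps complex relationships across conditions (the same
matcher applied between the complex sets of successive conditions), counts
core vs. attachment proteins in predictions, computes network summary
statistics, and ships a synthetic planted-complex benchmark generator so
everything is testable offline.

Intended users: computational/systems biologists studying condition-dependent
modular organisation of interactomes (e.g. stress response time courses), and
method developers who need a reproducible complex-prediction baseline with a
controlled benchmark.

## Worked example

```r
library(GECluster)

## planted benchmark: 20 complexes (sizes 3-10) on 200 background proteins,
## within-complex edge probability 0.9, background 0.01, GO fidelity 0.9
sim <- generateSynthetic(syntheticSpec(seed = 11))

res <- runPipeline(sim$static, sim$expression, sim$annotations,
                   reference = sim$truth)

res$dynamic
#> dynamic PPINetwork: 328 nodes, 925 edges
res$combined
#> CombinedNetwork: 328 nodes, 1747 edges (822 GO-added), total weight 1117
res$predicted
#> ComplexSet: 26 complexes, sizes 3-10 (median 5.5)
res$evaluation$match
#> MatchResult (M_thres = 0.2): N_c = 20, N_p = 26, N_mc = 19, N_mp = 22
#>   Recall = 0.9500  Precision = 0.8462  F1 = 0.8951
networkStats(res$dynamic)
#> NetworkStats: 328 nodes, 925 edges, 1 component(s)
#>   clustering coefficient 0.1539, diameter 8, characteristic path length 3.8127
```

Reading: all 328 expressed proteins survive the activity filter (every
planted complex is scheduled active by default), GO-slim sharing adds 822
edges on top of the 925 PPI edges, and GECluster recovers 19 of the 20
planted complexes (one small complex fragments), with 22 of 26 predictions
matching a true complex — F1 ≈ 0.90 under 10% edge and annotation noise.

A command-line front end over the same functions is installed at
`inst/scripts/gecluster.R` (subcommands `simulate`, `build-dynamic`,
`build-combined`, `cluster`, `evaluate`, `stats`, `evolve`, `composition`,
`run-all`, `sweep`; see `--help`).

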