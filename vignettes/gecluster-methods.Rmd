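---
title: "GECluster: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{GECluster: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(GECluster)
```

This vignette is the package's own account of the method it implements:
the models, the assumptions behind them, the tunable parameters, and the
places where the design was genuinely open and a choice had to be made.

## The model

### Expression activity and the dynamic network

A static PPI network aggregates interactions detected under every
condition, so at any given moment many of its proteins are simply not
there. The dynamic-network model assumes a protein participates in
interactions only while its coding gene is *expressed above its own
baseline*: gene `g` is active at time point `t` when

```
val(g, t) >= mean(g),
```

where `mean(g)` is the arithmetic mean of `g`'s expression over all time
points of the series. Replicate columns are averaged within their time
point first, so every time point contributes equally to the mean
regardless of replicate count.

Two conventions deserve note:

* **The comparison is inclusive (`>=`, not `>`).** A perfectly flat
  profile equals its own mean everywhere; under a strict inequality every
  constitutively expressed housekeeping gene would be declared never
  active, which is biologically perverse. The inclusive rule keeps
  constant genes active at all time points.
* **Proteins without an expression record are treated as not expressed.**
  The activity rule cannot be evaluated for them, and expression
  platforms measuring only part of the proteome are precisely what makes
  dynamic networks much smaller than static ones.

`buildDynamic()` retains a protein iff it is active at *any* (default) or
*all* selected time points — the aggregation over a multi-point selection
is exposed as an explicit `mode` parameter because either reading is
defensible for multi-stage series; `any` is the default since a protein
present during part of a condition still participates in it. Edges
survive iff both endpoints are retained, and retained proteins left with
no surviving edge are dropped (an interactor-free protein cannot join any
complex; the count of such drops is recorded in the provenance report).

### GO-slim weighting and the combined network

Complex co-members overwhelmingly share high-level functional
annotations. The combined network encodes this as an integer edge weight:
for every protein pair of the dynamic network,

```
w(u, v) = | terms(u) n terms(v) |
```

over GO-slim annotations (all three aspects — BP, MF, CC — counted
alike, since coarse functional agreement is what matters at slim
resolution). Pairs with `w > 0` but no PPI edge get a new *GO-added*
edge; PPI edges with `w = 0` are **kept**, because the combined network
is a weighted *dynamic* network — annotation incompleteness should not
delete experimentally observed interactions. A pair sharing `k` terms
yields a single edge of weight `k`, never `k` parallel edges.

### FS-Weight and the density criterion

FS-Weight scores the topological plausibility that two proteins are
functionally linked, from closed neighbourhoods `N_i` (protein plus
interactors) on the **dynamic** network:

```
FS(i,j) = [2c / (d_i + 2c + l_ij)] * [2c / (d_j + 2c + l_ji)]
c    = |N_i n N_j|,  d_i = |N_i \ N_j|,
l_ij = max(0, N_avg - |N_i|),  N_avg = 2|E| / |V|.
```

The penalty `l` inflates the denominator for proteins whose neighbourhood
is smaller than the network average, damping similarity estimates built
on very little evidence; it is never negative. The score is symmetric,
lies in [0, 1], equals 1 for identical closed neighbourhoods, and is 0
when the neighbourhoods are disjoint. FS-Weight is deliberately computed
on the dynamic topology (not the combined network), because its
average-degree normalisation is defined against observed physical
interactions; GO-added edges would dilute it with annotation density.

Cluster quality is the edge density

```
Cluster_Coefficient = 2m / (n (n-1)),
```

with `m` the internal edge count and `n >= 2` the member count. `m` is
counted over **combined-network** edges (any weight, including GO-added
edges and weight-0 PPI edges), the same adjacency structure the expansion
walks; a variant counting PPI edges only can be had by passing the
dynamic network to `clusterCoefficient()`.

### The clustering algorithm

Seeds are visited in non-increasing combined-network degree (all edges
count); ties break lexicographically, which together with a fully
deterministic candidate order makes reruns byte-identical. From a seed,
the cluster repeatedly admits the first admissible candidate among the
combined-network neighbours of the current members, ordered by
(1) descending total edge weight to the current members, (2) descending
FS-Weight to the seed, (3) identifier. A candidate is admissible iff

* it has FS-Weight `>= fsMin` with **every** current member (the
  similarity test is a conjunction — one failure rejects, whatever the
  density effect), and
* the density does not decrease: `new >= old - 1e-12`.

Expansion stops when no candidate is admissible. Because the first
admitted pair is always an edge (density 1) and the density may never
decrease, emitted clusters are exactly the maximal greedy cliques of the
combined network that survive the pairwise similarity gate — GO-added
edges are what lets incompletely observed PPI cliques still close.

Two loop details are not fixed by the procedure's description and are
package choices: (1) with `overlap = FALSE` (default) the members of an
*emitted* cluster are consumed and later seeds cannot recruit them,
giving disjoint output; (2) clusters that end below `minSize` are
discarded and their members are *released* — they stay available as
later candidates and seeds, so a small failed expansion around a
peripheral seed cannot permanently orphan its proteins. Setting
`overlap = TRUE` lets assigned proteins re-join later clusters as members
(never as seeds).

### Evaluation, evolution, composition

Predicted and reference complexes match when the overlap score
`M(A,B) = |A n B|^2 / (|A||B|)` reaches `M_thres`; recall counts matched
reference complexes over all reference complexes, precision matched
predictions over all predictions, and `F1` is their harmonic mean. Before
matching, the reference is *curated* to the evaluated network: members
absent from the network are removed and complexes falling below `minSize`
are dropped, since a complex whose subunits are not expressed under the
condition is unpredictable in principle.

Cross-condition relationships reuse the same matcher between the complex
sets of different conditions (`relateComplexSets()`), with the same
`M_thres = 0.2` default — no separate threshold is introduced because no
principle distinguishes "matches the reference" from "matches the
neighbouring condition". Core/attachment composition
(`complexComposition()`) takes caller-supplied core and attachment lists
(these classifications come from curated external resources; inferring
them from topology would be a different method) and reports distinct
counts plus the per-protein complex number. No significance test is
attached to composition differences; the counts are descriptive.

Network statistics: the clustering coefficient is the mean *local*
clustering coefficient with degree < 2 nodes contributing 0; the
characteristic path length is the mean shortest-path length over
connected pairs; the **diameter is the maximum shortest-path length**.
(The alternative "average distance" reading of diameter collapses into
the characteristic path length and cannot produce a diameter three times
the path length, as real interactomes show; the max reading is the only
consistent one.) Disconnected networks report path statistics over
connected pairs plus a component count.

## Parameters

| parameter | default | units / range | why this default |
|---|---|---|---|
| `fsMin` | 0.25 | FS-Weight, [0,1] | threshold region where F1 peaks on training-style data; `sweepFsMin()` reproduces the curve |
| `minSize` | 3 | proteins | benchmark complex sets are filtered to size >= 3; pairs are not complexes |
| `mThres` | 0.2 | match score, (0,1] | the conventional complex-matching threshold in this literature |
| `mode` | `"any"` | — | a protein active during part of a condition participates in it |
| `replicatePolicy` | `"mean"` | — | triplicate designs; the mean is the obvious replicate summary |
| `overlap` | `FALSE` | — | disjoint complexes match the benchmark's structure |

## The synthetic benchmark

`generateSynthetic()` plants `nComplexes` disjoint complexes (sizes
uniform in `sizeRange`) on `nBackground` background proteins:
within-complex pairs get edges with probability `pIn`, all other pairs
with `pOut`; each complex has a private GO-slim term carried by each
member with probability `fidelity`, while background proteins draw one
decoy term from a pool of `nDecoyTerms`; expression is a two-level step
function (`highValue` during the complex's scheduled active stages,
`lowValue` otherwise, replicated `nReplicates` times per stage), so the
`>=`-mean activity rule holds *by construction* exactly during active
stages. Background expression flips between the two levels at random.
A `bgExpressedFraction < 1` omits part of the background from the
expression matrix entirely — the generator's way of scheduling proteins
"never expressed", since any gene with a record is active somewhere under
the `>=` rule. The step function rather than realistic noise is the
point: activity depends only on the value–mean relation, so a controlled
mean relation is what correctness arguments need; Gaussian noise of
configurable `noiseSd` can be overlaid.

Defaults (20 complexes of 3–10 proteins, 200 background, `pIn = 0.9`,
`pOut = 0.01`, `fidelity = 0.9`, 3 stages in triplicate) give a network
of ~330 proteins with ~10% missing within-complex edges and ~10%
unannotated members — a deliberately hard but recoverable regime.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: scale-free degree structure and hubs shared
between complexes; overlapping and nested complexes; correlated,
autocorrelated or missing expression measurements; annotation terms
shared across complexes or between complexes and background; identifier
namespace mismatches between expression and interaction data. Results on
the benchmark bound algorithmic correctness, not field performance.

## Numerical and degenerate-input choices

* The non-decrease comparison uses an absolute tolerance of `1e-12`
  ("decreased" means `new < old - 1e-12`), so exact-tie admissions are
  never lost to floating-point noise; all density values are ratios of
  small integers, so no looser tolerance is needed.
* FS-Weight returns 0 outright when the closed neighbourhoods are
  disjoint, avoiding 0/0 for isolated proteins.
* An empty network clusters to an empty complex set (not an error);
  all-inactive selections produce an empty dynamic network.
* Zero denominators in recall/precision are reported as 0 with a warning.
* Expression files with empty or non-numeric cells are rejected, not
  imputed: the activity rule needs a value at every time point.
* Writers sort members/pairs lexicographically and format numbers in a
  parse-exact form, so write–read–write chains are byte-stable.

## Problem sizes used by the test-suite

The bundled tests and the acceptance script run entirely on generated
data: benchmark networks of 130–330 proteins, oracle comparisons on
random graphs of up to 30 nodes (all pairs, 1e-12 tolerance), and
five-replicate comparisons for the dynamic-vs-static contrast. These
sizes exercise every code path while keeping a full run in the order of
two minutes.

## Known limitations

* Greedy single-candidate admission has no backtracking; a poor early
  admission can truncate a cluster (mitigated, not removed, by the
  weight-then-similarity candidate order).
* Because density starts at 1 and may not decrease, predicted complexes
  are cliques *of the combined network*; complexes that are neither
  PPI-dense nor annotation-coherent cannot be found.
* One protein, one complex (by default): moonlighting proteins are
  assigned to whichever eligible cluster's seed ranks first.
* Gene and protein identifiers are equated verbatim; no namespace
  mapping is attempted.
* GO structure is ignored beyond term identity (no ancestry, no
  information content) — intentionally, as slims are already a
  flattened ontology view.
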