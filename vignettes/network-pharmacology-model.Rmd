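---
title: "From formula components to mechanism chains: the netpharm model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From formula components to mechanism chains: the netpharm model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netpharm)
```

## The problem

A multi-component herbal formula acts on a disease through many weak,
overlapping component–target relationships. Deciding which components are
*functionally core* — and through which receptor-to-effector routes their
effect reaches the pathogenic genes — requires propagating the
component–target layer through the protein–protein interaction (PPI)
network down to the disease genes, and then compressing that large graph
to its load-bearing part. `netpharm` implements that chain as five
composable stages: ADME screening, network assembly, importance-based
space reduction, core-component selection, and cascade scoring.

## ADME screening

Components are judged by conjunction of independent rules: molecular
weight < 500 Da, H-bond donors ≤ 5, H-bond acceptors ≤ 10, rotatable
bonds ≤ 10, −2 < logP < 5 (all drug-likeness heuristics), oral
bioavailability ≥ 30 % (a practical oral-activity floor), and — when the
upstream predictor classes are present — GI absorption "high" required,
"high" hERG inhibitors removed, carcinogenicity "negative" required.

Two deliberate choices:

* **Inclusive count bounds.** The donor/acceptor/rotatable-bond rules use
  ≤, not <. The decisive case is quercetin (5 donors), a canonical active
  flavonoid that any sensible screen must keep — a strict `<5` donor rule
  would reject it while it appears in every published core-component
  selection for this formula. `adme_rules(strict = TRUE)` restores the
  strict reading for sensitivity analyses.
* **Unknown never decides.** Categorical predictor values of `"unknown"`
  skip their rule by default rather than failing it, because these values
  come from external predictors the package does not call; a missing
  prediction is not evidence of toxicity. `unknown = "fail"` is available
  for conservative screens.

## Network assembly

The C-T layer is strictly bipartite; each target carries `nc`, its count
of regulating components. Pathogenic genes carry `nv`, their count of
supporting literature reports. PPI edges are admitted only between genes
already present as targets or pathogenic genes — importing the full
interactome would swamp the disease-relevant core with generic hubs and
is off by default (`expand_ppi = TRUE` allows one-hop expansion). Each
pathogenic gene links to a single disease node; the graph is kept simple,
with edge-type precedence CT > GD > PPI when layers would duplicate an
edge. Importance is computed on the T-P subnetwork: the induced gene-only
graph with PPI edges, because the question the importance score answers —
which proteins relay the intervention — only concerns the gene layer.
Pathogenic genes absent from both the target list and the PPI file remain
as isolated T-P nodes; they score zero importance and drop out at the
median threshold.

## The importance score and the effective intervention space

For node $i$ in the T-P graph with effective diameter $\emptyset$ (the
maximum shortest-path length, taken over connected components when the
graph is disconnected):

$$IM_i \;=\; \frac{(\emptyset+1) - \sum d_{jk}(i)/m}{\emptyset}
\;\times\; \frac{\sum_{j<k} g_{jk}(i)/g_{jk}}{n(n-1)/2}$$

The second factor is betweenness-like: the fraction of shortest paths
between other node pairs that transit $i$, summed over unordered pairs
and normalised by $n(n-1)/2$. The first factor is a relay-length bonus:
$\sum d_{jk}(i)/m$ is the mean hop length of the shortest paths through
$i$ (each of the $m$ transit paths counted once, so a pair with several
shortest routes through $i$ contributes each route), and nodes mediating
*short* relays — direct bridges between neighbourhoods — score closer to
$\emptyset/\emptyset$ than nodes sitting in the middle of long chains.
A node with no transit path scores exactly zero.

Numerical conventions, all of which the test suite pins against an
exhaustive path-enumeration oracle:

* Pair sums run over unordered pairs $j \ne i \ne k$ (the standard
  transit-betweenness convention); including endpoint pairs would give
  leaves positive scores, contradicting the hub-detection intent.
* Disconnected pairs contribute nothing; the diameter is the maximum over
  components; isolated nodes have importance 0.
* The $n(n-1)/2$ normalisation (rather than $(n-1)(n-2)/2$) is kept as
  designed; it merely caps the attainable maximum below 1 and cancels in
  every median comparison.
* Transit path lengths necessarily lie in $[2, \emptyset]$, so the first
  factor lies in $[1/\emptyset, (\emptyset-1)/\emptyset]$ whenever
  $m > 0$ — a bound asserted as a property test.

The **effective intervention space (EIS)** is the induced subgraph on
nodes with $IM$ strictly above the median of all scores (the even-$n$
median is the mean of the two middle values; ties at the median are
excluded, keeping the rule deterministic). A strict threshold on an
all-equal score vector would keep nothing, which is reported as an error
suggesting the inclusive mode rather than silently returning an empty
space. EIS nodes are categorised by membership: target ∩ pathogenic
(essential-common), pathogenic only (disease-specific), target only
(component-specific).

## Selecting the core group of functional components

The published formulation gives a knapsack objective but reports an
accumulative coverage curve, so both are provided:

* **Greedy curve (default).** Components are added in order of marginal
  gain in EIS-node coverage, ties broken lexicographically by id; the
  curve of cumulative coverage is cut at a threshold, default 0.95. The
  weights are $w_i = |T_i \cap EIS|/|EIS|$ and the contribution
  $v_i = |(T_i \cup N_{EIS}(T_i)) \cap PG \cap EIS| / |PG \cap EIS|$
  ($T_i$: targets of component $i$; $N_{EIS}$: EIS neighbourhoods). The
  original description never defines $w_i, v_i$ operationally; these
  definitions make the curve's y-axis exactly "target coverage of
  effective proteins", which is what the reported percentages measure.
* **Knapsack (alternative).** Maximise $\sum v_i x_i$ subject to
  $\sum w_i x_i \le R$ by 0/1 dynamic programming on a discretised weight
  grid (default resolution 1/1000, round half-up — an explicit
  approximation knob; integer weights at resolution 1 are exact, which is
  how the optimality property is tested against subset enumeration). No
  reference value of $R$ exists, so knapsack mode always takes a
  user-supplied budget.

Greedy marginal gains are non-increasing by construction, and the final
cumulative coverage equals the coverage of the union of all component
target sets regardless of ordering — both asserted as property tests.

## Maximum-targeting-weight cascades

On a directed signalling graph, each candidate mechanism chain is a
minimum-weight path from a source (in-degree-0 node — a receptor, where
an orally absorbed component first acts) to a sink (out-degree-0
effector). Edge weights default to 1; Dijkstra distances are used so
user-supplied weights work unchanged. Among equal-weight paths the
lexicographically smallest node sequence is chosen, making results
reproducible without seeds.

Each path node contributes
$IM_i + R_i + D_i \pm R_{avg} \pm D_{avg}$, where
$R_i = (NV_i - \min_{PG})/(\max_{PG} - \min_{PG})$ and
$D_i = (NC_i - \min_{TG})/(\max_{TG} - \min_{TG})$ are min-max
normalisations over the pathogenic-gene and target-gene sets (degenerate
spreads map to 0 — no spread, no signal), and the averages are added when
the node belongs to the respective set and subtracted otherwise. The raw
sum is unbounded in path length, while the published retained scores lie
in $[0.70, 0.96]$; the package therefore reports both the raw sum and a
per-node mean, applies the retention threshold (default 0.7, strictly
greater) to the mean, and documents this normalisation as an inference —
reproduction of the published numeric scores is not claimed. $IM$ for
signalling nodes is computed on the undirected view of the signalling
graph, the same score used everywhere else.

Retained cascades are merged into targeting modules. One subtlety: a
terminal effector shared by otherwise unrelated routes (in the published
chains, FOS is reached both from the ADCY1 branch and from the DRD1/DRD5
branch) would fuse the two routes into a single weak component under a
naive union. Module detection therefore sets aside nodes that only ever
appear as cascade terminals, finds components on the remaining backbone,
and attaches each terminal to every module feeding it — which reproduces
the two-module structure of the published chains from their printed node
sequences. `bridge_sinks = TRUE` gives the naive components.

## Enrichment

Over-representation uses the exact upper-tail hypergeometric probability;
the universe defaults to the union of collection genes because no
background is otherwise specified, and an explicit universe can be
passed. Significance follows the raw p < 0.05 convention by default, with
BH-adjusted mode available; adjusted values are reported in either case.
No set-size filters are applied by default. Method comparison
(`compare_importance_methods()`) scores the T-P graph with each
centrality, keeps above-median nodes, and measures coverage of the terms
jointly significant for the full target list and the pathogenic genes —
the functional ground truth the intervention is supposed to span.

## The synthetic bundle: what it does and does not emulate

`generate_bundle()` plants every structure the pipeline is supposed to
find, then hands the pipeline only the raw tables:

* **Gene layer**: `n_hubs` (15) hub genes on a backbone path, each with
  `leaves_per_hub` (19) spokes — 300 genes whose degree distribution is
  heavy-tailed like a real interactome's, and whose transit structure
  makes hubs (and only hubs) score positive importance. The planted hub
  set is therefore exactly the EIS, deterministically.
* **Components**: 200 across 7 herbs. Seven cover components partition
  the hubs between them; decoys target spokes, a few also one hub of the
  largest cover group, so greedy selection has to resolve ties and
  zero-gain tails. ADME violations (rate 0.1 per rule) are planted only
  outside the cover so the planted selection survives screening; the
  ledger records every violator.
* **Evidence**: `nv` follows a discrete Pareto tail (exponent 2.5, capped
  at 100), matching the empirical pattern that most disease genes have a
  single supporting report and a few have dozens.
* **Signalling**: a planted chain whose nodes are all target∩pathogenic
  with maximal `nv`/`nc`, next to a background DAG of mostly unlabelled
  nodes; every planted per-node term exceeds every background term, so
  the planted chain is the top-ranked cascade by construction, not by
  chance.

One global seed fans out to per-section seeds, so adding a generator
section never changes earlier sections, and regeneration is
byte-identical per seed. What the bundle does *not* emulate: realistic
chemistry (placeholder property values, no SMILES), PPI noise such as
false-positive edges or confidence scores, correlated evidence counts,
and overlap between the signalling graph and the T-P gene layer. Passing
the planted-recovery tests therefore demonstrates the algorithms'
correctness on clean structure, not robustness to the noise of real
databases.

## Problem sizes and determinism

The suite exercises: exhaustive importance-oracle checks on all 772
labeled connected graphs with 3–5 nodes plus seeded 6–8-node and 200
30-node random graphs; knapsack optimality on 500 random instances of up
to 20 items against meet-in-the-middle enumeration; hypergeometric
exactness by direct tail summation over universes up to 30; and
planted-structure recovery on three bundle seeds. These sizes were chosen
so every check is exact rather than statistical. All pipeline stages are
deterministic given their inputs; the only randomness in the package is
in the generator, which is fully seed-driven.

## Known limitations

* The importance computation is exact and dense ($O(n^3)$ vectorised);
  it is comfortable to a few thousand T-P nodes but not designed for
  full-interactome graphs.
* Signalling graphs are treated as plain directed graphs: activation and
  inhibition signs are ignored, and second messengers (cAMP, DAG) are
  ordinary nodes.
* Gene identifiers are opaque case-sensitive strings; no alias mapping.
* The cascade score normalisation (per-node mean) is a documented
  inference, configurable via `retain_cascades(score_column = "raw")`.
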