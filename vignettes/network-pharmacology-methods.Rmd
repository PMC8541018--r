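---
title: "Methods: context-specific network pharmacology with netpharm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: context-specific network pharmacology with netpharm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netpharm)
```

## The problem

A multitarget drug engages tens of proteins at widely varying potencies.
Whether a given target is *relevant* in a given disease depends on three
separable questions: is the target engaged at concentrations the body can
reach; is it associated with the disease; and how central is it within the
disease's protein-interaction neighbourhood. netpharm operationalizes each
question as one pipeline stage over plain-text inputs, so the whole analysis
is reproducible offline and every stage can be validated against planted
ground truth.

## Stage models and assumptions

### Potency curation

Each affinity record carries one measured potency (Ki, EC50 or IC50, stored
internally in nM). A target is retained iff

$$\min_{\text{records of } s} \text{activity}(s) < t,$$

with the ceiling $t = 2000$ nM by default, a conventional bound for the
highest physiologically attainable free concentration of an orally dosed
small molecule. Three deliberate choices:

* **Strict inequality** at the boundary: a measurement exactly at the
  ceiling is judged not physiologically engaged.
* **Aggregation by minimum** across conflicting literature values: a target
  engaged at *any* reported potency below the ceiling is in scope. The
  alternative (mean, or manual adjudication) would make the filter depend on
  how many times a value was re-measured; the minimum is monotone,
  idempotent and auditable.
* **Direction agnosticism**: agonists, antagonists, inhibitors and
  allosteric modulators all pass. The filter asks whether the drug engages
  the protein, not what it does to it — pharmacodynamic sign is carried
  along as an annotation.

The assumptions are that measure types are comparable at this resolution
(Ki vs EC50 vs IC50 differences are well within the order-of-magnitude
uncertainty of cross-study potencies) and that the curation itself is
trusted; the package validates units and enumerations but does not
re-adjudicate the literature.

### Set intersection

The three-way Venn partition is computed over normalized symbols
(uppercased, alias-mapped) with no score weighting: a disease association
either exists or it does not. Association scores only enter through the
optional `min_score` pre-filter of the reader, whose default is 0 — any
association evidence counts, since the upstream evidence integration is
already a curated aggregate. All listings are alphabetical so that outputs
diff cleanly.

### Disease-restricted interaction network

Edges are STRING-style confidence-scored pairs. The inclusion threshold is
**inclusive** (`combined_score >= 400` by default, the conventional
medium-confidence cutoff; configurable because the appropriate stringency is
snapshot- and question-dependent). Duplicate undirected pairs are merged
keeping the **maximum** score — for a confidence score the strongest
evidence line is the defensible merge — and self-loops are dropped.

The context restriction is a plain induced subgraph on the dual-disease
protein set. Drug-anchored degrees are computed on the edge subset touching
at least one drug target; the degree of a drug target is its incident-edge
count there, so an edge between two drug targets contributes one to each
endpoint. Targets absent from the network are reported with degree 0:
silently dropping them would bias any downstream ranking toward
well-annotated proteins. Ranking is by descending degree with alphabetical
tie-break, making the output a deterministic permutation of its input.

Vertex degree is used as the centrality measure because it is the quantity
the published table reports and the most robust one under network
subsampling; betweenness or eigenvector centralities are deliberately out
of scope.

### Markov clustering

The common-target subnetwork is clustered with the MCL algorithm, chosen
because it is the clustering the STRING service itself offers and it
requires no pre-specified cluster count. On the weighted adjacency matrix
(weights = combined_score/1000) each node first receives a self-loop equal
to its maximum incident weight (1 for isolated nodes) — the standard
regularization that prevents period-2 oscillation of the flow — and columns
are normalized to a stochastic matrix $M$. Iteration alternates expansion
($M \leftarrow M^e$, $e = 2$) and inflation (element-wise power $r = 2$
followed by column renormalization), with entries below $10^{-12}$ pruned
for numerical stability, until the maximum absolute change falls below the
tolerance ($10^{-6}$) or the iteration cap (100) is hit; hitting the cap
warns and flags the result rather than failing. Clusters are the connected
components of the converged matrix's support (entries above $10^{-7}$);
ids are contiguous from 1, ordered by decreasing size with the
alphabetically smallest member breaking ties. Because flow never crosses
between components, disconnected nodes can never be co-clustered — the
degenerate edgeless network yields one singleton cluster per node.

Inflation 2.0 is the field's default granularity; raising it fragments
clusters. The parameters are exposed but the defaults are not tuned per
dataset.

### Over-representation analysis

For a query of $n$ genes against a term of $K$ genes in a background of
$N$, the p-value is the one-sided upper tail
$P(X \ge k)$, $X \sim \mathrm{Hypergeom}(N, K, n)$, summed in log space
from log-binomial coefficients with a log-sum-exp reduction; this keeps
12+ significant digits even for extreme overlaps. Depletion is out of
scope. FDR control is Benjamini–Hochberg step-up — the procedure the major
enrichment services document — with Bonferroni available; the adjustment is
computed across exactly the terms tested after the `min_term_size` floor
(default 2, the smallest overlap worth reporting).

The background is the test's sampling frame and the main modelling choice:
by default it is the union of the collection's members, but an explicit
genome size (e.g. 20000) can be supplied to honour a whole-genome
background when the collection covers only part of the genome. With a
numeric background the term sizes are taken at face value; with a symbol
background, terms and query are first intersected with it and query
symbols outside it are dropped with a warning.

## The synthetic-data module

The generators exist so that every pipeline stage can be checked against a
planted truth rather than against a database snapshot. The default
specification *is* the study condition of the worked example: 66 curated
drug targets of which 30 fall below the 2 µM ceiling; disease sets of 2473
and 970 targets sharing 475; and 10 below-threshold drug targets common to
both diseases. Quantities the worked example does not pin down were fixed
once at plausible values and are not revisited: the split of the remaining
retained targets into disease-exclusive regions (12 in disease A only, 3 in
disease B only), a 3500-symbol genome (comfortably above the 2973-symbol
union), an Erdős–Rényi PPI base graph on 200 dual-disease proteins plus the
common targets at edge probability 0.05, one planted hub with 50 guaranteed
extra edges (far above the ~10 expected background degree, so hub recovery
is essentially deterministic), combined scores uniform on [400, 1000], and
a 50-term GMT whose first term contains 8 of the 10 common targets.

Each generator draws from its own named pseudo-random stream derived from
the master seed, so adding a generator never perturbs existing fixtures,
and two calls with the same specification are byte-identical. Ground truth
is emitted as sidecar JSON next to each file, so tests compare pipeline
output against the sidecar, never against the generator's internals.

What the generators do **not** emulate — and hence what passing tests do
not show about real data: realistic association-score distributions and
their evidence structure, the topology of real PPI networks (degree
heavy tails, cliquishness of complexes), correlated and hierarchically
nested gene sets (a GO DAG), identifier mess beyond case/alias variation,
and any biology in the symbol labels. The suite demonstrates algorithmic
correctness and exact planted-structure recovery, not robustness to
annotation noise.

## Numerical and interface choices

* Units accepted: pM, nM, µM (and the "uM" spelling); canonical unit nM.
  A unit suffix inside the activity field is honoured when no unit column
  exists; a bare number is nM.
* Duplicate disease associations keep the maximum score; duplicate
  affinity rows are kept untouched until the potency filter aggregates.
* Identifiers are HGNC-style uppercased symbols; Ensembl-style exports
  must be pre-mapped via `alias_map`. Alias values are assumed canonical,
  which is what makes normalization idempotent.
* Determinism throughout: the pipeline itself uses no random numbers, all
  orderings are total (degree then symbol; p-value then term id;
  alphabetical elsewhere), and `report.json` contains no timestamps, so
  identical inputs give byte-identical reports. GraphML export goes
  through igraph and is byte-stable across runs.
* Empty inputs degrade explicitly: an empty common-target list skips
  clustering and enrichment with warnings and the report records empty
  tables; validation failures name the offending row, column or line.

## Problem sizes in the test suite

Unit and property tests run at small sizes (universes of a few hundred
symbols, graphs of 15–40 nodes, 10–100 trials per property) chosen so the
whole suite exercises every contract in seconds; the end-to-end acceptance
checks run the generators at their default study-condition scale for ten
seeds. The exhaustive hypergeometric oracle enumerates all subsets up to
$N = 12$, the largest size where full enumeration is still instant; the
null-calibration check uses 2000 simulated queries.

## Known limitations

* Published absolute degree values and enrichment p-values depend on
  database snapshots (interaction sets, annotation releases, number of
  terms tested) that this package deliberately does not ship; the packaged
  worked-example table is a fixture, and the 66-target curation file is a
  synthetic stand-in with the published summary structure.
* The potency filter does not model pharmacokinetics; the ceiling is a
  plain configurable cutoff.
* No orthology mapping, no live identifier resolution, no GO propagation;
  gene-set semantics are exactly what the GMT file states.
* MCL on very large networks would need a sparse implementation; the dense
  matrix used here is appropriate for the hundreds-of-nodes contexts the
  pipeline produces.
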