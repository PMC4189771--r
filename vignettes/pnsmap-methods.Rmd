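---
title: "Methods: exemplar clustering of protein-network similarity in the immune lineage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: exemplar clustering of protein-network similarity in the immune lineage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pnsmap)
```

## Overview

`pnsmap` asks a protein-level question of regulator-centric expression
data: which groups of proteins with similar interaction partners are
activated in which immune cell lineages? The pipeline has five analytic
stages — interactome filtering, similarity-matrix construction, affinity
propagation, lineage integration, and term enrichment — plus a simulator
that plants known structure through all five. This vignette records the
model, its assumptions, the tunable parameters, and the design choices
made where more than one defensible option existed.

## Interactome filtering

Evidence rows are kept only when all four criteria hold: experimentally
verified, both interactors in the target organism (default NCBI taxon
10090, mouse), at least one supporting publication, and a physically
binding interaction type. The two evidence criteria are taken as boolean
input columns rather than inferred from interaction-type ontologies;
mapping a provider's controlled vocabulary onto these booleans is the
caller's responsibility via the column dialect. Gene symbols are
uppercased and matched exactly thereafter — the regulator, module and
exemplar tables in this domain mix symbol casing, and deterministic joins
matter more than preserving case. Self-interactions are dropped by
default because neighborhood-overlap similarity is defined over
*partners*; a flag retains them. Mirrored duplicate records collapse to a
single undirected edge, so edge counts reported by the package are
post-deduplication.

"Hub" has no standard definition; `hubs()` defaults to the top 10% of the
degree distribution with all ties at the cutoff included, and the
fraction is a parameter.

## The similarity matrix

For genes with at least one partner, the Simpson index
\[
S_{AB} = \frac{|N(A) \cap N(B)|}{\min(|N(A)|, |N(B)|)}
\]
normalizes shared partners by the smaller degree. The motivation is the
scale-free shape of interactomes: a 5-partner gene whose partners all lie
inside a 200-partner hub's neighborhood is maximally similar to it under
Simpson, while Jaccard would dilute the score by the hub's degree. Both
indices are implemented; Simpson is the default and Simpson ≥ Jaccard
holds pairwise by construction (the minimum denominator never exceeds the
union), a property the test suite asserts on random neighborhood pairs.

Two conventions matter:

* the pair itself is excluded from both neighborhoods, so an edge between
  `A` and `B` does not count toward their shared partners (it would
  otherwise inflate the similarity of adjacent low-degree pairs);
* candidate genes without any interaction are dropped from the matrix and
  reported, not carried as zero rows. Clustering genes the interactome
  knows nothing about would only manufacture an artifactual "no-data"
  cluster; the dropped/retained split is logged instead, and per-module
  coverage is reported separately by `module_coverage()`.

The diagonal is left empty at this stage: it is the preference slot the
clustering step fills.

## Affinity propagation

The PNSM is clustered with affinity propagation: every gene is
simultaneously a data point and a candidate exemplar, and two message
matrices are iterated,
\[
r(A,B) \leftarrow s(A,B) - \max_{B' \neq B}\{a(A,B') + s(A,B')\}
\]
\[
a(A,B) \leftarrow \min\Big\{0,\; r(B,B) + \sum_{A' \notin \{A,B\}} \max(0, r(A',B))\Big\},
\qquad
a(B,B) \leftarrow \sum_{A' \neq B} \max(0, r(A',B)),
\]
each damped as `damping · old + (1 − damping) · new`. Exemplars are the
genes with `a(B,B) + r(B,B) > 0`; non-exemplars join the exemplar they
are most similar to.

Parameter choices, with defaults:

* **Preference** (`"median"`): a single scalar, the median of all
  off-diagonal similarities, broadcast to every gene. A per-gene numeric
  vector is accepted for sensitivity analyses. The scalar-broadcast
  reading is the convention of the original algorithm and makes the
  cluster count a pure function of the data; per-gene medians would bias
  genes in dense similarity neighborhoods toward exemplarhood.
* **Damping 0.5**, the original algorithm's practice; undamped messages
  oscillate on symmetric inputs, and the configuration rejects
  `damping = 1` (frozen messages).
* **Convergence**: exemplar set unchanged for 50 consecutive iterations,
  capped at 1000. A run that exhausts the cap returns
  `converged = FALSE` with a warning rather than an error.
* **Tie breaking.** Two mechanisms, deliberately separated. An eps-scale
  perturbation (machine epsilon relative, seeded) is always applied, as
  in the reference implementations of the algorithm: exactly tied
  similarities otherwise sustain message oscillations indefinitely on
  symmetric input. A *user-visible* jitter (`noise_scale`, as a fraction
  of the similarity range) is off by default in `ap_config()` but on at
  `1e-6` in the pipeline defaults, because PNSMs of genes with identical
  neighborhoods contain many similarities that are exactly 1.0.
* **Refinement.** After convergence, each cluster's exemplar is re-chosen
  as the member maximizing total within-cluster similarity, and points
  are reassigned — the standard final step of the algorithm. Without it,
  converged runs occasionally carry a within-cluster suboptimal exemplar.

`brute_force_exemplars()` enumerates every nonempty exemplar subset (≤ 12
genes) and maximizes the same net-similarity objective,
Σ<sub>non-exemplars</sub> s(A, exemplar(A)) + Σ<sub>exemplars</sub> s(B,B),
breaking ties toward the lexicographically smallest exemplar set. It is
an oracle: independent of the message-passing path, and used by the tests
to confirm that converged runs on well-separated matrices attain the
global optimum. Affinity propagation carries no global optimality
guarantee in general — when a planted "cluster" has a single member, both
this implementation and independent references converge to a
configuration a few thousandths short of the enumerated optimum — so the
oracle comparison is asserted for planted clusters of at least two
members, where the within-cluster similarity premise is meaningful.

## Lineage integration

Associations follow the chain cell type → activators (packaged
ten-lineage table) → regulated modules → member genes. An exemplar is
associated with a cell type when at least `min_genes` (default 1) of its
members sit in modules driven by at least one of that type's activators;
with exactly one association it is *lineage-specific*, with all ten
*common*, otherwise *shared*. The default threshold is the weakest
defensible reading — any member gene in a lineage-regulated module — and
is a parameter precisely because it is a judgment call; raising it trades
sensitivity for specificity of the association.

Module regulation wiring is an *input* (a regulator → module table), never
inferred from expression by this package. Edges in the regulator/module
multigraph require only module membership of an exemplar's gene, not that
the gene be a direct target of the specific regulator; the stricter
reading would need per-regulator target lists, which the input schema
does not carry.

## Enrichment

Over-representation uses the upper-tail hypergeometric distribution
(`P(X ≥ k)` for overlap k, term size K, query size n, universe N), with
Benjamini–Hochberg adjustment and α = 0.05 on the adjusted value by
default (a raw-p mode exists for comparison with legacy outputs).
Annotation sets are intersected with the universe first; zero-overlap
terms report p = 1. The default universe is the set of PNSM genes — the
population from which exemplars are actually drawn; using all module
genes (including the majority absent from the interactome) would
overstate significance and is left as an explicit caller choice. Original
analyses of this kind used web-service tools whose p-values depend on
database versions and proprietary backgrounds; those numbers are not
reproduction targets, and the packaged tables carry them only as
descriptive annotation.

True-path propagation unions each term's descendants' genes up the DAG
before testing; `significance_trajectory()` then reports the subgraph of
significant terms with their ancestor paths. Note that propagation does
not make ancestors' p-values monotone — only the gene-set superset
relation is guaranteed, and only that is asserted.

## The synthetic generator

The generator targets the signal the clustering actually consumes:
*similarity of neighborhoods*, not within-group edge density. Each
planted group's members are wired to the same dedicated partner hubs, so
intra-group Simpson similarity is ≈ 1 by construction and decays with
noise; the rest of the gene universe grows by preferential attachment
(m = 2), reproducing the heavy degree tail of real interactomes; spurious
edges appear independently with probability `noise_edge_prob`.

The standard conditions — 5 groups × 20 genes, 8 shared partners per
group, 1% noise, a 150-gene universe — are chosen so that desk-scale runs
mirror the qualitative regime of the real analysis: strong intra-group
similarity (mean ≥ 0.8), near-zero inter-group similarity (≤ 0.1), and a
similarity matrix small enough to brute-force spot-check. Module padding
with non-interacting genes reproduces partial interactome coverage
(default 30%, versus real catalogs where most module genes have no
catalogued interaction and maxima sit near 48%). Planted lineage wiring
uses only regulators *exclusive* to a cell type for specific groups —
shared activators (SFPI1, CEBPB, GATA3 serve up to five lineages) would
otherwise make every "specific" module multi-lineage under the default
association rule — and one regulator of every type for common groups.
Cell types without any exclusive activator (e.g. monocytes, whose two
activators are both shared) cannot anchor a planted specific group.

What the simulator does **not** emulate: study-scale sizes (tens of
thousands of edges, thousands of module genes), correlated experimental
biases of interaction databases (literature-driven degree inflation),
isoform ambiguity, or expression-derived module inference. Passing tests
therefore demonstrate correctness of the computations and recoverability
of clean planted structure — not that biological conclusions at study
scale are insensitive to database choice.

## Numerical and degenerate-input choices

* Similarity of a pair whose only partners are each other is defined as 0
  (the exclusion convention empties both neighborhoods); Simpson with a
  degree-0 gene is an error by contract, and such genes never enter the
  matrix.
* Fewer than two retained candidates is a pipeline error (nothing to
  cluster); an empty post-filter interactome is a warning plus an empty
  network, since emptiness is data-dependent.
* Malformed interaction rows (unparseable taxon, blank symbol) are
  reported and retained; they fail the same-organism criterion rather
  than disappearing silently.
* All generators and the clustering jitter are seed-deterministic; the
  pipeline threads one top-level seed through every stage, and reruns
  with the same configuration reproduce artifact checksums exactly.
* Test and acceptance problem sizes (n ≤ 8 for exhaustive search, 100
  trials for the oracle comparison, the 150-gene standard dataset,
  enumeration up to N = 20 for the hypergeometric check) keep the full
  suite under a minute while exercising every code path; they are desk
  conditions, chosen once.

## Known limitations

* Exemplar counts and memberships at study scale depend on interactome
  database version; only distributional properties are testable.
* The association rule treats module membership as the lineage link;
  direct regulator → target evidence would be stricter but needs richer
  input.
* Affinity propagation approximates the net-similarity optimum; the
  package documents (and tests) the conditions under which the optimum is
  attained rather than claiming it universally.
* Leveraged/hierarchical variants for matrices too large for memory are
  out of scope; the dense PNSM at the real scale (~2000² doubles) fits
  comfortably, but much larger universes would not.
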