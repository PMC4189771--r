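# pnsmap

Differential protein-network analysis for the immune cell lineage:
affinity propagation on interactome similarity matrices.

## The problem

Large gene-expression compendia of the mouse immune system organize genes
into regulator-driven co-expression modules for each hematopoietic cell
type, but say nothing about the physical protein-interaction machinery
those programs activate. `pnsmap` integrates the two layers. Starting from
a curated binary protein interactome and a table of known transcriptional
activators of the ten main immune lineages (B cells, dendritic cells,
granulocytes, hematopoietic stem cells, macrophages, monocytes, NK cells,
NKT cells, αβ and γδ T cells), it finds *exemplars* — groups of proteins
that share interaction partners — and asks which of them are activated in
one lineage only and which are common to all ten.

The package is aimed at computational immunologists and systems biologists
who want a tested, scriptable version of this analysis, plus a
ground-truth simulator to validate every stage at desk scale.

## The method

1. **Interactome filtering.** Interaction evidence records are retained
   only when they are (a) experimentally verified, (b) within the target
   organism (mouse, taxon 10090, by default), (c) supported by at least
   one publication, and (d) physically binding. The survivors form an
   undirected, deduplicated binary network.
2. **Protein network similarity matrix (PNSM).** For every pair of
   module-assigned genes *A*, *B* with at least one interaction partner,
   the Simpson overlap index

   S(A,B) = |N(A) ∩ N(B)| / min(|N(A)|, |N(B)|)

   measures shared partners relative to the least-connected gene, so
   degree-imbalanced pairs (ubiquitous in scale-free interactomes) are not
   penalized. The Jaccard index |N(A)∩N(B)| / |N(A)∪N(B)| is available as
   an alternative.
3. **Affinity propagation.** The PNSM is clustered by message passing:
   responsibilities r(A,B) = s(A,B) − max_{B′≠B} {a(A,B′) + s(A,B′)} and
   availabilities a(A,B) = min{0, r(B,B) + Σ_{A′∉{A,B}} max(0, r(A′,B))}
   are exchanged (damped, default 0.5) until the exemplar set is stable.
   Every gene is simultaneously a candidate exemplar; the number of
   clusters emerges from the input preference, set by default to the
   median off-diagonal similarity. A brute-force exemplar-set search over
   small matrices serves as an independent optimum in the test suite.
4. **Lineage integration.** Exemplars are linked to cell types through the
   chain cell type → activators → regulated modules → member genes, then
   classified as *lineage-specific* (one cell type), *common* (all ten) or
   *shared*. Two bipartite views are exported (regulator/module multigraph
   with one parallel edge per exemplar, and exemplar/cell-type graph).
5. **Enrichment.** Each exemplar's members are tested for annotation-term
   over-representation with an upper-tail hypergeometric test,
   Benjamini–Hochberg adjustment, true-path propagation up the term DAG,
   and significance-trajectory subgraphs.
6. **Synthetic data.** `generate_interactome()` plants groups of genes
   wired to shared partner hubs on a preferential-attachment background;
   `generate_lineage()` and `generate_annotations()` plant cell-type
   associations and enriched terms, so the whole pipeline can be verified
   against known truth.

## Worked example

```r
library(pnsmap)

## planted-truth simulation: 5 groups x 20 genes, 8 shared partners each,
## scale-free background, 1% noise edges
sim  <- generate_interactome(seed = 7)
sim$network
#> protein_network: 190 nodes, 1056 edges

pnsm <- build_pnsm(sim$network, unlist(sim$truth$groups))
#> PNSM: 100/100 candidate gene(s) retained (0 without interactions dropped)
res  <- run_affinity_propagation(pnsm, ap_config(noise_scale = 1e-6, seed = 7))
res
#> ap_result: 5 exemplar(s) over 100 gene(s); converged after 85 iteration(s); net similarity 95.0000

## integrate with the packaged ten-lineage regulator table
lm   <- load_regulator_table()
lin  <- generate_lineage(sim$truth, lm)
lmap <- lineage_map(lm, lin$modules, lin$regulation)
associate_exemplars(res, lmap)[, c("exemplar", "n_genes", "n_cell_types", "specificity")]
#>   exemplar n_genes n_cell_types      specificity
#> 1 GENE0007      20            1 lineage-specific
#> 2 GENE0022      20            1 lineage-specific
#> 3 GENE0044      20            1 lineage-specific
#> 4 GENE0080      20            1 lineage-specific
#> 5 GENE0093      20           10           common
```

The five planted groups are recovered exactly: each group's 20 genes share
one exemplar, four groups associate with their single planted cell type,
and the fifth — whose module is wired to a regulator of every lineage — is
classified common. `run_pipeline(run_config(...))` chains the same steps
from files on disk and writes TSV/SIF/GraphML artifacts with a
checksummed manifest.

The packaged fixtures under `inst/extdata/` include the ten-lineage
regulator table and the summary tables of lineage-specific (19 rows, 8 of
them — 42% — associated with hematopoietic stem cells) and common (25
rows) exemplars.

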