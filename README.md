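# kgsketch

Schematic subgraph extraction from biomedical knowledge graphs.

Pathway diagrams summarize mechanisms with a handful of named entities and
the connections between them. Biomedical knowledge graphs (KGs) —
PheKnowLator, KG-COVID-19 and kin — already contain that material as
ontology-grounded nodes and predicate-labelled triples, but they are far too
large and too generic to draw. kgsketch is for researchers who want to go
from a short list of concept labels ("IRS1 → autophagy") to a small,
Cytoscape-ready subgraph that connects those concepts through meaningful
intermediates.

The package implements a pipeline of *semantic graphical actions*:

- **Indexing**: fuzzy substring matching from free-text concept labels to KG
  nodes, with explicit disambiguation (interactive, pinned, or logged
  auto-selection) — one gene symbol can match hundreds of isoforms,
  variants and GO terms.
- **Path search**: enumeration of *all* tied shortest paths between each
  source/target pair, by BFS over the undirected view of the triples.
- **Path ranking**, choosing among ties:
  - *PDP* (path-degree product): `score = (∏ᵥ deg(v))^(-w)` over the
    intermediate nodes `v`, maximized — prefers paths through low-degree
    intermediates and so avoids hubs such as taxon nodes reachable via
    `only_in_taxon` from almost everything;
  - *CS* (cosine similarity): `score = Σᵥ cos(eᵥ, e_target)` over every
    non-target path node, with node2vec embeddings (walk length 10,
    20 walks/node, window 10, 128 dimensions) — prefers paths that stay
    semantically close to the target;
  - *edge-class constraints*: require or prohibit predicates along the
    path, applied before scoring (optionally soft: relaxed with a flag when
    nothing would survive).
- **Augmentation**: attach distance-1 neighbors of a stated ontological
  category (e.g. every drug targeting a protein in the subgraph).
- **Export**: GraphML, SIF and TSV attribute tables for Cytoscape, plus a
  per-pair path report.

## Worked example

`toy_kg_a()` is a hand-checkable 8-node miniature of an insulin-signaling
neighborhood, including a high-degree "Homo sapiens" taxon hub (`n5`) and a
drug node (`n7`).

```r
library(kgsketch)

kg <- toy_kg_a()
kg
#> <knowledge_graph> 8 nodes, 9 edges, 5 predicate classes

paths <- kg_shortest_paths(kg, "n1", "n4")   # IRS1 -> autophagy
tidy(rank_paths(paths, "pdp", kg = kg, w = 1))
#> # A tibble: 2 × 5
#>   path                 length  score  rank selected
#>   <chr>                 <int>  <dbl> <int> <lgl>
#> 1 n1 -> n2 -> n3 -> n4      3 0.0833     1 TRUE
#> 2 n1 -> n5 -> n3 -> n4      3 0.0625     2 FALSE
```

Both shortest paths have length 3, but the first runs through the AKT/mTOR
signaling axis (intermediate degrees 3·4, score 1/12) while the second hops
through the taxon hub (degrees 4·4, score 1/16) — PDP selects the
mechanistically informative one. The full pipeline, with drug augmentation:

```r
res <- run_pipeline(pipeline_config(
  kg = kg,
  examples = tibble::tibble(source = "IRS1", target = "autophagy"),
  action = "pdp", w = 1,
  augment = category_filter("drug")))
#> Resolved 'IRS1' -> n1 (IRS1), score 100.0, from 1 candidate(s).
#> Resolved 'autophagy' -> n4 (autophagy), score 100.0, from 1 candidate(s).
#> Pair (n1 -> n4): 2 shortest path(s), selected n1 -> n2 -> n3 -> n4.

res
#> <kgsketch_result>
#> <kg_subgraph> 5 nodes (augmented: 1, input: 2, intermediate: 2), 4 edges, 1 pair(s)
#>   1/1 pair(s) connected

res$stats
#> <subgraph_stats> 5 nodes, 4 edges, 1 pair(s)
#>   edge classes: interacts_with (2), participates_in (1), targets (1)
```

The subgraph contains the two input concepts, the two signaling
intermediates, and one augmented drug (`drug-X`, which targets mTOR).
Passing `out_prefix =` writes `*.graphml`, `*.sif`, node/edge attribute
tables and a `*_paths.tsv` report ranking every tied path. `autoplot()`
methods plot score profiles and subgraph composition;
`plot_rank_comparison()` contrasts the CS and PDP orderings of one path
set, which are typically far from correlated.

Real KGs load from TSV via `read_kg(nodes, edges, dialect_kgx())` (headered
KGX files) or `dialect_pheknowlator()` (headerless id/label + triple files);
`kg_dialect()` builds custom column mappings. A thin CLI wraps the same
functions:

```sh
inst/scripts/kgsketch run --nodes nodes.tsv --edges edges.tsv \
  --examples pairs.tsv --action pdp --exclude-predicate only_in_taxon \
  --augment-category drug --seed 1 --out results/sketch
```

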