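---
title: "Extracting pathway schematics from knowledge graphs: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting pathway schematics from knowledge graphs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kgsketch)
```

## The problem

Pathway diagrams — "molecular cartoons" — condense mechanistic claims into a
handful of named entities and the connections between them. Biomedical
knowledge graphs (KGs) such as PheKnowLator or KG-COVID-19 contain the raw
material for such figures: ontology-grounded nodes for genes, proteins,
processes, drugs and diseases, linked by predicate-labelled triples. But a KG
is both too large and too generic to draw directly. kgsketch implements the
intermediate step: given a short list of concept labels and the source→target
connections a figure should show, it extracts a small, semantically meaningful
subgraph that can be handed to Cytoscape.

The pipeline has four stages, each a "semantic graphical action":

1. **Indexing** — map each free-text concept label to one KG node.
2. **Path search** — enumerate *all* tied shortest paths between each
   resolved source/target pair, ignoring triple direction.
3. **Path ranking** — choose one path per pair by hub avoidance (PDP),
   embedding similarity to the target (CS), and/or edge-class constraints.
4. **Augmentation** — optionally attach distance-1 neighbors of a stated
   ontological category (e.g. drugs targeting proteins in the subgraph).

## The graph model

A `knowledge_graph` wraps a node tibble (`id`, `label`, `category`) and an
edge tibble (`subject`, `predicate`, `object`). Identity is the id string,
compared byte-exactly; labels are display text and are never used as
identity, because label ambiguity is precisely what the indexing stage
exists to resolve. Three structural conventions matter downstream:

* **Traversal is undirected.** Triples keep their stored direction for
  display, but degree, neighbors and shortest paths all use the undirected
  view. Directionality in biomedical KGs is predicate-specific and often
  arbitrary relative to the mechanism a figure depicts; searching without
  direction finds more candidate connections at the cost of admitting paths
  whose arrows do not compose, a trade-off we accept and document.
* **Parallel edges are distinct.** Two triples with the same endpoints but
  different predicates are both kept and both count toward degree, because
  edge-class constraints must be able to distinguish them.
* **Self-loops count once** toward degree. They are rare in practice; the
  convention only has to be consistent.

When a node file has no category column, a node's category defaults to the
CURIE prefix of its id (the text before the first `:`). Prefixes encode the
source ontology in every major public KG, which is what category filtering
needs; an explicit prefix→category map (`category_filter(prefix_map = )`)
covers sources whose prefix is not itself the desired category name.

## Indexing

`find_candidates()` is a two-stage matcher. The primary stage is exact
case-insensitive substring containment, scored `100 · |query| / |label|`, so
an exact label match scores 100 and shorter labels outrank longer ones. Only
when the substring stage finds nothing does a fuzzy fallback run: a
partial-ratio score based on the generalized Levenshtein distance between the
query and the best-matching substring of each label (via `utils::adist(partial
= TRUE)`), thresholded at 85/100 by default. Two stages rather than one keep
the behavior auditable: a hit is either a literal substring or an explicit
near-miss, and fuzzy noise can never outrank a literal hit. Ties are broken
lexicographically by node id so reruns are identical. The default candidate
cap is 50, configurable — single gene symbols in a full-size KG can return
hundreds of matches (isoforms, variants, transcripts, GO terms), which is why
resolution is a separate, explicit step (`resolve_concept()`: interactive,
pinned, or auto-top-candidate with logging).

## Path search

`kg_shortest_paths()` runs a breadth-first search from the source to label
distances, restricts to the shortest-path DAG by a backward sweep from the
target, then emits all shortest node sequences by depth-first traversal in
lexicographic successor order. Consequences of this construction:

* Paths are node-simple, and every returned path has exactly the minimal
  edge count — ties are enumerated exhaustively, which matters because real
  KG pairs routinely tie on dozens of equal-length paths.
* Output order is lexicographic in the node sequence, so enumeration order
  can never leak nondeterminism into the ranking tie-breaks.
* Parallel edges do **not** multiply the path count: a path is a node
  sequence, carrying one deterministic representative edge per hop (first by
  predicate sort order). `expand_edge_variants()` produces the full
  Cartesian product of per-hop parallel-edge choices when constraints need
  to inspect every predicate combination.
* `max_paths` (default 500) truncates pathological hub blow-ups with an
  explicit flag and warning. The default sits comfortably above the tie
  counts we expect on real KGs while bounding worst-case work.
* A pair whose endpoints coincide yields one zero-length path rather than an
  error; disconnected endpoints yield an empty list, which the pipeline
  reports (`path = "NONE"`) without aborting, since a partially connected
  schematic is still useful.

## Path ranking

**Path-degree product.** `score_pdp()` computes
`(∏ degree(v) over intermediate nodes v)^(−w)`, maximized. Low-degree
intermediates give large scores, so the action avoids hubs — the canonical
failure being a taxon node ("Homo sapiens") reachable from almost everything
via `only_in_taxon`, which connects any two human entities in two
uninformative hops. Endpoint degrees are excluded: they are shared by every
path of a pair and cannot change the ranking. Because `x^(−w)` is a strictly
monotone transform of the degree product, the induced *ranking* is identical
for every `w > 0`; the exponent (default 0.4, the convention in the
path-degree-product literature) only shapes reported score magnitudes. The
package therefore treats `w` as a reporting parameter, and the test suite
asserts ranking invariance across `w ∈ {0.1, 0.4, 1, 3}`.

**Cosine similarity.** `score_cs()` sums the cosine similarity between the
target node's embedding and the embedding of every other node along the path
(source included — its term is constant per pair and ranking-neutral).
Higher scores mean the path gets, and stays, semantically close to the
target. Embeddings come from `train_embeddings()`: uniform seeded random
walks over the undirected multigraph (walk length 10, 20 walks per node —
first-order walks, equivalent to node2vec with both bias parameters at 1,
which is the behavior when no return/in-out preference is specified),
followed by a single-threaded skip-gram model with negative sampling
(window 10, 128 dimensions, 5 epochs, 5 negatives). The trainer uses its own
seeded RNG, so a fixed seed reproduces the table exactly within an
environment; isolated nodes never occur in walks and keep their seeded
initialization vectors, so the table always covers the whole graph and a
missing entry is treated as a hard error rather than a silent zero. Because
training is stochastic across environments, exact-value tests inject fixed
tables via `fixed_embeddings()`; training itself is covered by shape,
coverage and determinism-under-seed contracts.

**Edge-class constraints.** `edge_constraint()` requires or prohibits
predicates along a path. Semantics: a surviving path contains no prohibited
predicate and — if requirements exist — at least one required predicate
("at least one" rather than "every edge" is our reading of requiring an
edge class *on a path*; it is the permissive choice and is documented here
because the alternative is defensible). Constraints are applied **before**
scoring, so they dominate both ranking actions; with `soft = TRUE` a
constraint that would eliminate every path is dropped entirely and the
relaxation is flagged on the result and in the path report.

**Tie-breaking.** Scores tie in practice (identical embeddings, symmetric
degree patterns). `rank_paths()` breaks ties by path length (vacuous among
tied shortest paths but a safe invariant), then lexicographic node sequence,
then predicate sequence — a total order, so the selected path is a pure
function of the inputs.

## Augmentation

`augment_neighbors()` scans the immediate neighbors of the extracted
(non-augmented) subgraph nodes and admits those whose category passes the
filter, together with every edge linking them to the scanned nodes. Two
consequences are deliberate: the operation is idempotent (a second pass adds
nothing, because augmented nodes never seed the scan), and edges between two
augmented nodes are never introduced — augmentation decorates the schematic
with a star of neighbors rather than growing the graph another hop.

## The pipeline and reproducibility

`run_pipeline()` composes the stages per concept pair and takes the set
union of selected paths into one subgraph, with node provenance recorded as
`input` / `intermediate` / `augmented`. The accuracy property the pipeline
aims at is input recapitulation: every resolved input node appears in the
output whenever its pairs are connected in the KG. Every user-facing choice
(resolved node, selected path, relaxed constraint, truncation) is surfaced
as a message or warning so a batch run is auditable, and with a fixed seed
plus pinned (or auto) resolution two runs produce byte-identical SIF and
path-report files — asserted in the test suite.

Outputs follow Cytoscape conventions: GraphML with node attributes (label,
category, provenance), SIF triples, and TSV attribute tables. SIF cannot
express isolated nodes; these are emitted only to GraphML/attribute outputs
with a warning. Input KG files are unquoted TSV in either a headerless
id/label + triple layout or a headered KGX-style layout, selected by a
`kg_dialect()` object; fields containing literal tabs are rejected rather
than quoted, matching how public KG exports behave. Edges referencing ids
absent from the node file get placeholder nodes (empty label) and a warning
rather than a failed load.

## What the synthetic fixtures emulate — and what they do not

`toy_kg_a()` is a hand-built 8-node miniature of an insulin-signaling
neighborhood whose every quantity is checkable by hand: two tied shortest
paths between IRS1 and autophagy, one through a signaling intermediate
(degree product 12) and one through the taxon hub (degree product 16), a
drug node for augmentation, and an isolated node for the disconnected-pair
and SIF edge cases. `random_kg()` generates seeded multigraphs with a
designated hub fraction (default 0.1) wired at 10× attachment weight and
predominantly `only_in_taxon` hub edges, so hub avoidance, constraint
filtering and category augmentation are exercised non-trivially; node ids
are CURIEs whose prefix encodes the category, so serialization closure holds
across both TSV dialects.

These fixtures reproduce the *structural* pathologies of real KGs (hubs,
parallel predicates, ambiguous labels, disconnection) at desk scale. They do
not emulate real degree distributions, ontology vocabularies or
million-edge scale, so passing tests demonstrate correctness of the
algorithms and contracts — not retrieval quality on any particular public KG
build, which depends on the build's content and version. Test and
verification problem sizes — 12-node/25-edge graphs for the path-search
oracle (100 seeds), 14-node graphs for augmentation brute force (50 seeds),
a 200-node/600-edge graph for the embedding contract — were chosen as the
smallest sizes at which every behavior of interest (ties, hubs, parallel
edges, multi-component graphs) occurs routinely.

## Numerical choices and degenerate inputs

* PDP uses `prod()` of double-precision degrees; at schematic path lengths
  (a handful of intermediates) overflow is unreachable.
* Cosine similarity refuses zero-norm vectors (error, not `NaN`).
* A zero-length path scores PDP 1 (empty product) and CS 0 (empty sum).
* Degenerate inputs are kept total where a partial result is useful (empty
  example file → empty subgraph and header-only outputs; disconnected pair
  → `NONE` row) and fail fast where silence would corrupt results (unknown
  node ids, missing embeddings, malformed TSV rows with their line number,
  unknown config keys).

## Known limitations

* Direction and sign (activation/inhibition arrows) are not modelled;
  undirected search can select paths whose stored directions do not compose.
* Indexing is lexical only; synonym expansion and protein-family grounding
  (e.g. a generic "AKT" standing for three isoforms) are out of scope, and
  the package surfaces the ambiguity rather than resolving it.
* Layout, glyphs and aesthetics are explicitly not produced — the output is
  a semantic schematic for a drawing tool, not a drawing.
* Embedding vectors are comparable only within one training run; the cache
  exists so one table serves a whole analysis.
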