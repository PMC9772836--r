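#' Ontological-category filter for neighbor augmentation
#'
#' Augmentation restricts added neighbors to stated ontological categories
#' (for instance `"drug"`, to surface compounds targeting pathway proteins).
#' A node's category is its explicit category field when present; otherwise
#' the CURIE prefix of its id, optionally translated through `prefix_map`
#' (e.g. `c(DrugCentral = "drug", PharmGKB = "drug")`), stands in.
#'
#' @param categories Non-empty character vector of allowed categories.
#' @param prefix_map Optional named character vector mapping CURIE prefixes
#'   to category names for nodes without an explicit category.
#' @return A `category_filter` object.
#' @examples
#' category_filter("drug")
#' @export
category_filter <- function(categories, prefix_map = NULL) {
  categories <- as.character(categories)
  if (length(categories) == 0) {
    abort("`categories` must be non-empty.")
  }
  if (!is.null(prefix_map) && is.null(names(prefix_map))) {
    abort("`prefix_map` must be a named character vector.")
  }
  structure(list(categories = categories, prefix_map = prefix_map),
            class = "category_filter")
}

#' Resolve the effective category of every knowledge-graph node
#'
#' @param kg A `knowledge_graph`.
#' @param prefix_map Optional prefix-to-category mapping (see
#'   [category_filter()]).
#' @return Named character vector: node id -> category.
#' @export
node_categories <- function(kg, prefix_map = NULL) {
  assert_kg(kg)
  cats <- kg$nodes$category
  if (!is.null(prefix_map)) {
    mapped <- unname(prefix_map[cats])
    cats <- ifelse(is.na(mapped), cats, mapped)
  }
  setNames(cats, kg$nodes$id)
}

#' Augment a subgraph with category-filtered nearest neighbors
#'
#' Scans the immediate neighbors of the extracted (non-augmented) subgraph
#' nodes and adds every neighbor whose category passes the filter, together
#' with all edges linking it to those nodes. Added nodes carry provenance
#' `"augmented"`; the original subgraph content is untouched. Because only
#' non-augmented nodes seed the scan, the operation is idempotent — a second
#' pass with the same filter adds nothing — and edges between two augmented
#' nodes are never introduced.
#'
#' @param kg The full `knowledge_graph`.
#' @param sg A [kg_subgraph()] whose nodes all exist in `kg`.
#' @param filter A [category_filter()].
#' @return A new `kg_subgraph` containing `sg` plus the admitted neighbors.
#' @examples
#' kg <- toy_kg_a()
#' sg <- paths_to_subgraph(kg, list(rank_paths(kg_shortest_paths(kg, "n2", "n3"),
#'                                             "pdp", kg = kg)),
#'                         input_ids = c("n2", "n3"))
#' augment_neighbors(kg, sg, category_filter("drug"))
#' @export
augment_neighbors <- function(kg, sg, filter) {
  assert_kg(kg)
  assert_subgraph(sg)
  stopifnot(inherits(filter, "category_filter"))
  assert_node(kg, sg$nodes$id)

  seeds <- sg$nodes$id[sg$nodes$provenance != "augmented"]
  cats <- node_categories(kg, filter$prefix_map)
  present <- sg$nodes$id

  cand <- purrr::map_dfr(seeds, function(v) {
    nb <- kg_neighbors(kg, v)
    nb[!(nb$neighbor %in% present) &
         cats[nb$neighbor] %in% filter$categories, , drop = FALSE]
  })
  if (nrow(cand) == 0) return(sg)

  new_ids <- sort(unique(cand$neighbor))
  new_nodes <- kg$nodes[match(new_ids, kg$nodes$id), , drop = FALSE]
  new_nodes$provenance <- "augmented"
  new_edges <- dplyr::distinct(cand[, c("subject", "predicate", "object")])
  # drop edges already present in the subgraph
  key <- function(e) paste(e$subject, e$predicate, e$object, sep = "\r")
  new_edges <- new_edges[!(key(new_edges) %in% key(sg$edges)), , drop = FALSE]
  if (nrow(new_edges) > 0) new_edges$provenance <- "augmented"

  kg_subgraph(dplyr::bind_rows(sg$nodes, new_nodes),
              dplyr::bind_rows(sg$edges, new_edges),
              sg$pair_index)
}
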