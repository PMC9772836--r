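#' Build a knowledge graph from node and edge tables
#'
#' A knowledge graph is a labelled multigraph: nodes are ontology-grounded
#' entities (genes, proteins, processes, drugs, ...) identified by a CURIE or
#' IRI string, and edges are predicate-labelled triples
#' (`subject`, `predicate`, `object`). Triples are stored with their original
#' direction, but all traversal (degree, neighbors, shortest paths) uses the
#' undirected view, since path search over biomedical KGs is routinely done
#' without regard to direction.
#'
#' Parallel edges (same endpoints, different predicate) are kept as distinct
#' edges and each contributes to degree; predicate identity matters for
#' edge-class constraints. Self-loops are permitted and contribute 1 to degree.
#'
#' @param nodes A data frame with columns `id` (non-empty, unique), `label`
#'   (may be empty, never `NA`) and optionally `category`. Missing `category`
#'   entries default to the CURIE prefix of the id (text before the first
#'   `":"`, or `""` when there is none).
#' @param edges A data frame with columns `subject`, `predicate`, `object`;
#'   both endpoints must appear in `nodes$id`.
#' @return An object of class `knowledge_graph` with components `nodes`
#'   (tibble), `edges` (tibble) and a derived adjacency index.
#' @examples
#' kg <- toy_kg_a()
#' kg
#' kg_degree(kg, "n5")
#' @export
knowledge_graph <- function(nodes, edges = NULL) {
  nodes <- as_tibble(nodes)
  if (!all(c("id", "label") %in% names(nodes))) {
    abort("`nodes` must have columns `id` and `label`.")
  }
  nodes$id <- as.character(nodes$id)
  nodes$label <- as.character(nodes$label)
  nodes$label[is.na(nodes$label)] <- ""
  if (!"category" %in% names(nodes)) nodes$category <- NA_character_
  nodes$category <- as.character(nodes$category)
  missing_cat <- is.na(nodes$category) | nodes$category == ""
  nodes$category[missing_cat] <- curie_prefix(nodes$id[missing_cat])
  nodes <- nodes[, c("id", "label", "category")]

  if (any(nodes$id == "" | is.na(nodes$id))) {
    abort("Node ids must be non-empty.")
  }
  if (anyDuplicated(nodes$id)) {
    dup <- unique(nodes$id[duplicated(nodes$id)])
    abort(paste0("Duplicate node id(s): ", paste(head(dup, 5), collapse = ", ")))
  }

  if (is.null(edges)) {
    edges <- tibble(subject = character(), predicate = character(),
                    object = character())
  }
  edges <- as_tibble(edges)
  if (!all(c("subject", "predicate", "object") %in% names(edges))) {
    abort("`edges` must have columns `subject`, `predicate` and `object`.")
  }
  edges <- edges[, c("subject", "predicate", "object")]
  edges$subject <- as.character(edges$subject)
  edges$predicate <- as.character(edges$predicate)
  edges$object <- as.character(edges$object)

  unknown <- setdiff(c(edges$subject, edges$object), nodes$id)
  if (length(unknown) > 0) {
    abort(paste0("Edge endpoint(s) absent from node table: ",
                 paste(head(unknown, 5), collapse = ", ")),
          class = "kg_missing_node")
  }

  structure(
    list(nodes = nodes, edges = edges, adjacency = build_adjacency(nodes, edges)),
    class = "knowledge_graph"
  )
}

# adjacency: node id -> integer indices of incident edges (self-loops once)
build_adjacency <- function(nodes, edges) {
  m <- nrow(edges)
  loops <- edges$object == edges$subject
  idx <- c(seq_len(m), seq_len(m)[!loops])
  at <- c(edges$subject, edges$object[!loops])
  adj <- split(idx, factor(at, levels = nodes$id))
  lapply(adj, sort)
}

curie_prefix <- function(id) {
  has <- grepl(":", id, fixed = TRUE)
  ifelse(has, sub(":.*$", "", id), "")
}

#' @export
print.knowledge_graph <- function(x, ...) {
  cat(sprintf("<knowledge_graph> %d nodes, %d edges, %d predicate classes\n",
              nrow(x$nodes), nrow(x$edges), length(unique(x$edges$predicate))))
  invisible(x)
}

is_knowledge_graph <- function(x) inherits(x, "knowledge_graph")

assert_kg <- function(kg) {
  if (!is_knowledge_graph(kg)) abort("Expected a `knowledge_graph` object.")
  invisible(kg)
}

assert_node <- function(kg, v) {
  missing <- setdiff(v, kg$nodes$id)
  if (length(missing) > 0) {
    abort(paste0("Unknown node id(s): ", paste(missing, collapse = ", ")),
          class = "kg_missing_node")
  }
  invisible(v)
}

#' Node tables and edge tables of a knowledge graph
#'
#' @param kg A `knowledge_graph`.
#' @return A tibble: nodes (`id`, `label`, `category`) or edges
#'   (`subject`, `predicate`, `object`).
#' @export
kg_nodes <- function(kg) {
  assert_kg(kg)
  kg$nodes
}

#' @rdname kg_nodes
#' @export
kg_edges <- function(kg) {
  assert_kg(kg)
  kg$edges
}

#' Undirected degree of knowledge-graph nodes
#'
#' Counts incident edges in the undirected multigraph view. Parallel edges
#' each count; a self-loop counts once. This is the degree `d` used by the
#' path-degree-product ranking, which prefers paths through low-degree
#' intermediates and thereby avoids hubs such as taxon nodes.
#'
#' @param kg A `knowledge_graph`.
#' @param v Character vector of node ids.
#' @return Integer vector of degrees, one per element of `v`.
#' @examples
#' kg_degree(toy_kg_a(), c("n4", "n5"))
#' @export
kg_degree <- function(kg, v) {
  assert_kg(kg)
  assert_node(kg, v)
  lengths(kg$adjacency[v])
}

#' Neighbors of a node in the undirected view
#'
#' Returns one row per incident edge, so a neighbor linked by two parallel
#' predicates appears twice. When `predicates` is given, only edges whose
#' predicate is in that set are traversed; an empty character vector
#' traverses nothing.
#'
#' @param kg A `knowledge_graph`.
#' @param v A single node id.
#' @param predicates Optional character vector of predicate classes to
#'   restrict traversal to (`NULL` means no restriction).
#' @return A tibble with columns `neighbor`, `subject`, `predicate`,
#'   `object`, ordered by neighbor id then predicate.
#' @examples
#' kg_neighbors(toy_kg_a(), "n3")
#' kg_neighbors(toy_kg_a(), "n3", predicates = "targets")
#' @export
kg_neighbors <- function(kg, v, predicates = NULL) {
  assert_kg(kg)
  stopifnot(length(v) == 1)
  assert_node(kg, v)
  e <- kg$edges[kg$adjacency[[v]], , drop = FALSE]
  if (!is.null(predicates)) {
    e <- e[e$predicate %in% predicates, , drop = FALSE]
  }
  out <- tibble(
    neighbor = as.character(ifelse(e$subject == v, e$object, e$subject)),
    subject = e$subject,
    predicate = e$predicate,
    object = e$object
  )
  out[order(out$neighbor, out$predicate, out$subject), ]
}

# distinct neighbor ids, sorted (traversal helper used by BFS / walks)
kg_neighbor_ids <- function(kg, v) {
  e <- kg$edges[kg$adjacency[[v]], , drop = FALSE]
  sort(unique(ifelse(e$subject == v, e$object, e$subject)))
}
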