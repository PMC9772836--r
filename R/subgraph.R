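#' An extracted schematic subgraph
#'
#' The union of the selected shortest paths over all concept pairs, plus any
#' augmented neighbors. Every node carries a provenance flag: `"input"`
#' (a resolved concept), `"intermediate"` (introduced by path search) or
#' `"augmented"` (added by neighbor augmentation). Edges carry provenance
#' `"path"` or `"augmented"`.
#'
#' @param nodes Tibble with columns `id`, `label`, `category`, `provenance`.
#' @param edges Tibble with columns `subject`, `predicate`, `object` and
#'   optionally `provenance` (defaults to `"path"`).
#' @param pair_index Optional named list mapping `"source|target"` keys to
#'   the selected [kg_path()] for that pair.
#' @return A `kg_subgraph` object.
#' @export
kg_subgraph <- function(nodes, edges, pair_index = list()) {
  nodes <- as_tibble(nodes)
  edges <- as_tibble(edges)
  stopifnot(all(c("id", "label", "category", "provenance") %in% names(nodes)))
  stopifnot(all(c("subject", "predicate", "object") %in% names(edges)))
  if (!"provenance" %in% names(edges)) {
    edges$provenance <- rep("path", nrow(edges))
  }
  if (anyDuplicated(nodes$id)) abort("Duplicate node ids in subgraph.")
  dangling <- setdiff(c(edges$subject, edges$object), nodes$id)
  if (length(dangling) > 0) {
    abort(paste0("Subgraph edges reference missing node(s): ",
                 paste(head(dangling, 5), collapse = ", ")),
          class = "kg_missing_node")
  }
  structure(list(nodes = nodes, edges = edges, pair_index = pair_index),
            class = "kg_subgraph")
}

assert_subgraph <- function(sg) {
  if (!inherits(sg, "kg_subgraph")) abort("Expected a `kg_subgraph` object.")
  invisible(sg)
}

#' @export
print.kg_subgraph <- function(x, ...) {
  prov <- table(x$nodes$provenance)
  cat(sprintf("<kg_subgraph> %d nodes (%s), %d edges, %d pair(s)\n",
              nrow(x$nodes),
              paste(sprintf("%s: %d", names(prov), prov), collapse = ", "),
              nrow(x$edges), length(x$pair_index)))
  invisible(x)
}

#' Assemble a subgraph from selected paths
#'
#' Takes the set union of the selected path per pair: nodes appearing as
#' resolved inputs are flagged `"input"`, every other path node
#' `"intermediate"`. Duplicate edges across pairs collapse to one.
#'
#' @param kg The source `knowledge_graph`.
#' @param ranked A list of `ranked_paths` results (one per pair); pairs with
#'   no path contribute only their endpoint input nodes when these resolved.
#' @param input_ids Character vector of resolved input node ids.
#' @return A [kg_subgraph()].
#' @export
paths_to_subgraph <- function(kg, ranked, input_ids) {
  assert_kg(kg)
  sel <- purrr::compact(purrr::map(ranked, selected_path))
  path_nodes <- unique(unlist(purrr::map(sel, "nodes")))
  all_ids <- unique(c(input_ids, path_nodes))
  assert_node(kg, all_ids)
  edges <- purrr::map_dfr(sel, "edges")
  edges <- dplyr::distinct(edges)
  if (nrow(edges) > 0) edges$provenance <- "path"
  else edges <- tibble(subject = character(), predicate = character(),
                       object = character(), provenance = character())
  nodes <- kg$nodes[match(all_ids, kg$nodes$id), , drop = FALSE]
  nodes$provenance <- ifelse(nodes$id %in% input_ids, "input", "intermediate")
  keys <- purrr::map(ranked, function(rp) {
    paste(rp$pair[["source"]], rp$pair[["target"]], sep = "|")
  })
  pair_index <- setNames(purrr::map(ranked, selected_path), keys)
  kg_subgraph(nodes, edges, pair_index)
}

#' @method tidy kg_subgraph
#' @export
tidy.kg_subgraph <- function(x, ...) x$nodes

#' @method glance kg_subgraph
#' @export
glance.kg_subgraph <- function(x, ...) {
  tibble(
    n_nodes = nrow(x$nodes),
    n_edges = nrow(x$edges),
    n_input = sum(x$nodes$provenance == "input"),
    n_intermediate = sum(x$nodes$provenance == "intermediate"),
    n_augmented = sum(x$nodes$provenance == "augmented"),
    n_pairs = length(x$pair_index)
  )
}
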