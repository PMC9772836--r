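#' A path through a knowledge graph
#'
#' A simple (node-distinct) path: an ordered node-id sequence plus one edge
#' record per hop. Where two nodes are joined by parallel edges the
#' representative edge is the one whose predicate sorts first (then edge-table
#' order); [expand_edge_variants()] enumerates the alternatives.
#'
#' @param nodes Character vector of node ids.
#' @param edges A tibble of edge records (`subject`, `predicate`, `object`),
#'   one row per consecutive node pair.
#' @return A `kg_path` object with fields `nodes`, `edges`, `length`.
#' @export
kg_path <- function(nodes, edges) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes) && length(nodes) > 1) {
    abort("A path must visit distinct nodes.")
  }
  edges <- as_tibble(edges)
  if (nrow(edges) != max(length(nodes) - 1L, 0L)) {
    abort("A path needs exactly one edge per consecutive node pair.")
  }
  structure(list(nodes = nodes, edges = edges, length = nrow(edges)),
            class = "kg_path")
}

#' @export
print.kg_path <- function(x, ...) {
  cat(sprintf("<kg_path> %s (length %d)\n", path_string(x), x$length))
  invisible(x)
}

path_string <- function(path) paste(path$nodes, collapse = " -> ")

# deterministic representative edge for an unordered node pair
edges_between <- function(kg, a, b) {
  idx <- intersect(kg$adjacency[[a]], kg$adjacency[[b]])
  if (a == b) idx <- kg$adjacency[[a]][kg$edges$subject[kg$adjacency[[a]]] == kg$edges$object[kg$adjacency[[a]]]]
  e <- kg$edges[idx, , drop = FALSE]
  e[order(e$predicate, e$subject, e$object), , drop = FALSE]
}

edges_for_sequence <- function(kg, nodes, pick = 1L) {
  if (length(nodes) < 2) {
    return(tibble(subject = character(), predicate = character(),
                  object = character()))
  }
  purrr::map_dfr(seq_len(length(nodes) - 1L), function(i) {
    edges_between(kg, nodes[i], nodes[i + 1L])[pick, , drop = FALSE]
  })
}

#' Enumerate all tied shortest paths between two nodes
#'
#' Breadth-first search over the undirected view of the triples, followed by
#' depth-first traversal of the shortest-path DAG. All distinct shortest
#' *node sequences* are returned (parallel edges between a node pair do not
#' multiply the count; see [expand_edge_variants()]), in lexicographic order
#' of the node-id sequence. Real KG pairs routinely tie on dozens of equally
#' short paths, which is why the downstream ranking actions exist.
#'
#' @param kg A `knowledge_graph`.
#' @param source,target Node ids. When identical, a single zero-length path
#'   is returned.
#' @param max_paths Truncate the enumeration after this many paths; the
#'   result then carries `attr(, "truncated") = TRUE` and a warning is
#'   emitted. Default 500.
#' @return A list of [kg_path()] objects (empty when the endpoints are
#'   disconnected), with attribute `truncated`.
#' @examples
#' kg_shortest_paths(toy_kg_a(), "n1", "n4")
#' @export
kg_shortest_paths <- function(kg, source, target, max_paths = 500L) {
  assert_kg(kg)
  assert_node(kg, c(source, target))
  if (!is.numeric(max_paths) || max_paths < 1) {
    abort("`max_paths` must be a positive integer.")
  }
  max_paths <- as.integer(max_paths)

  if (source == target) {
    out <- list(kg_path(source, tibble(subject = character(),
                                       predicate = character(),
                                       object = character())))
    attr(out, "truncated") <- FALSE
    return(out)
  }

  dist <- bfs_distances(kg, source)
  if (is.na(dist[[target]])) {
    out <- list()
    attr(out, "truncated") <- FALSE
    return(out)
  }

  # restrict to nodes on some shortest path: backward sweep from target
  on_path <- new.env(parent = emptyenv())
  assign(target, TRUE, envir = on_path)
  frontier <- target
  while (length(frontier) > 0) {
    nxt <- character()
    for (v in frontier) {
      preds <- kg_neighbor_ids(kg, v)
      preds <- preds[!is.na(dist[preds]) & dist[preds] == dist[[v]] - 1L]
      for (u in preds) {
        if (!exists(u, envir = on_path, inherits = FALSE)) {
          assign(u, TRUE, envir = on_path)
          nxt <- c(nxt, u)
        }
      }
    }
    frontier <- unique(nxt)
  }

  # forward DFS in lexicographic successor order emits sorted sequences
  sequences <- list()
  truncated <- FALSE
  walk <- function(prefix, v) {
    if (truncated) return()
    if (v == target) {
      if (length(sequences) >= max_paths) {
        truncated <<- TRUE
        return()
      }
      sequences[[length(sequences) + 1L]] <<- c(prefix, v)
      return()
    }
    succ <- kg_neighbor_ids(kg, v)
    succ <- succ[!is.na(dist[succ]) & dist[succ] == dist[[v]] + 1L]
    succ <- succ[vapply(succ, exists, TRUE, envir = on_path, inherits = FALSE)]
    for (w in succ) walk(c(prefix, v), w)
  }
  walk(character(), source)

  if (truncated) {
    warn(sprintf("Shortest-path enumeration for (%s, %s) truncated at %d paths.",
                 source, target, max_paths))
  }
  out <- lapply(sequences, function(ns) kg_path(ns, edges_for_sequence(kg, ns)))
  attr(out, "truncated") <- truncated
  out
}

bfs_distances <- function(kg, source) {
  dist <- setNames(rep(NA_integer_, nrow(kg$nodes)), kg$nodes$id)
  dist[[source]] <- 0L
  frontier <- source
  d <- 0L
  while (length(frontier) > 0) {
    d <- d + 1L
    nxt <- character()
    for (v in frontier) {
      for (w in kg_neighbor_ids(kg, v)) {
        if (is.na(dist[[w]])) {
          dist[[w]] <- d
          nxt <- c(nxt, w)
        }
      }
    }
    frontier <- nxt
  }
  dist
}

#' Expand a path into its parallel-edge variants
#'
#' A node sequence may be realizable through several predicate combinations
#' when consecutive nodes are joined by parallel edges. Edge-class
#' constraints need to see every combination, so this expands one path into
#' one variant per element of the Cartesian product of the per-hop edge
#' choices (deterministic order: predicate-sorted per hop, first hop varying
#' slowest).
#'
#' @param kg A `knowledge_graph`.
#' @param path A [kg_path()] valid in `kg`.
#' @return A list of `kg_path` objects; a path with no parallel edges
#'   expands to itself.
#' @export
expand_edge_variants <- function(kg, path) {
  assert_kg(kg)
  stopifnot(inherits(path, "kg_path"))
  if (path$length == 0) return(list(path))
  per_hop <- lapply(seq_len(path$length), function(i) {
    edges_between(kg, path$nodes[i], path$nodes[i + 1L])
  })
  counts <- vapply(per_hop, nrow, 0L)
  if (any(counts == 0)) abort("Path edge missing from graph.")
  combos <- expand.grid(rev(lapply(counts, seq_len)),
                        KEEP.OUT.ATTRS = FALSE)[, rev(seq_along(counts)), drop = FALSE]
  purrr::map(seq_len(nrow(combos)), function(k) {
    e <- purrr::map_dfr(seq_along(per_hop), function(i) {
      per_hop[[i]][combos[k, i], , drop = FALSE]
    })
    kg_path(path$nodes, e)
  })
}
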