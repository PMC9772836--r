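# Independent brute-force oracles. These deliberately avoid the package's
# adjacency index and scoring code paths: degrees are counted straight off
# the edge tibble, paths are enumerated by exhaustive depth-limited DFS over
# pairwise edge lookups, and scores are recomputed with naive arithmetic.

oracle_degree <- function(kg, v) {
  e <- kg_edges(kg)
  sum(e$subject == v | e$object == v)
}

oracle_adjacent_ids <- function(kg, v) {
  e <- kg_edges(kg)
  inc <- e[e$subject == v | e$object == v, , drop = FALSE]
  unique(ifelse(inc$subject == v, inc$object, inc$subject))
}

# all simple paths s -> t as "|"-joined id strings, shortest length only
oracle_shortest_sequences <- function(kg, s, t) {
  if (s == t) return(s)
  found <- character()
  n <- nrow(kg_nodes(kg))
  dfs <- function(path) {
    v <- path[length(path)]
    if (v == t) {
      found[[length(found) + 1L]] <<- paste(path, collapse = "|")
      return()
    }
    if (length(path) > n) return()
    for (w in oracle_adjacent_ids(kg, v)) {
      if (!w %in% path) dfs(c(path, w))
    }
  }
  dfs(s)
  if (length(found) == 0) return(character())
  lens <- lengths(strsplit(found, "|", fixed = TRUE))
  sort(found[lens == min(lens)])
}

oracle_pdp <- function(path, kg, w) {
  nodes <- path$nodes
  if (length(nodes) <= 2) return(1)
  inter <- nodes[-c(1, length(nodes))]
  degs <- vapply(inter, function(v) oracle_degree(kg, v), 0)
  prod(degs)^(-w)
}

oracle_cosine <- function(u, v) sum(u * v) / sqrt(sum(u^2) * sum(v^2))

oracle_cs <- function(path, emb, target) {
  others <- path$nodes[path$nodes != target]
  tv <- emb$vectors[target, ]
  sum(vapply(others, function(v) oracle_cosine(emb$vectors[v, ], tv), 0))
}

# brute-force neighbor augmentation: full scan of all edges
oracle_augment <- function(kg, seed_ids, allowed, prefix_map = NULL) {
  cats <- node_categories(kg, prefix_map)
  e <- kg_edges(kg)
  add_nodes <- character()
  add_edges <- e[0, ]
  for (i in seq_len(nrow(e))) {
    for (side in list(c(e$subject[i], e$object[i]),
                      c(e$object[i], e$subject[i]))) {
      inside <- side[1]; outside <- side[2]
      if (inside %in% seed_ids && !(outside %in% seed_ids) &&
          cats[[outside]] %in% allowed) {
        add_nodes <- union(add_nodes, outside)
        add_edges <- unique(rbind(add_edges, e[i, ]))
      }
    }
  }
  list(nodes = sort(add_nodes), edges = add_edges)
}

path_seq_string <- function(p) paste(p$nodes, collapse = "|")

# first node pair (in id order) with >= min_paths tied shortest paths
find_tied_pair <- function(kg, min_paths = 2) {
  ids <- kg_nodes(kg)$id
  for (i in seq_along(ids)) {
    for (j in seq_along(ids)) {
      if (i >= j) next
      paths <- suppressWarnings(
        kg_shortest_paths(kg, ids[i], ids[j], max_paths = 200))
      if (length(paths) >= min_paths) {
        return(list(source = ids[i], target = ids[j], paths = paths))
      }
    }
  }
  NULL
}

small_random_kg <- function(seed, n = 12, m = 25, hub_fraction = 0.15) {
  random_kg(fixture_spec(n, m, hub_fraction = hub_fraction, seed = seed))
}

# the injected 2-d table used throughout the CS examples
toy_cs_table <- function() {
  fixed_embeddings(list(n1 = c(0, 1), n2 = c(1, 0), n3 = c(0, 1),
                        n5 = c(-1, 0), n4 = c(1, 0)))
}
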