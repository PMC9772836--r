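#' Hyperparameters for node2vec embedding training
#'
#' Defaults follow the values customarily used for ranking KG paths by
#' semantic similarity: walk length 10, 20 walks per node, context window 10
#' and 128 dimensions. Walks are first-order uniform random walks over the
#' undirected multigraph (equivalent to node2vec with return and in-out
#' parameters both 1); parallel edges weight neighbor choice by multiplicity.
#'
#' @param walk_length Nodes per random walk (default 10).
#' @param num_walks Walks started from every non-isolated node (default 20).
#' @param window Skip-gram context window (default 10).
#' @param dimensions Embedding dimension (default 128).
#' @param seed Integer seed controlling both walk generation and the
#'   skip-gram trainer (default 1).
#' @param epochs Training epochs over the walk corpus (default 5).
#' @param negative Negative samples per positive pair (default 5).
#' @param learning_rate Initial SGD learning rate (default 0.025).
#' @return A `node2vec_params` object.
#' @export
node2vec_params <- function(walk_length = 10L, num_walks = 20L, window = 10L,
                            dimensions = 128L, seed = 1L, epochs = 5L,
                            negative = 5L, learning_rate = 0.025) {
  vals <- c(walk_length = walk_length, num_walks = num_walks, window = window,
            dimensions = dimensions, epochs = epochs, negative = negative)
  if (any(vals < 1)) abort("All node2vec count parameters must be positive.")
  if (learning_rate <= 0) abort("`learning_rate` must be positive.")
  structure(list(walk_length = as.integer(walk_length),
                 num_walks = as.integer(num_walks),
                 window = as.integer(window),
                 dimensions = as.integer(dimensions),
                 seed = as.integer(seed),
                 epochs = as.integer(epochs),
                 negative = as.integer(negative),
                 learning_rate = learning_rate),
            class = "node2vec_params")
}

new_embedding_table <- function(mat) {
  structure(list(vectors = mat, dimension = ncol(mat)),
            class = "embedding_table")
}

#' @export
print.embedding_table <- function(x, ...) {
  cat(sprintf("<embedding_table> %d nodes x %d dimensions\n",
              nrow(x$vectors), x$dimension))
  invisible(x)
}

#' Wrap explicit per-node vectors as an embedding table
#'
#' Lets path scoring run on hand-chosen vectors, bypassing stochastic
#' training — the standard way to test cosine-similarity ranking exactly.
#'
#' @param assignments A named list of equal-length numeric vectors, one per
#'   node id.
#' @return An `embedding_table`.
#' @examples
#' fixed_embeddings(list(a = c(1, 0), b = c(0, 1)))
#' @export
fixed_embeddings <- function(assignments) {
  if (length(assignments) == 0 || is.null(names(assignments))) {
    abort("`assignments` must be a non-empty named list.")
  }
  dims <- lengths(assignments)
  if (length(unique(dims)) != 1) {
    abort("All embedding vectors must share one dimension.",
          class = "kg_embedding_error")
  }
  mat <- do.call(rbind, lapply(assignments, as.numeric))
  rownames(mat) <- names(assignments)
  new_embedding_table(mat)
}

#' Look up one node's embedding vector
#'
#' @param emb An `embedding_table`.
#' @param id Node id. A missing entry is an error, never a silent zero
#'   vector.
#' @return Numeric vector of length `emb$dimension`.
#' @export
embedding_vector <- function(emb, id) {
  stopifnot(inherits(emb, "embedding_table"))
  if (!id %in% rownames(emb$vectors)) {
    abort(paste0("No embedding for node: ", id),
          class = "kg_missing_embedding")
  }
  emb$vectors[id, ]
}

#' Train node2vec embeddings for every node of a knowledge graph
#'
#' Generates seeded uniform random walks over the undirected multigraph and
#' trains a single-threaded skip-gram model with negative sampling on the
#' walk corpus. The run is deterministic for a fixed
#' [node2vec_params()] `seed`. Isolated nodes never appear in walks; they
#' keep their (seed-determined) initialization vectors so the table covers
#' the whole graph.
#'
#' @param kg A `knowledge_graph` with at least one edge.
#' @param params A [node2vec_params()].
#' @return An `embedding_table` covering every node of `kg`.
#' @export
train_embeddings <- function(kg, params = node2vec_params()) {
  assert_kg(kg)
  stopifnot(inherits(params, "node2vec_params"))
  if (nrow(kg$edges) == 0) {
    abort("Cannot train embeddings on a graph with no edges (walks undefined).",
          class = "kg_embedding_error")
  }
  ids <- kg$nodes$id
  # per-edge neighbor lists weight transition choice by edge multiplicity
  nbrs <- lapply(ids, function(v) {
    e <- kg$edges[kg$adjacency[[v]], , drop = FALSE]
    as.character(ifelse(e$subject == v, e$object, e$subject))
  })
  names(nbrs) <- ids
  active <- ids[lengths(nbrs) > 0]

  withr::with_seed(params$seed, {
    walks <- vector("list", length(active) * params$num_walks)
    k <- 0L
    for (rep in seq_len(params$num_walks)) {
      for (start in active) {
        walk <- integer(params$walk_length)
        cur <- start
        walk[1] <- match(cur, ids)
        for (step in seq_len(params$walk_length - 1L)) {
          nb <- nbrs[[cur]]
          cur <- nb[[sample.int(length(nb), 1L)]]
          walk[step + 1L] <- match(cur, ids)
        }
        k <- k + 1L
        walks[[k]] <- walk - 1L
      }
    }
    cpp_seed <- sample.int(.Machine$integer.max, 1L)
  })

  mat <- sgns_train(walks, length(ids), params$dimensions, params$window,
                    params$negative, params$epochs, params$learning_rate,
                    as.double(cpp_seed))
  rownames(mat) <- ids
  new_embedding_table(mat)
}

#' Read or write an embedding cache as a TSV of id + vector
#'
#' Stores vectors with round-trip-exact decimal formatting, so a cached
#' table reloads bit-identically and downstream rankings are unchanged.
#'
#' @param emb An `embedding_table`.
#' @param path Cache file path.
#' @return `write_embeddings()` returns `path` invisibly;
#'   `read_embeddings()` returns an `embedding_table`.
#' @export
write_embeddings <- function(emb, path) {
  stopifnot(inherits(emb, "embedding_table"))
  tab <- as_tibble(emb$vectors, .name_repair = ~ paste0("d", seq_along(.x)))
  tab <- dplyr::bind_cols(tibble(id = rownames(emb$vectors)), tab)
  readr::write_tsv(tab, path, escape = "none")
  invisible(path)
}

#' @rdname write_embeddings
#' @export
read_embeddings <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(
    id = readr::col_character(), .default = readr::col_double()))
  mat <- as.matrix(tab[, -1, drop = FALSE])
  rownames(mat) <- tab$id
  colnames(mat) <- NULL
  new_embedding_table(mat)
}

#' Cosine similarity between two vectors
#'
#' @param u,v Numeric vectors of equal length with non-zero norm.
#' @return The cosine of the angle between `u` and `v`, in `[-1, 1]`.
#' @examples
#' cosine_similarity(c(1, 0), c(0, 1))
#' @export
cosine_similarity <- function(u, v) {
  if (length(u) != length(v)) {
    abort("Vectors must share a dimension.")
  }
  nu <- sqrt(sum(u^2))
  nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) {
    abort("Cosine similarity is undefined for a zero-norm vector.",
          class = "kg_undefined_similarity")
  }
  sum(u * v) / (nu * nv)
}
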