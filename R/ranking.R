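#' Path-degree-product score of a path
#'
#' `PDP(path) = (prod of degrees of the intermediate nodes)^(-w)`. Higher is
#' better: a path whose intermediates have low degree scores above one
#' running through a hub (for example a taxon node attached to most of the
#' graph), so maximizing PDP steers the schematic toward specific molecular
#' interactions instead of generic facts. A path with no intermediate node
#' scores 1. Endpoint degrees are shared by every path of a pair and are
#' deliberately excluded; since `x^(-w)` is a monotone transform for every
#' `w > 0`, the induced ranking does not depend on the damping exponent.
#'
#' @param path A [kg_path()].
#' @param kg The `knowledge_graph` the path lives in.
#' @param w Positive damping exponent (default 0.4).
#' @return A single positive number.
#' @examples
#' kg <- toy_kg_a()
#' p <- kg_shortest_paths(kg, "n1", "n4")[[1]]
#' score_pdp(p, kg, w = 1)
#' @export
score_pdp <- function(path, kg, w = 0.4) {
  stopifnot(inherits(path, "kg_path"))
  assert_kg(kg)
  if (!is.numeric(w) || w <= 0) abort("`w` must be a positive real.")
  n <- length(path$nodes)
  if (n <= 2) return(1)
  inter <- path$nodes[-c(1L, n)]
  degs <- kg_degree(kg, inter)
  stopifnot(all(degs > 0))  # a node on a path has at least its path edges
  prod(as.numeric(degs))^(-w)
}

#' Cosine-similarity score of a path toward its target
#'
#' Sums the cosine similarity between the target node's embedding and the
#' embedding of every other node along the path (source and intermediates).
#' Higher is better: the path gets — and stays — semantically close to the
#' target. A zero-length path (source equals target) scores 0.
#'
#' @param path A [kg_path()].
#' @param emb An `embedding_table` covering every path node.
#' @param target Node id of the pair's target (must have an embedding).
#' @return A single number in `[-L, L]` for a length-`L` path.
#' @export
score_cs <- function(path, emb, target) {
  stopifnot(inherits(path, "kg_path"))
  tvec <- embedding_vector(emb, target)
  others <- path$nodes[path$nodes != target]
  if (length(others) == 0) return(0)
  sum(vapply(others, function(v) {
    cosine_similarity(embedding_vector(emb, v), tvec)
  }, 0))
}

#' Edge-class constraints on candidate paths
#'
#' Requirements or prohibitions of edge classes (predicates) along a path.
#' A path survives when it contains no prohibited predicate and — if any
#' predicate is required — at least one required predicate. With
#' `soft = TRUE` a constraint that would eliminate every path is ignored
#' instead, and the relaxation is flagged.
#'
#' @param require Character vector of predicates at least one of which must
#'   appear on a surviving path (empty = no requirement).
#' @param prohibit Character vector of predicates that must not appear.
#' @param soft Fall back to the unconstrained set when nothing survives?
#' @return An `edge_constraint` object.
#' @examples
#' edge_constraint(prohibit = "only_in_taxon")
#' @export
edge_constraint <- function(require = character(), prohibit = character(),
                            soft = FALSE) {
  require <- as.character(require)
  prohibit <- as.character(prohibit)
  if (length(intersect(require, prohibit)) > 0) {
    abort("A predicate cannot be both required and prohibited.")
  }
  structure(list(require = require, prohibit = prohibit, soft = isTRUE(soft)),
            class = "edge_constraint")
}

#' Filter path variants by an edge-class constraint
#'
#' @param paths A list of [kg_path()] objects (typically the output of
#'   [expand_edge_variants()] over all tied shortest paths).
#' @param constraint An [edge_constraint()].
#' @return A list with components `paths` (the survivors, or the original
#'   list when a soft constraint was relaxed) and `relaxed` (logical).
#' @export
apply_edge_constraints <- function(paths, constraint) {
  stopifnot(inherits(constraint, "edge_constraint"))
  keep <- vapply(paths, function(p) {
    preds <- p$edges$predicate
    if (any(preds %in% constraint$prohibit)) return(FALSE)
    if (length(constraint$require) > 0 &&
        !any(preds %in% constraint$require)) return(FALSE)
    TRUE
  }, TRUE)
  survivors <- paths[keep]
  if (length(survivors) == 0 && length(paths) > 0 && constraint$soft) {
    return(list(paths = paths, relaxed = TRUE))
  }
  list(paths = survivors, relaxed = FALSE)
}

# deterministic tie-break key: length, node sequence, predicate sequence
path_sort_key <- function(p) {
  paste(formatC(p$length, width = 6, flag = "0"),
        paste(p$nodes, collapse = "\r"),
        paste(p$edges$predicate, collapse = "\r"))
}

#' Rank tied shortest paths by a semantic graphical action
#'
#' Applies the edge-class constraint first (constraints dominate scoring),
#' scores the survivors by the chosen action, and orders them best-first.
#' Ties are broken by path length, then lexicographic node sequence, then
#' predicate sequence, so a ranking is reproducible across runs. The full
#' ordering is retained so two actions' rankings over the same path set can
#' be compared.
#'
#' @param paths List of [kg_path()] objects sharing endpoints.
#' @param action `"pdp"` or `"cs"`.
#' @param kg The `knowledge_graph` (required for PDP).
#' @param w PDP damping exponent (default 0.4).
#' @param embeddings An `embedding_table` (required for CS).
#' @param target Target node id (required for CS).
#' @param constraint Optional [edge_constraint()].
#' @param pair Optional named character vector `c(source=, target=)` for
#'   reporting; inferred from the first path when omitted.
#' @return A `ranked_paths` object: paths in best-first order with scores;
#'   see [tidy.ranked_paths()].
#' @examples
#' kg <- toy_kg_a()
#' paths <- kg_shortest_paths(kg, "n1", "n4")
#' rank_paths(paths, "pdp", kg = kg, w = 1)
#' @export
rank_paths <- function(paths, action = c("pdp", "cs"), kg = NULL, w = 0.4,
                       embeddings = NULL, target = NULL, constraint = NULL,
                       pair = NULL) {
  action <- match.arg(action)
  if (is.null(pair)) {
    if (length(paths) > 0) {
      p1 <- paths[[1]]
      pair <- c(source = p1$nodes[1], target = p1$nodes[length(p1$nodes)])
    } else {
      pair <- c(source = NA_character_, target = NA_character_)
    }
  }
  relaxed <- FALSE
  if (!is.null(constraint)) {
    res <- apply_edge_constraints(paths, constraint)
    relaxed <- res$relaxed
    if (length(res$paths) == 0 && length(paths) > 0) {
      abort(sprintf("No path between %s and %s satisfies the hard edge constraint.",
                    pair[["source"]], pair[["target"]]),
            class = "kg_no_path_after_constraint")
    }
    paths <- res$paths
  }

  scores <- switch(action,
    pdp = {
      if (is.null(kg)) abort("PDP ranking needs `kg`.")
      vapply(paths, score_pdp, 0, kg = kg, w = w)
    },
    cs = {
      if (is.null(embeddings)) abort("CS ranking needs `embeddings`.")
      tgt <- target %||% pair[["target"]]
      vapply(paths, score_cs, 0, emb = embeddings, target = tgt)
    }
  )
  if (length(paths) > 0 && !all(is.finite(scores))) {
    abort("Path scores must be finite.")
  }

  keys <- vapply(paths, path_sort_key, "")
  ord <- order(-scores, keys)

  structure(
    list(pair = pair, action = action, w = if (action == "pdp") w else NA_real_,
         paths = paths[ord], scores = scores[ord], relaxed = relaxed),
    class = "ranked_paths"
  )
}

#' Selected (top-ranked) path of a ranking
#'
#' @param rp A `ranked_paths` object.
#' @return A [kg_path()], or `NULL` when the pair had no path.
#' @export
selected_path <- function(rp) {
  stopifnot(inherits(rp, "ranked_paths"))
  if (length(rp$paths) == 0) return(NULL)
  rp$paths[[1]]
}

#' @export
print.ranked_paths <- function(x, ...) {
  cat(sprintf("<ranked_paths> pair (%s -> %s), action %s, %d path(s)%s\n",
              x$pair[["source"]], x$pair[["target"]], toupper(x$action),
              length(x$paths),
              if (x$relaxed) ", constraint relaxed" else ""))
  if (length(x$paths) > 0) {
    cat(sprintf("  selected: %s (score %.6g)\n",
                path_string(x$paths[[1]]), x$scores[[1]]))
  }
  invisible(x)
}

#' Tidy a path ranking into a tibble
#'
#' @param x A `ranked_paths` object.
#' @param ... Unused.
#' @return One row per path: `path`, `length`, `score`, `rank`, `selected`.
#' @method tidy ranked_paths
#' @export
tidy.ranked_paths <- function(x, ...) {
  if (length(x$paths) == 0) {
    return(tibble(path = character(), length = integer(), score = double(),
                  rank = integer(), selected = logical()))
  }
  tibble(
    path = vapply(x$paths, path_string, ""),
    length = vapply(x$paths, function(p) p$length, 0L),
    score = x$scores,
    rank = seq_along(x$paths),
    selected = seq_along(x$paths) == 1L
  )
}

#' One-row summary of a path ranking
#'
#' @param x A `ranked_paths` object.
#' @param ... Unused.
#' @return A one-row tibble: pair ids, action, path count, selected path
#'   string and score, relaxation flag.
#' @method glance ranked_paths
#' @export
glance.ranked_paths <- function(x, ...) {
  tibble(
    source = x$pair[["source"]], target = x$pair[["target"]],
    action = x$action, n_paths = length(x$paths),
    selected = if (length(x$paths) > 0) path_string(x$paths[[1]]) else NA_character_,
    best_score = if (length(x$paths) > 0) x$scores[[1]] else NA_real_,
    constraint_relaxed = x$relaxed
  )
}

#' Plot the score profile of a path ranking
#'
#' @param object A `ranked_paths` object.
#' @param ... Unused.
#' @return A ggplot: score against rank, selected path highlighted.
#' @method autoplot ranked_paths
#' @export
autoplot.ranked_paths <- function(object, ...) {
  tb <- tidy(object)
  ggplot2::ggplot(tb, ggplot2::aes(x = .data$rank, y = .data$score)) +
    ggplot2::geom_point(ggplot2::aes(color = .data$selected), size = 2) +
    ggplot2::scale_color_manual(values = c(`TRUE` = "#D55E00", `FALSE` = "grey40"),
                                guide = "none") +
    ggplot2::labs(x = "Rank (best first)",
                  y = paste(toupper(object$action), "score"),
                  title = sprintf("%s → %s", object$pair[["source"]],
                                  object$pair[["target"]])) +
    ggplot2::theme_minimal()
}

#' Compare two actions' rankings of the same path set
#'
#' Tied shortest paths can be ordered very differently by hub avoidance
#' (PDP) and by embedding similarity (CS); this rank-vs-rank scatter makes
#' the disagreement visible.
#'
#' @param rp_a,rp_b Two `ranked_paths` objects over the same set of paths.
#' @return A ggplot of rank under `rp_a` against rank under `rp_b`.
#' @export
plot_rank_comparison <- function(rp_a, rp_b) {
  stopifnot(inherits(rp_a, "ranked_paths"), inherits(rp_b, "ranked_paths"))
  key_a <- vapply(rp_a$paths, path_sort_key, "")
  key_b <- vapply(rp_b$paths, path_sort_key, "")
  if (!setequal(key_a, key_b)) {
    abort("The two rankings must cover the same path set.")
  }
  tb <- tibble(
    path = vapply(rp_a$paths, path_string, ""),
    rank_a = seq_along(key_a),
    rank_b = match(key_a, key_b)
  )
  ggplot2::ggplot(tb, ggplot2::aes(x = .data$rank_a, y = .data$rank_b)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         color = "grey60") +
    ggplot2::geom_point(size = 2, alpha = 0.8) +
    ggplot2::labs(x = paste(toupper(rp_a$action), "rank"),
                  y = paste(toupper(rp_b$action), "rank")) +
    ggplot2::theme_minimal()
}
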