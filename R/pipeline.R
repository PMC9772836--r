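#' Configuration for a full schematic-extraction run
#'
#' Collects everything a run needs: the KG (an in-memory `knowledge_graph`
#' or node/edge file paths plus a dialect), the concept-pair examples, how
#' to resolve concepts, which ranking action to apply, edge-class
#' constraints, augmentation, and output destinations. Validation happens
#' here, before any compute.
#'
#' @param kg A `knowledge_graph`, or `NULL` to load from files.
#' @param nodes_path,edges_path KG file paths (used when `kg` is `NULL`).
#' @param dialect A [kg_dialect()] for the KG files.
#' @param examples A tibble with columns `source`/`target`, or a path to an
#'   example file (see [read_concept_pairs()]).
#' @param pinning Named character vector mapping concept labels to node
#'   ids, or a path to a pinning file; pinned labels skip candidate search.
#' @param resolution `"auto"` (top candidate, logged), `"pinned"` (every
#'   label must be pinned) or `"interactive"`.
#' @param action Ranking action, `"pdp"` or `"cs"`.
#' @param w PDP damping exponent (default 0.4).
#' @param node2vec A [node2vec_params()] for CS embedding training.
#' @param seed Integer seed for the run (overrides `node2vec$seed`).
#' @param constraint Optional [edge_constraint()].
#' @param augment Optional [category_filter()]; `NULL` disables
#'   augmentation.
#' @param embeddings Optional pre-trained `embedding_table` or path to a
#'   cache written by [write_embeddings()]; skips training for CS runs.
#' @param out_prefix Output path prefix, or `NULL` to skip writing files.
#' @param formats Output formats for [write_subgraph()].
#' @param max_paths Shortest-path truncation cap per pair (default 500).
#' @param max_results,fuzzy_threshold Candidate-search settings (see
#'   [find_candidates()]).
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(kg = NULL, nodes_path = NULL, edges_path = NULL,
                            dialect = dialect_kgx(), examples,
                            pinning = NULL, resolution = c("auto", "pinned",
                                                           "interactive"),
                            action = c("pdp", "cs"), w = 0.4,
                            node2vec = node2vec_params(), seed = 1L,
                            constraint = NULL, augment = NULL,
                            embeddings = NULL, out_prefix = NULL,
                            formats = c("graphml", "sif", "node_attributes",
                                        "edge_attributes"),
                            max_paths = 500L, max_results = 50L,
                            fuzzy_threshold = 85) {
  resolution <- match.arg(resolution)
  action <- match.arg(action)
  formats <- match.arg(formats, several.ok = TRUE)
  if (is.null(kg) && (is.null(nodes_path) || is.null(edges_path))) {
    abort("Provide either `kg` or both `nodes_path` and `edges_path`.",
          class = "kg_validation_error")
  }
  if (!is.null(kg)) assert_kg(kg)
  if (is.character(pinning) && length(pinning) == 1 && is.null(names(pinning))) {
    pinning <- read_pinning(pinning)
  }
  if (!is.null(constraint)) stopifnot(inherits(constraint, "edge_constraint"))
  if (!is.null(augment)) stopifnot(inherits(augment, "category_filter"))
  stopifnot(inherits(node2vec, "node2vec_params"))
  node2vec$seed <- as.integer(seed)
  structure(list(kg = kg, nodes_path = nodes_path, edges_path = edges_path,
                 dialect = dialect, examples = examples, pinning = pinning,
                 resolution = resolution, action = action, w = w,
                 node2vec = node2vec, seed = as.integer(seed),
                 constraint = constraint, augment = augment,
                 embeddings = embeddings, out_prefix = out_prefix,
                 formats = formats, max_paths = as.integer(max_paths),
                 max_results = as.integer(max_results),
                 fuzzy_threshold = fuzzy_threshold),
            class = "pipeline_config")
}

#' Build a pipeline configuration from a YAML file
#'
#' Flat keys mirroring the [pipeline_config()] arguments, plus
#' `constraint.require` / `constraint.prohibit` / `constraint.soft`,
#' `augment.categories` / `augment.prefix_map`, and `node2vec.*` entries.
#' Unknown keys are rejected.
#'
#' @param path Path to a YAML configuration file.
#' @return A `pipeline_config` object.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("File not found: ", path), class = "kg_io_error")
  }
  cfg <- yaml::read_yaml(path)
  known <- c("nodes_path", "edges_path", "dialect", "examples", "pinning",
             "resolution", "action", "w", "seed", "out_prefix", "formats",
             "max_paths", "max_results", "fuzzy_threshold", "embeddings",
             "constraint", "augment", "node2vec")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown) > 0) {
    abort(paste0("Unknown configuration key(s): ",
                 paste(unknown, collapse = ", ")),
          class = "kg_validation_error")
  }
  dialect <- switch(cfg$dialect %||% "kgx",
                    kgx = dialect_kgx(),
                    pheknowlator = dialect_pheknowlator(),
                    abort("Config `dialect` must be 'kgx' or 'pheknowlator'; build custom dialects in R.",
                          class = "kg_validation_error"))
  constraint <- NULL
  if (!is.null(cfg$constraint)) {
    constraint <- edge_constraint(
      require = unlist(cfg$constraint$require) %||% character(),
      prohibit = unlist(cfg$constraint$prohibit) %||% character(),
      soft = isTRUE(cfg$constraint$soft))
  }
  augment <- NULL
  if (!is.null(cfg$augment)) {
    augment <- category_filter(unlist(cfg$augment$categories),
                               prefix_map = unlist(cfg$augment$prefix_map))
  }
  n2v <- do.call(node2vec_params, cfg$node2vec %||% list())
  pipeline_config(
    nodes_path = cfg$nodes_path, edges_path = cfg$edges_path,
    dialect = dialect, examples = cfg$examples, pinning = cfg$pinning,
    resolution = cfg$resolution %||% "auto", action = cfg$action %||% "pdp",
    w = cfg$w %||% 0.4, node2vec = n2v, seed = cfg$seed %||% 1L,
    constraint = constraint, augment = augment, embeddings = cfg$embeddings,
    out_prefix = cfg$out_prefix,
    formats = cfg$formats %||% c("graphml", "sif", "node_attributes",
                                 "edge_attributes"),
    max_paths = cfg$max_paths %||% 500L,
    max_results = cfg$max_results %||% 50L,
    fuzzy_threshold = cfg$fuzzy_threshold %||% 85)
}

#' Run the full schematic-extraction pipeline
#'
#' For each concept pair: resolve both labels to nodes, enumerate all tied
#' shortest paths, expand parallel-edge variants, apply the edge-class
#' constraint, rank by the configured action and take the selected path
#' into the union subgraph. Optionally augment with category-filtered
#' neighbors, then write Cytoscape-consumable outputs and a path report.
#' Pairs with no connecting path are reported with a warning, not fatal.
#' With a fixed seed and non-interactive resolution, two runs produce
#' byte-identical outputs.
#'
#' @param config A [pipeline_config()].
#' @return A `kgsketch_result` with components `subgraph`, `ranked` (one
#'   `ranked_paths` per pair), `stats` ([subgraph_stats()]), `resolutions`
#'   (tibble label/node id), and `files` (paths written).
#' @examples
#' kg <- toy_kg_a()
#' cfg <- pipeline_config(kg = kg,
#'                        examples = tibble::tibble(source = "IRS1",
#'                                                  target = "autophagy"),
#'                        action = "pdp", w = 1)
#' run_pipeline(cfg)
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  kg <- config$kg %||% read_kg(config$nodes_path, config$edges_path,
                               config$dialect)
  examples <- config$examples
  if (is.character(examples)) examples <- read_concept_pairs(examples)
  examples <- as_tibble(examples)
  if (nrow(examples) == 0) {
    warn("Example file contains no concept pairs; the subgraph is empty.")
  }

  # --- indexing -------------------------------------------------------------
  labels <- unique(c(examples$source, examples$target))
  resolutions <- purrr::map_chr(setNames(labels, labels), function(lab) {
    pinned <- if (!is.null(config$pinning) && lab %in% names(config$pinning)) {
      config$pinning[[lab]]
    } else NULL
    if (!is.null(pinned)) {
      return(resolve_concept(tibble(), selection = pinned, kg = kg,
                             raw_label = lab))
    }
    if (config$resolution == "pinned") {
      abort(paste0("Resolution mode 'pinned' but no pinned id for label: ", lab),
            class = "kg_unresolved_concept")
    }
    cand <- find_candidates(kg, lab, max_results = config$max_results,
                            fuzzy_threshold = config$fuzzy_threshold)
    resolve_concept(cand, selection = config$resolution, kg = kg,
                    raw_label = lab)
  })

  # --- embeddings (CS only) -------------------------------------------------
  emb <- NULL
  if (config$action == "cs") {
    emb <- config$embeddings
    if (is.character(emb)) emb <- read_embeddings(emb)
    if (is.null(emb)) emb <- train_embeddings(kg, config$node2vec)
  }

  # --- per-pair search + ranking --------------------------------------------
  ranked <- purrr::map(seq_len(nrow(examples)), function(i) {
    src <- resolutions[[examples$source[i]]]
    tgt <- resolutions[[examples$target[i]]]
    pair <- c(source = src, target = tgt)
    paths <- kg_shortest_paths(kg, src, tgt, max_paths = config$max_paths)
    if (length(paths) == 0) {
      warn(sprintf("No path between '%s' (%s) and '%s' (%s); pair skipped.",
                   examples$source[i], src, examples$target[i], tgt))
      return(structure(list(pair = pair, action = config$action,
                            w = config$w, paths = list(), scores = double(),
                            relaxed = FALSE),
                       class = "ranked_paths"))
    }
    variants <- purrr::list_flatten(purrr::map(paths, expand_edge_variants,
                                               kg = kg))
    rp <- rank_paths(variants, action = config$action, kg = kg, w = config$w,
                     embeddings = emb, target = tgt,
                     constraint = config$constraint, pair = pair)
    inform(sprintf("Pair (%s -> %s): %d shortest path(s), selected %s%s.",
                   src, tgt, length(paths), path_string(selected_path(rp)),
                   if (rp$relaxed) " [constraint relaxed]" else ""))
    rp
  })

  # --- assembly + augmentation ---------------------------------------------
  sg <- paths_to_subgraph(kg, ranked, input_ids = unname(resolutions))
  if (!is.null(config$augment)) {
    sg <- augment_neighbors(kg, sg, config$augment)
  }
  stats <- subgraph_stats(sg, ranked)

  files <- character()
  if (!is.null(config$out_prefix)) {
    files <- write_subgraph(sg, config$out_prefix, config$formats)
    report <- paste0(config$out_prefix, "_paths.tsv")
    write_path_report(ranked, report)
    files["path_report"] <- report
  }

  structure(list(subgraph = sg, ranked = ranked, stats = stats,
                 resolutions = tibble(label = names(resolutions),
                                      node_id = unname(resolutions)),
                 files = files),
            class = "kgsketch_result")
}

#' @export
print.kgsketch_result <- function(x, ...) {
  cat("<kgsketch_result>\n")
  print(x$subgraph)
  connected <- sum(vapply(x$ranked, function(r) length(r$paths) > 0, TRUE))
  cat(sprintf("  %d/%d pair(s) connected\n", connected, length(x$ranked)))
  if (length(x$files) > 0) {
    cat(sprintf("  files: %s\n", paste(basename(x$files), collapse = ", ")))
  }
  invisible(x)
}

#' @method glance kgsketch_result
#' @export
glance.kgsketch_result <- function(x, ...) {
  dplyr::bind_cols(
    glance(x$subgraph),
    tibble(n_connected_pairs = sum(vapply(x$ranked, function(r)
      length(r$paths) > 0, TRUE)))
  )
}

#' Network and semantic summaries of an extracted subgraph
#'
#' Computes the per-pair selected path lengths, the node and edge counts,
#' and the edge-class and node-category histograms — the descriptors by
#' which subgraphs produced by different ranking actions are compared
#' (hub-heavy actions inflate `only_in_taxon`-type classes; similarity
#' ranking shifts the ontology mix).
#'
#' @param sg A [kg_subgraph()].
#' @param ranked The list of `ranked_paths` from the same run.
#' @return A `subgraph_stats` object with fields `pairs` (tibble
#'   source/target/path_length), `n_nodes`, `n_edges`, `edge_types` and
#'   `categories` (count tibbles).
#' @export
subgraph_stats <- function(sg, ranked = list()) {
  assert_subgraph(sg)
  pairs <- purrr::map_dfr(ranked, function(rp) {
    sel <- selected_path(rp)
    tibble(source = rp$pair[["source"]], target = rp$pair[["target"]],
           path_length = if (is.null(sel)) NA_integer_ else sel$length)
  })
  if (nrow(pairs) == 0) {
    pairs <- tibble(source = character(), target = character(),
                    path_length = integer())
  }
  edge_types <- dplyr::count(sg$edges, .data$predicate, name = "n")
  categories <- dplyr::count(sg$nodes, .data$category, name = "n")
  structure(list(pairs = pairs, n_nodes = nrow(sg$nodes),
                 n_edges = nrow(sg$edges),
                 edge_types = dplyr::arrange(edge_types, dplyr::desc(.data$n),
                                             .data$predicate),
                 categories = dplyr::arrange(categories, dplyr::desc(.data$n),
                                             .data$category)),
            class = "subgraph_stats")
}

#' @export
print.subgraph_stats <- function(x, ...) {
  cat(sprintf("<subgraph_stats> %d nodes, %d edges, %d pair(s)\n",
              x$n_nodes, x$n_edges, nrow(x$pairs)))
  if (nrow(x$edge_types) > 0) {
    cat("  edge classes:",
        paste(sprintf("%s (%d)", x$edge_types$predicate, x$edge_types$n),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' @method tidy subgraph_stats
#' @export
tidy.subgraph_stats <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(dplyr::rename(x$edge_types, value = "predicate"),
                  property = "edge_type"),
    dplyr::mutate(dplyr::rename(x$categories, value = "category"),
                  property = "category")
  )[, c("property", "value", "n")]
}

#' @method glance subgraph_stats
#' @export
glance.subgraph_stats <- function(x, ...) {
  tibble(n_nodes = x$n_nodes, n_edges = x$n_edges, n_pairs = nrow(x$pairs),
         mean_path_length = mean(x$pairs$path_length, na.rm = TRUE),
         n_edge_types = nrow(x$edge_types),
         n_categories = nrow(x$categories))
}

#' Plot subgraph edge-class and category composition
#'
#' @param object A `subgraph_stats` object.
#' @param ... Unused.
#' @return A ggplot with one facet per property (edge classes, node
#'   categories).
#' @method autoplot subgraph_stats
#' @export
autoplot.subgraph_stats <- function(object, ...) {
  tb <- tidy(object)
  ggplot2::ggplot(tb, ggplot2::aes(x = stats::reorder(.data$value, .data$n),
                                   y = .data$n)) +
    ggplot2::geom_col(fill = "#0072B2") +
    ggplot2::coord_flip() +
    ggplot2::facet_wrap(~ .data$property, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "Count") +
    ggplot2::theme_minimal()
}
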