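#' Describe a TSV dialect for knowledge-graph node and edge files
#'
#' Public KG builds ship as two tab-separated files — node labels and triples —
#' but column layouts differ between projects. A dialect maps the roles the
#' loader needs (`id`, `label`, `category` for nodes; `subject`, `predicate`,
#' `object` for edges) onto column names (files with a header) or 1-based
#' column positions (files without one).
#'
#' Two presets cover the common conventions:
#' * `dialect_pheknowlator()`: headerless files; nodes are `id<TAB>label`,
#'   edges are `subject<TAB>predicate<TAB>object` triples.
#' * `dialect_kgx()`: headered KGX-style files; nodes carry `id`, `category`,
#'   `name`, edges carry `subject`, `predicate`, `object`.
#'
#' @param name Dialect name (free text; presets use `"pheknowlator"`,
#'   `"kgx"`, `"generic"`).
#' @param node_columns Named list/vector mapping roles `id`, `label` and
#'   optionally `category` to column names or positions.
#' @param edge_columns Named list/vector mapping roles `subject`, `predicate`,
#'   `object` to column names or positions.
#' @param has_header Logical: do both files carry a header row? When `FALSE`
#'   the mappings must be integer positions.
#' @return A `kg_dialect` object.
#' @examples
#' dialect_kgx()
#' kg_dialect("mine", list(id = "curie", label = "name"),
#'            list(subject = "s", predicate = "p", object = "o"))
#' @export
kg_dialect <- function(name, node_columns, edge_columns, has_header = TRUE) {
  node_columns <- as.list(node_columns)
  edge_columns <- as.list(edge_columns)
  if (!all(c("id", "label") %in% names(node_columns))) {
    abort("`node_columns` must map at least the `id` and `label` roles.",
          class = "kg_dialect_error")
  }
  if (!all(c("subject", "predicate", "object") %in% names(edge_columns))) {
    abort("`edge_columns` must map `subject`, `predicate` and `object`.",
          class = "kg_dialect_error")
  }
  structure(
    list(name = name, node_columns = node_columns,
         edge_columns = edge_columns, has_header = isTRUE(has_header)),
    class = "kg_dialect"
  )
}

#' @rdname kg_dialect
#' @export
dialect_pheknowlator <- function() {
  kg_dialect("pheknowlator",
             node_columns = list(id = 1L, label = 2L),
             edge_columns = list(subject = 1L, predicate = 2L, object = 3L),
             has_header = FALSE)
}

#' @rdname kg_dialect
#' @export
dialect_kgx <- function() {
  kg_dialect("kgx",
             node_columns = list(id = "id", label = "name", category = "category"),
             edge_columns = list(subject = "subject", predicate = "predicate",
                                 object = "object"),
             has_header = TRUE)
}

#' @export
print.kg_dialect <- function(x, ...) {
  cat(sprintf("<kg_dialect> %s (%s)\n", x$name,
              if (x$has_header) "headered" else "headerless"))
  invisible(x)
}

# Read one TSV with strict field-count checking; returns a character tibble.
read_strict_tsv <- function(path, has_header) {
  if (!file.exists(path)) {
    abort(paste0("File not found: ", path), class = "kg_io_error")
  }
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(tibble())
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  counts <- lengths(fields)
  if (length(unique(counts)) > 1) {
    bad <- which(counts != counts[1])[1]
    abort(sprintf("Malformed row at line %d of %s: expected %d fields, found %d.",
                  bad, path, counts[1], counts[bad]),
          class = "kg_parse_error")
  }
  mat <- do.call(rbind, fields)
  if (has_header) {
    header <- mat[1, ]
    mat <- mat[-1, , drop = FALSE]
    colnames(mat) <- header
  } else {
    colnames(mat) <- paste0("V", seq_len(ncol(mat)))
  }
  as_tibble(mat)
}

pick_column <- function(tab, ref, path, role) {
  if (is.numeric(ref)) {
    if (ref < 1 || ref > ncol(tab)) {
      abort(sprintf("Column position %d for role `%s` out of range in %s.",
                    as.integer(ref), role, path),
            class = "kg_dialect_error")
    }
    return(tab[[as.integer(ref)]])
  }
  if (!ref %in% names(tab)) {
    abort(sprintf("Column `%s` (role `%s`) not found in %s.", ref, role, path),
          class = "kg_dialect_error")
  }
  tab[[ref]]
}

#' Read a knowledge graph from node and edge TSV files
#'
#' Edges that reference ids absent from the node file do not fail the load:
#' a placeholder node with an empty label is created for each such id and a
#' warning reports them, since partial node files are common in the wild.
#'
#' @param nodes_path Path to the node-label TSV.
#' @param edges_path Path to the triple TSV.
#' @param dialect A [kg_dialect()] describing both files (default KGX).
#' @return A [knowledge_graph()].
#' @examples
#' dir <- tempfile(); dir.create(dir)
#' paths <- write_kg(toy_kg_a(), file.path(dir, "toy"), dialect_kgx())
#' read_kg(paths[["nodes"]], paths[["edges"]], dialect_kgx())
#' @export
read_kg <- function(nodes_path, edges_path, dialect = dialect_kgx()) {
  if (!inherits(dialect, "kg_dialect")) abort("`dialect` must be a kg_dialect.")
  ntab <- read_strict_tsv(nodes_path, dialect$has_header)
  etab <- read_strict_tsv(edges_path, dialect$has_header)

  if (nrow(ntab) == 0) {
    nodes <- tibble(id = character(), label = character())
  } else {
    nodes <- tibble(
      id = pick_column(ntab, dialect$node_columns$id, nodes_path, "id"),
      label = pick_column(ntab, dialect$node_columns$label, nodes_path, "label")
    )
    if (!is.null(dialect$node_columns$category)) {
      nodes$category <- pick_column(ntab, dialect$node_columns$category,
                                    nodes_path, "category")
    }
  }
  nodes <- nodes[!duplicated(nodes$id), , drop = FALSE]

  if (nrow(etab) == 0) {
    edges <- tibble(subject = character(), predicate = character(),
                    object = character())
  } else {
    edges <- tibble(
      subject = pick_column(etab, dialect$edge_columns$subject, edges_path, "subject"),
      predicate = pick_column(etab, dialect$edge_columns$predicate, edges_path, "predicate"),
      object = pick_column(etab, dialect$edge_columns$object, edges_path, "object")
    )
  }

  orphan <- setdiff(c(edges$subject, edges$object), nodes$id)
  if (length(orphan) > 0) {
    warn(sprintf("%d edge endpoint id(s) missing from the node file; placeholder nodes created: %s",
                 length(orphan), paste(head(orphan, 5), collapse = ", ")))
    placeholder <- tibble(id = orphan, label = "")
    if ("category" %in% names(nodes)) placeholder$category <- NA_character_
    nodes <- dplyr::bind_rows(nodes, placeholder)
  }
  knowledge_graph(nodes, edges)
}

check_tsv_safe <- function(x, what) {
  if (any(grepl("\t", x, fixed = TRUE))) {
    abort(paste0("Tab character inside a ", what,
                 " field; unquoted TSV cannot represent it."),
          class = "kg_io_error")
  }
  invisible(x)
}

#' Write a knowledge graph as node and edge TSV files
#'
#' Inverse of [read_kg()]; used to materialize fixture graphs and to re-export
#' graphs between dialects. Fields containing tab characters are rejected
#' (unquoted TSV). Output is UTF-8.
#'
#' @param kg A `knowledge_graph`.
#' @param out_prefix Path prefix; files are written as
#'   `<prefix>_nodes.tsv` and `<prefix>_edges.tsv`.
#' @param dialect Target [kg_dialect()].
#' @return Named character vector of the two paths written
#'   (`nodes`, `edges`).
#' @export
write_kg <- function(kg, out_prefix, dialect = dialect_kgx()) {
  assert_kg(kg)
  check_tsv_safe(unlist(kg$nodes), "node")
  check_tsv_safe(unlist(kg$edges), "edge")
  nodes_path <- paste0(out_prefix, "_nodes.tsv")
  edges_path <- paste0(out_prefix, "_edges.tsv")

  roles_to_table <- function(mapping, values) {
    if (dialect$has_header) {
      cols <- lapply(names(mapping), function(role) values[[role]])
      names(cols) <- vapply(mapping, as.character, "")
      as_tibble(cols)
    } else {
      pos <- vapply(mapping, as.integer, 0L)
      cols <- vector("list", max(pos))
      for (role in names(mapping)) cols[[pos[[role]]]] <- values[[role]]
      cols <- lapply(cols, function(x) x %||% rep("", length(values[[1]])))
      names(cols) <- paste0("V", seq_along(cols))
      as_tibble(cols)
    }
  }

  nvals <- list(id = kg$nodes$id, label = kg$nodes$label,
                category = kg$nodes$category)
  nmap <- dialect$node_columns
  ntab <- roles_to_table(nmap, nvals)
  evals <- list(subject = kg$edges$subject, predicate = kg$edges$predicate,
                object = kg$edges$object)
  etab <- roles_to_table(dialect$edge_columns, evals)

  readr::write_tsv(ntab, nodes_path, col_names = dialect$has_header,
                   escape = "none", na = "")
  readr::write_tsv(etab, edges_path, col_names = dialect$has_header,
                   escape = "none", na = "")
  c(nodes = nodes_path, edges = edges_path)
}

subgraph_to_igraph <- function(sg) {
  igraph::graph_from_data_frame(
    d = data.frame(from = sg$edges$subject, to = sg$edges$object,
                   predicate = sg$edges$predicate,
                   provenance = sg$edges$provenance,
                   stringsAsFactors = FALSE),
    directed = TRUE,
    vertices = data.frame(name = sg$nodes$id, label = sg$nodes$label,
                          category = sg$nodes$category,
                          provenance = sg$nodes$provenance,
                          stringsAsFactors = FALSE)
  )
}

#' Write an extracted subgraph in Cytoscape-consumable formats
#'
#' @param sg A [kg_subgraph()].
#' @param out_prefix Path prefix for the output files.
#' @param formats Subset of `"graphml"`, `"sif"`, `"node_attributes"`,
#'   `"edge_attributes"`. SIF rows are `subject<TAB>predicate<TAB>object`;
#'   SIF cannot express isolated nodes, which are emitted only to GraphML and
#'   the node-attribute table (with a warning).
#' @return Named character vector of file paths written.
#' @export
write_subgraph <- function(sg, out_prefix,
                           formats = c("graphml", "sif", "node_attributes",
                                       "edge_attributes")) {
  assert_subgraph(sg)
  formats <- match.arg(formats, several.ok = TRUE)
  written <- character()

  if ("sif" %in% formats) {
    linked <- unique(c(sg$edges$subject, sg$edges$object))
    isolated <- setdiff(sg$nodes$id, linked)
    if (length(isolated) > 0) {
      warn(sprintf("SIF cannot express %d isolated node(s); emitted only to GraphML/attribute outputs.",
                   length(isolated)))
    }
    path <- paste0(out_prefix, ".sif")
    readr::write_tsv(sg$edges[, c("subject", "predicate", "object")], path,
                     col_names = FALSE, escape = "none")
    written["sif"] <- path
  }
  if ("graphml" %in% formats) {
    path <- paste0(out_prefix, ".graphml")
    igraph::write_graph(subgraph_to_igraph(sg), path, format = "graphml")
    written["graphml"] <- path
  }
  if ("node_attributes" %in% formats) {
    path <- paste0(out_prefix, "_nodes.tsv")
    readr::write_tsv(sg$nodes, path, escape = "none")
    written["node_attributes"] <- path
  }
  if ("edge_attributes" %in% formats) {
    path <- paste0(out_prefix, "_edges.tsv")
    readr::write_tsv(sg$edges, path, escape = "none")
    written["edge_attributes"] <- path
  }
  written
}

#' Read a GraphML subgraph export back into a `kg_subgraph`
#'
#' @param path A GraphML file produced by [write_subgraph()].
#' @return A [kg_subgraph()].
#' @export
read_subgraph_graphml <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("File not found: ", path), class = "kg_io_error")
  }
  g <- igraph::read_graph(path, format = "graphml")
  vdf <- igraph::as_data_frame(g, what = "vertices")
  edf <- igraph::as_data_frame(g, what = "edges")
  kg_subgraph(
    nodes = tibble(id = vdf$name, label = vdf$label, category = vdf$category,
                   provenance = vdf$provenance),
    edges = tibble(subject = edf$from, predicate = edf$predicate,
                   object = edf$to,
                   provenance = edf$provenance %||% rep("path", nrow(edf)))
  )
}

#' Write a per-pair path report
#'
#' One row per (pair, path): source and target ids, the path as a
#' `->`-joined node sequence, its length, the action score, the rank and a
#' `selected` flag. Pairs with no path between them appear as a single row
#' with `path = "NONE"` and an empty rank, so disconnected pairs stay visible
#' in the report instead of silently vanishing.
#'
#' @param ranked A list of [rank_paths()] results.
#' @param out_path Output TSV path.
#' @return `out_path`, invisibly.
#' @export
write_path_report <- function(ranked, out_path) {
  rows <- purrr::map_dfr(ranked, function(rp) {
    if (length(rp$paths) == 0) {
      return(tibble(source = rp$pair[["source"]], target = rp$pair[["target"]],
                    path = "NONE", length = NA_integer_, action = rp$action,
                    score = NA_real_, rank = NA_integer_, selected = FALSE,
                    constraint_relaxed = rp$relaxed))
    }
    tb <- tidy(rp)
    tibble(source = rp$pair[["source"]], target = rp$pair[["target"]],
           path = tb$path, length = tb$length, action = rp$action,
           score = tb$score, rank = tb$rank, selected = tb$selected,
           constraint_relaxed = rp$relaxed)
  })
  if (nrow(rows) == 0) {
    rows <- tibble(source = character(), target = character(),
                   path = character(), length = integer(), action = character(),
                   score = double(), rank = integer(), selected = logical(),
                   constraint_relaxed = logical())
  }
  readr::write_tsv(rows, out_path, escape = "none")
  invisible(out_path)
}
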