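#' The toy insulin-signaling knowledge graph
#'
#' A fixed 8-node, 9-edge miniature of an insulin-signaling neighborhood,
#' small enough to verify every operation by hand yet exhibiting the
#' pathologies the semantic actions exist for: a high-degree taxon hub
#' (`n5`, "Homo sapiens") reachable via uninformative `only_in_taxon`
#' edges, a drug node (`n7`) for augmentation, ambiguous-looking labels for
#' indexing, and an isolated node (`n8`).
#'
#' @return A `knowledge_graph` with 8 nodes and 9 edges.
#' @examples
#' toy_kg_a()
#' @export
toy_kg_a <- function() {
  nodes <- tibble(
    id = paste0("n", 1:8),
    label = c("IRS1", "AKT serine/threonine kinase 1 (human)",
              "mTOR (human)", "autophagy", "Homo sapiens",
              "insulin receptor substrate 1 (human)", "drug-X", "orphan"),
    category = c("gene", "protein", "protein", "biological_process",
                 "taxon", "protein", "drug", "class")
  )
  edges <- tibble(
    subject = c("n1", "n2", "n3", "n1", "n2", "n3", "n6", "n7", "n6"),
    predicate = c("interacts_with", "interacts_with", "participates_in",
                  "only_in_taxon", "only_in_taxon", "only_in_taxon",
                  "only_in_taxon", "targets", "has_gene_template"),
    object = c("n2", "n3", "n4", "n5", "n5", "n5", "n5", "n3", "n1")
  )
  knowledge_graph(nodes, edges)
}

#' Specification for a random fixture knowledge graph
#'
#' Describes a seeded pseudo-random multigraph shaped like a miniature
#' biomedical KG: a designated fraction of nodes act as taxon-like hubs
#' with elevated attachment probability (so hub-avoidance ranking is
#' exercised non-trivially), edges touching a hub are predominantly
#' `only_in_taxon`, and node ids are CURIEs whose prefix encodes the
#' category (so category resolution works through either an explicit
#' column or the prefix default).
#'
#' @param n_nodes Number of nodes (>= 1).
#' @param n_edges Number of edges (>= 0); parallel edges and self-loops are
#'   allowed, so any count is feasible when `n_nodes >= 1`.
#' @param predicates Named numeric vector of predicate sampling weights for
#'   non-hub edges.
#' @param hub_fraction Fraction of nodes wired as hubs (default 0.1).
#' @param seed Integer seed.
#' @return A `fixture_spec` object.
#' @export
fixture_spec <- function(n_nodes, n_edges,
                         predicates = c(interacts_with = 0.5,
                                        participates_in = 0.25,
                                        targets = 0.15,
                                        has_gene_template = 0.1),
                         hub_fraction = 0.1, seed = 1L) {
  if (n_nodes < 1) abort("`n_nodes` must be >= 1.", class = "kg_validation_error")
  if (n_edges < 0) abort("`n_edges` must be >= 0.", class = "kg_validation_error")
  if (n_edges > 0 && n_nodes < 1) {
    abort("Cannot place edges in an empty graph.", class = "kg_validation_error")
  }
  if (hub_fraction < 0 || hub_fraction > 1) {
    abort("`hub_fraction` must be in [0, 1].", class = "kg_validation_error")
  }
  if (is.null(names(predicates)) || any(predicates < 0) || sum(predicates) <= 0) {
    abort("`predicates` must be a named non-negative weight vector.",
          class = "kg_validation_error")
  }
  structure(list(n_nodes = as.integer(n_nodes), n_edges = as.integer(n_edges),
                 predicates = predicates, hub_fraction = hub_fraction,
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

#' Generate a random fixture knowledge graph
#'
#' Deterministic for a fixed [fixture_spec()] (seed included): the same spec
#' always yields the identical graph. Non-hub node categories cycle over
#' gene / protein / process / drug; ids look like `"prot:0004"` so the CURIE
#' prefix doubles as the category.
#'
#' @param spec A [fixture_spec()].
#' @return A `knowledge_graph` with exactly the requested node and edge
#'   counts.
#' @examples
#' random_kg(fixture_spec(12, 25, seed = 1))
#' @export
random_kg <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  n <- spec$n_nodes
  m <- spec$n_edges
  n_hubs <- min(n, ceiling(spec$hub_fraction * n))
  base_cats <- c("gene", "prot", "proc", "drug")

  withr::with_seed(spec$seed, {
    cats <- c(rep("taxon", n_hubs),
              base_cats[((seq_len(n - n_hubs) - 1L) %% length(base_cats)) + 1L])
    ids <- sprintf("%s:%04d", cats, seq_len(n))
    labels <- sprintf("%s %d", toupper(cats), seq_len(n))
    nodes <- tibble(id = ids, label = labels)  # category from prefix

    if (m > 0) {
      weight <- rep(1, n)
      if (n_hubs > 0) weight[seq_len(n_hubs)] <- 10
      subj <- ids[sample.int(n, m, replace = TRUE, prob = weight)]
      obj <- ids[sample.int(n, m, replace = TRUE, prob = weight)]
      hub_ids <- ids[seq_len(n_hubs)]
      touches_hub <- subj %in% hub_ids | obj %in% hub_ids
      pred <- sample(names(spec$predicates), m, replace = TRUE,
                     prob = spec$predicates)
      pred[touches_hub & stats::runif(m) < 0.8] <- "only_in_taxon"
      edges <- tibble(subject = subj, predicate = pred, object = obj)
    } else {
      edges <- NULL
    }
  })
  knowledge_graph(nodes, edges)
}
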