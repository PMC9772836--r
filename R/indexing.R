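#' Find candidate knowledge-graph nodes for a free-text concept label
#'
#' Concept labels lifted from a figure rarely match KG node labels exactly,
#' and one label can hit many nodes (genes, variants, transcripts and GO
#' terms often share name fragments). Matching runs in two stages:
#'
#' 1. *Substring stage*: every node whose label contains the query as a
#'    case-insensitive substring is a candidate, scored
#'    `100 * nchar(query) / nchar(label)` — an exact (case-insensitive)
#'    label match scores 100, and shorter labels outrank longer ones.
#' 2. *Fuzzy fallback*: only when the substring stage finds nothing, labels
#'    are scored by a partial-ratio style measure
#'    (`100 * (1 - d / nchar(query))`, where `d` is the generalized
#'    Levenshtein distance of the query to the best-matching substring of
#'    the label), and candidates at or above `fuzzy_threshold` are kept.
#'    This recovers near-miss queries such as "oxidative stress" against
#'    "response to oxidative stress".
#'
#' Candidates are ordered by descending score, ties broken lexicographically
#' by node id, and truncated to `max_results`.
#'
#' @param kg A non-empty `knowledge_graph`.
#' @param query Concept label (non-empty string).
#' @param max_results Maximum candidates returned (default 50).
#' @param fuzzy_threshold Minimum fuzzy score, 0–100 (default 85).
#' @return A tibble with columns `node_id`, `label`, `score`.
#' @examples
#' find_candidates(toy_kg_a(), "mtor")
#' @export
find_candidates <- function(kg, query, max_results = 50L,
                            fuzzy_threshold = 85) {
  assert_kg(kg)
  if (nrow(kg$nodes) == 0) abort("The knowledge graph has no nodes.")
  if (!is.character(query) || length(query) != 1 || !nzchar(query)) {
    abort("`query` must be a non-empty string.", class = "kg_validation_error")
  }
  if (max_results < 1) abort("`max_results` must be positive.")

  labels <- kg$nodes$label
  lq <- tolower(query)
  ll <- tolower(labels)
  hit <- grepl(lq, ll, fixed = TRUE)

  if (any(hit)) {
    score <- 100 * nchar(query) / nchar(labels[hit])
    out <- tibble(node_id = kg$nodes$id[hit], label = labels[hit],
                  score = pmin(score, 100))
  } else {
    nonempty <- nzchar(labels)
    d <- rep(Inf, length(labels))
    d[nonempty] <- as.vector(adist(lq, ll[nonempty], partial = TRUE))
    score <- 100 * (1 - d / nchar(query))
    keep <- is.finite(score) & score >= fuzzy_threshold
    out <- tibble(node_id = kg$nodes$id[keep], label = labels[keep],
                  score = pmax(pmin(score[keep], 100), 0))
  }
  out <- out[order(-out$score, out$node_id), , drop = FALSE]
  head(out, max_results)
}

#' Resolve a concept to one knowledge-graph node
#'
#' The indexing step ends with a single node standing for each input
#' concept. Three resolution modes:
#'
#' * a pinned node id (`selection = "<node id>"`) bypasses the candidate
#'   list entirely but must exist in `kg`;
#' * `"auto"` takes the top-ranked candidate and reports the choice;
#' * `"interactive"` prompts with the ranked list (interactive sessions
#'   only).
#'
#' @param candidates A candidate tibble from [find_candidates()] (may be
#'   empty when a pinned id is supplied).
#' @param selection `"auto"`, `"interactive"`, or a node id to pin.
#' @param kg The `knowledge_graph` (needed to validate a pinned id).
#' @param raw_label The original concept label, used in messages.
#' @return A single node id.
#' @export
resolve_concept <- function(candidates, selection = "auto", kg = NULL,
                            raw_label = NULL) {
  lab <- raw_label %||% "<unknown concept>"
  if (!selection %in% c("auto", "interactive")) {
    if (!is.null(kg)) assert_node(kg, selection)
    return(selection)
  }
  if (nrow(candidates) == 0) {
    abort(paste0("Concept could not be resolved (no candidates): ", lab),
          class = "kg_unresolved_concept")
  }
  if (selection == "interactive") {
    if (!interactive()) {
      abort("Interactive resolution requires an interactive session; use `auto` or pin a node id.",
            class = "kg_validation_error")
    }
    cat(sprintf("Candidates for '%s':\n", lab))
    for (i in seq_len(nrow(candidates))) {
      cat(sprintf("  [%d] %s  %s  (score %.1f)\n", i, candidates$node_id[i],
                  candidates$label[i], candidates$score[i]))
    }
    pick <- as.integer(readline("Select a candidate number: "))
    if (is.na(pick) || pick < 1 || pick > nrow(candidates)) {
      abort("Invalid selection.", class = "kg_validation_error")
    }
    return(candidates$node_id[pick])
  }
  choice <- candidates$node_id[1]
  inform(sprintf("Resolved '%s' -> %s (%s), score %.1f, from %d candidate(s).",
                 lab, choice, candidates$label[1], candidates$score[1],
                 nrow(candidates)))
  choice
}

#' Read a concept-pair example file
#'
#' The example file lists the desired connections of the schematic: one row
#' per pair, columns `source` and `target` holding free-text concept labels.
#' Both TSV and CSV are accepted (sniffed from the header line).
#'
#' @param path Path to the example file.
#' @return A tibble with columns `source`, `target`.
#' @export
read_concept_pairs <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("File not found: ", path), class = "kg_io_error")
  }
  first <- readr::read_lines(path, n_max = 1)
  delim <- if (length(first) == 1 && grepl("\t", first)) "\t" else ","
  tab <- readr::read_delim(path, delim = delim, col_types = readr::cols(
    .default = readr::col_character()), progress = FALSE)
  if (!all(c("source", "target") %in% names(tab))) {
    abort("Example file must have columns `source` and `target`.",
          class = "kg_parse_error")
  }
  as_tibble(tab[, c("source", "target")])
}

#' Read a pinning file mapping concept labels to node ids
#'
#' A two-column TSV/CSV (`label`, `node_id`) fixing the resolution of
#' specific concepts ahead of time, which makes batch runs reproducible.
#'
#' @param path Path to the pinning file.
#' @return A named character vector: label -> node id.
#' @export
read_pinning <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("File not found: ", path), class = "kg_io_error")
  }
  first <- readr::read_lines(path, n_max = 1)
  delim <- if (length(first) == 1 && grepl("\t", first)) "\t" else ","
  tab <- readr::read_delim(path, delim = delim, col_types = readr::cols(
    .default = readr::col_character()), progress = FALSE)
  if (!all(c("label", "node_id") %in% names(tab))) {
    abort("Pinning file must have columns `label` and `node_id`.",
          class = "kg_parse_error")
  }
  setNames(tab$node_id, tab$label)
}
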