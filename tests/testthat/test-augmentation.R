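toy_n2n3_subgraph <- function(kg = toy_kg_a()) {
  rp <- rank_paths(kg_shortest_paths(kg, "n2", "n3"), "pdp", kg = kg)
  paths_to_subgraph(kg, list(rp), input_ids = c("n2", "n3"))
}

test_that("drug-filtered augmentation of the toy subgraph adds n7 and one edge", {
  kg <- toy_kg_a()
  sg <- toy_n2n3_subgraph(kg)
  aug <- augment_neighbors(kg, sg, category_filter("drug"))
  expect_identical(nrow(aug$nodes), nrow(sg$nodes) + 1L)
  expect_identical(nrow(aug$edges), nrow(sg$edges) + 1L)
  expect_identical(aug$nodes$id[aug$nodes$provenance == "augmented"], "n7")
  added <- aug$edges[aug$edges$provenance == "augmented", ]
  expect_identical(paste(added$subject, added$predicate, added$object),
                   "n7 targets n3")
  # original content untouched
  expect_identical(aug$nodes[aug$nodes$provenance != "augmented", ], sg$nodes)
  expect_identical(aug$edges[aug$edges$provenance != "augmented", ], sg$edges)
})

test_that("augmentation with a category matching no neighbor is the identity", {
  kg <- toy_kg_a()
  sg <- toy_n2n3_subgraph(kg)
  expect_identical(augment_neighbors(kg, sg, category_filter("disease")), sg)
})

test_that("augmentation is idempotent", {
  kg <- toy_kg_a()
  sg <- toy_n2n3_subgraph(kg)
  once <- augment_neighbors(kg, sg, category_filter("drug"))
  twice <- augment_neighbors(kg, once, category_filter("drug"))
  expect_identical(twice, once)
})

test_that("unknown subgraph nodes raise a missing-node error", {
  kg <- toy_kg_a()
  sg <- kg_subgraph(tibble::tibble(id = "ghost", label = "", category = "",
                                   provenance = "input"),
                    tibble::tibble(subject = character(),
                                   predicate = character(),
                                   object = character(),
                                   provenance = character()))
  expect_error(augment_neighbors(kg, sg, category_filter("drug")),
               class = "kg_missing_node")
})

test_that("prefix maps translate CURIE prefixes into filter categories", {
  nodes <- tibble::tibble(
    id = c("PR:1", "DrugCentral:7", "PharmGKB:9"),
    label = c("protein", "infliximab-like", "prednisolone-like"))
  edges <- tibble::tibble(subject = c("DrugCentral:7", "PharmGKB:9"),
                          predicate = "targets", object = "PR:1")
  kg <- knowledge_graph(nodes, edges)
  sg <- kg_subgraph(tibble::tibble(id = "PR:1", label = "protein",
                                   category = "PR", provenance = "input"),
                    edges[0, ])
  aug <- augment_neighbors(kg, sg, category_filter(
    "drug", prefix_map = c(DrugCentral = "drug", PharmGKB = "drug")))
  expect_setequal(aug$nodes$id[aug$nodes$provenance == "augmented"],
                  c("DrugCentral:7", "PharmGKB:9"))
  expect_identical(nrow(aug$edges), 2L)
})

test_that("augmentation matches brute force on 50 random fixtures", {
  for (seed in 1:50) {
    kg <- small_random_kg(seed, n = 14, m = 28)
    ids <- kg_nodes(kg)$id
    withr::with_seed(seed + 2000, seeds <- sample(ids, 3))
    sg <- kg_subgraph(
      dplyr::mutate(kg_nodes(kg)[match(seeds, ids), ], provenance = "input"),
      tibble::tibble(subject = character(), predicate = character(),
                     object = character(), provenance = character()))
    aug <- augment_neighbors(kg, sg, category_filter("drug"))
    want <- oracle_augment(kg, seeds, "drug")

    added_nodes <- sort(aug$nodes$id[aug$nodes$provenance == "augmented"])
    expect_identical(added_nodes, want$nodes)
    added_edges <- aug$edges[aug$edges$provenance == "augmented", 1:3]
    expect_setequal(paste(added_edges$subject, added_edges$predicate,
                          added_edges$object),
                    paste(want$edges$subject, want$edges$predicate,
                          want$edges$object))

    # every added node is distance 1 from a seed and category-matched
    cats <- node_categories(kg)
    for (u in added_nodes) {
      expect_identical(unname(cats[u]), "drug")
      expect_true(any(kg_neighbors(kg, u)$neighbor %in% seeds) ||
                    any(seeds %in% kg_neighbors(kg, u)$neighbor))
    }
    # a neighbor may attach via multiple edges, never fewer than one each
    expect_gte(nrow(added_edges), length(added_nodes))
  }
})
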